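#' Group comparison with diagnostic-driven test dispatch
#'
#' Reproduces the statistics-dispatch convention used throughout the
#' analyses: Shapiro-Wilk per group (alpha = 0.05) gates the parametric
#' branch and Levene's test decides the post hoc. Two unpaired groups use a
#' two-sample t test when all groups are normal (classic when Levene passes,
#' Welch otherwise), else the Mann-Whitney rank-sum test. Two paired groups
#' use the paired t test when normal, else the Wilcoxon signed-rank test.
#' More than two normal groups use one-way ANOVA with Bonferroni's post hoc
#' under equal variances or Games-Howell under unequal variances; non-normal
#' multi-group data use Kruskal-Wallis. A named `policy` runs the requested
#' test instead and records the choice.
#'
#' @param groups Named list of numeric vectors (>= 2 groups; each n >= 3
#'   for the `"auto"` policy), or a data frame with columns `value` and
#'   `group`.
#' @param paired Logical; paired groups must have equal lengths.
#' @param policy `"auto"` or a test name: `"t"`, `"wilcox"`, `"anova"`,
#'   `"kruskal"`.
#' @param alpha Significance level of the normality/variance gates (0.05).
#' @return A `spq_group_compare` object with fields `test_name`,
#'   `statistic`, `p_value`, `diagnostics` (per-group Shapiro p, Levene p),
#'   `summaries` (n, mean, sem, median, IQR per group) and `posthoc`
#'   (pairwise tibble, multi-group parametric branch only).
#' @export
group_compare <- function(groups, paired = FALSE, policy = "auto",
                          alpha = 0.05) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("value", "group") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) == 0)) stop("empty group")
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_len(k))
  }
  if (paired) {
    if (k != 2) stop("paired comparison requires exactly 2 groups")
    if (length(groups[[1]]) != length(groups[[2]])) {
      stop("paired groups must have equal length")
    }
  }
  ns <- vapply(groups, length, integer(1))
  if (identical(policy, "auto") && any(ns < 3)) {
    stop("auto policy requires each group n >= 3")
  }
  summaries <- dplyr::bind_rows(lapply(names(groups), function(g) {
    v <- groups[[g]]
    tibble::tibble(group = g, n = length(v), mean = mean(v),
                   sem = stats::sd(v) / sqrt(length(v)),
                   median = stats::median(v), iqr = stats::IQR(v))
  }))
  shapiro_p <- vapply(groups, function(v) {
    if (length(unique(v)) < 3 || length(v) < 3) return(0)  # treat as non-normal
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  all_normal <- all(shapiro_p > alpha)
  vals <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups), ns))
  levene_p <- tryCatch(
    car::leveneTest(vals ~ grp, center = "mean")[1, "Pr(>F)"],
    error = function(e) NA_real_)
  equal_var <- !is.na(levene_p) && levene_p > alpha

  posthoc <- NULL
  if (identical(policy, "auto")) {
    if (k == 2 && !paired) {
      if (all_normal) {
        ht <- stats::t.test(groups[[1]], groups[[2]], var.equal = equal_var)
        test_name <- if (equal_var) "two-sample t" else "Welch t"
      } else {
        ht <- stats::wilcox.test(groups[[1]], groups[[2]], exact = FALSE)
        test_name <- "Mann-Whitney U"
      }
    } else if (k == 2 && paired) {
      if (all_normal) {
        ht <- stats::t.test(groups[[1]], groups[[2]], paired = TRUE)
        test_name <- "paired t"
      } else {
        ht <- stats::wilcox.test(groups[[1]], groups[[2]], paired = TRUE,
                                 exact = FALSE)
        test_name <- "Wilcoxon signed-rank"
      }
    } else {
      if (all_normal) {
        fit <- stats::aov(vals ~ grp)
        sm <- summary(fit)[[1]]
        ht <- list(statistic = sm[1, "F value"], p.value = sm[1, "Pr(>F)"])
        if (equal_var) {
          test_name <- "one-way ANOVA + Bonferroni"
          pw <- stats::pairwise.t.test(vals, grp,
                                       p.adjust.method = "bonferroni")
          posthoc <- pairwise_tibble(pw$p.value)
        } else {
          test_name <- "one-way ANOVA + Games-Howell"
          posthoc <- games_howell(groups)
        }
      } else {
        ht <- stats::kruskal.test(vals, grp)
        test_name <- "Kruskal-Wallis"
      }
    }
  } else {
    ht <- switch(
      policy,
      t = stats::t.test(groups[[1]], groups[[2]], paired = paired),
      wilcox = stats::wilcox.test(groups[[1]], groups[[2]], paired = paired,
                                  exact = FALSE),
      anova = {
        fit <- stats::aov(vals ~ grp)
        sm <- summary(fit)[[1]]
        list(statistic = sm[1, "F value"], p.value = sm[1, "Pr(>F)"])
      },
      kruskal = stats::kruskal.test(vals, grp),
      stop("unknown policy: ", policy))
    test_name <- paste0(policy, " (requested)")
  }
  structure(
    list(test_name = test_name,
         statistic = unname(if (is.list(ht)) ht$statistic else ht$statistic),
         p_value = unname(ht$p.value),
         diagnostics = tibble::tibble(group = names(groups),
                                      shapiro_p = unname(shapiro_p),
                                      levene_p = levene_p,
                                      alpha = alpha),
         summaries = summaries,
         posthoc = posthoc,
         policy = policy, paired = paired),
    class = "spq_group_compare")
}

pairwise_tibble <- function(pmat) {
  idx <- which(!is.na(pmat), arr.ind = TRUE)
  tibble::tibble(group1 = rownames(pmat)[idx[, 1]],
                 group2 = colnames(pmat)[idx[, 2]],
                 p_adj = pmat[idx])
}

# Games-Howell pairwise comparisons: Welch-type t with studentized-range
# reference distribution; used when variances are unequal
games_howell <- function(groups) {
  k <- length(groups)
  nm <- names(groups)
  means <- vapply(groups, mean, numeric(1))
  vars <- vapply(groups, stats::var, numeric(1))
  ns <- vapply(groups, length, numeric(1))
  out <- list()
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    se2 <- vars[i] / ns[i] + vars[j] / ns[j]
    t_ <- (means[i] - means[j]) / sqrt(se2)
    df <- se2^2 / ((vars[i] / ns[i])^2 / (ns[i] - 1) +
                     (vars[j] / ns[j])^2 / (ns[j] - 1))
    p <- stats::ptukey(abs(t_) * sqrt(2), k, df, lower.tail = FALSE)
    out[[length(out) + 1]] <- tibble::tibble(
      group1 = nm[i], group2 = nm[j],
      estimate = unname(means[i] - means[j]),
      statistic = unname(t_), df = unname(df), p_adj = unname(p))
  }
  dplyr::bind_rows(out)
}

#' @export
print.spq_group_compare <- function(x, ...) {
  cat(sprintf("<spq_group_compare> %s: statistic %.4g, p = %.4g\n",
              x$test_name, x$statistic, x$p_value))
  invisible(x)
}

#' @export
tidy.spq_group_compare <- function(x, ...) {
  tibble::tibble(test_name = x$test_name, statistic = x$statistic,
                 p_value = x$p_value)
}

#' @export
glance.spq_group_compare <- function(x, ...) {
  tibble::tibble(test_name = x$test_name, statistic = x$statistic,
                 p_value = x$p_value,
                 n_groups = nrow(x$summaries),
                 all_normal = all(x$diagnostics$shapiro_p >
                                    x$diagnostics$alpha[1]),
                 levene_p = x$diagnostics$levene_p[1])
}
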