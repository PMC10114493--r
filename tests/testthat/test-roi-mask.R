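horizontal_skeleton <- function(nr = 400, nc = 400, row = 200,
                                pixel_size_um = 0.0526) {
  m <- matrix(0, nr, nc)
  m[row, ] <- 1
  skeleton_image(m, pixel_size_um = pixel_size_um)
}

test_that("growing a straight skeleton by 95 px gives a 191-px band", {
  sk <- horizontal_skeleton()
  mask <- grow_skeleton(sk, 95L)
  # vertical extent at a column far from the ends
  expect_equal(sum(mask$pixels[, 200]), 191)
  expect_equal(sum(mask$pixels[, 50]), 191)
  expect_equal(mask$grow_radius_px, 95L)
})

test_that("growth radius 0 reproduces the skeleton; small disks enumerate", {
  sk <- horizontal_skeleton(21, 21, 11)
  expect_equal(grow_skeleton(sk, 0L)$pixels, sk$pixels)

  m <- matrix(0, 21, 21); m[11, 11] <- 1
  single <- skeleton_image(m)
  mask <- grow_skeleton(single, 2L)
  # brute-force enumeration of integer offsets with sqrt(dx^2+dy^2) <= 2
  cnt <- 0L
  for (dy in -2:2) for (dx in -2:2) if (sqrt(dx^2 + dy^2) <= 2) cnt <- cnt + 1L
  expect_equal(sum(mask$pixels), cnt)
  expect_equal(cnt, 13L)
})

test_that("skeleton growth is monotone in radius and commutes with shifts", {
  m <- matrix(0, 41, 41)
  m[cbind(10:25, 10:25)] <- 1  # diagonal stroke
  sk <- skeleton_image(m)
  m1 <- grow_skeleton(sk, 3L)$pixels
  m2 <- grow_skeleton(sk, 7L)$pixels
  expect_true(all(m2[m1 == 1] == 1))

  shift <- matrix(0, 41, 41)
  shift[cbind(10:25 + 5, 10:25 + 3)] <- 1
  ms <- grow_skeleton(skeleton_image(shift), 3L)$pixels
  expect_equal(ms[(1 + 5):41, (1 + 3):41], m1[1:(41 - 5), 1:(41 - 3)])
})

test_that("square-element growth contains the disk and is available", {
  sk <- horizontal_skeleton(41, 41, 21)
  dsk <- grow_skeleton(sk, 5L, shape = "disk")$pixels
  sq <- grow_skeleton(sk, 5L, shape = "square")$pixels
  expect_true(all(sq[dsk == 1] == 1))
  expect_equal(sum(sq[, 21]), 11)
})

test_that("skeleton length follows the step-sum convention", {
  m <- matrix(0, 12, 12); m[6, 2:11] <- 1
  expect_equal(skeleton_length_um(skeleton_image(m, 0.0526)), 9 * 0.0526)

  d <- matrix(0, 5, 5); d[cbind(1:3, 1:3)] <- 1
  expect_equal(skeleton_length_um(skeleton_image(d, 1)), 2 * sqrt(2))

  s <- matrix(0, 3, 3); s[2, 2] <- 1
  expect_equal(skeleton_length_um(skeleton_image(s, 1)), 0)

  # corner is measured through orthogonal steps, not a diagonal shortcut
  l <- matrix(0, 4, 4); l[2, 2] <- 1; l[2, 3] <- 1; l[3, 3] <- 1
  expect_equal(skeleton_length_um(skeleton_image(l, 1)), 2)
})

test_that("skeleton length is invariant to rotation and reflection", {
  set.seed(5)
  m <- matrix(0, 30, 30)
  # random monotone staircase path
  y <- 15; x <- 3; m[y, x] <- 1
  for (i in 1:20) {
    step <- sample(list(c(0, 1), c(1, 1), c(-1, 1)), 1)[[1]]
    y <- y + step[1]; x <- x + step[2]
    m[y, x] <- 1
  }
  len <- skeleton_length_um(skeleton_image(m, 1))
  rot <- t(m)[, nrow(m):1]                # 90 degrees
  refl <- m[, ncol(m):1]                  # mirror
  expect_equal(skeleton_length_um(skeleton_image(rot, 1)), len)
  expect_equal(skeleton_length_um(skeleton_image(refl, 1)), len)
})

test_that("thick strokes warn and are thinned before analysis", {
  m <- matrix(0, 10, 10); m[4:6, 2:9] <- 1
  expect_warning(sk <- skeleton_image(m), "thinning")
  expect_true(sum(sk$pixels) < sum(m))
  # thinned stroke is one pixel wide
  p <- sk$pixels
  expect_true(all(colSums(p[, 3:8]) <= 2))
})

test_that("apply_mask zeroes outside and preserves inside", {
  set.seed(9)
  img <- make_proj(matrix(runif(100), 10, 10))
  expect_equal(apply_mask(img, full_mask(10, 10))$pixels, img$pixels)
  empty <- roi_mask(matrix(0, 10, 10))
  expect_true(all(apply_mask(img, empty)$pixels == 0))

  half <- matrix(0, 10, 10); half[, 1:5] <- 1
  const <- make_proj(matrix(0.7, 10, 10))
  out <- apply_mask(const, roi_mask(half))
  expect_equal(sum(out$pixels > 0), sum(half))
  expect_error(apply_mask(img, roi_mask(matrix(1, 4, 4))), "shapes")
})
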