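test_that("8-bit conversion is a linear min-max rescale with round-half-up", {
  st <- array(c(0, 255, 510, 100), c(2, 2, 1))
  out <- to_8bit(st)
  expect_equal(out[1, 1, 1], 0)
  expect_equal(out[2, 1, 1], 128)   # 255/510*255 = 127.5 rounds up
  expect_equal(out[1, 2, 1], 255)
  expect_true(all(to_8bit(array(0, c(4, 4, 2))) == 0))
  expect_true(all(to_8bit(array(7, c(4, 4, 2))) == 0))  # constant stack
})

test_that("8-bit conversion is idempotent", {
  set.seed(1)
  st <- array(runif(4 * 4 * 3, 0, 255), c(4, 4, 3))
  once <- to_8bit(st)
  expect_identical(to_8bit(once), once)
})

test_that("Gaussian filter conserves intensity and fixes constants", {
  delta <- matrix(0, 21, 21); delta[11, 11] <- 5
  f <- gaussian_filter(delta, 3)
  expect_equal(sum(f), 5, tolerance = 1e-6)
  expect_equal(which(f == max(f)), 11 + 10 * 21)
  const <- matrix(3.7, 15, 15)
  expect_equal(gaussian_filter(const, 3), const, tolerance = 1e-9)
})

test_that("Gaussian filter matches a brute-force convolution oracle", {
  img <- matrix(0, 17, 17)
  img[6, 7] <- 2; img[12, 11] <- 5
  radius <- 3; sigma <- radius / 2
  hw <- ceiling(2 * sigma)
  g <- dnorm(-hw:hw, 0, sigma)
  k <- outer(g, g); k <- k / sum(k)
  oracle <- matrix(0, 17, 17)
  for (i in 1:17) for (j in 1:17) {
    acc <- 0
    for (di in -hw:hw) for (dj in -hw:hw) {
      ii <- min(max(i + di, 1), 17); jj <- min(max(j + dj, 1), 17)
      acc <- acc + k[di + hw + 1, dj + hw + 1] * img[ii, jj]
    }
    oracle[i, j] <- acc
  }
  expect_equal(gaussian_filter(img, radius), oracle, tolerance = 1e-8)
})

test_that("threshold detection finds isolated spots with sub-pixel centroids", {
  blank <- matrix(1, 40, 40)
  expect_equal(nrow(threshold_detect(blank, 0.99, 4)), 0)
  expect_error(threshold_detect(blank, 1.2, 4), "percentile")

  spot <- synaptrack:::add_gaussian_spots(matrix(0, 40, 40), 17.3, 22.6,
                                          1000, 1.5)
  ft <- threshold_detect(spot, 0.97, 4)
  expect_equal(nrow(ft), 1)
  expect_lt(sqrt((ft$x - 17.3)^2 + (ft$y - 22.6)^2), 0.5)

  two <- synaptrack:::add_gaussian_spots(matrix(0, 40, 40), c(12, 22),
                                         c(20, 20), c(1000, 1000), 1.5)
  expect_equal(nrow(threshold_detect(two, 0.95, 4)), 2)
})

test_that("detection count is monotone non-increasing in the percentile", {
  set.seed(13)
  fr <- matrix(rnorm(80 * 80, 10, 0.5), 80, 80)
  xy <- expand.grid(x = seq(12, 68, 14), y = seq(12, 68, 14))
  fr <- synaptrack:::add_gaussian_spots(fr, xy$x, xy$y,
                                        runif(nrow(xy), 200, 1200), 1.5)
  counts <- vapply(c(0.90, 0.95, 0.975, 0.99),
                   function(p) nrow(threshold_detect(fr, p, 4)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("features returned under a mask lie inside the mask", {
  fix <- tiny_movie("primary")
  g <- fix$gt$geometry
  ft <- detect_features(fix$movie$tcr, geometry = g)
  idx <- cbind(pmin(pmax(round(ft$y), 1), nrow(g$mask)),
               pmin(pmax(round(ft$x), 1), ncol(g$mask)))
  expect_true(all(g$mask[idx]))
})

test_that("actin positive mask recovers the true geometry", {
  fix <- tiny_movie("primary")
  true_g <- fix$gt$geometry
  rec <- actin_positive_mask(fix$movie$actin)
  expect_lt(abs(rec$cell_radius - true_g$cell_radius) / true_g$cell_radius,
            0.1)
  expect_lt(abs(rec$csmac_radius - true_g$csmac_radius) / true_g$csmac_radius,
            0.2)
  # eroded true cSMAC disc is fully excluded from the analyzable mask
  r <- synaptrack:::pixel_radii(nrow(rec$mask), ncol(rec$mask), true_g$center)
  core <- r <= true_g$csmac_radius - 2
  expect_false(any(rec$mask[core]))
})

test_that("detection accuracy behaves as a matched-truth recall", {
  truth <- data.frame(frame = rep(1:2, each = 4),
                      x = rep(c(10, 20, 30, 40), 2),
                      y = rep(c(10, 20, 30, 40), 2))
  expect_equal(detection_accuracy(truth, truth), 1.0)
  half <- truth[truth$x <= 20, ]
  expect_equal(detection_accuracy(half, truth), 0.5)
  # invariant to feature order
  shuf <- truth[sample(nrow(truth)), ]
  expect_equal(detection_accuracy(shuf, truth), 1.0)
  expect_error(detection_accuracy(truth, truth[0, ]), "empty")
})
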