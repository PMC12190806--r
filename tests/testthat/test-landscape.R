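eff_pts <- function(qtc, qlc, morph = "spring") {
  pts <- data.frame(group = paste0("g", seq_along(qtc)), morph = morph,
                    qtc = qtc, qlc = qlc,
                    effectiveness = qtc * qlc)
  class(pts) <- c("effectiveness_points", "data.frame")
  pts
}

test_that("landscape scaling is min-max and affine-invariant", {
  ls <- build_landscape(eff_pts(c(0, 5, 10), c(1, 2, 3)))
  expect_equal(ls$x, c(0, 0.5, 1))
  expect_equal(ls$y, c(0, 0.5, 1))
  # affine change of raw units leaves scaled coordinates unchanged
  ls2 <- build_landscape(eff_pts(c(0, 5, 10) * 7 + 3, c(1, 2, 3) * 0.1))
  expect_equal(ls2$x, ls$x)
  expect_equal(ls2$y, ls$y)
  expect_error(build_landscape(eff_pts(c(1, 2), c(1, 2))), "at least 3")
  expect_error(build_landscape(eff_pts(c(2, 2, 2), c(1, 2, 3))), "degenerate")
})

test_that("Clark-Evans statistic separates regular from clustered patterns", {
  # coincident points: zero nearest-neighbour distances
  co <- matrix(0.5, 5, 2)
  expect_equal(clark_evans(co, n_mc = 99, seed = 1)$statistic, 0)

  # regular grid: R > 1 and minimal two-sided MC p
  gr <- as.matrix(expand.grid(seq(0.1, 0.9, length.out = 6),
                              seq(0.1, 0.9, length.out = 6)))
  ce <- clark_evans(gr, n_mc = 999, seed = 2)
  expect_gt(ce$statistic, 1)
  expect_lte(ce$p, 2 / 1000)

  # the edge correction enlarges the expected distance, hence shrinks R
  set.seed(4)
  xy <- cbind(runif(25), runif(25))
  r_d <- clark_evans(xy, correction = "donnelly", n_mc = 99, seed = 5)
  r_0 <- clark_evans(xy, correction = "none", n_mc = 99, seed = 5)
  expect_lt(r_d$statistic, r_0$statistic)

  # determinism under a fixed seed
  expect_identical(clark_evans(xy, n_mc = 199, seed = 7)$p,
                   clark_evans(xy, n_mc = 199, seed = 7)$p)
})

test_that("Hopkins-Skellam index detects clustering", {
  co <- matrix(0.5, 5, 2)
  expect_equal(hopkins_skellam(co, n_mc = 99, seed = 1)$statistic, 0)

  set.seed(2)
  tight <- cbind(runif(20, 0.48, 0.52), runif(20, 0.48, 0.52))
  hs <- hopkins_skellam(tight, n_mc = 499, seed = 3)
  expect_lt(hs$statistic, 0.2)
  expect_lte(hs$p, 0.05)

  set.seed(6)
  xy <- cbind(runif(25), runif(25))
  expect_identical(hopkins_skellam(xy, n_mc = 199, seed = 9)$statistic,
                   hopkins_skellam(xy, n_mc = 199, seed = 9)$statistic)
})

test_that("validity-index panel votes for the evident cluster count", {
  xy <- gaussian_blobs(n_per = 20, sd = 0.03, seed = 2)
  cv <- majority_cluster_count(xy, 2:8)
  expect_equal(cv$k, 3)
  expect_equal(sum(cv$votes), 10)   # ten indices, one vote each
  expect_equal(length(cv$labels), nrow(xy))
  expect_equal(length(unique(cv$labels)), 3)

  # deterministic: same input, same vote, regardless of caller RNG state
  set.seed(999)
  cv2 <- majority_cluster_count(xy, 2:8)
  expect_identical(cv2$index_votes, cv$index_votes)

  # duplicating every point must not change the verdict
  cv3 <- majority_cluster_count(rbind(xy, xy), 2:8)
  expect_equal(cv3$k, 3)

  # tie-break contract: reported k is the smallest modal candidate
  set.seed(10)
  blob <- cbind(rnorm(25, 0.5, 0.1), rnorm(25, 0.5, 0.1))
  cvb <- majority_cluster_count(blob, 2:8)
  mode_ks <- cvb$k_range[cvb$votes == max(cvb$votes)]
  expect_equal(cvb$k, min(mode_ks))
  expect_identical(cvb$tie, length(mode_ks) > 1)

  # too few points truncates the range with a warning
  expect_warning(cvs <- majority_cluster_count(xy[1:5, ], 2:8), "truncated")
  expect_lte(max(cvs$k_range), 4)
})

test_that("component correlation matches the direct formula", {
  pts <- eff_pts(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_equal(qtc_qlc_correlation(pts)$r, 1)

  orth <- eff_pts(c(0, 1, 0, -1), c(1, 0, -1, 0))
  expect_equal(qtc_qlc_correlation(orth)$r, 0)

  set.seed(12)
  five <- eff_pts(runif(5, 0, 3), runif(5, 0, 5))
  ct <- qtc_qlc_correlation(five)
  manual <- sum((five$qtc - mean(five$qtc)) * (five$qlc - mean(five$qlc))) /
    sqrt(sum((five$qtc - mean(five$qtc))^2) * sum((five$qlc - mean(five$qlc))^2))
  expect_equal(ct$r, manual, tolerance = 1e-12)

  expect_error(qtc_qlc_correlation(eff_pts(c(1, 1, 1), c(1, 2, 3))),
               "zero variance")
})
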