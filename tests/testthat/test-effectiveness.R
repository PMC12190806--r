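make_surveys <- function(visits_per_survey, n_surveys = 12, duration = 5,
                         group = "bees", morph = "spring") {
  survey_table(data.frame(
    survey = seq_len(n_surveys), plant = "P1", morph = morph,
    duration_min = duration, group = group,
    visits = rep_len(visits_per_survey, n_surveys)))
}

test_that("quantity component is a visits-per-plant-hour rate", {
  su <- make_surveys(c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0))  # 6 visits / 1 h
  expect_equal(qtc(su, "bees", "spring"), 6)
  expect_equal(qtc(make_surveys(0), "bees", "spring"), 0)
  # doubling all durations at fixed visits halves the rate
  su2 <- make_surveys(c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0), duration = 10)
  expect_equal(qtc(su2, "bees", "spring"), 3)
  expect_error(qtc(su, "bees", "summer"), "no survey effort")
})

test_that("quality component averages seeds over all visited flowers", {
  sv <- single_visits(data.frame(
    flower = 1:10, morph = "spring", group = "bees",
    fruit_set = c(TRUE, TRUE, rep(FALSE, 8)),
    viable_seeds = c(3, 5, rep(0, 8)),
    unfertilised_ovules = c(14, 12, rep(16, 8)),
    aborted_seeds = c(3, 3, rep(4, 8))))
  expect_equal(qlc(sv, "bees", "spring"), 0.8)
  expect_warning(expect_true(is.na(qlc(sv, "moths", "spring"))), "no single-visit")

  # unbiasedness against the two-stage oracle E = f * m * q
  sc <- tiny_scenario(f = 0.5, q = 0.4, ovules = 20, seed = 17)
  reps <- vapply(1:40, function(i) {
    sv <- gen_single_visits(sc, n_flowers = 60, morphs = "spring",
                            seed = 100 + i)
    qlc(sv, "bees", "spring")
  }, numeric(1))
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 4.0), 2 * se + 1e-9)
})

test_that("effectiveness is the exact product and shares normalise", {
  qt <- data.frame(group = c("a", "b"), morph = "spring", qtc = c(2, 1))
  ql <- data.frame(group = c("a", "b"), morph = "spring", qlc = c(3, 2))
  pts <- effectiveness_points(qt, ql)
  expect_equal(pts$effectiveness, c(2 * 3, 1 * 2))

  sh <- seed_shares(pts, "spring")
  expect_equal(sh$share, c(6, 2) / 8)
  expect_equal(sum(sh$share), 1)
  # invariance under common rescaling of effectiveness
  pts2 <- pts; pts2$effectiveness <- pts2$effectiveness * 13
  expect_equal(seed_shares(pts2, "spring")$share, sh$share)

  # missing component drops the point with a notice
  ql3 <- data.frame(group = c("a", "b"), morph = "spring", qlc = c(3, NA))
  expect_message(p3 <- effectiveness_points(qt, ql3), "missing component")
  expect_equal(nrow(p3), 1)
})

test_that("binomial GLM deviance test matches closed-form log-likelihoods", {
  flat <- binomial_glm_lrt(c(10, 10), c(20, 20), c("a", "b"))
  expect_equal(flat$deviance, 0, tolerance = 1e-10)
  expect_equal(flat$p, 1, tolerance = 1e-8)

  sep <- suppressWarnings(binomial_glm_lrt(c(20, 0), c(20, 20), c("a", "b")))
  expect_equal(sep$deviance, -2 * 40 * log(0.5), tolerance = 1e-6)

  # random two-level inputs: LRT equals the closed-form deviance difference
  set.seed(31)
  for (i in 1:20) {
    tot <- sample(5:40, 2, replace = TRUE)
    suc <- c(rbinom(1, tot[1], 0.7), rbinom(1, tot[2], 0.3))
    fit <- suppressWarnings(binomial_glm_lrt(suc, tot, c("a", "b")))
    ll <- function(s, n, p) {
      p <- min(max(p, 1e-12), 1 - 1e-12)
      s * log(p) + (n - s) * log(1 - p)
    }
    p_pool <- sum(suc) / sum(tot)
    dev_closed <- 2 * (ll(suc[1], tot[1], suc[1] / tot[1]) +
                       ll(suc[2], tot[2], suc[2] / tot[2]) -
                       ll(suc[1], tot[1], p_pool) - ll(suc[2], tot[2], p_pool))
    expect_equal(fit$deviance, dev_closed, tolerance = 1e-8)
    # saturated-factor property: fitted proportions are pooled proportions
    expect_equal(unname(fit$fitted_props), suc / tot, tolerance = 1e-8)
  }
  expect_error(binomial_glm_lrt(c(5, 5), c(4, 10), c("a", "b")), "exceed")
})

test_that("weighted PIE comparison detects concentration and is symmetric", {
  visits <- c(250, 250, 250, 250)
  # seed counts proportional to visits: identical estimates, no difference
  prop <- weighted_pie_comparison(visits, rep(0.25, 4), 1000, B = 400, seed = 1)
  expect_equal(prop$visits$pie, prop$seeds$pie)
  expect_equal(prop$verdict, "not different")

  conc <- weighted_pie_comparison(visits, c(0.97, 0.01, 0.01, 0.01), 1000,
                                  B = 400, seed = 2)
  expect_lt(conc$seeds$pie, conc$visits$pie)
  expect_equal(conc$verdict, "different")

  # verdict symmetric under exchanging the two weightings
  swap <- weighted_pie_comparison(conc$seed_counts,
                                  visits / sum(visits), sum(visits),
                                  B = 400, seed = 3)
  expect_equal(swap$verdict, conc$verdict)
})
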