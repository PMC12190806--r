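test_that("PIE closed form agrees with the pair-count oracle and is well-behaved", {
  expect_equal(hurlbert_pie(c(5)), 0)
  expect_equal(hurlbert_pie(c(10, 10)), 100 / 190)
  expect_equal(hurlbert_pie(c(2, 2)), (4 / 3) * 0.5)
  expect_error(hurlbert_pie(c(1)), "N < 2")

  set.seed(42)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    counts <- as.numeric(rmultinom(1, sample(5:50, 1), runif(k)))
    counts <- counts[counts > 0]
    if (sum(counts) < 2) next
    expect_equal(hurlbert_pie(counts), pie_pair_oracle(counts),
                 tolerance = 1e-12)
    expect_equal(pie_unbiased(counts), hurlbert_pie(counts),
                 tolerance = 1e-12)
    # label permutation invariance
    expect_equal(hurlbert_pie(sample(counts)), hurlbert_pie(counts))
  }

  # adding a singleton of a new group to a pure sample raises diversity
  expect_gt(hurlbert_pie(c(20, 1)), hurlbert_pie(c(20, 0)))
})

test_that("bootstrap PIE interval behaves like a sampling distribution", {
  e1 <- pie_bootstrap(c(500, 500), B = 1000, seed = 1)
  expect_gt(0.5, e1$ci_low)
  expect_lt(0.5, e1$ci_high)
  expect_lt(e1$ci_high - e1$ci_low, 0.05)

  e2 <- pie_bootstrap(c(500, 500), B = 1000, seed = 1)
  expect_identical(e1[c("pie", "se", "ci_low", "ci_high")],
                   e2[c("pie", "se", "ci_low", "ci_high")])

  deg <- pie_bootstrap(c(40, 0), B = 200, seed = 2)
  expect_equal(deg$pie, 0)
  expect_equal(c(deg$ci_low, deg$ci_high), c(0, 0))

  expect_warning(pie_bootstrap(c(10, 10), B = 50, seed = 1), "unstable")

  cmp <- compare_estimates(pie_bootstrap(c(500, 500), B = 500, seed = 3),
                           pie_bootstrap(c(900, 100), B = 500, seed = 4))
  expect_equal(cmp$verdict, "different")
})

test_that("Bray-Curtis matches hand-computed dissimilarities", {
  m <- rbind(a = c(2, 1), b = c(1, 1), c = c(2, 1), d = c(0, 3))
  d <- as.matrix(bray_curtis(m, scale = "counts"))
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "b"], 1 / 5)
  disj <- as.matrix(bray_curtis(rbind(c(1, 0), c(0, 1)), scale = "counts"))
  expect_equal(disj[1, 2], 1)

  expect_message(bray_curtis(rbind(c(1, 2), c(0, 0), c(2, 2)),
                             scale = "counts"), "all-zero")
  expect_error(suppressMessages(
    bray_curtis(rbind(c(1, 2), c(0, 0), c(0, 0)), scale = "counts")),
    "non-empty")
})

test_that("permanova partitions composition with sequential SS", {
  # identical composition in both seasons: season explains nothing
  m <- rbind(c(30, 10, 5), c(10, 30, 5), c(5, 10, 30),
             c(30, 10, 5), c(10, 30, 5), c(5, 10, 30))
  meta <- data.frame(season = rep(c("spring", "summer"), each = 3))
  d <- bray_curtis(m)
  res <- permanova(d, meta, "season", n_perm = 199, seed = 1)
  expect_lt(res$table$f, 1e-10)
  expect_gt(res$table$p, 0.9)

  # well-separated clusters reach the minimal attainable p
  set.seed(8)
  g1 <- matrix(rpois(100, 20), 10) +
    matrix(rep(c(100, 0, 0, 0, 0, 0, 0, 0, 0, 0), each = 10), 10)
  g2 <- matrix(rpois(100, 20), 10) +
    matrix(rep(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 100), each = 10), 10)
  m2 <- rbind(g1, g2)
  meta2 <- data.frame(grp = rep(c("x", "y"), each = 10))
  res2 <- permanova(bray_curtis(m2), meta2, "grp", n_perm = 999, seed = 2)
  expect_equal(res2$table$p, 1 / 1000)

  # label-order invariance of SS and F
  perm <- sample(nrow(m2))
  res3 <- permanova(bray_curtis(m2[perm, ]),
                    data.frame(grp = meta2$grp[perm]), "grp",
                    n_perm = 199, seed = 3)
  expect_equal(res3$table$ss, res2$table$ss, tolerance = 1e-10)
  expect_equal(res3$table$f, res2$table$f, tolerance = 1e-10)

  expect_error(permanova(d, data.frame(x = rep("a", 6)), "x"), "single level")
  conf <- data.frame(a = rep(c("u", "v"), each = 3),
                     b = rep(c("p", "q"), each = 3))
  expect_error(permanova(d, conf, c("a", "b")), "confounded")
})

test_that("principal coordinates reproduce geometry", {
  # two units at distance 1: +/- 0.5 on one axis, all the variation
  d2 <- stats::as.dist(matrix(c(0, 1, 1, 0), 2))
  p2 <- suppressWarnings(pcoa(d2, k = 2))
  expect_equal(sort(p2$points[, 1]), c(-0.5, 0.5))
  expect_equal(p2$prop[1], 1)

  # equilateral triangle: two equal eigenvalues carrying 50% each
  d3 <- stats::dist(rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)))
  p3 <- pcoa(d3, k = 2)
  expect_equal(p3$prop[1], 0.5, tolerance = 1e-10)
  expect_equal(p3$prop[2], 0.5, tolerance = 1e-10)

  # Euclidean input distances are reproduced exactly
  set.seed(5)
  pts <- matrix(rnorm(30), 10, 3)
  din <- stats::dist(pts)
  emb <- pcoa(din, k = 3)
  expect_equal(as.numeric(stats::dist(emb$points)), as.numeric(din),
               tolerance = 1e-9)
})

test_that("group scores project abundance gradients onto axes", {
  # two independent gradients so the ordination is genuinely 2-D
  m <- rbind(c(10, 0, 5, 1), c(8, 2, 5, 9), c(2, 8, 5, 2), c(0, 10, 5, 8))
  colnames(m) <- c("g1", "g2", "g3", "g4")
  d <- bray_curtis(m, scale = "counts")
  ord <- pcoa(d, k = 2)
  expect_warning(sc <- group_scores(ord, m, scale = "counts"), "zero-variance")
  # g1 and g2 load on axis 1 with opposite signs; constant g3 scores 0
  expect_lt(sc["g1", 1] * sc["g2", 1], 0)
  expect_equal(unname(sc["g3", ]), c(0, 0))
  # the group aligned with positive axis-1 units scores positive there
  pos_units <- ord$points[, 1] > 0
  up <- if (mean(m[pos_units, "g1"]) > mean(m[!pos_units, "g1"])) "g1" else "g2"
  expect_gt(sc[up, 1], 0)

  # axis reflection flips scores (up to the same sign)
  ord2 <- ord
  ord2$points[, 1] <- -ord2$points[, 1]
  sc2 <- suppressWarnings(group_scores(ord2, m, scale = "counts"))
  expect_equal(sc2[, 1], -sc[, 1], tolerance = 1e-12)
})
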