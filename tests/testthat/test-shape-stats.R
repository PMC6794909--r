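test_that("shape PCA satisfies the trace identity and preserves distances", {
  set.seed(7)
  shape <- matrix(rnorm(40 * 12), 40, 12)
  pca <- shape_pca(shape)
  total_var <- sum(diag(stats::cov(shape)))
  expect_equal(sum(pca$eigenvalues), total_var, tolerance = 1e-9)
  expect_equal(colMeans(pca$scores), rep(0, ncol(pca$scores)),
               tolerance = 1e-9, ignore_attr = TRUE)
  # full-basis scores are an isometry of the centered data
  expect_equal(as.matrix(dist(pca$scores)), as.matrix(dist(shape)),
               tolerance = 1e-9)

  # data on a line: all variance on the first axis
  line <- outer(rnorm(20), c(1, 2, -1, 0.5))
  pl <- shape_pca(line)
  expect_equal(pl$variance_fractions[1], 1, tolerance = 1e-9)
  expect_lt(max(pl$variance_fractions[-1]), 1e-12)

  expect_warning(shape_pca(matrix(1, 5, 4)), "degenerate")
})

test_that("PC retention picks the smallest leading set reaching the threshold", {
  fake <- structure(list(variance_fractions = c(0.5, 0.3, 0.15, 0.05),
                         eigenvalues = c(0.5, 0.3, 0.15, 0.05)),
                    class = "shape_pca")
  expect_equal(retain_pcs(fake, 0.90), 1:3)
  expect_equal(retain_pcs(fake, 1.0), 1:4)
  fake2 <- structure(list(variance_fractions = c(0.95, 0.04, 0.01),
                          eigenvalues = c(0.95, 0.04, 0.01)),
                     class = "shape_pca")
  expect_equal(retain_pcs(fake2, 0.90), 1L)
  expect_error(retain_pcs(fake, 0), "threshold")
})

test_that("pairwise MANOVA reduces to the classical F test in one dimension", {
  set.seed(17)
  y <- c(rnorm(15), rnorm(15, 1))
  g <- rep(c("a", "b"), each = 15)
  res <- pairwise_manova(matrix(y, ncol = 1), g, correction = "none")
  f_classic <- summary(stats::aov(y ~ g))[[1]]$`F value`[1]
  p_classic <- summary(stats::aov(y ~ g))[[1]]$`Pr(>F)`[1]
  expect_equal(res$approx_F, f_classic, tolerance = 1e-9)
  expect_equal(res$p, p_classic, tolerance = 1e-9)
  # equals the squared two-sample t statistic
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(res$approx_F, unname(tt$statistic^2), tolerance = 1e-9)
})

test_that("pairwise MANOVA separates distinct groups and applies Bonferroni", {
  set.seed(19)
  sim <- simulate_shape_groups(div = 1, noise_sd = 0.15)
  pca <- shape_pca(sim$shape)
  sc <- pca$scores[, retain_pcs(pca, 0.9), drop = FALSE]
  res <- pairwise_manova(sc, sim$labels)
  expect_equal(nrow(res), 3)
  expect_true(all(res$p_adj <= 1))
  expect_true(all(res$p_adj >= res$p))
  expect_true(all(res$p_adj < 0.05))
  expect_error(pairwise_manova(matrix(rnorm(32), 8, 4),
                               rep(c("a", "b"), 4)),
               "retained axes")
})

test_that("two-way MANOVA validates factors and detects planted interactions", {
  set.seed(23)
  sc <- matrix(rnorm(60 * 4), 60, 4)
  sp <- rep(c("donkey", "horse"), each = 30)
  expect_error(two_way_manova(sc, sp, rep("female", 60)),
               "fewer than 2")
  sx <- rep(c("female", "male"), 30)
  sx_bad <- ifelse(sp == "donkey", "female", sx)
  expect_error(two_way_manova(sc, sp, sx_bad), "empty cell")

  # geldings are excluded from the sex factor
  sx_g <- sx; sx_g[1:5] <- "gelding"
  res <- two_way_manova(sc, sp, sx_g)
  expect_setequal(res$term, c("factor_a", "factor_b", "interaction"))
  expect_true(all(res$p >= 0 & res$p <= 1))

  # power: sex effect in one species only, 1 SD, n = 30 per cell
  hits <- 0L
  for (r in 1:60) {
    n_cell <- 30
    sp2 <- rep(c("donkey", "horse", "hybrid"), each = 2 * n_cell)
    sx2 <- rep(rep(c("female", "male"), each = n_cell), 3)
    y <- matrix(rnorm(length(sp2) * 5), ncol = 5)
    shift <- sp2 == "horse" & sx2 == "male"
    y[shift, ] <- y[shift, ] + 1
    res2 <- two_way_manova(y, sp2, sx2)
    if (res2$p[res2$term == "interaction"] < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / 60, 0.8)
})

test_that("Procrustes variance matches direct summation and midpoint algebra", {
  set.seed(29)
  shape <- matrix(rnorm(25 * 9), 25, 9)
  labels <- rep(c("a", "b"), c(12, 13))
  pv <- procrustes_variance(shape, labels)
  for (g in c("a", "b")) {
    rows <- shape[labels == g, ]
    mu <- colMeans(rows)
    brute <- mean(vapply(seq_len(nrow(rows)), function(i)
      sum((rows[i, ] - mu)^2), numeric(1)))
    expect_equal(unname(pv[g]), brute, tolerance = 1e-12)
  }
  # two specimens at distance d: variance d^2 / 4
  two <- rbind(rep(0, 4), c(3, 0, 0, 0))
  expect_equal(unname(procrustes_variance(two, c("g", "g"))["g"]),
               9 / 4, tolerance = 1e-12)
  # identical members: zero
  expect_equal(unname(procrustes_variance(rbind(two[1, ], two[1, ]),
                                          c("g", "g"))["g"]), 0)
  expect_warning(procrustes_variance(shape, c("solo", labels[-1])),
                 "singleton")
  # invariant to a common rotation of the shape variables
  q <- qr.Q(qr(matrix(rnorm(81), 9, 9)))
  expect_equal(procrustes_variance(shape %*% q, labels), pv,
               tolerance = 1e-9)
})

test_that("disparity permutation test is seed-stable and detects variance gaps", {
  set.seed(31)
  shape <- rbind(matrix(rnorm(30 * 6, sd = 1), 30, 6),
                 matrix(rnorm(30 * 6, sd = 2), 30, 6))
  labels <- rep(c("a", "b"), each = 30)
  r1 <- disparity_test(shape, labels, n_perm = 199, seed = 5)
  r2 <- disparity_test(shape, labels, n_perm = 199, seed = 5)
  expect_identical(r1$pairwise, r2$pairwise)
  expect_equal(min(r1$pairwise$p), 1 / 200)

  # power: one group with 4x the noise variance, n = 30 each
  hits <- 0L
  for (r in 1:30) {
    sh <- rbind(matrix(rnorm(30 * 6, sd = 1), 30, 6),
                matrix(rnorm(30 * 6, sd = 2), 30, 6))
    res <- disparity_test(sh, labels, n_perm = 199, seed = r)
    if (res$pairwise$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 30, 0.9)
  expect_error(disparity_test(shape, labels, n_perm = 10), "at least 99")
})
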