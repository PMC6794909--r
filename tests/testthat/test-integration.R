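test_that("two-block PLS matches a dense eigendecomposition oracle", {
  set.seed(3)
  x <- matrix(rnorm(6 * 4), 6, 4)
  y <- matrix(rnorm(6 * 5), 6, 5)
  rownames(x) <- rownames(y) <- letters[1:6]
  fit <- two_block_pls(x, y)
  # oracle: singular values of C are sqrt of eigenvalues of C C^T
  cmat <- crossprod(sweep(x, 2, colMeans(x)), sweep(y, 2, colMeans(y))) / 5
  ev <- eigen(cmat %*% t(cmat), symmetric = TRUE)$values
  expect_equal(fit$singular_values[1:4], sqrt(pmax(ev, 0)),
               tolerance = 1e-10)
  expect_equal(sum(fit$covariance_fractions), 1, tolerance = 1e-12)
  expect_true(all(diff(fit$singular_values) <= 1e-12))
  # loadings orthonormal within blocks
  expect_equal(crossprod(fit$xloadings), diag(4), tolerance = 1e-9)

  # self-covariation
  self <- two_block_pls(x, x)
  expect_equal(self$r_pls, 1, tolerance = 1e-9)

  # symmetry in block order
  rev <- two_block_pls(y, x)
  expect_equal(rev$r_pls, fit$r_pls, tolerance = 1e-12)

  # blockwise orthogonal transforms leave r_pls unchanged
  qx <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  qy <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  fit2 <- two_block_pls(x %*% qx, y %*% qy)
  expect_equal(fit2$r_pls, fit$r_pls, tolerance = 1e-12)

  # rank-1 construction concentrates the covariance on the first axis
  set.seed(5)
  blocks <- simulate_coupled_blocks(n = 200, rho = 1, noise_sd = 0.01)
  r1 <- two_block_pls(blocks$x, blocks$y)
  expect_gt(r1$covariance_fractions[1], 0.99)

  rownames(y) <- rev(letters[1:6])
  expect_error(two_block_pls(x, y), "mismatch")
})

test_that("PLS permutation test is seed-stable, calibrated-ish and powerful", {
  set.seed(7)
  blocks <- simulate_coupled_blocks(n = 30, rho = 0.8)
  f1 <- pls_permutation_test(blocks$x, blocks$y, n_perm = 199, seed = 4)
  f2 <- pls_permutation_test(blocks$x, blocks$y, n_perm = 199, seed = 4)
  expect_identical(f1$p_value, f2$p_value)
  expect_identical(f1$perm_r, f2$perm_r)
  expect_lt(f1$p_value, 0.05)
  expect_gt(f1$z_score, 2)

  # strongly coupled blocks detected across replicates
  set.seed(9)
  hits <- vapply(1:20, function(r) {
    b <- simulate_coupled_blocks(n = 30, rho = 0.9, signal_sd = 1,
                                 noise_sd = 0.3)
    pls_permutation_test(b$x, b$y, n_perm = 199, seed = r)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # p monotone decreasing in generating coupling strength (on average)
  set.seed(11)
  mean_p <- vapply(c(0, 0.5, 0.95), function(rho) {
    mean(vapply(1:15, function(r) {
      b <- simulate_coupled_blocks(n = 30, rho = rho)
      pls_permutation_test(b$x, b$y, n_perm = 99, seed = r)$p_value
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_p) < 0))
})

test_that("effect sizes standardize rPLS and stay comparable across n", {
  set.seed(13)
  perm <- rnorm(500, 0.4, 0.05)
  es0 <- pls_effect_size(tanh(mean(atanh(perm))), perm)
  expect_equal(es0$z_score, 0, tolerance = 0.05)
  es_big <- pls_effect_size(0.9, rnorm(500, 0.05, 0.03))
  expect_gt(es_big$z_score, 3)
  expect_error(pls_effect_size(0.5, rep(0.2, 200)), "zero permutation spread")
  expect_error(pls_effect_size(0.5, rnorm(50)), "at least 99")

  # the property the method exists for: the null location and scale of z are
  # n-invariant (standard-normal-like) while the null of raw rPLS shifts
  # strongly with n
  set.seed(17)
  null_stats <- function(n) {
    fits <- lapply(1:60, function(r) {
      b <- simulate_coupled_blocks(n = n, rho = 0)
      pls_permutation_test(b$x, b$y, n_perm = 199, seed = 100 + r)
    })
    c(z = mean(vapply(fits, `[[`, 0, "z_score")),
      r = mean(vapply(fits, `[[`, 0, "r_pls")))
  }
  s30 <- null_stats(30); s300 <- null_stats(300)
  expect_gt(s30[["r"]] - s300[["r"]], 0.15)    # raw r null shifts with n
  expect_lt(abs(s30[["z"]] - s300[["z"]]), 0.5) # z null does not
  expect_lt(abs(s30[["z"]]), 0.5)
  # under a common alternative both sample sizes give clearly positive z
  set.seed(18)
  z_alt <- vapply(c(30, 90), function(n) {
    mean(vapply(1:30, function(r) {
      b <- simulate_coupled_blocks(n = n, rho = 0.75)
      pls_permutation_test(b$x, b$y, n_perm = 199, seed = 200 + r)$z_score
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(z_alt > 2))
})

test_that("two-sample effect-size comparison separates unequal couplings", {
  a <- list(z_score = 3, z_se = 1)
  expect_equal(compare_effect_sizes(a, a)$statistic, 0)
  expect_equal(compare_effect_sizes(a, a)$p_value, 1)
  expect_error(compare_effect_sizes(a, list(z_score = 1)), "z_se")

  set.seed(19)
  hits <- vapply(1:20, function(r) {
    b1 <- simulate_coupled_blocks(n = 30, rho = 0.9, noise_sd = 0.2)
    b0 <- simulate_coupled_blocks(n = 30, rho = 0, noise_sd = 0.2)
    f1 <- pls_permutation_test(b1$x, b1$y, n_perm = 199, seed = r)
    f0 <- pls_permutation_test(b0$x, b0$y, n_perm = 199, seed = r + 500)
    compare_effect_sizes(f1, f0)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})

test_that("covariation network recovers a planted edge and skips sparse pairs", {
  sp <- generator_spec(
    bones = c(humerus = 5L, femur = 5L, radio_ulna = 5L, tibia = 5L),
    n = c(donkey = 30L, horse = 30L, hybrid = 30L), mules = 15L,
    integration = data.frame(bone_a = "humerus", bone_b = "femur", rho = 0.8),
    seed = 42L)
  gs <- generate_study(sp)
  net <- suppressWarnings(covariation_network(gs$study, n_perm = 199,
                                              seed = 7))
  e <- net$edges
  planted <- e$bone_a == "humerus" & e$bone_b == "femur"
  expect_true(all(e$significant[planted]))
  # family-wise error control: at most a stray non-planted edge
  expect_lte(sum(e$significant[!planted]), 1)
  expect_true(all(e$p_adj >= e$p))

  # determinism given the seed
  net2 <- suppressWarnings(covariation_network(gs$study, n_perm = 199,
                                               seed = 7))
  expect_identical(net$edges, net2$edges)

  # a pair with < 4 shared specimens in a group is skipped with a warning
  study <- gs$study
  keep <- dimnames(study$bones$tibia)[[3]]
  donkeys <- study$specimens$specimen_id[study$specimens$group == "donkey"]
  study$bones$tibia <- study$bones$tibia[, , !(keep %in% donkeys[-(1:3)])]
  w <- testthat::capture_warnings(
    net3 <- covariation_network(study, n_perm = 199, seed = 7))
  expect_true(any(grepl("skipped", w)))
  e3 <- net3$edges
  expect_false(any(e3$group == "donkey" &
                     (e3$bone_a == "tibia" | e3$bone_b == "tibia")))

  # group comparison table covers every group pair per edge, Bonferroni-capped
  cmp <- compare_network_effects(net)
  expect_equal(nrow(cmp), nrow(e))  # 3 group pairs x (edges / 3 groups)
  expect_true(all(cmp$p_adj >= cmp$p - 1e-15))
})

test_that("PLS shape changes deform the consensus along the first axis", {
  sp <- generator_spec(bones = c(humerus = 6L, femur = 6L),
                       n = c(donkey = 40L, horse = 40L, hybrid = 20L),
                       mules = 10L,
                       integration = data.frame(bone_a = "humerus",
                                                bone_b = "femur", rho = 1),
                       integration_sd = 0.05, seed = 9L)
  gs <- generate_study(sp)
  g1 <- gpa(gs$study$bones$humerus)
  g2 <- gpa(gs$study$bones$femur)
  fit <- two_block_pls(g1$shape, g2$shape)
  sc <- pls_shape_changes(fit, g1, g2, quantile = 0.05)
  expect_equal(dim(sc$block1$shape_lo), dim(g1$consensus))
  expect_equal(length(sc$block1$displacement), 6)
  # median-quantile shapes sit near the consensus
  sc50 <- pls_shape_changes(fit, g1, g2, quantile = 0.5)
  expect_equal(sc50$block1$shape_lo, sc50$block1$shape_hi, tolerance = 1e-12)
  expect_lt(max(abs(sc50$block1$shape_lo - g1$consensus)), 0.02)
  # displacements invariant to a global rotation of the aligned sample
  rot <- quat_to_rot(c(1, 2, 3, 4))
  arr <- g1$aligned
  for (i in seq_len(dim(arr)[3])) arr[, , i] <- arr[, , i] %*% rot
  g1r <- list(consensus = g1$consensus %*% rot, aligned = arr,
              shape = NULL, projection = "tangent")
  class(g1r) <- "gpa"
  g1r$shape <- tangent_project(g1r)
  fit_r <- two_block_pls(g1r$shape, g2$shape)
  sc_r <- pls_shape_changes(fit_r, g1r, g2, quantile = 0.05)
  expect_equal(unname(sc_r$block1$displacement),
               unname(sc$block1$displacement), tolerance = 1e-8)

  # DOT export writes one graph per group
  net <- suppressWarnings(covariation_network(gs$study, n_perm = 99, seed = 1))
  dot <- withr::local_tempfile(fileext = ".dot")
  write_network_dot(net, dot)
  txt <- readLines(dot)
  expect_equal(sum(grepl("^graph", txt)), 3)
})
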