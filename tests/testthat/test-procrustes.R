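test_that("centroid size matches closed forms and direct summation", {
  square <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(centroid_size(square), sqrt(2), tolerance = 1e-12)

  set.seed(21)
  x <- rand_config(10)
  expect_equal(centroid_size(3 * x), 3 * centroid_size(x), tolerance = 1e-12)

  brute <- sqrt(sum(vapply(seq_len(nrow(x)), function(i)
    sum((x[i, ] - colMeans(x))^2), numeric(1))))
  expect_equal(centroid_size(x), brute, tolerance = 1e-12)

  rot <- quat_to_rot(rnorm(4))
  expect_equal(centroid_size(sweep(x %*% rot, 2, c(5, -2, 1), `+`)),
               centroid_size(x), tolerance = 1e-9)
  expect_warning(centroid_size(matrix(1, 4, 3)), "coincident")
})

test_that("ordinary Procrustes fit is proper, symmetric and optimal", {
  set.seed(31)
  a <- rand_config(8)
  b <- sweep(a %*% quat_to_rot(rnorm(4)) * 2.5, 2, c(3, -1, 7), `+`)
  fit <- ordinary_procrustes(a, b)
  expect_equal(fit$distance, 0, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  reflected <- a %*% diag(c(-1, 1, 1))
  expect_gt(procrustes_distance(a, reflected), 0.05)

  for (i in 1:5) {
    x <- rand_config(6); y <- rand_config(6)
    expect_equal(procrustes_distance(x, y), procrustes_distance(y, x),
                 tolerance = 1e-12)
  }
  expect_error(ordinary_procrustes(rand_config(5), rand_config(6)),
               "mismatch")
})

test_that("ordinary Procrustes distance matches the quaternion search oracle", {
  set.seed(41)
  for (i in 1:5) {
    a <- rand_config(4); b <- rand_config(4)
    expect_equal(procrustes_distance(a, b), opa_distance_oracle(a, b),
                 tolerance = 1e-4)
  }
})

test_that("GPA removes similarity transforms and satisfies its invariants", {
  set.seed(51)
  base <- rand_config(7)
  arr <- array(NA_real_, c(7, 3, 5))
  for (i in 1:5)
    arr[, , i] <- sweep(base %*% quat_to_rot(rnorm(4)) * runif(1, 0.5, 4),
                        2, rnorm(3, sd = 10), `+`)
  fit <- gpa(arr)
  d <- as.matrix(dist(fit$shape))
  expect_lt(max(d), 1e-8)

  # invariants: unit centroid sizes, consensus = mean, centered at origin
  set.seed(52)
  base2 <- rand_config(8)
  arr2 <- array(rep(base2, 12), c(8, 3, 12)) +
    array(rnorm(8 * 3 * 12, sd = 0.15), c(8, 3, 12))
  fit2 <- gpa(arr2)
  expect_equal(max(abs(apply(fit2$aligned, 3, centroid_size) - 1)), 0,
               tolerance = 1e-9)
  expect_equal(fit2$consensus, apply(fit2$aligned, c(1, 2), mean),
               tolerance = 1e-9)
  expect_equal(colMeans(fit2$consensus), c(0, 0, 0), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(colMeans(fit2$shape), rep(0, 24), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("two-configuration consensus is equidistant from both", {
  set.seed(61)
  arr <- array(c(rand_config(6), rand_config(6)), c(6, 3, 2))
  fit <- gpa(arr)
  d1 <- sqrt(sum((fit$aligned[, , 1] - fit$consensus)^2))
  d2 <- sqrt(sum((fit$aligned[, , 2] - fit$consensus)^2))
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("GPA consensus beats random reference shapes", {
  set.seed(71)
  base <- rand_config(6)
  arr <- array(rep(base, 20), c(6, 3, 20)) +
    array(rnorm(6 * 3 * 20, sd = 0.2), c(6, 3, 20))
  fit <- gpa(arr)
  ss_consensus <- sum(vapply(seq_len(20), function(i)
    procrustes_distance(arr[, , i], fit$consensus)^2, numeric(1)))
  for (r in 1:100) {
    ref <- rand_config(6)
    ss_ref <- sum(vapply(seq_len(20), function(i)
      procrustes_distance(arr[, , i], ref)^2, numeric(1)))
    expect_lte(ss_consensus, ss_ref + 1e-10)
  }
})

test_that("GPA results are invariant to input transforms and ordering", {
  set.seed(81)
  base <- rand_config(6)
  arr <- array(rep(base, 10), c(6, 3, 10)) +
    array(rnorm(6 * 3 * 10, sd = 0.15), c(6, 3, 10))
  fit <- gpa(arr)
  # transform every input arbitrarily
  arr2 <- arr
  for (i in 1:10) {
    arr2[, , i] <- sweep(arr2[, , i] %*% quat_to_rot(rnorm(4)) *
                           runif(1, 0.1, 9), 2, rnorm(3, sd = 30), `+`)
  }
  fit2 <- gpa(arr2)
  expect_equal(as.matrix(dist(fit$shape)), as.matrix(dist(fit2$shape)),
               tolerance = 1e-8)
  # reorder inputs: distances unchanged
  ord <- sample(10)
  fit3 <- gpa(arr[, , ord])
  expect_equal(as.matrix(dist(fit$shape))[ord, ord],
               as.matrix(dist(fit3$shape)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("Procrustes distance obeys symmetry and the triangle inequality", {
  set.seed(91)
  for (rep in 1:20) {
    a <- rand_config(5); b <- rand_config(5); cc <- rand_config(5)
    dab <- procrustes_distance(a, b)
    dbc <- procrustes_distance(b, cc)
    dac <- procrustes_distance(a, cc)
    expect_lte(dac, dab + dbc + 1e-9)
  }
})

test_that("tangent projection behaves like Procrustes distance locally", {
  set.seed(101)
  base <- center_scale <- rand_config(8)
  arr <- array(NA_real_, c(8, 3, 15))
  for (i in 1:15) arr[, , i] <- base + rand_config(8, sd = 0.004)
  fit <- gpa(arr)
  td <- as.matrix(dist(fit$shape))
  pd <- matrix(0, 15, 15)
  for (i in 1:14) for (j in (i + 1):15)
    pd[i, j] <- pd[j, i] <- procrustes_distance(arr[, , i], arr[, , j])
  off <- upper.tri(td)
  expect_lt(max(abs(td[off] - pd[off]) / pd[off]), 0.01)

  # residual projection offered as alternative
  fit_res <- gpa(arr, projection = "residual")
  expect_equal(dim(fit_res$shape), dim(fit$shape))
})
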