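# Independent oracles and small data builders used across the suite.

# A random non-degenerate k x 3 configuration.
rand_config <- function(k, sd = 1) matrix(rnorm(3 * k, sd = sd), k, 3)

quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Brute-force ordinary-Procrustes distance: minimize over rotations
# parameterized by unit quaternions (dense random starts + local polish).
# Independent of the SVD route used by the package.
opa_distance_oracle <- function(a, b, n_starts = 2000, n_polish = 8) {
  cs <- function(x) { x <- sweep(x, 2, colMeans(x)); x / sqrt(sum(x^2)) }
  ac <- cs(a); bc <- cs(b)
  obj <- function(q) sqrt(sum((ac - bc %*% quat_to_rot(q))^2))
  qs <- matrix(rnorm(4 * n_starts), ncol = 4)
  vals <- apply(qs, 1, obj)
  best <- order(vals)[seq_len(n_polish)]
  polished <- vapply(best, function(i) {
    stats::optim(qs[i, ], obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))$value
  }, numeric(1))
  min(polished)
}

# Shape variables drawn directly in a p-dimensional trait space (no
# superimposition): three groups with parent means separated by `div` along
# the first axis and the hybrid placed at (f, t) in the first two axes.
simulate_shape_groups <- function(n = c(donkey = 30, horse = 30, hybrid = 30),
                                  p = 8, div = 1, f = 0.5, t = 0,
                                  noise_sd = 0.1) {
  labels <- rep(names(n), n)
  means <- rbind(donkey = c(0, rep(0, p - 1)),
                 horse = c(div, rep(0, p - 1)),
                 hybrid = c(f * div, t * div, rep(0, p - 2)))
  shape <- means[labels, , drop = FALSE] +
    matrix(rnorm(sum(n) * p, sd = noise_sd), sum(n), p)
  rownames(shape) <- sprintf("s%03d", seq_len(sum(n)))
  list(shape = shape, labels = labels)
}

# Paired blocks with a single latent factor shared at correlation `rho`
# along the first axis of each block.
simulate_coupled_blocks <- function(n = 30, p = 6, q = 6, rho = 0.8,
                                    signal_sd = 1, noise_sd = 0.3) {
  l1 <- rnorm(n); l2 <- rho * l1 + sqrt(1 - rho^2) * rnorm(n)
  x <- matrix(rnorm(n * p, sd = noise_sd), n, p)
  y <- matrix(rnorm(n * q, sd = noise_sd), n, q)
  x[, 1] <- x[, 1] + signal_sd * l1
  y[, 1] <- y[, 1] + signal_sd * l2
  rownames(x) <- rownames(y) <- sprintf("s%03d", seq_len(n))
  list(x = x, y = y)
}

# Apply a random rigid motion to every configuration of every bone of a
# study, plus isotropic scaling: a common factor (a unit change, which no
# table should react to) or a per-configuration factor (which only the
# scale-free shape analyses can ignore).
perturb_study <- function(study, scale = c("common", "per_config")) {
  scale <- match.arg(scale)
  s_common <- runif(1, 0.2, 5)
  for (b in names(study$bones)) {
    arr <- study$bones[[b]]
    for (i in seq_len(dim(arr)[3])) {
      s <- if (scale == "common") s_common else runif(1, 0.2, 5)
      arr[, , i] <- arr[, , i] %*% quat_to_rot(rnorm(4)) * s
      arr[, , i] <- sweep(arr[, , i], 2, runif(3, -50, 50), `+`)
    }
    study$bones[[b]] <- arr
  }
  study
}

tiny_tps <- function(path) {
  writeLines(c("LM3=4",
               "0 0 0", "1 0 0", "1 1 0", "0 1 1",
               "ID=alpha",
               "LM3=4",
               "0.5 0 0", "1.5 0.25 0", "1 1 0.5", "0 1 1",
               "ID=beta"), path)
  path
}
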