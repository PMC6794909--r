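# Size analysis and shape-size regression.

#' ANOVA and pairwise t-tests on log centroid size
#'
#' One-way ANOVA on log10 centroid sizes followed by all pairwise t-tests with
#' Bonferroni correction.
#'
#' @param log_sizes Numeric vector of log10 centroid sizes.
#' @param labels Group labels (>= 2 groups, each n >= 2).
#' @return Object of class `size_anova`: `F`, `df`, `p`, `pairwise` (data
#'   frame of Bonferroni-adjusted pairwise t-test p-values), `group_means`.
#' @export
size_anova <- function(log_sizes, labels) {
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop_mh("need at least 2 groups")
  if (any(table(labels) < 2L)) stop_mh("each group needs n >= 2")
  wv <- tapply(log_sizes, labels, stats::var)
  if (any(wv == 0))
    warn_mh("zero within-group size variance in group(s): ",
            paste(names(which(wv == 0)), collapse = ", "))
  fit <- stats::aov(log_sizes ~ labels)
  tab <- summary(fit)[[1]]
  pt <- stats::pairwise.t.test(log_sizes, labels,
                               p.adjust.method = "bonferroni")
  pm <- pt$p.value
  pairs <- which(!is.na(pm), arr.ind = TRUE)
  pairwise <- data.frame(group_1 = colnames(pm)[pairs[, 2]],
                         group_2 = rownames(pm)[pairs[, 1]],
                         p_adj = pm[pairs])
  structure(list(F = tab$`F value`[1], df = tab$Df, p = tab$`Pr(>F)`[1],
                 pairwise = pairwise,
                 group_means = tapply(log_sizes, labels, mean)),
            class = "size_anova")
}

#' @export
print.size_anova <- function(x, ...) {
  cat(sprintf("Size ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p))
  cat("Pairwise t-tests (Bonferroni):\n")
  print(x$pairwise, digits = 4)
  invisible(x)
}

# Internal: total R^2 of the multivariate regression of y (n x p) on a single
# centered predictor, plus the model SS. Uses trace(SS_model)/trace(SS_total).
shape_size_r2 <- function(yc, xc) {
  ssx <- sum(xc^2)
  b <- crossprod(xc, yc) / ssx               # 1 x p slope vector
  ss_model <- sum(b^2) * ssx
  ss_total <- sum(yc^2)
  c(r2 = ss_model / ss_total, ss_model = ss_model)
}

#' Multivariate regression of shape on log centroid size
#'
#' Least-squares fit of every shape variable on log10 centroid size. The
#' coefficient of determination is `trace(SS_model) / trace(SS_total)`;
#' significance is assessed by permuting the size values.
#'
#' @param shape n x p matrix of shape variables (n >= 4).
#' @param log_sizes Numeric vector of log10 centroid sizes.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional RNG seed.
#' @return Object of class `allometry_fit`: `r_squared`, `p_value`,
#'   `slope` (p-vector of regression coefficients), `n_perm`.
#' @export
shape_size_regression <- function(shape, log_sizes, n_perm = 999L,
                                  seed = NULL) {
  shape <- as.matrix(shape)
  n <- nrow(shape)
  if (n < 4L) stop_mh("need at least 4 specimens")
  if (length(log_sizes) != n) stop_mh("log_sizes length mismatch")
  xc <- log_sizes - mean(log_sizes)
  if (sum(xc^2) == 0) stop_mh("constant size vector: slope undefined")
  yc <- sweep(shape, 2, colMeans(shape))
  obs <- shape_size_r2(yc, xc)
  set_seed_if(seed)
  perm <- vapply(seq_len(n_perm),
                 function(i) shape_size_r2(yc, sample(xc))[["r2"]],
                 numeric(1))
  slope <- as.numeric(crossprod(xc, yc) / sum(xc^2))
  structure(list(r_squared = unname(obs[["r2"]]),
                 p_value = perm_pvalue(perm, obs[["r2"]]),
                 slope = slope, n_perm = n_perm, seed = seed),
            class = "allometry_fit")
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat(sprintf("Shape ~ log10(centroid size): R^2 = %.4f, p = %.4g (%d perms)\n",
              x$r_squared, x$p_value, x$n_perm))
  invisible(x)
}

# Residual sums of squares of the multivariate linear model y ~ X via a
# precomputed thin-Q factor of the design.
rss_from_q <- function(q, y) sum(y^2) - sum(crossprod(q, y)^2)

#' Test of homogeneity of allometric slopes among groups
#'
#' Compares the full model `shape ~ size + group + size:group` to the reduced
#' model `shape ~ size + group` via sums of squared Procrustes deviations,
#' with significance from residual randomization (RRPP): residuals of the
#' reduced model are permuted across specimens and added back to its fitted
#' values. A small p-value means the allometric slopes are NOT parallel.
#'
#' @param shape n x p matrix of shape variables.
#' @param log_sizes Numeric vector of log10 centroid sizes.
#' @param labels Group labels (each group n >= 3).
#' @param n_perm Number of RRPP permutations (default 999).
#' @param seed Optional RNG seed.
#' @return Object of class `slope_homogeneity`: `ss_interaction`, `F`,
#'   `p_value`, `df`.
#' @export
slope_homogeneity <- function(shape, log_sizes, labels, n_perm = 999L,
                              seed = NULL) {
  shape <- as.matrix(shape)
  labels <- factor(labels)
  n <- nrow(shape)
  if (any(table(labels) < 3L)) stop_mh("each group needs n >= 3")
  wsx <- tapply(log_sizes, labels, stats::var)
  if (any(wsx == 0))
    stop_mh("constant size within group(s): ",
            paste(names(which(wsx == 0)), collapse = ", "))
  x_red <- stats::model.matrix(~ log_sizes + labels)
  x_full <- stats::model.matrix(~ log_sizes * labels)
  q_red <- qr.Q(qr(x_red))
  q_full <- qr.Q(qr(x_full))
  df_int <- ncol(x_full) - ncol(x_red)
  df_res <- n - ncol(x_full)
  fitted_red <- q_red %*% crossprod(q_red, shape)
  resid_red <- shape - fitted_red

  stat <- function(y) {
    rss_r <- rss_from_q(q_red, y)
    rss_f <- rss_from_q(q_full, y)
    ss_int <- rss_r - rss_f
    c(ss = ss_int, F = (ss_int / df_int) / (rss_f / df_res))
  }
  obs <- stat(shape)
  set_seed_if(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    stat(fitted_red + resid_red[sample.int(n), , drop = FALSE])[["F"]]
  }, numeric(1))
  structure(list(ss_interaction = unname(obs[["ss"]]), F = unname(obs[["F"]]),
                 p_value = perm_pvalue(perm, obs[["F"]]),
                 df = c(interaction = df_int, residual = df_res),
                 n_perm = n_perm, seed = seed),
            class = "slope_homogeneity")
}

#' @export
print.slope_homogeneity <- function(x, ...) {
  cat(sprintf(paste0("Homogeneity of allometric slopes (RRPP, %d perms):\n",
                     "  size x group: SS = %.4g, F = %.4g, p = %.4g\n"),
              x$n_perm, x$ss_interaction, x$F, x$p_value))
  cat("  (small p: slopes not parallel)\n")
  invisible(x)
}
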