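# Shape-space ordination, group testing and disparity.

#' Principal component analysis of shape variables
#'
#' Eigendecomposition of the specimen covariance of tangent-space shape
#' variables. For 3D Procrustes data at most `min(n - 1, 3k - 7)` axes carry
#' variance.
#'
#' @param shape n x p matrix of shape variables (rows = specimens).
#' @return Object of class `shape_pca`: `eigenvalues` (descending),
#'   `axes` (orthonormal loadings, columns), `scores` (n x m, zero column
#'   means), `variance_fractions` (sums to 1), `center`, `degenerate` flag.
#' @export
shape_pca <- function(shape) {
  shape <- as.matrix(shape)
  if (nrow(shape) < 3L) stop_mh("PCA needs at least 3 specimens")
  pr <- stats::prcomp(shape, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  degenerate <- sum(ev) == 0
  if (degenerate) {
    warn_mh("degenerate sample: all specimens identical")
    vf <- rep(0, length(ev))
  } else vf <- ev / sum(ev)
  structure(list(eigenvalues = ev, axes = pr$rotation, scores = pr$x,
                 variance_fractions = vf, center = pr$center,
                 degenerate = degenerate),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat("Shape PCA:", nrow(x$scores), "specimens,",
      length(x$eigenvalues), "axes\n")
  m <- min(5L, length(x$variance_fractions))
  cat("  variance fractions:",
      paste(format(x$variance_fractions[seq_len(m)], digits = 3),
            collapse = " "),
      if (length(x$variance_fractions) > m) "..." else "", "\n")
  invisible(x)
}

#' @export
plot.shape_pca <- function(x, axes = c(1, 2), groups = NULL, ...) {
  sc <- x$scores[, axes, drop = FALSE]
  col <- if (is.null(groups)) 1 else as.integer(factor(groups))
  graphics::plot(sc, col = col, pch = 19,
                 xlab = sprintf("PC%d (%.1f%%)", axes[1],
                                100 * x$variance_fractions[axes[1]]),
                 ylab = sprintf("PC%d (%.1f%%)", axes[2],
                                100 * x$variance_fractions[axes[2]]), ...)
  if (!is.null(groups))
    graphics::legend("topright", legend = levels(factor(groups)),
                     col = seq_along(levels(factor(groups))), pch = 19)
  invisible(x)
}

#' Leading principal components reaching a variance threshold
#'
#' @param pca A [shape_pca] fit.
#' @param threshold Fraction of total variance to capture (default 0.90).
#' @return Integer indices of the smallest leading axis set whose variance
#'   fractions sum to at least `threshold`.
#' @export
retain_pcs <- function(pca, threshold = 0.90) {
  stopifnot(inherits(pca, "shape_pca"))
  if (threshold <= 0 || threshold > 1)
    stop_mh("threshold must be in (0, 1]")
  nonnull <- which(pca$variance_fractions > .Machine$double.eps * 100)
  if (length(nonnull) == 0L) return(integer(0))
  cum <- cumsum(pca$variance_fractions)
  m <- which(cum >= threshold - 1e-12)[1]
  if (is.na(m)) m <- max(nonnull)
  seq_len(min(m, max(nonnull)))
}

wilks_test <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- factor(labels)
  if (ncol(scores) == 1L) {
    # one response: Wilks' lambda reduces to the classical one-way F test
    fit <- stats::aov(scores[, 1] ~ labels)
    tab <- summary(fit)[[1]]
    return(data.frame(df = tab$Df[1], wilks = NA_real_,
                      approx_F = tab$`F value`[1], num_df = tab$Df[1],
                      den_df = tab$Df[2], p = tab$`Pr(>F)`[1]))
  }
  fit <- stats::manova(scores ~ labels)
  tab <- tryCatch(summary(fit, test = "Wilks")$stats,
                  error = function(e)
                    stop_mh("MANOVA failed (likely singular within-group ",
                            "covariance): ", conditionMessage(e)))
  data.frame(df = tab[1, "Df"], wilks = tab[1, "Wilks"],
             approx_F = tab[1, "approx F"], num_df = tab[1, "num Df"],
             den_df = tab[1, "den Df"], p = tab[1, "Pr(>F)"])
}

#' Pairwise MANOVA on retained principal component scores
#'
#' For each pair of groups, a multivariate location test (Wilks' lambda with
#' its F approximation) on the supplied scores, with optional Bonferroni
#' adjustment over the pairs.
#'
#' @param scores n x m matrix of PC scores (m >= 1).
#' @param labels Group labels (length n, >= 2 groups).
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @return Data frame with one row per group pair: Wilks' lambda, approximate
#'   F, degrees of freedom, `p` and `p_adj`.
#' @export
pairwise_manova <- function(scores, labels,
                            correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  scores <- as.matrix(scores)
  labels <- factor(labels)
  groups <- levels(labels)
  if (length(groups) < 2L) stop_mh("need at least 2 groups")
  m <- ncol(scores)
  small <- table(labels) <= m
  if (any(small))
    stop_mh("group(s) ", paste(names(which(small)), collapse = ", "),
            " have n <= number of retained axes (", m,
            "); lower the retention threshold")
  pairs <- utils::combn(groups, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    sel <- labels %in% c(g1, g2)
    sub <- scores[sel, , drop = FALSE]
    if (sum(apply(sub, 2, stats::var)) == 0) {
      warn_mh("degenerate pair ", g1, "-", g2, ": zero variance")
      return(data.frame(group_1 = g1, group_2 = g2, df = NA, wilks = NA,
                        approx_F = NA, num_df = NA, den_df = NA, p = NA))
    }
    cbind(data.frame(group_1 = g1, group_2 = g2),
          wilks_test(sub, droplevels(labels[sel])))
  }))
  n_pairs <- ncol(pairs)
  out$p_adj <- if (correction == "bonferroni")
    pmin(1, out$p * n_pairs) else out$p
  rownames(out) <- NULL
  out
}

#' Two-way MANOVA for the species-by-sex interaction
#'
#' Crossed two-factor multivariate linear model on PC scores. Geldings (or any
#' levels named in `drop_levels_b`) are removed from the second factor before
#' fitting. A significant interaction signals that species differences in
#' shape are not the same in both sexes, so downstream analyses should be
#' stratified by sex for that bone.
#'
#' @param scores n x m matrix of PC scores.
#' @param factor_a First factor (species/group).
#' @param factor_b Second factor (sex).
#' @param drop_levels_b Levels of `factor_b` excluded before fitting
#'   (default `"gelding"`).
#' @return Data frame with one row per model term (`factor_a`, `factor_b`,
#'   `interaction`) carrying Wilks' lambda, approximate F and `p`.
#' @export
two_way_manova <- function(scores, factor_a, factor_b,
                           drop_levels_b = "gelding") {
  scores <- as.matrix(scores)
  keep <- !(as.character(factor_b) %in% drop_levels_b) & !is.na(factor_b) &
    !is.na(factor_a)
  scores <- scores[keep, , drop = FALSE]
  a <- droplevels(factor(factor_a[keep]))
  b <- droplevels(factor(factor_b[keep]))
  if (nlevels(a) < 2L) stop_mh("factor_a has fewer than 2 observed levels")
  if (nlevels(b) < 2L) stop_mh("factor_b has fewer than 2 observed levels")
  cells <- table(a, b)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop_mh("empty cell(s) in the factor cross: ",
            paste(sprintf("%s x %s", rownames(cells)[empty[, 1]],
                          colnames(cells)[empty[, 2]]), collapse = ", "))
  }
  if (ncol(scores) == 1L) {
    # one response: Wilks reduces to the classical two-way F tests
    tab0 <- stats::anova(stats::lm(scores[, 1] ~ a * b))
    tab <- cbind(Df = tab0$Df, Wilks = NA_real_,
                 `approx F` = tab0$`F value`, `num Df` = tab0$Df,
                 `den Df` = tab0$Df[nrow(tab0)], `Pr(>F)` = tab0$`Pr(>F)`)
    rownames(tab) <- rownames(tab0)
  } else {
    fit <- stats::manova(scores ~ a * b)
    tab <- tryCatch(summary(fit, test = "Wilks")$stats,
                    error = function(e)
                      stop_mh("two-way MANOVA failed: ", conditionMessage(e)))
  }
  terms <- rownames(tab)[seq_len(nrow(tab) - 1L)]
  labels <- c(a = "factor_a", b = "factor_b", `a:b` = "interaction")
  data.frame(term = unname(labels[terms]),
             df = tab[terms, "Df"], wilks = tab[terms, "Wilks"],
             approx_F = tab[terms, "approx F"],
             num_df = tab[terms, "num Df"], den_df = tab[terms, "den Df"],
             p = tab[terms, "Pr(>F)"], row.names = NULL)
}

#' Procrustes variance (morphological disparity) per group
#'
#' Mean squared Euclidean distance of group members to their group mean shape
#' (divisor n, the geomorph convention).
#'
#' @param shape n x p matrix of shape variables.
#' @param labels Group labels.
#' @return Named numeric vector of per-group variances; singleton groups get
#'   `NA` with a warning.
#' @export
procrustes_variance <- function(shape, labels) {
  shape <- as.matrix(shape)
  labels <- factor(labels)
  out <- vapply(levels(labels), function(g) {
    rows <- shape[labels == g, , drop = FALSE]
    if (nrow(rows) < 2L) {
      warn_mh("group '", g, "' is a singleton: Procrustes variance undefined")
      return(NA_real_)
    }
    centered <- sweep(rows, 2, colMeans(rows))
    sum(centered^2) / nrow(rows)
  }, numeric(1))
  out
}

#' Permutation comparison of group disparities
#'
#' Tests, for each pair of groups, the absolute difference of Procrustes
#' variances against a null built by permuting group labels. P-values use the
#' `(count + 1)/(n_perm + 1)` convention and are Bonferroni-adjusted over the
#' pairs.
#'
#' @param shape n x p matrix of shape variables.
#' @param labels Group labels.
#' @param n_perm Number of permutations (>= 99; default 999).
#' @param seed Optional RNG seed.
#' @return Object of class `disparity_test`: `variances` (per group) and
#'   `pairwise` (data frame with observed difference, `p`, `p_adj`).
#' @export
disparity_test <- function(shape, labels, n_perm = 999L, seed = NULL) {
  if (n_perm < 99L) stop_mh("n_perm must be at least 99")
  shape <- as.matrix(shape)
  labels <- factor(labels)
  set_seed_if(seed)
  obs <- procrustes_variance(shape, labels)
  groups <- levels(labels)
  pairs <- utils::combn(groups, 2)
  n_pairs <- ncol(pairs)
  perm_diff <- matrix(NA_real_, n_perm, n_pairs)
  for (b in seq_len(n_perm)) {
    pl <- sample(labels)
    pv <- suppressWarnings(procrustes_variance(shape, pl))
    for (j in seq_len(n_pairs))
      perm_diff[b, j] <- abs(pv[pairs[1, j]] - pv[pairs[2, j]])
  }
  pw <- do.call(rbind, lapply(seq_len(n_pairs), function(j) {
    d_obs <- abs(obs[pairs[1, j]] - obs[pairs[2, j]])
    data.frame(group_1 = pairs[1, j], group_2 = pairs[2, j],
               abs_diff = d_obs, p = perm_pvalue(perm_diff[, j], d_obs))
  }))
  pw$p_adj <- pmin(1, pw$p * n_pairs)
  rownames(pw) <- NULL
  structure(list(variances = obs, pairwise = pw, n_perm = n_perm,
                 seed = seed),
            class = "disparity_test")
}

#' @export
print.disparity_test <- function(x, ...) {
  cat("Morphological disparity (Procrustes variance)\n")
  print(signif(x$variances, 4))
  cat("Pairwise permutation comparisons (", x$n_perm, " permutations):\n",
      sep = "")
  print(x$pairwise, digits = 4)
  invisible(x)
}
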