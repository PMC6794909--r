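# Morphological integration: two-block PLS, permutation tests, effect sizes,
# cross-dataset comparisons and covariation networks over bone pairs.

#' Two-block partial least squares analysis
#'
#' Singular value decomposition of the cross-covariance matrix between two
#' centered blocks of shape variables measured on the same specimens. The
#' first paired singular axes maximize the covariance between block scores;
#' `r_pls`, the Pearson correlation of the first-axis score pair, measures the
#' strength of morphological integration.
#'
#' @param block1,block2 n x p and n x q matrices with matched specimen rows
#'   (row names, when present, are checked; n >= 4).
#' @return Object of class `pls`: `singular_values` (descending),
#'   `covariance_fractions` (squared singular values normalized to sum 1),
#'   `xloadings`, `yloadings` (orthonormal columns), `xscores`, `yscores`,
#'   `r_pls`, `n`.
#' @export
two_block_pls <- function(block1, block2) {
  x <- as.matrix(block1); y <- as.matrix(block2)
  if (nrow(x) != nrow(y))
    stop_mh("blocks have different specimen counts: ", nrow(x), " vs ",
            nrow(y))
  if (!is.null(rownames(x)) && !is.null(rownames(y)) &&
      !identical(rownames(x), rownames(y))) {
    off <- union(setdiff(rownames(x), rownames(y)),
                 setdiff(rownames(y), rownames(x)))
    stop_mh("specimen mismatch between blocks",
            if (length(off)) paste0(": ", paste(off, collapse = ", "))
            else ": same set but different order")
  }
  n <- nrow(x)
  if (n < 4L) stop_mh("need at least 4 specimens")
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  s <- svd(crossprod(xc, yc) / (n - 1))
  pos <- s$d > max(s$d[1], .Machine$double.eps) * 1e-12
  if (!any(pos)) stop_mh("zero cross-covariance between blocks")
  xs <- xc %*% s$u
  ys <- yc %*% s$v
  structure(list(singular_values = s$d,
                 covariance_fractions = s$d^2 / sum(s$d^2),
                 xloadings = s$u, yloadings = s$v,
                 xscores = xs, yscores = ys,
                 r_pls = stats::cor(xs[, 1], ys[, 1]), n = n),
            class = "pls")
}

#' @export
print.pls <- function(x, ...) {
  cat("Two-block PLS:", x$n, "specimens\n")
  cat(sprintf("  rPLS (axis 1) = %.4f\n", x$r_pls))
  m <- min(3L, length(x$covariance_fractions))
  cat("  covariance fractions:",
      paste(format(x$covariance_fractions[seq_len(m)], digits = 3),
            collapse = " "),
      if (length(x$covariance_fractions) > m) "..." else "", "\n")
  if (!is.null(x$p_value))
    cat(sprintf("  permutation p = %.4g, z = %.3f (se %.3f, %d perms)\n",
                x$p_value, x$z_score, x$z_se, x$n_perm))
  invisible(x)
}

#' @export
plot.pls <- function(x, groups = NULL, ...) {
  col <- if (is.null(groups)) 1 else as.integer(factor(groups))
  graphics::plot(x$xscores[, 1], x$yscores[, 1], col = col, pch = 19,
                 xlab = "Block 1, PLS axis 1", ylab = "Block 2, PLS axis 1",
                 ...)
  invisible(x)
}

# First-axis r for permuted block2 rows; shares the centering work.
pls_r_first <- function(xc, yc, n) {
  s <- svd(crossprod(xc, yc) / (n - 1), nu = 1L, nv = 1L)
  stats::cor(xc %*% s$u[, 1], yc %*% s$v[, 1])[1]
}

#' Permutation test and effect size for two-block PLS
#'
#' Rows of the second block are permuted `n_perm` times and the first-axis
#' correlation recomputed, giving the null distribution of `r_pls`. The
#' p-value uses the `(count >= observed + 1)/(n_perm + 1)` convention. The
#' standardized effect size enables comparisons across datasets (see
#' [pls_effect_size()]).
#'
#' @inheritParams two_block_pls
#' @param n_perm Number of permutations (>= 99; default 999).
#' @param seed Optional RNG seed.
#' @return Object of class `c("pls_test", "pls")` extending [two_block_pls()]
#'   with `p_value`, `z_score`, `z_se`, `perm_r` and `n_perm`.
#' @export
pls_permutation_test <- function(block1, block2, n_perm = 999L, seed = NULL) {
  if (n_perm < 99L) stop_mh("n_perm must be at least 99")
  fit <- two_block_pls(block1, block2)
  x <- as.matrix(block1); y <- as.matrix(block2)
  n <- nrow(x)
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  set_seed_if(seed)
  perm_r <- vapply(seq_len(n_perm), function(i) {
    pls_r_first(xc, yc[sample.int(n), , drop = FALSE], n)
  }, numeric(1))
  es <- pls_effect_size(fit$r_pls, perm_r)
  fit$p_value <- perm_pvalue(perm_r, fit$r_pls)
  fit$z_score <- es$z_score
  fit$z_se <- es$z_se
  fit$perm_r <- perm_r
  fit$n_perm <- n_perm
  fit$seed <- seed
  class(fit) <- c("pls_test", "pls")
  fit
}

#' Standardized effect size of an observed rPLS
#'
#' Fisher-transforms the observed and permuted correlations and standardizes
#' the observed value against the permutation null:
#' `z = (t(r_obs) - mean(t(r_perm))) / sd(t(r_perm))`. Because z is a standard
#' deviate of its own null distribution it is comparable across datasets whose
#' raw rPLS values are not (different n and variable counts shift the null).
#' `z_se` is the spread of the standardized null distribution, used by
#' [compare_effect_sizes()].
#'
#' @param r_obs Observed first-axis correlation.
#' @param perm_r Permutation distribution of the correlation (length >= 99).
#' @param transform `"fisher"` (default) or `"none"` (raw r).
#' @return List with `z_score` and `z_se`.
#' @export
pls_effect_size <- function(r_obs, perm_r, transform = c("fisher", "none")) {
  transform <- match.arg(transform)
  if (length(perm_r) < 99L)
    stop_mh("permutation distribution must have at least 99 values")
  t_obs <- if (transform == "fisher") fisher_z(r_obs) else r_obs
  t_perm <- if (transform == "fisher") fisher_z(perm_r) else perm_r
  spread <- stats::sd(t_perm)
  if (spread == 0) stop_mh("zero permutation spread: effect size undefined")
  z_null <- (t_perm - mean(t_perm)) / spread
  list(z_score = (t_obs - mean(t_perm)) / spread,
       z_se = stats::sd(z_null))
}

#' Two-sample comparison of PLS effect sizes
#'
#' Compares the standardized integration strength of two datasets:
#' `|z_a - z_b| / sqrt(se_a^2 + se_b^2)` referred to the standard normal
#' (two-sided).
#'
#' @param result_a,result_b [pls_permutation_test()] fits (or lists carrying
#'   `z_score` and `z_se`).
#' @return List with `statistic` and `p_value`.
#' @export
compare_effect_sizes <- function(result_a, result_b) {
  for (r in list(result_a, result_b))
    if (is.null(r$z_score) || is.null(r$z_se))
      stop_mh("both results must carry z_score and z_se ",
              "(run pls_permutation_test first)")
  stat <- abs(result_a$z_score - result_b$z_score) /
    sqrt(result_a$z_se^2 + result_b$z_se^2)
  list(statistic = stat, p_value = 2 * stats::pnorm(-stat))
}

#' Default anatomical bone-pair sets
#'
#' Three pair families over the 16 equid limb bones: serial homologs
#' (developmentally corresponding fore/hind elements), within-limb adjacent
#' bones (the articulation chains of each limb, with the talus and calcaneus
#' each linked to both the tibia and the metatarsal), and functionally
#' equivalent fore/hind bones. Fully overridable: any data frame with columns
#' `bone_a`, `bone_b`, `pair_set` works downstream.
#'
#' @param bones Restrict pairs to these bones (default: all 16).
#' @return Data frame with columns `bone_a`, `bone_b`, `pair_set`.
#' @export
default_pair_sets <- function(bones = equid_bones()) {
  serial <- rbind(c("scapula", "coxal"), c("humerus", "femur"),
                  c("radio_ulna", "tibia"), c("metacarpal", "metatarsal"),
                  c("phalanx_ant_prox", "phalanx_post_prox"),
                  c("phalanx_ant_mid", "phalanx_post_mid"),
                  c("phalanx_ant_dist", "phalanx_post_dist"))
  fore <- c("scapula", "humerus", "radio_ulna", "metacarpal",
            "phalanx_ant_prox", "phalanx_ant_mid", "phalanx_ant_dist")
  hind <- c("coxal", "femur", "tibia", "metatarsal",
            "phalanx_post_prox", "phalanx_post_mid", "phalanx_post_dist")
  chain <- function(b) cbind(b[-length(b)], b[-1])
  adjacent <- rbind(chain(fore), chain(hind),
                    c("tibia", "talus"), c("tibia", "calcaneus"),
                    c("talus", "metatarsal"), c("calcaneus", "metatarsal"))
  functional <- rbind(c("scapula", "femur"), c("humerus", "tibia"),
                      c("radio_ulna", "metatarsal"))
  df <- rbind(data.frame(bone_a = serial[, 1], bone_b = serial[, 2],
                         pair_set = "serial_homologs"),
              data.frame(bone_a = adjacent[, 1], bone_b = adjacent[, 2],
                         pair_set = "within_limb_adjacent"),
              data.frame(bone_a = functional[, 1], bone_b = functional[, 2],
                         pair_set = "functional_equivalents"))
  df <- df[df$bone_a %in% bones & df$bone_b %in% bones, , drop = FALSE]
  key <- apply(df[, c("bone_a", "bone_b")], 1,
               function(r) paste(sort(r), collapse = "|"))
  df <- df[!duplicated(key), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Covariation network over bone pairs
#'
#' For each analysis group and each bone pair, runs a separate GPA per bone on
#' all specimens carrying that bone, takes the shape variables of the group's
#' specimens common to both bones, and computes the two-block PLS with its
#' permutation test and effect size. P-values are Bonferroni-adjusted within
#' each family of tests sharing a bone: an edge is significant only if it
#' survives in both of its bones' families.
#'
#' @param study A [study_dataset].
#' @param pair_sets Data frame with columns `bone_a`, `bone_b`, `pair_set`
#'   (default [default_pair_sets()] restricted to bones present).
#' @param groups Group labels to analyze (default: all groups present).
#' @param n_perm Permutations per test (default 999).
#' @param seed Seed; deterministically split per group and pair.
#' @param alpha Significance level (default 0.05).
#' @param min_n Minimum shared specimens per pair (default 4).
#' @return Object of class `covariation_network`: `edges`, a data frame with
#'   one row per group x pair (`r_pls`, `p`, `p_adj`, `z`, `z_se`,
#'   `significant`), plus `alpha`, `n_perm`, `seed`. Pairs with too few shared
#'   specimens are skipped with a warning.
#' @export
covariation_network <- function(study, pair_sets = NULL, groups = NULL,
                                n_perm = 999L, seed = NULL, alpha = 0.05,
                                min_n = 4L) {
  stopifnot(inherits(study, "study_dataset"))
  if (is.null(pair_sets)) pair_sets <- default_pair_sets(names(study$bones))
  if (is.null(groups)) groups <- sort(unique(study$specimens$group))
  need <- union(pair_sets$bone_a, pair_sets$bone_b)
  absent <- setdiff(need, names(study$bones))
  if (length(absent)) {
    warn_mh("bone(s) absent from study, pairs skipped: ",
            paste(absent, collapse = ", "))
    pair_sets <- pair_sets[!(pair_sets$bone_a %in% absent |
                               pair_sets$bone_b %in% absent), , drop = FALSE]
  }
  # one GPA per bone, on all specimens of that bone
  fits <- lapply(union(pair_sets$bone_a, pair_sets$bone_b), function(b)
    gpa(study$bones[[b]]))
  names(fits) <- union(pair_sets$bone_a, pair_sets$bone_b)

  rows <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    g_ids <- study$specimens$specimen_id[study$specimens$group == g]
    for (pi in seq_len(nrow(pair_sets))) {
      a <- pair_sets$bone_a[pi]; b <- pair_sets$bone_b[pi]
      ids <- intersect(intersect(rownames(fits[[a]]$shape), g_ids),
                       rownames(fits[[b]]$shape))
      if (length(ids) < min_n) {
        warn_mh("pair ", a, "-", b, " in group '", g, "' has ",
                length(ids), " shared specimens (< ", min_n, "): skipped")
        next
      }
      fit <- pls_permutation_test(fits[[a]]$shape[ids, , drop = FALSE],
                                  fits[[b]]$shape[ids, , drop = FALSE],
                                  n_perm = n_perm,
                                  seed = derive_seed(seed, gi * 1000L + pi))
      rows[[length(rows) + 1L]] <-
        data.frame(group = g, bone_a = a, bone_b = b,
                   pair_set = pair_sets$pair_set[pi], n = length(ids),
                   r_pls = fit$r_pls, p = fit$p_value,
                   z = fit$z_score, z_se = fit$z_se)
    }
  }
  edges <- do.call(rbind, rows)
  if (is.null(edges)) stop_mh("no testable pairs")
  # Bonferroni within each family of tests sharing a bone, per group;
  # an edge must survive in both of its bones' families.
  edges$p_adj <- NA_real_
  edges$significant <- NA
  for (g in unique(edges$group)) {
    sel <- edges$group == g
    fam <- table(c(edges$bone_a[sel], edges$bone_b[sel]))
    m_a <- fam[edges$bone_a[sel]]
    m_b <- fam[edges$bone_b[sel]]
    p_a <- pmin(1, edges$p[sel] * as.numeric(m_a))
    p_b <- pmin(1, edges$p[sel] * as.numeric(m_b))
    edges$p_adj[sel] <- pmax(p_a, p_b)
    edges$significant[sel] <- p_a < alpha & p_b < alpha
  }
  rownames(edges) <- NULL
  structure(list(edges = edges, alpha = alpha, n_perm = n_perm, seed = seed),
            class = "covariation_network")
}

#' @export
print.covariation_network <- function(x, ...) {
  cat("Covariation network (", x$n_perm, " permutations, alpha = ",
      x$alpha, ")\n", sep = "")
  print(x$edges[, c("group", "bone_a", "bone_b", "pair_set", "n", "r_pls",
                    "p_adj", "significant")], digits = 3)
  invisible(x)
}

#' Compare integration effect sizes between groups across a network
#'
#' Two-sample z comparisons ([compare_effect_sizes()]) of the same bone pair
#' between every two groups of a [covariation_network()] fit, with Bonferroni
#' correction over all comparisons in the table.
#'
#' @param network A [covariation_network()] fit.
#' @return Data frame with one row per pair x group comparison: `z_1`, `z_2`,
#'   `statistic`, `p`, `p_adj`.
#' @export
compare_network_effects <- function(network) {
  stopifnot(inherits(network, "covariation_network"))
  e <- network$edges
  key <- paste(e$bone_a, e$bone_b, sep = "|")
  rows <- list()
  for (k in unique(key)) {
    sub <- e[key == k, , drop = FALSE]
    if (nrow(sub) < 2L) next
    cmb <- utils::combn(nrow(sub), 2)
    for (j in seq_len(ncol(cmb))) {
      i1 <- cmb[1, j]; i2 <- cmb[2, j]
      cmp <- compare_effect_sizes(
        list(z_score = sub$z[i1], z_se = sub$z_se[i1]),
        list(z_score = sub$z[i2], z_se = sub$z_se[i2]))
      rows[[length(rows) + 1L]] <-
        data.frame(bone_a = sub$bone_a[i1], bone_b = sub$bone_b[i1],
                   group_1 = sub$group[i1], group_2 = sub$group[i2],
                   z_1 = sub$z[i1], z_2 = sub$z[i2],
                   statistic = cmp$statistic, p = cmp$p_value)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$p_adj <- pmin(1, out$p * nrow(out))
  rownames(out) <- NULL
  out
}

#' Shape changes along the first PLS axis
#'
#' Deforms each block's consensus shape along its first-axis loadings to the
#' requested score quantiles, and reports per-landmark displacement magnitudes
#' between the two extremes (the basis of deformation-intensity figures).
#'
#' @param result A [two_block_pls()] (or [pls_permutation_test()]) fit.
#' @param gpa1,gpa2 The [gpa] fits the two blocks were taken from.
#' @param quantile Score quantile for the extremes (default 0.05: shapes at
#'   the 5% and 95% score quantiles). `0.5` returns (near-)consensus shapes.
#' @return List with elements `block1` and `block2`, each containing
#'   `shape_lo`, `shape_hi` (k x 3 matrices) and `displacement`
#'   (per-landmark norms of `shape_hi - shape_lo`).
#' @export
pls_shape_changes <- function(result, gpa1, gpa2, quantile = 0.05) {
  stopifnot(inherits(result, "pls"), inherits(gpa1, "gpa"),
            inherits(gpa2, "gpa"))
  one <- function(scores, loadings, fit) {
    k <- nrow(fit$consensus)
    lo <- stats::quantile(scores[, 1], quantile)
    hi <- stats::quantile(scores[, 1], 1 - quantile)
    dir <- unflatten_config(loadings[, 1], k)
    shape_lo <- fit$consensus + lo * dir
    shape_hi <- fit$consensus + hi * dir
    disp <- sqrt(rowSums((shape_hi - shape_lo)^2))
    names(disp) <- rownames(fit$consensus)
    list(shape_lo = shape_lo, shape_hi = shape_hi, displacement = disp)
  }
  list(block1 = one(result$xscores, result$xloadings, gpa1),
       block2 = one(result$yscores, result$yloadings, gpa2))
}

#' Export a covariation network as a DOT graph
#'
#' Writes an undirected graph per group; edge width is proportional to rPLS
#' and non-significant edges are drawn dashed (the conventional rendering of
#' covariation diagrams).
#'
#' @param network A [covariation_network()] fit.
#' @param path Output `.dot` file path.
#' @return `path`, invisibly.
#' @export
write_network_dot <- function(network, path) {
  stopifnot(inherits(network, "covariation_network"))
  abb <- bone_abbreviations()
  lab <- function(b) if (b %in% names(abb)) abb[[b]] else b
  lines <- character(0)
  for (g in unique(network$edges$group)) {
    sub <- network$edges[network$edges$group == g, , drop = FALSE]
    lines <- c(lines, sprintf("graph \"%s\" {", g))
    for (i in seq_len(nrow(sub))) {
      style <- if (isTRUE(sub$significant[i])) "solid" else "dashed"
      lines <- c(lines, sprintf(
        "  \"%s\" -- \"%s\" [penwidth=%.2f, style=%s, label=\"%.2f\"];",
        lab(sub$bone_a[i]), lab(sub$bone_b[i]),
        0.5 + 4 * max(sub$r_pls[i], 0), style, sub$r_pls[i]))
    }
    lines <- c(lines, "}")
  }
  writeLines(lines, path)
  invisible(path)
}
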