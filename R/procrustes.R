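# Superimposition core: centroid size, ordinary and generalized Procrustes
# analysis, tangent-space shape variables, Procrustes distances.

#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of the landmarks to their
#' centroid; the standard size measure of geometric morphometrics. Invariant
#' to rotation and translation, linear under isotropic scaling.
#'
#' @param coords k x 3 coordinate matrix (or a [landmark_config]).
#' @return Positive scalar; `0` (with a warning) if all landmarks coincide.
#' @export
centroid_size <- function(coords) {
  if (inherits(coords, "landmark_config")) coords <- coords$coords
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) stop_mh("centroid size needs at least 2 landmarks")
  if (any(!is.finite(coords))) stop_mh("non-finite coordinates")
  centered <- sweep(coords, 2, colMeans(coords))
  cs <- sqrt(sum(centered^2))
  if (cs == 0) warn_mh("degenerate configuration: all landmarks coincident")
  cs
}

center_scale <- function(coords) {
  centered <- sweep(coords, 2, colMeans(coords))
  cs <- sqrt(sum(centered^2))
  if (cs == 0) stop_mh("degenerate configuration: zero centroid size")
  centered / cs
}

#' Ordinary Procrustes superimposition of two configurations
#'
#' Centers both configurations, scales each to unit centroid size, and finds
#' the proper rotation (determinant +1; no reflection) of `b` minimizing the
#' root-summed-squared deviation from `a`.
#'
#' @param a,b k x 3 coordinate matrices (or [landmark_config] objects) with
#'   equal landmark counts.
#' @return Object of class `opa`: `rotation` (3 x 3), `aligned` (the
#'   transformed `b`), `target` (centered, scaled `a`), and `distance`
#'   (symmetric in `a`, `b`).
#' @export
ordinary_procrustes <- function(a, b) {
  if (inherits(a, "landmark_config")) a <- a$coords
  if (inherits(b, "landmark_config")) b <- b$coords
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b)))
    stop_mh("landmark count mismatch: ", nrow(a), " vs ", nrow(b))
  ac <- center_scale(a)
  bc <- center_scale(b)
  rot <- optimal_rotation(ac, bc)
  aligned <- bc %*% rot
  structure(list(rotation = rot, aligned = aligned, target = ac,
                 distance = sqrt(sum((ac - aligned)^2))),
            class = "opa")
}

#' @export
print.opa <- function(x, ...) {
  cat("Ordinary Procrustes fit: distance =", format(x$distance), "\n")
  invisible(x)
}

#' Procrustes distance between two configurations
#'
#' @inheritParams ordinary_procrustes
#' @return Non-negative scalar.
#' @export
procrustes_distance <- function(a, b) ordinary_procrustes(a, b)$distance

#' Generalized Procrustes analysis
#'
#' Iterative superimposition of a sample of configurations: each configuration
#' is centered and scaled to unit centroid size, then rotated (proper
#' rotations only) to the running consensus until the consensus stabilizes.
#' The final consensus is oriented along its principal axes so repeated runs
#' and reordered inputs produce the same orientation. Shape variables are the
#' flattened deviations from the consensus, by default orthogonally projected
#' to the tangent space at the consensus.
#'
#' @param coords k x 3 x n array of configurations (n >= 2), or a list of
#'   [landmark_config] objects.
#' @param max_iter Maximum align-to-consensus iterations (default 100).
#' @param tol Convergence tolerance on the root-mean-square change of the
#'   consensus (default 1e-10).
#' @param projection `"tangent"` (orthogonal projection at the consensus,
#'   default) or `"residual"` (raw Procrustes residuals).
#' @return Object of class `gpa`: `consensus` (k x 3 mean shape, centered at
#'   the origin), `aligned` (k x 3 x n superimposed coordinates, each of unit
#'   centroid size), `csize` (original centroid sizes), `shape` (n x 3k matrix
#'   of shape variables), `iterations`, `converged`, `projection`.
#' @export
gpa <- function(coords, max_iter = 100L, tol = 1e-10,
                projection = c("tangent", "residual")) {
  projection <- match.arg(projection)
  if (is.list(coords) && !is.array(coords)) {
    configs <- coords
    validate_equal_k(configs)
    k <- nrow(configs[[1]]$coords)
    coords <- array(NA_real_, c(k, 3L, length(configs)),
                    dimnames = list(rownames(configs[[1]]$coords),
                                    c("x", "y", "z"),
                                    vapply(configs, `[[`, "", "specimen_id")))
    for (i in seq_along(configs)) coords[, , i] <- configs[[i]]$coords
  }
  dims <- dim(coords)
  if (length(dims) != 3L || dims[2] != 3L)
    stop_mh("coords must be a k x 3 x n array")
  k <- dims[1]; n <- dims[3]
  if (n < 2L) stop_mh("GPA needs at least 2 configurations")
  if (k < 4L) stop_mh("GPA needs at least 4 landmarks")

  csize <- apply(coords, 3, centroid_size)
  x <- array(apply(coords, 3, center_scale), dim = dims,
             dimnames = dimnames(coords))

  ref <- x[, , 1]
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n)) x[, , i] <- x[, , i] %*% optimal_rotation(ref, x[, , i])
    consensus <- apply(x, c(1, 2), mean)
    consensus_scaled <- consensus / sqrt(sum(consensus^2))
    delta <- sqrt(mean((consensus_scaled - ref)^2))
    ref <- consensus_scaled
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warn_mh("GPA did not converge in ", max_iter, " iterations")
  # final alignment to the converged reference; consensus = arithmetic mean
  for (i in seq_len(n)) x[, , i] <- x[, , i] %*% optimal_rotation(ref, x[, , i])
  consensus <- apply(x, c(1, 2), mean)

  # orient along the principal axes of the consensus, with deterministic signs
  rot <- principal_axes_rotation(consensus)
  consensus <- consensus %*% rot
  for (i in seq_len(n)) x[, , i] <- x[, , i] %*% rot

  res <- structure(list(consensus = consensus, aligned = x, csize = csize,
                        shape = NULL, iterations = iter, converged = converged,
                        projection = projection),
                   class = "gpa")
  res$shape <- tangent_project(res, projection)
  res
}

principal_axes_rotation <- function(consensus) {
  e <- eigen(crossprod(consensus), symmetric = TRUE)
  v <- e$vectors
  for (j in 1:3) {
    i <- which.max(abs(consensus %*% v[, j]))
    if ((consensus %*% v[, j])[i] < 0) v[, j] <- -v[, j]
  }
  if (det(v) < 0) v[, 3] <- -v[, 3]
  v
}

#' @export
print.gpa <- function(x, ...) {
  cat("Generalized Procrustes analysis\n")
  cat("  configurations:", dim(x$aligned)[3],
      " landmarks:", dim(x$aligned)[1], "\n")
  cat("  iterations:", x$iterations,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  projection:", x$projection, "\n")
  invisible(x)
}

#' @export
summary.gpa <- function(object, ...) {
  cat("Generalized Procrustes analysis\n")
  print(object)
  d <- sqrt(rowSums(object$shape^2))
  cat("  shape distance to consensus: mean", format(mean(d), digits = 4),
      " max", format(max(d), digits = 4), "\n")
  cat("  centroid size: ", paste(format(range(object$csize), digits = 4),
                                 collapse = " - "), "\n")
  invisible(object)
}

#' Tangent-space shape variables from a GPA fit
#'
#' Flattens the deviations of the aligned configurations from the consensus
#' and (for `projection = "tangent"`) orthogonally projects them onto the
#' tangent space at the consensus. Euclidean distances between rows
#' approximate Procrustes distances for small shape deviations.
#'
#' @param aligned A [gpa] fit.
#' @param projection `"tangent"` or `"residual"`.
#' @return n x 3k matrix of shape variables (rows sum to the zero vector).
#' @export
tangent_project <- function(aligned, projection = c("tangent", "residual")) {
  stopifnot(inherits(aligned, "gpa"))
  projection <- match.arg(projection)
  cvec <- flatten_config(aligned$consensus)
  n <- dim(aligned$aligned)[3]
  v <- t(vapply(seq_len(n),
                function(i) flatten_config(aligned$aligned[, , i]) - cvec,
                numeric(length(cvec))))
  if (projection == "tangent") {
    unit <- cvec / sqrt(sum(cvec^2))
    v <- v - (v %*% unit) %*% t(unit)
  }
  rownames(v) <- dimnames(aligned$aligned)[[3]]
  v
}
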