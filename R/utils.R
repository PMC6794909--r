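# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
flatten_config <- function(x) as.numeric(t(x))

#' @keywords internal
#' @noRd
unflatten_config <- function(v, k) matrix(v, nrow = k, ncol = 3L, byrow = TRUE)

# Deterministic per-stage seed splitting. Keeps derived seeds inside the
# 32-bit integer range required by set.seed().
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) %% 2147483629 + 7919 * (offset %% 251) + offset) %% 2147483629) + 1L
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# Permutation p-value with the +1 correction.
perm_pvalue <- function(perm_stats, observed) {
  (sum(perm_stats >= observed) + 1) / (length(perm_stats) + 1)
}

# Proper rotation (det +1) minimizing || a - b %*% R ||_F for centered a, b.
optimal_rotation <- function(a, b) {
  m <- crossprod(b, a)
  s <- svd(m)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# Random proper rotation from a uniform quaternion.
random_rotation <- function() {
  q <- stats::rnorm(4)
  quaternion_to_rotation(q)
}

quaternion_to_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}

# Fisher's z transformation, clipped away from |r| = 1.
fisher_z <- function(r) {
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  atanh(r)
}

stop_mh <- function(...) stop(..., call. = FALSE)
warn_mh <- function(...) warning(..., call. = FALSE)
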