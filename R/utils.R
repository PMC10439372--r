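#' @keywords internal
"_PACKAGE"

#' Small 3-vector helpers
#'
#' Euclidean norm, normalization, cross product, degree/radian conversion
#' and Rodrigues rotation for the plain numeric 3-vectors (metres) used
#' throughout the geometry and statics code.
#'
#' @param v,a,b,k Numeric 3-vectors (`k` is the rotation axis).
#' @param tol Zero-vector guard for normalization.
#' @param d,r Angles in degrees / radians.
#' @param theta Rotation angle, radians.
#' @return A numeric scalar or 3-vector.
#' @name vec3
NULL

#' @rdname vec3
#' @export
vnorm <- function(v) sqrt(sum(v * v))

#' @rdname vec3
#' @export
unitize <- function(v, tol = 1e-12) {
  n <- vnorm(v)
  if (n < tol) stop("cannot normalize a (near-)zero vector", call. = FALSE)
  v / n
}

#' @rdname vec3
#' @export
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @rdname vec3
#' @export
deg2rad <- function(d) d * pi / 180

#' @rdname vec3
#' @export
rad2deg <- function(r) r * 180 / pi

#' @rdname vec3
#' @export
rotate_about <- function(v, k, theta) {
  k <- unitize(k)
  v * cos(theta) + cross3(k, v) * sin(theta) + k * sum(k * v) * (1 - cos(theta))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Package-scoped counters (attachment clamping warnings etc.)
.cuffmc_state <- new.env(parent = emptyenv())
.cuffmc_state$clamp_count <- 0L

#' Reset and read the attachment-clamp warning counter
#'
#' Perturbed attachment coordinates are clamped to the bone's attachment
#' bounding box (fractions in \[-1, 1\]); each clamp increments a
#' package-level counter so long Monte Carlo runs can report how often the
#' Gaussian tails were truncated.
#'
#' @return `clamp_counter()` returns the current count (integer);
#'   `reset_clamp_counter()` resets it to zero and invisibly returns the
#'   previous value.
#' @export
clamp_counter <- function() .cuffmc_state$clamp_count

#' @rdname clamp_counter
#' @export
reset_clamp_counter <- function() {
  old <- .cuffmc_state$clamp_count
  .cuffmc_state$clamp_count <- 0L
  invisible(old)
}

## Deterministic per-analysis seed derivation, kept below 2^31.
derive_seed <- function(base_seed, species, instance) {
  sp <- match(species, c("human", "chimpanzee"))
  inst <- match(instance, c("early_support", "mid_support", "late_support"))
  if (is.na(sp) || is.na(inst)) stop("unknown species or instance", call. = FALSE)
  as.integer((as.numeric(base_seed) * 97L + sp * 13L + inst) %% 2147483629)
}
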