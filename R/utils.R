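# Unit conventions: geometry in mm at the interface, hemodynamics in SI
# internally, pressures reported in mmHg and flows in L/min.
MMHG_PA <- 133.322
M3S_PER_LMIN <- 1 / 60000

#' Unit conversion helpers
#'
#' Fixed conversion constants used throughout the package:
#' 1 mmHg = 133.322 Pa, 1 L/min = 1/60000 m^3/s.
#'
#' @param x numeric vector.
#' @return numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
mmhg_to_pa <- function(x) x * MMHG_PA

#' @rdname units
#' @export
pa_to_mmhg <- function(x) x / MMHG_PA

#' @rdname units
#' @export
lmin_to_si <- function(x) x * M3S_PER_LMIN

#' @rdname units
#' @export
si_to_lmin <- function(x) x / M3S_PER_LMIN

# Run code with a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Normal draws truncated at +-3 sd, sampled by inverse-CDF so that a single
# runif stream keeps the draw deterministic and rejection-free.
rnorm_trunc3 <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, length.out = n))
  sdv <- cv * mean
  lo <- pnorm(-3)
  u <- runif(n, lo, 1 - lo)
  mean + sdv * qnorm(u)
}

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) abort("cannot normalize a zero-length vector")
  v / n
}

# Row-wise Euclidean norms of a matrix.
row_norms <- function(m) sqrt(rowSums(m^2))

cumulative_arclength <- function(pts) {
  if (nrow(pts) < 2) return(0)
  unname(c(0, cumsum(row_norms(diff(pts)))))
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

stopifnot_positive <- function(value, field) {
  if (!all(is.finite(value)) || any(value <= 0)) {
    abort(sprintf("field '%s' must be finite and > 0", field))
  }
  invisible(value)
}
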