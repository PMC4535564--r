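# Sobol low-discrepancy sequence, dimensions 1..10.
# Direction numbers from the Joe & Kuo table (primitive polynomial degree s,
# coefficient encoding a, initial m_1..m_s); dimension 1 is the van der
# Corput sequence in base 2. 30-bit integers keep bitwXor in range.

.sobol_dirs <- list(
  list(s = 1L, a = 0L, m = c(1L)),            # dim 2
  list(s = 2L, a = 1L, m = c(1L, 3L)),        # dim 3
  list(s = 3L, a = 1L, m = c(1L, 3L, 1L)),    # dim 4
  list(s = 3L, a = 2L, m = c(1L, 1L, 1L)),    # dim 5
  list(s = 4L, a = 1L, m = c(1L, 1L, 3L, 3L)),     # dim 6
  list(s = 4L, a = 4L, m = c(1L, 3L, 5L, 13L)),    # dim 7
  list(s = 5L, a = 2L, m = c(1L, 1L, 5L, 5L, 17L)),# dim 8
  list(s = 5L, a = 4L, m = c(1L, 1L, 5L, 5L, 5L)), # dim 9
  list(s = 5L, a = 7L, m = c(1L, 1L, 7L, 11L, 19L))# dim 10
)

.sobol_bits <- 30L

# direction integers V_k = m_k * 2^(bits-k), k = 1..nbits
.sobol_direction_integers <- function(dim, nbits) {
  if (dim == 1L) {
    m <- rep(1L, nbits)
  } else {
    d <- .sobol_dirs[[dim - 1L]]
    s <- d$s; a <- d$a
    m <- integer(nbits)
    m[seq_len(min(s, nbits))] <- d$m[seq_len(min(s, nbits))]
    if (nbits > s) {
      for (k in (s + 1L):nbits) {
        mk <- bitwXor(m[k - s], bitwShiftL(m[k - s], s))
        if (s > 1L) for (i in seq_len(s - 1L)) {
          if (bitwAnd(bitwShiftR(a, s - 1L - i), 1L) == 1L)
            mk <- bitwXor(mk, bitwShiftL(m[k - i], i))
        }
        m[k] <- mk
      }
    }
  }
  m * 2^(.sobol_bits - seq_len(nbits))
}

#' Sobol low-discrepancy points in the unit hypercube
#'
#' Deterministic quasi-random sequence (indices 1..n of the binary
#' radical-inverse construction; the first point of every dimension is
#' 0.5). Supports up to 10 dimensions, more than enough for the
#' four-parameter material identification this package performs.
#'
#' @param n number of points, >= 1.
#' @param dim dimension, 1..10.
#' @return `n` x `dim` matrix with entries in (0, 1).
#' @export
sobol_points <- function(n, dim) {
  stopifnot(n >= 1, dim >= 1)
  if (dim > 10L)
    stop("sobol_points supports at most 10 dimensions", call. = FALSE)
  n <- as.integer(n)
  nbits <- max(1L, ceiling(log2(n + 1)))
  idx <- seq_len(n)
  bits <- vapply(seq_len(nbits),
                 function(k) bitwAnd(bitwShiftR(idx, k - 1L), 1L),
                 integer(n))
  bits <- matrix(bits, nrow = n)
  out <- matrix(0, n, dim)
  for (d in seq_len(dim)) {
    v <- .sobol_direction_integers(d, nbits)
    x <- integer(n)
    for (k in seq_len(nbits)) {
      on <- bits[, k] == 1L
      if (any(on)) x[on] <- bitwXor(x[on], v[k])
    }
    out[, d] <- x / 2^.sobol_bits
  }
  out
}

#' Sobol design of experiments over parameter bounds
#'
#' Scales a Sobol point set to the (alpha, mu, beta, g_visc) bounds box of
#' a [fit_config()], giving the uniformly spread initial candidate
#' population of the inverse-identification loop.
#'
#' @param config a [fit_config()] carrying the bounds.
#' @param n number of candidates.
#' @return `n` x 4 matrix, columns `alpha`, `mu`, `beta`, `g_visc`, all
#'   rows inside the bounds.
#' @export
sobol_doe <- function(config, n) {
  stopifnot(inherits(config, "fit_config"), n >= 1)
  lo <- config$lower; hi <- config$upper
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(lo >= hi))
    stop("degenerate parameter bounds", call. = FALSE)
  u <- sobol_points(n, length(lo))
  x <- sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
  colnames(x) <- names(lo)
  x
}
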