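# Sobol low-discrepancy sequence, 3 dimensions, 30-bit precision.
# Direction numbers from the Joe-Kuo tables (dimension 2: x+1, m = 1;
# dimension 3: x^2+x+1, m = 1,3); dimension 1 is the van der Corput
# sequence in base 2.

.SOBOL_NBITS <- 30L

# direction numbers v[k, d] as integers (m_k * 2^(nbits - k))
.sobol_directions <- function() {
  nb <- .SOBOL_NBITS
  m <- matrix(0, nrow = nb, ncol = 3)
  m[, 1] <- 1
  # dim 2: s = 1, a = 0
  m[1, 2] <- 1
  for (k in 2:nb) m[k, 2] <- bitwXor(2L * m[k - 1L, 2], m[k - 1L, 2])
  # dim 3: s = 2, a = 1
  m[1, 3] <- 1
  m[2, 3] <- 3
  for (k in 3:nb) {
    m[k, 3] <- bitwXor(bitwXor(2L * m[k - 1L, 3], 4L * m[k - 2L, 3]),
                       m[k - 2L, 3])
  }
  v <- matrix(0, nrow = nb, ncol = 3)
  for (k in seq_len(nb)) v[k, ] <- m[k, ] * 2^(nb - k)
  v
}

# Evaluate an expression with R's RNG seeded locally, restoring global state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Scrambled Sobol points on the unit cube
#'
#' Generates `n` quasi-random points in `[0, 1)^3` from the Sobol sequence
#' (Gray-code construction), scrambled by a random digital shift keyed by
#' `seed`. The index-0 point of the raw sequence is skipped so the
#' unscrambled design never contains the degenerate all-zeros point.
#'
#' @param n number of points (>= 0).
#' @param seed integer seed controlling the digital shift; the same seed
#'   reproduces the same point set bit-exactly.
#' @return numeric matrix with `n` rows and 3 columns, entries in `[0, 1)`.
#' @examples
#' u <- sobol_unit_cube(8, seed = 1)
#' @export
sobol_unit_cube <- function(n, seed = 1L) {
  if (length(n) != 1L || is.na(n) || n < 0) stop("`n` must be >= 0")
  n <- as.integer(n)
  if (n == 0L) return(matrix(numeric(0), ncol = 3))
  v <- .sobol_directions()
  shift <- with_local_seed(seed, {
    as.integer(floor(stats::runif(3) * 2^.SOBOL_NBITS))
  })
  x <- integer(3)                      # raw sequence state at index 0
  out <- matrix(0, nrow = n, ncol = 3)
  for (i in seq_len(n)) {
    # lowest zero bit of (index - 1); indices run 1..n (index 0 skipped)
    j <- i - 1L
    c_bit <- 1L
    while (bitwAnd(j, 1L) == 1L) {
      j <- bitwShiftR(j, 1L)
      c_bit <- c_bit + 1L
    }
    for (d in 1:3) x[d] <- bitwXor(x[d], as.integer(v[c_bit, d]))
    out[i, ] <- bitwXor(x, shift) / 2^.SOBOL_NBITS
  }
  out
}
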