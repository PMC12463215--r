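# Gray-code Sobol sequence, direction numbers from the Joe-Kuo table
# (new-joe-kuo-6) for the first five dimensions. Dimension 1 is the van der
# Corput sequence in base 2.
SOBOL_DEF <- list(
  list(s = 1, a = 0, m = c(1)),        # dim 2
  list(s = 2, a = 1, m = c(1, 3)),     # dim 3
  list(s = 3, a = 1, m = c(1, 3, 1)),  # dim 4
  list(s = 3, a = 2, m = c(1, 1, 1))   # dim 5
)
SOBOL_BITS <- 30L

# Direction integers v_j * 2^SOBOL_BITS for one dimension.
sobol_directions <- function(def) {
  nb <- SOBOL_BITS
  if (is.null(def)) return(2^(nb - seq_len(nb)))  # dim 1
  s <- def$s; a <- def$a; m <- def$m
  mm <- numeric(nb)
  mm[seq_len(s)] <- m
  if (nb > s) {
    for (j in (s + 1):nb) {
      val <- bitwXor2(mm[j - s], mm[j - s] * 2^s)
      if (s > 1) {
        for (k in seq_len(s - 1)) {
          a_k <- bitwAnd(bitwShiftR(a, s - 1 - k), 1)  # coefficient a_k
          if (a_k == 1)
            val <- bitwXor2(val, mm[j - k] * 2^k)
        }
      }
      mm[j] <- val
    }
  }
  mm * 2^(nb - seq_len(nb))
}

# XOR for doubles holding nonnegative integers < 2^31 would overflow bitwXor
# at bit 30 shifts; do it via 32-bit ints when safe, else manual.
bitwXor2 <- function(x, y) {
  if (x < 2^31 && y < 2^31) return(bitwXor(as.integer(x), as.integer(y)))
  # manual xor on doubles (up to 2^53)
  r <- 0; b <- 1
  while (x > 0 || y > 0) {
    xb <- x %% 2; yb <- y %% 2
    if (xb != yb) r <- r + b
    x <- x %/% 2; y <- y %/% 2; b <- b * 2
  }
  r
}

#' Sobol quasi-random points
#'
#' Unscrambled Sobol sequence (Gray-code construction, Joe-Kuo direction
#' numbers) in up to 5 dimensions. The sequence starts at the origin point,
#' matching the standard convention.
#'
#' @param n Number of points.
#' @param d Dimension (1..5).
#' @param skip Number of initial points to skip.
#' @return An `n x d` matrix of points in `[0,1)`.
#' @export
sobol_points <- function(n, d = 5, skip = 0) {
  stopifnot(n >= 1, d >= 1, d <= 5)
  dirs <- lapply(seq_len(d), function(j)
    sobol_directions(if (j == 1) NULL else SOBOL_DEF[[j - 1]]))
  total <- n + skip
  x <- matrix(0, total, d)
  state <- numeric(d)
  for (i in seq_len(total - 1)) {
    c_i <- 1L
    ii <- i - 1
    while (ii %% 2 == 1) { ii <- ii %/% 2; c_i <- c_i + 1L }
    for (j in seq_len(d)) {
      state[j] <- bitwXor2(state[j], dirs[[j]][c_i])
      x[i + 1, j] <- state[j] / 2^SOBOL_BITS
    }
  }
  x[(skip + 1):total, , drop = FALSE]
}

# Free-parameter ranges of the simulation ensemble.
PARAM_RANGES <- data.frame(
  name = c("tau", "omega_t", "omega_p", "shape", "scale"),
  min = c(0.5, 0.05, 0.05, 2, 100),
  max = c(3, 0.25, 0.25, 3, 600)
)
SIGMA_FIXED <- 0.005

#' Sample ensemble parameter draws by Sobol sequence
#'
#' Draws the five free simulation parameters — divergence threshold `tau`
#' (Myr), thermal and precipitation niche widths `omega_t`, `omega_p`
#' (normalized units), dispersal kernel shape and scale (km) — from a Sobol
#' sequence scaled to their ranges (tau 0.5-3, widths 0.05-0.25, shape 2-3,
#' scale 100-600). The evolutionary step `sigma` is fixed at 0.005.
#'
#' @param n Number of draws.
#' @param skip Points of the sequence to skip (0 starts at the origin point);
#'   deterministic — equal `skip` always yields the same draws.
#' @return Data frame with columns `tau`, `omega_t`, `omega_p`, `shape`,
#'   `scale`, `sigma`.
#' @export
sample_parameters <- function(n, skip = 0) {
  stopifnot(n >= 1)
  u <- sobol_points(n, d = 5, skip = skip)
  out <- as.data.frame(
    sweep(sweep(u, 2, PARAM_RANGES$max - PARAM_RANGES$min, `*`),
          2, PARAM_RANGES$min, `+`))
  names(out) <- PARAM_RANGES$name
  out$sigma <- SIGMA_FIXED
  out
}
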