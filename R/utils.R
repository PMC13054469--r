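# Internal helpers: condition signalling, seeded RNG scope, FFT utilities.

# Signal a classed error so callers can condition on failure modes
# (e.g. "needletrack_insufficient_observations") rather than match messages.
stop_needletrack <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("needletrack_", class), "needletrack_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Evaluate code under a fixed RNG seed without disturbing the caller's RNG
# state (simulation outputs are reproducible, the session stream is untouched).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Smallest power of two >= n (FFT-friendly padding).
next_pow2 <- function(n) {
  2^ceiling(log2(max(1, n)))
}

# FFT-bin frequencies in MHz for an even or odd length grid.
fft_freqs <- function(n, sample_rate) {
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)
  if (n == 1) k <- 0
  k / n * sample_rate
}

# Analytic signal via the one-sided spectrum (Hilbert-transform construction).
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0L) stop_needletrack("invalid_signal", "empty signal")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

vec_norm <- function(v) sqrt(sum(v^2))
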