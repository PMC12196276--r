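# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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

# Deterministic per-subject substream seed, kept below .Machine$integer.max.
substream_seed <- function(seed, index, stream = 0L) {
  ((as.numeric(seed) * 1009 + index * 7919 + stream * 104729) %% 2147483629) + 1
}

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

# Linear convolution of a real series with a complex kernel via FFT,
# returning the "same"-length central part (kernel assumed odd-length,
# centered).
conv_same <- function(x, kernel) {
  nx <- length(x)
  nk <- length(kernel)
  stopifnot(nk %% 2L == 1L)
  nfft <- stats::nextn(nx + nk - 1L, 2L)
  X <- stats::fft(c(x, rep(0, nfft - nx)))
  K <- stats::fft(c(kernel, rep(0 + 0i, nfft - nk)))
  full <- stats::fft(X * K, inverse = TRUE) / nfft
  half <- (nk - 1L) %/% 2L
  full[(half + 1L):(half + nx)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cmc <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "cmcgait_error")))
}
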