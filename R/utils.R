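# Internal numeric helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
}

# Centered moving-average smoothing, edges padded by replication.
smooth_ma <- function(x, k = 5L) {
  n <- length(x)
  if (n == 0L || k <= 1L) return(x)
  k <- min(k, n)
  half <- (k - 1L) %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[n], k - 1L - half))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 1L))[(k - 1L + 1L):(k - 1L + n)]
}

# Magnitude of the analytic signal (FFT construction of the Hilbert transform).
analytic_envelope <- function(x) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Min-max normalization onto [0, 1]; a constant series maps to all zeros.
minmax_norm <- function(x) {
  r <- range(x)
  if (!is.finite(r[1L]) || r[2L] - r[1L] <= 0) return(rep(0, length(x)))
  (x - r[1L]) / (r[2L] - r[1L])
}

# Linear resampling of a series onto `n_out` points.
resample_series <- function(x, n_out) {
  n <- length(x)
  if (n == 0L) return(rep(0, n_out))
  if (n == 1L) return(rep(x, n_out))
  stats::approx(seq(0, 1, length.out = n), x, xout = seq(0, 1, length.out = n_out))$y
}

db_to_amp <- function(db) 10 ^ (db / 20)
amp_to_db <- function(a) 20 * log10(a)

`%||%` <- function(a, b) if (is.null(a)) b else a
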