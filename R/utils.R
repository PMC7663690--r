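# Internal helpers shared across modules.

# Evaluate expr with a temporarily seeded RNG, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Trapezoidal integral of y over x (both numeric, same length).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

# Hann window of length n (periodic form is unnecessary here; symmetric).
hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
}

# One-sided windowed periodogram. Mean is removed; scaling is such that the
# integral of `power` over `f` approximates the signal variance, so a
# sinusoid of amplitude A carries band-integrated power A^2/2.
periodogram <- function(x, fs, window = c("hann", "rect")) {
  window <- match.arg(window)
  n <- length(x)
  stopifnot(n >= 8L)
  x <- x - mean(x)
  w <- if (window == "hann") hann_window(n) else rep(1, n)
  X <- stats::fft(x * w)
  nk <- floor(n / 2) + 1L
  p <- Mod(X[seq_len(nk)])^2 / (fs * sum(w^2))
  # double interior bins to fold negative frequencies into the one-sided form
  if (nk > 2L) {
    last <- if (n %% 2 == 0) nk - 1L else nk
    p[2L:last] <- 2 * p[2L:last]
  }
  list(f = (seq_len(nk) - 1L) * fs / n, power = p, fs = fs, n = n,
       window = window)
}

# Indices of strict local maxima of x (plateaus: first sample of the run).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2L:(n - 1L)
  which(x[i] > x[i - 1L] & x[i] >= x[i + 1L]) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
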