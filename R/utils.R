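#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so package functions are deterministic without
#' clobbering the caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# root-mean-square
rms <- function(x) sqrt(mean(x^2))

# population (1/n) standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# truncated-normal draws by rejection (bounds generous, acceptance is high)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * (n - length(out)) + 8, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

# single-sided periodogram peak frequency (rectangular window)
dominant_frequency <- function(x, fs) {
  n <- length(x)
  p <- Mod(fft(x))^2
  half <- p[seq_len(floor(n / 2) + 1)]
  half[1] <- 0  # ignore DC
  (which.max(half) - 1) * fs / n
}
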