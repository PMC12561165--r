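# Independent oracles shared across test files. These deliberately avoid the
# package's own computation paths.

# Direct discretization of the S-transform integral: time-domain Gaussian
# window of std 1/f (N/n in bins), periodized over +-20 record lengths and
# summed explicitly.
st_direct_sum <- function(x, fs, f_max) {
  N <- length(x); tj <- 0:(N - 1)
  freqs <- 0:f_max
  S <- matrix(0 + 0i, length(freqs), N)
  S[1, ] <- mean(x)
  for (r in seq_along(freqs)[-1]) {
    n <- round(freqs[r] * N / fs)
    xe <- x * exp(-2i * pi * n * tj / N)
    W <- matrix(0, N, N)
    for (rep in -20:20) {
      dt <- outer(0:(N - 1), tj, "-") + rep * N
      W <- W + (n / (N * sqrt(2 * pi))) * exp(-dt^2 * n^2 / (2 * N^2))
    }
    S[r, ] <- W %*% xe
  }
  S
}

# Brute-force DTW: recursively enumerate every monotone alignment path.
dtw_brute <- function(a, b) {
  rec <- function(i, j) {
    cost <- abs(a[i] - b[j])
    if (i == 1 && j == 1) return(cost)
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    cost + best
  }
  rec(length(a), length(b))
}
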