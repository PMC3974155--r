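# Internal helpers shared across modules.
#
# Time convention: timestamps are seconds from session start; analysis windows
# are given in milliseconds and converted here, once.  Every window is
# half-open [a, b): a sample or spike at time t belongs to the window iff
# a <= t < b.

ms_to_s <- function(ms) ms / 1000

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
#' @noRd
in_window <- function(t, a, b) t >= a & t < b

# Count events (e.g. spikes) in the half-open window [a, b) of a sorted
# vector, via binary search.  O(log n) per window.
count_in_window <- function(sorted_t, a, b) {
  findInterval(b, sorted_t, left.open = TRUE) -
    findInterval(a, sorted_t, left.open = TRUE)
}

# Indices of the samples of a uniformly sampled signal (first sample at t0,
# rate fs) falling in [a, b).  Sample k (1-based) sits at t0 + (k - 1) / fs.
sample_index_range <- function(a, b, t0, fs, n) {
  lo <- ceiling((a - t0) * fs - 1e-9) + 1
  hi <- ceiling((b - t0) * fs - 1e-9)        # last sample with t < b
  lo <- max(lo, 1L)
  hi <- min(hi, n)
  if (hi < lo) return(integer(0))
  seq.int(lo, hi)
}

# Discrete Gaussian kernel on a 1-unit grid, truncated at +/- 4 sigma and
# normalized to sum 1 (so convolution preserves area on interior bins).
gaussian_kernel <- function(sigma, step = 1) {
  half <- max(1L, ceiling(4 * sigma / step))
  x <- seq(-half, half) * step
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# "Same"-length convolution with a symmetric normalized kernel.
smooth_same <- function(x, kernel) {
  half <- (length(kernel) - 1L) / 2L
  padded <- c(rep(x[1], half), x, rep(x[length(x)], half))
  stats::convolve(padded, rev(kernel), type = "filter")
}

# Derive a reproducible child seed for a named stage from a top-level seed.
# Keeps the result a positive 32-bit integer.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483647) + 1L
}

stop_bfc <- function(...) stop(sprintf(...), call. = FALSE)
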