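# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# Exhaustive peak scan: every sample is tested as a candidate local
# maximum (plateaus reported at their first sample), prominence found by
# walking sample-by-sample to higher ground on each side.
oracle_detect <- function(v, threshold = 0.09, prominence = 0.09) {
  n <- length(v)
  hits <- data.frame(frame = integer(), amplitude = numeric(),
                     prominence = numeric())
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[i]) j <- j + 1L
      if (j < n && v[j + 1L] < v[i]) {
        h <- v[i]
        # left walk
        lmin <- h
        k <- i - 1L
        while (k >= 1L && v[k] <= h) {
          if (v[k] < lmin) lmin <- v[k]
          k <- k - 1L
        }
        if (k < 1L) lmin <- min(v[1:(i - 1L)])
        # right walk
        rmin <- h
        k <- j + 1L
        while (k <= n && v[k] <= h) {
          if (v[k] < rmin) rmin <- v[k]
          k <- k + 1L
        }
        if (k > n) rmin <- min(v[(j + 1L):n])
        prom <- h - max(lmin, rmin)
        if (h >= threshold && prom >= prominence)
          hits <- rbind(hits, data.frame(frame = i, amplitude = h,
                                         prominence = prom))
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  hits
}

# Per-level counting oracle for the cumulative-length curve.
oracle_cumlen <- function(profile, levels, pixel_len) {
  out <- numeric(length(levels))
  for (k in seq_along(levels)) {
    cnt <- 0L
    for (p in profile) if (p >= levels[k]) cnt <- cnt + 1L
    out[k] <- cnt * pixel_len
  }
  out
}

# Sort-and-interpolate percentile (linear interpolation between order
# statistics), written out longhand.
oracle_percentile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[min(lo + 2, length(s))] - s[lo + 1])
}

# Pearson r through the raw covariance sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  sxy / sqrt(sxx * syy)
}

# A varied random dF/F-like trace: coloured noise plus a few rendered
# bumps, exercising sub-threshold wiggles and overlapping peaks.
random_trace <- function(n = 150, seed = 1) {
  set.seed(seed)
  noise <- as.numeric(stats::filter(stats::rnorm(n, 0, 0.12),
                                    rep(1 / 3, 3), sides = 2))
  noise[is.na(noise)] <- 0
  tt <- (seq_len(n) - 1) / 31
  for (k in seq_len(sample(0:3, 1))) {
    t0 <- stats::runif(1, 0, max(tt))
    a <- stats::runif(1, 0.05, 1.5)
    noise <- noise + a * calcium_kernel(tt - t0)
  }
  noise
}
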