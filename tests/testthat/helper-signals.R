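# Shared helpers for the test suite: quick signal builders, band
# energies, and a memoised full-pipeline cohort shared by the
# evaluation and acceptance tests.

rms <- function(v) sqrt(mean(v^2))

tone <- function(freq_hz, fs = 1024, dur_s = 20, amp = 1) {
  amp * sin(2 * pi * freq_hz * (0:(dur_s * fs - 1)) / fs)
}

band_energy_frac <- function(x, fs, f_lo, f_hi) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), plot = FALSE,
                          taper = 0)
  sum(sp$spec[sp$freq >= f_lo & sp$freq <= f_hi]) / sum(sp$spec)
}

bandpass_aa <- function(x, fs = 1024) {
  zero_phase_filter(x, signal::butter(4, c(4, 8) / (fs / 2), "pass"))
}

# direct Haar analysis-matrix oracle for dyadic lengths: rows are the
# scaled sums/differences applied recursively to the running
# approximation; returns coefficients ordered (d1, d2, ..., dN, aN)
haar_matrix_coeffs <- function(x) {
  a <- x
  out <- list()
  lev <- 0L
  while (length(a) > 1L) {
    lev <- lev + 1L
    half <- length(a) / 2
    S <- matrix(0, half, length(a))
    D <- matrix(0, half, length(a))
    for (i in seq_len(half)) {
      S[i, 2 * i - 1] <- S[i, 2 * i] <- 1 / sqrt(2)
      D[i, 2 * i - 1] <- 1 / sqrt(2)
      D[i, 2 * i] <- -1 / sqrt(2)
    }
    out[[lev]] <- as.numeric(D %*% a)
    a <- as.numeric(S %*% a)
  }
  c(out, list(a))
}

# Full-pipeline study cohort (25 organized vs 25 disorganized), scored
# once per test run and shared between the evaluation and acceptance
# tests. Built lazily on first use.
.cohort_cache <- new.env(parent = emptyenv())

cohort_experiment <- function(seed = 7) {
  key <- paste0("ex", seed)
  if (is.null(.cohort_cache[[key]])) {
    coh <- synthesize_cohort(25, 25, seed = seed)
    .cohort_cache[[key]] <- run_experiment(coh$records, coh$labels,
                                           seed = seed)
  }
  .cohort_cache[[key]]
}
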