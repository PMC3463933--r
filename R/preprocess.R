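# Signal conditioning ahead of QRST cancellation: zero-phase baseline
# removal, high-frequency lowpass, and powerline notch.

#' Zero-phase IIR filtering
#'
#' Applies a `signal` filter object forward and backward (squaring the
#' magnitude response, cancelling the phase) with reflect padding at
#' both ends to suppress edge transients.
#'
#' @param x numeric vector.
#' @param filt a filter object from e.g. [signal::butter()], or a list
#'   with elements `b` and `a`.
#' @param pad padding length in samples; default the signal length,
#'   capped at 8192.
#' @param reflection `"odd"` (default) mirrors the signal through each
#'   endpoint value, preserving value and slope -- right for
#'   DC-blocking filters (highpass, notch), whose resonances a slope
#'   kink would excite. `"even"` mirrors without the flip, keeping the
#'   pad at the signal's own level -- right for DC-passing filters
#'   (lowpass), where an odd pad's shifted level would smear back into
#'   the record.
#' @return Filtered vector, same length as `x`.
#' @export
zero_phase_filter <- function(x, filt, pad = NULL,
                              reflection = c("odd", "even")) {
  reflection <- match.arg(reflection)
  n <- length(x)
  if (is.null(pad)) pad <- min(n - 1L, 8192L)
  pad <- max(1L, min(pad, n - 1L))
  left <- rev(x[2:(pad + 1)])
  right <- rev(x[(n - pad):(n - 1)])
  xe <- if (reflection == "odd")
    c(2 * x[1] - left, x, 2 * x[n] - right)
  else c(left, x, right)
  y <- .iir_steady(filt, xe)
  y <- rev(.iir_steady(filt, rev(y)))
  y[(pad + 1):(pad + n)]
}

# single-pass IIR with the filter initialized in steady state at the
# first sample, so a pad whose level differs from the signal mean does
# not launch a step transient
.iir_steady <- function(filt, x) {
  b <- filt$b
  a <- filt$a
  dc <- sum(b) / sum(a)
  y0 <- x[1] * dc
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x[1], length(b) - 1L),
                            init.y = rep(y0, length(a) - 1L)))
}

.check_record_length <- function(rec, f_edge, what) {
  # require ~3 impulse-response lengths (one cutoff period each)
  need <- ceiling(3 * rec$fs_hz / f_edge)
  if (length(rec$samples) < need)
    stop(what, ": record too short (", length(rec$samples),
         " samples) for a ", f_edge, " Hz edge at ", rec$fs_hz,
         " Hz; need >= ", need, " samples -- pad or use a longer excerpt",
         call. = FALSE)
}

#' Remove baseline wander
#'
#' Zero-phase highpass (4th-order Butterworth, -3 dB at 0.5 Hz) applied
#' forward/backward, removing respiratory and electrode-drift baseline
#' wander while leaving the 4-8 Hz atrial band untouched.
#'
#' @param rec an `ecg_record` (fs > 1 Hz).
#' @param cutoff_hz highpass edge; default 0.5 Hz.
#' @return Filtered `ecg_record`.
#' @export
remove_baseline <- function(rec, cutoff_hz = 0.5) {
  stopifnot(inherits(rec, "ecg_record"))
  if (rec$fs_hz <= 1) stop("sampling rate must exceed 1 Hz")
  .check_record_length(rec, cutoff_hz, "remove_baseline")
  hp <- signal::butter(4, cutoff_hz / (rec$fs_hz / 2), type = "high")
  rec$samples <- zero_phase_filter(rec$samples, hp)
  rec$stage <- "filtered"
  rec
}

#' Remove high-frequency noise
#'
#' Zero-phase lowpass (4th-order Butterworth, -3 dB at 70 Hz).
#'
#' @param rec an `ecg_record`.
#' @param cutoff_hz lowpass edge; default 70 Hz (must be below Nyquist).
#' @return Filtered `ecg_record`.
#' @export
remove_highfreq <- function(rec, cutoff_hz = 70) {
  stopifnot(inherits(rec, "ecg_record"))
  if (cutoff_hz >= rec$fs_hz / 2)
    stop("lowpass cutoff must be below the Nyquist rate")
  lp <- signal::butter(4, cutoff_hz / (rec$fs_hz / 2), type = "low")
  rec$samples <- zero_phase_filter(rec$samples, lp,
                                   pad = min(length(rec$samples) - 1L,
                                             2048L),
                                   reflection = "even")
  rec$stage <- "filtered"
  rec
}

#' Remove powerline interference
#'
#' Zero-phase second-order IIR notch (constrained biquad, quality
#' factor 30) centred on the mains frequency.
#'
#' @param rec an `ecg_record`.
#' @param mains_hz mains frequency; 50 Hz default, 60 Hz supported.
#' @param q notch quality factor (centre / -3 dB width).
#' @return Filtered `ecg_record`.
#' @export
remove_powerline <- function(rec, mains_hz = 50, q = 30) {
  stopifnot(inherits(rec, "ecg_record"))
  if (mains_hz >= rec$fs_hz / 2)
    stop("mains_hz must be below the Nyquist rate (",
         rec$fs_hz / 2, " Hz)")
  w0 <- 2 * pi * mains_hz / rec$fs_hz
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  flt <- signal::Arma(b = b, a = a)
  rec$samples <- zero_phase_filter(rec$samples, flt,
                                   pad = min(length(rec$samples) - 1L,
                                             4096L))
  rec$stage <- "filtered"
  rec
}

#' Full preprocessing chain
#'
#' Resamples to the analysis rate when needed, then applies the three
#' conditioning filters in order: baseline highpass, 70 Hz lowpass,
#' mains notch.
#'
#' @param rec an `ecg_record`.
#' @param analysis_fs_hz target analysis rate (default 1024 Hz).
#' @param mains_hz mains frequency for the notch (default 50 Hz).
#' @return Conditioned `ecg_record`, stage `"filtered"`.
#' @export
preprocess_chain <- function(rec, analysis_fs_hz = 1024, mains_hz = 50) {
  stopifnot(inherits(rec, "ecg_record"))
  if (length(rec$samples) < 2) stop("record is empty or degenerate")
  if (!isTRUE(all.equal(rec$fs_hz, analysis_fs_hz)))
    rec <- resample_record(rec, analysis_fs_hz)
  rec <- remove_baseline(rec)
  rec <- remove_highfreq(rec)
  rec <- remove_powerline(rec, mains_hz = mains_hz)
  rec
}
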