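# Synthetic AF-like signal generation: atrial f waves with a tunable
# organization level, a ventricular QRST train at irregular RR
# intervals, and the usual recording nuisances (baseline wander,
# powerline, broadband noise). Gives every downstream stage a
# ground-truth input.

#' Specify a synthetic atrial-activity signal
#'
#' The f-wave model is a harmonic sawtooth-like series at
#' `fundamental_freq_hz` with slow sinusoidal frequency modulation,
#' linearly mixed with band-limited (3-12 Hz) filtered noise. The
#' mixing weight of the deterministic part is `organization`; of the
#' stochastic part, `1 - organization`. At `organization = 1` the
#' output is fully deterministic; at 0 it is pure band-limited noise.
#'
#' Defaults put the fundamental at 6 Hz, the middle of the 4-8 Hz band
#' where fibrillatory waves concentrate, with three decaying harmonics
#' (the classic sawtooth-like f-wave shape), a slow 0.1 Hz / 0.5 Hz-deep
#' frequency wobble, and a 0.1 mV peak amplitude typical of V1 f waves.
#'
#' @param fundamental_freq_hz nominal f-wave rate (Hz).
#' @param n_harmonics number of harmonics (>= 1), amplitude decaying 1/h.
#' @param organization real in \[0, 1\]; 1 = fully regular f waves,
#'   0 = broadband (band-limited) noise.
#' @param fm_hz slow frequency-modulation rate (Hz).
#' @param fm_dev_hz peak frequency deviation (Hz).
#' @param amp_mV peak amplitude (mV, >= 0).
#' @param duration_s duration (s, > 0).
#' @param fs_hz sampling rate (Hz, > 0).
#' @param seed integer seed for the stochastic component.
#' @return Object of class `aa_synth_spec`.
#' @export
aa_synth_spec <- function(fundamental_freq_hz = 6, n_harmonics = 3L,
                          organization = 0.5, fm_hz = 0.1,
                          fm_dev_hz = 0.5, amp_mV = 0.1,
                          duration_s = 30, fs_hz = 1024, seed = 1L) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be > 0")
  if (!is.numeric(fs_hz) || fs_hz <= 0) stop("fs_hz must be > 0")
  if (!is.numeric(amp_mV) || amp_mV < 0) stop("amp_mV must be >= 0")
  if (organization < 0 || organization > 1)
    stop("organization must lie in [0, 1]")
  if (n_harmonics < 1) stop("n_harmonics must be >= 1")
  structure(
    list(fundamental_freq_hz = fundamental_freq_hz,
         n_harmonics = as.integer(n_harmonics),
         organization = organization, fm_hz = fm_hz,
         fm_dev_hz = fm_dev_hz, amp_mV = amp_mV,
         duration_s = duration_s, fs_hz = fs_hz, seed = as.integer(seed)),
    class = "aa_synth_spec")
}

#' Synthesize an atrial-activity signal
#'
#' @param spec an [aa_synth_spec()].
#' @return An `aa_signal` of `round(duration_s * fs_hz)` samples, scaled
#'   to `amp_mV` peak.
#' @export
synthesize_aa <- function(spec) {
  stopifnot(inherits(spec, "aa_synth_spec"))
  n <- round(spec$duration_s * spec$fs_hz)
  t <- (seq_len(n) - 1) / spec$fs_hz
  # instantaneous frequency f0 + dev*sin(2 pi fm t); integrate for phase
  phase <- spec$fundamental_freq_hz * t
  if (spec$fm_hz > 0 && spec$fm_dev_hz > 0)
    phase <- phase - spec$fm_dev_hz / (2 * pi * spec$fm_hz) *
      (cos(2 * pi * spec$fm_hz * t) - 1)
  det_part <- numeric(n)
  for (h in seq_len(spec$n_harmonics))
    det_part <- det_part + sin(2 * pi * h * phase) / h
  stoch_part <- numeric(n)
  if (spec$organization < 1) {
    stoch_part <- withr::with_seed(spec$seed, stats::rnorm(n))
    stoch_part <- .bandpass_3_12(stoch_part, spec$fs_hz)
  }
  # mix equal-power components so the organization weight is an energy
  # ratio, then scale the mixture to the requested peak amplitude
  unit_rms <- function(v) { r <- sqrt(mean(v^2)); if (r > 0) v / r else v }
  x <- spec$organization * unit_rms(det_part) +
    (1 - spec$organization) * unit_rms(stoch_part)
  pk <- max(abs(x))
  if (pk > 0) x <- x / pk * spec$amp_mV
  aa_signal(x, spec$fs_hz, source_record_id = "synthetic-aa")
}

.bandpass_3_12 <- function(x, fs) {
  bp <- signal::butter(2, c(3, 12) / (fs / 2), type = "pass")
  zero_phase_filter(x, bp)
}

#' Specify a synthetic AF-like ECG
#'
#' Additive model: atrial activity from [synthesize_aa()], a ventricular
#' train (Gaussian-shaped QRS of about 80 ms width plus a smoother T
#' wave per beat) at RR intervals drawn i.i.d. from a gamma distribution
#' (mean `mean_rr_s`, coefficient of variation `rr_cv` -- the
#' "absolutely arrhythmic" RR irregularity of AF), a baseline-wander
#' sinusoid, a powerline sinusoid, and white noise.
#'
#' @param aa an [aa_synth_spec()] for the atrial component.
#' @param mean_rr_s mean RR interval (s); default 0.6 (100 bpm, typical
#'   of AF).
#' @param rr_cv coefficient of variation of the RR intervals.
#' @param qrs_amp_mV R-wave amplitude (mV).
#' @param t_amp_mV T-wave amplitude (mV).
#' @param baseline_wander_amp_mV,baseline_wander_freq_hz respiratory
#'   baseline drift; frequency must stay below 0.5 Hz.
#' @param powerline_freq_hz,powerline_amp_mV mains interference
#'   (default 50 Hz).
#' @param noise_std_mV white measurement-noise standard deviation (mV).
#' @param seed integer seed.
#' @return Object of class `ecg_synth_spec`.
#' @export
ecg_synth_spec <- function(aa = aa_synth_spec(), mean_rr_s = 0.6,
                           rr_cv = 0.2, qrs_amp_mV = 1.0,
                           t_amp_mV = 0.25,
                           baseline_wander_amp_mV = 0.1,
                           baseline_wander_freq_hz = 0.3,
                           powerline_freq_hz = 50,
                           powerline_amp_mV = 0.02,
                           noise_std_mV = 0.01, seed = 1L) {
  stopifnot(inherits(aa, "aa_synth_spec"))
  amps <- c(qrs_amp_mV, t_amp_mV, baseline_wander_amp_mV,
            powerline_amp_mV, noise_std_mV)
  if (any(amps < 0)) stop("all amplitudes must be >= 0")
  if (mean_rr_s <= 0) stop("mean_rr_s must be > 0")
  if (rr_cv < 0) stop("rr_cv must be >= 0")
  if (mean_rr_s - 3 * rr_cv * mean_rr_s <= 0.2)
    stop("mean_rr_s - 3*rr_cv*mean_rr_s must exceed the 0.2 s ",
         "refractory floor; beats would overlap pathologically")
  if (baseline_wander_freq_hz >= 0.5)
    stop("baseline_wander_freq_hz must be < 0.5 Hz")
  structure(
    list(aa = aa, mean_rr_s = mean_rr_s, rr_cv = rr_cv,
         qrs_amp_mV = qrs_amp_mV, t_amp_mV = t_amp_mV,
         baseline_wander_amp_mV = baseline_wander_amp_mV,
         baseline_wander_freq_hz = baseline_wander_freq_hz,
         powerline_freq_hz = powerline_freq_hz,
         powerline_amp_mV = powerline_amp_mV,
         noise_std_mV = noise_std_mV, seed = as.integer(seed)),
    class = "ecg_synth_spec")
}

#' Synthesize an AF-like ECG record
#'
#' @param spec an [ecg_synth_spec()].
#' @return An `ecg_record` with two ground-truth attributes for testing:
#'   `aa_truth` (the clean atrial component, numeric vector) and
#'   `r_peak_truth` (1-based sample indices of the QRS centres).
#' @export
synthesize_ecg <- function(spec) {
  stopifnot(inherits(spec, "ecg_synth_spec"))
  fs <- spec$aa$fs_hz
  n <- round(spec$aa$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  aa <- synthesize_aa(spec$aa)
  x <- aa$samples

  out <- withr::with_seed(spec$seed, {
    # RR renewal process: i.i.d. gamma, mean mean_rr_s, CV rr_cv
    dur <- spec$aa$duration_s
    n_max <- ceiling(dur / spec$mean_rr_s * 2 + 20)
    rr <- if (spec$rr_cv > 0) {
      shp <- 1 / spec$rr_cv^2
      stats::rgamma(n_max, shape = shp, scale = spec$mean_rr_s / shp)
    } else rep(spec$mean_rr_s, n_max)
    rr <- pmax(rr, 0.25)
    beat_times <- cumsum(rr)
    beat_times <- beat_times[beat_times < dur - 0.05]
    list(beat_times = beat_times, noise = stats::rnorm(n))
  })
  beat_idx <- round(out$beat_times * fs) + 1L

  vent <- numeric(n)
  qrs_sigma <- 0.080 / 6            # ~80 ms total Gaussian QRS width
  t_sigma <- 0.060
  t_offset <- 0.25                  # T apex 250 ms after R
  for (bt in out$beat_times) {
    vent <- vent + spec$qrs_amp_mV * exp(-(t - bt)^2 / (2 * qrs_sigma^2))
    vent <- vent + spec$t_amp_mV *
      exp(-(t - bt - t_offset)^2 / (2 * t_sigma^2))
  }
  x <- x + vent +
    spec$baseline_wander_amp_mV *
      sin(2 * pi * spec$baseline_wander_freq_hz * t) +
    spec$powerline_amp_mV * sin(2 * pi * spec$powerline_freq_hz * t) +
    spec$noise_std_mV * out$noise

  rec <- ecg_record(x, fs, record_id = sprintf("synth-%d", spec$seed))
  attr(rec, "aa_truth") <- aa$samples
  attr(rec, "r_peak_truth") <- beat_idx
  rec
}

#' Synthesize a labeled two-class cohort
#'
#' Draws per-record organization levels uniformly from
#' `[org_high - 0.05, org_high]` for the organized class and
#' `[org_low, org_low + 0.05]` for the disorganized class, then
#' synthesizes one ECG per record with a seed derived deterministically
#' from `seed`. Emulates a terminating-vs-nonterminating (or
#' NSR-vs-relapse) study cohort.
#'
#' @param n_organized,n_disorganized class sizes.
#' @param base_spec template [ecg_synth_spec()]; its `aa$organization`
#'   and seeds are overridden per record.
#' @param org_high,org_low organization anchors, `0 <= org_low <
#'   org_high <= 1`; the two sampling windows must not overlap.
#' @param seed cohort seed.
#' @return List with `records` (list of `ecg_record`) and `labels`
#'   (factor, `"organized"` / `"disorganized"`), plus per-record
#'   organization values in `organization`.
#' @export
synthesize_cohort <- function(n_organized, n_disorganized,
                              base_spec = ecg_synth_spec(),
                              org_high = 0.9, org_low = 0.3,
                              seed = 1L) {
  if (!(org_low >= 0 && org_high <= 1 && org_low < org_high))
    stop("need 0 <= org_low < org_high <= 1")
  if (org_high - 0.05 < org_low + 0.05)
    stop("organization sampling ranges overlap: widen org_high - org_low")
  n_organized <- as.integer(n_organized)
  n_disorganized <- as.integer(n_disorganized)
  n_tot <- n_organized + n_disorganized
  if (n_tot == 0)
    return(list(records = list(), labels = factor(character(),
                levels = c("organized", "disorganized")),
                organization = numeric(0)))
  orgs <- withr::with_seed(seed, c(
    stats::runif(n_organized, org_high - 0.05, org_high),
    stats::runif(n_disorganized, org_low, org_low + 0.05)))
  labels <- factor(rep(c("organized", "disorganized"),
                       c(n_organized, n_disorganized)),
                   levels = c("organized", "disorganized"))
  records <- vector("list", n_tot)
  sd0 <- (as.integer(seed) %% 200000L) * 10000L  # keep derived seeds < 2^31
  for (i in seq_len(n_tot)) {
    sp <- base_spec
    sp$aa$organization <- orgs[i]
    sp$aa$seed <- sd0 + i
    sp$seed <- sd0 + 5000L + i
    rec <- synthesize_ecg(sp)
    rec$record_id <- sprintf("cohort%d-%s-%02d", seed,
                             substr(as.character(labels[i]), 1, 3), i)
    records[[i]] <- rec
  }
  list(records = records, labels = labels, organization = orgs)
}
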