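# Relative wavelet energies and Wavelet Entropy -- the organization
# score at the heart of the package.

#' Relative subband energy distribution
#'
#' Collapses a wavelet decomposition into the probability-like vector
#' \eqn{E_m}: the fraction of total coefficient energy carried by each
#' scale, \eqn{E_m = \sum_i |C_m(i)|^2 / \sum_m \sum_i |C_m(i)|^2}. By
#' construction the distribution is non-negative and sums to one. By
#' default only the `N` detail subbands enter the distribution; set
#' `include_approximation = TRUE` in the spec to append the level-`N`
#' approximation band.
#'
#' @param dec a `wavelet_decomposition` from [wavelet_decompose()].
#' @return Object of class `energy_distribution`: numeric vector `E`
#'   (named d1..dN, plus aN when included) with the spec attached.
#' @export
relative_energy <- function(dec) {
  if (!inherits(dec, "wavelet_decomposition"))
    stop("dec must be a wavelet_decomposition")
  e <- vapply(dec$details, function(c) sum(c^2), numeric(1))
  names(e) <- paste0("d", seq_along(e))
  if (dec$spec$include_approximation)
    e <- c(e, aN = sum(dec$approx^2))
  tot <- sum(e)
  if (tot <= 0)
    stop("zero total energy: cannot normalize an all-zero decomposition",
         call. = FALSE)
  structure(e / tot, class = "energy_distribution", spec = dec$spec)
}

#' Wavelet Entropy of an energy distribution
#'
#' Shannon entropy of the relative wavelet energies,
#' \eqn{WE = -\sum_m E_m \log(E_m)} with \eqn{0 \log 0 := 0}. A signal
#' whose energy sits in a single subband (a periodic, monofrequency,
#' "organized" signal) scores near 0; a broadband, disorganized signal
#' spreads energy over all subbands and scores near the maximum
#' \eqn{\log N}. The logarithm base defaults to 10, under which the
#' seven-band maximum is \eqn{\log_{10} 7 \approx 0.845}.
#'
#' @param E an `energy_distribution`, or a bare non-negative numeric
#'   vector summing to 1.
#' @param log_base base of the logarithm; taken from the attached spec
#'   when `E` is an `energy_distribution`, else 10.
#' @return Scalar entropy in `[0, log(length(E))]`.
#' @examples
#' wavelet_entropy(c(1, 0, 0, 0, 0, 0, 0))        # 0: fully organized
#' wavelet_entropy(rep(1 / 7, 7))                 # log10(7): disorganized
#' @export
wavelet_entropy <- function(E, log_base = NULL) {
  if (is.null(log_base)) {
    spec <- attr(E, "spec")
    log_base <- if (!is.null(spec)) spec$log_base else 10
  }
  E <- as.numeric(E)
  if (any(E < -1e-12)) stop("energy distribution has negative entries")
  if (abs(sum(E) - 1) > 1e-6)
    stop("energy distribution not normalized: sums to ", format(sum(E)),
         call. = FALSE)
  nz <- E[E > 0]
  # + 0 maps IEEE negative zero (fully concentrated input) to plain 0
  -sum(nz * log(nz, base = log_base)) + 0
}

#' Wavelet Entropy score of an ECG record
#'
#' The full scoring chain on one record: condition the signal
#' ([preprocess_chain()]), expose the atrial activity by QRST
#' cancellation ([detect_r_peaks()] + [cancel_qrst()]), decompose it
#' ([wavelet_decompose()]), and take the entropy of the relative
#' subband energies. The scalar returned is the organization predictor:
#' higher entropy means more disorganized f waves.
#'
#' When no ventricular complexes can be detected (for instance a signal
#' that is already pure atrial activity), cancellation is skipped and
#' the conditioned signal is scored directly.
#'
#' @param rec an `ecg_record`.
#' @param spec a [wavelet_spec()]; default seven-level biorthogonal 4.4.
#' @param analysis_fs_hz analysis sampling rate (Hz); records at other
#'   rates are resampled. Default 1024, placing the seventh detail band
#'   at 4-8 Hz.
#' @param cancel logical: attempt QRST cancellation (default `TRUE`).
#' @param n_singular number of singular components in the cancellation
#'   template, passed to [cancel_qrst()].
#' @return Scalar Wavelet Entropy.
#' @export
we_score <- function(rec, spec = wavelet_spec(), analysis_fs_hz = 1024,
                     cancel = TRUE, n_singular = 2L) {
  stopifnot(inherits(rec, "ecg_record"))
  rec <- preprocess_chain(rec, analysis_fs_hz = analysis_fs_hz)
  aa <- rec
  if (cancel) {
    beats <- tryCatch(detect_r_peaks(rec), error = function(e) NULL)
    if (!is.null(beats) && length(beats$r_peak_indices) >= 3L) {
      aa <- cancel_qrst(rec, beats, n_singular = n_singular)
    } else {
      message("we_score: no reliable QRS detections; scoring without ",
              "cancellation (record ", rec$record_id, ")")
    }
  }
  wavelet_entropy(relative_energy(wavelet_decompose(aa, spec)))
}
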