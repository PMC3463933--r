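# Ventricular (QRST) cancellation: R-peak detection and subtraction of
# an adaptive singular-value beat template, leaving the atrial activity
# as the residual.

#' Detect R peaks
#'
#' Energy-based detector: zero-phase 10-30 Hz bandpass to isolate QRS
#' energy, squaring, a ~120 ms moving-average envelope, adaptive
#' thresholding, and a 0.2 s refractory constraint. Peak positions are
#' refined to the local absolute maximum of the bandpassed signal.
#'
#' @param rec a preprocessed `ecg_record` at the analysis rate.
#' @param threshold_frac envelope threshold as a fraction of its robust
#'   (98th percentile) maximum; default 0.2.
#' @return Object of class `beat_set`: `r_peak_indices` (1-based,
#'   strictly increasing), `window_pre_s`, `window_post_s`,
#'   `fs_hz`.
#' @export
detect_r_peaks <- function(rec, threshold_frac = 0.2) {
  stopifnot(inherits(rec, "ecg_record"))
  fs <- rec$fs_hz
  x <- rec$samples
  if (length(x) < fs)
    stop("record too short for beat detection (< 1 s)")
  bp <- signal::butter(3, c(10, 30) / (fs / 2), type = "pass")
  xb <- zero_phase_filter(x, bp, pad = min(length(x) - 1L, 1024L))
  env <- xb^2
  w <- max(3L, round(0.12 * fs))
  env <- as.numeric(stats::filter(env, rep(1 / w, w), sides = 2))
  env[is.na(env)] <- 0
  robust_max <- stats::quantile(env, 0.98, names = FALSE)
  # guard against flat/noise-only records: envelope must dominate the
  # record's broadband floor
  if (robust_max <= 0 || robust_max < 4 * stats::median(env))
    stop("no QRS complexes found; review signal polarity, amplitude ",
         "or detector threshold", call. = FALSE)
  thr <- threshold_frac * robust_max
  above <- env > thr
  refract <- round(0.2 * fs)
  peaks <- integer(0)
  i <- 1L; n <- length(x)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      seg <- i:j
      p <- seg[which.max(env[seg])]
      # refine on the bandpassed signal
      lo <- max(1L, p - round(0.05 * fs))
      hi <- min(n, p + round(0.05 * fs))
      p <- (lo:hi)[which.max(abs(xb[lo:hi]))]
      if (!length(peaks) || p - peaks[length(peaks)] >= refract)
        peaks <- c(peaks, p)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(peaks))
    stop("no QRS complexes found; review signal polarity, amplitude ",
         "or detector threshold", call. = FALSE)
  structure(
    list(r_peak_indices = peaks, window_pre_s = 0.3, window_post_s = 0.5,
         fs_hz = fs),
    class = "beat_set")
}

#' @export
print.beat_set <- function(x, ...) {
  cat(sprintf("beat_set: %d beats, window -%g/+%g s @ %g Hz\n",
              length(x$r_peak_indices), x$window_pre_s, x$window_post_s,
              x$fs_hz))
  invisible(x)
}

#' Cancel QRST complexes by an adaptive singular-value template
#'
#' Builds the R-peak-aligned beat matrix, takes its singular value
#' decomposition, reconstructs each beat from the top `n_singular`
#' components with per-beat least-squares coefficients (the adaptive
#' part), and subtracts the reconstruction inside each beat window.
#' Samples outside all beat windows are left bit-identical. A 20 ms
#' linear taper at the window edges avoids subtraction discontinuities.
#' Beats correlating poorly (r < 0.5) with the rank-1 template are
#' treated as ectopic-like and subtracted as the mean template with the
#' least-squares scale clipped to \[0, 2\].
#'
#' @param rec the preprocessed `ecg_record`.
#' @param beats a `beat_set` from [detect_r_peaks()] (>= 3 beats).
#' @param n_singular number of singular components (1-3; default 2).
#' @return An `aa_signal`: the residual atrial activity, same length
#'   and rate as the input.
#' @export
cancel_qrst <- function(rec, beats, n_singular = 2L) {
  stopifnot(inherits(rec, "ecg_record"), inherits(beats, "beat_set"))
  n_singular <- as.integer(n_singular)
  if (n_singular < 1L || n_singular > 3L)
    stop("n_singular must be 1, 2 or 3")
  fs <- rec$fs_hz
  x <- rec$samples
  n <- length(x)
  pre <- round(beats$window_pre_s * fs)
  post <- round(beats$window_post_s * fs)
  L <- pre + post + 1L
  pk <- beats$r_peak_indices
  if (length(pk) >= 2L) {
    # typical spacing: isolated short AF intervals are tolerated (the
    # edge taper absorbs them), systematic overlap is not
    typ_rr <- stats::median(diff(pk))
    if (L - typ_rr > 0.5 * L)
      stop("beat windows overlap by more than 50%: RR intervals too ",
           "short for a -", beats$window_pre_s, "/+",
           beats$window_post_s, " s window", call. = FALSE)
  }
  full <- pk[pk - pre >= 1L & pk + post <= n]
  if (length(full) < 3L)
    stop("need at least 3 fully-contained beats for the SVD template")
  segs <- lapply(full, function(p) (p - pre):(p + post))

  # The atrial band must not steer the fit: per-beat coefficients
  # estimated on the raw windows absorb each window's f-wave projection
  # and subtract it with the template. Coefficients are therefore fit
  # on an AA-band-suppressed (3.5-9 Hz bandstop) copy of the signal,
  # where the QRST still carries nearly all its energy.
  bs_filt <- signal::butter(3, c(3.5, 9) / (fs / 2), type = "stop")
  xb <- zero_phase_filter(x, bs_filt)

  # Iterated template refinement. AF-length RR intervals make adjacent
  # windows overlap, so a raw beat matrix carries each neighbour's QRST
  # tail at an RR-dependent offset; an SVD of it bakes that smear into
  # the leading components. Each round subtracts the current estimate
  # of every OTHER beat from each window before re-taking the SVD.
  m <- length(full)
  padw <- round(fs)                    # bandstop smear allowance (1 s)
  scs <- numeric(m)
  recons <- rep(list(numeric(L)), m)
  tmpl <- numeric(L)
  for (iter in 1:3) {
    vent <- numeric(n)
    for (i in seq_len(m))
      vent[segs[[i]]] <- vent[segs[[i]]] + recons[[i]]
    W <- t(vapply(seq_len(m), function(i) {
      s <- segs[[i]]
      x[s] - (vent[s] - recons[[i]])
    }, numeric(L)))
    V <- svd(W, nu = 0, nv = n_singular)$v   # L x k template basis
    t1 <- V[, 1]
    # template shape: the beats' mean expressed in the top-k singular
    # subspace; per-beat adaptation is a least-squares scale of that
    # shape (a scalar stays well conditioned on the bandstopped fit,
    # where higher-order T-wave directions lose their leverage)
    cbar <- colMeans(W %*% V)
    tmpl <- as.numeric(V %*% cbar)
    # two fitted components per beat: the template scale and the
    # template's derivative (absorbs sub-sample alignment jitter)
    tmpl_d <- c(diff(tmpl), 0)
    kerns <- list(tmpl, tmpl_d)
    # the bandstop smears the kernels past their window; carry the
    # smeared versions on a padded support so overlaps are exact
    kb <- lapply(kerns, function(kk)
      zero_phase_filter(c(numeric(padw), kk, numeric(padw)), bs_filt))
    Lz <- length(kb[[1]])
    q <- 2L
    # all coefficients jointly: the windows overlap, so the
    # least-squares fit is a small banded normal system rather than m
    # independent ones
    G <- matrix(0, q * m, q * m)
    b <- numeric(q * m)
    starts_z <- vapply(segs, function(s) s[1] - padw, numeric(1))
    for (i in seq_len(m)) {
      idx <- starts_z[i] + seq_len(Lz) - 1L
      keep <- idx >= 1L & idx <= n
      for (a in 1:q)
        b[(i - 1L) * q + a] <- sum(xb[idx[keep]] * kb[[a]][keep])
      for (j in i:m) {
        d <- starts_z[j] - starts_z[i]
        if (d >= Lz) break
        lo <- max(1L, 1L + d); hi <- Lz
        gi <- starts_z[i] + (lo:hi) - 1L
        ok <- gi >= 1L & gi <= n
        li <- (lo:hi)[ok]; lj <- li - d
        for (a in 1:q) for (cc in 1:q) {
          v <- sum(kb[[a]][li] * kb[[cc]][lj])
          G[(i - 1L) * q + a, (j - 1L) * q + cc] <- v
          G[(j - 1L) * q + cc, (i - 1L) * q + a] <- v
        }
      }
    }
    cf <- solve(G + diag(1e-9 * max(diag(G)), q * m), b)
    scs <- cf[seq(1, q * m, by = q)]
    dts <- cf[seq(2, q * m, by = q)]
    # ectopic-like beats (poor template correlation): clipped scale,
    # no jitter term
    for (i in seq_len(m)) {
      r1 <- suppressWarnings(stats::cor(W[i, ], t1))
      if (!is.finite(r1) || abs(r1) < 0.5) {
        scs[i] <- min(max(scs[i], 0), 2)
        dts[i] <- 0
      }
      dts[i] <- min(max(dts[i], -3), 3)  # at most a few samples of shift
    }
    recons <- lapply(seq_len(m), function(i)
      scs[i] * tmpl + dts[i] * tmpl_d)
  }
  mean_beat <- tmpl

  taper <- rep(1, L)
  nt <- max(1L, round(0.02 * fs))
  taper[seq_len(nt)] <- seq(0, 1, length.out = nt)
  taper[(L - nt + 1L):L] <- seq(1, 0, length.out = nt)

  out <- x
  for (i in seq_along(full)) {
    s <- segs[[i]]
    out[s] <- out[s] - recons[[i]] * taper
  }
  # beats too close to the record edge for a full window: scale the
  # mean template over the overlapping part
  for (p in setdiff(pk, full)) {
    lo <- max(1L, p - pre); hi <- min(n, p + post)
    if (hi <= lo) next
    wseg <- (lo - (p - pre) + 1L):(L - ((p + post) - hi))
    mseg <- mean_beat[wseg]
    sc <- sum(out[lo:hi] * mseg) / max(sum(mseg^2), 1e-12)
    out[lo:hi] <- out[lo:hi] - min(max(sc, 0), 2) * mseg * taper[wseg]
  }
  aa_signal(out, fs, source_record_id = rec$record_id)
}
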