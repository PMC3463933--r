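# ECG record containers and I/O: CSV dialect, minimal WFDB (format 16),
# and rate conversion.

#' Construct an ECG record
#'
#' @param samples numeric vector of amplitudes in millivolts.
#' @param fs_hz sampling rate in Hz (> 0).
#' @param lead lead label; single-lead V1 semantics by default.
#' @param record_id identifier carried through the pipeline.
#' @param stage provenance: one of `"raw"`, `"filtered"`, `"upsampled"`.
#' @return Object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs_hz, lead = "V1", record_id = "rec",
                       stage = c("raw", "filtered", "upsampled")) {
  stage <- match.arg(stage)
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("record must contain at least one sample")
  if (any(!is.finite(samples))) stop("samples must be finite")
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0)
    stop("fs_hz must be a positive scalar")
  structure(
    list(samples = samples, fs_hz = fs_hz, lead = lead,
         record_id = record_id, stage = stage),
    class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ecg_record '%s' [%s, %s]: %d samples @ %g Hz (%.1f s)\n",
              x$record_id, x$lead, x$stage, length(x$samples), x$fs_hz,
              length(x$samples) / x$fs_hz))
  invisible(x)
}

#' Construct an atrial-activity signal
#'
#' The residual after ventricular cancellation; same length and rate as
#' its source record.
#'
#' @param samples numeric vector (mV).
#' @param fs_hz sampling rate (Hz).
#' @param source_record_id id of the ECG the activity was extracted from.
#' @return Object of class `aa_signal`.
#' @export
aa_signal <- function(samples, fs_hz, source_record_id = "rec") {
  samples <- as.numeric(samples)
  if (!is.numeric(fs_hz) || fs_hz <= 0) stop("fs_hz must be positive")
  structure(
    list(samples = samples, fs_hz = fs_hz,
         source_record_id = source_record_id),
    class = "aa_signal")
}

#' @export
print.aa_signal <- function(x, ...) {
  cat(sprintf("aa_signal (from '%s'): %d samples @ %g Hz\n",
              x$source_record_id, length(x$samples), x$fs_hz))
  invisible(x)
}

# ---- CSV dialect -----------------------------------------------------
# Fixed two-column dialect, "time_s,amplitude_mV", with metadata in
# leading '#' comment lines so a record round-trips with its rate.

#' Write an ECG record as CSV
#'
#' Columns `time_s,amplitude_mV`; sampling rate, lead and record id are
#' stored in `# key=value` comment lines so [read_record()] can restore
#' them.
#'
#' @param rec an `ecg_record`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_csv_record <- function(rec, path) {
  stopifnot(inherits(rec, "ecg_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# fs_hz=%.10g", rec$fs_hz),
    sprintf("# lead=%s", rec$lead),
    sprintf("# record_id=%s", rec$record_id),
    "time_s,amplitude_mV"), con)
  t <- (seq_along(rec$samples) - 1) / rec$fs_hz
  utils::write.table(
    data.frame(t = sprintf("%.10g", t),
               a = sprintf("%.8g", rec$samples)),
    con, sep = ",", col.names = FALSE, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_csv_record <- function(path, fs_hz = NULL, lead = "V1",
                             record_id = NULL) {
  lines <- readLines(path, n = 64L)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  if (is.null(fs_hz)) {
    if (is.null(meta$fs_hz))
      stop("CSV '", path, "' does not declare a sampling rate: ",
           "missing 'fs_hz' header key (and none was supplied)",
           call. = FALSE)
    fs_hz <- as.numeric(meta$fs_hz)
  }
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_s", "amplitude_mV") %in% names(df)))
    stop("CSV '", path, "' must have columns time_s,amplitude_mV",
         call. = FALSE)
  if (is.unsorted(df$time_s, strictly = TRUE))
    stop("CSV '", path, "' time column is not strictly increasing",
         call. = FALSE)
  ecg_record(df$amplitude_mV, fs_hz,
             lead = meta$lead %||% lead,
             record_id = record_id %||% meta$record_id %||%
               sub("\\.[^.]*$", "", basename(path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- minimal WFDB (single-segment, format 16) ------------------------

#' Write an ECG record as a WFDB record pair
#'
#' Produces `<record>.hea` and `<record>.dat` with 16-bit little-endian
#' samples (format 16). The gain is chosen so the full signal span fits
#' the 16-bit range; amplitudes are in mV after gain/baseline.
#'
#' @param rec an `ecg_record`.
#' @param record_path path without extension (directory + record name).
#' @param adc_gain analogue-to-digital gain in adu/mV (default 200, the
#'   usual Holter setting).
#' @return `record_path`, invisibly.
#' @export
write_wfdb_record <- function(rec, record_path, adc_gain = 200) {
  stopifnot(inherits(rec, "ecg_record"))
  rng <- max(abs(rec$samples), 1e-12)
  if (rng * adc_gain > 32000) adc_gain <- 32000 / rng
  dig <- as.integer(round(rec$samples * adc_gain))
  name <- basename(record_path)
  hea <- c(
    sprintf("%s 1 %.10g %d", name, rec$fs_hz, length(dig)),
    sprintf("%s.dat 16 %.10g(0)/mV 16 0 %d 0 0 %s",
            name, adc_gain, dig[1], rec$lead))
  writeLines(hea, paste0(record_path, ".hea"))
  writeBin(dig, paste0(record_path, ".dat"), size = 2L,
           endian = "little")
  invisible(record_path)
}

.read_wfdb_record <- function(record_path, lead = NULL) {
  hea_path <- paste0(record_path, ".hea")
  if (!file.exists(hea_path)) stop("no header file: ", hea_path)
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^#", lines)]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n_sig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(top[3]) else 250
  n_samp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  sig <- lines[1 + seq_len(n_sig)]
  fields <- strsplit(trimws(sig), "\\s+")
  fmt <- vapply(fields, function(f) sub("x.*|:.*|\\+.*", "", f[2]), "")
  if (any(fmt != "16"))
    stop("only WFDB format 16 is supported (got ",
         paste(unique(fmt), collapse = ","), ")", call. = FALSE)
  gains <- vapply(fields, function(f) {
    g <- sub("\\(.*", "", f[3]); g <- sub("/.*", "", g)
    v <- suppressWarnings(as.numeric(g))
    if (is.na(v) || v == 0) 200 else v
  }, numeric(1))
  baselines <- vapply(fields, function(f) {
    b <- regmatches(f[3], regexpr("\\(([-0-9]+)\\)", f[3]))
    if (length(b)) as.numeric(gsub("[()]", "", b)) else 0
  }, numeric(1))
  leads <- vapply(fields, function(f)
    if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else "", "")
  dat_file <- file.path(dirname(record_path), fields[[1]][1])
  raw <- readBin(dat_file, integer(), n = file.size(dat_file) / 2,
                 size = 2L, endian = "little")
  if (is.na(n_samp)) n_samp <- length(raw) %/% n_sig
  mat <- matrix(raw[seq_len(n_samp * n_sig)], ncol = n_sig, byrow = TRUE)
  idx <- 1L
  if (!is.null(lead)) {
    idx <- match(lead, leads)
    if (is.na(idx))
      stop("lead '", lead, "' not found in record (has: ",
           paste(leads, collapse = ", "), ")", call. = FALSE)
  }
  ecg_record((mat[, idx] - baselines[idx]) / gains[idx], fs,
             lead = if (nzchar(leads[idx])) leads[idx] else "V1",
             record_id = basename(record_path))
}

#' Read an ECG record
#'
#' @param path CSV file path, or WFDB record path without extension.
#' @param format `"csv"` or `"wfdb"`; guessed from the path when omitted
#'   (`.csv` suffix means CSV).
#' @param lead lead to extract from a multi-lead WFDB record; `NULL`
#'   takes the first signal.
#' @param fs_hz sampling rate override for CSV files lacking the
#'   `# fs_hz=` header key.
#' @return An `ecg_record` with samples in mV.
#' @export
read_record <- function(path, format = c("auto", "csv", "wfdb"),
                        lead = NULL, fs_hz = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb"
  switch(format,
    csv = .read_csv_record(path, fs_hz = fs_hz,
                           lead = lead %||% "V1"),
    wfdb = .read_wfdb_record(sub("\\.hea$", "", path), lead = lead))
}

# ---- resampling ------------------------------------------------------

.rational_ratio <- function(r, max_den = 512L) {
  # continued-fraction rational approximation of the rate ratio
  best <- c(1L, 1L); err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    if (p < 1) next
    e <- abs(r - p / q)
    if (e < err - 1e-15) { best <- c(p, q); err <- e }
    if (err < 1e-12) break
  }
  best
}

#' Resample a record to a new rate
#'
#' Rational-factor rate conversion by zero-insertion, zero-phase FIR
#' anti-imaging/anti-aliasing lowpass, and decimation. Content below 80%
#' of the lower of the two Nyquist rates passes essentially untouched,
#' which is what beat-alignment upsampling (e.g. 128 to 1024 Hz) needs.
#'
#' @param rec an `ecg_record`.
#' @param target_fs_hz desired sampling rate (Hz, > 0).
#' @return `ecg_record` at the new rate, stage `"upsampled"`.
#' @export
resample_record <- function(rec, target_fs_hz) {
  stopifnot(inherits(rec, "ecg_record"))
  if (!is.numeric(target_fs_hz) || target_fs_hz <= 0)
    stop("target_fs_hz must be positive")
  if (isTRUE(all.equal(target_fs_hz, rec$fs_hz))) return(rec)
  pq <- .rational_ratio(target_fs_hz / rec$fs_hz)
  p <- pq[1]; q <- pq[2]
  x <- rec$samples
  up <- numeric(length(x) * p)
  up[seq(1, length(up), by = p)] <- x * p
  c_norm <- min(1 / p, 1 / q)      # lower Nyquist, normalized to fs*p/2
  ord <- 2L * ceiling(18 / c_norm / 2L)
  h <- signal::fir1(ord, 0.9 * c_norm)
  filt <- .zero_phase_fir(up, h)
  n_out <- round(length(x) * p / q)
  idx <- 1 + (seq_len(n_out) - 1) * q
  idx <- idx[idx <= length(filt)]
  ecg_record(filt[idx], rec$fs_hz * p / q, lead = rec$lead,
             record_id = rec$record_id, stage = "upsampled")
}

# zero-phase FIR by symmetric-kernel centred convolution with reflect
# padding (linear-phase kernel, delay compensated)
.zero_phase_fir <- function(x, h) {
  nh <- length(h)
  half <- (nh - 1) %/% 2
  pad <- min(length(x) - 1L, nh)
  xe <- c(rev(x[2:(pad + 1)]), x, rev(x[(length(x) - pad):(length(x) - 1)]))
  # full convolution; zero-phase sample for xe[m] sits at index m + half
  z <- stats::convolve(xe, h, type = "open")
  z[(pad + 1 + half):(pad + half + length(x))]
}
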