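# Evaluation harness: threshold classification, ROC-optimal threshold,
# repeated stratified 2-fold cross-validation, and group statistics.

#' Labeled organization scores
#'
#' @param scores numeric vector of Wavelet Entropy values, one per
#'   record.
#' @param labels logical or two-level factor; `TRUE` (or the second
#'   level) marks the positive class -- the disorganized,
#'   non-terminating / relapse group, which carries the higher entropy.
#' @param record_ids optional identifiers.
#' @return Object of class `labeled_scores`.
#' @export
labeled_scores <- function(scores, labels, record_ids = NULL) {
  if (is.factor(labels)) {
    if (nlevels(labels) != 2) stop("labels must have exactly two levels")
    labels <- labels == levels(labels)[2]
  }
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length")
  if (is.null(record_ids))
    record_ids <- sprintf("rec%03d", seq_along(scores))
  structure(
    list(scores = as.numeric(scores), labels = labels,
         record_ids = record_ids),
    class = "labeled_scores")
}

.check_two_class <- function(ls) {
  if (!any(ls$labels) || all(ls$labels))
    stop("both classes must be present", call. = FALSE)
}

#' Classify scores at a threshold
#'
#' Scores above the threshold are called positive (the disorganized /
#' higher-entropy class).
#'
#' @param ls a [labeled_scores()] object.
#' @param threshold decision threshold.
#' @return Named numeric vector: `sensitivity` (TP / positives),
#'   `specificity` (TN / negatives), `accuracy`.
#' @export
classify <- function(ls, threshold) {
  stopifnot(inherits(ls, "labeled_scores"))
  .check_two_class(ls)
  pred <- ls$scores > threshold
  tp <- sum(pred & ls$labels); fn <- sum(!pred & ls$labels)
  tn <- sum(!pred & !ls$labels); fp <- sum(pred & !ls$labels)
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    accuracy = (tp + tn) / length(pred))
}

#' ROC sweep and accuracy-optimal threshold
#'
#' Sweeps every midpoint between adjacent sorted unique scores (plus
#' flanking thresholds below and above all scores) and selects the
#' threshold maximizing accuracy. Ties are broken by the larger
#' sensitivity + specificity, then by the lower threshold.
#'
#' @param ls a [labeled_scores()] object with >= 2 records per class.
#' @return Object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `accuracy` (aligned vectors), `optimal_threshold`,
#'   `optimal_accuracy`.
#' @export
roc_optimal_threshold <- function(ls) {
  stopifnot(inherits(ls, "labeled_scores"))
  .check_two_class(ls)
  if (sum(ls$labels) < 2 || sum(!ls$labels) < 2)
    stop("need at least 2 records per class for a ROC sweep")
  u <- sort(unique(ls$scores))
  thr <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
           u[length(u)] + 1)
  m <- vapply(thr, function(th) classify(ls, th), numeric(3))
  acc <- m["accuracy", ]; ss <- m["sensitivity", ] + m["specificity", ]
  best <- which(acc == max(acc))
  best <- best[ss[best] == max(ss[best])]
  best <- best[which.min(thr[best])]
  structure(
    list(thresholds = thr, sensitivity = m["sensitivity", ],
         specificity = m["specificity", ], accuracy = acc,
         optimal_threshold = thr[best], optimal_accuracy = acc[best]),
    class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "roc_result: %d thresholds; optimal %.4g (accuracy %.1f%%)\n",
    length(x$thresholds), x$optimal_threshold, 100 * x$optimal_accuracy))
  invisible(x)
}

#' Group statistics
#'
#' The statistical comparison between the two entropy groups: two-sided
#' two-sample Student's t-test with pooled variance (the design checks
#' homoscedasticity first), per-group Shapiro-Wilk normality tests, and
#' Levene's test (centred on the mean) for equality of variances.
#'
#' @param ls a [labeled_scores()] object, >= 3 records per group.
#' @return List: `t_statistic`, `p_value`, `mean_pos`, `mean_neg`,
#'   `sd_pos`, `sd_neg`, `shapiro_p_pos`, `shapiro_p_neg`, `levene_p`.
#' @export
group_stats <- function(ls) {
  stopifnot(inherits(ls, "labeled_scores"))
  .check_two_class(ls)
  pos <- ls$scores[ls$labels]; neg <- ls$scores[!ls$labels]
  if (length(pos) < 3 || length(neg) < 3)
    stop("need >= 3 records per group for normality testing")
  if (stats::sd(pos) == 0 && stats::sd(neg) == 0)
    stop("degenerate input: both groups have zero variance")
  tt <- stats::t.test(pos, neg, var.equal = TRUE)
  lev <- car::leveneTest(
    c(pos, neg),
    factor(rep(c("pos", "neg"), c(length(pos), length(neg)))),
    center = mean)
  shap_p <- function(v) if (stats::sd(v) > 0)
    stats::shapiro.test(v)$p.value else NA_real_
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       mean_pos = mean(pos), mean_neg = mean(neg),
       sd_pos = stats::sd(pos), sd_neg = stats::sd(neg),
       shapiro_p_pos = shap_p(pos), shapiro_p_neg = shap_p(neg),
       levene_p = lev[["Pr(>F)"]][1])
}

# deterministic per-class stratified fold assignment; members are
# ordered canonically (by record id) before the seeded shuffle so the
# assignment does not depend on input record order
.stratified_folds <- function(labels, ids, n_folds, run_seed) {
  fold <- integer(length(labels))
  withr::with_seed(run_seed, {
    for (cls in c(FALSE, TRUE)) {
      idx <- which(labels == cls)
      idx <- idx[order(ids[idx])]
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Repeated stratified k-fold cross-validation
#'
#' Per run, records are split into `n_folds` stratified folds (class
#' proportions preserved to within one record). Each fold in turn is
#' held out: the remaining data is the learning set, from which the
#' ROC-optimal entropy threshold is derived; sensitivity, specificity
#' and accuracy are then measured on the held-out fold, and the
#' learning-set group statistics are recorded. The final report
#' averages all `n_runs * n_folds` validation folds with equal weight.
#'
#' @param ls a [labeled_scores()] object; each class needs >= `n_folds`
#'   members.
#' @param n_folds folds per run (default 2).
#' @param n_runs repeated runs (default 5).
#' @param seed integer; run `r` uses derived seed `seed + r`.
#' @return Object of class `cv_report`: `per_fold` data frame (run,
#'   fold, learned_threshold, sensitivity, specificity, accuracy,
#'   p_value, group means/sds), `averages` named vector, `n_runs`,
#'   `n_folds`, `seed`.
#' @export
stratified_cv <- function(ls, n_folds = 2L, n_runs = 5L, seed = 1L) {
  stopifnot(inherits(ls, "labeled_scores"))
  .check_two_class(ls)
  n_folds <- as.integer(n_folds); n_runs <- as.integer(n_runs)
  if (sum(ls$labels) < n_folds || sum(!ls$labels) < n_folds)
    stop("each class needs at least n_folds = ", n_folds, " members")
  rows <- list()
  for (r in seq_len(n_runs)) {
    fold <- .stratified_folds(ls$labels, ls$record_ids, n_folds, seed + r)
    for (f in seq_len(n_folds)) {
      learn <- labeled_scores(ls$scores[fold != f], ls$labels[fold != f],
                              ls$record_ids[fold != f])
      valid <- labeled_scores(ls$scores[fold == f], ls$labels[fold == f],
                              ls$record_ids[fold == f])
      roc <- roc_optimal_threshold(learn)
      met <- classify(valid, roc$optimal_threshold)
      gs <- tryCatch(group_stats(learn), error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        run = r, fold = f, learned_threshold = roc$optimal_threshold,
        sensitivity = met["sensitivity"], specificity = met["specificity"],
        accuracy = met["accuracy"],
        p_value = if (!is.null(gs)) gs$p_value else NA_real_,
        mean_pos = if (!is.null(gs)) gs$mean_pos else NA_real_,
        mean_neg = if (!is.null(gs)) gs$mean_neg else NA_real_,
        sd_pos = if (!is.null(gs)) gs$sd_pos else NA_real_,
        sd_neg = if (!is.null(gs)) gs$sd_neg else NA_real_,
        row.names = NULL)
    }
  }
  per_fold <- do.call(rbind, rows)
  avg_cols <- c("sensitivity", "specificity", "accuracy",
                "learned_threshold")
  structure(
    list(per_fold = per_fold,
         averages = colMeans(per_fold[avg_cols]),
         n_runs = n_runs, n_folds = n_folds, seed = seed),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  a <- x$averages
  cat(sprintf(
    "cv_report: %d x %d-fold CV (seed %d)\n  sens %.2f%%  spec %.2f%%  acc %.2f%%  (mean threshold %.4g)\n",
    x$n_runs, x$n_folds, x$seed, 100 * a["sensitivity"],
    100 * a["specificity"], 100 * a["accuracy"],
    a["learned_threshold"]))
  invisible(x)
}

#' Per-family experiment driver
#'
#' Scores every record with each requested wavelet family, runs the
#' repeated stratified cross-validation and the group statistics per
#' family, and assembles the per-family summary table (group means and
#' SDs, P value, averaged sensitivity / specificity / accuracy).
#' Classification agreement across families can be inspected through
#' the returned per-record prediction matrix (each family applied at
#' its own full-cohort ROC-optimal threshold).
#'
#' @param records list of `ecg_record`.
#' @param labels two-level factor or logical; positive = disorganized
#'   class (see [labeled_scores()]).
#' @param families character vector of wavelet family names.
#' @param levels decomposition depth (default 7).
#' @param n_folds,n_runs,seed cross-validation settings.
#' @param cancel forward to [we_score()].
#' @return List: `table` (data frame, one row per family), `cv` (named
#'   list of `cv_report`), `scores` (families x records matrix of WE),
#'   `predictions` (families x records logical matrix), `labels`.
#' @export
run_experiment <- function(records, labels,
                           families = wavelet_families(),
                           levels = 7L, n_folds = 2L, n_runs = 5L,
                           seed = 1L, cancel = TRUE) {
  if (is.factor(labels)) labels_l <- labels == levels(labels)[2]
  else labels_l <- as.logical(labels)
  n <- length(records)
  if (n != length(labels_l)) stop("records and labels differ in length")
  ids <- vapply(records, function(r) r$record_id, "")
  # preprocessing + cancellation happen once; only the decomposition
  # family varies across the table rows
  aa_list <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- preprocess_chain(records[[i]])
    beats <- if (cancel)
      tryCatch(detect_r_peaks(rec), error = function(e) NULL) else NULL
    aa_list[[i]] <- if (!is.null(beats) &&
                        length(beats$r_peak_indices) >= 3L)
      cancel_qrst(rec, beats) else rec
  }
  score_mat <- matrix(NA_real_, length(families), n,
                      dimnames = list(families, ids))
  pred_mat <- matrix(NA, length(families), n,
                     dimnames = list(families, ids))
  cv_list <- list(); tab_rows <- list()
  for (fam in families) {
    spec <- wavelet_spec(fam, levels = levels)
    score_mat[fam, ] <- vapply(aa_list, function(aa)
      wavelet_entropy(relative_energy(wavelet_decompose(aa, spec))),
      numeric(1))
    ls <- labeled_scores(score_mat[fam, ], labels_l, ids)
    cv <- stratified_cv(ls, n_folds = n_folds, n_runs = n_runs,
                        seed = seed)
    cv_list[[fam]] <- cv
    gs <- group_stats(ls)
    roc <- roc_optimal_threshold(ls)
    pred_mat[fam, ] <- ls$scores > roc$optimal_threshold
    tab_rows[[fam]] <- data.frame(
      family = fam,
      we_mean_pos = gs$mean_pos, we_sd_pos = gs$sd_pos,
      we_mean_neg = gs$mean_neg, we_sd_neg = gs$sd_neg,
      p_value = gs$p_value,
      sensitivity = unname(cv$averages["sensitivity"]),
      specificity = unname(cv$averages["specificity"]),
      accuracy = unname(cv$averages["accuracy"]),
      row.names = NULL)
  }
  list(table = do.call(rbind, c(tab_rows, make.row.names = FALSE)),
       cv = cv_list, scores = score_mat, predictions = pred_mat,
       labels = labels_l)
}
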