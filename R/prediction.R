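# Similarity-weighted individualized cross-individual pain prediction and
# its leave-one-individual-out evaluation.

#' Predict a rating from an N2-P2 amplitude
#'
#' Evaluates the rating-on-amplitude line `a * x + b` of a fitted model.
#' Predictions are not clipped to the NRS range unless requested.
#'
#' @param x N2-P2 amplitude(s), uV.
#' @param model an `lep_pain_model` or any list with `a` and `b`.
#' @param clip clip predictions to [0, 10].
#' @return predicted rating(s).
#' @export
predict_with_model <- function(x, model, clip = FALSE) {
  y <- model$a * x + model$b
  if (clip) y <- pmin(10, pmax(0, y))
  y
}

#' Euclidean distance of isEEG correlates to each training subject
#'
#' Distances are computed on the selected feature keys, optionally after
#' z-scoring each key using the mean and SD estimated from the training
#' subjects only (the test subject never informs the standardization).
#'
#' @param test_vector named numeric vector of the test subject's feature
#'   values (names are feature keys, e.g. `"Cz|alpha2|nmssd"`).
#' @param training_vectors list (or matrix with one row per training
#'   subject) of equally named vectors.
#' @param selected_keys keys entering the distance (default: all shared).
#' @param standardize z-score across training subjects first (default TRUE).
#' @return numeric vector of distances, one per training subject.
#' @export
compute_diffs <- function(test_vector, training_vectors,
                          selected_keys = NULL, standardize = TRUE) {
  if (is.list(training_vectors))
    training_vectors <- do.call(rbind, training_vectors)
  keys <- selected_keys %||% colnames(training_vectors)
  missing <- setdiff(keys, colnames(training_vectors))
  if (length(missing) > 0 || !all(keys %in% names(test_vector)))
    stop_painlep("missing feature key(s): %s",
                 paste(union(missing, setdiff(keys, names(test_vector))), collapse = ", "))
  tr <- training_vectors[, keys, drop = FALSE]
  te <- test_vector[keys]
  if (standardize) {
    mu <- colMeans(tr)
    sig <- apply(tr, 2, sd)
    sig[sig == 0 | !is.finite(sig)] <- 1
    tr <- sweep(sweep(tr, 2, mu), 2, sig, "/")
    te <- (te - mu) / sig
  }
  sqrt(rowSums(sweep(tr, 2, te)^2))
}

#' Similarity weights from feature distances
#'
#' Training subjects whose distance exceeds the mean distance receive weight
#' zero; the others receive `max(diff) - diff_n`, so the nearest subject
#' gets the largest weight. The mean and max are taken over all N-1
#' distances (including those subsequently zeroed). If every distance is
#' equal, all weights are zero (callers fall back to the unweighted mean).
#'
#' @param diffs non-negative finite distances.
#' @return non-negative weights, same length.
#' @examples
#' compute_weights(c(1, 2, 3, 10))  # 9 8 7 0
#' @export
compute_weights <- function(diffs) {
  if (length(diffs) < 1 || any(!is.finite(diffs)) || any(diffs < 0))
    stop_painlep("diffs must be finite, non-negative and non-empty")
  w <- max(diffs) - diffs
  w[diffs > mean(diffs)] <- 0
  w
}

#' Weighted average of per-model predictions
#'
#' `sum(w_n * R_n) / sum(w_n)`. When every weight is zero the unweighted
#' mean of all predictions is returned and flagged via the `"fallback"`
#' attribute.
#'
#' @param predictions per-training-subject predicted ratings.
#' @param weights weights from [compute_weights()].
#' @return predicted rating with attribute `fallback` (logical).
#' @export
weighted_predict <- function(predictions, weights) {
  if (length(predictions) != length(weights))
    stop_painlep("predictions (%d) and weights (%d) differ in length",
                 length(predictions), length(weights))
  sw <- sum(weights)
  if (sw == 0)
    return(structure(mean(predictions), fallback = TRUE))
  structure(sum(weights * predictions) / sw, fallback = FALSE)
}

#' Mean absolute error
#'
#' @param true,predicted numeric vectors of equal length.
#' @return `mean(abs(true - predicted))`.
#' @export
mae <- function(true, predicted) {
  if (length(true) != length(predicted))
    stop_painlep("length mismatch in mae()")
  mean(abs(true - predicted))
}

#' Paired t-test on per-subject MAE values
#'
#' One-sample t statistic on the paired differences
#' `mae_individualized - mae_conventional`, with a two-sided p-value.
#'
#' @param mae_individualized,mae_conventional equal-length numeric vectors
#'   (>= 3 pairs).
#' @return list with `t`, `p`, `df`, `mean_diff`.
#' @export
paired_ttest <- function(mae_individualized, mae_conventional) {
  if (length(mae_individualized) != length(mae_conventional))
    stop_painlep("paired inputs differ in length")
  d <- mae_individualized - mae_conventional
  n <- length(d)
  if (n < 3) stop_painlep("need at least 3 pairs")
  if (sd(d) == 0) stop_painlep("zero-variance differences: paired t undefined")
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  list(t = t_stat, p = 2 * pt(-abs(t_stat), df = n - 1), df = n - 1,
       mean_diff = mean(d))
}

# named feature vector "channel|band|feature" -> value
flatten_features <- function(features) {
  stats::setNames(features$value,
                  paste(features$channel, features$band, features$feature,
                        sep = "|"))
}

#' Leave-one-individual-out evaluation of both prediction schemes
#'
#' For each included held-out subject: every other included subject's fitted
#' model predicts the held-out subject's fast-pain trial ratings from the
#' N2-P2 amplitudes; the individualized scheme averages these predictions
#' with similarity weights derived from isEEG feature distances, while the
#' conventional scheme uses the unweighted mean over all training models.
#' Per-subject MAE is reported for both schemes.
#'
#' The feature keys entering the distance are, by default (`"auto"`), those
#' significant in [run_group_correlation()] computed on the training
#' subjects only (no test-subject leakage); if none reach significance, or
#' with `selected_keys = "all"`, every key of the LEP channel is used.
#'
#' @param cohort an `lep_cohort` or list of subjects with `subject_id`,
#'   `trials`, `features`.
#' @param selected_keys `"auto"`, `"all"`, or an explicit character vector
#'   of keys (`"channel|band|feature"`).
#' @param alpha significance level for the automatic key selection.
#' @param standardize z-score features across training subjects before the
#'   distance.
#' @param clip clip predicted ratings to [0, 10].
#' @param lep_channel channel whose keys form the fallback set.
#' @param min_trials minimum fast-pain trials per model fit.
#' @return data.frame of class `loocv_result`, one row per evaluated
#'   subject: `subject_id`, `n_trials`, `mae_individualized`,
#'   `mae_conventional`, `fallback_used`; attributes `skipped` (excluded
#'   subject ids) and `ttest` (the paired comparison, when >= 3 subjects).
#' @export
loocv_evaluate <- function(cohort, selected_keys = "auto", alpha = 0.05,
                           standardize = TRUE, clip = FALSE,
                           lep_channel = "Cz", min_trials = 3) {
  subjects <- if (inherits(cohort, "lep_cohort")) cohort$subjects else cohort
  models <- fit_cohort_models(subjects, min_trials = min_trials)
  included <- which(models$included)
  if (length(included) < 3)
    stop_painlep("need at least 3 included subjects, got %d", length(included))
  skipped <- models$subject_id[!models$included]
  fvecs <- lapply(subjects, function(s) flatten_features(s$features))
  feat_table <- cohort_feature_table(subjects)
  rows <- list()
  for (m in included) {
    train <- setdiff(included, m)
    train_models <- lapply(train, function(n)
      list(a = models$a[n], b = models$b[n]))
    # feature keys: significant correlates identified on training subjects only
    keys <- NULL
    if (identical(selected_keys, "auto")) {
      sig <- tryCatch({
        cr <- run_group_correlation(
          feat_table[feat_table$subject_id %in% models$subject_id[train], ],
          models[train, ], alpha = alpha)
        unique(paste(cr$channel, cr$band, cr$feature, sep = "|")[cr$significant])
      }, error = function(e) character(0))
      if (length(sig) > 0) keys <- sig
    } else if (!identical(selected_keys, "all")) {
      keys <- selected_keys
    }
    if (is.null(keys)) {
      all_keys <- names(fvecs[[m]])
      keys <- grep(paste0("^", lep_channel, "\\|"), all_keys, value = TRUE)
      if (length(keys) == 0) keys <- all_keys
    }
    diffs <- compute_diffs(fvecs[[m]], fvecs[train], keys, standardize)
    w <- compute_weights(diffs)
    fast <- select_fast_pain(subjects[[m]]$trials)
    fast <- fast[is.finite(fast$n2p2_uV), , drop = FALSE]
    preds <- vapply(train_models, function(tm)
      predict_with_model(fast$n2p2_uV, tm, clip = clip),
      numeric(nrow(fast)))
    if (nrow(fast) == 1) preds <- matrix(preds, nrow = 1)
    fallback <- FALSE
    indiv <- apply(preds, 1, function(p) {
      wp <- weighted_predict(p, w)
      if (attr(wp, "fallback")) fallback <<- TRUE
      as.numeric(wp)
    })
    conv <- rowMeans(preds)
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = models$subject_id[m], n_trials = nrow(fast),
      mae_individualized = mae(fast$rating, indiv),
      mae_conventional = mae(fast$rating, conv),
      fallback_used = fallback, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  tt <- if (nrow(out) >= 3 && sd(out$mae_individualized - out$mae_conventional) > 0)
    paired_ttest(out$mae_individualized, out$mae_conventional) else NULL
  structure(out, skipped = skipped, ttest = tt,
            class = c("loocv_result", "data.frame"))
}

#' Summarize a leave-one-out evaluation
#'
#' @param object a `loocv_result`.
#' @param ... unused.
#' @return list with per-scheme mean/SD MAE and the paired test.
#' @export
summary.loocv_result <- function(object, ...) {
  list(n_subjects = nrow(object),
       mae_individualized_mean = mean(object$mae_individualized),
       mae_individualized_sd = sd(object$mae_individualized),
       mae_conventional_mean = mean(object$mae_conventional),
       mae_conventional_sd = sd(object$mae_conventional),
       ttest = attr(object, "ttest"),
       skipped = attr(object, "skipped"))
}
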