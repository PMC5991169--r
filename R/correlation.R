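# Cross-individual correlation of isEEG features with the fast-pain model
# parameters (c, d), with Bonferroni family-wise control.

#' Pearson correlation with a two-sided t-test p-value
#'
#' Product-moment correlation computed from first principles, with the
#' two-sided p-value from the t distribution on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (>= 4), both non-constant.
#' @return list with `r` and `p`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop_painlep("x and y lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop_painlep("need at least 4 complete pairs, got %d", n)
  if (sd(x) == 0 || sd(y) == 0)
    stop_painlep("correlation undefined for a constant input")
  xc <- x - mean(x); yc <- y - mean(y)
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  r <- max(-1, min(1, r))
  if (abs(r) == 1) return(list(r = r, p = 0))
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t_stat), df = n - 2))
}

#' Bonferroni significance mask
#'
#' Marks p-values significant when `p < alpha / n_tests`.
#'
#' @param p numeric p-values.
#' @param alpha family-wise level (default 0.05).
#' @param n_tests family size; must be at least `length(p)`.
#' @return logical vector.
#' @export
bonferroni_mask <- function(p, alpha = 0.05, n_tests = length(p)) {
  if (n_tests < 1) stop_painlep("n_tests must be positive")
  if (n_tests < length(p))
    stop_painlep("n_tests (%d) smaller than the number of p-values (%d)",
                 n_tests, length(p))
  p < alpha / n_tests
}

#' Group-level correlation of isEEG features with model parameters
#'
#' For every channel x band x feature key, correlates the feature values
#' across included subjects with each fast-pain model parameter (`c` and
#' `d`), applying Bonferroni correction over the full grid of tests.
#'
#' @param features long data.frame with columns `subject_id`, `channel`,
#'   `band`, `feature`, `value` (one row per subject per key).
#' @param models data.frame from [fit_cohort_models()] (columns
#'   `subject_id`, `c`, `d`, `included`).
#' @param alpha family-wise level.
#' @param method `"pearson"` (default) or `"spearman"` (rank-transformed
#'   Pearson).
#' @param min_subjects minimum number of included subjects (default 10).
#' @return data.frame of class `correlation_result` with columns `channel`,
#'   `band`, `feature`, `parameter`, `r`, `p`, `p_threshold`, `significant`;
#'   attributes `n_tests`, `alpha`, `n_subjects`.
#' @export
run_group_correlation <- function(features, models, alpha = 0.05,
                                  method = c("pearson", "spearman"),
                                  min_subjects = 10) {
  method <- match.arg(method)
  inc <- models[models$included %||% TRUE & !is.na(models$c), , drop = FALSE]
  ids <- inc$subject_id
  if (length(ids) < min_subjects)
    stop_painlep("only %d included subjects (need >= %d)", length(ids), min_subjects)
  missing <- setdiff(ids, unique(features$subject_id))
  if (length(missing) > 0)
    stop_painlep("subjects without features: %s", paste(missing, collapse = ", "))
  keys <- unique(features[, c("channel", "band", "feature")])
  rows <- list()
  for (k in seq_len(nrow(keys))) {
    sel <- features$channel == keys$channel[k] &
      features$band == keys$band[k] & features$feature == keys$feature[k]
    fsub <- features[sel, ]
    v <- fsub$value[match(ids, fsub$subject_id)]
    if (anyNA(v))
      stop_painlep("missing feature %s/%s/%s for some subjects",
                   keys$channel[k], keys$band[k], keys$feature[k])
    for (param in c("c", "d")) {
      pv <- inc[[param]]
      xx <- v; yy <- pv
      if (method == "spearman") { xx <- rank(xx); yy <- rank(yy) }
      ct <- pearson_cor(xx, yy)
      rows[[length(rows) + 1L]] <- data.frame(
        channel = keys$channel[k], band = keys$band[k],
        feature = keys$feature[k], parameter = param,
        r = ct$r, p = ct$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  n_tests <- nrow(out)
  out$p_threshold <- alpha / n_tests
  out$significant <- bonferroni_mask(out$p, alpha, n_tests)
  rownames(out) <- NULL
  structure(out, n_tests = n_tests, alpha = alpha, n_subjects = length(ids),
            class = c("correlation_result", "data.frame"))
}

# long feature table for a cohort (subject_id column added)
cohort_feature_table <- function(cohort) {
  subjects <- if (inherits(cohort, "lep_cohort")) cohort$subjects else cohort
  out <- do.call(rbind, lapply(subjects, function(s)
    cbind(subject_id = s$subject_id, s$features, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
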