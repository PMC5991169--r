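# Per-subject linear fast-pain model: rating y on N2-P2 amplitude x
# (y = a x + b), reparameterized to amplitude-on-rating form
# (x = c y + d with c = 1/a, d = -b/a).

#' Select fast-pain trials
#'
#' Keeps trials whose rating strictly exceeds the fast-pain (pinprick)
#' threshold of 4 on the NRS; order is preserved.
#'
#' @param trials data.frame with a `rating` column.
#' @param threshold NRS threshold (default 4, exclusive).
#' @return subset of `trials`.
#' @export
select_fast_pain <- function(trials, threshold = 4) {
  trials[trials$rating > threshold, , drop = FALSE]
}

#' Subject inclusion rule
#'
#' A subject enters the group analysis only if at least one fast-pain trial
#' reached NRS 7 or above; subjects whose fast-pain trials all stayed below
#' 7 are discarded.
#'
#' @param trials data.frame with a `rating` column (all trials; fast-pain
#'   selection is applied internally).
#' @param min_rating inclusion threshold (default 7, inclusive).
#' @return logical.
#' @export
check_inclusion <- function(trials, min_rating = 7) {
  fast <- select_fast_pain(trials)
  nrow(fast) > 0 && any(fast$rating >= min_rating)
}

#' Reparameterize the rating-on-amplitude model
#'
#' Maps the slope/intercept `(a, b)` of `y = a x + b` to the slope/intercept
#' `(c, d) = (1/a, -b/a)` of the equivalent amplitude-on-rating line
#' `x = c y + d`; `d` is the x-intercept of the original line. The map is an
#' involution: applying it to `(c, d)` returns `(a, b)`.
#'
#' @param a,b slope and intercept of the rating-on-amplitude line.
#' @param tol singularity tolerance on `|a|`.
#' @return named numeric `c(c = 1/a, d = -b/a)`.
#' @examples
#' reparameterize(2, -3)  # c = 0.5, d = 1.5
#' @export
reparameterize <- function(a, b, tol = 1e-8) {
  if (abs(a) <= tol)
    stop_painlep("slope a = %g is within tolerance of zero: reparameterization undefined", a)
  c(c = 1 / a, d = -b / a)
}

#' Fit a subject's fast-pain model
#'
#' Ordinary least squares of rating on amplitude gives `(a, b)`; `(c, d)`
#' follow by algebraic inversion via [reparameterize()] (not a second
#' regression, so the exact identities c = 1/a and d = -b/a hold).
#'
#' @param x N2-P2 amplitudes (uV) of fast-pain trials.
#' @param y NRS ratings of the same trials.
#' @param min_trials minimum number of trials (default 3).
#' @return list of class `lep_pain_model`: `a`, `b`, `c`, `d`,
#'   `n_fast_trials`, `fit_r` (Pearson correlation of the fit).
#' @export
fit_lep_pain <- function(x, y, min_trials = 3) {
  if (length(x) != length(y)) stop_painlep("x and y lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < min_trials)
    stop_painlep("insufficient data: %d fast-pain trials (< %d)", length(x), min_trials)
  if (sd(x) == 0) stop_painlep("degenerate design: zero variance in LEP amplitudes")
  a <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b <- mean(y) - a * mean(x)
  cd <- reparameterize(a, b)
  fit_r <- if (sd(y) == 0) 0 else suppressWarnings(stats::cor(x, y))
  structure(list(a = a, b = b, c = unname(cd["c"]), d = unname(cd["d"]),
                 n_fast_trials = length(x), fit_r = fit_r),
            class = "lep_pain_model")
}

#' @export
print.lep_pain_model <- function(x, ...) {
  cat(sprintf("LEP-pain model: y = %.4f x + %.4f  (x = %.3f y + %.3f; n = %d, r = %.3f)\n",
              x$a, x$b, x$c, x$d, x$n_fast_trials, x$fit_r))
  invisible(x)
}

#' Fit models for every included subject of a cohort
#'
#' Applies fast-pain selection and the inclusion rule, then fits the linear
#' model for each included subject.
#'
#' @param cohort an `lep_cohort` (see [simulate_cohort()]) or a list of
#'   subjects each carrying `subject_id` and a `trials` data.frame.
#' @param min_trials minimum fast-pain trials per fit.
#' @return data.frame with one row per subject: `subject_id`, `a`, `b`, `c`,
#'   `d`, `n_fast_trials`, `fit_r`, `included`.
#' @export
fit_cohort_models <- function(cohort, min_trials = 3) {
  subjects <- if (inherits(cohort, "lep_cohort")) cohort$subjects else cohort
  rows <- lapply(subjects, function(s) {
    inc <- check_inclusion(s$trials)
    if (!inc)
      return(data.frame(subject_id = s$subject_id, a = NA_real_, b = NA_real_,
                        c = NA_real_, d = NA_real_, n_fast_trials = NA_integer_,
                        fit_r = NA_real_, included = FALSE,
                        stringsAsFactors = FALSE))
    fast <- select_fast_pain(s$trials)
    m <- fit_lep_pain(fast$n2p2_uV, fast$rating, min_trials = min_trials)
    data.frame(subject_id = s$subject_id, a = m$a, b = m$b, c = m$c, d = m$d,
               n_fast_trials = m$n_fast_trials, fit_r = m$fit_r,
               included = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
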