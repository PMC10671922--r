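#' Confusion-matrix counts for binary predictions
#'
#' Tallies true/false positives and negatives for a pair of binary vectors,
#' with class 1 taken as the positive class.
#'
#' @param data A data frame containing the truth and estimate columns.
#' @param truth,estimate Column names (unquoted) holding the true and the
#'   predicted 0/1 labels.
#'
#' @return A one-row tibble with integer columns `tp`, `fp`, `fn`, `tn`;
#'   their sum equals `nrow(data)`.
#'
#' @examples
#' d <- tibble::tibble(label = c(1, 0, 1, 0), pred = c(1, 0, 0, 1))
#' confusion_counts(d, label, pred)
#' @export
confusion_counts <- function(data, truth, estimate) {
  y_true <- dplyr::pull(data, {{ truth }})
  y_pred <- dplyr::pull(data, {{ estimate }})
  if (length(y_true) != length(y_pred)) {
    abort("`truth` and `estimate` must have equal length.")
  }
  check_binary(y_true, "truth")
  check_binary(y_pred, "estimate")
  tibble::tibble(
    tp = sum(y_true == 1 & y_pred == 1),
    fp = sum(y_true == 0 & y_pred == 1),
    fn = sum(y_true == 1 & y_pred == 0),
    tn = sum(y_true == 0 & y_pred == 0)
  )
}

#' F-beta score from confusion counts
#'
#' Computes the Fβ score
#' \deqn{F_\beta = \frac{(1+\beta^2)\,TP}{(1+\beta^2)\,TP + FP + \beta^2\,FN}}
#' from a row of confusion counts. The default `beta = 2` gives the F2
#' score, which weights recall four times as heavily as precision and
#' simplifies to \eqn{TP / (TP + 0.2\,FP + 0.8\,FN)}; recall-first scoring
#' is the norm in screening settings, where a missed positive costs far
#' more than a false alarm.
#'
#' When `tp`, `fp` and `fn` are all zero (an all-negative prediction on an
#' all-negative truth) the score is undefined; `zero_division` is returned
#' with a warning.
#'
#' @param counts A data frame with columns `tp`, `fp`, `fn` (and usually
#'   `tn`), e.g. from [confusion_counts()]. Only the first row is used.
#' @param beta Positive weight on recall; `beta = 2` is the F2 score.
#' @param zero_division Value in \[0, 1\] returned when the score is
#'   undefined.
#'
#' @return A single numeric score in \[0, 1\].
#'
#' @examples
#' f_beta(tibble::tibble(tp = 80, fp = 10, fn = 20, tn = 100))
#' @export
f_beta <- function(counts, beta = 2, zero_division = 0) {
  if (!is.data.frame(counts) || !all(c("tp", "fp", "fn") %in% names(counts))) {
    abort("`counts` must be a data frame with columns tp, fp, fn.")
  }
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0) {
    abort("`beta` must be a single positive number.")
  }
  if (zero_division < 0 || zero_division > 1) {
    abort("`zero_division` must lie in [0, 1].")
  }
  tp <- counts$tp[1L]; fp <- counts$fp[1L]; fn <- counts$fn[1L]
  if (any(c(tp, fp, fn) < 0)) abort("confusion counts must be non-negative.")
  denom <- (1 + beta^2) * tp + fp + beta^2 * fn
  if (denom == 0) {
    warn("F-beta undefined (tp = fp = fn = 0); returning `zero_division`.")
    return(zero_division)
  }
  (1 + beta^2) * tp / denom
}

#' Per-model F-beta scores of a predictions table
#'
#' Thresholds each model's probability column and scores it against the
#' `label` column, yielding the score vector that drives consensus-adaptive
#' weighting.
#'
#' @inheritParams soft_fuse
#' @param beta,zero_division Passed to [f_beta()].
#'
#' @return A tibble with columns `model` and `score`, one row per model
#'   column of `data`, in table order.
#'
#' @examples
#' preds <- simulate_predictions(n_samples = 200, seed = 1)
#' model_scores(preds)
#' @export
model_scores <- function(data, threshold = 0.5, beta = 2, zero_division = 0) {
  validate_predictions(data, require_labels = TRUE)
  check_threshold(threshold)
  mods <- model_cols(data)
  scores <- vapply(mods, function(m) {
    d <- tibble::tibble(label = data$label,
                        pred = as.integer(data[[m]] >= threshold))
    f_beta(confusion_counts(d, .data$label, .data$pred),
           beta = beta, zero_division = zero_division)
  }, numeric(1))
  tibble::tibble(model = mods, score = unname(scores))
}

check_threshold <- function(threshold, call = rlang::caller_env()) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    abort("`threshold` must be a single number strictly inside (0, 1).",
          call = call)
  }
  invisible(threshold)
}
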