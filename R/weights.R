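#' Consensus-adaptive fusion weights
#'
#' Turns a vector of per-model validation scores \eqn{X_i} (F2 scores in
#' this package's workflow, on any common scale) into fusion weights
#' \deqn{w_i = \frac{X_i^{\,C}}{\sum_j X_j^{\,C}}.}
#' With `c = 1` this is plain score-proportional weighting (CAW V1); a
#' larger exponent sharpens the weights toward the better-scoring models
#' (CAW V2), approaching one-hot on the best model as `c` grows. Weights
#' are invariant to the scale of the scores, so percentages and fractions
#' give identical results.
#'
#' The power is computed on the log scale (a softmax over `c * log(X)`),
#' so large exponents neither overflow nor underflow.
#'
#' @param scores A data frame with columns `model` (unique names) and
#'   `score` (non-negative, at least one positive), e.g. from
#'   [model_scores()]; or a named numeric vector.
#' @param c Positive sharpening exponent.
#'
#' @return A tibble with columns `model` and `weight`; weights are
#'   non-negative and sum to 1, in the input's model order.
#'
#' @examples
#' scores <- tibble::tibble(
#'   model = c("efficientnet", "xception", "mobilenetv2",
#'             "inceptionv3", "resnet50"),
#'   score = c(93.89, 92.03, 92.43, 91.01, 88.98)
#' )
#' caw_weights(scores)          # proportional (V1)
#' caw_weights(scores, c = 2.6) # sharpened (V2)
#' @export
caw_weights <- function(scores, c = 1) {
  scores <- as_score_tbl(scores)
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0) {
    abort("`c` must be a single positive number.")
  }
  tibble::tibble(model = scores$model,
                 weight = power_weights(scores$score, c))
}

#' @rdname caw_weights
#' @export
caw_v1_weights <- function(scores) caw_weights(scores, c = 1)

#' @rdname caw_weights
#' @export
caw_v2_weights <- function(scores, c) caw_weights(scores, c = c)

# log-domain power weighting: w_i = x_i^c / sum_j x_j^c, stable for large c.
power_weights <- function(x, c) {
  lw <- c * log(x)                 # zero scores -> -Inf -> weight 0
  lw <- lw - max(lw)
  w <- exp(lw)
  w / sum(w)
}

as_score_tbl <- function(scores, call = rlang::caller_env()) {
  if (is.numeric(scores)) {
    nm <- names(scores) %||% paste0("model_", seq_along(scores))
    scores <- tibble::tibble(model = nm, score = unname(scores))
  }
  if (!is.data.frame(scores) || !all(c("model", "score") %in% names(scores))) {
    abort("`scores` must be a data frame with columns `model` and `score`.",
          call = call)
  }
  if (nrow(scores) < 1L) abort("`scores` has no rows.", call = call)
  if (anyDuplicated(scores$model)) {
    abort("`scores$model` must be unique.", call = call)
  }
  if (anyNA(scores$score) || any(scores$score < 0)) {
    abort("scores must be non-negative and non-missing.", call = call)
  }
  if (all(scores$score == 0)) {
    abort("degenerate score vector: all scores are zero.", call = call)
  }
  tibble::as_tibble(scores[c("model", "score")])
}

#' Exhaustive grid search for the sharpening exponent C
#'
#' Sweeps the exponent of [caw_weights()] over an inclusive grid
#' (default 0.5 to 20 in steps of 0.1, 196 points). For each candidate C
#' and each cross-validation fold, weights are derived from that fold's
#' validation scores, the fold's validation predictions are soft-fused,
#' and the fused labels are scored; the objective is the mean fused
#' F-beta score across folds. The best C is the smallest grid point
#' attaining the maximum — ties go to the least-sharpened weighting.
#'
#' The grid is built by integer stepping (`c_min + k * c_step`) so that
#' repeated floating-point addition cannot drift off the intended points.
#'
#' @inheritParams model_scores
#' @param data A predictions table with a `label` column (see
#'   [read_predictions()] for the format).
#' @param folds Integer vector of fold ids (1..k) aligned to the rows of
#'   `data`, e.g. from [make_folds()].
#' @param c_min,c_max,c_step Inclusive grid bounds and step; all positive,
#'   `c_min <= c_max`.
#'
#' @return An object of class `caw_search`: a list with `best_c`, the
#'   objective value at the optimum (`best_objective`), and `curve`, a
#'   tibble of all `(c, objective)` grid points. Supports [tidy()],
#'   [glance()] and [autoplot()].
#'
#' @examples
#' preds <- simulate_predictions(n_samples = 400, seed = 3)
#' folds <- make_folds(preds, k = 4, seed = 3)
#' fit <- search_c(preds, folds, c_max = 5)
#' glance(fit)
#' @export
search_c <- function(data, folds, c_min = 0.5, c_max = 20, c_step = 0.1,
                     beta = 2, threshold = 0.5) {
  validate_predictions(data, require_labels = TRUE)
  check_threshold(threshold)
  folds <- check_folds(folds, nrow(data))
  grid <- c_grid(c_min, c_max, c_step)

  probs <- prob_matrix(data)
  objective <- matrix(NA_real_, nrow = length(grid),
                      ncol = max(folds))
  for (f in sort(unique(folds))) {
    val <- folds == f
    val_data <- data[val, , drop = FALSE]
    scores <- model_scores(val_data, threshold = threshold, beta = beta)
    # all grid weights at once: models x grid points
    w <- vapply(grid, function(cc) power_weights(scores$score, cc),
                numeric(nrow(scores)))
    fused <- probs[val, , drop = FALSE] %*% w   # samples x grid points
    y <- val_data$label
    objective[, f] <- apply(fused, 2L, function(p) {
      d <- tibble::tibble(label = y, pred = as.integer(p >= threshold))
      f_beta(confusion_counts(d, .data$label, .data$pred), beta = beta)
    })
  }
  curve <- tibble::tibble(c = grid,
                          objective = rowMeans(objective, na.rm = TRUE))
  best <- which.max(curve$objective)  # which.max takes the first maximum
  structure(
    list(best_c = curve$c[best],
         best_objective = curve$objective[best],
         curve = curve),
    class = "caw_search"
  )
}

c_grid <- function(c_min, c_max, c_step, call = rlang::caller_env()) {
  if (!(c_min > 0 && c_min <= c_max && c_step > 0)) {
    abort("grid requires 0 < c_min <= c_max and c_step > 0.", call = call)
  }
  k <- round((c_max - c_min) / c_step)
  c_min + (0:k) * c_step
}

check_folds <- function(folds, n, call = rlang::caller_env()) {
  folds <- as.integer(folds)
  if (length(folds) != n || anyNA(folds) || any(folds < 1L)) {
    abort("`folds` must be positive fold ids, one per row of `data`.",
          call = call)
  }
  folds
}

#' @export
print.caw_search <- function(x, ...) {
  cat("C grid search (", nrow(x$curve), " points, c in [",
      min(x$curve$c), ", ", max(x$curve$c), "])\n", sep = "")
  cat("best c:", format(x$best_c), " mean fused score:",
      format(round(x$best_objective, 4)), "\n")
  invisible(x)
}

#' @rdname search_c
#' @param x A `caw_search` object.
#' @param ... Unused.
#' @export
tidy.caw_search <- function(x, ...) x$curve

#' @rdname search_c
#' @export
glance.caw_search <- function(x, ...) {
  tibble::tibble(best_c = x$best_c,
                 best_objective = x$best_objective,
                 n_grid = nrow(x$curve))
}
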