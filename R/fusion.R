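#' Soft (probability-averaging) ensemble fusion
#'
#' Combines the model probability columns of a predictions table into a
#' single fused probability per sample as the weighted arithmetic mean
#' \eqn{\sum_m w_m p_{im}}, then thresholds it into a fused label. Because
#' the weights are a convex combination, the fused probability always lies
#' between the per-sample minimum and maximum of the model probabilities.
#' This is the "fuzzy" fusion route: models contribute their continuous
#' confidence, not a hard vote.
#'
#' @param data A predictions table (see [read_predictions()]): optional
#'   `sample_id` and `label` columns plus one probability column per model.
#' @param weights A data frame with columns `model` and `weight`, e.g. from
#'   [caw_weights()]. Model names must match the table's model columns
#'   (any order); weights must be non-negative and sum to 1.
#' @param threshold Decision threshold on the fused probability, strictly
#'   inside (0, 1). Samples with fused probability `>= threshold` are
#'   labelled positive.
#'
#' @return A tibble with the table's `sample_id` and `label` columns (when
#'   present) plus `fused_prob` and `fused_label`.
#'
#' @examples
#' preds <- simulate_predictions(n_samples = 100, seed = 1)
#' w <- caw_weights(model_scores(preds), c = 2.6)
#' soft_fuse(preds, w)
#' @export
soft_fuse <- function(data, weights, threshold = 0.5) {
  validate_predictions(data)
  check_threshold(threshold)
  w <- align_weights(weights, model_cols(data))
  fused <- as.vector(prob_matrix(data) %*% w)
  # guard against tiny negative/overshoot from floating-point dot products
  fused <- pmin(pmax(fused, 0), 1)
  out <- data[intersect(c("sample_id", "label"), names(data))]
  out$fused_prob <- fused
  out$fused_label <- as.integer(fused >= threshold)
  tibble::as_tibble(out)
}

#' Majority-vote ensemble fusion
#'
#' The classical hard-fusion baseline: each model casts a binary vote by
#' thresholding its own probability, and the ensemble label is the most
#' frequent vote. With an even number of models an exact tie is resolved
#' by `tie_rule`; the default calls ties positive, the conservative choice
#' when missing a positive case is costlier than a false alarm.
#'
#' @inheritParams soft_fuse
#' @param tie_rule Label assigned on an exact vote tie: `"positive"` (1)
#'   or `"negative"` (0).
#'
#' @return A tibble with the table's `sample_id` and `label` columns (when
#'   present) plus `n_votes` (positive votes) and `vote_label`.
#'
#' @examples
#' preds <- simulate_predictions(n_samples = 100, seed = 1)
#' majority_vote(preds)
#' @export
majority_vote <- function(data, threshold = 0.5,
                          tie_rule = c("positive", "negative")) {
  validate_predictions(data)
  check_threshold(threshold)
  tie_rule <- match.arg(tie_rule)
  votes <- prob_matrix(data) >= threshold
  n_votes <- rowSums(votes)
  n_models <- ncol(votes)
  lab <- ifelse(n_votes * 2 == n_models,
                as.integer(tie_rule == "positive"),
                as.integer(n_votes * 2 > n_models))
  out <- data[intersect(c("sample_id", "label"), names(data))]
  out$n_votes <- as.integer(n_votes)
  out$vote_label <- lab
  tibble::as_tibble(out)
}

# Reorder a weights table to `models`; validates names, range and sum.
align_weights <- function(weights, models, call = rlang::caller_env()) {
  if (!is.data.frame(weights) ||
      !all(c("model", "weight") %in% names(weights))) {
    abort("`weights` must be a data frame with columns `model` and `weight`.",
          call = call)
  }
  if (!setequal(weights$model, models) ||
      length(weights$model) != length(models)) {
    abort(paste0("weight models {", toString(weights$model),
                 "} do not match prediction columns {",
                 toString(models), "}."), call = call)
  }
  w <- weights$weight[match(models, weights$model)]
  if (anyNA(w) || any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    abort("weights must be non-negative and sum to 1 (within 1e-9).",
          call = call)
  }
  w
}
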