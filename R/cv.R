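#' Stratified cross-validation folds
#'
#' Assigns each row of a labelled predictions table to one of `k` folds.
#' Stratified assignment (the default) partitions each class separately,
#' so per-class counts differ by at most one across folds — essential at
#' low prevalence, where unstratified folds can end up with no positive
#' validation samples at all.
#'
#' @inheritParams search_c
#' @param k Number of folds, at least 2 and at most `nrow(data)`.
#' @param seed Optional integer; when given, the assignment is reproducible
#'   and the caller's RNG state is left untouched.
#' @param stratified Stratify by `label` (default) or partition at random.
#'
#' @return An integer vector of fold ids in `1..k`, one per row.
#'
#' @examples
#' preds <- simulate_predictions(n_samples = 103, seed = 1)
#' table(make_folds(preds, k = 4, seed = 1), preds$label)
#' @export
make_folds <- function(data, k = 4, seed = NULL, stratified = TRUE) {
  validate_predictions(data, require_labels = TRUE)
  n <- nrow(data)
  if (!is.numeric(k) || length(k) != 1L || k < 2 || k > n) {
    abort("`k` must satisfy 2 <= k <= nrow(data).")
  }
  k <- as.integer(k)
  labels <- data$label
  if (length(unique(labels)) < 2L) {
    abort("both classes must be present to build folds.")
  }
  strata <- if (stratified) labels else rep(0L, n)
  with_seed_or_rng(seed, {
    fold_of <- integer(n)
    sizes <- integer(k)
    for (cl in unique(strata)) {
      idx <- sample(which(strata == cl))
      cnt <- length(idx)
      cls_counts <- rep(cnt %/% k, k)
      r <- cnt %% k
      if (r > 0) {
        # remainders go to the currently least-filled folds (random ties),
        # keeping overall fold sizes within one of each other
        ord <- order(sizes, stats::runif(k))
        cls_counts[ord[seq_len(r)]] <- cls_counts[ord[seq_len(r)]] + 1L
      }
      fold_of[idx] <- rep(seq_len(k), times = cls_counts)
      sizes <- sizes + cls_counts
    }
    fold_of
  })
}

#' Stratified train/test split
#'
#' Holds out a fraction of a labelled predictions table as a test set,
#' stratified by class, mirroring the usual 80/20 protocol that precedes
#' cross-validation.
#'
#' @inheritParams make_folds
#' @param test_frac Fraction of each class held out, strictly in (0, 1).
#'
#' @return A list with tibbles `train` and `test`.
#'
#' @examples
#' preds <- simulate_predictions(n_samples = 500, seed = 1)
#' sp <- train_test_split(preds, seed = 1)
#' nrow(sp$test)
#' @export
train_test_split <- function(data, test_frac = 0.2, seed = NULL) {
  validate_predictions(data, require_labels = TRUE)
  if (test_frac <= 0 || test_frac >= 1) {
    abort("`test_frac` must lie strictly in (0, 1).")
  }
  test_idx <- with_seed_or_rng(seed, {
    unlist(lapply(unique(data$label), function(cl) {
      idx <- which(data$label == cl)
      sample(idx, size = round(length(idx) * test_frac))
    }), use.names = FALSE)
  })
  list(train = tibble::as_tibble(data[-test_idx, , drop = FALSE]),
       test  = tibble::as_tibble(data[test_idx, , drop = FALSE]))
}

#' Cross-validated evaluation of base models and fusion methods
#'
#' The package's main harness. For each fold it scores every base model on
#' the fold's validation samples, derives score-proportional (V1) weights,
#' and scores majority vote and V1 soft fusion on that fold. A single
#' exhaustive [search_c()] across all folds selects the sharpening
#' exponent; V2 soft fusion is then scored per fold with weights from that
#' fold's scores at the selected C. Scores are reported as mean ± sample
#' standard deviation across folds on the percent scale, together with the
#' summary statistics of [summarize_methods()]. The deployable weight
#' vectors (`weights_v1`, `weights_v2`) are computed from the
#' fold-averaged model scores.
#'
#' @inheritParams search_c
#' @inheritParams majority_vote
#' @param k Fold count used when `folds` is not supplied.
#' @param folds Optional precomputed fold ids from [make_folds()].
#' @param seed Optional integer seed for fold assignment.
#'
#' @return An object of class `caw_cv`: a list with
#'   \describe{
#'     \item{per_method}{tibble `method`, `mean`, `sd` (percent F2 across
#'       folds); methods are the model columns plus `majority_vote`,
#'       `caw_v1`, `caw_v2`.}
#'     \item{fold_scores}{tibble `fold`, `method`, `score` (percent).}
#'     \item{weights_v1, weights_v2}{deployable weight tibbles.}
#'     \item{best_c}{selected exponent; `c_search` holds the full curve.}
#'     \item{summary}{one-row tibble from [summarize_methods()].}
#'   }
#'   Supports [tidy()], [glance()] and [autoplot()].
#'
#' @examples
#' preds <- simulate_predictions(n_samples = 600, seed = 7)
#' fit <- run_cv(preds, k = 4, seed = 7, c_max = 5)
#' tidy(fit)
#' glance(fit)
#' @export
run_cv <- function(data, k = 4, folds = NULL, seed = NULL,
                   c_min = 0.5, c_max = 20, c_step = 0.1,
                   beta = 2, threshold = 0.5,
                   tie_rule = c("positive", "negative")) {
  validate_predictions(data, require_labels = TRUE)
  tie_rule <- match.arg(tie_rule)
  if (is.null(folds)) folds <- make_folds(data, k = k, seed = seed)
  folds <- check_folds(folds, nrow(data))
  fold_ids <- sort(unique(folds))
  mods <- model_cols(data)

  per_fold <- purrr::map(fold_ids, function(f) {
    val <- data[folds == f, , drop = FALSE]
    if (sum(val$label == 1) == 0L || sum(val$label == 0) == 0L) {
      abort(paste0("fold ", f, " validation part lacks one class; ",
                   "use stratified folds."))
    }
    scores <- model_scores(val, threshold = threshold, beta = beta)
    list(fold = f, val = val, scores = scores)
  })

  srch <- search_c(data, folds, c_min = c_min, c_max = c_max,
                   c_step = c_step, beta = beta, threshold = threshold)

  score_fused <- function(val, labels_col) {
    d <- tibble::tibble(label = val$label, pred = labels_col)
    100 * f_beta(confusion_counts(d, .data$label, .data$pred), beta = beta)
  }
  fold_scores <- purrr::map_dfr(per_fold, function(pf) {
    val <- pf$val
    w1 <- caw_weights(pf$scores, c = 1)
    w2 <- caw_weights(pf$scores, c = srch$best_c)
    tibble::tibble(
      fold = pf$fold,
      method = c(mods, "majority_vote", "caw_v1", "caw_v2"),
      score = c(100 * pf$scores$score,
                score_fused(val, majority_vote(val, threshold,
                                               tie_rule)$vote_label),
                score_fused(val, soft_fuse(val, w1, threshold)$fused_label),
                score_fused(val, soft_fuse(val, w2, threshold)$fused_label))
    )
  })

  per_method <- fold_scores |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(mean = mean(.data$score),
                     sd = stats::sd(.data$score), .groups = "drop") |>
    dplyr::arrange(match(.data$method,
                         c(mods, "majority_vote", "caw_v1", "caw_v2")))

  avg_scores <- per_fold |>
    purrr::map_dfr("scores") |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(score = mean(.data$score), .groups = "drop") |>
    dplyr::arrange(match(.data$model, mods))

  structure(
    list(per_method = per_method,
         fold_scores = fold_scores,
         weights_v1 = caw_weights(avg_scores, c = 1),
         weights_v2 = caw_weights(avg_scores, c = srch$best_c),
         best_c = srch$best_c,
         c_search = srch,
         summary = summarize_methods(
           tibble::deframe(per_method[c("method", "mean")])),
         config = list(k = length(fold_ids), beta = beta,
                       threshold = threshold, tie_rule = tie_rule,
                       c_min = c_min, c_max = c_max, c_step = c_step,
                       seed = seed)),
    class = "caw_cv"
  )
}

#' Gap between the best and worst model scores
#'
#' `max(score) - min(score)`, on the scale of the input. Larger gaps
#' between base models are where sharpened (V2) weighting has the most
#' room to help.
#'
#' @inheritParams caw_weights
#'
#' @return A single number.
#'
#' @examples
#' best_worst_gap(c(63.76, 66.75, 60.58, 71.20, 67.42))
#' @export
best_worst_gap <- function(scores) {
  scores <- as_score_tbl(scores)
  if (nrow(scores) < 2L) abort("need at least two models.")
  max(scores$score) - min(scores$score)
}

#' Summary statistics over a column of method scores
#'
#' Given one F2 score per method — the base models plus the reserved
#' methods `majority_vote`, `caw_v1` and `caw_v2` — computes the mean over
#' all methods, the gain of V2 fusion over the best base model, and the
#' gain of V2 over V1.
#'
#' @param f2_by_method Named numeric vector or two-column data frame
#'   (`method`, `score`-like) of scores on the percent scale; must contain
#'   `majority_vote`, `caw_v1`, `caw_v2` and at least one base model.
#'
#' @return A one-row tibble with `mean_of_methods`,
#'   `improvement_over_best_base` and `improvement_v2_over_v1`.
#'
#' @examples
#' summarize_methods(c(
#'   efficientnet = 93.89, xception = 92.03, mobilenetv2 = 92.43,
#'   inceptionv3 = 91.01, resnet50 = 88.98,
#'   majority_vote = 94.12, caw_v1 = 94.55, caw_v2 = 95.48
#' ))
#' @export
summarize_methods <- function(f2_by_method) {
  if (is.data.frame(f2_by_method)) {
    if (ncol(f2_by_method) < 2L) {
      abort("`f2_by_method` needs a method column and a score column.")
    }
    f2_by_method <- tibble::deframe(f2_by_method[1:2])
  }
  x <- f2_by_method
  ensemble <- c("majority_vote", "caw_v1", "caw_v2")
  missing <- setdiff(ensemble, names(x))
  if (length(missing) > 0L) {
    abort(paste0("missing methods: ", toString(missing), "."))
  }
  base <- x[setdiff(names(x), ensemble)]
  if (length(base) == 0L) abort("no base-model scores supplied.")
  tibble::tibble(
    mean_of_methods = mean(x),
    improvement_over_best_base = unname(x["caw_v2"] - max(base)),
    improvement_v2_over_v1 = unname(x["caw_v2"] - x["caw_v1"])
  )
}

#' @export
print.caw_cv <- function(x, ...) {
  cat("Cross-validated CAW evaluation (", x$config$k, " folds, beta = ",
      x$config$beta, ")\n", sep = "")
  cat("selected C:", format(x$best_c), "\n\n")
  print(dplyr::mutate(x$per_method,
                      dplyr::across(c("mean", "sd"), ~ round(.x, 2))))
  cat("\n")
  print(dplyr::mutate(x$summary, dplyr::across(dplyr::everything(),
                                               ~ round(.x, 2))))
  invisible(x)
}

#' @rdname run_cv
#' @param x A `caw_cv` object.
#' @param ... Unused.
#' @export
tidy.caw_cv <- function(x, ...) x$per_method

#' @rdname run_cv
#' @export
glance.caw_cv <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(best_c = x$best_c,
                                  k = x$config$k), x$summary)
}
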