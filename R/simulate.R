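#' Simulate correlated probabilistic classifier outputs
#'
#' Generates a labelled predictions table emulating the outputs of several
#' trained binary classifiers on the same test set, so every fusion and
#' evaluation step can be exercised without any trained model. Labels are
#' drawn independently at the given prevalence. Each sample carries a
#' latent signal \eqn{s = +1} (positive) or \eqn{-1} (negative) and a
#' shared noise draw \eqn{u}; model \eqn{m}'s raw score is
#' \deqn{z_{im} = d_m s_i + \sigma\left(\sqrt{\rho}\, u_i +
#'   \sqrt{1-\rho}\, e_{im}\right)}
#' with independent per-model noise \eqn{e_{im}}, mapped to (0, 1) by the
#' logistic function. The gain \eqn{d_m} ("discrimination") controls how
#' well model m separates the classes; \eqn{\rho} is the fraction of noise
#' variance shared across models, so \eqn{\rho = 1} with equal gains makes
#' all model columns identical and \eqn{\rho = 0} makes their errors
#' independent.
#'
#' The defaults mimic a screening-mammography ensemble: five models of
#' unequal but overlapping skill, substantially correlated errors (the
#' models saw the same images), and 14% positive prevalence.
#'
#' @param n_samples Number of samples.
#' @param prevalence Positive-class probability, strictly in (0, 1).
#' @param discriminations Non-negative latent signal gain per model; its
#'   length sets the number of models.
#' @param correlation Shared-noise fraction in \[0, 1\].
#' @param noise_sd Standard deviation of the total noise, positive.
#' @param model_ids Optional model column names; defaults to
#'   `model_1 ... model_m`.
#' @param seed Optional integer for full reproducibility.
#'
#' @return A predictions table: tibble with `sample_id`, `label` and one
#'   probability column per model.
#'
#' @examples
#' preds <- simulate_predictions(n_samples = 1000, seed = 42)
#' model_scores(preds)
#' @export
simulate_predictions <- function(n_samples = 2000,
                                 prevalence = 0.14,
                                 discriminations = c(2.2, 1.8, 1.9, 1.6, 1.3),
                                 correlation = 0.5,
                                 noise_sd = 1,
                                 model_ids = NULL,
                                 seed = NULL) {
  if (n_samples < 1) abort("`n_samples` must be at least 1.")
  if (prevalence <= 0 || prevalence >= 1) {
    abort("`prevalence` must lie strictly in (0, 1).")
  }
  if (any(discriminations < 0) || length(discriminations) < 1L) {
    abort("`discriminations` must be non-negative, length >= 1.")
  }
  if (correlation < 0 || correlation > 1) {
    abort("`correlation` must lie in [0, 1].")
  }
  if (noise_sd <= 0) abort("`noise_sd` must be positive.")
  m <- length(discriminations)
  model_ids <- model_ids %||% paste0("model_", seq_len(m))
  if (length(model_ids) != m || anyDuplicated(model_ids)) {
    abort("`model_ids` must be unique and match `discriminations`.")
  }

  with_seed_or_rng(seed, {
    label <- rbinom(n_samples, 1L, prevalence)
    s <- ifelse(label == 1L, 1, -1)
    u <- rnorm(n_samples)
    e <- matrix(rnorm(n_samples * m), nrow = n_samples)
    z <- outer(s, discriminations) +
      noise_sd * (sqrt(correlation) * u +
                    sqrt(1 - correlation) * e)
    probs <- plogis(z)
    colnames(probs) <- model_ids
    dplyr::bind_cols(
      tibble::tibble(sample_id = sprintf("s%05d", seq_len(n_samples)),
                     label = label),
      tibble::as_tibble(probs)
    )
  })
}
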