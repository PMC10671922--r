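test_that("folds partition the samples with near-equal sizes per class", {
  preds <- simulate_predictions(n_samples = 103, prevalence = 0.4, seed = 51)
  folds <- make_folds(preds, k = 4, seed = 51)
  expect_length(folds, 103)
  expect_setequal(unique(folds), 1:4)
  sizes <- as.vector(table(folds))
  expect_setequal(sizes, c(26, 26, 26, 25))   # counting oracle for n = 103
  per_class <- table(folds, preds$label)
  expect_true(all(apply(per_class, 2, function(x) max(x) - min(x)) <= 1))
})

test_that("fold assignment is reproducible under a fixed seed", {
  preds <- simulate_predictions(n_samples = 200, seed = 52)
  expect_identical(make_folds(preds, k = 4, seed = 9),
                   make_folds(preds, k = 4, seed = 9))
})

test_that("fold construction rejects degenerate requests", {
  preds <- simulate_predictions(n_samples = 20, prevalence = 0.5, seed = 53)
  expect_error(make_folds(preds, k = 25), "2 <= k")
  single <- dplyr::mutate(preds, label = 1L)
  expect_error(make_folds(single, k = 2), "both classes")
})

test_that("stratified train/test split holds out the right fraction", {
  preds <- simulate_predictions(n_samples = 500, prevalence = 0.2, seed = 54)
  sp <- train_test_split(preds, test_frac = 0.2, seed = 54)
  expect_equal(nrow(sp$test), round(sum(preds$label == 1) * 0.2) +
                 round(sum(preds$label == 0) * 0.2))
  expect_equal(nrow(sp$train) + nrow(sp$test), 500)
  expect_equal(sum(sp$test$label == 1), round(sum(preds$label == 1) * 0.2))
})

test_that("identical models collapse every method to the single-model F2", {
  withr::with_seed(55, {
    label <- rbinom(120, 1, 0.4)
    p <- plogis(2 * ifelse(label == 1, 1, -1) + rnorm(120))
    preds <- make_preds(cbind(p, p, p), labels = label)
  })
  fit <- run_cv(preds, k = 3, seed = 55, c_max = 3)
  means <- fit$per_method$mean
  expect_equal(means, rep(means[1], length(means)), tolerance = 1e-9)
  expect_length(means, 6)   # three models + three fusion methods
  expect_equal(fit$weights_v1$weight, rep(1 / 3, 3))
  expect_equal(fit$weights_v2$weight, rep(1 / 3, 3))
})

test_that("report is deterministic under a fixed seed and recomputable", {
  preds <- simulate_predictions(n_samples = 400, seed = 56)
  a <- run_cv(preds, k = 4, seed = 3, c_max = 4)
  b <- run_cv(preds, k = 4, seed = 3, c_max = 4)
  expect_equal(a$per_method, b$per_method)
  expect_equal(a$best_c, b$best_c)

  # round trip: per-model fold scores recompute from the fold's rows
  folds <- make_folds(preds, k = 4, seed = 3)
  c2 <- run_cv(preds, folds = folds, c_max = 4)
  for (f in 1:4) {
    sc <- model_scores(preds[folds == f, ])
    got <- dplyr::filter(c2$fold_scores, fold == f,
                         !method %in% c("majority_vote", "caw_v1", "caw_v2"))
    expect_equal(got$score, 100 * sc$score)
  }

  # derived summary recomputes exactly from the per-method means
  expect_equal(c2$summary,
               summarize_methods(tibble::deframe(
                 c2$per_method[c("method", "mean")])))
})

test_that("sharpened fusion beats proportional fusion given one strong model", {
  # Monte-Carlo check: one near-perfect model among weak correlated ones
  preds <- simulate_predictions(
    n_samples = 10000, prevalence = 0.3,
    discriminations = c(6, 0.4, 0.4, 0.4, 0.4),
    correlation = 0.2, seed = 57)
  fit <- run_cv(preds, k = 4, seed = 57, c_max = 10)
  m <- tibble::deframe(fit$per_method[c("method", "mean")])
  uniform <- soft_fuse(preds, uniform_weights(model_cols(preds)))
  uni_f2 <- 100 * f_beta(confusion_counts(
    tibble::tibble(l = preds$label, p = uniform$fused_label), l, p))
  expect_gte(m[["caw_v2"]], m[["caw_v1"]])
  expect_gte(m[["caw_v1"]], uni_f2 - 1e-9)
  # V2's weight on the known-best model at least matches V1's
  expect_gte(fit$weights_v2$weight[1], fit$weights_v1$weight[1])
  expect_gte(fit$best_c, 1)
})

test_that("a validation fold with one class only is refused with advice", {
  preds <- make_preds(matrix(stats::runif(12), ncol = 2),
                      labels = rep(c(1, 0), each = 3))
  expect_error(run_cv(preds, folds = rep(c(1, 2), each = 3), c_max = 2),
               "stratified")
})

test_that("best_worst_gap is max minus min on the input scale", {
  expect_equal(best_worst_gap(f2_inbreast), 10.62)      # published gap
  expect_equal(best_worst_gap(c(a = 5, b = 1, c = 3)), 4)
  expect_equal(best_worst_gap(c(a = 2, b = 2)), 0)
  expect_error(best_worst_gap(c(a = 1)), "two models")
})

test_that("summarize_methods reproduces the published derived statistics", {
  cols <- list(cropped = methods_cropped_ddsm, ddsm = methods_ddsm,
               inbreast = methods_inbreast)
  expected <- list(
    cropped = c(92.81, 1.59, 0.93),
    ddsm = c(76.08, 1.32, 0.69),
    inbreast = c(68.21, 1.11, 0.33)
  )
  for (nm in names(cols)) {
    s <- summarize_methods(cols[[nm]])
    expect_equal(round(s$mean_of_methods, 2), expected[[nm]][1])
    expect_equal(round(s$improvement_over_best_base, 2), expected[[nm]][2])
    expect_equal(round(s$improvement_v2_over_v1, 2), expected[[nm]][3])
  }
  expect_error(summarize_methods(methods_ddsm[1:6]), "missing methods")
})

test_that("tidy and glance expose the report tables", {
  preds <- simulate_predictions(n_samples = 300, seed = 58)
  fit <- run_cv(preds, k = 3, seed = 58, c_max = 3)
  expect_identical(tidy(fit), fit$per_method)
  g <- glance(fit)
  expect_equal(g$best_c, fit$best_c)
  expect_equal(g$mean_of_methods, fit$summary$mean_of_methods)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(fit$c_search), "ggplot")
})
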