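# Published per-model F2 columns (percent) used as worked-value fixtures,
# in fixed model order: EfficientNet, Xception, MobileNetV2, InceptionV3,
# ResNet50, then the three fusion methods where applicable.
ensemble_models <- c("efficientnet", "xception", "mobilenetv2",
                     "inceptionv3", "resnet50")

f2_cropped_ddsm <- tibble::tibble(
  model = ensemble_models,
  score = c(93.89, 92.03, 92.43, 91.01, 88.98)
)
f2_ddsm <- tibble::tibble(
  model = ensemble_models,
  score = c(81.03, 68.06, 69.56, 76.74, 67.93)
)
f2_inbreast <- tibble::tibble(
  model = ensemble_models,
  score = c(63.76, 66.75, 60.58, 71.20, 67.42)
)

# Full method columns (five base models + majority vote + CAW V1 + V2).
methods_cropped_ddsm <- c(
  efficientnet = 93.89, xception = 92.03, mobilenetv2 = 92.43,
  inceptionv3 = 91.01, resnet50 = 88.98,
  majority_vote = 94.12, caw_v1 = 94.55, caw_v2 = 95.48
)
methods_ddsm <- c(
  efficientnet = 81.03, xception = 68.06, mobilenetv2 = 69.56,
  inceptionv3 = 76.74, resnet50 = 67.93,
  majority_vote = 81.32, caw_v1 = 81.66, caw_v2 = 82.35
)
methods_inbreast <- c(
  efficientnet = 63.76, xception = 66.75, mobilenetv2 = 60.58,
  inceptionv3 = 71.20, resnet50 = 67.42,
  majority_vote = 71.68, caw_v1 = 71.98, caw_v2 = 72.31
)

# Small hand-buildable predictions table.
make_preds <- function(probs, labels = NULL, models = NULL) {
  probs <- as.matrix(probs)
  models <- models %||% paste0("m", seq_len(ncol(probs)))
  colnames(probs) <- models
  out <- tibble::as_tibble(probs)
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = paste0("s", seq_len(nrow(probs)))), out)
  if (!is.null(labels)) {
    out <- dplyr::mutate(out, label = labels, .after = "sample_id")
  }
  out
}

uniform_weights <- function(models) {
  tibble::tibble(model = models, weight = rep(1 / length(models),
                                              length(models)))
}

`%||%` <- rlang::`%||%`
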