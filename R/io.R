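#' Read and write predictions tables
#'
#' The on-disk interchange format is plain comma-separated text with a
#' header: `sample_id`, `label` (0/1, may be empty throughout) and one
#' probability column per model. `read_predictions()` validates the file
#' on the way in — unique sample ids, binary labels, probabilities inside
#' \[0, 1\] — and names the offending row and column on failure.
#'
#' @param path Path to a CSV file.
#'
#' @return `read_predictions()` returns a validated predictions table
#'   (tibble); `write_predictions()` returns `data` invisibly.
#'
#' @examples
#' preds <- simulate_predictions(n_samples = 20, seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_predictions(preds, f)
#' identical(dim(read_predictions(f)), dim(preds))
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  data <- readr::read_csv(path, show_col_types = FALSE,
                          progress = FALSE, col_types = readr::cols())
  if (!"sample_id" %in% names(data)) {
    abort("malformed header: `sample_id` column missing.")
  }
  if ("label" %in% names(data)) {
    if (all(is.na(data$label))) {
      data$label <- NULL   # empty label column means unlabelled
    } else {
      data$label <- as.integer(data$label)
    }
  }
  validate_predictions(data)
  data
}

#' @rdname read_predictions
#' @param data A predictions table.
#' @export
write_predictions <- function(data, path) {
  validate_predictions(data)
  readr::write_csv(data, path, progress = FALSE)
  invisible(data)
}

#' Read and write weight tables
#'
#' Two-column CSV (`model`, `weight`); weights are written at 6 decimal
#' places, so tables rounded further (e.g. to 3 d.p. for display) should
#' be compared after re-rounding.
#'
#' @param path Path to a CSV file.
#'
#' @return `read_weights()` returns a tibble with `model` and `weight`;
#'   `write_weights()` returns `weights` invisibly.
#' @export
read_weights <- function(path) {
  w <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("model", "weight") %in% names(w))) {
    abort("weights file needs columns `model` and `weight`.")
  }
  tibble::as_tibble(w)
}

#' @rdname read_weights
#' @param weights A data frame with columns `model` and `weight`.
#' @export
write_weights <- function(weights, path) {
  align_weights(weights, weights$model)  # validation only
  out <- weights
  out$weight <- round(out$weight, 6)
  readr::write_csv(out, path, progress = FALSE)
  invisible(weights)
}
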