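#' The predictions-table convention
#'
#' Most functions in cawfuse operate on a *predictions table*: a data frame
#' with one row per sample, an optional `sample_id` column (unique
#' identifiers), an optional `label` column (0/1 true class, 1 = positive),
#' and one numeric column per base model holding that model's predicted
#' probability of the positive class, in \[0, 1\]. Every column that is not
#' `sample_id` or `label` is treated as a model column.
#'
#' @name predictions-table
#' @keywords internal
NULL

#' Names of the model probability columns of a predictions table
#'
#' Every column other than `sample_id` and `label`, in table order.
#'
#' @param data A predictions table.
#' @return A character vector of model column names.
#' @export
model_cols <- function(data) {
  setdiff(names(data), c("sample_id", "label"))
}

# Validate a predictions table; returns it invisibly. `require_labels`
# additionally demands a complete binary label column.
validate_predictions <- function(data, require_labels = FALSE,
                                 call = rlang::caller_env()) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame (predictions table).", call = call)
  }
  mods <- model_cols(data)
  if (length(mods) == 0L) {
    abort("predictions table has no model columns.", call = call)
  }
  if (nrow(data) == 0L) {
    abort("predictions table has no rows.", call = call)
  }
  if ("sample_id" %in% names(data) && anyDuplicated(data$sample_id)) {
    dup <- data$sample_id[duplicated(data$sample_id)][1L]
    abort(paste0("duplicate sample_id: ", dup), call = call)
  }
  for (m in mods) {
    p <- data[[m]]
    if (!is.numeric(p)) {
      abort(paste0("model column '", m, "' is not numeric."), call = call)
    }
    bad <- which(!is.finite(p) | p < 0 | p > 1)
    if (length(bad) > 0L) {
      abort(paste0("model column '", m, "', row ", bad[1L],
                   ": probability ", format(p[bad[1L]]),
                   " outside [0, 1]."), call = call)
    }
  }
  if (require_labels) {
    if (!"label" %in% names(data)) {
      abort("predictions table must have a `label` column.", call = call)
    }
    check_binary(data$label, "label", call = call)
  } else if ("label" %in% names(data) && !all(is.na(data$label))) {
    check_binary(data$label, "label", call = call)
  }
  invisible(data)
}

check_binary <- function(x, name, call = rlang::caller_env()) {
  if (length(x) == 0L) abort(paste0("`", name, "` is empty."), call = call)
  if (anyNA(x) || !all(x %in% c(0, 1))) {
    abort(paste0("`", name, "` must contain only 0 and 1."), call = call)
  }
  invisible(x)
}

# n x m numeric matrix of model probabilities, columns in table order.
prob_matrix <- function(data) {
  mods <- model_cols(data)
  m <- as.matrix(data[mods])
  storage.mode(m) <- "double"
  colnames(m) <- mods
  m
}

# Run `code` under a temporary RNG state seeded with `seed`; with seed NULL
# the current RNG stream is used (and advanced).
with_seed_or_rng <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
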