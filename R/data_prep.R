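#' Balance classes by undersampling the majority class
#'
#' Keeps every minority-class row and a uniformly random subset of the
#' majority class of the same size, the standard remedy when one class
#' dwarfs the other (e.g. reducing 48,600 negatives against 7,290
#' positives to 7,290 of each). Already-balanced input is returned
#' unchanged.
#'
#' @param data A data frame with a binary `label` column (0/1).
#' @param seed Optional integer; makes the majority subset reproducible.
#'
#' @return The retained rows as a tibble, `2 * min(class counts)` of them,
#'   in original row order.
#'
#' @examples
#' d <- tibble::tibble(label = rep(c(1, 0), c(10, 40)))
#' table(undersample_balance(d, seed = 1)$label)
#' @export
undersample_balance <- function(data, seed = NULL) {
  if (!is.data.frame(data) || !"label" %in% names(data)) {
    abort("`data` must be a data frame with a `label` column.")
  }
  check_binary(data$label, "label")
  counts <- table(factor(data$label, levels = c(0, 1)))
  if (any(counts == 0)) abort("both classes must be present.")
  minority <- as.numeric(names(counts)[which.min(counts)])
  n_min <- min(counts)
  keep_minor <- which(data$label == minority)
  major_idx <- which(data$label != minority)
  keep_major <- with_seed_or_rng(seed, sample(major_idx, n_min))
  tibble::as_tibble(data[sort(c(keep_minor, keep_major)), , drop = FALSE])
}

#' Class-balanced training batches
#'
#' Splits a labelled table into batches of `batch_size` rows, each holding
#' exactly half of each class — the per-batch class equalization used when
#' a dataset is too small to undersample outright. Per epoch, each class
#' is consumed as a random permutation, so no row of a class repeats until
#' that class is exhausted; the smaller class (and the tail of the larger
#' one, to fill the final batch) is then re-drawn as needed.
#'
#' @inheritParams undersample_balance
#' @param batch_size Even batch size, at least 2.
#'
#' @return A tibble with columns `batch` (1..n_batches), `row` (row index
#'   into `data`) and `label`. The number of batches is
#'   `ceiling(majority count / (batch_size / 2))`, enough for one pass
#'   over the majority class.
#'
#' @examples
#' d <- tibble::tibble(label = rep(c(1, 0), c(100, 60)))
#' b <- make_balanced_batches(d, batch_size = 32, seed = 1)
#' table(b$batch, b$label)  # every batch 16/16
#' @export
make_balanced_batches <- function(data, batch_size = 32, seed = NULL) {
  if (!is.data.frame(data) || !"label" %in% names(data)) {
    abort("`data` must be a data frame with a `label` column.")
  }
  check_binary(data$label, "label")
  if (length(batch_size) != 1L || batch_size < 2 || batch_size %% 2 != 0) {
    abort("`batch_size` must be even and >= 2.")
  }
  half <- batch_size / 2
  idx0 <- which(data$label == 0)
  idx1 <- which(data$label == 1)
  if (length(idx0) == 0L || length(idx1) == 0L) {
    abort("both classes must be present.")
  }
  n_batches <- ceiling(max(length(idx0), length(idx1)) / half)
  need <- n_batches * half
  with_seed_or_rng(seed, {
    draw <- function(idx) {
      # concatenated random permutations: no repeats until exhaustion
      reps <- ceiling(need / length(idx))
      seq <- unlist(replicate(reps, sample(idx), simplify = FALSE))
      seq[seq_len(need)]
    }
    seq0 <- draw(idx0)
    seq1 <- draw(idx1)
    tibble::tibble(
      batch = rep(seq_len(n_batches), each = batch_size),
      row = as.vector(rbind(matrix(seq1, nrow = half),
                            matrix(seq0, nrow = half))),
    ) |>
      dplyr::mutate(label = data$label[.data$row])
  })
}

#' Plan augmentation counts to a balanced target size
#'
#' Computes how many augmented copies each class needs so that both
#' classes reach `target_total / 2` rows, originals included — a count
#' contract for an external augmenter (the affine image transforms
#' themselves are out of scope here). Copies are spread across originals
#' as evenly as possible: per-original copy counts differ by at most one.
#'
#' @inheritParams undersample_balance
#' @param target_total Even total size after augmentation; each class's
#'   half must be at least its original count.
#'
#' @return A tibble with one row per class: `label`, `n_originals`,
#'   `n_copies`, `n_total` (`= target_total / 2`), and a list column
#'   `copies_per_original` of per-original copy counts (descending).
#'
#' @examples
#' d <- tibble::tibble(label = rep(c(1, 0), c(80, 248)))
#' plan_augmentation(d, target_total = 4000)
#' @export
plan_augmentation <- function(data, target_total) {
  if (!is.data.frame(data) || !"label" %in% names(data)) {
    abort("`data` must be a data frame with a `label` column.")
  }
  check_binary(data$label, "label")
  if (length(target_total) != 1L || target_total < 2 ||
      target_total %% 2 != 0) {
    abort("`target_total` must be even and >= 2.")
  }
  per_class <- target_total / 2
  counts <- table(factor(data$label, levels = c(0, 1)))
  if (any(counts > per_class)) {
    abort(paste0("target_total/2 = ", per_class,
                 " is below a class's original count (",
                 max(counts), ")."))
  }
  purrr::map_dfr(c(0, 1), function(cl) {
    n_orig <- unname(counts[as.character(cl)])
    n_copies <- per_class - n_orig
    base <- n_copies %/% n_orig
    extra <- n_copies %% n_orig
    tibble::tibble(
      label = cl,
      n_originals = as.integer(n_orig),
      n_copies = as.integer(n_copies),
      n_total = as.integer(per_class),
      copies_per_original = list(rep(c(base + 1L, base),
                                     c(extra, n_orig - extra)))
    )
  })
}
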