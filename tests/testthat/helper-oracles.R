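# Brute-force oracle for the C search: loop over every grid point and
# recompute weights and fused scores per fold with plain arithmetic,
# sharing no code with search_c's vectorized path.
brute_force_curve <- function(data, folds, grid, threshold = 0.5) {
  f2_hand <- function(truth, pred) {
    tp <- sum(truth == 1 & pred == 1)
    fp <- sum(truth == 0 & pred == 1)
    fn <- sum(truth == 1 & pred == 0)
    if (tp + fp + fn == 0) 0 else 5 * tp / (5 * tp + fp + 4 * fn)
  }
  vapply(grid, function(cc) {
    per_fold <- vapply(sort(unique(folds)), function(f) {
      val <- data[folds == f, , drop = FALSE]
      mods <- setdiff(names(val), c("sample_id", "label"))
      x <- vapply(mods, function(m) {
        f2_hand(val$label, as.integer(val[[m]] >= threshold))
      }, numeric(1))
      w <- x^cc / sum(x^cc)
      fused <- as.matrix(val[mods]) %*% w
      f2_hand(val$label, as.integer(fused >= threshold))
    }, numeric(1))
    mean(per_fold)
  }, numeric(1))
}
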