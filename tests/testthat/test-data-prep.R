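test_that("undersampling equalizes classes at the minority count", {
  # the screening-scale case: 7,290 positives vs 48,600 negatives
  d <- tibble::tibble(label = rep(c(1L, 0L), c(7290, 48600)))
  kept <- undersample_balance(d, seed = 1)
  expect_equal(nrow(kept), 14580)
  expect_equal(unname(table(kept$label)), c(7290L, 7290L),
               ignore_attr = TRUE)
})

test_that("undersampling keeps all minority rows, subsets the majority", {
  d <- tibble::tibble(id = 1:14, label = rep(c(0L, 1L), c(10, 4)))
  kept <- undersample_balance(d, seed = 2)
  expect_equal(nrow(kept), 8)
  expect_setequal(kept$id[kept$label == 1], 11:14)
  expect_true(all(kept$id[kept$label == 0] %in% 1:10))
  # bit-identical under the same seed
  expect_identical(kept, undersample_balance(d, seed = 2))
  expect_false(identical(kept, undersample_balance(d, seed = 3)))
})

test_that("balanced input passes through undersampling unchanged", {
  d <- tibble::tibble(id = 1:10, label = rep(c(0L, 1L), 5))
  expect_identical(undersample_balance(d, seed = 4), d)
})

test_that("undersampling refuses single-class input", {
  expect_error(undersample_balance(tibble::tibble(label = rep(1L, 5))),
               "both classes")
})

test_that("every emitted batch is exactly class-balanced", {
  d <- tibble::tibble(label = rep(c(1L, 0L), c(100, 60)))
  b <- make_balanced_batches(d, batch_size = 32, seed = 5)
  counts <- table(b$batch, b$label)
  expect_true(all(counts == 16))
  expect_equal(nrow(counts), ceiling(100 / 16))
  # majority class (positives) draws contain no duplicate before exhaustion
  pos_draws <- b$row[b$label == 1]
  expect_false(anyDuplicated(pos_draws[1:100]) > 0)
  expect_setequal(pos_draws[1:100], which(d$label == 1))
  # minority class repeats, as it must
  expect_gt(sum(duplicated(b$row[b$label == 0])), 0)
})

test_that("balanced labels give clean balanced batches", {
  d <- tibble::tibble(label = rep(c(1L, 0L), 32))
  b <- make_balanced_batches(d, batch_size = 32, seed = 6)
  expect_true(all(table(b$batch, b$label) == 16))
  expect_equal(max(b$batch), 2)
})

test_that("a two-sample batch holds one of each class", {
  d <- tibble::tibble(label = c(1L, 0L))
  b <- make_balanced_batches(d, batch_size = 2, seed = 7)
  expect_equal(nrow(b), 2)
  expect_setequal(b$row, 1:2)
})

test_that("odd batch sizes are rejected", {
  d <- tibble::tibble(label = c(1L, 0L))
  expect_error(make_balanced_batches(d, batch_size = 31), "even")
})

test_that("augmentation plan hits the target with equal classes", {
  # stratified 80% of 410 with 100 malignant: 80 positives, 248 negatives
  d <- tibble::tibble(label = rep(c(1L, 0L), c(80, 248)))
  plan <- plan_augmentation(d, target_total = 4000)
  expect_equal(plan$n_total, c(2000L, 2000L))
  expect_equal(plan$n_copies[plan$label == 1], 1920L)
  expect_equal(plan$n_copies[plan$label == 0], 1752L)
  expect_equal(sum(plan$n_originals) + sum(plan$n_copies), 4000L)
})

test_that("copies spread across originals differing by at most one", {
  d <- tibble::tibble(label = rep(c(1L, 0L), c(3, 5)))
  plan <- plan_augmentation(d, target_total = 16)
  pos <- plan$copies_per_original[plan$label == 1][[1]]
  expect_equal(sort(pos, decreasing = TRUE), c(2, 2, 1))  # 5 copies over 3
  neg <- plan$copies_per_original[plan$label == 0][[1]]
  expect_equal(sum(neg), 3)
  expect_lte(max(neg) - min(neg), 1)
})

test_that("already-at-target classes need zero copies", {
  d <- tibble::tibble(label = rep(c(1L, 0L), c(6, 6)))
  plan <- plan_augmentation(d, target_total = 12)
  expect_equal(plan$n_copies, c(0L, 0L))
})

test_that("targets below the original counts are rejected", {
  d <- tibble::tibble(label = rep(c(1L, 0L), c(10, 3)))
  expect_error(plan_augmentation(d, target_total = 12), "below")
  expect_error(plan_augmentation(d, target_total = 25), "even")
})
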