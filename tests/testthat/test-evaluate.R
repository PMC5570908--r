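test_that("fold assignment is stratified, balanced, and seeded", {
  w <- small_world(seed = 1)
  f1 <- kfold_assign(w$gold, k = 5, seed = 3)
  f2 <- kfold_assign(w$gold, k = 5, seed = 3)
  expect_identical(f1, f2)
  expect_true(max(table(f1$pos_fold)) - min(table(f1$pos_fold)) <= 1)
  expect_true(max(table(f1$neg_fold)) - min(table(f1$neg_fold)) <= 1)
  expect_error(kfold_assign(w$gold, k = 1), "at least 2")
})

test_that("cross-validation scores every pair exactly once with no training leakage", {
  w <- small_world(seed = 2)
  inp <- world_inputs(w)
  cv <- kfold_cross_validate(w$gold, inp, k = 5, seed = 11)
  expect_equal(nrow(cv), nrow(w$gold$positives) + nrow(w$gold$negatives))
  expect_equal(anyDuplicated(cv[, .(e3, substrate, label)]), 0L)

  # structural no-leakage audit: each fold's training keys exclude each of
  # its test pairs
  fps <- attr(cv, "fingerprints")
  for (f in seq_along(fps)) {
    test_keys <- paste(cv[fold == f, e3], cv[fold == f, substrate], sep = "\r")
    expect_length(intersect(test_keys, fps[[f]]$train_keys), 0L)
  }
  # fingerprints differ across folds (different training sets)
  expect_equal(anyDuplicated(vapply(fps, `[[`, "", "fingerprint")), 0L)

  cv2 <- kfold_cross_validate(w$gold, inp, k = 5, seed = 11)
  expect_identical(cv$lr_comp, cv2$lr_comp)
  expect_identical(attr(cv, "folds"), attr(cv2, "folds"))
})

test_that("TP/FP curve pools counts with >= call semantics and flags degenerate cells", {
  res <- data.table(
    label = c(1L, 1L, 1L, 0L, 0L, 0L),
    lr_comp = c(10, 5, 2, 4, 1, 0.5)
  )
  low <- tp_fp_curve(res, cutoffs = 0)
  expect_equal(low$tp, 3L)
  expect_equal(low$fp, 3L)
  high <- tp_fp_curve(res, cutoffs = 100)
  expect_equal(high$tp, 0L)
  expect_equal(high$fp, 0L)
  expect_true(is.nan(high$tp_fp_ratio))
  mid <- tp_fp_curve(res, cutoffs = 5)  # ties at the cutoff count as calls
  expect_equal(mid$tp, 2L)
  expect_equal(mid$fp, 0L)
  expect_equal(mid$tp_fp_ratio, Inf)
  expect_equal(tp_fp_curve(res, cutoffs = 2)$sensitivity, 1)
})

test_that("AUROC equals the all-pairs comparison oracle, with ties at 1/2", {
  expect_equal(roc_auroc(data.table(label = c(1, 1, 0, 0),
                                    lr_comp = c(9, 8, 2, 1)))$auroc, 1)
  expect_equal(roc_auroc(data.table(label = c(1, 1, 0, 0),
                                    lr_comp = rep(3, 4)))$auroc, 0.5)
  expect_equal(roc_auroc(data.table(
    label = rep(c(1, 0), each = 4),
    lr_comp = c(0.9, 0.8, 0.7, 0.6, 0.65, 0.5, 0.4, 0.3)
  ))$auroc, 15 / 16)

  set.seed(21)
  for (i in 1:20) {
    np <- sample(2:25, 1)
    nn <- sample(2:25, 1)
    pos <- sample(seq(0, 5, 0.5), np, replace = TRUE)
    neg <- sample(seq(0, 5, 0.5), nn, replace = TRUE)
    r <- roc_auroc(data.table(label = rep(c(1L, 0L), c(np, nn)),
                              lr_comp = c(pos, neg)))
    expect_equal(r$auroc, oracle_auroc(pos, neg), tolerance = 1e-12)
    expect_true(r$ci95[1] <= r$auroc && r$auroc <= r$ci95[2])
  }
  expect_error(roc_auroc(data.table(label = c(1, 1), lr_comp = c(1, 2))),
               "both positive and negative")
})

test_that("ROC points form a valid staircase", {
  set.seed(5)
  r <- roc_auroc(data.table(label = rep(c(1L, 0L), each = 30),
                            lr_comp = c(rnorm(30, 1.5), rnorm(30))))
  pts <- r$points  # cutoffs descending
  expect_true(all(diff(pts$sensitivity) >= 0))
  expect_true(all(diff(pts$specificity) <= 0))
  expect_true(all(pts$sensitivity >= 0 & pts$sensitivity <= 1))
  expect_true(all(pts$specificity >= 0 & pts$specificity <= 1))
})

test_that("Park partition classifies by component membership", {
  train <- data.table(e3 = "A", substrate = "B")
  expect_equal(as.character(park_partition(
    data.table(e3 = c("A", "A", "X", "X"),
               substrate = c("B", "Bprime", "B", "Y")), train)),
    c("C1", "C2", "C2", "C3"))

  # independent recount on a random split of a toy world
  set.seed(14)
  w <- small_world(seed = 9)
  pos <- as.data.table(w$gold$positives)
  idx <- sample(nrow(pos), nrow(pos) %/% 3)
  test <- pos[idx]; train2 <- pos[-idx]
  cls <- park_partition(test, train2)
  for (i in seq_len(nrow(test))) {
    seen_e <- test$e3[i] %in% train2$e3
    seen_s <- test$substrate[i] %in% train2$substrate
    want <- if (seen_e && seen_s) "C1" else if (seen_e || seen_s) "C2" else "C3"
    expect_equal(as.character(cls[i]), want)
  }
})

test_that("one-tailed Fisher matches the exhaustive hypergeometric oracle", {
  expect_equal(fisher_one_tailed(1, 1, 1, 1), 5 / 6, tolerance = 1e-12)
  cases <- list(c(2, 98, 21, 79), c(1, 1, 1, 1), c(5, 5, 1, 9),
                c(0, 10, 5, 5), c(8, 2, 2, 8), c(3, 7, 7, 3))
  for (cs in cases) {
    expect_equal(fisher_one_tailed(cs[1], cs[2], cs[3], cs[4]),
                 oracle_fisher(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-12, info = paste(cs, collapse = ","))
  }
  # agreement with stats::fisher.test in the matching direction
  expect_equal(fisher_one_tailed(2, 98, 21, 79),
               stats::fisher.test(matrix(c(2, 98, 21, 79), 2, byrow = TRUE),
                                  alternative = "less")$p.value,
               tolerance = 1e-9)
  expect_error(fisher_one_tailed(0, 0, 1, 1), "degenerate")
  expect_error(fisher_one_tailed(0, 5, 0, 7), "degenerate")
  expect_error(fisher_one_tailed(-1, 5, 2, 7), "non-negative")
})

test_that("holdout evaluation trains once on the full gold standard", {
  w <- small_world(seed = 10)
  inp <- world_inputs(w)
  pos <- as.data.table(w$gold$positives)
  neg <- as.data.table(w$gold$negatives)
  gold <- gold_standard(pos[1:30], neg[1:60])
  ev <- evaluate_holdout(gold, pos[31:40], neg[61:80], inp, seed = 3)
  expect_equal(nrow(ev$results), 30L)
  expect_s3_class(ev$roc, "esi_roc")
  expect_identical(sort(ev$model$train_pos_keys),
                   sort(paste(pos$e3[1:30], pos$substrate[1:30], sep = "\r")))
})
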