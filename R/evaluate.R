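#' Stratified k-fold assignment
#'
#' Positives and negatives are stratified independently so every fold
#' preserves the positive:negative ratio; fold sizes within a stratum
#' differ by at most one.
#'
#' @param gold `esi_gold` object.
#' @param k number of folds.
#' @param seed integer seed.
#' @return list with integer vectors `pos_fold`, `neg_fold`.
#' @export
kfold_assign <- function(gold, k = 5L, seed = 1L) {
  if (k < 2L) stop("k must be at least 2")
  set.seed(seed)
  np <- nrow(gold$positives)
  nn <- nrow(gold$negatives)
  if (np < k || nn < k) stop("too few pairs for ", k, " non-empty folds")
  list(pos_fold = sample(rep_len(seq_len(k), np)),
       neg_fold = sample(rep_len(seq_len(k), nn)))
}

#' k-fold cross-validation of the full pipeline
#'
#' For each fold, a complete model is retrained on the remaining k-1 folds
#' only -- enrichment tables, motifs, and all likelihood-ratio tables are
#' re-estimated, so no information from the held-out pairs leaks into
#' training -- and the held-out fold is scored. Results are concatenated
#' across folds.
#'
#' @param gold `esi_gold` object.
#' @param inputs `esi_inputs` bundle.
#' @param k number of folds (default 5).
#' @param seed integer seed (fold assignment and per-fold training splits).
#' @param config model configuration.
#' @return `data.table` (`e3`, `substrate`, `label` 1/0, `fold`, `lr_comp`,
#'   `score`) with attributes `folds` (the assignment) and `fingerprints`
#'   (per-fold training fingerprint plus training pair keys, for leakage
#'   audits).
#' @export
kfold_cross_validate <- function(gold, inputs, k = 5L, seed = 1L,
                                 config = esi_config()) {
  folds <- kfold_assign(gold, k = k, seed = seed)
  pos <- as.data.table(gold$positives)[, .(e3, substrate)]
  neg <- as.data.table(gold$negatives)[, .(e3, substrate)]
  inputs <- prepare_inputs(inputs)
  res <- vector("list", k)
  fps <- vector("list", k)
  for (f in seq_len(k)) {
    train_gold <- gold_standard(pos[folds$pos_fold != f],
                                neg[folds$neg_fold != f])
    fold_seed <- (seed * 97L + f) %% .Machine$integer.max
    model <- train_model(train_gold, inputs, config = config,
                         seed = fold_seed)
    test <- rbind(pos[folds$pos_fold == f][, label := 1L],
                  neg[folds$neg_fold == f][, label := 0L])
    sc <- score_pairs(test[, .(e3, substrate)], model, inputs)
    res[[f]] <- data.table(e3 = test$e3, substrate = test$substrate,
                           label = test$label, fold = f,
                           lr_comp = sc$lr_comp, score = sc$score)
    fps[[f]] <- list(
      fingerprint = model$fingerprint,
      train_keys = c(pair_keys(train_gold$positives),
                     pair_keys(train_gold$negatives)),
      train_pos = train_gold$positives
    )
  }
  out <- rbindlist(res)
  setattr(out, "folds", folds)
  setattr(out, "fingerprints", fps)
  out[]
}

#' TP/FP ratio as a function of the likelihood-ratio cutoff
#'
#' Counts are pooled across folds: at each cutoff a pair is called positive
#' when its composite likelihood ratio is greater than or equal to the
#' cutoff. `tp_fp_ratio` is `Inf` when `fp = 0` and `tp > 0`, and `NaN`
#' (flagged undefined) when both are zero.
#'
#' @param results cross-validation results ([kfold_cross_validate()]) or any
#'   table with `label` and `lr_comp`.
#' @param cutoffs cutoff grid; default = all unique observed `lr_comp`.
#' @return `data.table` (`cutoff`, `tp`, `fp`, `sensitivity`,
#'   `specificity`, `tp_fp_ratio`).
#' @export
tp_fp_curve <- function(results, cutoffs = NULL) {
  results <- as.data.table(results)
  if (!nrow(results)) stop("empty results")
  if (is.null(cutoffs)) cutoffs <- sort(unique(results$lr_comp))
  t_n <- sum(results$label == 1L)
  f_n <- sum(results$label == 0L)
  out <- rbindlist(lapply(cutoffs, function(ct) {
    called <- results$lr_comp >= ct
    tp <- sum(called & results$label == 1L)
    fp <- sum(called & results$label == 0L)
    data.table(cutoff = ct, tp = tp, fp = fp,
               sensitivity = if (t_n) tp / t_n else NA_real_,
               specificity = if (f_n) 1 - fp / f_n else NA_real_,
               tp_fp_ratio = if (fp > 0) tp / fp
                             else if (tp > 0) Inf else NaN)
  }))
  out[]
}

#' ROC curve and AUROC with 95% confidence interval
#'
#' The AUROC is the Mann-Whitney rank statistic (ties count 1/2); the 95%
#' confidence interval uses the Hanley-McNeil normal approximation. ROC
#' points sweep all unique observed values as cutoffs (>= call semantics).
#'
#' @param results table with `label` (1/0) and `lr_comp` columns, or two
#'   vectors via `scores`/`labels`.
#' @return list of class `esi_roc`: `points` (cutoff, sensitivity,
#'   specificity), `auroc`, `ci95`, `n_pos`, `n_neg`.
#' @export
roc_auroc <- function(results) {
  results <- as.data.table(results)
  pos <- results[label == 1L, lr_comp]
  neg <- results[label == 0L, lr_comp]
  if (!length(pos) || !length(neg)) {
    stop("ROC requires both positive and negative pairs")
  }
  np <- length(pos)
  nn <- length(neg)
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  # Hanley & McNeil (1982) standard error
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (np - 1) * (q1 - auc^2) +
                (nn - 1) * (q2 - auc^2)) / (np * nn))
  ci <- c(max(0, auc - 1.96 * se), min(1, auc + 1.96 * se))
  cuts <- sort(unique(c(pos, neg)), decreasing = TRUE)
  pts <- data.table(
    cutoff = cuts,
    sensitivity = vapply(cuts, function(ct) mean(pos >= ct), 0),
    specificity = vapply(cuts, function(ct) mean(neg < ct), 0)
  )
  structure(list(points = pts, auroc = auc, ci95 = ci,
                 n_pos = np, n_neg = nn),
            class = "esi_roc")
}

#' @export
print.esi_roc <- function(x, ...) {
  cat(sprintf("AUROC %.3f (95%% CI %.3f-%.3f; %d pos, %d neg)\n",
              x$auroc, x$ci95[1], x$ci95[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' Pair-input C1/C2/C3 partition of a test set
#'
#' Classifies each test pair by whether its components occur in the
#' training pairs: `C1` = both the E3 and the substrate are seen in
#' training, `C2` = exactly one is, `C3` = neither. This guards
#' against over-estimating pair-input prediction performance.
#'
#' @param test,train pair tables.
#' @return factor (levels C1, C2, C3), one entry per test pair.
#' @export
park_partition <- function(test, train) {
  test <- as.data.table(test)
  train <- as.data.table(train)
  e3_seen <- test$e3 %in% unique(train$e3)
  sub_seen <- test$substrate %in% unique(train$substrate)
  cls <- ifelse(e3_seen & sub_seen, "C1",
                ifelse(e3_seen | sub_seen, "C2", "C3"))
  factor(cls, levels = c("C1", "C2", "C3"))
}

#' One-tailed Fisher's exact test on a 2x2 table
#'
#' Computes the hypergeometric tail probability of tables at least as
#' extreme as `(a, b; c, d)` in the direction of the observed deviation
#' from independence (row 1 = a, b; row 2 = c, d; margins fixed).
#'
#' @param a,b,c,d non-negative cell counts.
#' @return the one-tailed p-value.
#' @export
fisher_one_tailed <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if ((a + b) == 0 || (c + d) == 0) stop("degenerate table: empty row")
  if ((a + c) == 0 || (b + d) == 0) stop("degenerate table: empty column")
  n <- a + b + c + d
  expected_a <- (a + b) * (a + c) / n
  if (a <= expected_a) {
    phyper(a, a + c, b + d, a + b)
  } else {
    phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
  }
}

#' Score an independent hold-out set with a model trained on the full gold
#' standard
#'
#' The hold-out protocol: train on the (earlier) gold standard, score a
#' later, independent set of positives against a matched negative set, and
#' report the ROC.
#'
#' @param gold training `esi_gold`.
#' @param holdout_pos,holdout_neg hold-out pair tables.
#' @param inputs `esi_inputs` bundle.
#' @param config model configuration.
#' @param seed seed for training splits.
#' @return list with `results` (scored table) and `roc`.
#' @export
evaluate_holdout <- function(gold, holdout_pos, holdout_neg, inputs,
                             config = esi_config(), seed = 1L) {
  model <- train_model(gold, inputs, config = config, seed = seed)
  inputs <- prepare_inputs(inputs)
  test <- rbind(as.data.table(holdout_pos)[, .(e3, substrate)][, label := 1L],
                as.data.table(holdout_neg)[, .(e3, substrate)][, label := 0L])
  sc <- score_pairs(test[, .(e3, substrate)], model, inputs)
  res <- data.table(e3 = test$e3, substrate = test$substrate,
                    label = test$label, lr_comp = sc$lr_comp,
                    score = sc$score)
  list(results = res, roc = roc_auroc(res), model = model)
}
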