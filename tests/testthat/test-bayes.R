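test_that("likelihood-ratio tables implement the smoothed TP/FP formula", {
  # single covering bin, no smoothing: (10/100)/(2/200) = 10
  t1 <- estimate_lr_table(rep(1, 10), rep(1, 2), c(0, Inf), smoothing = 0,
                          n_pos = 100, n_neg = 200)
  expect_equal(t1$lr, 10)

  # fp = 0 with s = 1: (9+1)/(99+1) / (0+1)/(199+1) = 20
  t2 <- estimate_lr_table(rep(1, 9), numeric(), c(0, Inf), smoothing = 1,
                          n_pos = 99, n_neg = 199)
  expect_equal(t2$lr, 20)

  # untouched bins are neutral; capping keeps ratios finite
  t3 <- estimate_lr_table(rep(0.5, 5), rep(0.5, 5), c(0, 1, 2, Inf))
  expect_equal(t3$lr[2:3], c(1, 1))
  t4 <- estimate_lr_table(rep(1, 1e4), numeric(), c(0, Inf), smoothing = 0,
                          n_pos = 1e4, n_neg = 1e4)
  expect_equal(t4$lr, 1e3)

  expect_error(estimate_lr_table(1, 1, c(2, 1, Inf)), "strictly increasing")
  expect_error(estimate_lr_table(1, 1, c(0, 1, 2)), "end at Inf")
  expect_error(estimate_lr_table(-1, 1, c(0, Inf)), "below the first bin")
})

test_that("same-distribution features give near-unit LRs in every bin", {
  set.seed(8)
  pos <- rexp(1e4)
  neg <- rexp(1e4)
  tab <- estimate_lr_table(pos, neg, c(0, 0.5, 1, 2, 4, Inf))
  expect_true(all(tab$lr >= 0.8 & tab$lr <= 1.25))
})

test_that("lookup is total over the covered axis and errors below it", {
  tab <- estimate_lr_table(c(0.1, 5), c(0.2, 0.3), c(0, 1, Inf))
  expect_equal(lookup_lr(tab, c(0, 0.99, 1, 1e9)),
               c(tab$lr[1], tab$lr[1], tab$lr[2], tab$lr[2]))
  expect_true(is.na(lookup_lr(tab, NA_real_)))
  expect_error(lookup_lr(tab, -0.5), "below the first bin")
})

test_that("combine_lr is a product with neutral empty input and rejects non-positive LRs", {
  expect_equal(combine_lr(c(2, 5)), 10)
  expect_equal(combine_lr(numeric()), 1)
  expect_equal(combine_lr(list()), 1)
  set.seed(3)
  v <- runif(6, 0.1, 20)
  expect_equal(combine_lr(v), combine_lr(rev(v)), tolerance = 1e-12)
  expect_equal(combine_lr(sample(v)), prod(v), tolerance = 1e-12)
  expect_error(combine_lr(c(2, 0)), "positive")
})

test_that("prior and posterior odds come from the gold-standard counts", {
  gold <- list(positives = data.table(e3 = sprintf("E%03d", 1:913),
                                      substrate = sprintf("S%03d", 1:913)),
               negatives = data.table(e3 = sprintf("N%04d", 1:2734),
                                      substrate = sprintf("M%04d", 1:2734)))
  pp <- prior_and_posterior(gold, lr_comp = 1)
  expect_equal(pp$p_positive, 913 / 3647)
  expect_equal(pp$o_prior, 913 / 2734)
  expect_equal(pp$o_post, pp$o_prior)
  pp2 <- prior_and_posterior(gold, lr_comp = 10)
  expect_equal(pp2$o_post, 10 * 913 / 2734)

  gold5 <- list(positives = gold$positives[1:5], negatives = gold$negatives[1:5])
  expect_equal(prior_and_posterior(gold5)$o_prior, 1)
  expect_error(prior_and_posterior(list(positives = gold$positives[0],
                                        negatives = gold$negatives)))
})

test_that("confidence score: worked value, closed forms, symmetry, monotonicity", {
  expect_equal(round(confidence_score(195.79), 3), 0.908)
  expect_equal(confidence_score(1), 0.5)
  expect_equal(round(confidence_score(10), 4), 0.7311)
  expect_equal(confidence_score(10), 1 / (1 + exp(-1)))
  # logistic symmetry score(lr) + score(1/lr) = 1
  for (lr in c(1e-3, 0.02, 0.5, 1, 3, 42, 1e4)) {
    expect_equal(confidence_score(lr) + confidence_score(1 / lr), 1,
                 tolerance = 1e-12)
  }
  v <- confidence_score(c(0.1, 1, 10, 100))
  expect_true(all(diff(v) > 0))
  expect_error(confidence_score(0), "positive")
  expect_error(confidence_score(-2), "positive")
})

test_that("enrichment calibration recovers planted signal and is seed-deterministic", {
  w <- small_world(seed = 2)
  gsp <- w$gold$positives
  gsn <- w$gold$negatives
  cal1 <- calibrate_enrichment_lr(gsp, gsn, w$domain_ann,
                                  c(0, 1, 2, 4, 8, 16, Inf), seed = 5)
  cal2 <- calibrate_enrichment_lr(gsp, gsn, w$domain_ann,
                                  c(0, 1, 2, 4, 8, 16, Inf), seed = 5)
  expect_identical(cal1$lr$lr, cal2$lr$lr)
  expect_identical(cal1$table$ratio, cal2$table$ratio)
  # planted pairs appear in the full-data table with ratio > 1
  planted <- as.data.table(w$truth$e3_domain_pair)
  hits <- merge(cal1$table, unique(planted[, .(label_e3, label_sub)]),
                by = c("label_e3", "label_sub"))
  expect_gt(nrow(hits), 0)
  expect_true(all(hits$ratio > 1))
  # top feature bin carries LR > 1
  expect_gt(cal1$lr$lr[nrow(cal1$lr)], 1)
})

test_that("label-shuffled calibration gives near-unit LRs", {
  # exchangeable world (skew 0): with a skewed E3 profile, hub-E3 identity
  # alone is weakly predictive, which is signal, not miscalibration
  w <- generate_world(world_config(
    n_e3 = 10L, n_proteins = 80L, n_gsp = 40L, n_gsn = 80L,
    n_domains = 20L, n_go_terms = 25L, n_motif_e3 = 2L,
    ppi_density = 0.12, seq_length = 120, e3_skew = 0, seed = 6
  ))
  set.seed(42)
  shuf <- as.data.table(w$domain_ann)
  shuf[, protein := sample(protein)]
  cal <- calibrate_enrichment_lr(w$gold$positives, w$gold$negatives,
                                 annotations(shuf, "domain"),
                                 c(0, 1, 2, 4, 8, 16, Inf), seed = 5)
  occupied <- cal$lr[tp + fp > 10]
  expect_true(all(abs(occupied$lr - 1) < 0.5))
})

test_that("evidence_lr applies the max-per-type rule and omits silent types", {
  w <- small_world(seed = 3)
  inp <- world_inputs(w)
  model <- train_model(w$gold, inp, seed = 9)
  pair <- w$gold$positives[1]
  per_type <- evidence_lr(pair, model, inp)
  expect_true(all(per_type > 0))
  expect_true(all(names(per_type) %in%
                    c("homology", "domain", "go", "network_n3",
                      "network_n4", "motif")))

  # brute force per-feature lookup for the domain type
  dom_feats <- esibayes:::max_ratio_features(pair, inp$domain_ann,
                                             model$domain$table)
  if (dom_feats > 0) {
    adt <- as.data.table(inp$domain_ann)
    e3_labels <- adt[protein == pair$e3, label]
    sub_labels <- adt[protein == pair$substrate, label]
    all_lrs <- c()
    for (le in e3_labels) for (ls in sub_labels) {
      row <- model$domain$table[label_e3 == le & label_sub == ls]
      if (nrow(row)) all_lrs <- c(all_lrs, lookup_lr(model$domain$lr, row$ratio))
    }
    expect_equal(unname(per_type[["domain"]]), max(all_lrs))
  }

  # an unknown pair fires nothing
  ghost <- evidence_lr(list(e3 = "GHOST1", substrate = "GHOST2"), model, inp)
  expect_length(ghost, 0L)
  expect_equal(combine_lr(ghost), 1)
})

test_that("scoring the training GSP beats the training GSN and neutral tables give 0.5", {
  w <- small_world(seed = 5)
  inp <- world_inputs(w)
  model <- train_model(w$gold, inp, seed = 4)
  sp <- score_pairs(w$gold$positives, model, inp)
  sn <- score_pairs(w$gold$negatives, model, inp)
  expect_gt(median(sp$lr_comp), median(sn$lr_comp))
  expect_equal(sp$lr_comp,
               apply(sp[, .(lr_homology, lr_domain, lr_go, lr_network_n3,
                            lr_network_n4, lr_motif)], 1,
                     function(r) combine_lr(r)),
               tolerance = 1e-12)
  expect_equal(sp$o_post, model$prior$o_prior * sp$lr_comp)

  # force all LR tables to 1: every prediction collapses to 0.5
  neutral <- model
  for (nm in c("lr_n3", "lr_n4", "homology", "lr_motif")) {
    neutral[[nm]]$lr <- rep(1, nrow(neutral[[nm]]))
  }
  neutral$domain$lr$lr <- rep(1, nrow(neutral$domain$lr))
  neutral$go$lr$lr <- rep(1, nrow(neutral$go$lr))
  s0 <- score_pairs(rbind(w$gold$positives[1:5], w$gold$negatives[1:5]),
                    neutral, inp)
  expect_equal(s0$score, rep(0.5, 10))
})

test_that("model archive round-trips bit-exactly and re-scores identically", {
  w <- small_world(seed = 7)
  inp <- world_inputs(w)
  model <- train_model(w$gold, inp, seed = 13)
  dir <- withr::local_tempdir()
  save_model(model, dir)
  back <- load_model(dir)
  expect_identical(back$fingerprint, model$fingerprint)
  expect_identical(back$domain$lr$lr, model$domain$lr$lr)
  expect_identical(back$go$lr$lr, model$go$lr$lr)
  expect_identical(back$lr_motif$lr, model$lr_motif$lr)
  expect_identical(back$domain$table$ratio, model$domain$table$ratio)

  pairs <- rbind(w$gold$positives[1:50], w$gold$negatives[1:50])
  s1 <- score_pairs(pairs, model, inp)
  s2 <- score_pairs(pairs, back, inp)
  expect_identical(s1$lr_comp, s2$lr_comp)
  expect_identical(s1$score, s2$score)

  # a second save of the reloaded model is byte-identical
  dir2 <- withr::local_tempdir()
  save_model(back, dir2)
  for (f in list.files(dir)) {
    expect_identical(unname(tools::md5sum(file.path(dir, f))),
                     unname(tools::md5sum(file.path(dir2, f))),
                     info = f)
  }
})

test_that("prediction for one pair agrees with batch scoring", {
  w <- small_world(seed = 8)
  inp <- world_inputs(w)
  model <- train_model(w$gold, inp, seed = 2)
  pair <- w$gold$positives[3]
  p <- predict_pair(pair, model, inp)
  batch <- score_pairs(pair, model, inp)
  expect_equal(p$lr_comp, batch$lr_comp)
  expect_equal(p$score, batch$score)
  expect_equal(combine_lr(p$per_type_lr), p$lr_comp)
})
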