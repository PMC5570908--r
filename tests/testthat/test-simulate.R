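test_that("world configuration validates its arguments", {
  expect_error(world_config(loop_boost = 1.2), "\\[0, 1\\]")
  expect_error(world_config(enrichment_strength = 0.5), ">= 1")
  expect_error(world_config(n_e3 = 2L, n_proteins = 3L, n_gsp = 100L),
               "exceeds")
})

test_that("same seed reproduces a byte-identical serialized world", {
  cfg <- world_config(n_e3 = 8L, n_proteins = 60L, n_gsp = 30L, n_gsn = 60L,
                      ppi_density = 0.2, seed = 17)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  world_to_files(generate_world(cfg), d1)
  world_to_files(generate_world(cfg), d2)
  files <- list.files(d1)
  expect_true(length(files) >= 8)
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  # a different seed changes the world
  cfg2 <- world_config(n_e3 = 8L, n_proteins = 60L, n_gsp = 30L, n_gsn = 60L,
                       ppi_density = 0.2, seed = 18)
  d3 <- withr::local_tempdir()
  world_to_files(generate_world(cfg2), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "gsp.tsv"))),
                         unname(tools::md5sum(file.path(d3, "gsp.tsv")))))
})

test_that("planted truth is discoverable: enriched pairs, motifs, orthologs, loops", {
  # full insertion puts the planted motifs in the sufficiently-strong
  # regime of the null-calibrated retention threshold (see the methods
  # vignette for the sensitivity bound at partial insertion)
  w <- small_world(seed = 21, n_gsp = 60L, ppi_density = 0.25,
                   motif_fg_rate = 1)
  # planted domain pairs reach the enrichment table with ratio > 1
  tab <- enriched_pair_table(w$gold$positives, w$domain_ann, min_ratio = 0)
  planted <- unique(as.data.table(w$truth$e3_domain_pair)[
    e3 %in% w$truth$domain_planted$e3, .(label_e3, label_sub)])
  found <- merge(tab, planted, by = c("label_e3", "label_sub"))
  expect_gte(nrow(found), ceiling(0.9 * nrow(planted)))
  expect_true(all(found$ratio > 1))

  # every planted motif is recovered by discovery on its own E3
  seqs <- w$sequences
  adj <- esibayes:::adjacency_list(w$ppi)
  mt <- as.data.table(w$truth$motifs)
  gsp <- as.data.table(w$gold$positives)
  for (j in seq_len(nrow(mt))) {
    e <- mt$e3[j]
    fg_ids <- unique(gsp[e3 == e, substrate])
    bg_ids <- setdiff(adj[[e]], fg_ids)
    ms <- discover_motifs(e, unname(seqs[fg_ids]), unname(seqs[bg_ids]),
                          widths = 3)
    pats <- vapply(ms, esibayes:::motif_pattern_string, character(1))
    expect_true(mt$pattern[j] %in% pats, info = e)
  }

  # mirrored pairs are exactly the homology-supported gold positives
  sup <- vapply(seq_len(nrow(gsp)), function(i) {
    homology_support(gsp[i], w$mouse_esis, w$omap)$supported
  }, logical(1))
  mirrored_keys <- paste(w$truth$mirrored$e3, w$truth$mirrored$substrate)
  expect_setequal(paste(gsp$e3[sup], gsp$substrate[sup]), mirrored_keys)

  # boosted pairs have at least one triangle through the query edge
  boosted <- as.data.table(w$truth$boosted)
  if (nrow(boosted)) {
    n3s <- vapply(seq_len(nrow(boosted)), function(i) {
      count_loops(boosted$e3[i], boosted$substrate[i], adj)[["n3"]]
    }, integer(1))
    expect_true(all(n3s >= 1L))
  }
})

test_that("planted signal is recovered across seeds: all motifs (full insertion), >=90% of enriched pairs", {
  motif_tot <- 0L; motif_rec <- 0L
  pair_tot <- 0L; pair_rec <- 0L
  for (s in 1:10) {
    w <- generate_world(world_config(motif_fg_rate = 1, seed = s))
    adj <- esibayes:::adjacency_list(w$ppi)
    gsp <- as.data.table(w$gold$positives)
    mt <- as.data.table(w$truth$motifs)
    for (j in seq_len(nrow(mt))) {
      e <- mt$e3[j]
      fg_ids <- unique(gsp[e3 == e, substrate])
      bg_ids <- setdiff(adj[[e]], fg_ids)
      ms <- discover_motifs(e, unname(w$sequences[fg_ids]),
                            unname(w$sequences[bg_ids]), widths = 3)
      pats <- vapply(ms, esibayes:::motif_pattern_string, character(1))
      motif_tot <- motif_tot + 1L
      motif_rec <- motif_rec + (mt$pattern[j] %in% pats)
    }
    tab <- enriched_pair_table(gsp, w$domain_ann, min_ratio = 1)
    planted <- unique(as.data.table(w$truth$e3_domain_pair)[
      e3 %in% w$truth$domain_planted$e3, .(label_e3, label_sub)])
    found <- merge(tab, planted, by = c("label_e3", "label_sub"))
    pair_tot <- pair_tot + nrow(planted)
    pair_rec <- pair_rec + nrow(found[ratio > 1])
  }
  expect_equal(motif_rec, motif_tot)
  expect_gte(pair_rec / pair_tot, 0.9)
})

test_that("the gold standard respects its invariants in generated worlds", {
  for (s in c(31, 32)) {
    w <- small_world(seed = s)
    kp <- paste(w$gold$positives$e3, w$gold$positives$substrate)
    kn <- paste(w$gold$negatives$e3, w$gold$negatives$substrate)
    expect_length(intersect(kp, kn), 0L)
    expect_equal(anyDuplicated(kp), 0L)
    expect_equal(anyDuplicated(kn), 0L)
    # negatives are network edges incident to E3s
    el <- igraph::as_edgelist(w$ppi)
    ekeys <- c(paste(el[, 1], el[, 2]), paste(el[, 2], el[, 1]))
    expect_true(all(kn %in% ekeys))
  }
})

test_that("CV AUROC responds monotonically to enrichment strength", {
  strengths <- c(1, 4, 8)
  mean_auc <- vapply(strengths, function(st) {
    aucs <- vapply(1:3, function(s) {
      w <- generate_world(world_config(
        n_e3 = 12L, n_proteins = 100L, n_gsp = 60L, n_gsn = 120L,
        enrichment_strength = st, loop_boost = 0, ortholog_coverage = 0,
        motif_fg_rate = 0.02, motif_bg_rate = 0.02, e3_skew = 0,
        ppi_density = 0.1, seq_length = 100, seed = 100 + s
      ))
      roc_auroc(kfold_cross_validate(w$gold, world_inputs(w), k = 5,
                                     seed = s))$auroc
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  expect_true(all(diff(mean_auc) > -0.03))
  expect_gt(mean_auc[3], mean_auc[1])
})
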