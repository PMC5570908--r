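# Shared fixtures and independent oracles. Everything is generated in code;
# nothing is read from disk except files the tests themselves write.

library(data.table)

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_aa_seqs <- function(n, len = 60) {
  vapply(seq_len(n), function(i) {
    paste(sample(AA20, len, replace = TRUE), collapse = "")
  }, character(1))
}

plant_in <- function(s, pat) {
  pos <- sample.int(nchar(s) - nchar(pat) + 1L, 1L)
  paste0(substr(s, 1L, pos - 1L), pat, substr(s, pos + nchar(pat), nchar(s)))
}

# A fixed 4-pair toy gold standard with hand-checkable annotations.
toy_gsp <- function() {
  data.table::data.table(
    e3 = c("E1", "E2", "E1", "E3"),
    substrate = c("S1", "S2", "S3", "S1")
  )
}

toy_domains <- function() {
  annotations(data.table::data.table(
    protein = c("E1", "E1", "E2", "E3", "S1", "S2", "S3"),
    label = c("DA", "DB", "DA", "DC", "DX", "DY", "DX")
  ), "domain")
}

# --- independent oracles --------------------------------------------------

# Enrichment ratio by explicit loops over GSP rows (no joins, no vectorized
# membership): the hand count of the four fractions.
oracle_enrichment_ratio <- function(le, ls, gsp, ann) {
  ann <- as.data.frame(ann)
  has <- function(p, l) any(ann$protein == p & ann$label == l)
  n <- nrow(gsp)
  both <- 0; e3m <- 0; subm <- 0
  for (i in seq_len(n)) {
    a <- has(gsp$e3[i], le)
    b <- has(gsp$substrate[i], ls)
    if (a) e3m <- e3m + 1
    if (b) subm <- subm + 1
    if (a && b) both <- both + 1
  }
  (both / n) / ((e3m / n) * (subm / n))
}

# Exhaustive enumeration of 3- and 4-loops through the edge (u, v) on the
# graph G' = g + (u, v), using the adjacency matrix directly.
oracle_loops <- function(u, v, g) {
  g2 <- igraph::add_edges(g, c(u, v))
  g2 <- igraph::simplify(g2)
  A <- as.matrix(igraph::as_adjacency_matrix(g2))
  vs <- rownames(A)
  others <- setdiff(vs, c(u, v))
  n3 <- 0L
  for (x in others) if (A[u, x] && A[v, x]) n3 <- n3 + 1L
  n4 <- 0L
  for (x in others) {
    for (y in others) {
      if (x != y && A[u, x] && A[x, y] && A[y, v]) n4 <- n4 + 1L
    }
  }
  c(n3 = n3, n4 = n4)
}

# All-pairs comparison AUROC (ties count 1/2).
oracle_auroc <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Motif score recomputed from the four counts: -log10 of the
# Bonferroni-adjusted binomial tail, tail as an explicit dbinom sum.
oracle_motif_score <- function(fg_hits, fg_total, bg_hits, bg_total, width) {
  p <- max((bg_hits + 1) / (bg_total + 1), 1 / (bg_total + 1))
  tail_p <- sum(dbinom(fg_hits:fg_total, fg_total, p))
  -log10(min(1, 20^width * tail_p))
}

# One-tailed Fisher p by exhaustive enumeration of all tables with the
# observed margins, summing dhyper mass over the extreme direction.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(ks, c1, n - c1, r1)
  exp_a <- r1 * c1 / n
  if (a <= exp_a) sum(probs[ks <= a]) else sum(probs[ks >= a])
}

# Tiny but complete world for fast end-to-end paths.
small_world <- function(seed = 1, ...) {
  args <- list(
    n_e3 = 10L, n_proteins = 80L, n_gsp = 40L, n_gsn = 80L,
    n_domains = 20L, n_go_terms = 25L, n_motif_e3 = 2L,
    ppi_density = 0.12, seq_length = 120, seed = seed
  )
  ov <- list(...)
  args[names(ov)] <- ov
  generate_world(do.call(world_config, args))
}
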