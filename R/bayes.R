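#' Default model configuration
#'
#' Bin edges are half-open `[lo, hi)` intervals covering the non-negative
#' feature axis of each evidence type; they are configuration, not data.
#' The smoothing pseudocount `s` enters the likelihood ratio as
#' `((tp+s)/(T+s)) / ((fp+s)/(F+s))`, and ratios are capped to `lr_cap` to
#' keep log-odds finite.
#'
#' @param der_edges,ger_edges bin edges for domain / GO enrichment ratios.
#' @param n3_edges,n4_edges bin edges for triangle / quadrilateral counts.
#' @param motif_edges bin edges for motif scores.
#' @param hom_edges bin edges for the boolean homology feature (0/1).
#' @param smoothing pseudocount (default 1).
#' @param lr_cap two-element range for likelihood-ratio capping.
#' @param min_ratio retention threshold for enrichment tables.
#' @param repeats,split enrichment-calibration protocol: `repeats` rounds of
#'   a `split` training fraction (defaults: 3 rounds of 2/3).
#' @param motif_widths,motif_min_fg,motif_score_threshold,motif_p_floor
#'   motif-discovery parameters (see [discover_motifs()]).
#' @return a list of class `esi_config`.
#' @export
esi_config <- function(der_edges = c(0, 1, 2, 4, 8, 16, Inf),
                       ger_edges = c(0, 1, 2, 4, 8, 16, Inf),
                       n3_edges = c(0, 1, 2, 3, 4, Inf),
                       n4_edges = c(0, 1, 3, 6, Inf),
                       motif_edges = c(0, 2, 5, 10, Inf),
                       hom_edges = c(0, 1, Inf),
                       smoothing = 1,
                       lr_cap = c(1e-3, 1e3),
                       min_ratio = 1,
                       repeats = 3L,
                       split = 2 / 3,
                       motif_widths = 3:5,
                       motif_min_fg = 3L,
                       motif_score_threshold = 2,
                       motif_p_floor = NULL) {
  structure(list(
    der_edges = der_edges, ger_edges = ger_edges,
    n3_edges = n3_edges, n4_edges = n4_edges,
    motif_edges = motif_edges, hom_edges = hom_edges,
    smoothing = smoothing, lr_cap = lr_cap, min_ratio = min_ratio,
    repeats = as.integer(repeats), split = split,
    motif_widths = as.integer(motif_widths),
    motif_min_fg = as.integer(motif_min_fg),
    motif_score_threshold = motif_score_threshold,
    motif_p_floor = motif_p_floor
  ), class = "esi_config")
}

validate_edges <- function(edges) {
  if (length(edges) < 2L || anyNA(edges)) stop("invalid bin edges")
  if (is.unsorted(edges, strictly = TRUE)) {
    stop("bin edges must be strictly increasing (overlapping or ",
         "non-covering bins)")
  }
  if (!is.infinite(edges[length(edges)])) {
    stop("bin edges must end at Inf to cover the feature axis")
  }
  edges
}

#' Estimate a binned likelihood-ratio table
#'
#' For each feature bin, the likelihood ratio is
#' `LR = P(f | positive) / P(f | negative) = (TP_f / T) / (FP_f / F)`,
#' smoothed with pseudocount `s` as `((TP_f+s)/(T+s)) / ((FP_f+s)/(F+s))`.
#' `T` and `F` default to the number of supplied feature values but may be
#' set larger when some gold-standard pairs do not fire the evidence at all
#' (they then count in the denominators only). Bins with `TP_f = FP_f = 0`
#' are neutral (`LR = 1`); ratios are capped to `lr_cap`.
#'
#' @param pos_features,neg_features numeric feature values observed on
#'   positive / negative pairs.
#' @param bin_edges strictly increasing edges of half-open bins `[lo, hi)`,
#'   ending at `Inf` and starting at or below the smallest feature.
#' @param smoothing pseudocount `s` (default 1).
#' @param n_pos,n_neg totals `T`, `F`.
#' @param lr_cap capping range.
#' @param evidence_type label stored on the table.
#' @return `data.table` (`lo`, `hi`, `tp`, `fp`, `lr`) of class
#'   `esi_lr_table`.
#' @export
estimate_lr_table <- function(pos_features, neg_features, bin_edges,
                              smoothing = 1,
                              n_pos = length(pos_features),
                              n_neg = length(neg_features),
                              lr_cap = c(1e-3, 1e3),
                              evidence_type = NA_character_) {
  if (n_pos <= 0L || n_neg <= 0L) {
    stop("need positive and negative totals > 0 for LR estimation")
  }
  edges <- validate_edges(bin_edges)
  nb <- length(edges) - 1L
  bin_of <- function(x) {
    x <- x[!is.na(x)]
    b <- findInterval(x, edges)
    if (any(b == 0L)) {
      stop("feature value below the first bin edge: bins do not cover ",
           "the feature axis")
    }
    b
  }
  tp <- tabulate(bin_of(pos_features), nbins = nb)
  fp <- tabulate(bin_of(neg_features), nbins = nb)
  s <- smoothing
  lr <- ((tp + s) / (n_pos + s)) / ((fp + s) / (n_neg + s))
  lr[tp == 0L & fp == 0L] <- 1
  lr <- pmin(pmax(lr, lr_cap[1L]), lr_cap[2L])
  tab <- data.table(lo = edges[-length(edges)], hi = edges[-1L],
                    tp = tp, fp = fp, lr = lr)
  setattr(tab, "edges", edges)
  setattr(tab, "n_pos", n_pos)
  setattr(tab, "n_neg", n_neg)
  setattr(tab, "smoothing", s)
  setattr(tab, "evidence_type", evidence_type)
  setattr(tab, "class", c("esi_lr_table", class(tab)))
  tab[]
}

#' Look up likelihood ratios for feature values
#' @param table an `esi_lr_table`.
#' @param x numeric feature values.
#' @return numeric LR vector (NA in, NA out).
#' @export
lookup_lr <- function(table, x) {
  edges <- attr(table, "edges", exact = TRUE)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  b <- findInterval(x[ok], edges)
  if (any(b == 0L)) stop("feature value below the first bin edge")
  out[ok] <- table$lr[b]
  out
}

#' Calibrate an enrichment evidence type (domains or GO terms)
#'
#' Repeated-split protocol: in each of `repeats` rounds, a fraction `split`
#' of the gold-standard positives defines the enriched label-pair table and
#' the held-out remainder is scored against it (feature = maximum matching
#' enrichment ratio, 0 when nothing matches); all negatives are scored each
#' round. TP/FP counts are pooled across rounds before the likelihood-ratio
#' table is estimated, and the final enrichment table is rebuilt on the full
#' positive set.
#'
#' @param gsp,gsn positive / negative pair tables.
#' @param ann annotation map.
#' @param bin_edges LR bin edges on the enrichment-ratio axis.
#' @param repeats,split protocol parameters (defaults 3 and 2/3).
#' @param min_ratio enrichment-table retention threshold.
#' @param smoothing pseudocount.
#' @param lr_cap capping range.
#' @param seed optional seed for the random splits.
#' @return list with `table` (full-data [enriched_pair_table()]) and `lr`
#'   (the pooled [estimate_lr_table()]).
#' @export
calibrate_enrichment_lr <- function(gsp, gsn, ann, bin_edges,
                                    repeats = 3L, split = 2 / 3,
                                    min_ratio = 1, smoothing = 1,
                                    lr_cap = c(1e-3, 1e3), seed = NULL) {
  gsp <- as.data.table(gsp)
  gsn <- as.data.table(gsn)
  n <- nrow(gsp)
  n_train <- floor(split * n)
  if (n_train < 1L || n_train >= n) {
    stop("gold-standard positives too small for a ", format(split),
         " split with non-empty hold-out")
  }
  if (!is.null(seed)) set.seed(seed)
  pos_feat <- numeric()
  neg_feat <- numeric()
  ns <- attr(ann, "namespace", exact = TRUE) %||% "domain"
  for (r in seq_len(repeats)) {
    tr <- sample.int(n, n_train)
    tab_r <- enriched_pair_table(gsp[tr], ann, min_ratio = min_ratio)
    pos_feat <- c(pos_feat, max_ratio_features(gsp[-tr], ann, tab_r))
    neg_feat <- c(neg_feat, max_ratio_features(gsn, ann, tab_r))
  }
  lrt <- estimate_lr_table(pos_feat, neg_feat, bin_edges,
                           smoothing = smoothing, lr_cap = lr_cap,
                           evidence_type = ns)
  list(table = enriched_pair_table(gsp, ann, min_ratio = min_ratio),
       lr = lrt)
}

#' Combine per-evidence likelihood ratios (naive Bayes)
#'
#' Under the conditional-independence assumption the composite likelihood
#' ratio is the product of the per-evidence-type ratios. Evidence types
#' with no firing feature are simply absent from the map (an empty map
#' gives the neutral value 1).
#'
#' @param per_type_lr named numeric vector (or list) of per-type LRs.
#' @return the composite likelihood ratio.
#' @export
combine_lr <- function(per_type_lr) {
  v <- unlist(per_type_lr, use.names = FALSE)
  v <- v[!is.na(v)]
  if (!length(v)) return(1)
  if (any(v <= 0)) stop("likelihood ratios must be positive")
  prod(v)
}

#' Prior and posterior odds of a true E3-substrate interaction
#'
#' The prior probability of a true interaction is estimated from the gold
#' standard as `T / (T + F)`; the prior odds are `T / F`, and the posterior
#' odds are `O_prior * LR_comp`.
#'
#' @param gold an `esi_gold` object (or list with `positives`, `negatives`).
#' @param lr_comp composite likelihood ratio(s).
#' @return list with `p_positive`, `o_prior`, `o_post`.
#' @export
prior_and_posterior <- function(gold, lr_comp = 1) {
  t_n <- nrow(gold$positives)
  f_n <- nrow(gold$negatives)
  if (t_n == 0L || f_n == 0L) stop("gold standard must have T > 0 and F > 0")
  p <- t_n / (t_n + f_n)
  o_prior <- p / (1 - p)
  list(p_positive = p, o_prior = o_prior, o_post = o_prior * lr_comp)
}

#' Normalized confidence score of a composite likelihood ratio
#'
#' Logistic normalization of the base-10 logarithm of the composite
#' likelihood ratio: `score = 1 / (1 + exp(-log10(LR_comp)))`. The score is
#' strictly increasing in the ratio, lies in (0, 1), and equals 0.5 at
#' `LR_comp = 1` (uninformative). The base-10 logarithm (rather than the
#' natural one, under which the formula would collapse to `LR/(1+LR)`)
#' reproduces the published worked value 0.908 at `LR_comp = 195.79`.
#'
#' @param lr_comp positive composite likelihood ratio(s).
#' @return score(s) in (0, 1).
#' @export
confidence_score <- function(lr_comp) {
  if (any(is.na(lr_comp)) || any(lr_comp <= 0)) {
    stop("lr_comp must be positive")
  }
  1 / (1 + exp(-log10(lr_comp)))
}

# ---- model training ----------------------------------------------------

#' Bundle the prediction inputs
#'
#' @param domain_ann,go_ann annotation maps ([annotations()]).
#' @param ppi igraph interaction network.
#' @param mouse_esis model-organism ESI pair table (may be empty).
#' @param omap ortholog map (`source`, `target`; may be empty).
#' @param sequences named character vector of protein sequences.
#' @return list of class `esi_inputs`.
#' @export
esi_inputs <- function(domain_ann, go_ann, ppi, mouse_esis, omap,
                       sequences) {
  structure(list(domain_ann = domain_ann, go_ann = go_ann, ppi = ppi,
                 mouse_esis = mouse_esis, omap = omap,
                 sequences = sequences),
            class = "esi_inputs")
}

EVIDENCE_TYPES <- c("homology", "domain", "go", "network_n3", "network_n4",
                    "motif")

# Cache the derived lookup structures (adjacency list, implied ortholog
# pair keys) on the inputs bundle so repeated score_pairs() calls -- e.g.
# the per-E3 chunks of a proteome scan -- do not rebuild them.
prepare_inputs <- function(inputs) {
  if (!is.null(inputs$adj) && !is.null(inputs$imp_keys)) return(inputs)
  inputs$adj <- adjacency_list(inputs$ppi)
  inputs$imp_keys <- pair_keys(
    implied_ortholog_pairs(inputs$mouse_esis, inputs$omap)
  )
  inputs
}

loop_features <- function(pairs, adj) {
  pairs <- as.data.table(pairs)
  n3 <- rep(NA_real_, nrow(pairs))
  n4 <- rep(NA_real_, nrow(pairs))
  present <- pairs$e3 %in% names(adj) & pairs$substrate %in% names(adj)
  for (i in which(present)) {
    cl <- count_loops(pairs$e3[i], pairs$substrate[i], adj)
    n3[i] <- cl[["n3"]]
    n4[i] <- cl[["n4"]]
  }
  list(n3 = n3, n4 = n4)
}

# Max matching motif score per pair; NA when the E3 has no motifs, the
# substrate has no sequence, or nothing matches.
motif_features <- function(pairs, motifs, sequences) {
  pairs <- as.data.table(pairs)
  out <- rep(NA_real_, nrow(pairs))
  if (!length(motifs)) return(out)
  mtab <- motifs_to_table(motifs)
  mtab[, regex := vapply(pattern, function(p)
    motif_regex(parse_motif_pattern(p)), character(1))]
  for (e in unique(mtab$e3)) {
    rows <- which(pairs$e3 == e)
    if (!length(rows)) next
    seqs <- sequences[pairs$substrate[rows]]
    known <- !is.na(seqs)
    if (!any(known)) next
    sub <- mtab[e3 == e]
    best <- rep(NA_real_, length(rows))
    for (j in seq_len(nrow(sub))) {
      hit <- known & grepl(sub$regex[j], seqs, perl = TRUE)
      upd <- hit & (is.na(best) | sub$motif_score[j] > best)
      best[upd] <- sub$motif_score[j]
    }
    out[rows] <- best
  }
  out
}

#' Train the naive Bayes ESI model
#'
#' Fits every evidence component on the gold standard: repeated-split
#' enrichment calibration for domain and GO label pairs
#' ([calibrate_enrichment_lr()]), direct LR estimation for triangle and
#' quadrilateral loop counts (pairs with both endpoints in the network),
#' the boolean ortholog-transfer feature, and per-E3 motif discovery
#' (foreground: the E3's gold-standard substrate sequences; background: the
#' sequences of the E3's network interactors) followed by LR estimation of
#' the motif-score feature.
#'
#' @param gold an `esi_gold` object.
#' @param inputs an `esi_inputs` bundle.
#' @param config an [esi_config()].
#' @param seed optional integer seed controlling the calibration splits.
#' @return list of class `esi_model`.
#' @export
train_model <- function(gold, inputs, config = esi_config(), seed = NULL) {
  gsp <- as.data.table(gold$positives)[, .(e3, substrate)]
  gsn <- as.data.table(gold$negatives)[, .(e3, substrate)]
  t_n <- nrow(gsp)
  f_n <- nrow(gsn)
  if (!is.null(seed)) set.seed(seed)

  dom <- calibrate_enrichment_lr(
    gsp, gsn, inputs$domain_ann, config$der_edges,
    repeats = config$repeats, split = config$split,
    min_ratio = config$min_ratio, smoothing = config$smoothing,
    lr_cap = config$lr_cap
  )
  go <- calibrate_enrichment_lr(
    gsp, gsn, inputs$go_ann, config$ger_edges,
    repeats = config$repeats, split = config$split,
    min_ratio = config$min_ratio, smoothing = config$smoothing,
    lr_cap = config$lr_cap
  )

  adj <- adjacency_list(inputs$ppi)
  lp <- loop_features(gsp, adj)
  ln <- loop_features(gsn, adj)
  lr_n3 <- estimate_lr_table(lp$n3[!is.na(lp$n3)], ln$n3[!is.na(ln$n3)],
                             config$n3_edges, smoothing = config$smoothing,
                             n_pos = t_n, n_neg = f_n,
                             lr_cap = config$lr_cap,
                             evidence_type = "network_n3")
  lr_n4 <- estimate_lr_table(lp$n4[!is.na(lp$n4)], ln$n4[!is.na(ln$n4)],
                             config$n4_edges, smoothing = config$smoothing,
                             n_pos = t_n, n_neg = f_n,
                             lr_cap = config$lr_cap,
                             evidence_type = "network_n4")

  imp <- implied_ortholog_pairs(inputs$mouse_esis, inputs$omap)
  imp_keys <- pair_keys(imp)
  hom_pos <- as.numeric(pair_keys(gsp) %in% imp_keys)
  hom_neg <- as.numeric(pair_keys(gsn) %in% imp_keys)
  lr_hom <- estimate_lr_table(hom_pos, hom_neg, config$hom_edges,
                              smoothing = config$smoothing,
                              n_pos = t_n, n_neg = f_n,
                              lr_cap = config$lr_cap,
                              evidence_type = "homology")

  seqs <- inputs$sequences
  motifs <- list()
  for (e in sort(unique(gsp$e3))) {
    fg_ids <- unique(gsp[e3 == e, substrate])
    fg <- seqs[intersect(fg_ids, names(seqs))]
    bg_ids <- setdiff(adj[[e]] %||% character(), fg_ids)
    bg <- seqs[intersect(bg_ids, names(seqs))]
    if (length(fg) < config$motif_min_fg || length(bg) == 0L) next
    motifs <- c(motifs, discover_motifs(
      e, unname(fg), unname(bg), widths = config$motif_widths,
      min_fg = config$motif_min_fg,
      score_threshold = config$motif_score_threshold,
      p_floor = config$motif_p_floor
    ))
  }
  mp <- motif_features(gsp, motifs, seqs)
  mn <- motif_features(gsn, motifs, seqs)
  lr_motif <- estimate_lr_table(mp[!is.na(mp)], mn[!is.na(mn)],
                                config$motif_edges,
                                smoothing = config$smoothing,
                                n_pos = t_n, n_neg = f_n,
                                lr_cap = config$lr_cap,
                                evidence_type = "motif")

  fp_file <- tempfile()
  writeLines(sort(c(pair_keys(gsp), paste0("NEG:", pair_keys(gsn)))),
             fp_file)
  fingerprint <- unname(tools::md5sum(fp_file))
  unlink(fp_file)

  structure(list(
    prior = prior_and_posterior(list(positives = gsp, negatives = gsn)),
    n_pos = t_n, n_neg = f_n,
    domain = dom, go = go,
    lr_n3 = lr_n3, lr_n4 = lr_n4,
    homology = lr_hom,
    motifs = motifs, lr_motif = lr_motif,
    config = config,
    fingerprint = fingerprint,
    train_e3s = sort(unique(c(gsp$e3, gsn$e3))),
    train_pos_keys = sort(pair_keys(gsp))
  ), class = "esi_model")
}

#' @export
print.esi_model <- function(x, ...) {
  cat("Naive Bayes ESI model\n")
  cat("  trained on", x$n_pos, "positives /", x$n_neg, "negatives\n")
  cat("  enriched domain pairs:", nrow(x$domain$table),
      "| GO pairs:", nrow(x$go$table),
      "| motifs:", length(x$motifs), "\n")
  cat("  fingerprint:", x$fingerprint, "\n")
  invisible(x)
}

#' Per-evidence likelihood ratios for one candidate pair
#'
#' Collects every firing feature per evidence type (all matching domain
#' pairs, all matching GO pairs, loop counts when both endpoints are in the
#' network, the ortholog-transfer flag, all matching motifs of the E3),
#' maps each through its likelihood-ratio table, and keeps the maximum per
#' type; types with no firing feature are omitted from the result.
#'
#' @param pair one-row pair table (or list with `e3`, `substrate`).
#' @param model a trained `esi_model`.
#' @param inputs the `esi_inputs` bundle used at prediction time.
#' @return named numeric vector of per-type LRs (possibly empty).
#' @export
evidence_lr <- function(pair, model, inputs) {
  p <- data.table(e3 = pair$e3, substrate = pair$substrate)
  sc <- score_pairs(p, model, inputs)
  v <- unlist(sc[1L, paste0("lr_", EVIDENCE_TYPES), with = FALSE])
  names(v) <- EVIDENCE_TYPES
  v[!is.na(v)]
}

#' Score candidate pairs with a trained model
#'
#' Vectorized scoring: per-evidence-type likelihood ratios (maximum over
#' firing features, `NA` when the type does not fire), their naive Bayes
#' product `lr_comp`, the posterior odds, and the normalized confidence
#' score.
#'
#' @param pairs pair table.
#' @param model trained `esi_model`.
#' @param inputs `esi_inputs` bundle.
#' @return `data.table` with `e3`, `substrate`, one `lr_<type>` column per
#'   evidence type, `lr_comp`, `o_post`, `score`.
#' @export
score_pairs <- function(pairs, model, inputs) {
  pairs <- as.data.table(pairs)[, .(e3, substrate)]
  n <- nrow(pairs)
  if (n == 0L) {
    out <- data.table(e3 = character(), substrate = character())
    for (ty in EVIDENCE_TYPES) out[, paste0("lr_", ty) := numeric()]
    out[, `:=`(lr_comp = numeric(), o_post = numeric(), score = numeric())]
    return(out[])
  }

  dom_feat <- max_ratio_features(pairs, inputs$domain_ann, model$domain$table)
  dom_lr <- ifelse(dom_feat > 0, lookup_lr(model$domain$lr, dom_feat),
                   NA_real_)
  go_feat <- max_ratio_features(pairs, inputs$go_ann, model$go$table)
  go_lr <- ifelse(go_feat > 0, lookup_lr(model$go$lr, go_feat), NA_real_)

  inputs <- prepare_inputs(inputs)
  lf <- loop_features(pairs, inputs$adj)
  n3_lr <- lookup_lr(model$lr_n3, lf$n3)
  n4_lr <- lookup_lr(model$lr_n4, lf$n4)

  hom <- pair_keys(pairs) %in% inputs$imp_keys
  hom_lr <- ifelse(hom, lookup_lr(model$homology, rep(1, n)), NA_real_)

  mf <- motif_features(pairs, model$motifs, inputs$sequences)
  motif_lr <- lookup_lr(model$lr_motif, mf)

  lrm <- cbind(homology = hom_lr, domain = dom_lr, go = go_lr,
               network_n3 = n3_lr, network_n4 = n4_lr, motif = motif_lr)
  lr_comp <- apply(lrm, 1L, function(r) combine_lr(r))
  out <- data.table(e3 = pairs$e3, substrate = pairs$substrate)
  for (ty in EVIDENCE_TYPES) out[, paste0("lr_", ty) := lrm[, ty]]
  out[, lr_comp := lr_comp]
  out[, o_post := model$prior$o_prior * lr_comp]
  out[, score := confidence_score(lr_comp)]
  out[]
}

#' Predict one E3-substrate interaction
#'
#' @inheritParams evidence_lr
#' @return list of class `esi_prediction` with the pair, the per-type LR
#'   map, `lr_comp`, `o_post`, and `score`.
#' @export
predict_pair <- function(pair, model, inputs) {
  per_type <- evidence_lr(pair, model, inputs)
  lr_comp <- combine_lr(per_type)
  structure(list(
    e3 = pair$e3, substrate = pair$substrate,
    per_type_lr = per_type, lr_comp = lr_comp,
    o_post = model$prior$o_prior * lr_comp,
    score = confidence_score(lr_comp)
  ), class = "esi_prediction")
}

#' @export
print.esi_prediction <- function(x, ...) {
  cat(sprintf("%s -> %s  LR %.4g  score %.3f\n", x$e3, x$substrate,
              x$lr_comp, x$score))
  if (length(x$per_type_lr)) {
    cat("  evidence:",
        paste(sprintf("%s=%.3g", names(x$per_type_lr), x$per_type_lr),
              collapse = ", "), "\n")
  }
  invisible(x)
}
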