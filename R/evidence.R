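#' Enrichment ratio of an (E3-side, substrate-side) label pair
#'
#' The enrichment ratio of an ordered annotation-label pair among known
#' E3-substrate interactions is
#' `Pr(l_e3 : l_sub | GSP) / (Pr(l_e3 | GSP) * Pr(l_sub | GSP))`,
#' where all probabilities are fractions of gold-standard positive pairs:
#' `Pr(l_e3 | GSP)` is the fraction of GSP pairs whose E3 carries `l_e3`,
#' `Pr(l_sub | GSP)` the fraction whose substrate carries `l_sub`, and the
#' joint term the fraction carrying both on their respective sides. The same
#' formula serves domains (DER) and GO terms (GER); ratio 1 is the
#' independence limit, ratios above 1 indicate recognition signal.
#'
#' @param label_e3,label_sub annotation labels (E3 side / substrate side).
#' @param gsp positive pair table.
#' @param ann annotation map (see [annotations()]).
#' @return the enrichment ratio (non-negative real).
#' @export
pair_enrichment_ratio <- function(label_e3, label_sub, gsp, ann) {
  gsp <- as.data.table(gsp)
  with_e3 <- ann[label == label_e3, protein]
  with_sub <- ann[label == label_sub, protein]
  h_e3 <- gsp$e3 %in% with_e3
  h_sub <- gsp$substrate %in% with_sub
  p_e3 <- mean(h_e3)
  p_sub <- mean(h_sub)
  if (p_e3 == 0 || p_sub == 0) {
    stop("undefined enrichment ratio: label '",
         if (p_e3 == 0) label_e3 else label_sub,
         "' absent from its side of the gold-standard positives")
  }
  mean(h_e3 & h_sub) / (p_e3 * p_sub)
}

#' Table of enriched label pairs over the gold-standard positives
#'
#' Enumerates every ordered `(label_e3, label_sub)` combination observed in
#' at least one positive pair, computes its enrichment ratio (see
#' [pair_enrichment_ratio()]), and keeps those with `ratio >= min_ratio`.
#'
#' @param gsp positive pair table.
#' @param ann annotation map.
#' @param min_ratio retention threshold (default 1 = at least independence).
#' @return `data.table` (`label_e3`, `label_sub`, `ratio`, `support`) of
#'   class `esi_enrichment`; `support` is the number of GSP pairs exhibiting
#'   the label pair.
#' @export
enriched_pair_table <- function(gsp, ann, min_ratio = 1) {
  gsp <- as.data.table(gsp)
  if (nrow(gsp) == 0L) stop("empty gold-standard positive set")
  n <- nrow(gsp)
  adt <- as.data.table(ann)[, .(protein, label)]
  idx <- data.table(pair = seq_len(n), e3 = gsp$e3, substrate = gsp$substrate)
  e3l <- merge(idx[, .(pair, protein = e3)], adt, by = "protein",
               allow.cartesian = TRUE)[, .(pair, label_e3 = label)]
  subl <- merge(idx[, .(pair, protein = substrate)], adt, by = "protein",
                allow.cartesian = TRUE)[, .(pair, label_sub = label)]
  # marginal pair counts per label on each side
  c_e3_tab <- unique(e3l)[, .(c_e3 = .N), by = label_e3]
  c_sub_tab <- unique(subl)[, .(c_sub = .N), by = label_sub]
  both <- merge(e3l, subl, by = "pair", allow.cartesian = TRUE)
  tab <- unique(both)[, .(support = .N), by = .(label_e3, label_sub)]
  tab <- merge(tab, c_e3_tab, by = "label_e3")
  tab <- merge(tab, c_sub_tab, by = "label_sub")
  tab[, ratio := (support * n) / (c_e3 * c_sub)]
  tab <- tab[is.finite(ratio) & ratio >= min_ratio,
             .(label_e3, label_sub, ratio, support)]
  setorder(tab, -ratio, label_e3, label_sub)
  setattr(tab, "n_pairs", n)
  setattr(tab, "namespace", attr(ann, "namespace", exact = TRUE))
  setattr(tab, "class", c("esi_enrichment", class(tab)))
  tab[]
}

# Max matching enrichment ratio per query pair; pairs with no matching
# (label_e3, label_sub) combination in `tab` get 0 (below any stored ratio).
max_ratio_features <- function(pairs, ann, tab) {
  pairs <- as.data.table(pairs)
  out <- numeric(nrow(pairs))
  if (nrow(pairs) == 0L || nrow(tab) == 0L) return(out)
  adt <- as.data.table(ann)[, .(protein, label)]
  idx <- data.table(pair = seq_len(nrow(pairs)), e3 = pairs$e3,
                    substrate = pairs$substrate)
  e3l <- merge(idx[, .(pair, protein = e3)], adt, by = "protein",
               allow.cartesian = TRUE)[, .(pair, label_e3 = label)]
  subl <- merge(idx[, .(pair, protein = substrate)], adt, by = "protein",
                allow.cartesian = TRUE)[, .(pair, label_sub = label)]
  tslim <- as.data.table(tab)[, .(label_e3, label_sub, ratio)]
  m <- merge(e3l, tslim, by = "label_e3", allow.cartesian = TRUE)
  m <- merge(m, subl, by = c("pair", "label_sub"))
  if (nrow(m) == 0L) return(out)
  mx <- m[, .(feature = max(ratio)), by = pair]
  out[mx$pair] <- mx$feature
  out
}

# Human pairs implied by model-organism ESIs under an ortholog map:
# (me, ms) with omap(me) x omap(ms) expanded.
implied_ortholog_pairs <- function(mouse_esis, omap) {
  mouse_esis <- as.data.table(mouse_esis)
  omap <- as.data.table(omap)
  if (nrow(mouse_esis) == 0L || nrow(omap) == 0L) {
    return(data.table(e3 = character(), substrate = character(),
                      source_e3 = character(), source_sub = character()))
  }
  m1 <- merge(mouse_esis[, .(source_e3 = e3, source_sub = substrate)],
              omap[, .(source_e3 = source, e3 = target)],
              by = "source_e3", allow.cartesian = TRUE)
  m2 <- merge(m1, omap[, .(source_sub = source, substrate = target)],
              by = "source_sub", allow.cartesian = TRUE)
  unique(m2[, .(e3, substrate, source_e3, source_sub)])
}

#' Ortholog-transfer support for a candidate pair
#'
#' A human pair is supported when some model-organism (mouse) E3-substrate
#' interaction maps onto it through the ortholog map: the query E3 is an
#' ortholog of the mouse E3 and the query substrate of the mouse substrate.
#'
#' @param pair one-row pair table (or list with `e3`, `substrate`).
#' @param mouse_esis mouse pair table.
#' @param omap ortholog map (`source`, `target`).
#' @return list with `supported` (logical) and `source_pair` (one-row
#'   `data.table` of the mouse pair, or `NULL`).
#' @export
homology_support <- function(pair, mouse_esis, omap) {
  imp <- implied_ortholog_pairs(mouse_esis, omap)
  hit <- imp[e3 == pair$e3 & substrate == pair$substrate]
  if (nrow(hit)) {
    list(supported = TRUE,
         source_pair = data.table(e3 = hit$source_e3[1L],
                                  substrate = hit$source_sub[1L]))
  } else {
    list(supported = FALSE, source_pair = NULL)
  }
}

# Named-list adjacency (character neighbor vectors) for fast repeated
# neighborhood lookups outside igraph's per-call overhead.
adjacency_list <- function(ppi) {
  al <- igraph::as_adj_list(ppi, mode = "all")
  nms <- igraph::V(ppi)$name
  out <- lapply(al, function(v) nms[as.integer(v)])
  names(out) <- nms
  out
}

#' Count interaction loops through a candidate E3-substrate edge
#'
#' The query edge `(e3, substrate)` is added to the interaction network and
#' the loops passing through it are counted: `n3` is the number of
#' three-interaction loops (triangles), i.e. common neighbors `x` of both
#' endpoints; `n4` is the number of four-interaction loops (quadrilaterals)
#' `e3 - x - y - substrate` with `x` a neighbor of the E3 (other than the
#' substrate), `y` a neighbor of the substrate (other than the E3),
#' `x != y`, and `(x, y)` an edge. Chords are permitted. Endpoints absent
#' from the network yield zero counts.
#'
#' @param e3,substrate protein identifiers.
#' @param ppi igraph network, or a precomputed adjacency list from
#'   `adjacency_list()` for repeated calls.
#' @return integer vector `c(n3 = ..., n4 = ...)`.
#' @export
count_loops <- function(e3, substrate, ppi) {
  adj <- if (inherits(ppi, "igraph")) adjacency_list(ppi) else ppi
  if (is.null(adj[[e3]]) || is.null(adj[[substrate]])) {
    return(c(n3 = 0L, n4 = 0L))
  }
  ne <- setdiff(adj[[e3]], c(e3, substrate))
  ns <- setdiff(adj[[substrate]], c(e3, substrate))
  n3 <- length(intersect(ne, ns))
  n4 <- 0L
  if (length(ne) && length(ns)) {
    for (x in ne) n4 <- n4 + length(intersect(adj[[x]], ns))
  }
  c(n3 = as.integer(n3), n4 = as.integer(n4))
}
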