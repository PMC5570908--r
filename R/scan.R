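#' Count the pairs a proteome-wide scan enumerates
#'
#' Lazily enumerates the ordered `(E3, protein)` pair space in per-E3
#' chunks (memory independent of the total pair count) and returns the
#' number of scored pairs and the number of excluded self-pairs.
#'
#' @param e3_list character vector of E3 identifiers (deduplicated).
#' @param proteome character vector of protein identifiers (deduplicated).
#' @param exclude_self drop pairs with `e3 == substrate` (default TRUE).
#' @return list with `n_pairs` and `n_self_excluded`.
#' @export
scan_enumeration <- function(e3_list, proteome, exclude_self = TRUE) {
  e3_list <- unique(as.character(e3_list))
  proteome <- unique(as.character(proteome))
  if (!length(e3_list) || !length(proteome)) {
    stop("empty E3 list or proteome")
  }
  n_pairs <- 0
  n_self <- 0
  for (e in e3_list) {
    k <- length(proteome)
    if (exclude_self) {
      s <- sum(proteome == e)
      n_self <- n_self + s
      k <- k - s
    }
    n_pairs <- n_pairs + k
  }
  list(n_pairs = n_pairs, n_self_excluded = n_self)
}

#' Proteome-wide E3-substrate scan
#'
#' Scores every ordered `(E3, protein)` pair (minus self-pairs, which are
#' excluded by default and reported separately), streaming one E3 at a
#' time, and emits the pairs whose confidence score reaches `min_score`,
#' sorted by score descending with a deterministic `(e3, substrate)`
#' tie-break.
#'
#' @param e3_list character vector of E3 identifiers.
#' @param proteome character vector of candidate substrate identifiers.
#' @param model trained `esi_model`.
#' @param inputs `esi_inputs` bundle.
#' @param min_score emission threshold on the confidence score.
#' @param exclude_self drop self-pairs (default TRUE).
#' @return `data.table` of predictions (see [score_pairs()]) with
#'   attributes `n_enumerated` and `n_self_excluded`.
#' @export
proteome_scan <- function(e3_list, proteome, model, inputs,
                          min_score = 0.5, exclude_self = TRUE) {
  e3_list <- unique(as.character(e3_list))
  proteome <- unique(as.character(proteome))
  if (!length(e3_list) || !length(proteome)) {
    stop("empty E3 list or proteome")
  }
  ctx <- prepare_inputs(inputs)
  n_enum <- 0
  n_self <- 0
  chunks <- vector("list", length(e3_list))
  for (i in seq_along(e3_list)) {
    e <- e3_list[i]
    subs <- proteome
    if (exclude_self) {
      self <- subs == e
      n_self <- n_self + sum(self)
      subs <- subs[!self]
    }
    if (!length(subs)) next
    n_enum <- n_enum + length(subs)
    sc <- score_pairs(data.table(e3 = e, substrate = subs), model, ctx)
    chunks[[i]] <- sc[score >= min_score]
  }
  out <- rbindlist(chunks[!vapply(chunks, is.null, TRUE)])
  if (nrow(out)) setorder(out, -score, e3, substrate)
  setattr(out, "n_enumerated", n_enum)
  setattr(out, "n_self_excluded", n_self)
  out[]
}
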