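#' Construct an ordered E3-substrate pair table
#'
#' An E3-substrate interaction (ESI) is a directional pair: the E3 ubiquitin
#' ligase recognizes the substrate, so `(e3, substrate)` and
#' `(substrate, e3)` are distinct pairs. Pairs are deduplicated; identifiers
#' are opaque, case-sensitive, whitespace-free accession strings.
#'
#' @param e3 character vector of E3 identifiers.
#' @param substrate character vector of substrate identifiers (same length).
#' @param pubmed,date optional per-pair provenance (recycled or NULL).
#' @param allow_self keep self-pairs (autoubiquitination)? If `FALSE`
#'   (default) self-pairs are dropped with a message rather than silently
#'   accepted.
#' @return a `data.table` with columns `e3`, `substrate` (and provenance
#'   columns when supplied), one row per distinct ordered pair.
#' @export
esi_pairs <- function(e3, substrate, pubmed = NULL, date = NULL,
                      allow_self = FALSE) {
  stopifnot(length(e3) == length(substrate))
  e3 <- as.character(e3)
  substrate <- as.character(substrate)
  bad <- !nzchar(e3) | !nzchar(substrate) | grepl("\\s", e3) |
    grepl("\\s", substrate) | is.na(e3) | is.na(substrate)
  if (any(bad)) {
    stop("invalid protein identifier(s) at row(s): ",
         paste(head(which(bad), 5L), collapse = ", "))
  }
  dt <- data.table(e3 = e3, substrate = substrate)
  if (!is.null(pubmed)) dt[, pubmed := as.character(pubmed)]
  if (!is.null(date)) dt[, date := as.Date(date)]
  if (!allow_self) {
    n_self <- sum(dt$e3 == dt$substrate)
    if (n_self > 0L) {
      message("dropping ", n_self,
              " self-pair(s); use allow_self = TRUE to keep them")
      dt <- dt[e3 != substrate]
    }
  }
  unique(dt, by = c("e3", "substrate"))
}

pair_keys <- function(pairs) paste(pairs$e3, pairs$substrate, sep = "\r")

#' Bundle gold-standard positive and negative ESI sets
#'
#' The positive set (GSP) holds literature-curated true E3-substrate
#' interactions; the negative set (GSN) holds E3-interactor pairs assumed
#' not to be ubiquitination events. The two sets must be disjoint and both
#' non-empty before any likelihood-ratio estimation.
#'
#' @param positives,negatives pair tables as returned by [esi_pairs()].
#' @return a list of class `esi_gold` with elements `positives`,
#'   `negatives`.
#' @export
gold_standard <- function(positives, negatives) {
  positives <- as.data.table(positives)
  negatives <- as.data.table(negatives)
  if (nrow(positives) == 0L) stop("gold standard has no positive pairs")
  if (nrow(negatives) == 0L) stop("gold standard has no negative pairs")
  if (any(pair_keys(negatives) %in% pair_keys(positives))) {
    stop("positives and negatives overlap")
  }
  structure(list(positives = positives, negatives = negatives),
            class = "esi_gold")
}

#' @export
print.esi_gold <- function(x, ...) {
  cat("Gold standard:", nrow(x$positives), "positive /",
      nrow(x$negatives), "negative ESI pairs\n")
  invisible(x)
}

read_tab_lines <- function(path, min_fields = 2L, comment = "#") {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, comment)
  idx <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < min_fields)) {
    bad <- idx[which(nf < min_fields)[1L]]
    stop("malformed line ", bad, " in '", path, "': expected at least ",
         min_fields, " tab-separated fields")
  }
  list(parts = parts, lines = idx)
}

#' Load a gold-standard pair list
#'
#' Reads a tab-separated file with one pair per line: `e3`, `substrate`,
#' optional PubMed id, optional date (ISO `YYYY-MM-DD`). Duplicate rows
#' collapse to one pair; `(A,B)` and `(B,A)` stay distinct.
#'
#' @param path file path.
#' @param date_cutoff optional `Date` (or string); rows are filtered by
#'   their date column relative to the cutoff.
#' @param after if `FALSE` (default) keep rows strictly before the cutoff
#'   (`date < cutoff`); if `TRUE` keep rows on/after it (`date >= cutoff`).
#'   Rows lacking a date are dropped when filtering, with a message.
#' @param allow_self see [esi_pairs()].
#' @return pair `data.table` (see [esi_pairs()]).
#' @export
load_gold_standard <- function(path, date_cutoff = NULL, after = FALSE,
                               allow_self = FALSE) {
  tl <- read_tab_lines(path, min_fields = 2L)
  parts <- tl$parts
  get_col <- function(i) {
    vapply(parts, function(p) if (length(p) >= i) p[[i]] else NA_character_,
           character(1))
  }
  e3 <- get_col(1L)
  sub <- get_col(2L)
  pm <- get_col(3L)
  dt_raw <- get_col(4L)
  dates <- suppressWarnings(as.Date(dt_raw))
  if (!is.null(date_cutoff)) {
    cutoff <- as.Date(date_cutoff)
    undated <- is.na(dates)
    if (any(undated)) {
      message("dropping ", sum(undated), " row(s) without a parseable date")
    }
    keep <- !undated & if (after) dates >= cutoff else dates < cutoff
    e3 <- e3[keep]; sub <- sub[keep]; pm <- pm[keep]; dates <- dates[keep]
  }
  if (length(e3) == 0L) {
    stop("no pairs loaded from '", path, "'",
         if (!is.null(date_cutoff)) " after date filtering" else "")
  }
  esi_pairs(e3, sub, pubmed = pm, date = dates, allow_self = allow_self)
}

#' Write a pair table to its canonical TSV
#' @param pairs pair table.
#' @param path output path.
#' @export
write_pairs <- function(pairs, path) {
  pairs <- as.data.table(pairs)
  cols <- intersect(c("e3", "substrate", "pubmed", "date"), names(pairs))
  fwrite(pairs[, cols, with = FALSE], path, sep = "\t", col.names = FALSE,
         quote = FALSE)
  invisible(path)
}

GO_ROOT_TERMS <- c("GO:0008150", "GO:0003674", "GO:0005575")

#' Load a protein annotation map (domains or GO terms)
#'
#' Accepts either a two-column `protein<TAB>label` TSV or, for the `go`
#' namespace, a GAF 2.x file (DB Object ID = column 2, Qualifier = column 4,
#' GO ID = column 5; rows whose qualifier contains `NOT` are skipped). GO
#' root terms (biological_process, molecular_function, cellular_component)
#' are excluded as uninformative. Unknown proteins simply map to the empty
#' label set downstream; duplicates are stored once.
#'
#' @param path file path.
#' @param namespace `"domain"` or `"go"`.
#' @param dialect `"auto"` (default), `"tsv"`, or `"gaf"`.
#' @return a `data.table` (`protein`, `label`) of class `esi_annotations`
#'   with a `namespace` attribute.
#' @export
load_annotations <- function(path, namespace = c("domain", "go"),
                             dialect = c("auto", "tsv", "gaf")) {
  namespace <- match.arg(namespace)
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "auto") {
    body <- lines[nzchar(lines) & !startsWith(lines, "!")]
    nf <- lengths(strsplit(head(body, 50L), "\t", fixed = TRUE))
    dialect <- if (any(startsWith(lines, "!")) || (length(nf) && all(nf >= 15L)))
      "gaf" else "tsv"
  }
  if (dialect == "gaf") {
    if (namespace != "go") stop("GAF dialect is only valid for namespace 'go'")
    body <- lines[nzchar(lines) & !startsWith(lines, "!")]
    parts <- strsplit(body, "\t", fixed = TRUE)
    short <- lengths(parts) < 5L
    if (any(short)) stop("malformed GAF line: fewer than 5 columns")
    qual <- vapply(parts, `[[`, character(1), 4L)
    ann <- data.table(
      protein = vapply(parts, `[[`, character(1), 2L),
      label = vapply(parts, `[[`, character(1), 5L)
    )[!grepl("NOT", qual, fixed = TRUE)]
  } else {
    tl <- read_tab_lines(path, min_fields = 2L)
    ann <- data.table(
      protein = vapply(tl$parts, `[[`, character(1), 1L),
      label = vapply(tl$parts, `[[`, character(1), 2L)
    )
  }
  if (namespace == "go") ann <- ann[!label %in% GO_ROOT_TERMS]
  ann <- unique(ann)
  if (nrow(ann) == 0L) stop("zero annotations parsed from '", path, "'")
  annotations(ann, namespace)
}

#' Construct an annotation map from a protein/label table
#' @param x data.frame with columns `protein`, `label`.
#' @param namespace `"domain"` or `"go"`.
#' @export
annotations <- function(x, namespace = c("domain", "go")) {
  namespace <- match.arg(namespace)
  ann <- unique(as.data.table(x)[, .(protein = as.character(protein),
                                     label = as.character(label))])
  setkey(ann, protein)
  setattr(ann, "namespace", namespace)
  setattr(ann, "class", c("esi_annotations", class(ann)))
  ann
}

#' Write an annotation map to two-column TSV
#' @param ann annotation map.
#' @param path output path.
#' @export
write_annotations <- function(ann, path) {
  fwrite(as.data.table(ann)[, .(protein, label)], path, sep = "\t",
         col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load an undirected protein-protein interaction network
#'
#' Accepts a two-column edge-list TSV or a PSI-MI TAB file (only columns 1-2
#' are used). Self-loops are dropped with a message; duplicate edges are
#' merged: the result is a simple undirected graph.
#'
#' @param path file path.
#' @return an `igraph` object.
#' @export
load_network <- function(path) {
  tl <- read_tab_lines(path, min_fields = 2L)
  a <- vapply(tl$parts, `[[`, character(1), 1L)
  b <- vapply(tl$parts, `[[`, character(1), 2L)
  if (length(a) == 0L) stop("no edges in '", path, "'")
  n_self <- sum(a == b)
  if (n_self > 0L) message("dropping ", n_self, " self-loop(s)")
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0L) stop("no non-loop edges in '", path, "'")
  g <- igraph::graph_from_data_frame(data.frame(a, b), directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a network as a two-column edge-list TSV
#' @param ppi igraph object.
#' @param path output path.
#' @export
write_network <- function(ppi, path) {
  el <- igraph::as_edgelist(ppi)
  # canonical edge orientation so re-serialization is byte-stable
  swap <- el[, 1] > el[, 2]
  el[swap, ] <- el[swap, c(2, 1)]
  dt <- data.table(a = el[, 1], b = el[, 2])
  setorder(dt, a, b)
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a source-to-target ortholog map
#'
#' Two-column TSV (`source_id`, `target_id`); one-to-many mappings allowed.
#' @param path file path.
#' @return `data.table` with columns `source`, `target`.
#' @export
load_ortholog_map <- function(path) {
  tl <- read_tab_lines(path, min_fields = 2L)
  unique(data.table(
    source = vapply(tl$parts, `[[`, character(1), 1L),
    target = vapply(tl$parts, `[[`, character(1), 2L)
  ))
}

#' Load protein sequences from FASTA
#'
#' The accession is the first whitespace-delimited token of the header.
#' Sequences must be non-empty and drawn from the 20-letter amino-acid
#' alphabet plus `X` (case-insensitive; stored uppercase).
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
load_sequences <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  seqs <- toupper(as.character(ss))
  if (any(!nzchar(seqs))) {
    stop("empty sequence record(s): ",
         paste(head(ids[!nzchar(seqs)], 5L), collapse = ", "))
  }
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "X]"), seqs)
  if (any(bad)) {
    stop("non-amino-acid characters in: ",
         paste(head(ids[bad], 5L), collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_sequences <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Sample a gold-standard negative set from the interaction network
#'
#' Negatives are drawn uniformly without replacement from oriented
#' `(e3, interactor)` pairs, where the underlying undirected edge is
#' incident to a protein in `e3_list`, excluding any pair already in the
#' gold-standard positive set. This mirrors the construction of a negative
#' set from physical E3 interactions that are not known ubiquitination
#' substrates.
#'
#' @param ppi igraph network.
#' @param e3_list character vector of E3 identifiers.
#' @param gsp positive pair table to exclude.
#' @param n number of negatives to draw (`0` allowed).
#' @param seed integer seed; same seed, same sample.
#' @return pair `data.table` of `n` negatives.
#' @export
sample_negative_set <- function(ppi, e3_list, gsp, n, seed) {
  el <- igraph::as_edgelist(ppi)
  cand <- rbind(
    data.table(e3 = el[, 1], substrate = el[, 2])[e3 %in% e3_list],
    data.table(e3 = el[, 2], substrate = el[, 1])[e3 %in% e3_list]
  )
  cand <- unique(cand)
  if (!is.null(gsp) && nrow(gsp)) {
    cand <- cand[!pair_keys(cand) %in% pair_keys(gsp)]
  }
  if (n > nrow(cand)) {
    stop("requested ", n, " negatives but only ", nrow(cand),
         " eligible E3-interactor pairs are available")
  }
  setorder(cand, e3, substrate)
  if (n == 0L) return(cand[0L])
  set.seed(seed)
  cand[sample.int(nrow(cand), n)][order(e3, substrate)]
}
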