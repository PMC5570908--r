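#' Construct a linear recognition motif
#'
#' A motif is an ungapped, position-specific pattern over the amino-acid
#' alphabet. The pattern string uses one character per position: an
#' uppercase residue for a fixed position or lowercase `x` for a wildcard
#' (e.g. `"PPxY"`). Bracketed residue sets (`"[ST]Q"`) are also accepted.
#'
#' @param pattern pattern string.
#' @param e3 the E3 the motif belongs to (optional).
#' @param motif_score enrichment score (`-log10` binomial tail), if known.
#' @param fg_hits,fg_total,bg_hits,bg_total supporting counts, if known.
#' @return an object of class `esi_motif`.
#' @export
motif <- function(pattern, e3 = NA_character_, motif_score = NA_real_,
                  fg_hits = NA_integer_, fg_total = NA_integer_,
                  bg_hits = NA_integer_, bg_total = NA_integer_) {
  pos <- parse_motif_pattern(pattern)
  structure(
    list(e3 = e3, pattern = pos, width = length(pos),
         motif_score = motif_score,
         fg_hits = fg_hits, fg_total = fg_total,
         bg_hits = bg_hits, bg_total = bg_total),
    class = "esi_motif"
  )
}

# "PPxY" / "[ST]Q" -> list of residue-set character vectors (wildcard = AA_ALPHABET)
parse_motif_pattern <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  chars <- strsplit(pattern, "")[[1L]]
  out <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      set <- character()
      while (j <= length(chars) && chars[j] != "]") {
        set <- c(set, toupper(chars[j])); j <- j + 1L
      }
      if (j > length(chars)) stop("unterminated '[' in motif pattern")
      if (!length(set) || !all(set %in% AA_ALPHABET)) {
        stop("invalid residue set in motif pattern: ", pattern)
      }
      out[[length(out) + 1L]] <- set
      i <- j + 1L
    } else if (ch %in% c("x", "X", ".")) {
      out[[length(out) + 1L]] <- AA_ALPHABET
      i <- i + 1L
    } else if (toupper(ch) %in% AA_ALPHABET) {
      out[[length(out) + 1L]] <- toupper(ch)
      i <- i + 1L
    } else {
      stop("invalid character '", ch, "' in motif pattern: ", pattern)
    }
  }
  out
}

motif_pattern_string <- function(m) {
  vap <- vapply(m$pattern, function(s) {
    if (length(s) >= length(AA_ALPHABET)) "x"
    else if (length(s) == 1L) s
    else paste0("[", paste(s, collapse = ""), "]")
  }, character(1))
  paste(vap, collapse = "")
}

motif_regex <- function(pattern) {
  paste(vapply(pattern, function(s) {
    if (length(s) >= length(AA_ALPHABET)) "."
    else if (length(s) == 1L) s
    else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' @export
print.esi_motif <- function(x, ...) {
  cat(sprintf("Motif %s (E3: %s) score %.2f [fg %s/%s, bg %s/%s]\n",
              motif_pattern_string(x), x$e3, x$motif_score,
              x$fg_hits, x$fg_total, x$bg_hits, x$bg_total))
  invisible(x)
}

#' Does a sequence contain a motif?
#'
#' A sequence contains a motif when some window of the motif's width
#' satisfies every fixed position's residue set.
#'
#' @param sequence character vector of amino-acid sequences.
#' @param motif an `esi_motif` (or pattern string).
#' @return logical vector.
#' @export
match_motif <- function(sequence, motif) {
  if (is.character(motif)) motif <- motif(motif)
  grepl(motif_regex(motif$pattern), sequence, perl = TRUE)
}

# Presence counts and motif score for a pattern. The one-sided binomial
# tail P(X >= fg_hits | n = fg_total, p) uses an add-one-smoothed
# background presence rate p = max((bg_hits + 1)/(bg_total + 1), p_floor),
# so a zero background frequency never divides by zero, and is
# Bonferroni-adjusted for the 20^width ungapped patterns of the width
# searched: motif_score = -log10(min(1, 20^width * tail)). The adjustment
# keeps the published retention threshold (score > 2) meaningful under the
# selection over all candidate patterns; without it a null foreground would
# routinely reach scores of 3-6. Computed in log space to survive extreme
# enrichment.
motif_stats <- function(pattern, fg, bg, p_floor = NULL) {
  rx <- motif_regex(pattern)
  fg_hits <- sum(grepl(rx, fg, perl = TRUE))
  bg_hits <- sum(grepl(rx, bg, perl = TRUE))
  p_floor <- p_floor %||% (1 / (length(bg) + 1))
  p <- min(max((bg_hits + 1) / (length(bg) + 1), p_floor), 1)
  w <- length(pattern)
  score <- if (fg_hits == 0L) 0 else {
    lt <- pbinom(fg_hits - 1L, length(fg), p, lower.tail = FALSE,
                 log.p = TRUE)
    -min(0, lt + w * log(20)) / log(10)
  }
  list(score = score, fg_hits = fg_hits, fg_total = length(fg),
       bg_hits = bg_hits, bg_total = length(bg))
}

# Distinct width-w windows per sequence -- plus, so that degenerate
# (PPxY-style) motifs are reachable, every variant with one interior
# position wildcarded -- pooled into presence counts. Leading/trailing
# wildcards are omitted: those patterns are equivalent to shorter motifs.
kmer_presence_counts <- function(seqs, w) {
  wild <- if (w >= 3L) 2:(w - 1L) else integer()
  lst <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < w) return(character())
    km <- unique(substring(s, seq_len(L - w + 1L), w:L))
    if (length(wild)) {
      for (p in wild) {
        v <- km
        substr(v, p, p) <- "x"
        km <- c(km, v)
      }
    }
    unique(km)
  })
  km <- unlist(lst, use.names = FALSE)
  if (!length(km)) {
    return(data.table(kmer = character(), hits = integer()))
  }
  data.table(kmer = km)[, .(hits = .N), by = kmer]
}

# Search for the best single motif of fixed width: score every exact w-mer
# seen in at least min_fg foreground sequences (this fixes all positions at
# once, the limit of iterative position fixing -- with unaligned sequences
# partial patterns match everything, so single-position steps carry no
# signal), take the top scorer (ties: lexicographically smallest k-mer),
# then greedily relax positions to wildcards while that improves the score
# (recovers PPxY-style degenerate motifs).
greedy_motif <- function(fg, bg, width, p_floor, min_fg) {
  fgc <- kmer_presence_counts(fg, width)
  fgc <- fgc[hits >= min_fg]
  if (!nrow(fgc)) return(NULL)
  bgc <- kmer_presence_counts(bg, width)
  m <- merge(fgc, bgc, by = "kmer", all.x = TRUE, suffixes = c("_fg", "_bg"))
  setnames(m, c("hits_fg", "hits_bg"), c("fg_hits", "bg_hits"),
           skip_absent = TRUE)
  if (!"bg_hits" %in% names(m)) setnames(m, "hits", "fg_hits")
  m[is.na(bg_hits), bg_hits := 0L]
  pf <- p_floor %||% (1 / (length(bg) + 1))
  p <- pmin(pmax((m$bg_hits + 1) / (length(bg) + 1), pf), 1)
  lt <- pbinom(m$fg_hits - 1L, length(fg), p, lower.tail = FALSE,
               log.p = TRUE)
  m[, score := -pmin(0, lt + width * log(20)) / log(10)]
  setorder(m, -score, kmer)
  best <- m[1L]
  pat <- parse_motif_pattern(best$kmer)
  cur <- motif_stats(pat, fg, bg, p_floor)
  # wildcard relaxation, earliest position first
  for (pos in seq_len(width)) {
    cand <- pat
    cand[[pos]] <- AA_ALPHABET
    if (all(vapply(cand, length, 1L) >= length(AA_ALPHABET))) next
    st <- motif_stats(cand, fg, bg, p_floor)
    if (st$fg_hits >= min_fg && st$score > cur$score + 1e-12) {
      pat <- cand
      cur <- st
    }
  }
  structure(
    list(e3 = NA_character_, pattern = pat, width = width,
         motif_score = cur$score,
         fg_hits = cur$fg_hits, fg_total = cur$fg_total,
         bg_hits = cur$bg_hits, bg_total = cur$bg_total),
    class = "esi_motif"
  )
}

#' Discover substrate-recognition motifs for one E3
#'
#' Greedy motif-x-style discovery. The foreground is the set of sequences of
#' the E3's known substrates; the background is the set of sequences of the
#' proteins that merely interact with the E3, which share the interaction
#' context but not the recognition signal. For each width `w`, every exact
#' `w`-mer present in at least `min_fg` foreground sequences is scored by
#' the enrichment of presence-in-sequence counts; the top scorer is then
#' greedily relaxed position-by-position to wildcards while that improves
#' the score. The motif score is the `-log10` one-sided binomial tail
#' `P(X >= fg_hits | n = fg_total, p)`, with an add-one-smoothed background
#' rate `p = max((bg_hits+1)/(bg_total+1), p_floor)` (so a zero background
#' frequency never divides by zero) and a Bonferroni adjustment for the
#' `20^w` candidate patterns of that width -- the adjustment calibrates the
#' retention threshold so that a foreground drawn from the background
#' distribution yields no motif in an overwhelming fraction of worlds.
#' Motifs scoring above `score_threshold` are retained; their matching
#' foreground sequences are removed before the search continues.
#'
#' @param e3 E3 identifier to attach to discovered motifs.
#' @param foreground,background character vectors of sequences.
#' @param widths motif widths to scan (default 3:5).
#' @param min_fg minimum foreground sequences (and minimum matches) for a
#'   motif (default 3).
#' @param score_threshold retention threshold on the motif score (default 2).
#' @param p_floor floor for the background match probability.
#' @return list of `esi_motif` objects (possibly empty).
#' @export
discover_motifs <- function(e3, foreground, background, widths = 3:5,
                            min_fg = 3L, score_threshold = 2,
                            p_floor = NULL) {
  if (length(background) == 0L) stop("empty background sequence set")
  if (length(foreground) < min_fg) return(list())
  p_floor <- p_floor %||% 1 / (length(background) + 1)
  out <- list()
  for (w in sort(widths)) {
    fg <- foreground
    repeat {
      if (length(fg) < min_fg) break
      m <- greedy_motif(fg, background, w, p_floor, min_fg)
      if (is.null(m) || m$motif_score <= score_threshold) break
      m$e3 <- e3
      out[[length(out) + 1L]] <- m
      fg <- fg[!grepl(motif_regex(m$pattern), fg, perl = TRUE)]
    }
  }
  out
}

# Motif list <-> serialization table
motifs_to_table <- function(motifs) {
  if (!length(motifs)) {
    return(data.table(e3 = character(), pattern = character(),
                      width = integer(), motif_score = numeric(),
                      fg_hits = integer(), fg_total = integer(),
                      bg_hits = integer(), bg_total = integer()))
  }
  rbindlist(lapply(motifs, function(m) data.table(
    e3 = m$e3, pattern = motif_pattern_string(m), width = m$width,
    motif_score = m$motif_score, fg_hits = m$fg_hits, fg_total = m$fg_total,
    bg_hits = m$bg_hits, bg_total = m$bg_total
  )))
}

table_to_motifs <- function(tab) {
  if (!nrow(tab)) return(list())
  lapply(seq_len(nrow(tab)), function(i) {
    motif(tab$pattern[i], e3 = tab$e3[i], motif_score = tab$motif_score[i],
          fg_hits = as.integer(tab$fg_hits[i]),
          fg_total = as.integer(tab$fg_total[i]),
          bg_hits = as.integer(tab$bg_hits[i]),
          bg_total = as.integer(tab$bg_total[i]))
  })
}
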