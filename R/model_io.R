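# Model archive: a directory of human-readable TSV tables plus a JSON
# schema snapshot. Doubles are serialized with %.17g so a reload re-scores
# bit-identically.

fmt_dbl <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else if (is.infinite(v)) {
      if (v > 0) "Inf" else "-Inf"
    } else sprintf("%.17g", v)
  }, character(1))
  out
}

write_lr_table <- function(tab, path) {
  out <- data.table(lo = fmt_dbl(tab$lo), hi = fmt_dbl(tab$hi),
                    tp = tab$tp, fp = tab$fp, lr = fmt_dbl(tab$lr))
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

read_lr_table <- function(path, n_pos, n_neg, smoothing, evidence_type) {
  raw <- fread(path, sep = "\t",
               colClasses = list(character = c("lo", "hi", "lr")))
  tab <- data.table(lo = as.numeric(raw$lo), hi = as.numeric(raw$hi),
                    tp = as.integer(raw$tp), fp = as.integer(raw$fp),
                    lr = as.numeric(raw$lr))
  setattr(tab, "edges", c(tab$lo, Inf))
  setattr(tab, "n_pos", n_pos)
  setattr(tab, "n_neg", n_neg)
  setattr(tab, "smoothing", smoothing)
  setattr(tab, "evidence_type", evidence_type)
  setattr(tab, "class", c("esi_lr_table", class(tab)))
  tab[]
}

write_enrichment_table <- function(tab, path) {
  out <- data.table(label_e3 = tab$label_e3, label_sub = tab$label_sub,
                    ratio = fmt_dbl(tab$ratio), support = tab$support)
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

read_enrichment_table <- function(path, namespace) {
  raw <- fread(path, sep = "\t", colClasses = list(character = "ratio"))
  tab <- data.table(label_e3 = as.character(raw$label_e3),
                    label_sub = as.character(raw$label_sub),
                    ratio = as.numeric(raw$ratio),
                    support = as.integer(raw$support))
  setattr(tab, "namespace", namespace)
  setattr(tab, "class", c("esi_enrichment", class(tab)))
  tab[]
}

MODEL_SCHEMA_VERSION <- "1"

#' Save a trained model to a directory archive
#'
#' Writes a versioned, human-readable archive: `schema.json` (version,
#' configuration, prior, training fingerprint) plus one TSV per evidence
#' table. [load_model()] restores an object that re-scores pairs
#' bit-identically.
#'
#' @param model trained `esi_model`.
#' @param dir target directory (created if missing).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- model$config
  meta <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    fingerprint = model$fingerprint,
    n_pos = model$n_pos, n_neg = model$n_neg,
    prior = model$prior[c("p_positive", "o_prior")],
    train_e3s = model$train_e3s,
    train_pos_keys = model$train_pos_keys,
    config = unclass(cfg)
  )
  jsonlite::write_json(meta, file.path(dir, "schema.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  write_enrichment_table(model$domain$table,
                         file.path(dir, "enriched_domain.tsv"))
  write_enrichment_table(model$go$table, file.path(dir, "enriched_go.tsv"))
  write_lr_table(model$domain$lr, file.path(dir, "lr_domain.tsv"))
  write_lr_table(model$go$lr, file.path(dir, "lr_go.tsv"))
  write_lr_table(model$lr_n3, file.path(dir, "lr_network_n3.tsv"))
  write_lr_table(model$lr_n4, file.path(dir, "lr_network_n4.tsv"))
  write_lr_table(model$homology, file.path(dir, "lr_homology.tsv"))
  write_lr_table(model$lr_motif, file.path(dir, "lr_motif.tsv"))
  mtab <- motifs_to_table(model$motifs)
  mtab[, motif_score := fmt_dbl(motif_score)]
  fwrite(mtab, file.path(dir, "motifs.tsv"), sep = "\t", quote = FALSE)
  invisible(dir)
}

#' Load a model archive written by [save_model()]
#' @param dir archive directory.
#' @return an `esi_model`.
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "schema.json"),
                              simplifyVector = TRUE)
  if (!identical(as.character(meta$schema_version), MODEL_SCHEMA_VERSION)) {
    stop("unsupported model schema version: ", meta$schema_version)
  }
  cfg_raw <- meta$config
  cfg <- do.call(esi_config, cfg_raw[!vapply(cfg_raw, is.null, TRUE)])
  n_pos <- as.integer(meta$n_pos)
  n_neg <- as.integer(meta$n_neg)
  s <- cfg$smoothing
  rd <- function(name, ty) {
    read_lr_table(file.path(dir, name), n_pos, n_neg, s, ty)
  }
  mtab_raw <- fread(file.path(dir, "motifs.tsv"), sep = "\t",
                    colClasses = list(character = c("motif_score")))
  if (nrow(mtab_raw)) {
    mtab_raw[, motif_score := as.numeric(motif_score)]
    mtab_raw[, pattern := as.character(pattern)]
    mtab_raw[, e3 := as.character(e3)]
  }
  motifs <- if (nrow(mtab_raw)) table_to_motifs(mtab_raw) else list()
  structure(list(
    prior = list(p_positive = meta$prior$p_positive,
                 o_prior = meta$prior$o_prior,
                 o_post = meta$prior$o_prior),
    n_pos = n_pos, n_neg = n_neg,
    domain = list(table = read_enrichment_table(
                    file.path(dir, "enriched_domain.tsv"), "domain"),
                  lr = rd("lr_domain.tsv", "domain")),
    go = list(table = read_enrichment_table(
                file.path(dir, "enriched_go.tsv"), "go"),
              lr = rd("lr_go.tsv", "go")),
    lr_n3 = rd("lr_network_n3.tsv", "network_n3"),
    lr_n4 = rd("lr_network_n4.tsv", "network_n4"),
    homology = rd("lr_homology.tsv", "homology"),
    motifs = motifs, lr_motif = rd("lr_motif.tsv", "motif"),
    config = cfg,
    fingerprint = meta$fingerprint,
    train_e3s = as.character(meta$train_e3s),
    train_pos_keys = as.character(meta$train_pos_keys)
  ), class = "esi_model")
}
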