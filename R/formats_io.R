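# Readers and writers for the delimited-text formats every other module
# consumes: detection tables (search-engine export at the protein level),
# predictor-call matrices, reference-evidence tables, FASTA proteomes, and
# the final compendium. The dialect is tab-separated UTF-8 with one header
# row; a missing (protein, sample) row means "not detected", because search
# engines do not export non-detections.

# ---- TSV dialect -----------------------------------------------------------

read_tsv_file <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  utils::read.delim(path, sep = "\t", header = TRUE, na.strings = "NA",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "#", fileEncoding = "UTF-8")
}

write_tsv_file <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, na = "NA",
                       row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) abort("cannot write %s: %s", path, conditionMessage(ok))
  invisible(path)
}

# ---- detection table -------------------------------------------------------

#' Default column schema for detection-table files
#'
#' Maps the fields the package needs onto the column names present in a
#' delimited export. Exports from different search engines name their columns
#' differently; pass a modified schema to [read_detection_table()] to adapt.
#'
#' @return named list of column names.
#' @export
detection_schema <- function() {
  list(protein_id = "protein_id", sample_id = "sample_id",
       prep_type = "prep_type", psm_count = "psm_count",
       peptide_ids = "peptide_ids",
       unique_peptide_count = "unique_peptide_count")
}

#' Construct a detection table
#'
#' A detection table holds per-(protein, sample) spectral evidence: PSM
#' counts, peptide identities (or a unique-peptide count when identities are
#' unavailable), and the preparation type of every sample (acetone
#' precipitation or gel extraction).
#'
#' @param entries data.frame with columns `protein_id`, `sample_id`,
#'   `psm_count`, `unique_peptide_count`, and optionally a list column
#'   `peptide_ids` of character vectors.
#' @param samples data.frame with columns `sample_id`, `prep_type`
#'   (`"acetone"` or `"gel"`).
#' @return object of class `detection_table`.
#' @export
detection_table <- function(entries, samples) {
  require_columns(entries, c("protein_id", "sample_id", "psm_count",
                             "unique_peptide_count"), "detection entries")
  require_columns(samples, c("sample_id", "prep_type"), "sample sheet")
  if (!all(samples$prep_type %in% c("acetone", "gel"))) {
    abort("prep_type must be 'acetone' or 'gel'")
  }
  require_unique(samples$sample_id, "sample_id in sample sheet")
  if (any(is.na(entries$psm_count)) || any(entries$psm_count < 0)) {
    abort("psm_count must be a non-negative integer")
  }
  if (any(entries$unique_peptide_count < 0, na.rm = TRUE)) {
    abort("unique_peptide_count must be non-negative")
  }
  bad <- entries$psm_count < entries$unique_peptide_count
  if (any(bad, na.rm = TRUE)) {
    abort("psm_count < unique_peptide_count for protein(s): %s",
          paste(unique(entries$protein_id[which(bad)]), collapse = ", "))
  }
  unknown <- setdiff(unique(entries$sample_id), samples$sample_id)
  if (length(unknown) > 0L) {
    abort("entries reference sample(s) absent from the sample sheet: %s",
          paste(unknown, collapse = ", "))
  }
  require_unique(paste(entries$protein_id, entries$sample_id, sep = "\r"),
                 "(protein_id, sample_id) pair")
  if (is.null(entries$peptide_ids)) entries$peptide_ids <- rep(list(NULL), nrow(entries))
  structure(list(entries = entries, samples = samples),
            class = "detection_table")
}

#' @export
print.detection_table <- function(x, ...) {
  cat(sprintf("detection_table: %d entries, %d proteins, %d samples (%d acetone + %d gel)\n",
              nrow(x$entries), length(unique(x$entries$protein_id)),
              nrow(x$samples), sum(x$samples$prep_type == "acetone"),
              sum(x$samples$prep_type == "gel")))
  invisible(x)
}

#' Read a detection table from a delimited file
#'
#' Expects one row per (protein, sample) with a positive PSM count; proteins
#' absent from a sample are treated as not detected there. The `peptide_ids`
#' column, when present, holds semicolon-joined peptide sequences.
#'
#' @param path file path.
#' @param schema column-name mapping, see [detection_schema()].
#' @return a [detection_table()].
#' @export
read_detection_table <- function(path, schema = detection_schema()) {
  df <- read_tsv_file(path)
  need <- c(schema$protein_id, schema$sample_id, schema$prep_type,
            schema$psm_count)
  require_columns(df, need, sprintf("detection table %s", path))
  has_pep <- schema$peptide_ids %in% names(df)
  has_cnt <- schema$unique_peptide_count %in% names(df)
  if (!has_pep && !has_cnt) {
    abort("detection table needs either a '%s' or a '%s' column",
          schema$peptide_ids, schema$unique_peptide_count)
  }
  pep <- if (has_pep) {
    lapply(df[[schema$peptide_ids]], function(s) {
      if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ";", fixed = TRUE)[[1]]
    })
  } else {
    rep(list(NULL), nrow(df))
  }
  upc <- if (has_cnt) as.integer(df[[schema$unique_peptide_count]])
         else vapply(pep, function(p) length(unique(p)), integer(1))
  entries <- data.frame(protein_id = as.character(df[[schema$protein_id]]),
                        sample_id = as.character(df[[schema$sample_id]]),
                        psm_count = as.integer(df[[schema$psm_count]]),
                        unique_peptide_count = upc,
                        stringsAsFactors = FALSE)
  entries$peptide_ids <- pep
  samples <- unique(data.frame(sample_id = as.character(df[[schema$sample_id]]),
                               prep_type = as.character(df[[schema$prep_type]]),
                               stringsAsFactors = FALSE))
  require_unique(samples$sample_id, "sample_id (conflicting prep_type)")
  detection_table(entries, samples)
}

#' Write a detection table to a delimited file
#'
#' Inverse of [read_detection_table()]: write-then-read is the identity.
#'
#' @param x a [detection_table()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_detection_table <- function(x, path) {
  stopifnot(inherits(x, "detection_table"))
  e <- x$entries
  df <- data.frame(protein_id = e$protein_id, sample_id = e$sample_id,
                   prep_type = x$samples$prep_type[match(e$sample_id, x$samples$sample_id)],
                   psm_count = e$psm_count,
                   unique_peptide_count = e$unique_peptide_count,
                   peptide_ids = vapply(e$peptide_ids, function(p) {
                     if (is.null(p) || length(p) == 0L) "" else paste(p, collapse = ";")
                   }, character(1)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$protein_id, df$sample_id), , drop = FALSE]
  write_tsv_file(df, path)
}

# ---- prediction matrix -----------------------------------------------------

#' Default predictor slot configuration
#'
#' Five subcellular-localization predictors, three transmembrane predictors
#' and two lumenal-transit-peptide predictors, named after the tools whose
#' calls the matrix records. Slot names are configuration, not behaviour:
#' any names may be supplied as long as the three groups are distinguished.
#'
#' @return named list with character vectors `loc`, `tm`, `lumen`.
#' @export
predictor_slots <- function() {
  list(loc = c("targetp", "chlorop", "wolfpsort", "yloc", "predotar"),
       tm = c("tmpred", "deeptmhmm", "cctop"),
       lumen = c("predsl", "targetp2"))
}

#' Construct a prediction matrix
#'
#' Per-protein predictor calls: logical plastid-localization calls (one
#' column per localization slot, prefixed `loc_`), integer transmembrane
#' segment counts (`tm_`), and logical lumenal-transit-peptide calls
#' (`lum_`). `NA` means the predictor made no call, which is distinct from a
#' negative call and is never silently coerced.
#'
#' @param df data.frame with `protein_id` plus the slot columns.
#' @param slots slot configuration, see [predictor_slots()].
#' @return object of class `prediction_matrix` (a data.frame).
#' @export
prediction_matrix <- function(df, slots = predictor_slots()) {
  cols <- c("protein_id", paste0("loc_", slots$loc), paste0("tm_", slots$tm),
            paste0("lum_", slots$lumen))
  require_columns(df, cols, "prediction matrix")
  require_unique(df$protein_id, "protein_id in prediction matrix")
  for (cl in paste0("loc_", slots$loc)) df[[cl]] <- as.logical(df[[cl]])
  for (cl in paste0("tm_", slots$tm)) {
    df[[cl]] <- as.integer(df[[cl]])
    if (any(df[[cl]] < 0, na.rm = TRUE)) abort("negative TM segment count in %s", cl)
  }
  for (cl in paste0("lum_", slots$lumen)) df[[cl]] <- as.logical(df[[cl]])
  structure(df[, cols, drop = FALSE], slots = slots,
            class = c("prediction_matrix", "data.frame"))
}

#' Read a prediction matrix from a delimited file
#' @param path file path.
#' @param slots slot configuration, see [predictor_slots()].
#' @return a [prediction_matrix()].
#' @export
read_prediction_matrix <- function(path, slots = predictor_slots()) {
  prediction_matrix(read_tsv_file(path), slots)
}

#' Write a prediction matrix to a delimited file
#' @param x a [prediction_matrix()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_prediction_matrix <- function(x, path) {
  write_tsv_file(as.data.frame(x)[order(x$protein_id), , drop = FALSE], path)
}

# ---- evidence table --------------------------------------------------------

#' Reference-database evidence slot names
#' @return character vector of chloroplast-empirical database slots.
#' @export
evidence_slots <- function() c("chl_ppdb", "chl_suba4", "chl_plprot")

#' Construct an evidence table
#'
#' Per-protein reference-database flags: chloroplast-empirical evidence (one
#' logical column per database slot), a literature flag, an
#' other-compartment-empirical flag, a lumen-specific empirical flag, and an
#' optional semicolon-joined list of reference-proteome ortholog identifiers.
#' Flags are never missing; absent values default to `FALSE`.
#'
#' @param df data.frame with `protein_id` plus the evidence columns.
#' @param slots chloroplast-empirical slot names, see [evidence_slots()].
#' @return object of class `evidence_table` (a data.frame) with a list column
#'   `ortholog_ids`.
#' @export
evidence_table <- function(df, slots = evidence_slots()) {
  require_columns(df, "protein_id", "evidence table")
  require_unique(df$protein_id, "protein_id in evidence table")
  flags <- c(slots, "literature_chloroplast", "other_compartment_empirical",
             "lumen_empirical")
  for (cl in flags) {
    v <- if (cl %in% names(df)) as.logical(df[[cl]]) else logical(nrow(df))
    v[is.na(v)] <- FALSE
    df[[cl]] <- v
  }
  df$ortholog_ids <- if (is.null(df$ortholog_ids)) {
    rep(list(character(0)), nrow(df))
  } else if (is.list(df$ortholog_ids)) {
    df$ortholog_ids
  } else {
    lapply(df$ortholog_ids, function(s) {
      if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ";", fixed = TRUE)[[1]]
    })
  }
  structure(df[, c("protein_id", flags, "ortholog_ids"), drop = FALSE],
            slots = slots, class = c("evidence_table", "data.frame"))
}

#' Read an evidence table from a delimited file
#' @param path file path.
#' @param slots chloroplast-empirical slot names, see [evidence_slots()].
#' @return an [evidence_table()].
#' @export
read_evidence_table <- function(path, slots = evidence_slots()) {
  evidence_table(read_tsv_file(path), slots)
}

#' Write an evidence table to a delimited file
#' @param x an [evidence_table()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_evidence_table <- function(x, path) {
  df <- as.data.frame(x)
  df$ortholog_ids <- vapply(df$ortholog_ids, function(o) {
    if (length(o) == 0L) "" else paste(o, collapse = ";")
  }, character(1))
  write_tsv_file(df[order(df$protein_id), , drop = FALSE], path)
}

# ---- FASTA proteome --------------------------------------------------------

#' Read a proteome from a FASTA file
#'
#' The protein identifier is the first whitespace-delimited token of the
#' header; the remainder of the header is kept as the annotation. Sequences
#' may contain the 20 standard residues plus X.
#'
#' @param path FASTA file path.
#' @param genome_source `"nuclear"` or `"plastid"`, recorded on every record.
#' @return data.frame with columns `protein_id`, `genome_source`, `sequence`,
#'   `annotation`.
#' @export
read_fasta_proteome <- function(path, genome_source = "nuclear") {
  if (!file.exists(path)) abort("file not found: %s", path)
  genome_source <- match.arg(genome_source, c("nuclear", "plastid"))
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) {
    warning("empty FASTA file: ", path)
    return(data.frame(protein_id = character(0), genome_source = character(0),
                      sequence = character(0), annotation = character(0),
                      stringsAsFactors = FALSE))
  }
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  ann <- trimws(sub("^\\S+\\s*", "", headers))
  require_unique(ids, "FASTA identifier")
  data.frame(protein_id = ids, genome_source = genome_source,
             sequence = as.character(aa), annotation = ann,
             stringsAsFactors = FALSE)
}

# ---- compendium ------------------------------------------------------------

#' Write the compendium table
#'
#' Serializes the joined per-protein results as tab-separated text with a
#' stable column order and rows sorted by `protein_id`, so repeated runs
#' produce byte-identical files.
#'
#' @param rows data.frame of per-protein results (must share a column set).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_compendium <- function(rows, path) {
  if (!is.data.frame(rows)) abort("compendium rows must be a data.frame")
  if (nrow(rows) > 0L && "protein_id" %in% names(rows)) {
    rows <- rows[order(rows$protein_id), , drop = FALSE]
  }
  write_tsv_file(rows, path)
}

#' Read a compendium table written by [write_compendium()]
#' @param path file path.
#' @return data.frame.
#' @export
read_compendium <- function(path) read_tsv_file(path)
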