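# Sub-organellar assignment within the curated stromal set: membrane calls by
# consensus of transmembrane predictors, lumen calls by agreement of both
# lumenal-transit-peptide predictors or by lumen-specific empirical evidence.

#' Membrane call by transmembrane-predictor consensus
#'
#' Each TM predictor votes when it reports at least one transmembrane
#' segment; `membrane` is true when at least `consensus_k` of the slots vote
#' (default majority, 2 of 3). A missing count (`NA`) is treated as zero
#' segments but tracked in `n_missing_tm`.
#'
#' @param matrix a [prediction_matrix()].
#' @param consensus_k minimum voting slots, default 2.
#' @return data.frame with `protein_id`, `tm_votes`, `max_tm_segments`,
#'   `n_missing_tm`, `membrane`.
#' @export
call_membrane <- function(matrix, consensus_k = 2L) {
  stopifnot(inherits(matrix, "prediction_matrix"))
  slots <- attr(matrix, "slots")
  if (consensus_k < 1 || consensus_k > length(slots$tm)) {
    abort("consensus_k must be between 1 and %d", length(slots$tm))
  }
  tm <- as.matrix(matrix[, paste0("tm_", slots$tm), drop = FALSE])
  votes <- rowSums(tm >= 1L, na.rm = TRUE)
  max_seg <- apply(tm, 1L, function(v) if (all(is.na(v))) 0L else max(v, na.rm = TRUE))
  data.frame(protein_id = matrix$protein_id,
             tm_votes = as.integer(votes),
             max_tm_segments = as.integer(max_seg),
             n_missing_tm = as.integer(rowSums(is.na(tm))),
             membrane = votes >= consensus_k,
             stringsAsFactors = FALSE)
}

#' Lumen call from transit-peptide predictors and empirical evidence
#'
#' A protein is lumenal when both lumenal-transit-peptide predictors call it
#' (basis `both_predictors`) or lumen-specific empirical evidence exists
#' (basis `empirical`; empirical takes precedence in the reported basis).
#'
#' @param matrix a [prediction_matrix()].
#' @param evidence an [evidence_table()] with the `lumen_empirical` flag.
#' @return data.frame with `protein_id`, `lumenal`, `lumenal_basis`
#'   (`"empirical"`, `"both_predictors"`, or `"none"`).
#' @export
call_lumenal <- function(matrix, evidence) {
  stopifnot(inherits(matrix, "prediction_matrix"))
  slots <- attr(matrix, "slots")
  lum <- as.matrix(matrix[, paste0("lum_", slots$lumen), drop = FALSE])
  both <- rowSums(lum, na.rm = TRUE) == ncol(lum)  # NA call is not agreement
  emp <- lookup_evidence(matrix$protein_id, evidence)$lumen_empirical
  basis <- ifelse(emp, "empirical", ifelse(both, "both_predictors", "none"))
  data.frame(protein_id = matrix$protein_id, lumenal = emp | both,
             lumenal_basis = basis, stringsAsFactors = FALSE)
}

#' Combined compartment calls
#'
#' Joins membrane and lumen calls (a protein may carry both) with the
#' sporadic-detection flag from the curation statistics.
#'
#' @param matrix a [prediction_matrix()].
#' @param evidence an [evidence_table()].
#' @param curation optional [curate()] result supplying the sporadic flag.
#' @param consensus_k membrane consensus threshold, default 2.
#' @return data.frame with one row per protein in `matrix`.
#' @export
compartment_calls <- function(matrix, evidence, curation = NULL,
                              consensus_k = 2L) {
  mem <- call_membrane(matrix, consensus_k)
  lum <- call_lumenal(matrix, evidence)
  out <- merge(mem, lum, by = "protein_id", sort = TRUE)
  out$sporadic_flag <- FALSE
  if (!is.null(curation)) {
    res <- curation$result
    spor <- vapply(strsplit(res$reason_codes, ";", fixed = TRUE),
                   function(v) "SPORADIC" %in% v, logical(1))
    out$sporadic_flag <- spor[match(out$protein_id, res$protein_id)]
    out$sporadic_flag[is.na(out$sporadic_flag)] <- FALSE
  }
  out
}

#' Compartment count and mass summary
#'
#' For the membrane and lumen compartments within a stromal protein set,
#' reports the protein count, the count as a percentage of the stromal set,
#' the summed mol % (mass), and the refined membrane count/fraction after
#' excluding sporadically detected proteins. A protein called both membrane
#' and lumenal contributes to both compartments.
#'
#' @param calls a [compartment_calls()] result.
#' @param abundance a [quantify_abundance()] result (proteins without an
#'   abundance record contribute zero mass).
#' @param stromal_ids character vector defining the stromal set summarized.
#' @param digits decimals for the percentage rounding, default 1.
#' @return data.frame with one row per reported compartment.
#' @export
compartment_summary <- function(calls, abundance, stromal_ids, digits = 1) {
  n <- length(stromal_ids)
  if (n == 0L) abort("empty stromal set")
  calls <- calls[calls$protein_id %in% stromal_ids, , drop = FALSE]
  mp <- function(ids) {
    m <- abundance$mol_percent[match(ids, abundance$protein_id)]
    sum(m, na.rm = TRUE)
  }
  mem_ids <- calls$protein_id[calls$membrane]
  mem_rep <- calls$protein_id[calls$membrane & !calls$sporadic_flag]
  lum_ids <- calls$protein_id[calls$lumenal]
  row <- function(name, ids) {
    data.frame(compartment = name, n_proteins = length(ids),
               count_percent = count_fraction(length(ids), n, digits),
               mass_mol_percent = mp(ids), stringsAsFactors = FALSE)
  }
  rbind(row("membrane", mem_ids),
        row("membrane_reproducible", mem_rep),
        row("lumen", lum_ids))
}
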