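# Inclusion/exclusion of detected proteins and the stromal-vs-CIP partition.
#
# A detected protein is flagged for removal when it was detected once with a
# single PSM, identified by a single unique peptide overall, or detected
# sporadically (in fewer than 40% of the samples of each preparation type).
# Flagged proteins are nevertheless retained when there is empirical
# chloroplast evidence (reference databases or literature) or the Atlas calls
# them plastid with at least `vote_threshold` predictors. Retained proteins
# whose only evidence places them in another compartment are classified as
# co-isolating proteins (CIPs); chloroplast evidence takes precedence.

REASON_CODES <- c("SINGLETON_PSM", "SINGLE_PEPTIDE", "SPORADIC",
                  "EXC_DB_EVIDENCE", "EXC_LITERATURE", "EXC_ATLAS_VOTES",
                  "CIP_OTHER_COMPARTMENT", "OK_REPRODUCIBLE")

#' Per-protein detection statistics
#'
#' Summarizes a detection table per protein: samples detected per preparation
#' type, detection frequencies per type, total PSMs, total unique peptides
#' (distinct peptide sequences pooled across all samples; when identities are
#' unavailable, the maximum per-sample unique-peptide count), and whether the
#' protein was detected exactly once with a single PSM. A preparation type
#' with no samples in the dataset yields an `NA` frequency (undefined, not
#' zero). Proteins with no detections get no row.
#'
#' @param table a [detection_table()].
#' @return data.frame with one row per detected protein.
#' @export
detection_stats <- function(table) {
  stopifnot(inherits(table, "detection_table"))
  n_acetone <- sum(table$samples$prep_type == "acetone")
  n_gel <- sum(table$samples$prep_type == "gel")
  e <- table$entries[table$entries$psm_count > 0, , drop = FALSE]
  if (nrow(e) == 0L) {
    return(data.frame(protein_id = character(0),
                      n_samples_detected_acetone = integer(0),
                      n_samples_detected_gel = integer(0),
                      total_psm = integer(0), total_unique_peptides = integer(0),
                      detected_once_with_one_psm = logical(0),
                      frequency_acetone = numeric(0), frequency_gel = numeric(0),
                      stringsAsFactors = FALSE))
  }
  prep <- table$samples$prep_type[match(e$sample_id, table$samples$sample_id)]
  ids <- sort(unique(e$protein_id))
  has_identities <- any(vapply(e$peptide_ids, function(p) length(p) > 0L, logical(1)))
  rows <- lapply(ids, function(id) {
    sel <- e$protein_id == id
    det_ace <- sum(prep[sel] == "acetone")
    det_gel <- sum(prep[sel] == "gel")
    total_psm <- sum(e$psm_count[sel])
    upep <- if (has_identities) {
      length(unique(unlist(e$peptide_ids[sel])))
    } else {
      max(e$unique_peptide_count[sel])
    }
    data.frame(protein_id = id,
               n_samples_detected_acetone = det_ace,
               n_samples_detected_gel = det_gel,
               total_psm = total_psm,
               total_unique_peptides = as.integer(upep),
               detected_once_with_one_psm = (det_ace + det_gel) == 1L && total_psm == 1L,
               frequency_acetone = if (n_acetone > 0) det_ace / n_acetone else NA_real_,
               frequency_gel = if (n_gel > 0) det_gel / n_gel else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Evidence-based exclusion rule
#'
#' Flags a protein for removal when it was detected once with one PSM, has a
#' single unique peptide in total, or is sporadic. Sporadic means a detection
#' frequency below `sporadic_threshold` in every preparation type for which
#' the dataset has samples: reproducible detection in acetone or in gel
#' samples alone suffices to escape the flag, and a frequency exactly at the
#' threshold passes (the criterion is strict "less than").
#'
#' @param stats one row (or several) of [detection_stats()].
#' @param sporadic_threshold frequency threshold, default 0.40.
#' @return data.frame with `protein_id`, logical `flagged`, and `codes`
#'   (semicolon-joined subset of SINGLETON_PSM, SINGLE_PEPTIDE, SPORADIC).
#' @export
apply_exclusion_rule <- function(stats, sporadic_threshold = 0.40) {
  require_columns(stats, c("protein_id", "detected_once_with_one_psm",
                           "total_unique_peptides", "frequency_acetone",
                           "frequency_gel"), "detection stats")
  singleton <- stats$detected_once_with_one_psm
  single_pep <- stats$total_unique_peptides == 1L
  freqs <- cbind(stats$frequency_acetone, stats$frequency_gel)
  sporadic <- apply(freqs, 1L, function(f) {
    f <- f[!is.na(f)]
    length(f) > 0L && all(f < sporadic_threshold)
  })
  codes <- mapply(function(a, b, c3) {
    paste(c("SINGLETON_PSM", "SINGLE_PEPTIDE", "SPORADIC")[c(a, b, c3)],
          collapse = ";")
  }, singleton, single_pep, sporadic)
  data.frame(protein_id = stats$protein_id,
             flagged = singleton | single_pep | sporadic,
             codes = unname(codes), stringsAsFactors = FALSE)
}

#' Retention exceptions for flagged proteins
#'
#' A protein flagged by the exclusion rule is retained anyway when any
#' chloroplast-empirical database slot is true, the literature flag is true,
#' or the Atlas vote count is at least `vote_threshold`.
#'
#' @param flagged result of [apply_exclusion_rule()] (only its flagged rows
#'   are re-examined; unflagged rows are retained unconditionally).
#' @param evidence an [evidence_table()].
#' @param atlas a [build_atlas()] result.
#' @param vote_threshold minimum predictor votes for retention, default 2.
#' @return data.frame with `protein_id`, logical `retained`, and `codes`
#'   (exclusion codes plus any exception code, semicolon-joined).
#' @export
apply_retention_exceptions <- function(flagged, evidence, atlas,
                                       vote_threshold = 2L) {
  require_columns(flagged, c("protein_id", "flagged", "codes"), "flag table")
  ev <- lookup_evidence(flagged$protein_id, evidence)
  votes <- lookup_votes(flagged$protein_id, atlas)
  db <- ev$any_chloroplast_db
  lit <- ev$literature_chloroplast
  atl <- votes >= vote_threshold
  retained <- !flagged$flagged | db | lit | atl
  codes <- flagged$codes
  add <- function(codes, sel, code) ifelse(sel, paste(codes, code, sep = ";"), codes)
  sel <- flagged$flagged
  codes <- add(codes, sel & db, "EXC_DB_EVIDENCE")
  codes <- add(codes, sel & lit, "EXC_LITERATURE")
  codes <- add(codes, sel & atl, "EXC_ATLAS_VOTES")
  data.frame(protein_id = flagged$protein_id, retained = retained,
             codes = sub("^;", "", codes), stringsAsFactors = FALSE)
}

#' Stromal versus co-isolating classification of retained proteins
#'
#' A retained protein is a CIP when empirical evidence places it in another
#' compartment, no chloroplast-empirical slot is true, the literature flag is
#' false, and the Atlas vote count is below `cip_vote_threshold`; otherwise
#' it is stromal. Chloroplast evidence therefore takes precedence over
#' other-compartment evidence.
#'
#' @param protein_ids character vector of retained proteins.
#' @param evidence an [evidence_table()].
#' @param atlas a [build_atlas()] result.
#' @param cip_vote_threshold votes at or above which prediction alone keeps a
#'   protein stromal, default 2.
#' @return data.frame with `protein_id`, `status` (`"stromal"` or `"CIP"`).
#' @export
classify_stromal_cip <- function(protein_ids, evidence, atlas,
                                 cip_vote_threshold = 2L) {
  ev <- lookup_evidence(protein_ids, evidence)
  votes <- lookup_votes(protein_ids, atlas)
  cip <- ev$other_compartment_empirical & !ev$any_chloroplast_db &
    !ev$literature_chloroplast & votes < cip_vote_threshold
  data.frame(protein_id = protein_ids,
             status = ifelse(cip, "CIP", "stromal"),
             stringsAsFactors = FALSE)
}

#' Curate a detected proteome
#'
#' Runs the full inclusion/exclusion and classification procedure: detection
#' statistics, the exclusion rule, retention exceptions, and the stromal/CIP
#' partition. Every detected protein receives exactly one status among
#' `stromal`, `CIP`, `removed`, with machine-readable reason codes. Proteins
#' detected but absent from the evidence table or Atlas are treated as
#' all-negative, with a warning.
#'
#' @param table a [detection_table()].
#' @param evidence an [evidence_table()].
#' @param atlas a [build_atlas()] result.
#' @param vote_threshold retention-exception vote threshold, default 2.
#' @param cip_vote_threshold CIP-rule vote threshold, default 2.
#' @param sporadic_threshold sporadic-detection frequency threshold, 0.40.
#' @return list of class `curation_result`: `result` (per-protein data.frame
#'   with `status`, `reason_codes` and all intermediate statistics) and
#'   `summary` (counts per status and per reason code).
#' @export
curate <- function(table, evidence, atlas, vote_threshold = 2L,
                   cip_vote_threshold = 2L, sporadic_threshold = 0.40) {
  stats <- detection_stats(table)
  if (nrow(stats) == 0L) abort("no detected proteins to curate")
  missing_ev <- setdiff(stats$protein_id, evidence$protein_id)
  missing_atl <- setdiff(stats$protein_id, atlas$protein_id)
  if (length(missing_ev) > 0L || length(missing_atl) > 0L) {
    warning(sprintf("%d detected protein(s) missing from evidence/Atlas; treated as all-negative",
                    length(union(missing_ev, missing_atl))))
  }
  flags <- apply_exclusion_rule(stats, sporadic_threshold)
  ret <- apply_retention_exceptions(flags, evidence, atlas, vote_threshold)
  status <- rep("removed", nrow(stats))
  codes <- ret$codes
  kept <- ret$retained
  if (any(kept)) {
    cls <- classify_stromal_cip(ret$protein_id[kept], evidence, atlas,
                                cip_vote_threshold)
    status[kept] <- cls$status
    codes[kept] <- ifelse(
      status[kept] == "CIP",
      paste_codes(codes[kept], "CIP_OTHER_COMPARTMENT"),
      ifelse(flags$flagged[kept], codes[kept],
             paste_codes(codes[kept], "OK_REPRODUCIBLE")))
  }
  result <- cbind(stats,
                  data.frame(flagged = flags$flagged, retained = ret$retained,
                             status = status, reason_codes = codes,
                             stringsAsFactors = FALSE))
  counts <- table(factor(result$status, levels = c("stromal", "CIP", "removed")))
  code_counts <- vapply(REASON_CODES, function(cd) {
    sum(vapply(strsplit(result$reason_codes, ";", fixed = TRUE),
               function(v) cd %in% v, logical(1)))
  }, integer(1))
  summary <- list(n_detected = nrow(result),
                  n_stromal = unname(counts[["stromal"]]),
                  n_cip = unname(counts[["CIP"]]),
                  n_removed = unname(counts[["removed"]]),
                  reason_code_counts = code_counts)
  structure(list(result = result, summary = summary), class = "curation_result")
}

#' @export
print.curation_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("curation: %d detected = %d stromal + %d CIP + %d removed\n",
              s$n_detected, s$n_stromal, s$n_cip, s$n_removed))
  invisible(x)
}

paste_codes <- function(codes, new) ifelse(nzchar(codes), paste(codes, new, sep = ";"), new)

# Internal: per-protein evidence flags, all-negative when absent.
lookup_evidence <- function(ids, evidence) {
  stopifnot(inherits(evidence, "evidence_table"))
  slots <- attr(evidence, "slots")
  idx <- match(ids, evidence$protein_id)
  get <- function(col) {
    v <- evidence[[col]][idx]
    v[is.na(v)] <- FALSE
    v
  }
  db <- Reduce(`|`, lapply(slots, get))
  list(any_chloroplast_db = db,
       literature_chloroplast = get("literature_chloroplast"),
       other_compartment_empirical = get("other_compartment_empirical"),
       lumen_empirical = get("lumen_empirical"))
}

# Internal: Atlas vote counts, 0 when absent.
lookup_votes <- function(ids, atlas) {
  stopifnot(inherits(atlas, "atlas"))
  v <- atlas$vote_count[match(ids, atlas$protein_id)]
  v[is.na(v)] <- 0L
  v
}
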