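#' Run the full curation-and-quantification pipeline
#'
#' Chains the pipeline stages on parsed inputs: builds the localization Atlas,
#' curates the detected proteins into stromal / CIP / removed, quantifies
#' relative abundance by emPAI from the acetone samples, assigns membrane and
#' lumen compartment calls, and assembles the per-protein compendium.
#'
#' @param detections a [detection_table()].
#' @param predictions a [prediction_matrix()] covering the proteome universe.
#' @param evidence an [evidence_table()].
#' @param proteome data.frame with `protein_id`, `sequence` (for the
#'   observable-peptide digest); optional if `observable_counts` given.
#' @param plastid_proteins optional data.frame of plastid-genome records with
#'   sequences (deduplicated here via [dedup_plastid_orfs()]).
#' @param digest a [digest_params()].
#' @param observable_counts optional named vector bypassing the digest.
#' @param vote_threshold,cip_vote_threshold,sporadic_threshold,consensus_k
#'   curation and compartment thresholds; see [curate()] and
#'   [call_membrane()].
#' @return list with `atlas`, `curation`, `abundance`, `compartments`,
#'   `compartment_summary`, `compendium`.
#' @export
run_stromal_pipeline <- function(detections, predictions, evidence,
                                 proteome = NULL, plastid_proteins = NULL,
                                 digest = digest_params(),
                                 observable_counts = NULL,
                                 vote_threshold = 2L, cip_vote_threshold = 2L,
                                 sporadic_threshold = 0.40, consensus_k = 2L) {
  plastid <- if (!is.null(plastid_proteins)) dedup_plastid_orfs(plastid_proteins)
  atlas <- build_atlas(predictions, plastid)
  curation <- curate(detections, evidence, atlas,
                     vote_threshold = vote_threshold,
                     cip_vote_threshold = cip_vote_threshold,
                     sporadic_threshold = sporadic_threshold)
  abundance <- quantify_abundance(detections, proteome, params = digest,
                                  observable_counts = observable_counts)
  calls <- compartment_calls(predictions, evidence, curation, consensus_k)
  stromal_ids <- curation$result$protein_id[curation$result$status == "stromal"]
  comp_summary <- if (length(stromal_ids) > 0L) {
    compartment_summary(calls, abundance, stromal_ids)
  }
  compendium <- build_compendium(curation, abundance, calls, atlas, evidence)
  list(atlas = atlas, curation = curation, abundance = abundance,
       compartments = calls, compartment_summary = comp_summary,
       compendium = compendium)
}

#' Bundled tomato lumenal-protein reference table
#'
#' The curated table of thylakoid-lumen proteins detected in the tomato
#' stromal proteome, with peptide/PSM counts, emPAI, mol % and detection
#' frequency as printed in the study that assembled the compendium. Used by
#' the worked examples and the acceptance checks.
#'
#' @return data.frame with 58 rows.
#' @export
tomato_lumen_table <- function() {
  read_tsv_file(system.file("extdata", "tomato_lumenal_proteins.tsv",
                            package = "stromatlas", mustWork = TRUE))
}

#' Bundled top-110 tomato stromal abundance table
#'
#' The 110 most abundant proteins of the tomato stromal proteome with their
#' printed mol % values and abundance ranks.
#'
#' @return data.frame with 110 rows.
#' @export
tomato_top110_table <- function() {
  read_tsv_file(system.file("extdata", "tomato_top110_stromal.tsv",
                            package = "stromatlas", mustWork = TRUE))
}
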