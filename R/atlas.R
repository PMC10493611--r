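# The consensus localization Atlas: the theoretical plastid proteome built
# from the union of per-predictor plastid calls over the deduced proteome,
# plus the deduplicated plastid-genome protein complement. A nuclear protein
# enters the Atlas when at least one localization predictor calls it plastid;
# plastid-genome proteins are members regardless of predictor votes.

#' Deduplicate plastid-genome open reading frames
#'
#' The chloroplast genome's inverted repeat carries genes in two identical
#' copies that encode identical proteins; the Atlas keeps one protein per
#' distinct amino-acid sequence. Identity is exact sequence equality, and the
#' retained identifier is the lexicographically smallest among duplicates.
#'
#' @param orfs data.frame with columns `protein_id`, `sequence`,
#'   `genome_source` (all `"plastid"`).
#' @return data.frame with one row per distinct sequence, ordered by
#'   `protein_id`.
#' @export
dedup_plastid_orfs <- function(orfs) {
  require_columns(orfs, c("protein_id", "sequence", "genome_source"),
                  "plastid ORF set")
  if (nrow(orfs) == 0L) return(orfs)
  if (!all(orfs$genome_source == "plastid")) {
    abort("dedup_plastid_orfs expects only plastid-genome records")
  }
  if (any(is.na(orfs$sequence) | !nzchar(orfs$sequence))) {
    abort("plastid ORF records lack sequences; deduplication undefined")
  }
  orfs <- orfs[order(orfs$protein_id), , drop = FALSE]
  keep <- !duplicated(orfs$sequence)  # first (smallest id) per sequence
  out <- orfs[keep, , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Build the localization Atlas
#'
#' One entry per protein in the prediction-matrix universe. `vote_count` is
#' the number of localization slots with a positive call; a missing call
#' (`NA`) counts as negative for voting but is tracked in `n_missing_calls`
#' so reports can distinguish "no call" from "negative call". Plastid-genome
#' proteins are Atlas members regardless of votes and must already be
#' deduplicated.
#'
#' @param matrix a [prediction_matrix()] covering the proteome universe.
#' @param plastid_proteins optional data.frame of deduplicated plastid-genome
#'   records (`protein_id`); every id must be present in `matrix`.
#' @return data.frame of class `atlas` with columns `protein_id`,
#'   `vote_count`, `n_missing_calls`, `plastid_genome`, `in_atlas`; the slot
#'   configuration is kept in the `"slots"` attribute.
#' @export
build_atlas <- function(matrix, plastid_proteins = NULL) {
  stopifnot(inherits(matrix, "prediction_matrix"))
  slots <- attr(matrix, "slots")
  loc <- as.matrix(matrix[, paste0("loc_", slots$loc), drop = FALSE])
  votes <- rowSums(loc, na.rm = TRUE)
  n_missing <- rowSums(is.na(loc))
  plastid <- rep(FALSE, nrow(matrix))
  if (!is.null(plastid_proteins) && nrow(plastid_proteins) > 0L) {
    require_columns(plastid_proteins, "protein_id", "plastid protein list")
    absent <- setdiff(plastid_proteins$protein_id, matrix$protein_id)
    if (length(absent) > 0L) {
      abort("plastid-genome protein(s) absent from the proteome universe: %s",
            paste(absent, collapse = ", "))
    }
    plastid <- matrix$protein_id %in% plastid_proteins$protein_id
  }
  out <- data.frame(protein_id = matrix$protein_id,
                    vote_count = as.integer(votes),
                    n_missing_calls = as.integer(n_missing),
                    plastid_genome = plastid,
                    in_atlas = votes >= 1L | plastid,
                    stringsAsFactors = FALSE)
  structure(out, slots = slots, class = c("atlas", "data.frame"))
}

#' Consensus tier of the Atlas
#'
#' Nuclear-encoded entries called plastid by at least `k` localization
#' predictors. `k` equal to the number of slots yields the all-predictor
#' core; tiers are nested (`consensus_tier(a, k + 1)` is a subset of
#' `consensus_tier(a, k)`).
#'
#' @param atlas an [build_atlas()] result.
#' @param k integer, `0 <= k <=` number of localization slots.
#' @return subset of the Atlas rows.
#' @export
consensus_tier <- function(atlas, k) {
  stopifnot(inherits(atlas, "atlas"))
  n_slots <- length(attr(atlas, "slots")$loc)
  if (length(k) != 1L || is.na(k) || k < 0 || k > n_slots) {
    abort("k must be between 0 and %d", n_slots)
  }
  atlas[!atlas$plastid_genome & atlas$vote_count >= k, , drop = FALSE]
}

#' Atlas coverage of the proteome
#'
#' Percentage of the deduced proteome that the Atlas covers, rounded half
#' away from zero to `digits` decimals.
#'
#' @param atlas an [build_atlas()] result, or an integer member count.
#' @param proteome_size positive integer.
#' @param digits decimals for rounding (0 gives the integer percentage).
#' @return percentage.
#' @export
atlas_coverage_fraction <- function(atlas, proteome_size, digits = 0) {
  if (proteome_size <= 0) abort("proteome_size must be > 0")
  n <- if (inherits(atlas, "atlas")) sum(atlas$in_atlas) else as.numeric(atlas)
  round_half_up(100 * n / proteome_size, digits)
}
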