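# emPAI-based relative abundance. PAI is the ratio of observed to observable
# peptides per protein; emPAI = 10^PAI - 1 is proportional to molar amount,
# and a protein's mol % is its emPAI divided by the summed emPAI of the
# quantified set, times 100. Quantification uses the acetone-precipitated
# samples, pooling distinct peptide identities across replicates.

#' Protein abundance index and its exponential form
#'
#' `pai = n_observed / n_observable`; `empai = 10^pai - 1`. `n_observed` may
#' exceed `n_observable` (modified peptides match outside the theoretical
#' digest); this is permitted with a warning.
#'
#' @param n_observed integer vector, distinct observed peptides per protein.
#' @param n_observable integer vector (or scalar), observable peptides per
#'   protein; must be >= 1.
#' @return data.frame with columns `pai`, `empai`.
#' @export
#' @examples
#' compute_empai(10, 10)  # pai 1, empai 9
#' compute_empai(5, 10)   # empai 10^0.5 - 1
compute_empai <- function(n_observed, n_observable) {
  if (any(is.na(n_observable)) || any(n_observable < 1)) {
    abort("n_observable must be >= 1 for every protein")
  }
  if (any(n_observed < 0)) abort("n_observed must be non-negative")
  if (any(n_observed > n_observable)) {
    warning("n_observed exceeds n_observable for ",
            sum(n_observed > n_observable), " protein(s)")
  }
  pai <- n_observed / n_observable
  data.frame(pai = pai, empai = 10^pai - 1)
}

#' Mol percent from emPAI values
#'
#' `mol_percent_i = 100 * empai_i / sum(empai)` over the quantified set; the
#' result sums to 100 and is invariant under uniform scaling of the input.
#'
#' @param empai non-negative numeric vector with at least one positive value.
#' @return numeric vector of mol % values.
#' @export
compute_mol_percent <- function(empai) {
  if (any(is.na(empai)) || any(empai < 0)) abort("emPAI values must be non-negative")
  total <- sum(empai)
  if (total <= 0) abort("all emPAI values are zero; mol %% undefined")
  100 * empai / total
}

#' Mol percent against an externally calibrated total emPAI
#'
#' Used when the summed emPAI of the full quantified set is known (or
#' calibrated from a reference protein whose emPAI and mol % are both
#' reported) but the full set itself is not at hand:
#' `total_empai = empai_ref / (mol_percent_ref / 100)`.
#'
#' @param empai emPAI value(s) of the protein(s) of interest.
#' @param total_empai summed emPAI of the quantified set (> 0).
#' @param digits if non-NULL, round half away from zero to this many decimals.
#' @return mol % value(s).
#' @export
mol_percent_from_total <- function(empai, total_empai, digits = NULL) {
  if (!is.numeric(total_empai) || total_empai <= 0) abort("total_empai must be > 0")
  mp <- 100 * empai / total_empai
  if (!is.null(digits)) mp <- round_half_up(mp, digits)
  mp
}

#' Decade abundance classes
#'
#' Bins mol % into five decade classes with lower-inclusive boundaries:
#' class 1 = `[1, Inf)`, class 2 = `[0.1, 1)`, class 3 = `[0.01, 0.1)`,
#' class 4 = `[0.001, 0.01)`, class 5 = `[0, 0.001)`.
#'
#' @param mol_percent non-negative numeric vector.
#' @return integer vector of classes 1-5.
#' @export
assign_abundance_class <- function(mol_percent) {
  if (any(is.na(mol_percent)) || any(mol_percent < 0)) {
    abort("mol_percent must be non-negative")
  }
  5L - findInterval(mol_percent, c(0.001, 0.01, 0.1, 1))
}

#' Fold ratio between two abundances
#'
#' @param mol_a,mol_b mol % (or any proportional abundance); `mol_b > 0`.
#' @param digits decimals for half-away-from-zero rounding (0 = integer fold).
#' @return rounded ratio `mol_a / mol_b`.
#' @export
#' @examples
#' fold_ratio(13.886, 0.506)      # 27
#' fold_ratio(0.408, 0.151, 1)    # 2.7
fold_ratio <- function(mol_a, mol_b, digits = 0) {
  if (any(mol_b <= 0)) abort("denominator abundance must be > 0")
  round_half_up(mol_a / mol_b, digits)
}

#' Percentage of a count subset
#'
#' @param subset_size,universe_size counts, `subset_size <= universe_size`,
#'   `universe_size > 0`.
#' @param digits decimals for half-away-from-zero rounding.
#' @return `100 * subset_size / universe_size`, rounded.
#' @export
count_fraction <- function(subset_size, universe_size, digits = 1) {
  if (universe_size <= 0) abort("universe_size must be > 0")
  if (any(subset_size > universe_size)) abort("subset larger than universe")
  round_half_up(100 * subset_size / universe_size, digits)
}

#' Mass share of a subset, by summed mol %
#'
#' @param subset_mol numeric vector of mol % of the subset.
#' @param reference_mol numeric vector of mol % of the reference set.
#' @param digits decimals for half-away-from-zero rounding.
#' @return `100 * sum(subset_mol) / sum(reference_mol)`, rounded.
#' @export
mass_fraction <- function(subset_mol, reference_mol, digits = 0) {
  ref <- sum(reference_mol)
  if (length(reference_mol) == 0L || ref <= 0) {
    abort("reference set must be non-empty with positive total mol %%")
  }
  round_half_up(100 * sum(subset_mol) / ref, digits)
}

#' Dynamic range of an abundance vector
#'
#' @param mol_percent strictly positive numeric vector.
#' @return `max / min` ratio.
#' @export
dynamic_range <- function(mol_percent) {
  if (length(mol_percent) == 0L) abort("empty abundance vector")
  if (any(mol_percent <= 0)) abort("dynamic range requires strictly positive values")
  max(mol_percent) / min(mol_percent)
}

#' Quantify relative abundance from a detection table
#'
#' For each protein detected in at least one acetone sample, pools the
#' distinct peptide identities across the acetone replicates (`n_observed`),
#' counts observable peptides from the protein sequence (or takes them from
#' `observable_counts`), and derives PAI, emPAI, mol %, and the decade
#' abundance class. Gel-extracted samples are excluded from quantification.
#'
#' @param detections a [detection_table()].
#' @param proteome data.frame with `protein_id`, `sequence` (may be omitted
#'   when `observable_counts` is given).
#' @param params a [digest_params()] for the observable-peptide count.
#' @param observable_counts optional named integer vector of observable
#'   peptides per protein, bypassing the digest.
#' @param pooling `"pool"` (distinct peptides pooled across acetone
#'   replicates; when identities are unavailable, the maximum per-replicate
#'   unique-peptide count) or `"mean"` (mean per-replicate count).
#' @return data.frame with columns `protein_id`, `n_observed`,
#'   `n_observable`, `pai`, `empai`, `mol_percent`, `abundance_class`.
#' @export
quantify_abundance <- function(detections, proteome = NULL,
                               params = digest_params(),
                               observable_counts = NULL,
                               pooling = c("pool", "mean")) {
  stopifnot(inherits(detections, "detection_table"))
  pooling <- match.arg(pooling)
  acetone <- detections$samples$sample_id[detections$samples$prep_type == "acetone"]
  if (length(acetone) == 0L) abort("no acetone samples: emPAI quantification undefined")
  e <- detections$entries
  e <- e[e$sample_id %in% acetone & e$psm_count > 0, , drop = FALSE]
  if (nrow(e) == 0L) abort("no acetone-sample detections to quantify")
  ids <- sort(unique(e$protein_id))

  has_identities <- any(vapply(e$peptide_ids, function(p) length(p) > 0L, logical(1)))
  n_observed <- vapply(ids, function(id) {
    rows <- e[e$protein_id == id, , drop = FALSE]
    if (pooling == "mean") {
      return(round_half_up(mean(rows$unique_peptide_count)))
    }
    if (has_identities) {
      length(unique(unlist(rows$peptide_ids)))
    } else {
      max(rows$unique_peptide_count)  # count-only export fallback
    }
  }, numeric(1))

  if (is.null(observable_counts)) {
    if (is.null(proteome)) abort("either a proteome or observable_counts is required")
    require_columns(proteome, c("protein_id", "sequence"), "proteome")
    idx <- match(ids, proteome$protein_id)
    if (anyNA(idx)) {
      abort("protein(s) detected but absent from the proteome: %s",
            paste(ids[is.na(idx)], collapse = ", "))
    }
    n_observable <- vapply(proteome$sequence[idx], digest_observable_peptides,
                           integer(1), params = params, USE.NAMES = FALSE)
  } else {
    n_observable <- unname(observable_counts[ids])
    if (anyNA(n_observable)) abort("observable_counts missing for some detected proteins")
  }
  if (any(n_observable < 1)) {
    abort("protein(s) with zero observable peptides cannot be quantified: %s",
          paste(ids[n_observable < 1], collapse = ", "))
  }

  pe <- compute_empai(n_observed, n_observable)
  mp <- compute_mol_percent(pe$empai)
  data.frame(protein_id = ids, n_observed = as.integer(n_observed),
             n_observable = as.integer(n_observable), pai = pe$pai,
             empai = pe$empai, mol_percent = mp,
             abundance_class = assign_abundance_class(mp),
             stringsAsFactors = FALSE, row.names = NULL)
}
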