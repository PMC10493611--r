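# Multi-set comparison of the curated proteome against reference protein
# sets, novelty detection through ortholog maps, and assembly of the final
# per-protein compendium.

#' Exhaustive region counts for 2-4 named sets
#'
#' Computes the count of every exclusive region of the Venn partition (all
#' `2^n - 1` non-empty membership patterns). Region counts sum to the size of
#' the union and are invariant to the order of the sets.
#'
#' @param sets named list of 2-4 character vectors (duplicates are ignored).
#' @return data.frame with one logical membership column per set, a `region`
#'   label (ampersand-joined set names), and `count`.
#' @export
set_overlap <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 4L) {
    abort("set_overlap expects a named list of 2-4 sets")
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("every set must be named")
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  n <- length(sets)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), n))[-1L, , drop = FALSE]
  names(patterns) <- names(sets)
  counts <- apply(patterns, 1L, function(p) {
    sum(apply(member, 1L, function(m) all(m == p)))
  })
  out <- cbind(patterns,
               region = apply(patterns, 1L, function(p) {
                 paste(names(sets)[as.logical(p)], collapse = "&")
               }),
               count = as.integer(counts))
  row.names(out) <- NULL
  out
}

#' Novel proteins relative to reference databases
#'
#' A protein is novel when its ortholog list is empty or none of its
#' orthologs appears in any reference set. Novelty is antitone in the
#' reference collection: adding a reference set can only shrink the result.
#'
#' @param stromal_ids character vector of proteins to test.
#' @param references list of character vectors in the reference
#'   (ortholog) identifier space.
#' @param ortholog_map named list: `protein_id` -> character vector of
#'   reference ortholog identifiers (empty vectors allowed). Must cover
#'   every id in `stromal_ids`.
#' @return character vector, the novel subset of `stromal_ids`.
#' @export
detect_novel <- function(stromal_ids, references, ortholog_map) {
  if (!all(stromal_ids %in% names(ortholog_map))) {
    abort("ortholog map does not cover the query set")
  }
  ref_union <- unique(unlist(references))
  novel <- vapply(stromal_ids, function(id) {
    orth <- ortholog_map[[id]]
    length(orth) == 0L || !any(orth %in% ref_union)
  }, logical(1))
  stromal_ids[novel]
}

#' Count overlap of tomato proteins with reference sets via orthologs
#'
#' Counts per tomato protein (a protein with several orthologs counts once);
#' the number of proteins with more than one ortholog in the intersection is
#' reported alongside, so the ortholog-level count is derivable.
#'
#' @param stromal_ids character vector of proteins.
#' @param references named list of reference-space sets.
#' @param ortholog_map as in [detect_novel()].
#' @return list with `per_set` (named count of proteins with at least one
#'   ortholog in each set), `core` (proteins present in all sets),
#'   `core_multi_ortholog` (core proteins with more than one ortholog found),
#'   and `core_ortholog_ids` (distinct reference ids behind the core).
#' @export
overlap_by_ortholog <- function(stromal_ids, references, ortholog_map) {
  if (!all(stromal_ids %in% names(ortholog_map))) {
    abort("ortholog map does not cover the query set")
  }
  hits <- lapply(references, function(ref) {
    vapply(stromal_ids, function(id) any(ortholog_map[[id]] %in% ref), logical(1))
  })
  in_all <- Reduce(`&`, hits)
  core_ids <- stromal_ids[in_all]
  core_orth <- lapply(core_ids, function(id) {
    o <- ortholog_map[[id]]
    o[o %in% unique(unlist(references))]
  })
  list(per_set = vapply(hits, sum, integer(1)),
       core = core_ids,
       core_multi_ortholog = sum(lengths(core_orth) > 1L),
       core_ortholog_ids = unique(unlist(core_orth)))
}

#' Assemble the per-protein compendium
#'
#' Full outer join of the component tables by `protein_id`; proteins missing
#' from a component get `NA` in its columns. Errors when any component has a
#' duplicated `protein_id`.
#'
#' @param curation a [curate()] result (or its `result` data.frame).
#' @param abundance optional [quantify_abundance()] result.
#' @param compartments optional [compartment_calls()] result.
#' @param atlas optional [build_atlas()] result.
#' @param evidence optional [evidence_table()].
#' @param functional_bins optional data.frame `protein_id`, `functional_bin`.
#' @return data.frame of class `compendium`, one row per protein in the
#'   union, ordered by `protein_id`.
#' @export
build_compendium <- function(curation, abundance = NULL, compartments = NULL,
                             atlas = NULL, evidence = NULL,
                             functional_bins = NULL) {
  cur <- if (inherits(curation, "curation_result")) curation$result else curation
  parts <- list(curation = cur, abundance = abundance,
                compartments = compartments, atlas = atlas,
                evidence = evidence, functional_bins = functional_bins)
  parts <- Filter(Negate(is.null), parts)
  out <- NULL
  for (nm in names(parts)) {
    p <- as.data.frame(parts[[nm]])
    require_columns(p, "protein_id", sprintf("compendium component '%s'", nm))
    require_unique(p$protein_id, sprintf("protein_id in component '%s'", nm))
    p <- p[, !vapply(p, is.list, logical(1)), drop = FALSE]  # drop list columns
    out <- if (is.null(out)) p else merge(out, p, by = "protein_id",
                                          all = TRUE, sort = TRUE)
  }
  out <- out[order(out$protein_id), , drop = FALSE]
  row.names(out) <- NULL
  class(out) <- c("compendium", "data.frame")
  out
}
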