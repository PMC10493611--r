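# Fixture builders shared across the test files. Everything is constructed in
# code; no binary fixtures.

default_samples <- function(n_acetone = 5, n_gel = 3) {
  data.frame(
    sample_id = c(sprintf("acetone_%d", seq_len(n_acetone)),
                  sprintf("gel_%d", seq_len(n_gel))),
    prep_type = c(rep("acetone", n_acetone), rep("gel", n_gel)),
    stringsAsFactors = FALSE)
}

# Build a detection table from a compact per-protein spec:
# list(protein_id = list(n_acetone_detected, n_gel_detected, psm_per_sample,
#                        unique_peptides_per_sample))
make_detection_table <- function(spec, samples = default_samples()) {
  ace <- samples$sample_id[samples$prep_type == "acetone"]
  gel <- samples$sample_id[samples$prep_type == "gel"]
  rows <- list()
  for (id in names(spec)) {
    s <- spec[[id]]
    in_samples <- c(utils::head(ace, s[[1]]), utils::head(gel, s[[2]]))
    for (sm in in_samples) {
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = id, sample_id = sm, psm_count = s[[3]],
        unique_peptide_count = s[[4]], stringsAsFactors = FALSE)
    }
  }
  entries <- if (length(rows) > 0L) do.call(rbind, rows) else {
    data.frame(protein_id = character(0), sample_id = character(0),
               psm_count = integer(0), unique_peptide_count = integer(0))
  }
  detection_table(entries, samples)
}

# Prediction matrix where each protein gets its first `votes[i]` localization
# slots positive, `tm[i]` segments on every TM slot, and both lumen slots set
# to `lumen[i]`.
make_prediction_matrix <- function(ids, votes = 0L, tm = 0L, lumen = FALSE,
                                   slots = predictor_slots()) {
  n <- length(ids)
  votes <- rep_len(votes, n); tm <- rep_len(tm, n); lumen <- rep_len(lumen, n)
  df <- data.frame(protein_id = ids, stringsAsFactors = FALSE)
  for (i in seq_along(slots$loc)) {
    df[[paste0("loc_", slots$loc[i])]] <- votes >= i
  }
  for (s in slots$tm) df[[paste0("tm_", s)]] <- as.integer(tm)
  for (s in slots$lumen) df[[paste0("lum_", s)]] <- lumen
  prediction_matrix(df, slots)
}

make_atlas <- function(ids, votes = 0L, plastid_ids = NULL) {
  m <- make_prediction_matrix(ids, votes)
  plastid <- if (!is.null(plastid_ids)) data.frame(protein_id = plastid_ids)
  build_atlas(m, plastid)
}

make_evidence <- function(ids, chl = FALSE, lit = FALSE, other = FALSE,
                          lumen = FALSE) {
  n <- length(ids)
  evidence_table(data.frame(
    protein_id = ids,
    chl_ppdb = rep_len(chl, n), chl_suba4 = FALSE, chl_plprot = FALSE,
    literature_chloroplast = rep_len(lit, n),
    other_compartment_empirical = rep_len(other, n),
    lumen_empirical = rep_len(lumen, n), stringsAsFactors = FALSE))
}

# Random amino-acid sequence over the 20 standard residues.
random_sequence <- function(n, aa = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

write_fasta <- function(ids, seqs, path, desc = NULL) {
  hdr <- if (is.null(desc)) ids else paste(ids, desc)
  writeLines(paste0(">", hdr, "\n", seqs), path)
  path
}
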