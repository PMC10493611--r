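# In-silico tryptic digestion and observable-peptide counting. emPAI needs,
# for every protein, the number of peptides the instrument could in principle
# have observed: fully tryptic peptides long enough to be searched and whose
# m/z falls in the acquired scan window at some selectable charge state.

# Monoisotopic residue masses (Da) for the 20 standard amino acids.
AA_MONO <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
             V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
             I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
             K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
             F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
MASS_WATER <- 18.0105646863
MASS_PROTON <- 1.00728

#' Digestion and observability parameters
#'
#' Controls the in-silico tryptic digest used to count observable peptides.
#' Trypsin cleaves C-terminal to K or R except when the next residue is P. A
#' peptide is observable when it meets the minimum length and some charge in
#' `charge_range` places its monoisotopic m/z, `(M + z * 1.00728) / z`, inside
#' `[mz_low, mz_high]`. Defaults mirror a typical Orbitrap acquisition: scan
#' window 300-1800 m/z, searched charge states 2-8, minimum peptide length 6,
#' no missed cleavages.
#'
#' @param max_missed_cleavages integer >= 0.
#' @param min_peptide_length integer >= 1, residues.
#' @param mz_low,mz_high m/z window bounds, `mz_low < mz_high`.
#' @param charge_range integer vector of charge states to consider.
#' @return named list of class `digest_params`.
#' @export
digest_params <- function(max_missed_cleavages = 0L, min_peptide_length = 6L,
                          mz_low = 300, mz_high = 1800, charge_range = 2:8) {
  stopifnot(max_missed_cleavages >= 0, min_peptide_length >= 1,
            mz_low < mz_high, length(charge_range) >= 1, all(charge_range >= 1))
  structure(list(max_missed_cleavages = as.integer(max_missed_cleavages),
                 min_peptide_length = as.integer(min_peptide_length),
                 mz_low = mz_low, mz_high = mz_high,
                 charge_range = as.integer(charge_range)),
            class = "digest_params")
}

#' Tryptic digest of a protein sequence
#'
#' Returns the distinct fully tryptic peptides of `sequence` with up to
#' `params$max_missed_cleavages` missed cleavages, before any length or m/z
#' filtering.
#'
#' @param sequence amino-acid string (20 standard residues plus X).
#' @param params a [digest_params()].
#' @return character vector of distinct peptides (empty for an empty input).
#' @export
digest_peptides <- function(sequence, params = digest_params()) {
  stopifnot(length(sequence) == 1L)
  if (is.na(sequence) || !nzchar(sequence)) return(character(0))
  res <- strsplit(toupper(sequence), "")[[1]]
  if (!all(res %in% c(names(AA_MONO), "X"))) {
    abort("sequence contains residues outside the 20 standard amino acids + X")
  }
  n <- length(res)
  # cut after position i when res[i] is K/R and res[i+1] is not P
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | res[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, if (n %in% cut_after) NULL else n)
  peps <- character(0)
  nseg <- length(bounds) - 1L
  for (i in seq_len(nseg)) {
    for (mc in 0:min(params$max_missed_cleavages, nseg - i)) {
      peps <- c(peps, paste(res[(bounds[i] + 1L):bounds[i + 1L + mc]],
                            collapse = ""))
    }
  }
  unique(peps)
}

#' Monoisotopic peptide mass
#'
#' Neutral monoisotopic mass of a peptide (sum of residue masses plus water).
#' Peptides containing X (unknown residue) have mass `NA`.
#'
#' @param peptides character vector of peptide sequences.
#' @return numeric vector of masses in Da.
#' @export
peptide_mass <- function(peptides) {
  vapply(peptides, function(p) {
    res <- strsplit(p, "")[[1]]
    if (any(res == "X")) return(NA_real_)
    sum(AA_MONO[res]) + MASS_WATER
  }, numeric(1), USE.NAMES = FALSE)
}

# Internal: which peptides pass the length and m/z observability filters.
is_observable <- function(peptides, params) {
  if (length(peptides) == 0L) return(logical(0))
  long_enough <- nchar(peptides) >= params$min_peptide_length
  mass <- peptide_mass(peptides)
  in_window <- vapply(mass, function(m) {
    if (is.na(m)) return(FALSE)
    mz <- (m + params$charge_range * MASS_PROTON) / params$charge_range
    any(mz >= params$mz_low & mz <= params$mz_high)
  }, logical(1))
  long_enough & in_window
}

#' Count observable peptides of a protein
#'
#' Number of distinct fully tryptic peptides of `sequence` that meet the
#' length criterion and whose monoisotopic m/z falls in the scan window at
#' some charge in `params$charge_range`. This is the emPAI denominator.
#'
#' @param sequence amino-acid string.
#' @param params a [digest_params()].
#' @return integer count (0 for an empty sequence, with a warning).
#' @export
digest_observable_peptides <- function(sequence, params = digest_params()) {
  if (is.na(sequence) || !nzchar(sequence)) {
    warning("empty sequence: 0 observable peptides")
    return(0L)
  }
  peps <- digest_peptides(sequence, params)
  sum(is_observable(peps, params))
}

#' Observable peptides themselves (identities, not just the count)
#'
#' Used by the synthetic-data generator to draw detected peptides from a
#' protein's digest.
#'
#' @inheritParams digest_observable_peptides
#' @return character vector of observable peptides.
#' @export
observable_peptides <- function(sequence, params = digest_params()) {
  peps <- digest_peptides(sequence, params)
  peps[is_observable(peps, params)]
}
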