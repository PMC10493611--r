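---
title: "Curating and quantifying a chloroplast stromal proteome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating and quantifying a chloroplast stromal proteome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromatlas)
```

## The problem

Shotgun proteomics of an isolated organelle fraction never yields the
organelle's proteome directly. The search-engine export at 1% FDR mixes
three populations: genuine residents, co-isolating proteins (CIPs) from
other compartments that reproducibly survive the fractionation, and
one-hit wonders — identifications resting on a single spectrum or a single
peptide that are as likely to be noise as biology. `stromatlas` implements
the curation and quantification procedure used to assemble a tomato
chloroplast stromal proteome compendium: it turns a per-protein,
per-sample evidence table into a defensible partition (stromal / CIP /
removed, each with machine-readable reason codes), estimates relative
molar abundance with emPAI, assigns sub-organellar compartments by
predictor consensus, and compares the result against reference protein
sets.

## The localization Atlas

Because no single subcellular-localization predictor is reliable, the
pipeline first builds a consensus **Atlas**: the union, over the whole
deduced proteome, of per-predictor plastid calls from five localization
tools, plus the plastid-genome-encoded proteins. A nuclear protein enters
the Atlas when *at least one* predictor calls it plastid — deliberately
liberal, since each tool brings a different algorithm and training set.
Vote counts (0–5) are retained so that downstream rules can ask for
stronger consensus, and `consensus_tier()` exposes the nested tiers (the
all-five core being the strictest). Plastid-genome open reading frames are
deduplicated by exact sequence identity before inclusion, because the
chloroplast genome's inverted repeat carries genes in two copies that
encode identical proteins; the retained identifier is the
lexicographically smallest, a deterministic tie-break.

A missing predictor call is recorded as missing, counts as a non-vote, and
is tracked separately (`n_missing_calls`), so a protein a predictor failed
on is never silently treated as a negative call.

## The curation rule

Detection evidence is summarized per protein: samples detected per
preparation type (acetone precipitation vs gel extraction), total PSMs,
and total unique peptides pooled across samples. A protein is *flagged*
when any of the following holds:

* detected once with a single PSM;
* identified by one unique peptide overall ("single peptide" is evaluated
  on peptide sequences pooled across all samples, matching how the
  dataset-level unique-peptide totals are reported);
* sporadic: detected in fewer than 40% of the samples of *each*
  preparation type. The test is per preparation type with OR-retention —
  reproducible detection in acetone alone or gel alone suffices — and a
  frequency exactly at 40% passes (2 of 5 acetone samples is enough; 1 of
  3 gel samples is not). A preparation type with no samples in the dataset
  contributes an undefined frequency, not a zero.

Flagged proteins are still retained when independent evidence argues for a
plastid location: empirical chloroplast evidence in any reference database
slot (PPDB, SUBA4, plprot by default), a literature flag, or an Atlas vote
count of at least 2. The vote threshold is configurable
(`vote_threshold`); 2 is the default because the retention criterion is
meant to demand more than the single vote that suffices for bare Atlas
membership, and it matches the "two or more algorithms" consensus used in
the novelty analysis.

Retained proteins are then partitioned: a protein is a **CIP** when
empirical evidence places it in another compartment *and* nothing argues
for the chloroplast (no database slot, no literature flag, fewer than 2
votes); otherwise it is **stromal**. Chloroplast evidence therefore takes
precedence over other-compartment evidence — a protein with both is kept
as stromal, reflecting possible dual localization.

The whole rule is deterministic boolean logic, so the test suite checks it
against an exhaustively enumerated truth table over all combinations of
the inputs, not against sampled cases. Two monotonicity properties follow
from the rule's shape and are also tested: adding chloroplast evidence can
only promote a protein (removed → retained, CIP → stromal), and adding
spectra can only promote, never demote.

## emPAI and mol %

Relative molar abundance uses the exponentially modified protein abundance
index. For each protein,

$$\mathrm{PAI} = \frac{n_\text{observed}}{n_\text{observable}},
\qquad \mathrm{emPAI} = 10^{\mathrm{PAI}} - 1,
\qquad \text{mol\,\%} = 100 \cdot
\frac{\mathrm{emPAI}}{\sum \mathrm{emPAI}}.$$

Quantification uses the acetone-precipitated samples only; gel extraction
deliberately removes an abundant mass window, which would bias spectral
counts. Observed peptides are the distinct peptide sequences pooled across
the acetone replicates (a per-replicate-mean alternative is exposed via
`pooling = "mean"`; when peptide identities are unavailable the maximum
per-replicate unique-peptide count is used as a conservative stand-in).

Observable peptides come from an in-silico tryptic digest
(`digest_observable_peptides()`): cleavage after K/R except before P, no
missed cleavages by default, minimum length 6 residues, and monoisotopic
m/z within 300–1800 at some charge state between 2 and 8 (proton mass
1.00728 Da). These defaults mirror a typical Orbitrap acquisition — the
scan window and minimum searched length are instrument settings, and MS2
precursor selection spans charges 2–8 — but every parameter is
configurable through `digest_params()`, because different search software
computes its emPAI denominator with different (and usually undocumented)
settings. Note a consequence of the charge floor: a short tryptic peptide
such as AAAAAR (monoisotopic mass 529.30 Da) is *not* observable at the
defaults, since its m/z at charge 2 falls below 300; it becomes observable
only if singly charged precursors are allowed.

Reported statistics — fold ratios between paralogs, count fractions, mass
fractions — round half away from zero at the printed precision
(`round_half_up()`), which is the convention that reproduces the published
values exactly (e.g. 13.886/0.506 → 27-fold; 159/1278 → 12.4%).

Abundance classes are decade bins of mol %, lower-inclusive:
class 1 = [1, ∞), class 2 = [0.1, 1), down to class 5 = [0, 0.001). Under
these boundaries the published top-110 table occupies exactly classes 1–2.

## Sub-organellar calls

Membrane calls use a majority consensus of the three transmembrane
predictors (at least 2 of 3 reporting ≥ 1 segment, configurable via
`consensus_k`); the tools disagree often enough that a single-tool call is
weak evidence, and majority is the symmetric conservative choice. Lumen
calls require *both* lumenal-transit-peptide predictors, or lumen-specific
empirical evidence, which takes precedence in the reported basis. The
compartment summary reports counts, count fractions of the stromal set,
summed mol % (mass), and a refined membrane count that excludes
sporadically detected proteins — membrane proteins in a soluble fraction
are expected to be depletion survivors, and sporadic ones likely carryover.

## The synthetic-data generator

`simulate_study()` generates a proteome, predictor matrix, detection table
and evidence table with known ground truth, so every stage of the pipeline
is testable without any external download. What it emulates:

* **Sample design**: 5 acetone + 3 gel samples.
* **Abundance**: log-normal true molar abundances (`sdlog` 2.5 by
  default — a heavy tail consistent with the several-orders-of-magnitude
  dynamic range seen in organellar proteomes), normalized to molar
  fractions.
* **Detection**: per sample, logistic probability in centred log
  abundance (slope 1.2, midpoint at the median), so abundant proteins are
  detected reproducibly and rare ones sporadically.
* **Spectra**: given detection, the PSM count is zero-truncated Poisson
  (a detected protein has ≥ 1 PSM by definition) with mean proportional to
  molar abundance *times observable-digest size*, normalized so that
  `psm_rate` (default 5, of the order of published PSM totals per protein
  per sample) is the expected count for an average-size protein at mean
  abundance. The size factor matters: at equal molar amounts a larger
  protein contributes proportionally more spectra, which is precisely the
  sampling logic emPAI assumes. Observed peptide identities are drawn, one
  per PSM with replacement, from the protein's observable digest.
* **Predictors and evidence**: per-slot Bernoulli calls at configurable
  sensitivity/specificity (defaults 0.85/0.95, typical of localization
  tools), TM segment counts only for membrane-labelled proteins, lumenal-TP
  calls for lumen-labelled ones, and database evidence flags with their own
  error rates.
* **Proteins**: random sequences of 150–1200 residues with natural
  amino-acid frequencies (K+R ≈ 11%), so tryptic digests have realistic
  peptide counts; compartment fractions within the chloroplast default to
  the published stromal-set shares (12.4% membrane, 4.6% lumen).

One global seed drives a separate stream per stage (offsets fixed per
stage), so regenerating the predictions does not perturb the detections.

What it does **not** emulate: spectra, retention times, search scoring,
FDR machinery, shared peptides between homologous proteins, and — most
importantly — the enrichment of the organelle fraction itself. Detection
depends only on abundance, not on compartment, so synthetic studies
contain far more non-plastid detections than a real chloroplast
preparation. Passing tests therefore demonstrate the correctness of the
rules and estimators, not that the defaults reproduce any particular real
dataset's composition.

## Validation strategy and numerical choices

* Printed-table checks: the bundled lumenal and top-110 abundance tables
  (under `inst/extdata/`) are inputs on which the arithmetic operations
  must reproduce the published percentages, ratios and the PSBQ mol %
  derived from a TL19-calibrated total emPAI. The implied total emPAI is
  checked for consistency across all 58 lumenal rows *within each row's
  printed precision* — rows with two significant figures of emPAI cannot
  pin the total more tightly than that, and pretending otherwise would
  manufacture precision.
* The curation rule is verified against a brute-force truth table; Venn
  region counts against exhaustive membership enumeration; the digest
  against an independent sliding-scan implementation; FASTA parsing against
  a naive line-by-line parse.
* End-to-end recovery: with ideal detection (probability 1), noiseless
  predictors and ample spectra, the pipeline must classify every true
  plastid protein as stromal and recover the abundance ranking (Spearman
  ρ > 0.9 at n = 500). This scenario uses an abundance dispersion of
  `sdlog = 1.5` rather than the generator default of 2.5: PAI is bounded
  by the digest size (at most `n_observable + 1` distinct values per
  protein), so over a six-decade dynamic range the least abundant decades
  all collapse onto the one-PSM floor and *no* spectral-counting index can
  order them. That floor — saturation at the top, quantization at the
  bottom — is a known limitation of emPAI, not of this implementation, and
  keeping the recovery scenario inside the index's resolving range makes
  the test informative about pipeline correctness.
* Problem sizes: unit and property tests run at 100–5,000 synthetic
  proteins and 500 for the recovery scenario; these sizes make the
  Monte-Carlo tolerances in the tests (3 points on predictor error rates,
  5% on the log-abundance dispersion) comfortably non-flaky while keeping
  the default suite fast.
* Degenerate inputs fail loudly: zero observable peptides, all-zero emPAI
  vectors, empty reference sets, a zero proteome size, out-of-range
  consensus thresholds and duplicate protein identifiers are all errors,
  never silent coercions.

## Worked example

```{r example}
cfg <- synthetic_config(n_proteins = 400, seed = 7)
study <- simulate_study(cfg)
plastid <- study$proteome[study$proteome$genome_source == "plastid", ]
res <- run_stromal_pipeline(study$detections, study$predictions,
                            study$evidence, study$proteome, plastid)
res$curation
head(res$abundance[order(-res$abundance$mol_percent),
                   c("protein_id", "n_observed", "n_observable",
                     "empai", "mol_percent", "abundance_class")])
res$compartment_summary
```

The printed-table arithmetic is just as direct:

```{r tables}
top <- tomato_top110_table()
mol <- function(nm) top$mol_percent[match(nm, top$protein_name)]
fold_ratio(mol("ATPB"), mol("ATPA"))        # ATP synthase beta vs alpha
fold_ratio(mol("CLPC1"), mol("CLPC2"), 1)   # Clp protease paralogs

lum <- tomato_lumen_table()
mass_fraction(lum$mol_percent[match("TL19", lum$protein_name)],
              lum$mol_percent)              # TL19 share of lumen mass
```

## Known limitations

* The observable-peptide definition is this package's own (fully tryptic,
  length and m/z filtered); commercial search software uses its own
  undocumented variant, so absolute emPAI values are comparable only
  within one definition. Ratios and mol % are much less sensitive to the
  choice.
* emPAI saturates for proteins whose digest is fully observed and
  quantizes at the one-peptide floor; mol % of extreme proteins is
  accordingly compressed.
* CIP classification encodes only the published rule; dual-localized
  proteins whose chloroplast residence is genuine but evidence-poor will
  be classified CIP.
* The generator's detection model is compartment-blind (see above), and
  peptides are unique to their protein — shared-peptide inference problems
  are out of scope.
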