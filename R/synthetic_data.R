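# Synthetic proteomes, predictor matrices and detection tables with known
# ground truth. The generator emulates the statistical structure of a
# stromal-proteomics study: eight MS samples (five acetone-precipitated,
# three gel-extracted), log-normally distributed true molar abundances (the
# observed dynamic range spans several orders of magnitude, demanding a
# heavy-tailed law), a logistic detection probability in log abundance,
# zero-truncated PSM counts given detection, and predictor calls with
# configurable sensitivity/specificity. One global seed drives a separate
# stream per stage so stages can be regenerated independently.

#' Configuration for the synthetic-data generator
#'
#' Defaults describe a leaf-chloroplast stromal study: about a fifth of the
#' proteome truly plastid-localized, a small plastid-genome complement,
#' membrane and lumen minorities within the chloroplast (12.4% and 4.6%), a
#' log-normal abundance law with `sdlog` 2.5, and a PSM rate of 5 expected
#' matches per detected protein per sample at mean abundance.
#'
#' @param n_proteins number of proteins (> 0).
#' @param frac_true_chloroplast proportion of proteins truly chloroplast.
#' @param frac_plastid_genome proportion encoded by the plastid genome
#'   (always chloroplast-localized).
#' @param frac_membrane,frac_lumen compartment proportions within the true
#'   chloroplast set; the remainder is stroma.
#' @param abundance_logmean,abundance_logsd parameters of the log-normal true
#'   molar-abundance law (natural log).
#' @param detection_slope,detection_midpoint logistic detection probability
#'   in centred log abundance: `plogis(slope * (log(a) - logmean - midpoint))`.
#'   `midpoint = -Inf` gives ideal (certain) detection; `Inf` gives none.
#' @param psm_rate expected PSMs per detected protein per sample at mean
#'   abundance (PSM counts are zero-truncated Poisson given detection).
#' @param predictor_sensitivity,predictor_specificity per-slot error rates
#'   shared by the localization, TM and lumenal-TP predictor groups.
#' @param evidence_sensitivity,evidence_specificity error rates of the
#'   reference-database evidence flags.
#' @param n_acetone,n_gel sample counts per preparation type.
#' @param min_seq_length,max_seq_length protein sequence length range.
#' @param seed integer seed (< 2^31) driving all per-stage streams.
#' @return named list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 2000L,
                             frac_true_chloroplast = 0.22,
                             frac_plastid_genome = 0.003,
                             frac_membrane = 0.124,
                             frac_lumen = 0.046,
                             abundance_logmean = 0,
                             abundance_logsd = 2.5,
                             detection_slope = 1.2,
                             detection_midpoint = 0,
                             psm_rate = 5,
                             predictor_sensitivity = 0.85,
                             predictor_specificity = 0.95,
                             evidence_sensitivity = 0.6,
                             evidence_specificity = 0.97,
                             n_acetone = 5L,
                             n_gel = 3L,
                             min_seq_length = 150L,
                             max_seq_length = 1200L,
                             seed = 1L) {
  props <- c(frac_true_chloroplast, frac_plastid_genome, frac_membrane,
             frac_lumen, predictor_sensitivity, predictor_specificity,
             evidence_sensitivity, evidence_specificity)
  if (any(is.na(props)) || any(props < 0) || any(props > 1)) {
    abort("all proportions and rates must lie in [0, 1]")
  }
  if (n_proteins < 1) abort("n_proteins must be positive")
  if (frac_plastid_genome > frac_true_chloroplast) {
    abort("frac_plastid_genome cannot exceed frac_true_chloroplast")
  }
  if (frac_membrane + frac_lumen > 1) abort("compartment fractions exceed 1")
  if (n_acetone < 0 || n_gel < 0 || n_acetone + n_gel < 1) {
    abort("at least one sample is required")
  }
  if (min_seq_length < 10 || max_seq_length < min_seq_length) {
    abort("invalid sequence length range")
  }
  if (abundance_logsd <= 0 || psm_rate <= 0) {
    abort("abundance_logsd and psm_rate must be positive")
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 frac_true_chloroplast = frac_true_chloroplast,
                 frac_plastid_genome = frac_plastid_genome,
                 frac_membrane = frac_membrane, frac_lumen = frac_lumen,
                 abundance_logmean = abundance_logmean,
                 abundance_logsd = abundance_logsd,
                 detection_slope = detection_slope,
                 detection_midpoint = detection_midpoint,
                 psm_rate = psm_rate,
                 predictor_sensitivity = predictor_sensitivity,
                 predictor_specificity = predictor_specificity,
                 evidence_sensitivity = evidence_sensitivity,
                 evidence_specificity = evidence_specificity,
                 n_acetone = as.integer(n_acetone), n_gel = as.integer(n_gel),
                 min_seq_length = as.integer(min_seq_length),
                 max_seq_length = as.integer(max_seq_length),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Stage offsets keep the per-stage RNG streams independent of one another.
stage_seed <- function(config, stage) {
  offset <- c(proteome = 11L, predictions = 23L, detections = 37L,
              evidence = 53L)[[stage]]
  (config$seed + offset) %% .Machine$integer.max
}

# Approximate amino-acid background frequencies; K+R together ~11% so random
# sequences digest into tryptic peptides of realistic length.
AA_FREQ <- c(A = 0.080, R = 0.055, N = 0.040, D = 0.054, C = 0.014,
             Q = 0.039, E = 0.067, G = 0.070, H = 0.022, I = 0.060,
             L = 0.096, K = 0.058, M = 0.024, F = 0.039, P = 0.047,
             S = 0.066, T = 0.053, W = 0.011, Y = 0.029, V = 0.068)

#' Generate a synthetic proteome with ground truth
#'
#' Draws protein sequences, genome sources, true compartments and true molar
#' abundances (log-normal, then normalized to molar fractions summing to 1).
#' Plastid-genome proteins are never `non_plastid`.
#'
#' @param config a [synthetic_config()].
#' @return list with `proteome` (data.frame `protein_id`, `genome_source`,
#'   `sequence`, `annotation`) and `truth` (data.frame `protein_id`,
#'   `genome_source`, `true_compartment`, `true_abundance`,
#'   `true_mol_fraction`).
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(stage_seed(config, "proteome"))
  n <- config$n_proteins
  ids <- sprintf("SYNP%05d", seq_len(n))
  n_plastid <- round(n * config$frac_plastid_genome)
  genome <- rep("nuclear", n)
  if (n_plastid > 0) genome[sample.int(n, n_plastid)] <- "plastid"

  chloro <- stats::runif(n) < config$frac_true_chloroplast
  chloro[genome == "plastid"] <- TRUE
  u <- stats::runif(n)
  comp <- ifelse(!chloro, "non_plastid",
                 ifelse(u < config$frac_membrane, "membrane",
                        ifelse(u < config$frac_membrane + config$frac_lumen,
                               "lumen", "stroma")))

  abund <- stats::rlnorm(n, config$abundance_logmean, config$abundance_logsd)
  lens <- sample(config$min_seq_length:config$max_seq_length, n, replace = TRUE)
  freq <- AA_FREQ / sum(AA_FREQ)
  sequences <- vapply(lens, function(L) {
    paste(sample(names(freq), L, replace = TRUE, prob = freq), collapse = "")
  }, character(1))

  proteome <- data.frame(protein_id = ids, genome_source = genome,
                         sequence = sequences,
                         annotation = paste("synthetic protein", seq_len(n)),
                         stringsAsFactors = FALSE)
  truth <- data.frame(protein_id = ids, genome_source = genome,
                      true_compartment = comp, true_abundance = abund,
                      true_mol_fraction = abund / sum(abund),
                      stringsAsFactors = FALSE)
  list(proteome = proteome, truth = truth)
}

#' Generate predictor calls from ground truth
#'
#' Each localization slot calls a true chloroplast protein positive with
#' probability `predictor_sensitivity` and any other protein with
#' `1 - predictor_specificity`; TM slots report segments only by the same
#' error model on the membrane label; lumenal-TP slots analogously on the
#' lumen label.
#'
#' @param proteome,truth a [generate_proteome()] result's components.
#' @param config a [synthetic_config()].
#' @param slots predictor slot names, see [predictor_slots()].
#' @return a [prediction_matrix()].
#' @export
generate_predictions <- function(proteome, truth, config,
                                 slots = predictor_slots()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!all(proteome$protein_id %in% truth$protein_id)) {
    abort("ground truth does not cover the proteome")
  }
  set.seed(stage_seed(config, "predictions"))
  truth <- truth[match(proteome$protein_id, truth$protein_id), ]
  n <- nrow(proteome)
  sens <- config$predictor_sensitivity
  spec <- config$predictor_specificity
  call_rate <- function(is_true) ifelse(is_true, sens, 1 - spec)

  df <- data.frame(protein_id = proteome$protein_id, stringsAsFactors = FALSE)
  is_chloro <- truth$true_compartment != "non_plastid"
  for (s in slots$loc) {
    df[[paste0("loc_", s)]] <- stats::runif(n) < call_rate(is_chloro)
  }
  is_mem <- truth$true_compartment == "membrane"
  for (s in slots$tm) {
    pos <- stats::runif(n) < call_rate(is_mem)
    df[[paste0("tm_", s)]] <- ifelse(pos, 1L + stats::rpois(n, 1.5), 0L)
  }
  is_lum <- truth$true_compartment == "lumen"
  for (s in slots$lumen) {
    df[[paste0("lum_", s)]] <- stats::runif(n) < call_rate(is_lum)
  }
  prediction_matrix(df, slots)
}

# Zero-truncated Poisson draws: a detected protein has >= 1 PSM by
# definition, so PSM counts are Poisson conditioned on positivity.
rztpois <- function(n, lambda) {
  lambda <- rep_len(lambda, n)
  u <- stats::runif(n, stats::dpois(0, lambda), 1)
  x <- stats::qpois(pmin(u, 1 - 1e-12), lambda)
  pmax(x, 1L)
}

#' Generate a detection table from ground truth
#'
#' Per sample, a protein is detected with logistic probability in centred log
#' abundance. Detected proteins receive a zero-truncated Poisson PSM count
#' whose mean is proportional to molar abundance times the size of the
#' protein's observable digest (at equal molar amounts, a larger protein
#' yields proportionally more spectra), normalized so that `psm_rate` is the
#' expected PSM count per sample for an average-size protein at mean
#' abundance. Observed peptides are drawn (one per PSM, with replacement)
#' from the observable tryptic digest, which reproduces the per-peptide
#' sampling logic underlying emPAI.
#'
#' @param proteome,truth a [generate_proteome()] result's components.
#' @param config a [synthetic_config()].
#' @param params a [digest_params()] for the in-silico digest.
#' @return a [detection_table()].
#' @export
generate_detections <- function(proteome, truth, config,
                                params = digest_params()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!all(proteome$protein_id %in% truth$protein_id)) {
    abort("ground truth does not cover the proteome")
  }
  set.seed(stage_seed(config, "detections"))
  truth <- truth[match(proteome$protein_id, truth$protein_id), ]
  n <- nrow(proteome)
  samples <- data.frame(
    sample_id = c(sprintf("acetone_%d", seq_len(config$n_acetone)),
                  sprintf("gel_%d", seq_len(config$n_gel))),
    prep_type = c(rep("acetone", config$n_acetone), rep("gel", config$n_gel)),
    stringsAsFactors = FALSE)

  z <- log(truth$true_abundance) - config$abundance_logmean
  p_detect <- stats::plogis(config$detection_slope * (z - config$detection_midpoint))

  digests <- lapply(proteome$sequence, observable_peptides, params = params)
  rel <- truth$true_abundance / mean(truth$true_abundance)
  d_rel <- lengths(digests) / max(mean(lengths(digests)), 1)
  lambda <- config$psm_rate * rel * d_rel
  entries <- vector("list", nrow(samples))
  for (j in seq_len(nrow(samples))) {
    hit <- which(stats::runif(n) < p_detect & lengths(digests) > 0L)
    if (length(hit) == 0L) {
      entries[[j]] <- NULL
      next
    }
    psm <- rztpois(length(hit), lambda[hit])
    peps <- mapply(function(i, s) {
      d <- digests[[i]]
      if (s >= 8L * length(d)) d else unique(sample(d, s, replace = TRUE))
    }, hit, psm, SIMPLIFY = FALSE)
    ent <- data.frame(protein_id = proteome$protein_id[hit],
                      sample_id = samples$sample_id[j],
                      psm_count = as.integer(psm),
                      unique_peptide_count = lengths(peps),
                      stringsAsFactors = FALSE)
    ent$peptide_ids <- peps
    entries[[j]] <- ent
  }
  entries <- Filter(Negate(is.null), entries)
  all_entries <- if (length(entries) > 0L) do.call(rbind, entries) else {
    d <- data.frame(protein_id = character(0), sample_id = character(0),
                    psm_count = integer(0), unique_peptide_count = integer(0),
                    stringsAsFactors = FALSE)
    d$peptide_ids <- list()
    d
  }
  detection_table(all_entries, samples)
}

#' Generate reference-database evidence from ground truth
#'
#' Chloroplast-empirical slots fire on true chloroplast proteins with
#' `evidence_sensitivity` and on others with `1 - evidence_specificity`;
#' other-compartment evidence mirrors that for non-plastid proteins; the
#' lumen-specific flag follows the lumen label.
#'
#' @param truth a [generate_proteome()] result's `truth` component.
#' @param config a [synthetic_config()].
#' @param slots chloroplast-empirical slot names, see [evidence_slots()].
#' @return an [evidence_table()].
#' @export
generate_evidence <- function(truth, config, slots = evidence_slots()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(stage_seed(config, "evidence"))
  n <- nrow(truth)
  is_chloro <- truth$true_compartment != "non_plastid"
  rate <- function(is_true, sens, spec) ifelse(is_true, sens, 1 - spec)
  df <- data.frame(protein_id = truth$protein_id, stringsAsFactors = FALSE)
  for (s in slots) {
    df[[s]] <- stats::runif(n) < rate(is_chloro, config$evidence_sensitivity,
                                      config$evidence_specificity)
  }
  df$literature_chloroplast <- stats::runif(n) < ifelse(is_chloro, 0.05, 0)
  df$other_compartment_empirical <-
    stats::runif(n) < rate(!is_chloro, config$evidence_sensitivity,
                           config$evidence_specificity)
  df$lumen_empirical <-
    stats::runif(n) < rate(truth$true_compartment == "lumen",
                           config$evidence_sensitivity,
                           config$evidence_specificity)
  evidence_table(df, slots)
}

#' Run the full synthetic study
#'
#' Convenience wrapper chaining [generate_proteome()],
#' [generate_predictions()], [generate_detections()] and
#' [generate_evidence()] under one configuration.
#'
#' @param config a [synthetic_config()].
#' @param params a [digest_params()].
#' @return list with `proteome`, `truth`, `predictions`, `detections`,
#'   `evidence`, `config`.
#' @export
simulate_study <- function(config = synthetic_config(),
                           params = digest_params()) {
  pg <- generate_proteome(config)
  list(proteome = pg$proteome, truth = pg$truth,
       predictions = generate_predictions(pg$proteome, pg$truth, config),
       detections = generate_detections(pg$proteome, pg$truth, config, params),
       evidence = generate_evidence(pg$truth, config),
       config = config)
}

#' Read a key=value configuration file
#'
#' Accepts one `key = value` pair per line (comments start with `#`); values
#' are coerced to numeric where possible and passed to [synthetic_config()].
#'
#' @param path file path.
#' @return a [synthetic_config()].
#' @export
read_synthetic_config <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) abort("malformed config line(s) in %s", path)
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- trimws(vapply(kv, `[`, character(1), 2L))
  args <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(args) <- keys
  unknown <- setdiff(keys, names(formals(synthetic_config)))
  if (length(unknown) > 0L) {
    abort("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  do.call(synthetic_config, args)
}

#' Write a synthetic study to a directory of TSV files
#'
#' Emits the same dialects the readers consume, each file prefixed by a
#' comment line echoing the generator seed.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_synthetic_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- function(path) {
    txt <- readLines(path, warn = FALSE)
    writeLines(c(sprintf("# seed=%d", study$config$seed), txt), path)
  }
  p <- file.path(dir, "detections.tsv")
  write_detection_table(study$detections, p); stamp(p)
  p <- file.path(dir, "predictions.tsv")
  write_prediction_matrix(study$predictions, p); stamp(p)
  p <- file.path(dir, "evidence.tsv")
  write_evidence_table(study$evidence, p); stamp(p)
  fa <- file.path(dir, "proteome.fasta")
  writeLines(paste0(">", study$proteome$protein_id, " ",
                    study$proteome$annotation, "\n", study$proteome$sequence),
             fa)
  invisible(dir)
}
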