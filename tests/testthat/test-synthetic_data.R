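test_that("generation is deterministic under a fixed seed", {
  cfg <- synthetic_config(n_proteins = 100, seed = 1)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$proteome, b$proteome)
  expect_identical(a$truth, b$truth)
  expect_identical(as.data.frame(a$predictions), as.data.frame(b$predictions))
  expect_identical(a$detections$entries, b$detections$entries)
  expect_identical(as.data.frame(a$evidence), as.data.frame(b$evidence))
})

test_that("ground truth respects configured proportions and invariants", {
  cfg <- synthetic_config(n_proteins = 500, frac_true_chloroplast = 1, seed = 2)
  pg <- generate_proteome(cfg)
  expect_false(any(pg$truth$true_compartment == "non_plastid"))
  expect_equal(sum(pg$truth$true_mol_fraction), 1, tolerance = 1e-9)
  # plastid-genome proteins are never non-plastid
  cfg2 <- synthetic_config(n_proteins = 1000, frac_true_chloroplast = 0.1,
                           frac_plastid_genome = 0.05, seed = 3)
  pg2 <- generate_proteome(cfg2)
  plastid <- pg2$truth$genome_source == "plastid"
  expect_true(sum(plastid) > 0)
  expect_false(any(pg2$truth$true_compartment[plastid] == "non_plastid"))
  expect_error(synthetic_config(n_proteins = 0), "positive")
  expect_error(synthetic_config(frac_true_chloroplast = 1.2), "\\[0, 1\\]")
})

test_that("log-abundance dispersion matches the configured law", {
  cfg <- synthetic_config(n_proteins = 10000, abundance_logsd = 1, seed = 4)
  pg <- generate_proteome(cfg)
  expect_equal(sd(log(pg$truth$true_abundance)), 1, tolerance = 0.05)
})

test_that("predictor error rates are honoured", {
  # noiseless limit: all five votes for chloroplast proteins, none otherwise
  cfg <- synthetic_config(n_proteins = 200, predictor_sensitivity = 1,
                          predictor_specificity = 1, seed = 5)
  pg <- generate_proteome(cfg)
  pm <- generate_predictions(pg$proteome, pg$truth, cfg)
  atl <- build_atlas(pm)
  chloro <- pg$truth$true_compartment != "non_plastid"
  expect_equal(atl$vote_count[chloro], rep(5L, sum(chloro)))
  expect_equal(atl$vote_count[!chloro], rep(0L, sum(!chloro)))

  # zero sensitivity empties the Atlas of nuclear proteins
  cfg0 <- synthetic_config(n_proteins = 200, predictor_sensitivity = 0,
                           predictor_specificity = 1, seed = 5)
  pm0 <- generate_predictions(pg$proteome, pg$truth, cfg0)
  expect_equal(sum(build_atlas(pm0)$in_atlas), 0L)

  # Monte-Carlo: empirical per-slot sensitivity within 3 points of 0.8
  cfgm <- synthetic_config(n_proteins = 5000, predictor_sensitivity = 0.8,
                           seed = 6)
  pgm <- generate_proteome(cfgm)
  pmm <- generate_predictions(pgm$proteome, pgm$truth, cfgm)
  chloro <- pgm$truth$true_compartment != "non_plastid"
  for (s in predictor_slots()$loc) {
    emp_sens <- mean(pmm[[paste0("loc_", s)]][chloro])
    expect_lt(abs(emp_sens - 0.8), 0.03)
  }
})

test_that("detection probability and PSM law behave at the limits", {
  cfg <- synthetic_config(n_proteins = 50, detection_midpoint = Inf, seed = 7)
  pg <- generate_proteome(cfg)
  dt <- generate_detections(pg$proteome, pg$truth, cfg)
  expect_equal(nrow(dt$entries), 0L)

  cfg1 <- synthetic_config(n_proteins = 50, detection_midpoint = -Inf, seed = 7)
  dt1 <- generate_detections(pg$proteome, pg$truth, cfg1)
  # certain detection: every protein in every one of the 8 samples, psm >= 1
  expect_equal(nrow(dt1$entries), 50L * 8L)
  expect_true(all(dt1$entries$psm_count >= 1L))
  expect_true(all(dt1$entries$psm_count >= dt1$entries$unique_peptide_count))
})

test_that("equal true abundances give equal expected PSM totals", {
  # two identical proteins with identical abundance, 200 replicate draws
  seq_xy <- random_sequence(300)
  proteome <- data.frame(protein_id = c("X", "Y"), genome_source = "nuclear",
                         sequence = seq_xy,
                         annotation = "", stringsAsFactors = FALSE)
  truth <- data.frame(protein_id = c("X", "Y"), genome_source = "nuclear",
                      true_compartment = "stroma", true_abundance = c(2, 2),
                      true_mol_fraction = c(0.5, 0.5), stringsAsFactors = FALSE)
  totals <- c(X = 0, Y = 0)
  for (rep in 1:200) {
    cfg <- synthetic_config(n_proteins = 2, detection_midpoint = -Inf,
                            psm_rate = 5, seed = rep)
    dt <- generate_detections(proteome, truth, cfg)
    agg <- tapply(dt$entries$psm_count, dt$entries$protein_id, sum)
    totals <- totals + agg[c("X", "Y")]
  }
  expect_lt(abs(totals[["X"]] - totals[["Y"]]) / mean(totals), 0.1)
})

test_that("config files round-trip through the key=value reader", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# generator settings", "n_proteins = 123", "seed = 42",
               "abundance_logsd = 1.5"), path)
  cfg <- read_synthetic_config(path)
  expect_equal(cfg$n_proteins, 123L)
  expect_equal(cfg$seed, 42L)
  expect_equal(cfg$abundance_logsd, 1.5)
  writeLines("nonsense = 1", path)
  expect_error(read_synthetic_config(path), "unknown config key")
})

test_that("a synthetic study written to disk reloads through the readers", {
  st <- simulate_study(synthetic_config(n_proteins = 30, seed = 13))
  dir <- withr::local_tempdir()
  write_synthetic_study(st, dir)
  dt <- read_detection_table(file.path(dir, "detections.tsv"))
  expect_equal(sort(unique(dt$entries$protein_id)),
               sort(unique(st$detections$entries$protein_id)))
  pm <- read_prediction_matrix(file.path(dir, "predictions.tsv"))
  expect_equal(nrow(pm), 30L)
  ev <- read_evidence_table(file.path(dir, "evidence.tsv"))
  expect_equal(nrow(ev), 30L)
  fa <- read_fasta_proteome(file.path(dir, "proteome.fasta"))
  expect_equal(fa$sequence, st$proteome$sequence)
  # seed echoed as a comment line
  expect_match(readLines(file.path(dir, "detections.tsv"), n = 1), "seed=13")
})

test_that("the pipeline recovers ground truth under ideal conditions", {
  # ideal detection and noiseless predictors; abundance dispersion kept
  # within emPAI's resolving range (PAI is bounded by the digest size, so a
  # six-decade dispersion would test the index's floor, not the pipeline)
  cfg <- synthetic_config(n_proteins = 500, frac_true_chloroplast = 1,
                          predictor_sensitivity = 1, predictor_specificity = 1,
                          evidence_sensitivity = 0, evidence_specificity = 1,
                          abundance_logsd = 1.5,
                          detection_midpoint = -Inf, psm_rate = 20, seed = 17)
  st <- simulate_study(cfg)
  plastid <- st$proteome[st$proteome$genome_source == "plastid", ]
  res <- run_stromal_pipeline(st$detections, st$predictions, st$evidence,
                              st$proteome, plastid)
  # every true plastid protein lands in the stromal set, none removed
  expect_equal(res$curation$summary$n_removed, 0L)
  expect_equal(res$curation$summary$n_stromal, 500L)
  # abundance ranking recovers the true molar fractions
  m <- merge(res$abundance, st$truth, by = "protein_id")
  rho <- cor(m$true_mol_fraction, m$mol_percent, method = "spearman")
  expect_gt(rho, 0.95)
})
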