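test_that("detection statistics summarize per prep type", {
  dt <- make_detection_table(list(
    singleton = list(1, 0, 1, 1),   # 1 acetone sample, 1 PSM, 1 peptide
    spread = list(2, 1, 5, 3),      # 2/5 acetone + 1/3 gel
    absent = list(0, 0, 5, 3)))     # never detected
  st <- detection_stats(dt)
  expect_setequal(st$protein_id, c("singleton", "spread"))
  s1 <- st[st$protein_id == "singleton", ]
  expect_true(s1$detected_once_with_one_psm)
  expect_equal(s1$total_psm, 1L)
  s2 <- st[st$protein_id == "spread", ]
  expect_false(s2$detected_once_with_one_psm)
  expect_equal(s2$frequency_acetone, 0.40)
  expect_equal(s2$frequency_gel, 1 / 3)
  expect_equal(s2$total_psm, 15L)

  # a prep type with no samples gives an undefined (NA) frequency, not zero
  dt_ace <- make_detection_table(list(p = list(2, 0, 3, 2)),
                                 samples = default_samples(n_gel = 0))
  st_ace <- detection_stats(dt_ace)
  expect_true(is.na(st_ace$frequency_gel))
  expect_equal(st_ace$frequency_acetone, 0.4)
})

test_that("peptide identities pool across samples for the single-peptide rule", {
  samples <- default_samples()
  entries <- data.frame(protein_id = c("P1", "P1"),
                        sample_id = c("acetone_1", "acetone_2"),
                        psm_count = c(3L, 2L),
                        unique_peptide_count = c(1L, 1L))
  entries$peptide_ids <- list("AAAAAK", "CCCCCK")  # different peptides
  st <- detection_stats(detection_table(entries, samples))
  expect_equal(st$total_unique_peptides, 2L)  # pooled distinct, not per-sample
})

test_that("the exclusion rule triggers on singletons, single peptides, and sporadic detection", {
  dt <- make_detection_table(list(
    once = list(1, 0, 1, 1),
    passes = list(2, 0, 10, 3),      # 2/5 acetone = 40% meets the threshold
    sporadic = list(1, 1, 5, 5)))    # 1/5 and 1/3, both below 40%
  fl <- apply_exclusion_rule(detection_stats(dt))
  f <- function(id) fl[fl$protein_id == id, ]
  expect_true(f("once")$flagged)
  expect_setequal(strsplit(f("once")$codes, ";")[[1]],
                  c("SINGLETON_PSM", "SINGLE_PEPTIDE", "SPORADIC"))
  expect_false(f("passes")$flagged)
  expect_true(f("sporadic")$flagged)
  expect_equal(f("sporadic")$codes, "SPORADIC")
})

test_that("retention exceptions rescue flagged proteins", {
  ids <- c("db", "none", "votes")
  dt <- make_detection_table(list(db = list(1, 0, 1, 1), none = list(1, 0, 1, 1),
                                  votes = list(1, 0, 1, 1)))
  fl <- apply_exclusion_rule(detection_stats(dt))
  ev <- make_evidence(ids, chl = c(TRUE, FALSE, FALSE))
  atl <- make_atlas(ids, votes = c(0L, 0L, 2L))
  ret <- apply_retention_exceptions(fl, ev, atl)
  r <- function(id) ret[ret$protein_id == id, ]
  expect_true(r("db")$retained)
  expect_match(r("db")$codes, "EXC_DB_EVIDENCE")
  expect_false(r("none")$retained)
  expect_false(grepl("EXC_", r("none")$codes))
  expect_true(r("votes")$retained)
  expect_match(r("votes")$codes, "EXC_ATLAS_VOTES")
})

test_that("stromal/CIP classification gives chloroplast evidence precedence", {
  ids <- c("cip", "both", "predicted")
  ev <- make_evidence(ids, chl = c(FALSE, TRUE, FALSE),
                      other = c(TRUE, TRUE, FALSE))
  atl <- make_atlas(ids, votes = c(0L, 0L, 4L))
  cls <- classify_stromal_cip(ids, ev, atl)
  expect_equal(cls$status, c("CIP", "stromal", "stromal"))
})

test_that("curation partitions every detected protein exactly once", {
  st <- simulate_study(synthetic_config(n_proteins = 400, seed = 9))
  atl <- build_atlas(st$predictions,
                     st$proteome[st$proteome$genome_source == "plastid", ])
  cur <- curate(st$detections, st$evidence, atl)
  res <- cur$result
  expect_equal(nrow(res), length(unique(st$detections$entries$protein_id)))
  expect_true(all(res$status %in% c("stromal", "CIP", "removed")))
  expect_equal(cur$summary$n_stromal + cur$summary$n_cip + cur$summary$n_removed,
               cur$summary$n_detected)
  # removed implies an exclusion code and no exception code
  rem <- res[res$status == "removed", ]
  expect_true(all(grepl("SINGLETON_PSM|SINGLE_PEPTIDE|SPORADIC", rem$reason_codes)))
  expect_false(any(grepl("EXC_", rem$reason_codes)))
  # CIP implies its code
  expect_true(all(grepl("CIP_OTHER_COMPARTMENT",
                        res$reason_codes[res$status == "CIP"])))
})

test_that("curation matches an exhaustive rule-table oracle", {
  # one synthetic protein per achievable combination of the rule inputs
  grid <- expand.grid(a = c(0L, 1L, 2L, 3L, 5L), g = c(0L, 1L, 3L),
                      psm = c(1L, 3L), upep = c(1L, 3L),
                      chl = c(TRUE, FALSE), lit = c(TRUE, FALSE),
                      votes = c(0L, 2L), other = c(TRUE, FALSE))
  grid <- grid[grid$a + grid$g > 0 & grid$psm >= grid$upep, ]
  ids <- sprintf("case%03d", seq_len(nrow(grid)))
  spec <- lapply(seq_len(nrow(grid)), function(i) {
    list(grid$a[i], grid$g[i], grid$psm[i], grid$upep[i])
  })
  names(spec) <- ids
  dt <- make_detection_table(spec)
  ev <- make_evidence(ids, chl = grid$chl, lit = grid$lit, other = grid$other)
  atl <- make_atlas(ids, votes = grid$votes)
  res <- curate(dt, ev, atl)$result
  res <- res[match(ids, res$protein_id), ]

  # independent first-principles evaluation of the published rule
  n_det <- grid$a + grid$g
  singleton <- n_det == 1L & grid$psm == 1L
  sporadic <- (grid$a / 5 < 0.40) & (grid$g / 3 < 0.40)
  flagged <- singleton | grid$upep == 1L | sporadic
  retained <- !flagged | grid$chl | grid$lit | grid$votes >= 2L
  cip <- retained & grid$other & !grid$chl & !grid$lit & grid$votes < 2L
  expected <- ifelse(!retained, "removed", ifelse(cip, "CIP", "stromal"))
  expect_equal(res$status, expected)
  expect_equal(res$flagged, unname(flagged))
})

test_that("adding evidence or spectra never demotes a protein", {
  dt <- make_detection_table(list(p = list(1, 0, 1, 1)))
  atl <- make_atlas("p", votes = 0L)
  base <- curate(dt, make_evidence("p", other = TRUE), atl)$result$status
  expect_equal(base, "removed")
  # chloroplast evidence can only promote: removed -> stromal
  with_chl <- curate(dt, make_evidence("p", chl = TRUE, other = TRUE),
                     atl)$result$status
  expect_equal(with_chl, "stromal")
  # more spectra can only promote: removed -> retained
  dt2 <- make_detection_table(list(p = list(4, 2, 6, 4)))
  more <- curate(dt2, make_evidence("p", other = FALSE), atl)$result$status
  expect_equal(more, "stromal")
  rank_of <- c(removed = 0, CIP = 1, stromal = 2)
  expect_true(rank_of[with_chl] >= rank_of[base])
  expect_true(rank_of[more] >= rank_of[base])
})

test_that("proteins missing from evidence or Atlas are treated as all-negative", {
  dt <- make_detection_table(list(known = list(5, 3, 10, 5),
                                  orphan = list(5, 3, 10, 5)))
  ev <- make_evidence("known")
  atl <- make_atlas("known", votes = 3L)
  expect_warning(cur <- curate(dt, ev, atl), "all-negative")
  res <- cur$result
  expect_equal(res$status[res$protein_id == "orphan"], "stromal")  # reproducible, no adverse evidence
})
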