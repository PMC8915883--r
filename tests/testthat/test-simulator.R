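# Synthetic V(D)J cohort generator: determinism, structural features,
# enrichment injection.

small_config <- function(...) {
  simulation_config(n_donors_case = 3, n_donors_control = 3,
                    clonotypes_per_repertoire = 300, seed = 42, ...)
}

test_that("same config and seed reproduce a repertoire exactly", {
  cfg <- small_config()
  r1 <- simulate_repertoire(cfg, "d1", "case")
  r2 <- simulate_repertoire(cfg, "d1", "case")
  expect_identical(r1$clonotypes, r2$clonotypes)
  # a different donor gets a different draw from its own stream
  r3 <- simulate_repertoire(cfg, "d2", "case")
  expect_false(identical(r1$clonotypes$cdr3_nt, r3$clonotypes$cdr3_nt))
})

test_that("cohorts have the requested arm sizes and are reproducible", {
  cfg <- small_config()
  cohort <- simulate_cohort(cfg)
  expect_length(cohort, 6L)
  conditions <- vapply(cohort, function(r) r$condition, character(1))
  expect_equal(sum(conditions == "case"), 3L)
  expect_equal(sum(conditions == "control"), 3L)
  expect_length(unique(vapply(cohort, function(r) r$donor_id, character(1))),
                6L)
  again <- simulate_cohort(cfg)
  for (i in seq_along(cohort)) {
    expect_identical(cohort[[i]]$clonotypes, again[[i]]$clonotypes)
  }
  expect_error(
    simulate_cohort(simulation_config(n_donors_case = 0)),
    class = "tcrcomp_config_error"
  )
})

test_that("generated nucleotide and protein sequences stay consistent", {
  cfg <- small_config(nonfunctional_rate = 0.3)
  rep <- simulate_repertoire(cfg, "d1", "control")
  expect_identical(rep$clonotypes$cdr3_aa,
                   translate_cdr3(rep$clonotypes$cdr3_nt))
})

test_that("nonfunctional_rate 0 leaves nothing for filter_functional", {
  cfg <- small_config(nonfunctional_rate = 0)
  rep <- simulate_repertoire(cfg, "d1", "control")
  expect_identical(suppressMessages(filter_functional(rep))$clonotypes,
                   rep$clonotypes)
})

test_that("functional synthetic CDR3s keep the C...F anchors", {
  cfg <- small_config(nonfunctional_rate = 0.2)
  for (cond in c("case", "control")) {
    rep <- suppressMessages(filter_functional(
      simulate_repertoire(cfg, "d1", cond)))
    expect_true(all(startsWith(rep$clonotypes$cdr3_aa, "C")))
    expect_true(all(endsWith(rep$clonotypes$cdr3_aa, "F")))
    pos1 <- positional_occurrence(rep, max_position = 1)
    expect_equal(pos1$occurrence[pos1$amino_acid == "C"], 100)
  }
})

test_that("positional enrichment realizes the requested effect at large n", {
  cfg <- simulation_config(
    clonotypes_per_repertoire = 50000, seed = 7,
    enrichments = list(enrichment("positional", "W", position = 5,
                                  effect = 15))
  )
  case <- suppressMessages(filter_functional(
    simulate_repertoire(cfg, "big", "case")))
  ctrl <- suppressMessages(filter_functional(
    simulate_repertoire(cfg, "big", "control")))
  wc <- positional_occurrence(case, max_position = 5)
  wk <- positional_occurrence(ctrl, max_position = 5)
  diff <- wc$occurrence[wc$position == 5 & wc$amino_acid == "W"] -
    wk$occurrence[wk$position == 5 & wk$amino_acid == "W"]
  expect_lt(abs(diff - 15), 1.5)
})

test_that("containment and segment enrichments shift their targets", {
  # donor_usage_noise = Inf switches off per-donor segment jitter so the
  # realized shift isolates the enrichment mechanism
  cfg <- simulation_config(
    clonotypes_per_repertoire = 20000, seed = 13, donor_usage_noise = Inf,
    enrichments = list(
      enrichment("containment", "K", effect = 12),
      enrichment("segment_usage", "TRBV20-1", effect = 8)
    )
  )
  case <- suppressMessages(filter_functional(
    simulate_repertoire(cfg, "big", "case")))
  ctrl <- suppressMessages(filter_functional(
    simulate_repertoire(cfg, "big", "control")))
  k_case <- aa_occurrence(case)
  k_ctrl <- aa_occurrence(ctrl)
  k_diff <- k_case$occurrence[k_case$amino_acid == "K"] -
    k_ctrl$occurrence[k_ctrl$amino_acid == "K"]
  expect_lt(abs(k_diff - 12), 2)
  v_case <- segment_usage(case, "V")
  v_ctrl <- segment_usage(ctrl, "V")
  v_diff <- v_case$usage[v_case$segment == "TRBV20-1"] -
    v_ctrl$usage[v_ctrl$segment == "TRBV20-1"]
  expect_lt(abs(v_diff - 8), 2)
})

test_that("without enrichment, case and control arms share one generative law", {
  cfg <- simulation_config(clonotypes_per_repertoire = 50000, seed = 3,
                           donor_usage_noise = Inf)
  case <- suppressMessages(filter_functional(
    simulate_repertoire(cfg, "null", "case")))
  ctrl <- suppressMessages(filter_functional(
    simulate_repertoire(cfg, "null", "control")))
  oc <- aa_occurrence(case)$occurrence
  ok <- aa_occurrence(ctrl)$occurrence
  expect_lt(max(abs(oc - ok)), 1)
})

test_that("infeasible enrichments are rejected as configuration errors", {
  expect_error(enrichment("positional", "W", position = 1, effect = 10),
               class = "tcrcomp_config_error")
  expect_error(enrichment("containment", "K", effect = 120),
               class = "tcrcomp_config_error")
  cfg <- small_config(
    enrichments = list(enrichment("containment", "A", effect = 99.9))
  )
  # nearly every clonotype already contains alanine: not enough candidates
  expect_error(simulate_repertoire(cfg, "d1", "case"),
               class = "tcrcomp_config_error")
  cfg2 <- small_config(
    enrichments = list(enrichment("segment_usage", "TRBV999", effect = 5))
  )
  expect_error(simulate_repertoire(cfg2, "d1", "case"),
               class = "tcrcomp_config_error")
})

test_that("clone sizes are skewed and independent of CDR3 content", {
  cfg <- simulation_config(clonotypes_per_repertoire = 50000, seed = 9)
  rep <- suppressMessages(filter_functional(
    simulate_repertoire(cfg, "d1", "control")))
  counts <- rep$clonotypes$count
  expect_gt(max(counts), 50)          # heavy tail
  expect_gt(mean(counts == 1), 0.5)   # most clones unexpanded
  # clone size is independent of CDR3 content: counts are uncorrelated
  # with residue containment, so weighted profiles agree in expectation
  for (letter in c("K", "W", "D")) {
    has <- as.numeric(grepl(letter, rep$clonotypes$cdr3_aa, fixed = TRUE))
    expect_lt(abs(cor(counts, has)), 0.05)
  }
})

test_that("written cohorts round-trip through the manifest reader", {
  dir <- withr::local_tempdir()
  cfg <- small_config(nonfunctional_rate = 0)
  cohort <- simulate_cohort(cfg)
  manifest <- write_cohort(cohort, dir)
  expect_true(file.exists(manifest))
  back <- suppressMessages(read_cohort(manifest, prepare = FALSE))
  expect_length(back, length(cohort))
  expect_equal(back[[1]]$clonotypes$cdr3_nt, cohort[[1]]$clonotypes$cdr3_nt)
  expect_equal(back[[1]]$donor_id, cohort[[1]]$donor_id)
})
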