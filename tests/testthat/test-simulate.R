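# Synthetic-study generator: determinism, planted-effect recovery,
# intron regimes, NMD arithmetic, truth-ledger completeness.

test_that("a fixed seed fixes every emitted byte", {
  cfg <- sim_config(seed = 9, n_genes = 10, effects = default_effects()[1:6, ],
                    n_null_events = 6)
  ref1 <- simulate_reference(cfg)
  ref2 <- simulate_reference(cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write_genome(ref1$genome, f1); write_genome(ref2$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
  g1 <- tempfile(); g2 <- tempfile()
  write_annotation(ref1$models, g1); write_annotation(ref2$models, g2)
  expect_identical(readLines(g1), readLines(g2))

  sim1 <- simulate_cohort(ref1, cfg)
  sim2 <- simulate_cohort(ref2, cfg)
  expect_identical(sim1$junctions$junctions, sim2$junctions$junctions)
  # and the RNG state of the caller is untouched
  withr::with_seed(1, {
    before <- runif(1)
  })
  withr::with_seed(1, {
    invisible(simulate_cohort(ref1, cfg))
    after <- runif(1)
  })
  expect_identical(before, after)
})

test_that("the configured number of genes is emitted", {
  cfg <- sim_config(seed = 2, n_genes = 30, effects = NULL, n_null_events = 10,
                    emit_sequences = FALSE)
  ref <- simulate_reference(cfg)
  expect_equal(nrow(ref$models$genes), 30)
  expect_null(ref$genome)
})

test_that("intron regimes realize the configured medians and GC", {
  cfg <- sim_config(seed = 4, n_genes = 500, effects = NULL, n_null_events = 0,
                    exons_per_gene = c(5L, 6L))
  ref <- simulate_reference(cfg)
  reg <- ref$intron_regime %>%
    mutate(length = end - start + 1)
  med <- tapply(reg$length, reg$regime, median)
  expect_lt(abs(med[["short_gc_rich"]] - 410) / 410, 0.2)
  expect_lt(abs(med[["long_gc_poor"]] - 1800) / 1800, 0.2)
  # GC of the realized sequences
  gc <- vapply(seq_len(nrow(reg)), function(i) {
    s <- substring(ref$genome[[reg$chrom[i]]], reg$start[i], reg$end[i])
    sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
  }, numeric(1))
  gcm <- tapply(gc, reg$regime, median)
  expect_lt(abs(gcm[["short_gc_rich"]] - 0.54), 0.03)
  expect_lt(abs(gcm[["long_gc_poor"]] - 0.43), 0.03)
})

test_that("null config yields no group PSI difference; planted effects recover", {
  eff <- tibble(type = "alt_3ss", group = "SF3B1:K700E", baseline_psi = 40,
                delta_psi = 30, consequence = "non_truncating", nmd_d = 1,
                expr_fc = 1)
  cfg <- sim_config(seed = 12, n_genes = 30, effects = eff, n_null_events = 25,
                    cohort = tibble(group = c("SF3B1:K700E", "none"),
                                    cell_fraction = "CD34", n = c(30, 30)),
                    emit_sequences = FALSE)
  ref <- simulate_reference(cfg)
  sim <- simulate_cohort(ref, cfg)
  psi <- compute_psi(sim$events, sim$junctions)
  by_group <- psi %>%
    left_join(sim$sheet %>% select(sample_id, genotype), by = "sample_id") %>%
    group_by(event_id, genotype) %>%
    summarise(m = mean(psi, na.rm = TRUE), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = genotype, values_from = m) %>%
    left_join(sim$truth %>% select(event_id, delta_psi, baseline_psi),
              by = "event_id")
  nulls <- by_group %>% filter(delta_psi == 0)
  expect_lt(max(abs(nulls$`SF3B1:K700E` - nulls$none)), 8)
  expect_lt(abs(mean(nulls$`SF3B1:K700E` - nulls$none)), 2)
  planted <- by_group %>% filter(delta_psi == 30)
  expect_lt(abs(planted$`SF3B1:K700E` - 70), 5)
  expect_lt(abs(planted$none - 40), 5)
})

test_that("NMD thinning matches the closed-form isoform mixture", {
  # d = 0.25, aberrant PSI 40% -> untreated observed PSI
  # 0.25*40 / (0.25*40 + 60) * 100 = 14.29
  eff <- tibble(type = "alt_3ss", group = "SF3B1:K700E", baseline_psi = 40,
                delta_psi = 0, consequence = "truncating_ptc", nmd_d = 0.25,
                expr_fc = 1)
  cfg <- sim_config(seed = 13, n_genes = 2, effects = eff,
                    cohort = tibble(group = "SF3B1:K700E",
                                    cell_fraction = "BMMNC", n = 30),
                    depth_mean = 500, depth_size = 100, rho = 0.002,
                    emit_sequences = FALSE)
  ref <- simulate_reference(cfg)
  chx <- simulate_chx_experiment(ref, cfg, n_pairs = 8, depth_mean = 500)
  psi <- compute_psi(chx$events, chx$junctions)
  st <- psi %>%
    left_join(chx$sheet %>% select(sample_id, chx_status), by = "sample_id") %>%
    group_by(chx_status) %>%
    summarise(m = mean(psi, na.rm = TRUE))
  expect_lt(abs(st$m[st$chx_status == "untreated"] - 14.29), 3)
  expect_lt(abs(st$m[st$chx_status == "treated"] - 40), 3)
})

test_that("d = 1 leaves treated and untreated PSI distributions identical", {
  eff <- tibble(type = "alt_3ss", group = "SF3B1:K700E", baseline_psi = 50,
                delta_psi = 0, consequence = "non_truncating", nmd_d = 1,
                expr_fc = 1, .rows = 40)
  cfg <- sim_config(seed = 14, n_genes = 40, effects = eff,
                    emit_sequences = FALSE,
                    cohort = tibble(group = "SF3B1:K700E",
                                    cell_fraction = "BMMNC", n = 4))
  ref <- simulate_reference(cfg)
  chx <- simulate_chx_experiment(ref, cfg, n_pairs = 6)
  psi <- compute_psi(chx$events, chx$junctions) %>%
    left_join(chx$sheet %>% select(sample_id, chx_status), by = "sample_id")
  ks <- suppressWarnings(ks.test(psi$psi[psi$chx_status == "treated"],
                                 psi$psi[psi$chx_status == "untreated"]))
  expect_gt(ks$p.value, 0.01)
})

test_that("d = 0 events are invisible untreated and visible treated", {
  eff <- tibble(type = "alt_3ss", group = "SF3B1:K700E", baseline_psi = 40,
                delta_psi = 0, consequence = "truncating_ptc", nmd_d = 0,
                expr_fc = 1)
  cfg <- sim_config(seed = 15, n_genes = 2, effects = eff,
                    emit_sequences = FALSE, depth_mean = 200,
                    cohort = tibble(group = "SF3B1:K700E",
                                    cell_fraction = "BMMNC", n = 4))
  ref <- simulate_reference(cfg)
  chx <- simulate_chx_experiment(ref, cfg, n_pairs = 4)
  psi <- compute_psi(chx$events, chx$junctions) %>%
    left_join(chx$sheet %>% select(sample_id, chx_status), by = "sample_id") %>%
    filter(event_id == ref$truth$event_id[1])
  expect_true(all(psi$inclusion_reads[psi$chx_status == "untreated"] == 0))
  expect_true(all(psi$inclusion_reads[psi$chx_status == "treated"] > 0))
})

test_that("the truth ledger is complete and unique", {
  st <- small_study(seed = 30)
  expect_true(all(st$ref$truth$event_id %in% st$ref$events$event_id))
  expect_equal(anyDuplicated(st$ref$truth$event_id), 0)
  planted <- st$ref$truth %>% filter(delta_psi != 0)
  expect_equal(nrow(planted), nrow(st$cfg$effects))
  expect_true(all(planted$baseline_psi + planted$delta_psi >= 0))
  expect_true(all(planted$baseline_psi + planted$delta_psi <= 100))
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(rho = 1.2), "rho")
  expect_error(sim_config(cohort = tibble(group = "g", cell_fraction = "CD34",
                                          n = 1)), ">= 2")
  expect_error(sim_config(effects = tibble(type = "alt_3ss", group = "nope",
                                           baseline_psi = 1, delta_psi = 30,
                                           consequence = "non_truncating",
                                           nmd_d = 1, expr_fc = 1)),
               "absent from cohort")
  expect_error(sim_config(effects = tibble(type = "alt_3ss",
                                           group = "SF3B1:K700E",
                                           baseline_psi = 90, delta_psi = 30,
                                           consequence = "non_truncating",
                                           nmd_d = 1, expr_fc = 1)),
               "within")
  cfg <- sim_config(seed = 1, n_genes = 2)
  expect_error(simulate_reference(cfg), "effect table")
})
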