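# CMH statistic, CHX response testing and CHX-specific discovery.

test_that("single-stratum CMH equals (T-1)/T times the Pearson chi-square", {
  tb <- matrix(c(30, 70, 10, 90), nrow = 2, byrow = TRUE)
  r <- cmh_test(list(tb))
  pearson <- suppressWarnings(chisq.test(tb, correct = FALSE))$statistic
  tt <- sum(tb)
  expect_equal(r$statistic, unname(pearson) * (tt - 1) / tt, tolerance = 1e-12)
})

test_that("CMH is stratum-order invariant and matches mantelhaen.test", {
  withr::with_seed(13, {
    tabs <- replicate(4, matrix(rpois(4, 40) + 1, 2), simplify = FALSE)
  })
  r1 <- cmh_test(tabs)
  r2 <- cmh_test(rev(tabs))
  expect_equal(r1$statistic, r2$statistic)
  arr <- array(unlist(tabs), dim = c(2, 2, 4))
  mh <- mantelhaen.test(arr, correct = FALSE)
  expect_equal(r1$statistic, unname(mh$statistic), tolerance = 1e-12)
  expect_equal(r1$p, mh$p.value, tolerance = 1e-12)
})

test_that("zero-margin strata are dropped and an all-zero test is null", {
  tabs <- list(matrix(c(0, 0, 5, 7), 2), matrix(c(3, 1, 4, 6), 2))
  r <- cmh_test(tabs)
  expect_equal(r$k_dropped, 1)
  expect_equal(r$k_used, 1)
  r0 <- cmh_test(list(matrix(c(0, 0, 5, 7), 2)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
})

test_that("pooling identical strata into one raises the statistic", {
  tb <- matrix(c(30, 70, 10, 90), nrow = 2, byrow = TRUE)
  k_sep <- cmh_test(rep(list(tb), 4))$statistic
  pooled <- cmh_test(list(tb * 4))$statistic
  # pooled total T is larger so the (T-1)/T correction loses less
  expect_gt(pooled, k_sep)
  expect_lt(pooled - k_sep, 0.5)
})

chx_fixture <- function(seed, d = 0.25, n_events = 6, n_pairs = 4,
                        depth = 500) {
  eff <- tibble(type = "alt_3ss", group = "SF3B1:K700E", baseline_psi = 40,
                delta_psi = 0, consequence = "truncating_ptc", nmd_d = d,
                expr_fc = 1, .rows = n_events)
  cfg <- sim_config(seed = seed, n_genes = n_events, effects = eff,
                    emit_sequences = FALSE, depth_size = 50,
                    cohort = tibble(group = "SF3B1:K700E",
                                    cell_fraction = "BMMNC", n = 4))
  ref <- simulate_reference(cfg)
  chx <- simulate_chx_experiment(ref, cfg, n_pairs = n_pairs,
                                 depth_mean = depth)
  list(ref = ref, chx = chx,
       psi = compute_psi(chx$events, chx$junctions))
}

test_that("identical treated/untreated data give null results in both methods", {
  psi <- tibble(
    event_id = "e1", sample_id = c("u1", "u2", "u3", "t1", "t2", "t3"),
    inclusion_reads = 20, exclusion_reads = 30, total_reads = 50,
    psi = 40
  )
  sheet <- sample_sheet(c("u1", "u2", "u3", "t1", "t2", "t3"), "BMMNC",
                        "SF3B1:K700E",
                        chx_status = rep(c("untreated", "treated"), each = 3),
                        pair_id = rep(c("p1", "p2", "p3"), 2))
  pt <- chx_response_test(psi, sheet, method = "paired_t")
  expect_equal(pt$p, 1)
  expect_false(pt$nmd_sensitive)
  cm <- chx_response_test(psi, sheet, method = "cmh")
  expect_equal(cm$statistic, 0)
  expect_equal(cm$p, 1)
})

test_that("NMD-degraded events are flagged sensitive, stable events are not", {
  fx <- chx_fixture(seed = 51, d = 0.25)
  r <- chx_response_test(fx$psi, fx$chx$sheet, method = "cmh")
  expect_true(all(r$nmd_sensitive))
  expect_true(all(r$psi_fc_chx > 1.5))
  fx1 <- chx_fixture(seed = 52, d = 1)
  r1 <- chx_response_test(fx1$psi, fx1$chx$sheet, method = "cmh")
  expect_true(all(!r1$nmd_sensitive))
  # paired t agrees on the strong depletion case
  rt <- chx_response_test(fx$psi, fx$chx$sheet, method = "paired_t")
  expect_true(all(rt$mean_psi_treated > rt$mean_psi_untreated))
})

test_that("sensitivity concentrates in truncating events by construction", {
  eff <- bind_rows(
    tibble(type = "alt_3ss", group = "SF3B1:K700E", baseline_psi = 40,
           delta_psi = 0, consequence = "truncating_ptc", nmd_d = 0.25,
           expr_fc = 1, .rows = 5),
    tibble(type = "alt_3ss", group = "SF3B1:K700E", baseline_psi = 40,
           delta_psi = 0, consequence = "non_truncating", nmd_d = 1,
           expr_fc = 1, .rows = 12)
  )
  cfg <- sim_config(seed = 53, n_genes = 17, effects = eff,
                    emit_sequences = FALSE, depth_size = 50,
                    cohort = tibble(group = "SF3B1:K700E",
                                    cell_fraction = "BMMNC", n = 4))
  ref <- simulate_reference(cfg)
  chx <- simulate_chx_experiment(ref, cfg, n_pairs = 4, depth_mean = 500)
  psi <- compute_psi(chx$events, chx$junctions)
  r <- chx_response_test(psi, chx$sheet, method = "cmh")
  cons <- ref$truth %>%
    transmute(event_id, class = sub("_(ptc|frameshift)$", "", consequence))
  cls <- classify_nmd_sensitivity(r, cons)
  sens <- cls$events %>% filter(nmd_sensitive)
  expect_true(all(sens$class == "truncating"))
  nt <- cls$events %>% filter(class == "non_truncating")
  expect_true(median(nt$psi_fc_chx) > 0.9 && median(nt$psi_fc_chx) < 1.1)
  expect_true(all(c("class", "nmd_sensitive", "n") %in% names(cls$table)))
})

test_that("d = 0 events are discovered as CHX-specific, others are not", {
  eff <- bind_rows(
    tibble(type = "alt_3ss", group = "SF3B1:K700E", baseline_psi = 40,
           delta_psi = 0, consequence = "truncating_ptc", nmd_d = 0,
           expr_fc = 1, .rows = 5),
    tibble(type = "alt_3ss", group = "SF3B1:K700E", baseline_psi = 40,
           delta_psi = 0, consequence = "truncating_ptc", nmd_d = 0.5,
           expr_fc = 1, .rows = 5)
  )
  cfg <- sim_config(seed = 54, n_genes = 10, effects = eff,
                    emit_sequences = FALSE, depth_mean = 200, depth_size = 50,
                    cohort = tibble(group = "SF3B1:K700E",
                                    cell_fraction = "BMMNC", n = 4))
  ref <- simulate_reference(cfg)
  chx <- simulate_chx_experiment(ref, cfg, n_pairs = 4, depth_mean = 200)
  psi <- compute_psi(chx$events, chx$junctions)
  spec <- discover_chx_specific_events(psi, chx$sheet)
  d0 <- ref$truth$event_id[ref$truth$nmd_d == 0]
  expect_setequal(spec$event_id, d0)
  # an event detected in one primary sample is excluded
  prim <- psi %>%
    filter(event_id == d0[1]) %>%
    slice(1) %>%
    mutate(inclusion_reads = 10, total_reads = 50)
  spec2 <- discover_chx_specific_events(psi, chx$sheet, psi_primary = prim)
  expect_false(d0[1] %in% spec2$event_id)
  expect_true(all(setdiff(d0, d0[1]) %in% spec2$event_id))
})
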