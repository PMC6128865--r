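# Target nomination: Fisher mutual exclusivity, the filter cascade,
# clone recapitulation, expression-PSI association.

test_that("Fisher exact matches published and enumerated values", {
  # the Q157-vs-S34 EZH2 alteration table
  t1 <- matrix(c(13, 53, 0, 32), nrow = 2, byrow = TRUE)
  r1 <- mutual_exclusivity_test(t1)
  expect_equal(round(r1$p, 3), 0.008)
  # perfect diagonal 5/5: 2 / choose(10, 5)
  r2 <- mutual_exclusivity_test(matrix(c(5, 0, 0, 5), 2))
  expect_equal(r2$p, 2 / choose(10, 5), tolerance = 1e-12)
  # symmetric table
  expect_equal(mutual_exclusivity_test(matrix(1, 2, 2))$p, 1)
})

test_that("Fisher p equals brute-force hypergeometric enumeration", {
  brute_fisher <- function(tb) {
    m <- sum(tb[1, ]); n <- sum(tb[2, ]); k <- sum(tb[, 1])
    xs <- max(0, k - n):min(k, m)
    probs <- dhyper(xs, m, n, k)
    obs <- dhyper(tb[1, 1], m, n, k)
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
  withr::with_seed(71, {
    for (i in 1:25) {
      tb <- matrix(rpois(4, sample(c(2, 10, 40), 1)), 2)
      if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) next
      expect_equal(mutual_exclusivity_test(tb)$p, brute_fisher(tb),
                   tolerance = 1e-7)
    }
  })
})

test_that("zero margins and zero cells are handled", {
  r <- mutual_exclusivity_test(matrix(c(0, 0, 3, 4), nrow = 2, byrow = TRUE))
  expect_equal(r$p, 1)
  expect_true(r$zero_margin)
  r2 <- mutual_exclusivity_test(matrix(c(13, 53, 0, 32), 2, byrow = TRUE))
  # Haldane-corrected odds ratio for the zero cell
  expect_equal(r2$odds_ratio, (13.5 * 32.5) / (53.5 * 0.5), tolerance = 1e-12)
  expect_error(mutual_exclusivity_test(matrix(c(1, -1, 2, 3), 2)))
})

fake_diff <- function(mean_mut, mean_ctrl, significant = TRUE) {
  tibble(event_id = paste0("e", seq_along(mean_mut)),
         mean_psi_mut = mean_mut, mean_psi_ctrl = mean_ctrl,
         significant = significant)
}

test_that("the filter cascade applies its thresholds as stated", {
  d <- fake_diff(c(12, 8, 15), c(5, 2, 9))
  chx <- tibble(event_id = "e2", sample_id = "x", inclusion_reads = 9,
                exclusion_reads = 91, total_reads = 100, psi = 9)
  out <- functional_target_filter(d, psi_chx = chx)
  # e1: 12 > 2*5 and 12 > 10 -> pass
  expect_true("e1" %in% out$event_id)
  # e2: mean 8 primary and 9 CHX -> fails the PSI floor
  expect_false("e2" %in% out$event_id)
  # e3: 15 < 2*9 -> fails the fold rule
  expect_false("e3" %in% out$event_id)
  # CHX rescue: barely detected primary, evident after CHX
  d2 <- fake_diff(4, 0.5)
  chx2 <- chx %>% mutate(event_id = "e1", psi = 30)
  expect_true(nrow(functional_target_filter(d2, psi_chx = chx2)) == 1)
  expect_equal(nrow(functional_target_filter(d2, psi_chx = NULL)), 0)
})

test_that("the cascade is monotone in its thresholds", {
  withr::with_seed(72, {
    d <- fake_diff(runif(50, 0, 40), runif(50, 0, 15),
                   significant = runif(50) < 0.6)
  })
  strict <- functional_target_filter(d, config = target_filter_config(
    min_mean_psi = 15, min_fold = 3
  ))
  relaxed <- functional_target_filter(d, config = target_filter_config(
    min_mean_psi = 8, min_fold = 2
  ))
  expect_true(all(strict$event_id %in% relaxed$event_id))
})

test_that("recapitulation requires significance and direction agreement", {
  sheet <- sample_sheet(paste0("c", 1:6), "cell_line",
                        rep(c("SF3B1:K700E", "none"), each = 3),
                        clone_id = paste0("clone", 1:6))
  mk_psi <- function(vals) {
    tibble(event_id = "e1", sample_id = paste0("c", 1:6),
           inclusion_reads = 1, exclusion_reads = 1, total_reads = 2,
           psi = vals)
  }
  prim_up <- tibble(event_id = "e1", direction = "up_in_mutant")
  # clones strongly up -> consistent
  r <- recapitulation_test(mk_psi(c(60, 62, 61, 30, 31, 29)), sheet, prim_up)
  expect_true(r$consistent)
  # clones strongly down while primary up -> not consistent
  r2 <- recapitulation_test(mk_psi(c(30, 31, 29, 60, 62, 61)), sheet, prim_up)
  expect_false(r2$consistent)
  expect_lt(r2$p, 0.05)
  # indistinguishable clones -> not consistent
  r3 <- recapitulation_test(mk_psi(c(50, 51, 49, 50, 51, 49)), sheet, prim_up)
  expect_false(r3$consistent)
  expect_error(recapitulation_test(mk_psi(rep(50, 6)), sheet[1:3, ], prim_up),
               ">= 2 clones")
})

eff_ids <- function(ref) ref$truth$event_id[ref$truth$delta_psi != 0]

test_that("planted clone effects are recapitulated; nulls are not", {
  eff <- tibble(type = "alt_3ss", group = "SF3B1:K700E", baseline_psi = 30,
                delta_psi = 30, consequence = "non_truncating", nmd_d = 1,
                expr_fc = 1, .rows = 10)
  cfg <- sim_config(seed = 73, n_genes = 60, effects = eff, n_null_events = 45,
                    emit_sequences = FALSE, depth_mean = 300,
                    cohort = tibble(group = c("SF3B1:K700E", "none"),
                                    cell_fraction = "CD34", n = c(10, 10)))
  ref <- simulate_reference(cfg)
  clones <- simulate_clones(ref, cfg, n_mut = 3, n_wt = 3)
  psi <- compute_psi(clones$events, clones$junctions)
  prim <- ref$truth %>%
    transmute(event_id, direction = ifelse(delta_psi >= 0, "up_in_mutant",
                                           "down_in_mutant"))
  r <- recapitulation_test(psi, clones$sheet, prim)
  planted <- r %>% filter(event_id %in% eff_ids(ref))
  expect_gte(mean(planted$consistent), 0.9)
  nulls <- r %>% filter(!event_id %in% eff_ids(ref))
  expect_lte(mean(nulls$consistent), 0.1)
})

test_that("expression-PSI association is calibrated and powered", {
  withr::with_seed(74, {
    n_ev <- 26; n_s <- 16
    ids <- paste0("e", seq_len(n_ev))
    events <- tibble(event_id = ids, gene_id = paste0("g", seq_len(n_ev)))
    expr <- tidyr::crossing(gene_id = events$gene_id,
                            sample_id = paste0("s", seq_len(n_s))) %>%
      mutate(log2_expr = rnorm(n(), 8, 1))
    psi_null <- expr %>%
      left_join(events, by = "gene_id") %>%
      transmute(event_id, sample_id, inclusion_reads = 1, exclusion_reads = 1,
                total_reads = 2, psi = rnorm(n(), 30, 5))
    out <- expression_psi_association(psi_null, expr, events, ids)
    expect_equal(nrow(out$per_event), n_ev)
    expect_gt(out$pooled$p_wald, 0.001)
    # per-event p-values roughly uniform under the null
    expect_gt(mean(out$per_event$p_wald > 0.05), 0.8)
    # planted dependence is detected
    psi_dep <- psi_null %>%
      left_join(events, by = "event_id") %>%
      left_join(expr, by = c("gene_id", "sample_id")) %>%
      transmute(event_id, sample_id, inclusion_reads, exclusion_reads,
                total_reads, psi = 30 + 3 * (log2_expr - 8) + rnorm(n(), 0, 1))
    out2 <- expression_psi_association(psi_dep, expr, events, ids)
    expect_lt(out2$pooled$p_wald, 0.01)
    expect_gt(out2$pooled$slope, 2)
    # constant expression is skipped
    expr_const <- expr %>% mutate(log2_expr = 8)
    out3 <- expression_psi_association(psi_null, expr_const, events, ids)
    expect_equal(nrow(out3$per_event), 0)
  })
})

test_that("the purity restriction drops low-purity samples", {
  events <- tibble(event_id = "e1", gene_id = "g1")
  expr <- tibble(gene_id = "g1", sample_id = paste0("s", 1:6),
                 log2_expr = c(1, 2, 3, 4, 5, 6))
  psi <- tibble(event_id = "e1", sample_id = paste0("s", 1:6),
                inclusion_reads = 1, exclusion_reads = 1, total_reads = 2,
                psi = c(11, 19, 32, 40, 50, 60))
  sheet <- sample_sheet(paste0("s", 1:6), "CD34", "SF3B1:K700E",
                        purity = c(0.95, 0.95, 0.95, 0.95, 0.5, 0.5))
  out <- expression_psi_association(psi, expr, events, "e1", sheet = sheet)
  expect_equal(out$per_event$n, 4)
})

test_that("specific-event selection applies the three rules", {
  d <- tibble(event_id = c("e1", "e2", "e3", "e4"),
              mean_psi_mut = c(30, 30, 30, 5),
              mean_psi_ctrl = c(0.5, 0.5, 8, 0.1))
  cons <- tibble(event_id = c("e1", "e2", "e3", "e4"),
                 class = c("non_truncating", "truncating", "non_truncating",
                           "non_truncating"))
  nmd <- tibble(event_id = "e1", nmd_sensitive = FALSE)
  # e1: passes all; e2: truncating; e3: not specific (30 < 10*(8+1));
  # e4: below the PSI floor
  ids <- select_specific_events(d, cons, nmd)
  expect_equal(ids, "e1")
  nmd2 <- tibble(event_id = "e1", nmd_sensitive = TRUE)
  expect_equal(length(select_specific_events(d, cons, nmd2)), 0)
})
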