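# Reproducibility experiments: seeded end-to-end studies that exercise
# the pipeline under its default conditions and measure calibration,
# power and recovery. Used by the test suite and scripts/acceptance.R.

#' Worked mutual-exclusivity example
#'
#' The published U2AF1 Q157 / S34 vs EZH2-alteration contingency table
#' (13 of 66 vs 0 of 32), tested for mutual exclusivity.
#'
#' @return One-row tibble: `p`, `odds_ratio`.
#' @export
xp_fisher_worked_example <- function() {
  tbl <- matrix(c(13, 66 - 13, 0, 32), nrow = 2, byrow = TRUE)
  r <- mutual_exclusivity_test(tbl)
  tibble(p = r$p, odds_ratio = r$odds_ratio)
}

# shared builder: a null reference with `n_events` background events
null_reference <- function(n_events, seed) {
  cfg <- sim_config(seed = seed, n_genes = ceiling(n_events / 3.5),
                    exons_per_gene = c(6L, 7L), effects = NULL,
                    n_null_events = n_events, emit_sequences = FALSE,
                    cohort = tibble(group = c("SF3B1:K700E", "none"),
                                    cell_fraction = "CD34", n = c(30L, 40L)))
  ref <- suppressWarnings(simulate_reference(cfg))
  if (nrow(ref$events) > n_events) {
    keep <- ref$events$event_id[seq_len(n_events)]
    ref$events <- ref$events[ref$events$event_id %in% keep, ]
    ref$truth <- ref$truth[ref$truth$event_id %in% keep, ]
  }
  list(cfg = cfg, ref = ref)
}

#' False-discovery calibration on a null cohort
#'
#' Simulates cohorts with no planted effects (default 5,000 events,
#' 30 mutated vs 40 control samples, beta-binomial overdispersion
#' 0.02), runs the differential-splicing stage, and reports the
#' fraction of seeds with zero discoveries at q < 0.01 plus a
#' Kolmogorov-Smirnov uniformity p-value for the raw p-values of the
#' first seed.
#'
#' @param n_events Number of null events.
#' @param n_seeds Number of simulated cohorts.
#' @param rho Beta-binomial overdispersion.
#' @param seed Base seed.
#' @return List: `frac_zero_discovery`, `ks_p`, `discoveries` (per
#'   seed), `n_events`.
#' @export
xp_null_fdr <- function(n_events = 5000, n_seeds = 20, rho = 0.02, seed = 1L) {
  nr <- null_reference(n_events, seed)
  discoveries <- integer(n_seeds)
  ks_p <- NA_real_
  for (s in seq_len(n_seeds)) {
    sim <- simulate_cohort(nr$ref, nr$cfg, seed = seed + 1000L + s, rho = rho)
    psi <- compute_psi(sim$events, sim$junctions)
    d <- differential_splicing(psi, sim$sheet, "SF3B1", fractions = "CD34")
    discoveries[s] <- sum(d$significant, na.rm = TRUE)
    if (s == 1) {
      ks_p <- suppressWarnings(ks.test(d$p[!is.na(d$p)], "punif"))$p.value
    }
  }
  list(frac_zero_discovery = mean(discoveries == 0), ks_p = ks_p,
       discoveries = discoveries, n_events = nrow(nr$ref$events))
}

#' Power to detect a 10% absolute PSI difference
#'
#' Plants an absolute PSI shift (default +10 on a 45% baseline) in
#' replicate events, with depth chosen so the within-group PSI
#' standard deviation is about 8%, at 30 mutated vs 40 control
#' samples, and reports the fraction detected two-sided at the given
#' alpha with the correct direction.
#'
#' @param n_events Replicate events.
#' @param delta_psi Planted absolute PSI difference (percentage points).
#' @param alpha Two-sided significance level.
#' @param depth_mean Junction read depth (180 puts the beta-binomial
#'   PSI standard deviation near 8% at rho = 0.02).
#' @param seed Seed.
#' @return List: `power`, `sd_within`, `n_events`.
#' @export
xp_power_dpsi10 <- function(n_events = 200, delta_psi = 10, alpha = 0.001,
                            depth_mean = 180, seed = 2L) {
  eff <- tibble(type = "alt_3ss", group = "SF3B1:K700E", baseline_psi = 45,
                delta_psi = delta_psi, consequence = "non_truncating",
                nmd_d = 1, expr_fc = 1, .rows = n_events)
  cfg <- sim_config(seed = seed, n_genes = n_events, effects = eff,
                    emit_sequences = FALSE, depth_mean = depth_mean,
                    depth_size = 50,
                    cohort = tibble(group = c("SF3B1:K700E", "none"),
                                    cell_fraction = "CD34", n = c(30L, 40L)))
  ref <- simulate_reference(cfg)
  sim <- simulate_cohort(ref, cfg)
  psi <- compute_psi(sim$events, sim$junctions)
  d <- differential_splicing(psi, sim$sheet, "SF3B1", fractions = "CD34")
  ctrl <- sim$sheet$sample_id[sim$sheet$genotype == "none"]
  sds <- psi %>%
    filter(.data$sample_id %in% ctrl) %>%
    group_by(.data$event_id) %>%
    summarise(s = sd(.data$psi, na.rm = TRUE), .groups = "drop")
  hits <- !is.na(d$p) & d$p < alpha & d$direction == "up_in_mutant"
  list(power = mean(hits), sd_within = mean(sds$s), n_events = n_events)
}

#' Consequence-classifier recovery across all five classes
#'
#' Generates events of every class with controlled sequence content
#' and reports the agreement between the classifier and the
#' generator's truth labels.
#'
#' @param n_per_class Events per consequence class.
#' @param seed Seed.
#' @return List: `agreement` (class-level), `mechanism_agreement`
#'   (within truncating), `n_events`, `by_class` tibble.
#' @export
xp_consequence_recovery <- function(n_per_class = 200, seed = 3L) {
  one <- function(type, consequence) {
    tibble(type = type, group = "SF3B1:K700E", baseline_psi = 10,
           delta_psi = 20, consequence = consequence, nmd_d = 1, expr_fc = 1)
  }
  pool <- bind_rows(
    one("alt_3ss", "truncating_ptc"), one("alt_3ss", "truncating_frameshift"),
    one("alt_3ss", "non_truncating"), one("alt_3ss", "non_coding"),
    one("alt_5ss", "truncating_ptc"), one("alt_5ss", "non_truncating"),
    one("cassette_exon", "alt_first_coding_exon"),
    one("cassette_exon", "alt_last_coding_exon"),
    one("cassette_exon", "truncating_frameshift"),
    one("cassette_exon", "non_truncating"),
    one("intron_retention", "truncating_ptc"),
    one("intron_retention", "truncating_frameshift")
  )
  reps <- ceiling(5 * n_per_class / nrow(pool))
  eff <- bind_rows(replicate(reps, pool, simplify = FALSE))
  cfg <- sim_config(seed = seed, n_genes = nrow(eff), effects = eff,
                    p_short_intron = 1,
                    motif = NULL,
                    cohort = tibble(group = c("SF3B1:K700E", "none"),
                                    cell_fraction = "CD34", n = c(3L, 3L)))
  ref <- simulate_reference(cfg)
  cons <- classify_consequence(ref$events, ref$models, ref$genome)
  cmp <- inner_join(cons, ref$truth %>% select("event_id", "consequence"),
                    by = "event_id") %>%
    mutate(truth_class = sub("_(ptc|frameshift)$", "", .data$consequence))
  trunc <- cmp %>% filter(.data$truth_class == "truncating")
  mech_truth <- ifelse(grepl("ptc$", trunc$consequence), "PTC_in_frame",
                       "frameshift")
  list(
    agreement = mean(cmp$class == cmp$truth_class),
    mechanism_agreement = mean(trunc$mechanism == mech_truth),
    n_events = nrow(cmp),
    by_class = cmp %>% count(.data$truth_class, .data$class),
    reference = ref,
    classified = cons
  )
}

#' NMD sensitivity and CHX-specific event recovery
#'
#' Paired CHX experiments (default 4 pairs at depth 500) over events
#' with degradation factors d = 0.25 (NMD-degraded), d = 1 (stable)
#' and d = 0 (completely degraded, hence CHX-specific), repeated over
#' seeds.
#'
#' @param n_d025,n_d1,n_d0 Events per degradation class.
#' @param n_pairs CHX pairs.
#' @param depth Junction depth.
#' @param n_seeds Repeated experiments.
#' @param seed Base seed.
#' @return List: `d025_sensitive_rate`, `d1_sensitive_rate`,
#'   `chx_specific_recovered` (mean fraction of d = 0 events
#'   recovered), `n_d0`.
#' @export
xp_nmd_recovery <- function(n_d025 = 60, n_d1 = 100, n_d0 = 50, n_pairs = 4,
                            depth = 500, n_seeds = 10, seed = 4L) {
  eff <- bind_rows(
    tibble(type = "alt_3ss", group = "SF3B1:K700E", baseline_psi = 40,
           delta_psi = 0, consequence = "truncating_ptc", nmd_d = 0.25,
           expr_fc = 1, .rows = n_d025),
    tibble(type = "alt_3ss", group = "SF3B1:K700E", baseline_psi = 40,
           delta_psi = 0, consequence = "non_truncating", nmd_d = 1,
           expr_fc = 1, .rows = n_d1),
    tibble(type = "alt_3ss", group = "SF3B1:K700E", baseline_psi = 40,
           delta_psi = 0, consequence = "truncating_ptc", nmd_d = 0,
           expr_fc = 1, .rows = n_d0)
  )
  cfg <- sim_config(seed = seed, n_genes = nrow(eff), effects = eff,
                    emit_sequences = FALSE, depth_size = 50,
                    cohort = tibble(group = "SF3B1:K700E",
                                    cell_fraction = "BMMNC", n = 4L))
  ref <- simulate_reference(cfg)
  ids <- split(ref$truth$event_id, ref$truth$nmd_d)
  rate_025 <- rate_1 <- spec_frac <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    chx <- simulate_chx_experiment(ref, cfg, n_pairs = n_pairs,
                                   depth_mean = depth,
                                   seed = seed + 100L + s)
    psi <- compute_psi(chx$events, chx$junctions)
    r <- chx_response_test(psi, chx$sheet, method = "cmh")
    # the d = 0 events are judged by CHX-specific discovery, not by the
    # q-value family shared with ordinary events
    r_main <- r %>% filter(.data$event_id %in% c(ids[["0.25"]], ids[["1"]]))
    rate_025[s] <- mean(r_main$nmd_sensitive[r_main$event_id %in% ids[["0.25"]]])
    rate_1[s] <- mean(r_main$nmd_sensitive[r_main$event_id %in% ids[["1"]]])
    spec <- discover_chx_specific_events(psi, chx$sheet)
    spec_frac[s] <- mean(ids[["0"]] %in% spec$event_id)
  }
  list(d025_sensitive_rate = mean(rate_025), d1_sensitive_rate = mean(rate_1),
       chx_specific_recovered = mean(spec_frac), n_d0 = n_d0,
       per_seed_d025 = rate_025)
}

#' Canonical-expression coupling and NB-GLM calibration
#'
#' Plants truncating PSI increases with NMD depletion on target genes
#' among a large null background, runs PSI adjustment and the
#' TMM-normalized NB GLM LRT, and reports the Spearman correlation
#' between the planted PSI shift and the estimated log2 fold change of
#' the canonical transcript, plus the type-I error rate on null genes.
#'
#' @param n_targets Genes with planted truncating events.
#' @param n_null Null genes.
#' @param seed Seed.
#' @return List: `spearman`, `type1`, `n_targets`, `n_null_tested`,
#'   `mean_target_log2fc`.
#' @export
xp_expression_coupling <- function(n_targets = 50, n_null = 2000, seed = 5L) {
  dps <- with_seed(seed, round(runif(n_targets, 15, 40)))
  eff <- tibble(type = "alt_3ss", group = "SF3B1:K700E", baseline_psi = 1,
                delta_psi = dps, consequence = "truncating_ptc", nmd_d = 0.25,
                expr_fc = 1)
  cfg <- sim_config(seed = seed, n_genes = n_targets + n_null, effects = eff,
                    n_null_events = 0, emit_sequences = FALSE,
                    depth_mean = 150,
                    cohort = tibble(group = c("SF3B1:K700E", "none"),
                                    cell_fraction = "CD34", n = c(30L, 40L)))
  ref <- simulate_reference(cfg)
  sim <- simulate_cohort(ref, cfg)
  psi <- compute_psi(sim$events, sim$junctions)
  d <- differential_splicing(psi, sim$sheet, "SF3B1", fractions = "CD34")
  cons <- ref$truth %>%
    transmute(.data$event_id,
              class = sub("_(ptc|frameshift)$", "", .data$consequence))
  adj <- canonical_count_adjust(sim$gene_counts, psi, cons, d, ref$events)
  groups <- setNames(
    factor(ifelse(sim$sheet$genotype == "none", "ctrl", "mut"),
           levels = c("ctrl", "mut")),
    sim$sheet$sample_id
  )
  ex <- nb_glm_lrt(adj, groups)
  tg <- ref$truth %>% filter(!is.na(.data$group))
  exj <- as_tibble(ex) %>%
    inner_join(tg %>% select("gene_id", "delta_psi"), by = "gene_id") %>%
    filter(.data$converged)
  null_p <- as_tibble(ex) %>%
    filter(!.data$gene_id %in% tg$gene_id, .data$converged) %>%
    pull("p")
  list(
    spearman = cor(exj$delta_psi, exj$log2_fc, method = "spearman"),
    type1 = mean(null_p < 0.05),
    n_targets = nrow(exj),
    n_null_tested = length(null_p),
    mean_target_log2fc = mean(exj$log2_fc)
  )
}

#' Positional motif-enrichment recovery
#'
#' A large run estimating the planted 2x CCNG excess in the 3'-most
#' exon quarter of included exons, plus repeated small runs measuring
#' the null coverage of the quarter 1-3 confidence intervals.
#'
#' @param n_seeds Small-run repetitions for CI coverage.
#' @param seed Base seed.
#' @return List: `q4_rr`, `q4_ci`, `q123_rr` (large run),
#'   `null_ci_coverage` (fraction of quarter 1-3 CIs covering 1 across
#'   small runs).
#' @export
xp_motif_recovery <- function(n_seeds = 200, seed = 6L) {
  big <- simulate_exon_motif_set(
    n_per_class = c(included = 600, skipped = 50, constitutive = 3000),
    seed = seed
  )
  cc <- motif_segment_enrichment(big$sequence[big$class == "included"],
                                 big$sequence[big$class == "constitutive"],
                                 "CCNG")
  cover <- matrix(NA, nrow = n_seeds, ncol = 3)
  for (s in seq_len(n_seeds)) {
    sm <- simulate_exon_motif_set(
      n_per_class = c(included = 120, skipped = 10, constitutive = 400),
      seed = seed + 1000L + s
    )
    r <- motif_segment_enrichment(sm$sequence[sm$class == "included"],
                                  sm$sequence[sm$class == "constitutive"],
                                  "CCNG")
    cover[s, ] <- r$ci_lo[1:3] <= 1 & r$ci_hi[1:3] >= 1
  }
  list(q4_rr = cc$relative_frequency[4],
       q4_ci = c(cc$ci_lo[4], cc$ci_hi[4]),
       q123_rr = cc$relative_frequency[1:3],
       null_ci_coverage = mean(cover))
}
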