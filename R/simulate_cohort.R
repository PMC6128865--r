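# Cohort-level simulation: junction/boundary/coverage tables, gene
# counts, sample sheets, CHX pairs and isogenic clones, all driven by a
# sim_reference and its ground-truth ledger.

# beta-binomial draw, vectorized; rho = 0 degenerates to binomial
rbetabinom <- function(n, size, prob, rho) {
  p <- prob
  if (rho > 0) {
    a <- p * (1 - rho) / rho
    b <- (1 - p) * (1 - rho) / rho
    ok <- p > 0 & p < 1
    p[ok] <- rbeta(sum(ok), a[ok], b[ok])
  }
  rbinom(n, size, p)
}

# per-(event, sample) true PSI given group/fraction membership
true_psi_grid <- function(truth, sheet) {
  grid <- tidyr::crossing(event_id = truth$event_id, sample_id = sheet$sample_id) %>%
    left_join(truth %>% select("event_id", "group", "baseline_psi", "delta_psi"),
              by = "event_id") %>%
    left_join(sheet %>% select("sample_id", "genotype", "cell_fraction"),
              by = "sample_id")
  grid %>%
    mutate(
      affected = !is.na(.data$group) &
        str_detect(.data$genotype, stringr::fixed(.data$group)),
      psi_true = .data$baseline_psi + ifelse(.data$affected, .data$delta_psi, 0)
    ) %>%
    select("event_id", "sample_id", "psi_true")
}

# which side of each event carries the PTC isoform (NMD thins that side)
ptc_side_of <- function(truth) {
  truth %>%
    mutate(ptc_side = case_when(
      !startsWith(coalesce(.data$consequence, ""), "truncating") ~ NA_character_,
      .data$type == "cassette_exon" ~ "exclusion",
      TRUE ~ "inclusion"
    )) %>%
    select("event_id", "ptc_side", "nmd_d")
}

# Draw per-(event, sample) inclusion/exclusion read counts.
# `d_mode`: "untreated" applies each event's nmd_d to the PTC side;
# "treated" sets d = 1 (NMD inhibited). `latent_p` optionally supplies
# pre-drawn beta success probabilities (shared within a CHX pair).
draw_event_counts <- function(truth, sheet, rho, depth_mean, depth_size,
                              d_mode = "untreated", latent_p = NULL) {
  grid <- true_psi_grid(truth, sheet)
  n <- nrow(grid)
  total <- rnbinom(n, mu = depth_mean, size = depth_size)
  p <- grid$psi_true / 100
  if (is.null(latent_p)) {
    if (rho > 0) {
      a <- p * (1 - rho) / rho
      b <- (1 - p) * (1 - rho) / rho
      ok <- p > 0 & p < 1
      p[ok] <- rbeta(sum(ok), a[ok], b[ok])
    }
  } else {
    p <- latent_p
  }
  incl <- rbinom(n, total, p)
  excl <- total - incl
  out <- grid %>%
    mutate(latent_p = p, incl = incl, excl = excl) %>%
    left_join(ptc_side_of(truth), by = "event_id")
  if (d_mode == "untreated") {
    thin_i <- !is.na(out$ptc_side) & out$ptc_side == "inclusion" & out$nmd_d < 1
    out$incl[thin_i] <- rbinom(sum(thin_i), out$incl[thin_i], out$nmd_d[thin_i])
    thin_e <- !is.na(out$ptc_side) & out$ptc_side == "exclusion" & out$nmd_d < 1
    out$excl[thin_e] <- rbinom(sum(thin_e), out$excl[thin_e], out$nmd_d[thin_e])
  }
  out
}

# expand event-level counts into junction/boundary records
emit_junction_records <- function(events, counts) {
  side_tbl <- events %>%
    select("event_id", "inclusion", "exclusion") %>%
    pivot_longer(c("inclusion", "exclusion"), names_to = "side", values_to = "key") %>%
    separate_rows("key", sep = ";")
  cdt <- as.data.table(counts[, c("event_id", "sample_id", "incl", "excl")])
  rec <- as.data.table(side_tbl)[cdt, on = "event_id", allow.cartesian = TRUE]
  rec[, count := ifelse(side == "inclusion", incl, excl)]
  is_boundary <- startsWith(rec$key, "B:")
  jx <- as_tibble(rec[!is_boundary, c("key", "sample_id", "count")])
  # events own disjoint junction sets by construction; aggregate only
  # if a (junction, sample) pair somehow repeats
  if (anyDuplicated(jx[, c("key", "sample_id")]) > 0) {
    jx <- jx %>%
      group_by(.data$key, .data$sample_id) %>%
      summarise(count = mean(.data$count), .groups = "drop")
  }
  jx <- jx %>% mutate(count = as.integer(round(.data$count)))
  jx <- bind_cols(parse_junction_key(jx$key), jx %>% select("sample_id", "count"))
  bd <- NULL
  if (any(is_boundary)) {
    b <- rec[is_boundary, ] %>%
      mutate(side_lr = sub("^B:(.*):(left|right)$", "\\2", .data$key),
             jkey = sub("^B:(.*):(left|right)$", "\\1", .data$key))
    bd <- bind_cols(parse_junction_key(b$jkey),
                    b %>% select(side = "side_lr", "sample_id", count = "count")) %>%
      mutate(count = as.integer(.data$count))
  }
  list(junctions = jx, boundaries = bd)
}

#' Simulate a mutation-stratified cohort
#'
#' For each event and sample, inclusion reads follow
#' `BetaBinomial(total, PSI/100, rho)` with group-appropriate PSI;
#' reads of the PTC-bearing isoform are thinned by the event's NMD
#' factor `d`; gene counts follow a negative binomial whose mean is
#' coupled to `(1 - truncating PSI/100)` where configured.
#'
#' @param reference A [simulate_reference()] result.
#' @param config The [sim_config()] (its `cohort` describes the design).
#' @param seed Seed for this cohort draw (defaults to `config$seed + 1`).
#' @param cohort Optional cohort design overriding `config$cohort`.
#' @param rho,depth_mean,depth_size Optional overrides of the noise model.
#' @return List of class `sim_cohort`: `junctions` ([junction_table()]),
#'   `gene_counts` (long tibble), `sheet` ([sample_sheet()]), `truth`,
#'   and `events` (the reference's event catalog).
#' @export
simulate_cohort <- function(reference, config, seed = config$seed + 1L,
                            cohort = NULL, rho = NULL, depth_mean = NULL,
                            depth_size = NULL) {
  cohort <- cohort %||% config$cohort
  rho <- rho %||% config$rho
  depth_mean <- depth_mean %||% config$depth_mean
  depth_size <- depth_size %||% config$depth_size
  with_seed(seed, {
    sheet <- cohort_sheet(cohort)
    truth <- reference$truth
    counts <- draw_event_counts(truth, sheet, rho, depth_mean, depth_size)
    rec <- emit_junction_records(reference$events, counts)
    cov <- emit_coverage(config, sheet)
    jt <- junction_table(rec$junctions, rec$boundaries, cov)
    gene_counts <- emit_gene_counts(reference, config, sheet, counts)
    structure(list(junctions = jt, gene_counts = gene_counts, sheet = sheet,
                   truth = truth, events = reference$events),
              class = "sim_cohort")
  })
}

cohort_sheet <- function(cohort) {
  rows <- purrr::pmap(cohort, function(group, cell_fraction, n, ...) {
    tibble(genotype = group, cell_fraction = cell_fraction, .rows = n)
  }) %>% list_rbind()
  sample_sheet(
    sample_id = sprintf("s%03d", seq_len(nrow(rows))),
    cell_fraction = rows$cell_fraction,
    genotype = rows$genotype
  )
}

emit_coverage <- function(config, sheet) {
  depl <- config$ir_depletion
  if (is.null(depl) && is.null(config$intronic_fraction)) return(NULL)
  frac <- config$intronic_fraction
  mult <- rep(1, nrow(sheet))
  if (!is.null(depl)) {
    for (g in names(depl)) {
      mult[str_detect(sheet$genotype, stringr::fixed(g))] <- depl[[g]]
    }
  }
  total <- rpois(nrow(sheet), 1e6)
  intronic <- rbinom(nrow(sheet), total, frac * mult)
  bind_rows(
    tibble(region_id = "all_introns", class = "intronic",
           sample_id = sheet$sample_id, count = intronic),
    tibble(region_id = "all_exons", class = "exonic",
           sample_id = sheet$sample_id, count = total - intronic)
  )
}

emit_gene_counts <- function(reference, config, sheet, counts) {
  genes <- reference$models$genes$gene_id
  base <- rlnorm(length(genes), log(config$gene_base_mean), 0.5)
  names(base) <- genes
  grid <- tidyr::crossing(gene_id = genes, sample_id = sheet$sample_id) %>%
    mutate(mu = base[.data$gene_id])
  truth <- reference$truth
  # expression fold change planted on affected samples of the target group
  fc_tbl <- truth %>%
    filter(!is.na(.data$group), .data$expr_fc != 1) %>%
    distinct(.data$gene_id, .data$group, .data$expr_fc)
  if (nrow(fc_tbl) > 0) {
    grid <- grid %>%
      left_join(fc_tbl, by = "gene_id") %>%
      left_join(sheet %>% select("sample_id", "genotype"), by = "sample_id") %>%
      mutate(mu = ifelse(!is.na(.data$group) &
                           str_detect(.data$genotype, stringr::fixed(.data$group)),
                         .data$mu * .data$expr_fc, .data$mu)) %>%
      select("gene_id", "sample_id", "mu")
  }
  if (isTRUE(config$couple_expression) &&
      any(startsWith(coalesce(truth$consequence, ""), "truncating"))) {
    trunc_psi <- truth %>%
      filter(startsWith(coalesce(.data$consequence, ""), "truncating")) %>%
      select("event_id", "gene_id") %>%
      inner_join(counts %>% select("event_id", "sample_id", psi_true = "latent_p"),
                 by = "event_id") %>%
      group_by(.data$gene_id, .data$sample_id) %>%
      summarise(trunc_p = max(.data$psi_true), .groups = "drop")
    grid <- grid %>%
      left_join(trunc_psi, by = c("gene_id", "sample_id")) %>%
      mutate(mu = .data$mu * (1 - coalesce(.data$trunc_p, 0))) %>%
      select("gene_id", "sample_id", "mu")
  }
  grid %>%
    mutate(count = rnbinom(n(), mu = .data$mu, size = 1 / config$gene_disp)) %>%
    select("gene_id", "sample_id", "count")
}

#' Simulate a paired CHX/untreated experiment
#'
#' Each pair shares its latent per-event isoform fraction; the treated
#' member is drawn with NMD inhibited (`d = 1`), the untreated member
#' with the event's configured `d` (`d = 0` makes the event invisible
#' untreated, i.e. CHX-specific).
#'
#' @param reference A [simulate_reference()] result.
#' @param config The [sim_config()].
#' @param n_pairs Number of CHX pairs (default 4, a typical design).
#' @param group Genotype of the paired samples.
#' @param depth_mean Junction depth in the CHX experiment.
#' @param seed Seed for this draw.
#' @return List of class `sim_chx`: `junctions`, `sheet`, `truth`,
#'   `events`.
#' @export
simulate_chx_experiment <- function(reference, config, n_pairs = 4L,
                                    group = "SF3B1:K700E", depth_mean = 500,
                                    seed = config$seed + 2L) {
  with_seed(seed, {
    ids_u <- sprintf("chx%02d_untreated", seq_len(n_pairs))
    ids_t <- sprintf("chx%02d_treated", seq_len(n_pairs))
    sheet <- sample_sheet(
      sample_id = c(ids_u, ids_t),
      cell_fraction = "BMMNC",
      genotype = group,
      chx_status = rep(c("untreated", "treated"), each = n_pairs),
      pair_id = rep(sprintf("p%02d", seq_len(n_pairs)), 2)
    )
    truth <- reference$truth
    sheet_u <- sheet %>% filter(.data$chx_status == "untreated")
    sheet_t <- sheet %>% filter(.data$chx_status == "treated")
    # latent isoform fraction shared within a pair
    cu <- draw_event_counts(truth, sheet_u, config$rho, depth_mean,
                            config$depth_size, d_mode = "untreated")
    latent <- cu$latent_p
    ct <- draw_event_counts(truth, sheet_t, config$rho, depth_mean,
                            config$depth_size, d_mode = "treated",
                            latent_p = latent)
    counts <- bind_rows(cu, ct)
    rec <- emit_junction_records(reference$events, counts)
    jt <- junction_table(rec$junctions, rec$boundaries)
    structure(list(junctions = jt, sheet = sheet, truth = truth,
                   events = reference$events),
              class = "sim_chx")
  })
}

#' Simulate isogenic CRISPR-style clones
#'
#' A small cell-line design (default 3 mutant vs 3 wild-type clones)
#' with tighter within-genotype dispersion, for recapitulation testing.
#'
#' @param reference A [simulate_reference()] result.
#' @param config The [sim_config()].
#' @param n_mut,n_wt Clones per genotype.
#' @param group Genotype knocked into the mutant clones.
#' @param rho Clone-level overdispersion (clones are less dispersed than
#'   patients).
#' @param depth_mean Junction depth.
#' @param seed Seed for this draw.
#' @return A `sim_cohort` whose sheet carries `clone_id` and
#'   `cell_fraction = "cell_line"`.
#' @export
simulate_clones <- function(reference, config, n_mut = 3L, n_wt = 3L,
                            group = "SF3B1:K700E", rho = 0.002,
                            depth_mean = 300, seed = config$seed + 3L) {
  cohort <- tibble(group = c(group, "none"), cell_fraction = "cell_line",
                   n = c(n_mut, n_wt))
  sim <- simulate_cohort(reference, config, seed = seed, cohort = cohort,
                         rho = rho, depth_mean = depth_mean)
  sim$sheet$clone_id <- paste0("clone_", seq_len(nrow(sim$sheet)))
  sim
}

#' Simulate exon sequence sets by motif class
#'
#' A lightweight generator of `included` / `skipped` / `constitutive`
#' exon sequences realizing the configured per-quarter motif rates,
#' used for positional motif-enrichment studies without building a full
#' reference.
#'
#' @param n_per_class Named integer vector of exon counts per class.
#' @param exon_length Range of exon lengths.
#' @param motif Motif composition config (see [default_motif_config()]).
#' @param seed Seed.
#' @return Tibble with `class` and `sequence`.
#' @export
simulate_exon_motif_set <- function(n_per_class = c(included = 200, skipped = 200,
                                                    constitutive = 1000),
                                    exon_length = c(120L, 240L),
                                    motif = default_motif_config(),
                                    seed = 1L) {
  with_seed(seed, {
    purrr::imap(n_per_class, function(n, cls) {
      lens <- sample(seq(exon_length[1], exon_length[2]), n, replace = TRUE)
      tibble(class = cls,
             sequence = vapply(lens, function(L) {
               plant_motifs(random_dna(L, gc = 0.5), cls, motif)
             }, character(1)))
    }) %>% list_rbind()
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort> ", nrow(x$sheet), " samples, ", nrow(x$events),
      " events\n", sep = "")
  invisible(x)
}

#' @export
print.sim_chx <- function(x, ...) {
  cat("<sim_chx> ", nrow(x$sheet) / 2, " CHX pairs, ", nrow(x$events),
      " events\n", sep = "")
  invisible(x)
}
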