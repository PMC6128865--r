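# Functional-target nomination: isogenic-clone recapitulation, the
# multi-criteria filter cascade, expression-PSI association, and
# mutation mutual exclusivity.

#' Target-filter configuration
#'
#' Thresholds of the functional-target cascade: significant in the
#' primary cohort (q below `q_primary`), recapitulated in isogenic
#' clones (p below `recapitulation_p` with consistent direction), a
#' mean PSI above `min_fold` times the control mean, and a mean PSI
#' above `min_mean_psi` in either primary or CHX-treated samples.
#'
#' @param min_mean_psi Mutant mean PSI floor (percent).
#' @param min_fold Minimum mutant/control mean PSI fold change.
#' @param specificity_fold Fold defining "almost specifically detected
#'   in mutated samples" (used by [select_specific_events()]).
#' @param recapitulation_p Clone-test p-value cutoff.
#' @param q_primary Primary-cohort q-value cutoff.
#' @param allow_chx_rescue Let the CHX-treated mean satisfy the PSI
#'   floor (events degraded by NMD in primary samples).
#' @param pseudocount Percentage points added to the control mean in
#'   fold computations.
#' @return List of class `target_filter_config`.
#' @export
target_filter_config <- function(min_mean_psi = 10, min_fold = 2,
                                 specificity_fold = 10, recapitulation_p = 0.05,
                                 q_primary = 0.01, allow_chx_rescue = TRUE,
                                 pseudocount = 1) {
  cfg <- list(min_mean_psi = min_mean_psi, min_fold = min_fold,
              specificity_fold = specificity_fold,
              recapitulation_p = recapitulation_p, q_primary = q_primary,
              allow_chx_rescue = allow_chx_rescue, pseudocount = pseudocount)
  if (any(unlist(cfg[1:5]) <= 0)) abort("all thresholds must be > 0")
  structure(cfg, class = "target_filter_config")
}

#' Test recapitulation of events in isogenic clones
#'
#' Welch t-test per event between mutant and wild-type clones;
#' an event is `consistent` when p < `p_cutoff` and the direction of
#' change (group means) matches the primary-cohort direction.
#'
#' @param psi_clones PSI tibble over clone samples.
#' @param sheet_clones Clone sample sheet (genotype distinguishes
#'   mutant from wild-type clones).
#' @param primary_direction Tibble `event_id`, `direction`
#'   (`up_in_mutant`/`down_in_mutant`) from the primary cohort, e.g.
#'   [associated_events()].
#' @param mutation Genotype label of the mutant clones.
#' @param p_cutoff Consistency cutoff.
#' @return Tibble: `event_id`, `t`, `df`, `p`, `clone_direction`,
#'   `consistent`, `assessable`.
#' @export
recapitulation_test <- function(psi_clones, sheet_clones, primary_direction,
                                mutation = "SF3B1", p_cutoff = 0.05) {
  mut <- sheet_clones$sample_id[str_detect(sheet_clones$genotype,
                                           stringr::fixed(mutation))]
  wt <- setdiff(sheet_clones$sample_id, mut)
  if (length(mut) < 2 || length(wt) < 2) {
    abort("need >= 2 clones per genotype")
  }
  res <- psi_clones %>%
    mutate(grp = ifelse(.data$sample_id %in% mut, "mut", "wt")) %>%
    group_by(.data$event_id) %>%
    summarise(
      test = list(welch_test(.data$psi[.data$grp == "mut"],
                             .data$psi[.data$grp == "wt"])),
      .groups = "drop"
    ) %>%
    tidyr::unnest("test") %>%
    mutate(
      clone_direction = ifelse(.data$mean_x >= .data$mean_y,
                               "up_in_mutant", "down_in_mutant"),
      assessable = is.na(.data$reason)
    )
  res %>%
    left_join(primary_direction %>% select("event_id", "direction"),
              by = "event_id") %>%
    mutate(consistent = .data$assessable & !is.na(.data$p) &
             .data$p < p_cutoff &
             !is.na(.data$direction) &
             .data$clone_direction == .data$direction) %>%
    select("event_id", "t", "df", "p", "clone_direction", "consistent",
           "assessable")
}

#' Apply the functional-target filter cascade
#'
#' Nominates events that are significant in the primary cohort,
#' recapitulated in isogenic clones (criterion skipped and recorded
#' when clone data are absent), show a mutant mean PSI above
#' `min_fold` times the control mean, and a mutant mean PSI above
#' `min_mean_psi` in primary or (optionally) CHX-treated samples.
#'
#' @param diff [differential_splicing()] result for the comparison of
#'   interest (one fraction, or pre-filtered).
#' @param psi_chx Optional PSI tibble over CHX-treated samples (any
#'   sample in it counts as treated material).
#' @param recapitulation Optional [recapitulation_test()] result.
#' @param config A [target_filter_config()].
#' @return Tibble of nominated events with per-criterion columns and a
#'   `provenance` note about skipped criteria.
#' @export
functional_target_filter <- function(diff, psi_chx = NULL, recapitulation = NULL,
                                     config = target_filter_config()) {
  d <- as_tibble(diff) %>%
    group_by(.data$event_id) %>%
    summarise(
      significant = any(.data$significant),
      mean_psi_mut = max(.data$mean_psi_mut, na.rm = TRUE),
      mean_psi_ctrl = min(.data$mean_psi_ctrl, na.rm = TRUE),
      .groups = "drop"
    )
  chx_mean <- if (!is.null(psi_chx)) {
    psi_chx %>%
      group_by(.data$event_id) %>%
      summarise(mean_psi_chx = mean(.data$psi, na.rm = TRUE), .groups = "drop")
  } else {
    tibble(event_id = character(), mean_psi_chx = double())
  }
  out <- d %>%
    left_join(chx_mean, by = "event_id") %>%
    mutate(
      fold_ok = .data$mean_psi_mut > config$min_fold * .data$mean_psi_ctrl,
      psi_floor_ok = .data$mean_psi_mut > config$min_mean_psi |
        (config$allow_chx_rescue &
           coalesce(.data$mean_psi_chx, 0) > config$min_mean_psi)
    )
  if (!is.null(recapitulation)) {
    out <- out %>%
      left_join(recapitulation %>% select("event_id", "consistent"),
                by = "event_id") %>%
      mutate(recapitulated = coalesce(.data$consistent, FALSE),
             provenance = "full_cascade") %>%
      select(-"consistent")
  } else {
    out <- out %>%
      mutate(recapitulated = TRUE, provenance = "no_clone_data")
  }
  out %>%
    mutate(pass = .data$significant & .data$recapitulated &
             .data$fold_ok & .data$psi_floor_ok) %>%
    filter(.data$pass)
}

#' Select events almost specific to the mutated samples
#'
#' The three selection rules of the expression-PSI association: (i)
#' mutant mean PSI at least `specificity_fold` times the control mean
#' (with pseudocount); (ii) mutant mean PSI above `min_mean_psi`;
#' (iii) non-truncating events not sensitive to NMD.
#'
#' @param diff [differential_splicing()] result.
#' @param consequences [classify_consequence()] output.
#' @param nmd Optional [chx_response_test()] result.
#' @param config A [target_filter_config()].
#' @return Character vector of event ids.
#' @export
select_specific_events <- function(diff, consequences, nmd = NULL,
                                   config = target_filter_config()) {
  d <- as_tibble(diff) %>%
    group_by(.data$event_id) %>%
    summarise(mean_psi_mut = max(.data$mean_psi_mut, na.rm = TRUE),
              mean_psi_ctrl = min(.data$mean_psi_ctrl, na.rm = TRUE),
              .groups = "drop") %>%
    filter(
      .data$mean_psi_mut >= config$specificity_fold *
        (.data$mean_psi_ctrl + config$pseudocount),
      .data$mean_psi_mut > config$min_mean_psi
    )
  keep <- consequences %>%
    filter(.data$class == "non_truncating") %>%
    pull("event_id")
  ids <- intersect(d$event_id, keep)
  if (!is.null(nmd)) {
    sens <- as_tibble(nmd) %>% filter(.data$nmd_sensitive) %>% pull("event_id")
    ids <- setdiff(ids, sens)
  }
  ids
}

#' Association between gene expression and PSI
#'
#' For selected events, regresses PSI on log2 expression of the host
#' gene (Gaussian identity link) per event, and pooled across events
#' with event fixed effects; reports the Wald p-value of the
#' expression coefficient. Samples can be restricted by a purity rule
#' (fraction of cells expressing the variant).
#'
#' @param psi PSI tibble.
#' @param expression Tibble `gene_id`, `sample_id`, `log2_expr`.
#' @param events Event catalog (`event_id`, `gene_id`).
#' @param event_ids Events to analyze (e.g. from
#'   [select_specific_events()]).
#' @param sheet Optional sample sheet with a `purity` column.
#' @param min_purity Samples below this purity are excluded (ignored
#'   when `sheet` is NULL).
#' @param min_samples Events with fewer defined samples are skipped.
#' @return List: `per_event` (slopes and Wald p per event), `pooled`
#'   (one-row tibble: pooled slope, `p_wald`, events and samples used).
#' @export
expression_psi_association <- function(psi, expression, events, event_ids,
                                       sheet = NULL, min_purity = 0.9,
                                       min_samples = 3) {
  dat <- psi %>%
    filter(.data$event_id %in% event_ids, !is.na(.data$psi)) %>%
    left_join(events %>% select("event_id", "gene_id"), by = "event_id") %>%
    inner_join(expression, by = c("gene_id", "sample_id"))
  if (!is.null(sheet)) {
    keep <- sheet %>%
      filter(coalesce(.data$purity, 0) > min_purity) %>%
      pull("sample_id")
    dat <- dat %>% filter(.data$sample_id %in% keep)
  }
  testable <- dat %>%
    group_by(.data$event_id) %>%
    summarise(n = n(), s = sd(.data$log2_expr), .groups = "drop") %>%
    filter(.data$n >= min_samples, .data$s > 0)
  per_event <- if (nrow(testable) == 0) {
    tibble(event_id = character(), slope = double(), p_wald = double(),
           n = integer())
  } else {
    dat %>%
      filter(.data$event_id %in% testable$event_id) %>%
      group_by(.data$event_id) %>%
      summarise(
        fit = list(summary(lm(psi ~ log2_expr,
                              data = pick(dplyr::everything())))$coefficients),
        n = n(),
        .groups = "drop"
      ) %>%
      mutate(slope = map_dbl(.data$fit, ~ .x[2, 1]),
             p_wald = map_dbl(.data$fit, ~ .x[2, 4])) %>%
      select("event_id", "slope", "p_wald", "n")
  }
  pooled <- NULL
  dat2 <- dat %>% filter(.data$event_id %in% per_event$event_id)
  if (nrow(dat2) > 0 && length(unique(dat2$event_id)) >= 1 &&
      sd(dat2$log2_expr) > 0) {
    fit <- if (length(unique(dat2$event_id)) > 1) {
      lm(psi ~ factor(event_id) + log2_expr, data = dat2)
    } else {
      lm(psi ~ log2_expr, data = dat2)
    }
    cf <- summary(fit)$coefficients
    pooled <- tibble(
      slope = unname(cf["log2_expr", 1]),
      se = unname(cf["log2_expr", 2]),
      p_wald = unname(cf["log2_expr", 4]),
      n_events = length(unique(dat2$event_id)),
      n_obs = nrow(dat2)
    )
  }
  list(per_event = per_event, pooled = pooled)
}

#' Mutation mutual-exclusivity test
#'
#' Two-sided Fisher exact test (point-probability method) on a 2x2
#' presence table, with the Haldane-corrected odds ratio when a zero
#' cell exists. A zero margin yields p = 1 with a flag.
#'
#' @param tbl 2x2 matrix of non-negative integer counts (rows:
#'   mutation groups; columns: alteration present/absent).
#' @return One-row tibble: `odds_ratio`, `p`, `zero_margin`.
#' @export
mutual_exclusivity_test <- function(tbl) {
  tbl <- as.matrix(tbl)
  if (!all(dim(tbl) == c(2, 2)) || any(tbl < 0) || any(tbl != floor(tbl))) {
    abort("a 2x2 table of non-negative integers is required")
  }
  if (any(rowSums(tbl) == 0) || any(colSums(tbl) == 0)) {
    return(tibble(odds_ratio = NA_real_, p = 1, zero_margin = TRUE))
  }
  ft <- fisher.test(tbl)
  or <- if (any(tbl == 0)) {
    ((tbl[1, 1] + 0.5) * (tbl[2, 2] + 0.5)) /
      ((tbl[1, 2] + 0.5) * (tbl[2, 1] + 0.5))
  } else {
    (tbl[1, 1] * tbl[2, 2]) / (tbl[1, 2] * tbl[2, 1])
  }
  tibble(odds_ratio = or, p = ft$p.value, zero_margin = FALSE)
}
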