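# Differential splicing: per-event Welch t-tests between
# genotype-defined groups per cell fraction, BH correction per
# (comparison x fraction) family, direction and tallies.

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t-test with Welch-Satterthwaite degrees of freedom
#' (via [stats::t.test()]). Undefined (flagged) when either group has
#' fewer than two defined values or both sample variances are zero.
#'
#' @param x,y Numeric vectors (NAs dropped).
#' @return One-row tibble: `t`, `df`, `p`, `mean_x`, `mean_y`,
#'   `reason` (NA when testable, else a skip code).
#' @export
welch_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    return(tibble(t = NA_real_, df = NA_real_, p = NA_real_,
                  mean_x = if (length(x)) mean(x) else NA_real_,
                  mean_y = if (length(y)) mean(y) else NA_real_,
                  reason = "too_few_values"))
  }
  if (var(x) == 0 && var(y) == 0) {
    return(tibble(t = NA_real_, df = NA_real_, p = NA_real_,
                  mean_x = mean(x), mean_y = mean(y),
                  reason = "zero_variance"))
  }
  tt <- t.test(x, y, var.equal = FALSE)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, mean_x = mean(x), mean_y = mean(y),
         reason = NA_character_)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH with monotonicity enforcement (via [stats::p.adjust()]).
#' NA p-values are excluded from the family and get NA q-values.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(pvals))
  ok <- !is.na(pvals)
  q[ok] <- p.adjust(pvals[ok], method = "BH")
  q
}

# scalar-list version of welch_test used in the per-event hot loop;
# code: 0 ok, 1 too few values, 2 zero variance in both groups
welch_scalars <- function(psi, grp) {
  x <- psi[grp == "mutant"]; y <- psi[grp == "control"]
  n_mut <- sum(!is.na(x)); n_ctrl <- sum(!is.na(y))
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  base <- list(n_mut = n_mut, n_ctrl = n_ctrl,
               mean_x = if (n_mut) mean(x) else NA_real_,
               mean_y = if (n_ctrl) mean(y) else NA_real_)
  if (n_mut < 2 || n_ctrl < 2) {
    return(c(base, list(t = NA_real_, df = NA_real_, p = NA_real_, code = 1L)))
  }
  if (var(x) == 0 && var(y) == 0) {
    return(c(base, list(t = NA_real_, df = NA_real_, p = NA_real_, code = 2L)))
  }
  tt <- t.test(x, y, var.equal = FALSE)
  c(base, list(t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, code = 0L))
}

# resolve a comparison's mutant and control sample sets
comparison_groups <- function(sheet, mutation, fraction,
                              controls = "none") {
  sub <- sheet %>%
    filter(.data$cell_fraction == fraction, .data$chx_status == "untreated")
  mut <- sub$sample_id[str_detect(sub$genotype, stringr::fixed(mutation))]
  ctrl <- sub$sample_id[sub$genotype %in% controls]
  list(mutant = mut, control = ctrl)
}

#' Differential splicing between mutation-defined groups
#'
#' Compares PSI between samples carrying a spliceosome mutation and
#' those without any splicing-factor mutation, per cell fraction, by
#' two-sided Welch t-test; q-values are BH-adjusted within each
#' (comparison x fraction) family; no PSI-difference floor is applied
#' at the testing stage. An event enters a comparison only if its PSI
#' is defined in at least `min_per_group` samples per group. The
#' cross-fraction "associated" set (significant in at least one
#' fraction) is available via [associated_events()].
#'
#' @param psi PSI tibble from [compute_psi()].
#' @param sheet Sample sheet.
#' @param mutation Mutation label matched against the genotype column
#'   (e.g. `"SF3B1"`, `"U2AF1:S34"`); prefix matching, so variant sites
#'   may be pooled or split.
#' @param fractions Cell fractions to test (each tested separately).
#' @param controls Genotype value(s) defining the control group.
#' @param groups Optional explicit list
#'   `list(mutant = sample_ids, control = sample_ids)` overriding the
#'   genotype-based grouping (used for co-mutation contrasts); applied
#'   within each fraction.
#' @param q_cutoff Significance cutoff on the q-value.
#' @param min_per_group Minimum defined-PSI samples per group.
#' @param pseudocount Percentage points added to both means in the PSI
#'   fold change.
#' @return Tibble of class `ss_diff`: one row per (event, fraction)
#'   with means, `delta_psi`, `psi_fc`, `t`, `df`, `p`, `q`,
#'   `direction`, `significant`, `reason`.
#' @export
differential_splicing <- function(psi, sheet, mutation,
                                  fractions = unique(sheet$cell_fraction),
                                  controls = "none", groups = NULL,
                                  q_cutoff = 0.01, min_per_group = 3,
                                  pseudocount = 1) {
  res <- map(fractions, function(fr) {
    gs <- groups %||% comparison_groups(sheet, mutation, fr, controls)
    if (!is.null(groups)) {
      sub <- sheet$sample_id[sheet$cell_fraction == fr]
      gs <- list(mutant = intersect(groups$mutant, sub),
                 control = intersect(groups$control, sub))
    }
    if (length(gs$mutant) == 0 || length(gs$control) == 0) {
      abort(paste0("empty group for ", mutation, " in fraction ", fr))
    }
    wide <- psi %>%
      filter(.data$sample_id %in% c(gs$mutant, gs$control)) %>%
      mutate(grp = ifelse(.data$sample_id %in% gs$mutant, "mutant", "control"))
    dt <- as.data.table(wide[, c("event_id", "psi", "grp")])
    per_event <- as_tibble(dt[, as.list(welch_scalars(psi, grp)),
                              by = "event_id"]) %>%
      mutate(
        reason = c(NA_character_, "too_few_values",
                   "zero_variance")[.data$code + 1L]
      ) %>%
      select(-"code") %>%
      rename(mean_psi_mut = "mean_x", mean_psi_ctrl = "mean_y") %>%
      mutate(
        reason = ifelse(.data$n_mut < min_per_group | .data$n_ctrl < min_per_group,
                        "too_few_defined", .data$reason),
        p = ifelse(is.na(.data$reason), .data$p, NA_real_),
        comparison = mutation, fraction = fr,
        delta_psi = .data$mean_psi_mut - .data$mean_psi_ctrl,
        psi_fc = (.data$mean_psi_mut + pseudocount) /
          (.data$mean_psi_ctrl + pseudocount)
      )
    per_event %>%
      mutate(
        q = bh_adjust(.data$p),
        direction = ifelse(.data$delta_psi >= 0, "up_in_mutant", "down_in_mutant"),
        significant = !is.na(.data$q) & .data$q < q_cutoff
      )
  }) %>% list_rbind()
  out <- res %>%
    select("event_id", "comparison", "fraction", "mean_psi_mut", "mean_psi_ctrl",
           "delta_psi", "psi_fc", "t", "df", "p", "q", "direction",
           "significant", "n_mut", "n_ctrl", "reason")
  attr(out, "q_cutoff") <- q_cutoff
  new_ss_tbl(out, "ss_diff")
}

#' Events associated with a mutation in at least one cell fraction
#'
#' @param diff A [differential_splicing()] result.
#' @return Tibble of distinct significant events with the fractions
#'   they were significant in.
#' @export
associated_events <- function(diff) {
  diff %>%
    filter(.data$significant) %>%
    group_by(.data$event_id, .data$comparison) %>%
    summarise(fractions = paste(sort(unique(.data$fraction)), collapse = ";"),
              direction = .data$direction[which.min(.data$q)],
              .groups = "drop")
}

#' Tally significant events by type and direction
#'
#' The shape of the per-mutation event-type bar charts: counts of
#' significantly associated events split by splicing pattern and by
#' direction of change in the mutated samples.
#'
#' @param diff A [differential_splicing()] result.
#' @param events Event catalog carrying `event_id` and `type`.
#' @return Tibble: `comparison`, `type`, `direction`, `n`.
#' @export
tally_splicing <- function(diff, events) {
  associated_events(diff) %>%
    left_join(events %>% select("event_id", "type"), by = "event_id") %>%
    count(.data$comparison, .data$type, .data$direction, name = "n")
}
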