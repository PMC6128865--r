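# NMD sensitivity from paired CHX-treated/untreated samples: paired t
# on PSI, Cochran-Mantel-Haenszel on read counts, and discovery of
# CHX-specific events.

#' Cochran-Mantel-Haenszel test over stratified 2x2 tables
#'
#' The classic CMH chi-square (1 df, no continuity correction) for K
#' 2x2 tables: `(sum_k (a_k - E a_k))^2 / sum_k Var a_k` with the
#' hypergeometric expectation and variance. Strata with a zero margin
#' contribute nothing and are dropped (counted). For a single stratum
#' the statistic equals `(T - 1) / T` times the Pearson chi-square.
#'
#' @param tables A 2x2xK array, or a list of 2x2 matrices.
#' @return One-row tibble: `statistic`, `p`, `k_used`, `k_dropped`.
#' @export
cmh_test <- function(tables) {
  if (is.array(tables) && length(dim(tables)) == 3) {
    tables <- lapply(seq_len(dim(tables)[3]), function(k) tables[, , k])
  }
  a <- e <- v <- numeric(0)
  dropped <- 0L
  for (tb in tables) {
    n1 <- sum(tb[1, ]); n2 <- sum(tb[2, ])
    m1 <- sum(tb[, 1]); m2 <- sum(tb[, 2])
    tt <- sum(tb)
    if (n1 == 0 || n2 == 0 || m1 == 0 || m2 == 0 || tt < 2) {
      dropped <- dropped + 1L
      next
    }
    a <- c(a, tb[1, 1])
    e <- c(e, n1 * m1 / tt)
    v <- c(v, n1 * n2 * m1 * m2 / (tt^2 * (tt - 1)))
  }
  if (length(a) == 0 || sum(v) == 0) {
    return(tibble(statistic = 0, p = 1, k_used = length(a), k_dropped = dropped))
  }
  stat <- (sum(a) - sum(e))^2 / sum(v)
  tibble(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE),
         k_used = length(a), k_dropped = dropped)
}

#' Test per-event PSI response to NMD inhibition (CHX)
#'
#' For each event, compares CHX-treated against untreated members of
#' each pair: the default method stratifies the per-pair 2x2
#' inclusion/exclusion x treated/untreated read-count tables in a CMH
#' test; `paired_t` runs a paired t-test on PSI. Both are two-sided;
#' q-values are BH-adjusted per method and the `nmd_sensitive` call
#' additionally requires an increase after treatment (treated mean PSI
#' above untreated).
#'
#' @param psi PSI tibble from [compute_psi()] over the CHX experiment
#'   samples (carries the read counts the CMH needs).
#' @param sheet Sample sheet with `chx_status` and `pair_id`.
#' @param method `"cmh"` (default) or `"paired_t"`.
#' @param q_cutoff Significance cutoff for the sensitivity call.
#' @param pseudocount Percentage points added to both means in the PSI
#'   fold change.
#' @return Tibble of class `ss_nmd`: `event_id`, `mean_psi_untreated`,
#'   `mean_psi_treated`, `psi_fc_chx`, `statistic`, `df`, `p`, `q`,
#'   `n_pairs`, `nmd_sensitive`.
#' @export
chx_response_test <- function(psi, sheet, method = c("cmh", "paired_t"),
                              q_cutoff = 0.01, pseudocount = 1) {
  method <- match.arg(method)
  pairs <- sheet %>%
    filter(!is.na(.data$pair_id)) %>%
    select("sample_id", "chx_status", "pair_id")
  if (nrow(pairs) == 0) abort("no CHX pairs in the sample sheet")
  dat <- psi %>%
    inner_join(pairs, by = "sample_id") %>%
    pivot_wider(id_cols = c("event_id", "pair_id"),
                names_from = "chx_status",
                values_from = c("psi", "inclusion_reads", "exclusion_reads"))
  need <- c("psi_untreated", "psi_treated", "inclusion_reads_untreated",
            "inclusion_reads_treated", "exclusion_reads_untreated",
            "exclusion_reads_treated")
  if (!all(need %in% names(dat))) abort("both treated and untreated samples are required")

  res <- dat %>%
    group_by(.data$event_id) %>%
    summarise(
      mean_psi_untreated = mean(.data$psi_untreated, na.rm = TRUE),
      mean_psi_treated = mean(.data$psi_treated, na.rm = TRUE),
      n_pairs = sum(!is.na(.data$psi_untreated) & !is.na(.data$psi_treated)),
      test = list(chx_one_event(dplyr::pick(dplyr::everything()), method)),
      .groups = "drop"
    ) %>%
    tidyr::unnest("test") %>%
    mutate(
      psi_fc_chx = (.data$mean_psi_treated + pseudocount) /
        (.data$mean_psi_untreated + pseudocount)
    )
  res <- res %>%
    mutate(
      q = bh_adjust(.data$p),
      nmd_sensitive = !is.na(.data$q) & .data$q < q_cutoff &
        .data$mean_psi_treated > .data$mean_psi_untreated
    ) %>%
    select("event_id", "mean_psi_untreated", "mean_psi_treated", "psi_fc_chx",
           "statistic", "df", "p", "q", "n_pairs", "nmd_sensitive")
  attr(res, "method") <- method
  new_ss_tbl(res, "ss_nmd")
}

chx_one_event <- function(d, method) {
  if (method == "paired_t") {
    ok <- !is.na(d$psi_untreated) & !is.na(d$psi_treated)
    if (sum(ok) < 2) {
      return(tibble(statistic = NA_real_, df = NA_real_, p = NA_real_))
    }
    diffs <- d$psi_treated[ok] - d$psi_untreated[ok]
    if (all(diffs == 0) || sd(diffs) == 0) {
      return(tibble(statistic = 0, df = sum(ok) - 1, p = 1))
    }
    tt <- t.test(d$psi_treated[ok], d$psi_untreated[ok], paired = TRUE)
    tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value)
  } else {
    tabs <- map(seq_len(nrow(d)), function(k) {
      matrix(round(c(d$inclusion_reads_treated[k], d$exclusion_reads_treated[k],
                     d$inclusion_reads_untreated[k], d$exclusion_reads_untreated[k])),
             nrow = 2, byrow = TRUE)
    })
    r <- cmh_test(tabs)
    tibble(statistic = r$statistic, df = 1, p = r$p)
  }
}

#' Cross-tabulate NMD sensitivity by transcript consequence
#'
#' @param nmd [chx_response_test()] result.
#' @param consequences [classify_consequence()] output.
#' @return List: `table` (tibble cross-tabulation) and `events` (the
#'   joined per-event labels).
#' @export
classify_nmd_sensitivity <- function(nmd, consequences) {
  joined <- as_tibble(nmd) %>%
    left_join(consequences %>% select("event_id", "class"), by = "event_id")
  list(
    events = joined,
    table = joined %>%
      filter(!is.na(.data$class)) %>%
      count(.data$class, .data$nmd_sensitive, name = "n")
  )
}

#' Discover events specifically detected after CHX treatment
#'
#' An event is "detected" in a sample when its inclusion evidence is
#' positive and its informative total meets the read threshold.
#' CHX-specific events are detected in at least one treated sample and
#' in none of the untreated/primary samples.
#'
#' @param psi_chx PSI tibble over the CHX experiment samples.
#' @param sheet_chx Its sample sheet.
#' @param psi_primary Optional PSI tibble over primary (untreated)
#'   cohort samples, also required to show no detection.
#' @param min_reads Detection read threshold.
#' @return Tibble of CHX-specific events with per-event detection
#'   counts.
#' @export
discover_chx_specific_events <- function(psi_chx, sheet_chx, psi_primary = NULL,
                                         min_reads = 5) {
  chx <- psi_chx %>%
    left_join(sheet_chx %>% select("sample_id", "chx_status"), by = "sample_id") %>%
    mutate(det = .data$inclusion_reads > 0 & .data$total_reads >= min_reads)
  per_event <- chx %>%
    group_by(.data$event_id) %>%
    summarise(
      n_detected_treated = sum(.data$det & .data$chx_status == "treated"),
      n_detected_untreated = sum(.data$det & .data$chx_status == "untreated"),
      .groups = "drop"
    )
  if (!is.null(psi_primary)) {
    prim <- psi_primary %>%
      mutate(det = .data$inclusion_reads > 0 & .data$total_reads >= min_reads) %>%
      group_by(.data$event_id) %>%
      summarise(n_detected_primary = sum(.data$det), .groups = "drop")
    per_event <- per_event %>%
      left_join(prim, by = "event_id") %>%
      mutate(n_detected_primary = coalesce(.data$n_detected_primary, 0L))
  } else {
    per_event$n_detected_primary <- 0L
  }
  per_event %>%
    filter(.data$n_detected_treated >= 1,
           .data$n_detected_untreated == 0,
           .data$n_detected_primary == 0)
}
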