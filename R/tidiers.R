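# broom-style tidiers for the result classes.

#' @method tidy ss_diff
#' @export
tidy.ss_diff <- function(x, ...) {
  as_tibble(x) %>%
    select("event_id", "comparison", "fraction", estimate = "delta_psi",
           statistic = "t", "df", p.value = "p", q.value = "q", "direction",
           "significant")
}

#' @method glance ss_diff
#' @export
glance.ss_diff <- function(x, ...) {
  as_tibble(x) %>%
    group_by(.data$comparison, .data$fraction) %>%
    summarise(
      n_events = n(),
      n_tested = sum(!is.na(.data$p)),
      n_significant = sum(.data$significant, na.rm = TRUE),
      q_cutoff = attr(x, "q_cutoff") %||% NA_real_,
      .groups = "drop"
    )
}

#' @method tidy ss_expression
#' @export
tidy.ss_expression <- function(x, ...) {
  as_tibble(x) %>%
    select("gene_id", estimate = "log2_fc", statistic = "lrt_stat",
           p.value = "p", q.value = "q", "significant")
}

#' @method glance ss_expression
#' @export
glance.ss_expression <- function(x, ...) {
  tibble(
    n_genes_tested = sum(x$converged),
    n_significant = sum(x$significant, na.rm = TRUE),
    n_nonconverged = sum(!x$converged)
  )
}

#' @method tidy ss_nmd
#' @export
tidy.ss_nmd <- function(x, ...) {
  as_tibble(x) %>%
    select("event_id", estimate = "psi_fc_chx", statistic = "statistic",
           p.value = "p", q.value = "q", "nmd_sensitive")
}

#' @method glance ss_nmd
#' @export
glance.ss_nmd <- function(x, ...) {
  tibble(
    method = attr(x, "method") %||% NA_character_,
    n_events = nrow(x),
    n_sensitive = sum(x$nmd_sensitive, na.rm = TRUE)
  )
}

#' @method tidy ss_motif
#' @export
tidy.ss_motif <- function(x, ...) {
  as_tibble(x) %>%
    select("motif", "segment", estimate = "relative_frequency",
           conf.low = "ci_lo", conf.high = "ci_hi")
}

#' @method glance ss_motif
#' @export
glance.ss_motif <- function(x, ...) {
  tibble(
    n_segments = nrow(x),
    n_enriched = sum(x$ci_lo > 1),
    n_depleted = sum(x$ci_hi < 1)
  )
}
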