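# Canonical-transcript expression: PSI-adjusted gene counts, TMM
# normalization, and a negative-binomial GLM likelihood-ratio test.

#' Adjust gene counts to the canonical (non-truncated) transcript
#'
#' For every gene carrying at least one truncating splicing event, the
#' event with the highest PSI fold change versus controls is selected
#' and the gene's counts are scaled by `(100 - PSI) / 100` per sample
#' (rounded to integers; samples with undefined PSI pass through
#' unadjusted). Genes without truncating events pass through.
#'
#' @param gene_counts Long tibble: `gene_id`, `sample_id`, `count`.
#' @param psi PSI tibble from [compute_psi()].
#' @param consequences [classify_consequence()] output.
#' @param diff [differential_splicing()] output (provides `psi_fc` for
#'   the event selection) carrying a `gene_id` column or joinable via
#'   `events`.
#' @param events Event catalog (`event_id`, `gene_id`).
#' @return Tibble like `gene_counts` with columns `count` (adjusted),
#'   `raw_count` and `adjusting_event` (NA when unadjusted).
#' @export
canonical_count_adjust <- function(gene_counts, psi, consequences, diff, events) {
  trunc_events <- consequences %>%
    filter(.data$class == "truncating") %>%
    select("event_id") %>%
    left_join(events %>% select("event_id", "gene_id"), by = "event_id") %>%
    inner_join(as_tibble(diff) %>% select("event_id", "psi_fc"), by = "event_id")
  chosen <- trunc_events %>%
    group_by(.data$gene_id) %>%
    slice_max(.data$psi_fc, n = 1, with_ties = FALSE) %>%
    ungroup() %>%
    select("gene_id", adjusting_event = "event_id")
  missing <- setdiff(chosen$gene_id, unique(gene_counts$gene_id))
  if (length(missing) > 0) {
    warn(paste0(length(missing), " gene(s) with truncating events absent from ",
                "the count table were skipped"))
  }
  gene_counts %>%
    left_join(chosen, by = "gene_id") %>%
    left_join(psi %>% select("event_id", "sample_id", "psi"),
              by = c(adjusting_event = "event_id", "sample_id")) %>%
    mutate(
      raw_count = .data$count,
      count = ifelse(is.na(.data$psi), .data$count,
                     round(.data$count * (100 - .data$psi) / 100))
    ) %>%
    select("gene_id", "sample_id", "count", "raw_count", "adjusting_event")
}

#' Weighted trimmed mean of M-values normalization factors
#'
#' Standard TMM: the reference is the sample whose upper quartile of
#' scaled counts is closest to the mean upper quartile; per sample, M
#' (log ratio) and A (log abundance) values over genes expressed in
#' both are trimmed (30% of M, 5% of A, each tail) and the
#' precision-weighted mean M gives the factor; factors are normalized
#' to geometric mean 1.
#'
#' @param gene_counts Long tibble (`gene_id`, `sample_id`, `count`) or
#'   a genes x samples matrix.
#' @return Tibble: `sample_id`, `lib_size`, `norm_factor`.
#' @export
tmm_normalize <- function(gene_counts) {
  m <- counts_matrix(gene_counts)
  lib <- colSums(m)
  if (any(lib == 0)) {
    abort(paste0("sample with all-zero counts: ",
                 paste(colnames(m)[lib == 0], collapse = ", ")))
  }
  uq <- apply(m, 2, function(x) quantile(x / sum(x), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(m)), function(j) {
    tmm_pair(m[, j], m[, ref], lib[j], lib[ref])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  tibble(sample_id = colnames(m), lib_size = unname(lib), norm_factor = unname(f))
}

# one sample against the reference (Robinson & Oshlack weighting)
tmm_pair <- function(x, r, nx, nr, logratio_trim = 0.3, sum_trim = 0.05) {
  keep <- x > 0 & r > 0
  x <- x[keep]; r <- r[keep]
  M <- log2((x / nx) / (r / nr))
  A <- 0.5 * log2((x / nx) * (r / nr))
  w <- (nx - x) / (nx * x) + (nr - r) / (nr * r)
  fin <- is.finite(M) & is.finite(A) & is.finite(w)
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  if (length(M) == 0 || max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * sum_trim) + 1; hiA <- n + 1 - loA
  keep2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  if (!any(keep2)) return(1)
  2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

counts_matrix <- function(gene_counts) {
  if (is.matrix(gene_counts)) return(gene_counts)
  wide <- gene_counts %>%
    select("gene_id", "sample_id", "count") %>%
    pivot_wider(names_from = "sample_id", values_from = "count", values_fill = 0)
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$gene_id
  m
}

#' Negative-binomial GLM likelihood-ratio test of differential expression
#'
#' Filters to genes expressed above `min_cpm` counts per million in at
#' least `min_samples` samples; fits, per gene, a log-link NB GLM with
#' `offset(log(lib_size * norm_factor))` and a two-level group
#' coefficient; the likelihood-ratio test against the intercept-only
#' model gives the p-value, BH-adjusted over tested genes. Gene-wise
#' dispersions are method-of-moments estimates shrunk 50% toward a
#' lowess mean-dispersion trend.
#'
#' @param gene_counts Long tibble or matrix of (adjusted) counts.
#' @param groups Named character/factor vector (by sample id) with two
#'   levels: control level first (log2 fold changes are mutant vs
#'   control).
#' @param norm Optional [tmm_normalize()] result (computed if NULL).
#' @param min_cpm,min_samples Expression filter.
#' @param q_cutoff Significance cutoff.
#' @return Tibble of class `ss_expression`: `gene_id`, `log_cpm`,
#'   `log2_fc`, `dispersion`, `lrt_stat`, `p`, `q`, `significant`,
#'   `converged`.
#' @export
nb_glm_lrt <- function(gene_counts, groups, norm = NULL, min_cpm = 1,
                       min_samples = 6, q_cutoff = 0.01) {
  m <- counts_matrix(gene_counts)
  groups <- groups[colnames(m)]
  if (anyNA(groups)) abort("groups must cover every sample")
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) abort("exactly two groups are required")
  if (any(table(groups) < 2)) abort("each group needs >= 2 samples")
  if (is.null(norm)) norm <- tmm_normalize(m)
  norm <- norm[match(colnames(m), norm$sample_id), ]
  eff_lib <- norm$lib_size * norm$norm_factor
  cpm <- t(t(m) / eff_lib) * 1e6
  keep <- rowSums(cpm > min_cpm) >= min_samples
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0) abort("no genes pass the expression filter")

  # method-of-moments dispersion, shrunk toward the mean-dispersion trend
  scaled <- t(t(m) / eff_lib) * mean(eff_lib)
  mu <- rowMeans(scaled)
  v <- apply(scaled, 1, function(x) {
    tapply(x, groups, var) %>% stats::weighted.mean(w = table(groups) - 1)
  })
  disp_raw <- pmax((v - mu) / mu^2, 1e-4)
  lo <- stats::lowess(log(mu), log(disp_raw), f = 0.5)
  trend <- exp(stats::approx(lo$x, lo$y, xout = log(mu), rule = 2)$y)
  # 75% weight on the trend: gene-wise moment estimates are noisy at
  # these sample sizes and the heavier shrinkage keeps the LRT calibrated
  disp <- exp(0.25 * log(disp_raw) + 0.75 * log(trend))

  off <- log(eff_lib)
  res <- map(seq_len(nrow(m)), function(i) {
    y <- m[i, ]
    fam <- MASS::negative.binomial(theta = 1 / disp[i])
    fit1 <- try(glm(y ~ groups + offset(off), family = fam), silent = TRUE)
    fit0 <- try(glm(y ~ 1 + offset(off), family = fam), silent = TRUE)
    if (inherits(fit1, "try-error") || inherits(fit0, "try-error") ||
        !fit1$converged || !fit0$converged) {
      return(tibble(gene_id = rownames(m)[i], log_cpm = NA_real_,
                    log2_fc = NA_real_, dispersion = disp[i],
                    lrt_stat = NA_real_, p = NA_real_, converged = FALSE))
    }
    lrt <- fit0$deviance - fit1$deviance
    tibble(
      gene_id = rownames(m)[i],
      log_cpm = log2(mean(y / eff_lib * 1e6) + 0.5),
      log2_fc = unname(coef(fit1)[2]) / log(2),
      dispersion = disp[i],
      lrt_stat = lrt,
      p = pchisq(lrt, df = 1, lower.tail = FALSE),
      converged = TRUE
    )
  }) %>% list_rbind()
  res <- res %>%
    mutate(q = bh_adjust(ifelse(.data$converged, .data$p, NA_real_)),
           significant = !is.na(.data$q) & .data$q < q_cutoff)
  attr(res, "norm") <- norm
  attr(res, "groups") <- groups
  new_ss_tbl(res, "ss_expression")
}
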