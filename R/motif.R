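# Sequence-level characterization: positional SSNG motif enrichment by
# exon quarter, 3' splice-site -3/+1 context, and intron feature
# comparison (length, GC).

# segment bounds: L split into n segments of near-equal length, the
# remainder going to the 3'-most segments
segment_bounds <- function(L, n_segments = 4) {
  base <- L %/% n_segments
  rem <- L %% n_segments
  lens <- rep(base, n_segments) + c(rep(0, n_segments - rem), rep(1, rem))
  end <- cumsum(lens)
  list(start = end - lens + 1, end = end)
}

# overlapping IUPAC matches per segment (match assigned to the segment
# containing its first base); vectorized over sequences via Biostrings
motif_segment_counts <- function(seqs, motif, n_segments = 4) {
  set <- Biostrings::DNAStringSet(seqs)
  hits <- Biostrings::vmatchPattern(motif, set, fixed = FALSE)
  starts <- Biostrings::startIndex(hits)
  lens <- nchar(seqs)
  counts <- matrix(0, nrow = length(seqs), ncol = n_segments)
  nts <- matrix(0, nrow = length(seqs), ncol = n_segments)
  for (i in seq_along(seqs)) {
    sb <- segment_bounds(lens[i], n_segments)
    nts[i, ] <- sb$end - sb$start + 1
    st <- starts[[i]]
    if (!is.null(st) && length(st) > 0) {
      counts[i, ] <- vapply(seq_len(n_segments), function(q) {
        sum(st >= sb$start[q] & st <= sb$end[q])
      }, numeric(1))
    }
  }
  list(matches = colSums(counts), nt = colSums(nts))
}

#' Positional motif enrichment by exon segment
#'
#' Divides each exon into `n_segments` near-equal segments (5'->3';
#' remainders go to the 3'-most segments), counts overlapping IUPAC
#' motif matches per segment (a match belongs to the segment holding
#' its first base), and reports the per-segment motif density of the
#' target exons relative to the baseline (constitutive) exons, with a
#' 95% CI from the normal approximation of the log rate ratio.
#'
#' @param target_seqs Character vector (or `DNAStringSet`) of
#'   sense-strand target exon sequences.
#' @param baseline_seqs Baseline (constitutive) exon sequences.
#' @param motif IUPAC motif, e.g. `"CCNG"` or `"GGNG"` (`S` = C/G,
#'   `N` = any).
#' @param n_segments Number of segments (default 4: exon quarters).
#' @param min_exon_nt Exons shorter than this are excluded (counted).
#' @return Tibble of class `ss_motif`: `motif`, `segment`,
#'   `target_matches`, `target_nt`, `baseline_matches`, `baseline_nt`,
#'   `relative_frequency`, `ci_lo`, `ci_hi`.
#' @export
motif_segment_enrichment <- function(target_seqs, baseline_seqs, motif,
                                     n_segments = 4, min_exon_nt = 4) {
  target_seqs <- as.character(target_seqs)
  baseline_seqs <- as.character(baseline_seqs)
  if (length(target_seqs) == 0 || length(baseline_seqs) == 0) {
    abort("both exon classes must be non-empty")
  }
  short_t <- nchar(target_seqs) < min_exon_nt
  short_b <- nchar(baseline_seqs) < min_exon_nt
  target_seqs <- target_seqs[!short_t]
  baseline_seqs <- baseline_seqs[!short_b]
  if (nchar(motif) > min(nchar(c(target_seqs, baseline_seqs))) %/% n_segments) {
    abort("motif longer than the shortest segment")
  }
  tc <- motif_segment_counts(target_seqs, motif, n_segments)
  bc <- motif_segment_counts(baseline_seqs, motif, n_segments)
  out <- tibble(
    motif = motif, segment = seq_len(n_segments),
    target_matches = tc$matches, target_nt = tc$nt,
    baseline_matches = bc$matches, baseline_nt = bc$nt
  ) %>%
    mutate(
      relative_frequency = (.data$target_matches / .data$target_nt) /
        (.data$baseline_matches / .data$baseline_nt),
      se_log = sqrt(1 / pmax(.data$target_matches, 0.5) +
                      1 / pmax(.data$baseline_matches, 0.5)),
      ci_lo = exp(log(.data$relative_frequency) - 1.96 * .data$se_log),
      ci_hi = exp(log(.data$relative_frequency) + 1.96 * .data$se_log)
    ) %>%
    select(-"se_log")
  attr(out, "excluded_short") <- c(target = sum(short_t), baseline = sum(short_b))
  new_ss_tbl(out, "ss_motif")
}

#' 3' splice-site context: the -3 and +1 bases
#'
#' For each acceptor, checks the canonical AG dinucleotide (the last
#' two intronic bases) and reports the -3 base (last intronic base
#' before the AG, the standard yAG convention) and the +1 base (first
#' exonic base), on the sense strand. A configurable window of intronic
#' and exonic context is also returned.
#'
#' @param acceptors Tibble with `chrom`, `intron_start`, `intron_end`,
#'   `strand` (the acceptor is the 3' end of the intron in transcript
#'   direction).
#' @param genome Named character vector or `DNAStringSet`.
#' @param window Nt of context on each side included in `context`.
#' @return Tibble: input columns plus `minus3`, `plus1`, `canonical_ag`
#'   and `context` (`intronic|exonic`).
#' @export
splice_site_context <- function(acceptors, genome, window = 6) {
  genome <- as_genome(genome)
  rows <- map(seq_len(nrow(acceptors)), function(i) {
    a <- acceptors[i, ]
    if (a$strand == "+") {
      ag <- fetch_seq(genome, a$chrom, a$intron_end - 1, a$intron_end, "+")
      minus3 <- fetch_seq(genome, a$chrom, a$intron_end - 2, a$intron_end - 2, "+")
      plus1 <- fetch_seq(genome, a$chrom, a$intron_end + 1, a$intron_end + 1, "+")
      ctx_i <- fetch_seq(genome, a$chrom, a$intron_end - window + 1, a$intron_end, "+")
      ctx_e <- fetch_seq(genome, a$chrom, a$intron_end + 1, a$intron_end + window, "+")
    } else {
      ag <- fetch_seq(genome, a$chrom, a$intron_start, a$intron_start + 1, "-")
      minus3 <- fetch_seq(genome, a$chrom, a$intron_start + 2, a$intron_start + 2, "-")
      plus1 <- fetch_seq(genome, a$chrom, a$intron_start - 1, a$intron_start - 1, "-")
      ctx_i <- fetch_seq(genome, a$chrom, a$intron_start, a$intron_start + window - 1, "-")
      ctx_e <- fetch_seq(genome, a$chrom, a$intron_start - window, a$intron_start - 1, "-")
    }
    tibble(minus3 = minus3, plus1 = plus1, canonical_ag = ag == "AG",
           context = paste0(ctx_i, "|", ctx_e))
  }) %>% list_rbind()
  bind_cols(as_tibble(acceptors), rows)
}

#' Compare intron features between two sets
#'
#' Per feature (length, GC fraction): median, IQR and a two-sided
#' Mann-Whitney U test (affected vs constitutive introns).
#'
#' @param affected,constitutive Tibbles with `chrom`, `start`, `end`
#'   (and `strand`, unused for these features).
#' @param genome Named character vector or `DNAStringSet`.
#' @return Tibble: `feature`, `median_affected`, `iqr_lo_affected`,
#'   `iqr_hi_affected`, same for constitutive, `p`.
#' @export
compare_intron_features <- function(affected, constitutive, genome) {
  genome <- as_genome(genome)
  if (nrow(affected) == 0 || nrow(constitutive) == 0) {
    abort("both intron sets must be non-empty")
  }
  feats <- function(introns) {
    seqs <- vapply(seq_len(nrow(introns)), function(i) {
      fetch_seq(genome, introns$chrom[i], introns$start[i], introns$end[i], "+")
    }, character(1))
    tibble(length = introns$end - introns$start + 1, gc = gc_fraction(seqs))
  }
  fa <- feats(affected); fc <- feats(constitutive)
  map(c("length", "gc"), function(feat) {
    x <- fa[[feat]]; y <- fc[[feat]]
    w <- suppressWarnings(wilcox.test(x, y))
    qa <- quantile(x, c(0.25, 0.5, 0.75)); qc <- quantile(y, c(0.25, 0.5, 0.75))
    tibble(
      feature = feat,
      median_affected = qa[2], iqr_lo_affected = qa[1], iqr_hi_affected = qa[3],
      median_constitutive = qc[2], iqr_lo_constitutive = qc[1],
      iqr_hi_constitutive = qc[3],
      p = w$p.value
    )
  }) %>% list_rbind()
}
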