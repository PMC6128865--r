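# Hand-built fixtures and independent oracles shared across tests.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# A minimal plus-strand gene: 3 exons of 30 nt, introns of 100 nt,
# CDS from position 10 of the mRNA to 12 nt before its end.
toy_models <- function(strand = "+") {
  ex_len <- c(30L, 30L, 30L)
  in_len <- c(100L, 100L)
  glen <- sum(ex_len) + sum(in_len)
  sense_start <- c(1L, 131L, 261L)
  sense_end <- sense_start + ex_len - 1L
  if (strand == "+") {
    start <- sense_start; end <- sense_end
  } else {
    start <- glen - sense_end + 1L; end <- glen - sense_start + 1L
  }
  gene_model_set(
    genes = tibble(gene_id = "gX", chrom = "chrT", strand = strand),
    exons = tibble(gene_id = "gX", transcript_id = "tX", exon_rank = 1:3,
                   start = start, end = end),
    cds = tibble(transcript_id = "tX", cds_start = 10L, cds_end = 78L)
  )
}

# genome for toy_models with a clean CDS (no internal stops) and
# GT..AG introns
toy_genome <- function(strand = "+", seed = 42) {
  withr::with_seed(seed, {
    utr5 <- paste(sample(c("A", "C", "G", "T"), 9, TRUE), collapse = "")
    n_cod <- (78 - 10 + 1) / 3  # 23 codons incl start and stop
    body <- paste(replicate(n_cod - 2, paste0(
      sample(c("C", "G", "A"), 1), sample(c("C", "G"), 1), sample(c("A", "C", "G", "T"), 1)
    )), collapse = "")
    mrna <- paste0(utr5, "ATG", body, "TAA", paste(rep("C", 90 - 78), collapse = ""))
    intr <- function() {
      s <- paste(sample(c("A", "C", "G", "T"), 100, TRUE, prob = c(.3, .2, .2, .3)),
                 collapse = "")
      substr(s, 1, 2) <- "GT"; substr(s, 99, 100) <- "AG"
      s
    }
    sense <- paste0(substr(mrna, 1, 30), intr(), substr(mrna, 31, 60), intr(),
                    substr(mrna, 61, 90))
    seq <- if (strand == "+") sense else {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(sense)))
    }
    stats::setNames(seq, "chrT")
  })
}

# small simulated study reused by several test files
small_study <- function(seed = 7) {
  cfg <- sim_config(seed = seed, n_genes = 40, n_null_events = 15)
  ref <- simulate_reference(cfg)
  sim <- simulate_cohort(ref, cfg)
  list(cfg = cfg, ref = ref, sim = sim)
}

# ---------------------------------------------------------------------------
# Independent consequence oracle: rebuilds the alternative mRNA from
# genomic segments with its own logic, locates the edit by longest
# common prefix/suffix alignment, and classifies by full codon-by-codon
# translation (Biostrings::translate). Shares no edit arithmetic with
# the package implementation.

oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

oracle_mrna <- function(models, transcript_id, genome) {
  ex <- models$exons[models$exons$transcript_id == transcript_id, ]
  ex <- ex[order(ex$exon_rank), ]
  gid <- ex$gene_id[1]
  strand <- models$genes$strand[models$genes$gene_id == gid]
  chr <- genome[[models$genes$chrom[models$genes$gene_id == gid]]]
  pieces <- vapply(seq_len(nrow(ex)), function(i) {
    s <- substring(chr, ex$start[i], ex$end[i])
    if (strand == "-") oracle_revcomp(s) else s
  }, character(1))
  paste(pieces, collapse = "")
}

# the alternative mRNA, built from the event's genomic coordinates
oracle_alt_mrna <- function(event, models, genome) {
  strand <- models$genes$strand[models$genes$gene_id == event$gene_id]
  chr <- genome[[event$chrom]]
  seg <- function(a, b) {
    s <- substring(chr, a, b)
    if (strand == "-") oracle_revcomp(s) else s
  }
  old <- oracle_mrna(models, event$transcript_id, genome)
  if (event$type == "intron_retention") {
    retained <- seg(event$anno_start, event$anno_end)
    up <- if (strand == "+") seg(event$anno_start - 10, event$anno_start - 1)
    else seg(event$anno_end + 1, event$anno_end + 10)
    # insert after the upstream exon: find by unique 10-mer flank
    at <- regexpr(up, old, fixed = TRUE)
    stopifnot(at > 0)
    ins_at <- at + 9
    paste0(substr(old, 1, ins_at), retained, substr(old, ins_at + 1, nchar(old)))
  } else if (event$type %in% c("alt_3ss", "alt_5ss")) {
    k <- abs(event$offset)
    if (event$type == "alt_3ss" && event$offset < 0) {
      retained <- if (strand == "+") seg(event$alt_end + 1, event$anno_end)
      else seg(event$anno_start, event$alt_start - 1)
      flank <- if (strand == "+") seg(event$anno_start - 10, event$anno_start - 1)
      else seg(event$anno_end + 1, event$anno_end + 10)
      at <- regexpr(flank, old, fixed = TRUE); stopifnot(at > 0)
      ins_at <- at + 9
      paste0(substr(old, 1, ins_at), retained, substr(old, ins_at + 1, nchar(old)))
    } else if (event$type == "alt_5ss" && event$offset > 0) {
      retained <- if (strand == "+") seg(event$anno_start, event$alt_start - 1)
      else seg(event$alt_end + 1, event$anno_end)
      flank <- if (strand == "+") seg(event$anno_start - 10, event$anno_start - 1)
      else seg(event$anno_end + 1, event$anno_end + 10)
      at <- regexpr(flank, old, fixed = TRUE); stopifnot(at > 0)
      ins_at <- at + 9
      paste0(substr(old, 1, ins_at), retained, substr(old, ins_at + 1, nchar(old)))
    } else {
      stop("oracle only supports insertion-type alternative sites")
    }
  } else if (event$type == "cassette_exon") {
    skipped <- seg(event$anno_start, event$anno_end)
    at <- regexpr(skipped, old, fixed = TRUE); stopifnot(at > 0)
    paste0(substr(old, 1, at - 1), substr(old, at + nchar(skipped), nchar(old)))
  } else {
    stop("oracle does not handle type ", event$type)
  }
}

oracle_classify <- function(event, models, genome) {
  cds <- models$cds[models$cds$transcript_id == event$transcript_id, ]
  if (nrow(cds) == 0) return("non_coding")
  c0 <- cds$cds_start; e0 <- cds$cds_end
  old <- oracle_mrna(models, event$transcript_id, genome)
  new <- oracle_alt_mrna(event, models, genome)
  net <- nchar(new) - nchar(old)
  # locate the edit by common prefix/suffix
  n_old <- nchar(old); n_new <- nchar(new)
  maxcmp <- min(n_old, n_new)
  oldc <- strsplit(old, "")[[1]]; newc <- strsplit(new, "")[[1]]
  lcp <- 0
  while (lcp < maxcmp && oldc[lcp + 1] == newc[lcp + 1]) lcp <- lcp + 1
  lcs <- 0
  while (lcs < maxcmp - lcp && oldc[n_old - lcs] == newc[n_new - lcs]) lcs <- lcs + 1
  d1 <- lcp + 1               # first differing old position
  d2 <- n_old - lcs           # last differing old position (d1 - 1 if pure insert)
  if (d2 < d1) {              # pure insertion before old position d1
    if (d1 <= c0 || d1 > e0) return("non_coding")
  } else {
    if (d2 < c0 || d1 > e0) return("non_coding")
    if (d1 <= c0 + 2 && d2 >= c0) return("alt_first_coding_exon")
    if (d2 >= e0 - 2 && d1 <= e0) return("alt_last_coding_exon")
  }
  # translate from the (possibly shifted) start codon
  c_new <- if (d1 <= c0) c0 + net else c0
  stopifnot(substr(new, c_new, c_new + 2) == "ATG")
  tail_len <- (nchar(new) - c_new + 1) %/% 3 * 3
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(new, c_new, c_new + tail_len - 1)),
    if.fuzzy.codon = "X"
  ))
  stop_aa <- regexpr("*", aa, fixed = TRUE)
  stop_first_base <- if (stop_aa > 0) c_new + 3 * (stop_aa - 1) else NA
  expected_stop <- e0 - 2 + net
  if (!is.na(stop_first_base) && stop_first_base < expected_stop) "truncating"
  else "non_truncating"
}
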