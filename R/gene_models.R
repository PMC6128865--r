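# Gene model container: genes, transcripts/exons, transcript-level CDS,
# derived introns. All coordinates are 1-based inclusive (GTF dialect);
# junction coordinates denote the first and last intronic bases.

#' Construct a validated gene model set
#'
#' The shared reference against which splice events and transcript
#' consequences are defined. Exons are genomic intervals ordered 5'->3'
#' along the transcript's strand; the CDS, when present, is given in
#' transcript (spliced mRNA) coordinates.
#'
#' @param genes Tibble with columns `gene_id`, `chrom`, `strand`.
#' @param exons Tibble with columns `gene_id`, `transcript_id`,
#'   `exon_rank` (1 = 5'-most exon of the transcript), `start`, `end`.
#' @param cds Tibble with columns `transcript_id`, `cds_start`,
#'   `cds_end` (transcript coordinates, 1-based inclusive). Transcripts
#'   absent from `cds` are retained and flagged non-coding.
#' @return An object of class `gene_model_set`: a list with tibbles
#'   `genes`, `exons`, `cds` and derived `introns` (first/last intronic
#'   base per consecutive exon pair).
#' @export
gene_model_set <- function(genes, exons, cds = NULL) {
  genes <- as_tibble(genes)
  exons <- as_tibble(exons)
  stopifnot_cols(genes, c("gene_id", "chrom", "strand"), "genes")
  stopifnot_cols(exons, c("gene_id", "transcript_id", "exon_rank", "start", "end"), "exons")
  if (!all(genes$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  if (any(exons$start > exons$end)) {
    bad <- which(exons$start > exons$end)[1]
    abort(paste0("exon with start > end (transcript ", exons$transcript_id[bad], ")"))
  }
  exons <- exons %>%
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) %>%
    arrange(.data$transcript_id, .data$exon_rank)

  if (is.null(cds)) {
    cds <- tibble(transcript_id = character(), cds_start = integer(), cds_end = integer())
  }
  cds <- as_tibble(cds)
  stopifnot_cols(cds, c("transcript_id", "cds_start", "cds_end"), "cds")

  obj <- structure(
    list(genes = genes, exons = exons, cds = cds, introns = derive_introns(exons, genes)),
    class = "gene_model_set"
  )
  validate_gene_model_set(obj)
}

derive_introns <- function(exons, genes) {
  exons %>%
    left_join(genes, by = "gene_id") %>%
    group_by(.data$gene_id, .data$transcript_id, .data$chrom, .data$strand) %>%
    arrange(.data$exon_rank, .by_group = TRUE) %>%
    reframe(intron_between(.data$start, .data$end, .data$strand[1])) %>%
    ungroup()
}

# introns between consecutive exons (exons in 5'->3' transcript order)
intron_between <- function(ex_start, ex_end, strand) {
  n <- length(ex_start)
  if (n < 2) {
    return(tibble(intron_rank = integer(0), start = integer(0), end = integer(0)))
  }
  if (strand == "+") {
    tibble(intron_rank = seq_len(n - 1L),
           start = ex_end[-n] + 1L, end = ex_start[-1L] - 1L)
  } else {
    tibble(intron_rank = seq_len(n - 1L),
           start = ex_end[-1L] + 1L, end = ex_start[-n] - 1L)
  }
}

validate_gene_model_set <- function(x) {
  # exons within a transcript: non-overlapping, strictly ordered 5'->3'
  chk <- x$exons %>%
    left_join(x$genes, by = "gene_id") %>%
    group_by(.data$transcript_id) %>%
    summarise(
      ok = {
        o <- order(.data$exon_rank)
        s <- .data$start[o]; e <- .data$end[o]
        if (.data$strand[1] == "+") all(diff(s) > 0) && all(s[-1] > e[-length(e)])
        else all(diff(s) < 0) && all(e[-1] < s[-length(s)])
      },
      .groups = "drop"
    )
  if (!all(chk$ok)) {
    abort(paste0("overlapping or mis-ordered exons in transcript ",
                 chk$transcript_id[!chk$ok][1]))
  }
  if (nrow(x$introns) > 0 && any(x$introns$end < x$introns$start)) {
    abort("derived intron with length < 1")
  }
  if (nrow(x$cds) > 0) {
    len <- transcript_lengths(x)
    cds <- x$cds %>% left_join(len, by = "transcript_id")
    if (any(is.na(cds$tx_length))) abort("CDS for unknown transcript")
    if (any(cds$cds_start < 1 | cds$cds_end > cds$tx_length)) {
      abort("CDS outside the exon union")
    }
    if (any(cds$cds_end - cds$cds_start + 1 < 3)) abort("CDS length < 3")
  }
  x
}

transcript_lengths <- function(models) {
  models$exons %>%
    group_by(.data$transcript_id) %>%
    summarise(tx_length = sum(.data$end - .data$start + 1L), .groups = "drop")
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat("<gene_model_set> ", nrow(x$genes), " genes, ",
      length(unique(x$exons$transcript_id)), " transcripts, ",
      nrow(x$introns), " introns, ", nrow(x$cds), " CDS records\n", sep = "")
  invisible(x)
}

# ordered exon table (5'->3') for one transcript, with transcript
# coordinates (tx_start/tx_end) of each exon
transcript_blocks <- function(models, transcript_id) {
  ex <- models$exons %>%
    filter(.data$transcript_id == !!transcript_id) %>%
    left_join(models$genes, by = "gene_id") %>%
    arrange(.data$exon_rank)
  if (nrow(ex) == 0) abort(paste0("unknown transcript: ", transcript_id))
  w <- ex$end - ex$start + 1L
  ex$tx_end <- cumsum(w)
  ex$tx_start <- ex$tx_end - w + 1L
  ex
}

# spliced mRNA sequence of a transcript (sense strand)
transcript_mrna <- function(models, transcript_id, genome) {
  genome <- as_genome(genome)
  ex <- transcript_blocks(models, transcript_id)
  paste(
    vapply(seq_len(nrow(ex)), function(i) {
      fetch_seq(genome, ex$chrom[i], ex$start[i], ex$end[i], ex$strand[i])
    }, character(1)),
    collapse = ""
  )
}
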