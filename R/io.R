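# Readers and writers for the standard formats: GTF gene models
# (rtracklayer), FASTA sequence (Biostrings), and the package's TSV
# dialects for junctions, boundary/region coverage, sample sheets and
# result tables.

#' Load gene models from a GTF file
#'
#' Reads `exon` and (optionally) `CDS` features, groups them by
#' `transcript_id`/`gene_id`, and returns a validated
#' [gene_model_set()]. Genomic CDS features are converted to transcript
#' coordinates. Transcripts without CDS are retained flagged non-coding.
#'
#' @param path Path to a GTF file.
#' @return A [gene_model_set()].
#' @export
load_annotation <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as_tibble(as.data.frame(gr))
  if (!all(c("gene_id", "transcript_id") %in% names(df))) {
    abort("GTF rows must carry gene_id and transcript_id attributes")
  }
  ex <- df %>%
    filter(.data$type == "exon") %>%
    transmute(
      gene_id = .data$gene_id, transcript_id = .data$transcript_id,
      chrom = as.character(.data$seqnames), strand = as.character(.data$strand),
      start = as.integer(.data$start), end = as.integer(.data$end)
    )
  if (nrow(ex) == 0) abort("GTF contains no exon features")
  # rank exons 5'->3' along the strand
  ex <- ex %>%
    mutate(.k = ifelse(.data$strand == "+", .data$start, -.data$start)) %>%
    arrange(.data$transcript_id, .data$.k) %>%
    group_by(.data$transcript_id) %>%
    mutate(exon_rank = row_number()) %>%
    ungroup() %>%
    select(-".k")

  genes <- ex %>% distinct(.data$gene_id, .data$chrom, .data$strand)
  if (anyDuplicated(genes$gene_id) > 0) {
    abort("gene with inconsistent chrom/strand across exons")
  }
  exons <- ex %>% select("gene_id", "transcript_id", "exon_rank", "start", "end")

  cds_rows <- df %>% filter(.data$type == "CDS")
  cds <- NULL
  if (nrow(cds_rows) > 0) {
    models0 <- gene_model_set(genes, exons)
    cds <- cds_rows %>%
      group_by(transcript_id = .data$transcript_id) %>%
      summarise(gstart = min(.data$start), gend = max(.data$end), .groups = "drop")
    cds <- cds %>%
      rowwise() %>%
      mutate(
        cds_start = genomic_to_tx(models0, .data$transcript_id,
                                  cds_pos_5p(models0, .data$transcript_id, .data$gstart, .data$gend)),
        cds_end = genomic_to_tx(models0, .data$transcript_id,
                                cds_pos_3p(models0, .data$transcript_id, .data$gstart, .data$gend))
      ) %>%
      ungroup() %>%
      select("transcript_id", "cds_start", "cds_end")
  }
  gene_model_set(genes, exons, cds)
}

cds_pos_5p <- function(models, tx, gstart, gend) {
  strand <- transcript_blocks(models, tx)$strand[1]
  if (strand == "+") gstart else gend
}
cds_pos_3p <- function(models, tx, gstart, gend) {
  strand <- transcript_blocks(models, tx)$strand[1]
  if (strand == "+") gend else gstart
}

# map a genomic position to transcript coordinates (must fall in an exon)
genomic_to_tx <- function(models, transcript_id, pos) {
  ex <- transcript_blocks(models, transcript_id)
  hit <- which(ex$start <= pos & pos <= ex$end)
  if (length(hit) != 1) abort(paste0("position ", pos, " not exonic in ", transcript_id))
  if (ex$strand[1] == "+") ex$tx_start[hit] + (pos - ex$start[hit])
  else ex$tx_start[hit] + (ex$end[hit] - pos)
}

#' Write gene models to a GTF file
#'
#' Inverse of [load_annotation()]: emits exon features plus genomic CDS
#' features derived from the transcript-coordinate CDS.
#'
#' @param models A [gene_model_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(models, path) {
  ex <- models$exons %>%
    left_join(models$genes, by = "gene_id") %>%
    mutate(type = "exon")
  cds <- NULL
  if (nrow(models$cds) > 0) {
    cds <- purrr::pmap(models$cds, function(transcript_id, cds_start, cds_end) {
      segs <- tx_interval_to_genomic(models, transcript_id, cds_start, cds_end)
      segs$transcript_id <- transcript_id
      seg_len <- segs$end - segs$start + 1L
      segs$phase <- as.integer((3L - cumsum(c(0L, seg_len[-length(seg_len)])) %% 3L) %% 3L)
      segs
    }) %>% list_rbind()
    gene_of <- models$exons %>% distinct(.data$transcript_id, .data$gene_id)
    cds <- cds %>%
      left_join(gene_of, by = "transcript_id") %>%
      left_join(models$genes %>% select("gene_id", "strand"), by = "gene_id") %>%
      mutate(type = "CDS", exon_rank = NA_integer_)
  }
  all_feats <- bind_rows(ex %>% mutate(phase = NA_integer_), cds)
  gr <- GenomicRanges::GRanges(
    seqnames = all_feats$chrom,
    ranges = IRanges::IRanges(all_feats$start, all_feats$end),
    strand = all_feats$strand,
    type = all_feats$type,
    gene_id = all_feats$gene_id,
    transcript_id = all_feats$transcript_id,
    phase = all_feats$phase
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

# genomic segments covered by a transcript-coordinate interval
tx_interval_to_genomic <- function(models, transcript_id, tx_from, tx_to) {
  ex <- transcript_blocks(models, transcript_id)
  hits <- ex %>% filter(.data$tx_end >= tx_from, .data$tx_start <= tx_to)
  purrr::pmap(hits, function(start, end, tx_start, tx_end, strand, chrom, ...) {
    lo <- max(tx_from, tx_start); hi <- min(tx_to, tx_end)
    if (strand == "+") {
      tibble(chrom = chrom, start = start + (lo - tx_start), end = start + (hi - tx_start))
    } else {
      tibble(chrom = chrom, start = end - (hi - tx_start), end = end - (lo - tx_start))
    }
  }) %>% list_rbind()
}

#' Load a genome FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of chromosome sequences.
#' @export
load_genome <- function(path) {
  as_genome(Biostrings::readDNAStringSet(path))
}

#' Write a genome FASTA
#' @param genome Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(as_genome(genome)), path)
  invisible(path)
}

#' Construct a junction table
#'
#' Per-sample splice-junction read counts, with optional exon-intron
#' boundary counts (intron-retention evidence) and exonic/intronic
#' region coverage.
#'
#' @param junctions Tibble: `chrom`, `intron_start`, `intron_end`,
#'   `strand`, `sample_id`, `count`.
#' @param boundaries Optional tibble: `chrom`, `intron_start`,
#'   `intron_end`, `strand`, `side` (`"left"`/`"right"`, 5'/3' end of
#'   the intron in genomic order), `sample_id`, `count`.
#' @param coverage Optional tibble: `region_id`, `class`
#'   (`"exonic"`/`"intronic"`), `sample_id`, `count`.
#' @return A `junction_table` (list of tibbles).
#' @export
junction_table <- function(junctions, boundaries = NULL, coverage = NULL) {
  junctions <- as_tibble(junctions)
  stopifnot_cols(junctions, c("chrom", "intron_start", "intron_end", "strand",
                              "sample_id", "count"), "junctions")
  if (any(junctions$intron_start > junctions$intron_end)) {
    abort("junction with intron_start > intron_end")
  }
  if (any(junctions$count < 0) || any(junctions$count != floor(junctions$count))) {
    abort("junction counts must be non-negative integers")
  }
  dup <- junctions %>%
    count(.data$chrom, .data$intron_start, .data$intron_end, .data$strand,
          .data$sample_id) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate (junction, sample) pair: ",
                 junction_key(dup$chrom[1], dup$intron_start[1],
                              dup$intron_end[1], dup$strand[1]),
                 " / ", dup$sample_id[1]))
  }
  if (!is.null(boundaries)) {
    boundaries <- as_tibble(boundaries)
    stopifnot_cols(boundaries, c("chrom", "intron_start", "intron_end", "strand",
                                 "side", "sample_id", "count"), "boundaries")
  }
  if (!is.null(coverage)) {
    coverage <- as_tibble(coverage)
    stopifnot_cols(coverage, c("region_id", "class", "sample_id", "count"), "coverage")
  }
  structure(list(junctions = junctions, boundaries = boundaries, coverage = coverage),
            class = "junction_table")
}

#' @export
print.junction_table <- function(x, ...) {
  cat("<junction_table> ", nrow(x$junctions), " junction records, ",
      length(unique(x$junctions$sample_id)), " samples",
      if (!is.null(x$boundaries)) paste0(", ", nrow(x$boundaries), " boundary records"),
      if (!is.null(x$coverage)) paste0(", ", nrow(x$coverage), " coverage records"),
      "\n", sep = "")
  invisible(x)
}

#' Load a junction TSV against a sample sheet
#'
#' The junction TSV dialect is the package's own minimal format: columns
#' `chrom`, `intron_start`, `intron_end`, `strand`, `sample_id`,
#' `count`. Every `sample_id` must appear in the sample sheet.
#'
#' @param path TSV path.
#' @param sheet Sample sheet tibble (see [sample_sheet()]).
#' @param boundaries_path,coverage_path Optional TSVs for boundary and
#'   region-coverage records.
#' @return A [junction_table()].
#' @export
load_junction_table <- function(path, sheet, boundaries_path = NULL,
                                coverage_path = NULL) {
  j <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot_cols(j, c("chrom", "intron_start", "intron_end", "strand",
                      "sample_id", "count"), path)
  unknown <- setdiff(unique(j$sample_id), sheet$sample_id)
  if (length(unknown) > 0) {
    abort(paste0("sample_id not in sample sheet: ", paste(unknown, collapse = ", ")))
  }
  b <- if (!is.null(boundaries_path)) readr::read_tsv(boundaries_path, show_col_types = FALSE)
  cv <- if (!is.null(coverage_path)) readr::read_tsv(coverage_path, show_col_types = FALSE)
  junction_table(j, b, cv)
}

#' Write a junction table's record tibbles to TSV
#' @param jt A [junction_table()].
#' @param path Junction TSV path; boundary/coverage files take suffixes
#'   `.boundaries.tsv` / `.coverage.tsv` next to it.
#' @return `path`, invisibly.
#' @export
write_junction_table <- function(jt, path) {
  write_results_table(jt$junctions, path)
  if (!is.null(jt$boundaries)) {
    write_results_table(jt$boundaries, paste0(path, ".boundaries.tsv"))
  }
  if (!is.null(jt$coverage)) {
    write_results_table(jt$coverage, paste0(path, ".coverage.tsv"))
  }
  invisible(path)
}

#' Convert 9-column splice-junction output to the junction dialect
#'
#' Convenience converter from the common aligner splice-junction format
#' (`chrom`, `start`, `end`, strand code 0/1/2, motif, annotated,
#' unique reads, multi reads, overhang), one file per sample.
#'
#' @param path Path to a 9-column tab-separated junction file.
#' @param sample_id Sample the file belongs to.
#' @param use_multi Add multi-mapping reads to the count (default FALSE).
#' @return Tibble in the package junction dialect.
#' @export
read_sj_file <- function(path, sample_id, use_multi = FALSE) {
  sj <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "strand_code",
                                            "motif", "annotated", "unique", "multi",
                                            "overhang"),
                        show_col_types = FALSE)
  strand <- c("0" = "+", "1" = "+", "2" = "-")[as.character(sj$strand_code)]
  tibble(
    chrom = sj$chrom, intron_start = as.integer(sj$start),
    intron_end = as.integer(sj$end),
    strand = unname(strand), sample_id = sample_id,
    count = as.integer(sj$unique + if (use_multi) sj$multi else 0L)
  ) %>% filter(!is.na(.data$strand))
}

#' Construct a sample sheet
#'
#' @param sample_id Unique sample identifiers.
#' @param cell_fraction One of `"BMMNC"`, `"CD34"`, `"cell_line"`,
#'   `"erythroid_d7"`, `"erythroid_d14"`.
#' @param genotype Genotype label(s), `";"`-separated
#'   (`"SF3B1:K700E"`, `"U2AF1:S34F"`, ..., `"none"`).
#' @param chx_status `"untreated"` or `"treated"`.
#' @param pair_id Links each CHX-treated sample to its untreated mate
#'   (NA outside the CHX experiment).
#' @param clone_id Isogenic clone identifier (NA for primary samples).
#' @param purity Fraction of cells expressing the variant (used by the
#'   expression-PSI association restriction), NA if unknown.
#' @return Tibble of class `sample_sheet`.
#' @export
sample_sheet <- function(sample_id, cell_fraction, genotype,
                         chx_status = "untreated", pair_id = NA_character_,
                         clone_id = NA_character_, purity = NA_real_) {
  sh <- tibble(
    sample_id = sample_id, cell_fraction = cell_fraction, genotype = genotype,
    chx_status = chx_status, pair_id = as.character(pair_id),
    clone_id = as.character(clone_id), purity = purity
  )
  validate_sample_sheet(sh)
}

validate_sample_sheet <- function(sh) {
  stopifnot_cols(sh, c("sample_id", "cell_fraction", "genotype", "chx_status"),
                 "sample sheet")
  if (anyDuplicated(sh$sample_id) > 0) abort("duplicate sample_id in sample sheet")
  fr_ok <- c("BMMNC", "CD34", "cell_line", "erythroid_d7", "erythroid_d14")
  if (!all(sh$cell_fraction %in% fr_ok)) {
    abort(paste0("unknown cell_fraction: ",
                 paste(setdiff(unique(sh$cell_fraction), fr_ok), collapse = ", ")))
  }
  if (!all(sh$chx_status %in% c("untreated", "treated"))) {
    abort("chx_status must be 'untreated' or 'treated'")
  }
  if (!"pair_id" %in% names(sh)) sh$pair_id <- NA_character_
  if (!"clone_id" %in% names(sh)) sh$clone_id <- NA_character_
  if (!"purity" %in% names(sh)) sh$purity <- NA_real_
  treated <- sh %>% filter(.data$chx_status == "treated", !is.na(.data$pair_id))
  untreated <- sh %>% filter(.data$chx_status == "untreated")
  for (p in treated$pair_id) {
    if (sum(untreated$pair_id == p, na.rm = TRUE) != 1) {
      abort(paste0("treated pair_id '", p, "' must match exactly one untreated sample"))
    }
  }
  new_ss_tbl(as_tibble(sh), "sample_sheet")
}

#' Load a sample sheet TSV
#' @param path TSV path.
#' @return Validated sample sheet tibble.
#' @export
load_sample_sheet <- function(path) {
  validate_sample_sheet(readr::read_tsv(path, show_col_types = FALSE,
                                        col_types = readr::cols(
                                          pair_id = readr::col_character(),
                                          clone_id = readr::col_character(),
                                          .default = readr::col_guess())))
}

#' Write a result tibble as a deterministic TSV
#'
#' Columns in their current order, floats at fixed precision
#' (`digits` significant digits), so that write -> read -> write is
#' byte-identical.
#'
#' @param records Data frame of results (an empty frame yields a
#'   header-only file).
#' @param path Output path.
#' @param digits Significant digits for floating-point columns.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path, digits = 10) {
  records <- as_tibble(records)
  out <- records %>%
    mutate(across(where(is.double), ~ signif(.x, digits)))
  # drop result-subclass attributes so read-back comparisons are plain
  class(out) <- class(tibble())
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}

#' Load a sample sheet-free results TSV
#' @param path TSV path.
#' @return Tibble.
#' @export
read_results_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
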