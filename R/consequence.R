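# Transcript-consequence annotation: reconstruct the alternative
# isoform implied by an event against its anchor transcript and
# classify the transcript-level consequence into five classes:
# truncating (frameshift or in-frame PTC), non-truncating, alternative
# first/last coding exon, non-coding.

# transcript introns in genomic coordinates with their rank
transcript_introns <- function(models, transcript_id) {
  models$introns %>% filter(.data$transcript_id == !!transcript_id)
}

# Express an event as an edit of the anchor transcript:
# at original transcript position `pos`, delete `del` bases and insert
# `ins` bases. Returns genomic description of the inserted segment too.
event_edit <- function(event, models) {
  tx <- event$transcript_id
  blocks <- transcript_blocks(models, tx)
  introns <- transcript_introns(models, tx)
  strand <- blocks$strand[1]
  find_intron <- function() {
    hit <- introns %>% filter(.data$start == event$anno_start,
                              .data$end == event$anno_end)
    if (nrow(hit) != 1) {
      abort(paste0("event ", event$event_id, " not anchored to an intron of ", tx))
    }
    hit
  }
  if (event$type %in% c("alt_3ss", "alt_5ss")) {
    intr <- find_intron()
    r <- intr$intron_rank
    k <- abs(event$offset)
    insertion <- event$offset < 0 && event$type == "alt_3ss" ||
      event$offset > 0 && event$type == "alt_5ss"
    if (event$type == "alt_3ss") {
      pos <- blocks$tx_start[r + 1]          # first base of downstream exon
      if (insertion) {
        # retained intronic segment adjacent to the acceptor
        seg <- if (strand == "+") c(event$anno_end - k + 1, event$anno_end)
        else c(event$anno_start, event$anno_start + k - 1)
        list(pos = pos, del = 0L, ins = k, seg = seg)
      } else {
        list(pos = pos, del = k, ins = 0L, seg = NULL)
      }
    } else {
      if (insertion) {
        pos <- blocks$tx_start[r + 1]        # insertion at the junction
        seg <- if (strand == "+") c(event$anno_start, event$anno_start + k - 1)
        else c(event$anno_end - k + 1, event$anno_end)
        list(pos = pos, del = 0L, ins = k, seg = seg)
      } else {
        pos <- blocks$tx_end[r] - k + 1      # truncated donor exon
        list(pos = pos, del = k, ins = 0L, seg = NULL)
      }
    }
  } else if (event$type == "intron_retention") {
    intr <- find_intron()
    r <- intr$intron_rank
    list(pos = blocks$tx_start[r + 1], del = 0L,
         ins = event$anno_end - event$anno_start + 1L,
         seg = c(event$anno_start, event$anno_end))
  } else if (event$type == "cassette_exon") {
    hit <- blocks %>% filter(.data$start == event$anno_start,
                             .data$end == event$anno_end)
    if (nrow(hit) != 1) {
      abort(paste0("event ", event$event_id, " skipped exon not in ", tx))
    }
    list(pos = hit$tx_start, del = hit$end - hit$start + 1L, ins = 0L, seg = NULL)
  } else if (event$type %in% c("mutually_exclusive", "alt_first_exon",
                               "alt_last_exon")) {
    # replace segment A (anno_*) of the anchor with segment B (alt_*)
    hit <- blocks %>% filter(.data$start <= event$anno_end,
                             .data$end >= event$anno_start)
    if (nrow(hit) == 0) {
      abort(paste0("event ", event$event_id, " segment not in ", tx))
    }
    list(pos = min(hit$tx_start), del = sum(hit$end - hit$start + 1L),
         ins = abs(event$alt_end - event$alt_start) + 1L,
         seg = c(min(event$alt_start, event$alt_end),
                 max(event$alt_start, event$alt_end)))
  } else {
    abort(paste0("unknown event type: ", event$type))
  }
}

#' Reconstruct the alternative isoform implied by an event
#'
#' Applies the event to its anchor transcript (inserted intronic
#' segment for upstream alternative 3' sites and intron retention,
#' removed exon for skipping, and so on), keeping the annotated start
#' codon, and returns the edited mRNA with the recomputed CDS (scanning
#' the reading frame from the annotated start for the terminating
#' stop).
#'
#' @param event One event row (tibble) from the catalog.
#' @param models A [gene_model_set()].
#' @param genome Named character vector or `DNAStringSet`.
#' @return List: `mrna` (edited sense sequence), `cds` (start/end in
#'   the edited transcript, NULL if the transcript is non-coding or the
#'   start codon was removed), `edit` (`pos`, `del`, `ins` in original
#'   transcript coordinates).
#' @export
reconstruct_isoform <- function(event, models, genome) {
  genome <- as_genome(genome)
  tx <- event$transcript_id
  mrna <- transcript_mrna(models, tx, genome)
  edit <- event_edit(event, models)
  strand <- models$genes$strand[models$genes$gene_id == event$gene_id]
  ins_seq <- if (!is.null(edit$seg)) {
    fetch_seq(genome, event$chrom, edit$seg[1], edit$seg[2], strand)
  } else ""
  new_mrna <- paste0(
    substr(mrna, 1, edit$pos - 1L), ins_seq,
    substr(mrna, edit$pos + edit$del, nchar(mrna))
  )
  cds_row <- models$cds %>% filter(.data$transcript_id == tx)
  cds <- NULL
  if (nrow(cds_row) == 1) {
    c0 <- cds_row$cds_start
    start_removed <- edit$del > 0L && edit$pos <= c0 + 2L &&
      edit$pos + edit$del - 1L >= c0
    start_split <- edit$del == 0L && edit$pos > c0 && edit$pos <= c0 + 2L
    start_intact <- !start_removed && !start_split
    edit_upstream <- (edit$del > 0L && edit$pos + edit$del - 1L < c0) ||
      (edit$del == 0L && edit$pos <= c0)
    new_c <- if (edit_upstream) c0 + edit$ins - edit$del else c0
    if (start_intact && substr(new_mrna, new_c, new_c + 2L) == "ATG") {
      stop_at <- scan_stop(new_mrna, new_c)
      cds <- c(new_c, if (is.na(stop_at)) nchar(new_mrna) else stop_at + 2L)
    }
  }
  list(mrna = new_mrna, cds = cds, edit = edit)
}

# first in-frame stop codon at or after `from`; returns its first base
scan_stop <- function(mrna, from) {
  n <- nchar(mrna)
  starts <- seq(from, n - 2L, by = 3L)
  if (length(starts) == 0) return(NA_integer_)
  cods <- substring(mrna, starts, starts + 2L)
  hit <- which(cods %in% stop_codons)
  if (length(hit) == 0) NA_integer_ else starts[hit[1]]
}

#' Classify the transcript-level consequence of splicing events
#'
#' Five classes: events entirely outside the CDS are `non_coding`;
#' events removing the first or last coding exon (start or stop codon)
#' are `alt_first_coding_exon` / `alt_last_coding_exon`; otherwise the
#' net length change inside the CDS decides: not a multiple of three is
#' `truncating` by `frameshift` (regardless of where the new stop
#' falls), a multiple of three with an in-frame stop strictly 5' of the
#' annotated stop is `truncating` by `PTC_in_frame`, and otherwise
#' `non_truncating`. The 50-nt exon-junction rule is emitted as an
#' auxiliary annotation (`ejc_rule_nmd`), not used for classification.
#'
#' @param events Event tibble (one or more rows).
#' @param models A [gene_model_set()].
#' @param genome Named character vector or `DNAStringSet`.
#' @return Tibble: `event_id`, `transcript_id`, `class`, `mechanism`
#'   (`frameshift`, `PTC_in_frame` or `none`), `indel_len` (net nt
#'   change), `ptc_pos` (transcript coordinate of the premature stop,
#'   NA otherwise), `ejc_rule_nmd`, `flagged_noncoding_tx`.
#' @export
classify_consequence <- function(events, models, genome) {
  genome <- as_genome(genome)
  map(seq_len(nrow(events)), function(i) {
    classify_one(events[i, ], models, genome)
  }) %>% list_rbind()
}

classify_one <- function(event, models, genome) {
  out <- tibble(
    event_id = event$event_id, transcript_id = event$transcript_id,
    class = NA_character_, mechanism = "none",
    indel_len = NA_integer_, ptc_pos = NA_integer_,
    ejc_rule_nmd = NA, flagged_noncoding_tx = FALSE
  )
  cds_row <- models$cds %>% filter(.data$transcript_id == event$transcript_id)
  if (nrow(cds_row) == 0) {
    out$class <- "non_coding"
    out$flagged_noncoding_tx <- TRUE
    return(out)
  }
  c0 <- cds_row$cds_start; e0 <- cds_row$cds_end
  rec <- reconstruct_isoform(event, models, genome)
  edit <- rec$edit
  net <- edit$ins - edit$del
  out$indel_len <- as.integer(net)

  if (event$type %in% c("alt_first_exon", "mutually_exclusive", "alt_last_exon")) {
    # terminal-exon replacement: consequence depends on whether the CDS
    # reaches into the replaced segment
    d1 <- edit$pos; d2 <- edit$pos + edit$del - 1L
    if (d2 < c0 || d1 > e0) { out$class <- "non_coding"; return(out) }
    if (d1 <= c0 + 2L && event$type != "alt_last_exon") {
      out$class <- "alt_first_coding_exon"; return(out)
    }
    if (d2 >= e0 - 2L) { out$class <- "alt_last_coding_exon"; return(out) }
    out$class <- "non_truncating"  # internal mutually-exclusive swap in frame
    if (net %% 3L != 0L) { out$class <- "truncating"; out$mechanism <- "frameshift" }
    return(out)
  }

  if (edit$del == 0L) {
    # pure insertion at `pos` (before the original base at pos)
    if (edit$pos <= c0) { out$class <- "non_coding"; return(out) }
    if (edit$pos > e0) { out$class <- "non_coding"; return(out) }
  } else {
    d1 <- edit$pos; d2 <- edit$pos + edit$del - 1L
    if (d2 < c0 || d1 > e0) { out$class <- "non_coding"; return(out) }
    touches_start <- d1 <= c0 + 2L && d2 >= c0
    touches_stop <- d2 >= e0 - 2L && d1 <= e0
    if (touches_start) { out$class <- "alt_first_coding_exon"; return(out) }
    if (touches_stop) { out$class <- "alt_last_coding_exon"; return(out) }
  }

  if (net %% 3L != 0L) {
    out$class <- "truncating"; out$mechanism <- "frameshift"
    if (!is.null(rec$cds)) {
      stop_at <- scan_stop(rec$mrna, rec$cds[1])
      expected_stop <- e0 - 2L + net
      if (!is.na(stop_at) && stop_at < expected_stop) {
        out$ptc_pos <- as.integer(stop_at)
      }
    }
  } else {
    stop_at <- if (!is.null(rec$cds)) scan_stop(rec$mrna, rec$cds[1]) else NA_integer_
    expected_stop <- e0 - 2L + net   # where the annotated stop now sits
    if (!is.na(stop_at) && stop_at < expected_stop) {
      out$class <- "truncating"; out$mechanism <- "PTC_in_frame"
      out$ptc_pos <- as.integer(stop_at)
    } else {
      out$class <- "non_truncating"
    }
  }
  if (!is.na(out$ptc_pos)) {
    out$ejc_rule_nmd <- ptc_in_nmd_zone(event, models, edit, out$ptc_pos)
  }
  out
}

# 50-nt rule: PTC more than 50 nt upstream of the final exon-exon
# junction of the edited transcript
ptc_in_nmd_zone <- function(event, models, edit, ptc_pos) {
  blocks <- transcript_blocks(models, event$transcript_id)
  jx <- blocks$tx_end[-nrow(blocks)]
  jx_new <- ifelse(jx >= edit$pos, jx + edit$ins - edit$del, jx)
  if (event$type == "cassette_exon") jx_new <- jx_new[jx != edit$pos - 1L + edit$del]
  if (length(jx_new) == 0) return(FALSE)
  last_jx <- max(jx_new)
  isTRUE(ptc_pos + 2L < last_jx - 50L)
}
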