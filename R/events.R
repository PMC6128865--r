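# Event enumeration from gene models + observed junctions, PSI
# quantification, and intronic read fractions.

intron_sites <- function(models) {
  models$introns %>%
    mutate(
      donor = ifelse(.data$strand == "+", .data$start, .data$end),
      acceptor = ifelse(.data$strand == "+", .data$end, .data$start),
      key = junction_key(.data$chrom, .data$start, .data$end, .data$strand)
    )
}

# anchor transcript per gene: the longest-CDS transcript, falling back
# to the longest transcript for non-coding genes
anchor_transcripts <- function(models) {
  cds_len <- models$cds %>%
    mutate(cds_len = .data$cds_end - .data$cds_start + 1L)
  models$exons %>%
    group_by(.data$gene_id, .data$transcript_id) %>%
    summarise(tx_len = sum(.data$end - .data$start + 1L), .groups = "drop") %>%
    left_join(cds_len, by = "transcript_id") %>%
    group_by(.data$gene_id) %>%
    arrange(desc(coalesce(.data$cds_len, 0L)), desc(.data$tx_len),
            .data$transcript_id, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    select("gene_id", anchor_transcript = "transcript_id")
}

#' Enumerate alternative splicing events
#'
#' Builds the event catalog from gene models plus observed junctions.
#' Intron-retention events are created for every annotated intron;
#' cassette exon, mutually exclusive and alternative first/last exon
#' events are derived from annotation-declared alternative structure;
#' novel (unannotated) observed junctions are assigned to at most one
#' event type by precedence: alternative 5'/3' splice site (shared
#' anchor site, within `max_offset` nt) first, then cassette exon (both
#' flanks annotated, one exon skipped). Junctions skipping more than
#' one exon ("coordinate" skips) are counted but not assigned;
#' junctions on chromosomes absent from the models are skipped with a
#' warning.
#'
#' @param models A [gene_model_set()].
#' @param junctions A [junction_table()] (or its `junctions` tibble).
#' @param max_offset Maximum distance (nt) between an alternative and
#'   its canonical splice site (default 500).
#' @return Tibble of events: `event_id`, `type`, `gene_id`,
#'   `transcript_id`, `chrom`, `strand`, `inclusion` / `exclusion`
#'   (";"-joined junction or `B:` boundary keys), `offset` (signed nt,
#'   alternative 5'/3' sites only; negative = insertion into the mRNA),
#'   `anno_start`/`anno_end` and `alt_start`/`alt_end` coordinates.
#'   Attribute `skipped` reports unassigned novel junction counts.
#' @export
enumerate_events <- function(models, junctions, max_offset = 500L) {
  jx <- if (inherits(junctions, "junction_table")) junctions$junctions else junctions
  anchors <- anchor_transcripts(models)
  anno <- intron_sites(models)

  obs <- jx %>%
    distinct(.data$chrom, .data$intron_start, .data$intron_end, .data$strand) %>%
    mutate(key = junction_key(.data$chrom, .data$intron_start, .data$intron_end,
                              .data$strand))
  off_chrom <- !obs$chrom %in% unique(models$genes$chrom)
  if (any(off_chrom)) {
    warn(paste0(sum(off_chrom), " junction(s) on chromosomes absent from the ",
                "gene models were skipped"))
    obs <- obs[!off_chrom, ]
  }
  novel <- obs %>% filter(!.data$key %in% anno$key)

  ev_ir <- ir_events(models, anno, anchors)
  ev_anno <- annotation_alternative_events(models, anno, anchors, obs)
  ev_novel <- novel_junction_events(models, anno, anchors, novel, max_offset)

  out <- bind_rows(ev_ir, ev_anno$events, ev_novel$events) %>%
    distinct(.data$event_id, .keep_all = TRUE) %>%
    arrange(.data$event_id)
  attr(out, "skipped") <- ev_novel$skipped
  out
}

ir_events <- function(models, anno, anchors) {
  ir <- anno %>%
    left_join(anchors, by = "gene_id") %>%
    # one IR event per distinct intron; anchored to the gene's anchor
    # transcript when it owns the intron, else any owner
    group_by(.data$chrom, .data$strand, .data$start, .data$end, .data$key) %>%
    summarise(
      gene_id = first(.data$gene_id),
      transcript_id = if (any(.data$transcript_id == .data$anchor_transcript))
        first(.data$anchor_transcript) else first(.data$transcript_id),
      .groups = "drop"
    )
  tibble(
    event_id = paste0("intron_retention|", ir$gene_id, "|", ir$key),
    type = "intron_retention", gene_id = ir$gene_id,
    transcript_id = ir$transcript_id, chrom = ir$chrom, strand = ir$strand,
    inclusion = paste0("B:", ir$key, ":left;B:", ir$key, ":right"),
    exclusion = ir$key, offset = NA_integer_,
    anno_start = ir$start, anno_end = ir$end,
    alt_start = NA_integer_, alt_end = NA_integer_
  )
}

# cassette / mutually exclusive / alternative first & last exon events
# declared by alternative transcript structure within a gene
annotation_alternative_events <- function(models, anno, anchors, obs) {
  events <- list()
  multi <- models$exons %>%
    group_by(.data$gene_id) %>%
    summarise(n_tx = n_distinct(.data$transcript_id), .groups = "drop") %>%
    filter(.data$n_tx > 1)
  for (g in multi$gene_id) {
    gi <- anno %>% filter(.data$gene_id == g)
    gx <- models$exons %>% filter(.data$gene_id == g)
    strand <- models$genes$strand[models$genes$gene_id == g]
    chrom <- models$genes$chrom[models$genes$gene_id == g]
    txs <- unique(gx$transcript_id)
    anchor <- anchors$anchor_transcript[anchors$gene_id == g]
    # annotated cassette: skip junction J in one transcript matching the
    # flanking introns a (same donor) and b (same acceptor) of another,
    # with exactly one exon of the other transcript inside J
    for (tskip in txs) {
      Js <- gi %>% filter(.data$transcript_id == tskip)
      for (j in seq_len(nrow(Js))) {
        J <- Js[j, ]
        for (tinc in setdiff(txs, tskip)) {
          ii <- gi %>% filter(.data$transcript_id == tinc)
          a <- ii %>% filter(.data$donor == J$donor, .data$key != J$key)
          b <- ii %>% filter(.data$acceptor == J$acceptor, .data$key != J$key)
          if (nrow(a) == 0 || nrow(b) == 0) next
          inside <- gx %>%
            filter(.data$transcript_id == tinc,
                   .data$start > J$start, .data$end < J$end)
          if (nrow(inside) != 1) next
          incl <- c(a$key[1], b$key[1])
          events[[length(events) + 1]] <- tibble(
            event_id = paste0("cassette_exon|", g, "|", J$key),
            type = "cassette_exon", gene_id = g, transcript_id = tinc,
            chrom = chrom, strand = strand,
            inclusion = join_keys(incl), exclusion = J$key,
            offset = NA_integer_,
            anno_start = inside$start, anno_end = inside$end,
            alt_start = J$start, alt_end = J$end
          )
        }
      }
    }
    # mutually exclusive exons: exon A in t1, exon B in t2, sharing
    # upstream donor and downstream acceptor, not overlapping
    for (t1 in txs) for (t2 in setdiff(txs, t1)) {
      i1 <- gi %>% filter(.data$transcript_id == t1) %>% arrange(.data$start)
      i2 <- gi %>% filter(.data$transcript_id == t2) %>% arrange(.data$start)
      if (nrow(i1) < 2 || nrow(i2) < 2) next
      for (k in seq_len(nrow(i1) - 1)) {
        up1 <- i1[k, ]; dn1 <- i1[k + 1, ]
        m_up <- i2 %>% filter(.data$donor == up1$donor)
        m_dn <- i2 %>% filter(.data$acceptor == dn1$acceptor)
        if (nrow(m_up) == 0 || nrow(m_dn) == 0) next
        exA <- gx %>% filter(.data$transcript_id == t1,
                             .data$start > min(up1$start, dn1$start),
                             .data$end < max(up1$end, dn1$end))
        exB <- gx %>% filter(.data$transcript_id == t2,
                             .data$start > min(m_up[1, ]$start, m_dn[1, ]$start),
                             .data$end < max(m_up[1, ]$end, m_dn[1, ]$end))
        if (nrow(exA) != 1 || nrow(exB) != 1) next
        if (exA$start <= exB$end && exB$start <= exA$end) next  # overlap
        if (identical(sort(c(up1$key, dn1$key)),
                      sort(c(m_up[1, ]$key, m_dn[1, ]$key)))) next
        ids <- sort(c(paste0(exA$start, "-", exA$end), paste0(exB$start, "-", exB$end)))
        events[[length(events) + 1]] <- tibble(
          event_id = paste0("mutually_exclusive|", g, "|", ids[1], "|", ids[2]),
          type = "mutually_exclusive", gene_id = g, transcript_id = t1,
          chrom = chrom, strand = strand,
          inclusion = join_keys(c(up1$key, dn1$key)),
          exclusion = join_keys(c(m_up[1, ]$key, m_dn[1, ]$key)),
          offset = NA_integer_,
          anno_start = exA$start, anno_end = exA$end,
          alt_start = exB$start, alt_end = exB$end
        )
      }
    }
    # alternative first/last exons: first (last) introns sharing
    # acceptor (donor) with distinct terminal exons; anchor transcript
    # provides the exclusion side
    first_introns <- gi %>%
      group_by(.data$transcript_id) %>%
      slice_min(.data$intron_rank, n = 1) %>%
      ungroup()
    last_introns <- gi %>%
      group_by(.data$transcript_id) %>%
      slice_max(.data$intron_rank, n = 1) %>%
      ungroup()
    af <- first_introns %>% filter(.data$transcript_id == anchor)
    for (tx in setdiff(txs, anchor)) {
      fi <- first_introns %>% filter(.data$transcript_id == tx)
      if (nrow(fi) == 0 || nrow(af) == 0) next
      if (fi$acceptor == af$acceptor && fi$donor != af$donor &&
          fi$key != af$key) {
        events[[length(events) + 1]] <- tibble(
          event_id = paste0("alt_first_exon|", g, "|", fi$key),
          type = "alt_first_exon", gene_id = g, transcript_id = anchor,
          chrom = chrom, strand = strand,
          inclusion = fi$key, exclusion = af$key, offset = NA_integer_,
          anno_start = af$start, anno_end = af$end,
          alt_start = fi$start, alt_end = fi$end
        )
      }
      li <- last_introns %>% filter(.data$transcript_id == tx)
      al <- last_introns %>% filter(.data$transcript_id == anchor)
      if (nrow(li) == 1 && nrow(al) == 1 &&
          li$donor == al$donor && li$acceptor != al$acceptor &&
          li$key != al$key) {
        events[[length(events) + 1]] <- tibble(
          event_id = paste0("alt_last_exon|", g, "|", li$key),
          type = "alt_last_exon", gene_id = g, transcript_id = anchor,
          chrom = chrom, strand = strand,
          inclusion = li$key, exclusion = al$key, offset = NA_integer_,
          anno_start = al$start, anno_end = al$end,
          alt_start = li$start, alt_end = li$end
        )
      }
    }
  }
  ev <- if (length(events) > 0) list_rbind(events) else NULL
  # require junction support: at least one observed junction per side
  if (!is.null(ev)) {
    seen <- obs$key
    supported <- purrr::map_lgl(seq_len(nrow(ev)), function(i) {
      any(split_keys(ev$inclusion[i]) %in% seen) &&
        any(split_keys(ev$exclusion[i]) %in% seen)
    })
    ev <- ev[supported, ]
  }
  list(events = ev)
}

novel_junction_events <- function(models, anno, anchors, novel, max_offset) {
  events <- list()
  skipped <- c(coordinate_skip = 0L, unassigned = 0L)
  anno <- anno %>% left_join(anchors, by = "gene_id")
  for (i in seq_len(nrow(novel))) {
    nv <- novel[i, ]
    nv_donor <- if (nv$strand == "+") nv$intron_start else nv$intron_end
    nv_acceptor <- if (nv$strand == "+") nv$intron_end else nv$intron_start
    cand <- anno %>% filter(.data$chrom == nv$chrom, .data$strand == nv$strand)
    same_donor <- cand %>% filter(.data$donor == nv_donor)
    same_acceptor <- cand %>% filter(.data$acceptor == nv_acceptor)
    acceptor_annotated <- nrow(same_acceptor) > 0
    donor_annotated <- nrow(same_donor) > 0

    if (donor_annotated && !acceptor_annotated) {
      # alternative 3' splice site: offset negative when the novel
      # acceptor lies upstream (transcript direction) of the canonical
      same_donor <- same_donor %>%
        mutate(off = if (nv$strand == "+") nv_acceptor - .data$acceptor
               else .data$acceptor - nv_acceptor) %>%
        filter(abs(.data$off) <= max_offset, .data$off != 0) %>%
        arrange(abs(.data$off))
      if (nrow(same_donor) > 0) {
        a <- same_donor[1, ]
        events[[length(events) + 1]] <- alt_site_event("alt_3ss", a, nv)
        next
      }
      skipped["unassigned"] <- skipped["unassigned"] + 1L
      next
    }
    if (acceptor_annotated && !donor_annotated) {
      same_acceptor <- same_acceptor %>%
        mutate(off = if (nv$strand == "+") .data$donor - nv_donor
               else nv_donor - .data$donor) %>%
        filter(abs(.data$off) <= max_offset, .data$off != 0) %>%
        arrange(abs(.data$off))
      if (nrow(same_acceptor) > 0) {
        a <- same_acceptor[1, ]
        events[[length(events) + 1]] <- alt_site_event("alt_5ss", a, nv)
        next
      }
      skipped["unassigned"] <- skipped["unassigned"] + 1L
      next
    }
    if (donor_annotated && acceptor_annotated) {
      # both flanks annotated: exon-skipping junction if donor/acceptor
      # come from the same transcript with >= 1 exon in between
      hit <- inner_join(
        same_donor %>% select("transcript_id", "gene_id", "anchor_transcript",
                              up_key = "key", up_rank = "intron_rank",
                              up_start = "start", up_end = "end"),
        same_acceptor %>% select("transcript_id", dn_key = "key",
                                 dn_rank = "intron_rank",
                                 dn_start = "start", dn_end = "end"),
        by = "transcript_id"
      ) %>% filter(.data$dn_rank > .data$up_rank)
      if (nrow(hit) > 0) {
        hit <- hit %>% arrange(.data$dn_rank - .data$up_rank)
        h <- hit[1, ]
        n_skipped <- h$dn_rank - h$up_rank
        if (n_skipped == 1) {
          gx <- models$exons %>%
            filter(.data$transcript_id == h$transcript_id,
                   .data$start > min(nv$intron_start, nv$intron_end),
                   .data$end < max(nv$intron_start, nv$intron_end))
          events[[length(events) + 1]] <- tibble(
            event_id = paste0("cassette_exon|", h$gene_id, "|", nv$key),
            type = "cassette_exon", gene_id = h$gene_id,
            transcript_id = h$transcript_id, chrom = nv$chrom,
            strand = nv$strand,
            inclusion = join_keys(c(h$up_key, h$dn_key)), exclusion = nv$key,
            offset = NA_integer_,
            anno_start = gx$start[1], anno_end = gx$end[1],
            alt_start = nv$intron_start, alt_end = nv$intron_end
          )
        } else {
          skipped["coordinate_skip"] <- skipped["coordinate_skip"] + 1L
        }
        next
      }
    }
    skipped["unassigned"] <- skipped["unassigned"] + 1L
  }
  list(events = if (length(events) > 0) list_rbind(events) else NULL,
       skipped = skipped)
}

alt_site_event <- function(type, a, nv) {
  tx <- if (!is.na(a$anchor_transcript) && a$transcript_id == a$anchor_transcript)
    a$anchor_transcript else a$transcript_id
  tibble(
    event_id = paste0(type, "|", a$gene_id, "|", nv$key),
    type = type, gene_id = a$gene_id, transcript_id = tx,
    chrom = nv$chrom, strand = nv$strand,
    inclusion = nv$key, exclusion = a$key, offset = as.integer(a$off),
    anno_start = a$start, anno_end = a$end,
    alt_start = nv$intron_start, alt_end = nv$intron_end
  )
}

#' Compute per-event, per-sample PSI
#'
#' PSI = 100 * inclusion / (inclusion + exclusion), where each side's
#' evidence is the mean read count over its junction (or, for intron
#' retention, exon-intron boundary) set — identical to summing for
#' single-junction sides. PSI is undefined (NA) when inclusion +
#' exclusion < `min_reads`. Events referencing junctions absent from
#' the table are treated as zero counts.
#'
#' @param events Event tibble from [enumerate_events()] (or the
#'   simulator's catalog).
#' @param junctions A [junction_table()].
#' @param min_reads Read threshold below which PSI is undefined.
#' @return Tibble: `event_id`, `sample_id`, `inclusion_reads`,
#'   `exclusion_reads`, `total_reads`, `psi`.
#' @export
compute_psi <- function(events, junctions, min_reads = 5) {
  jt <- if (inherits(junctions, "junction_table")) junctions else
    junction_table(junctions)
  samples <- unique(jt$junctions$sample_id)
  jx <- jt$junctions %>%
    mutate(key = junction_key(.data$chrom, .data$intron_start, .data$intron_end,
                              .data$strand)) %>%
    select("key", "sample_id", "count")
  if (!is.null(jt$boundaries)) {
    bd <- jt$boundaries %>%
      mutate(key = paste0("B:", junction_key(.data$chrom, .data$intron_start,
                                             .data$intron_end, .data$strand),
                          ":", .data$side)) %>%
      select("key", "sample_id", "count")
    jx <- bind_rows(jx, bd)
  }
  side_tbl <- events %>%
    select("event_id", "inclusion", "exclusion") %>%
    pivot_longer(c("inclusion", "exclusion"), names_to = "side",
                 values_to = "key") %>%
    separate_rows("key", sep = ";")
  # evidence aggregation is the hot path on large cohorts
  sdt <- as.data.table(side_tbl)
  jdt <- as.data.table(jx)
  m <- jdt[sdt, on = "key", allow.cartesian = TRUE, nomatch = NULL]
  agg <- m[, list(count = mean(count)), by = c("event_id", "side", "sample_id")]
  wide <- dcast.data.table(agg, event_id + sample_id ~ side,
                           value.var = "count",
                           fill = NA_real_)
  full <- wide[CJ(event_id = events$event_id, sample_id = samples),
               on = c("event_id", "sample_id")]
  if (!"inclusion" %in% names(full)) full$inclusion <- NA_real_
  if (!"exclusion" %in% names(full)) full$exclusion <- NA_real_
  evidence <- as_tibble(full) %>%
    mutate(inclusion_reads = coalesce(.data$inclusion, 0),
           exclusion_reads = coalesce(.data$exclusion, 0))
  evidence %>%
    mutate(
      total_reads = .data$inclusion_reads + .data$exclusion_reads,
      psi = ifelse(.data$total_reads >= min_reads,
                   100 * .data$inclusion_reads / .data$total_reads, NA_real_)
    ) %>%
    select("event_id", "sample_id", "inclusion_reads", "exclusion_reads",
           "total_reads", "psi")
}

#' Per-sample intronic read fraction
#'
#' The proportion of sequencing reads mapped to intronic regions:
#' intronic / (intronic + exonic), per sample. Samples with zero total
#' reads get NA and are flagged.
#'
#' @param coverage Region coverage tibble (`region_id`, `class`,
#'   `sample_id`, `count`) or a [junction_table()] carrying one.
#' @return Tibble: `sample_id`, `intronic`, `exonic`, `fraction`,
#'   `flagged`.
#' @export
intronic_read_fraction <- function(coverage) {
  if (inherits(coverage, "junction_table")) coverage <- coverage$coverage
  if (is.null(coverage)) abort("no region coverage records available")
  stopifnot_cols(coverage, c("region_id", "class", "sample_id", "count"),
                 "coverage")
  if (!all(c("exonic", "intronic") %in% coverage$class)) {
    abort("coverage must contain both exonic and intronic classes")
  }
  coverage %>%
    group_by(.data$sample_id) %>%
    summarise(
      intronic = sum(.data$count[.data$class == "intronic"]),
      exonic = sum(.data$count[.data$class == "exonic"]),
      .groups = "drop"
    ) %>%
    mutate(
      fraction = ifelse(.data$intronic + .data$exonic > 0,
                        .data$intronic / (.data$intronic + .data$exonic),
                        NA_real_),
      flagged = .data$intronic + .data$exonic == 0
    )
}
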