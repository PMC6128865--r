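# Seeded synthetic-study generator: reference (genome + gene models +
# planted events), mutation-stratified cohorts of junction counts with
# beta-binomial PSI noise, paired CHX experiments, isogenic clones, and
# a complete ground-truth ledger.
#
# Sequence construction happens in transcript ("sense") space per gene
# (one gene per chromosome); minus-strand genes are reverse-complemented
# into genomic space at the end.

# run code under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: the two intron
#' regimes (short/GC-rich vs long/GC-poor, parameterized to median 0.41
#' vs 1.8 kb and GC 54% vs 43%), the cohort design (30 mutated vs 40
#' control per cell fraction), the planted effect table, beta-binomial
#' overdispersion, junction depth, NMD degradation, the expression
#' model, and exon motif composition.
#'
#' @param seed Integer seed; fixing it fixes every emitted byte.
#' @param n_genes Number of genes (one per chromosome).
#' @param exons_per_gene Integer range (min, max) of exons per gene.
#' @param exon_length Integer range of exon lengths (nt).
#' @param intron_regimes Tibble with `regime`, `meanlog`, `sdlog`
#'   (lognormal length model) and `gc`. Defaults realize medians 410
#'   and 1800 nt with IQRs 0.16-1.1 and 0.58-5.8 kb, GC 0.54 and 0.43.
#' @param p_short_intron Probability an intron belongs to the
#'   short/GC-rich regime.
#' @param cohort Tibble `group`, `cell_fraction`, `n` describing the
#'   per-fraction design.
#' @param effects Planted effect table (see [default_effects()]); NULL
#'   plants nothing (a null cohort).
#' @param n_null_events Number of background events with no group
#'   difference, allocated across unused intron/exon slots.
#' @param null_types Event types used for background events.
#' @param baseline_psi_range Range baseline PSI values are drawn from
#'   for background events.
#' @param rho Beta-binomial overdispersion of junction sampling.
#' @param depth_mean,depth_size Negative-binomial model of per-event
#'   informative read totals.
#' @param gene_base_mean,gene_disp Negative-binomial expression model
#'   (mean across genes is lognormal around `gene_base_mean`).
#' @param couple_expression Couple gene counts of genes with planted
#'   truncating events to `(1 - truncating PSI/100)`.
#' @param intronic_fraction Baseline intronic read fraction for region
#'   coverage records.
#' @param ir_depletion Named vector of per-group multipliers on the
#'   intronic fraction (global intron-retention depletion).
#' @param minus3_probs Named probabilities of the acceptor -3 base.
#' @param motif Motif composition: `base_rate` (motifs per nt),
#'   `motifs`, and `multipliers[class, quarter]` matrices per motif.
#' @param emit_sequences Generate sequences (FALSE skips the genome for
#'   count-only studies; much faster).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 40L,
                       exons_per_gene = c(5L, 7L),
                       exon_length = c(90L, 240L),
                       intron_regimes = default_intron_regimes(),
                       p_short_intron = 0.5,
                       cohort = default_cohort(),
                       effects = default_effects(),
                       n_null_events = 0L,
                       null_types = c("cassette_exon", "intron_retention", "alt_3ss"),
                       baseline_psi_range = c(20, 80),
                       rho = 0.02,
                       depth_mean = 100, depth_size = 20,
                       gene_base_mean = 200, gene_disp = 0.1,
                       couple_expression = TRUE,
                       intronic_fraction = 0.10,
                       ir_depletion = NULL,
                       minus3_probs = c(T = 0.7, C = 0.2, A = 0.1),
                       motif = default_motif_config(),
                       emit_sequences = TRUE) {
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene), exon_length = as.integer(exon_length),
    intron_regimes = as_tibble(intron_regimes), p_short_intron = p_short_intron,
    cohort = as_tibble(cohort), effects = if (!is.null(effects)) as_tibble(effects),
    n_null_events = as.integer(n_null_events), null_types = null_types,
    baseline_psi_range = baseline_psi_range, rho = rho,
    depth_mean = depth_mean, depth_size = depth_size,
    gene_base_mean = gene_base_mean, gene_disp = gene_disp,
    couple_expression = couple_expression,
    intronic_fraction = intronic_fraction, ir_depletion = ir_depletion,
    minus3_probs = minus3_probs, motif = motif,
    emit_sequences = emit_sequences
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$rho < 0 || cfg$rho >= 1) abort("rho must be in [0, 1)")
  if (any(cfg$cohort$n < 2)) abort("group sizes must be >= 2")
  if (!is.null(cfg$effects) && nrow(cfg$effects) > 0) {
    psi_hi <- cfg$effects$baseline_psi + pmax(cfg$effects$delta_psi, 0)
    psi_lo <- cfg$effects$baseline_psi + pmin(cfg$effects$delta_psi, 0)
    if (any(psi_hi > 100) || any(psi_lo < 0)) {
      abort("baseline_psi + delta_psi must stay within [0, 100]")
    }
    known <- cfg$effects$group %in% cfg$cohort$group
    if (!all(known)) {
      abort(paste0("effect group absent from cohort design: ",
                   paste(unique(cfg$effects$group[!known]), collapse = ", ")))
    }
  }
  invisible(cfg)
}

#' @rdname sim_config
#' @export
default_intron_regimes <- function() {
  # lognormal parameters matched to median (IQR) 0.41 (0.16-1.1) kb vs
  # 1.8 (0.58-5.8) kb; sdlog = mean(log(q3/med), log(med/q1)) / 0.6745
  tibble(
    regime = c("short_gc_rich", "long_gc_poor"),
    meanlog = log(c(410, 1800)),
    sdlog = c(1.43, 1.70),
    gc = c(0.54, 0.43)
  )
}

#' @rdname sim_config
#' @export
default_cohort <- function() {
  tibble(
    group = c("SF3B1:K700E", "SRSF2:P95H", "none"),
    cell_fraction = "CD34",
    n = c(30L, 30L, 40L)
  )
}

#' Default planted effect table
#'
#' The generator's default conditions: alternative 3' splice-site
#' spikes specific to the SF3B1 group (near-zero control PSI, large
#' increase, mixed transcript consequences, NMD on the PTC events),
#' small broad intron-retention decreases, and cassette-exon inclusion
#' shifts for the SRSF2 group.
#'
#' @return Tibble with one row per planted event: `type`, `group`,
#'   `baseline_psi`, `delta_psi`, `consequence` (one of
#'   `truncating_ptc`, `truncating_frameshift`, `non_truncating`,
#'   `non_coding`, `alt_first_coding_exon`, `alt_last_coding_exon`),
#'   `nmd_d` (NMD read-survival factor in (0,1]; reads of the measured
#'   isoform are thinned by `nmd_d` in untreated samples) and
#'   `expr_fc` (expression fold change planted on the gene).
#' @export
default_effects <- function() {
  bind_rows(
    tibble(type = "alt_3ss", group = "SF3B1:K700E", baseline_psi = 1,
           delta_psi = 34,
           consequence = rep(c("truncating_ptc", "truncating_frameshift",
                               "non_truncating", "non_coding"), c(4, 3, 2, 1)),
           nmd_d = rep(c(0.25, 1), c(4, 6)), expr_fc = 1),
    tibble(type = "intron_retention", group = "SF3B1:K700E", baseline_psi = 30,
           delta_psi = -6, consequence = "truncating_ptc", nmd_d = 1,
           expr_fc = 1, .rows = 12),
    tibble(type = "cassette_exon", group = "SRSF2:P95H", baseline_psi = 50,
           delta_psi = rep(c(15, -15), each = 4),
           consequence = "truncating_frameshift", nmd_d = 1, expr_fc = 1)
  )
}

#' @rdname sim_config
#' @export
default_motif_config <- function() {
  base <- matrix(1, nrow = 3, ncol = 4,
                 dimnames = list(c("included", "skipped", "constitutive"), NULL))
  ccng <- base; ccng["included", 4] <- 2; ccng["skipped", 4] <- 0.5
  ggng <- base; ggng["included", 4] <- 0.5; ggng["skipped", 4] <- 2
  list(base_rate = 1 / 80,
       multipliers = list(CCNG = ccng, GGNG = ggng))
}

bases <- c("A", "C", "G", "T")

random_dna <- function(n, gc = 0.41) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(bases, n, replace = TRUE, prob = p), collapse = "")
}

stop_codons <- c("TAA", "TAG", "TGA")

# n random sense codons, none of them stops
random_codons <- function(n) {
  if (n <= 0) return(character(0))
  out <- paste0(sample(bases, n, TRUE), sample(bases, n, TRUE), sample(bases, n, TRUE))
  bad <- out %in% stop_codons
  while (any(bad)) {
    k <- sum(bad)
    out[bad] <- paste0(sample(bases, k, TRUE), sample(bases, k, TRUE),
                       sample(c("C", "G"), k, TRUE))
    bad <- out %in% stop_codons
  }
  out
}

codons_of <- function(seq) {
  n <- nchar(seq) %/% 3
  substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
}

# Build an insert of length k whose in-frame content is controlled.
# `phase` = number of bases already consumed of the current codon at the
# insertion point (0..2). `kind`: "ptc" plants one in-frame TAA;
# "clean" guarantees no in-frame stop. Trailing `fixed_tail` bases are
# preserved verbatim (e.g. the "AG" acceptor closing the insert).
controlled_insert <- function(k, phase, kind, fixed_tail = "") {
  tail_n <- nchar(fixed_tail)
  body <- strsplit(random_dna(k, gc = 0.55), "")[[1]]
  if (tail_n > 0) body[(k - tail_n + 1):k] <- strsplit(fixed_tail, "")[[1]]
  # positions of in-frame codon starts relative to insert (1-based):
  # first full codon begins after (3 - phase) %% 3 filler bases
  lead <- (3 - phase) %% 3
  starts <- seq(lead + 1, k - 2, by = 3)
  starts <- starts[starts >= 1 & starts + 2 <= k]
  fix_codon <- function(i) {
    # replace a mutable base of codon at i with C (stops contain no C)
    for (j in i:(i + 2)) {
      if (j <= k - tail_n) { body[j] <<- "C"; return(invisible(NULL)) }
    }
    abort("cannot repair insert codon without touching fixed tail")
  }
  for (i in starts) {
    cod <- paste(body[i:(i + 2)], collapse = "")
    if (cod %in% stop_codons) fix_codon(i)
  }
  if (kind == "ptc") {
    usable <- starts[starts + 2 <= k - tail_n]
    if (length(usable) == 0) abort("insert too short to host an in-frame PTC")
    i <- usable[ceiling(length(usable) / 2)]
    body[i:(i + 2)] <- c("T", "A", "A")
  }
  paste(body, collapse = "")
}

# ---------------------------------------------------------------------------
# simulate_reference

#' Simulate the reference: genome, gene models, planted events, truth
#'
#' Generates multi-exon gene models with CDS, exon sequences realizing
#' the configured motif rates, introns realizing the two length/GC
#' regimes, and the planted event geometry from the config's effect
#' table plus background null events. Deterministic under a fixed seed.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_reference`: `models` ([gene_model_set()]),
#'   `genome` (named character; NULL when `emit_sequences = FALSE`),
#'   `events` (SpliceEvent-schema tibble), `truth` (ground-truth
#'   ledger), `exon_classes` (per-exon motif class labels).
#' @export
simulate_reference <- function(config) {
  with_seed(config$seed, simulate_reference_impl(config))
}

simulate_reference_impl <- function(cfg) {
  effects <- cfg$effects %||% tibble(type = character(), group = character(),
                                     baseline_psi = double(), delta_psi = double(),
                                     consequence = character(), nmd_d = double(),
                                     expr_fc = double())
  n_planted <- nrow(effects)
  if (n_planted > cfg$n_genes) {
    abort(paste0("effect table has ", n_planted, " events but only ",
                 cfg$n_genes, " genes; raise n_genes or shrink effects"))
  }
  # background slots: roughly (exons_per_gene - 1) per gene beyond planted genes
  genes <- list(); exon_class_rows <- list(); event_rows <- list(); truth_rows <- list()
  null_left <- cfg$n_null_events
  gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  strands <- rep(c("+", "-"), length.out = cfg$n_genes)

  for (gi in seq_len(cfg$n_genes)) {
    planted <- if (gi <= n_planted) effects[gi, ] else NULL
    n_null_here <- 0L
    if (gi > n_planted && null_left > 0) {
      n_null_here <- min(null_left, cfg$exons_per_gene[2] - 2L)
    }
    g <- build_gene(cfg, gene_ids[gi], strands[gi], planted, n_null_here)
    if (n_null_here > 0) {
      achieved <- nrow(g$truth) - as.integer(!is.null(planted))
      null_left <- null_left - achieved
    }
    genes[[gi]] <- g
    exon_class_rows[[gi]] <- g$exon_classes
    event_rows[[gi]] <- g$events
    truth_rows[[gi]] <- g$truth
  }
  if (null_left > 0) {
    warn(paste0(null_left, " background events could not be allocated; ",
                "increase n_genes or exons_per_gene"))
  }

  exons <- list_rbind(map(genes, "exons"))
  gene_tbl <- list_rbind(map(genes, "gene"))
  cds <- list_rbind(map(genes, "cds"))
  models <- gene_model_set(gene_tbl, exons, cds)
  genome <- if (cfg$emit_sequences) {
    unlist(map(genes, "genome"))
  }
  structure(
    list(models = models, genome = genome,
         events = list_rbind(event_rows),
         truth = list_rbind(truth_rows),
         exon_classes = list_rbind(exon_class_rows),
         intron_regime = list_rbind(map(genes, "intron_regime"))),
    class = "sim_reference"
  )
}

#' @export
print.sim_reference <- function(x, ...) {
  cat("<sim_reference> ", nrow(x$models$genes), " genes, ",
      nrow(x$events), " events (", sum(x$truth$delta_psi != 0),
      " planted with effects)\n", sep = "")
  invisible(x)
}

# Build one gene in sense space, then convert to genomic coordinates.
build_gene <- function(cfg, gene_id, strand, planted, n_null_here) {
  n_ex <- sample(seq(cfg$exons_per_gene[1], cfg$exons_per_gene[2]), 1)
  conseq <- if (!is.null(planted)) planted$consequence else NA_character_
  # geometry requirements for the planted consequence
  cds_start_exon <- 1L
  cds_end_exon_back <- 0L   # offset from the last exon for the stop codon
  if (!is.null(planted)) {
    if (conseq == "non_coding") cds_start_exon <- 3L       # event in 5' UTR
    if (conseq == "alt_first_coding_exon") cds_start_exon <- 2L
    # a skipped last coding exon must carry the stop codon
    if (conseq == "alt_last_coding_exon") cds_end_exon_back <- 1L
    n_ex <- max(n_ex, 5L)
  }
  ex_len <- sample(seq(cfg$exon_length[1], cfg$exon_length[2]), n_ex, replace = TRUE)
  ex_len <- ex_len - (ex_len %% 3)  # keeps cassette skips frame-neutral by default
  regime_i <- sample(cfg$intron_regimes$regime, n_ex - 1, replace = TRUE,
                     prob = c(cfg$p_short_intron, 1 - cfg$p_short_intron))
  reg <- cfg$intron_regimes[match(regime_i, cfg$intron_regimes$regime), ]
  # floor keeps room for splice sites and planted offsets; cap keeps the
  # lognormal tail from blowing up the toy genome
  in_len <- as.integer(pmin(50000, pmax(70, round(rlnorm(n_ex - 1, reg$meanlog,
                                                         reg$sdlog)))))

  # choose the slot (intron or exon index) for the planted event
  event_plan <- plan_gene_events(cfg, planted, conseq, n_ex, cds_start_exon,
                                 n_null_here)
  # frame control for planted events: frame-shifting cassette skips need
  # a non-multiple-of-3 exon; in-frame intron retention needs a
  # multiple-of-3 intron (and frame-shifting retention the opposite)
  for (p in event_plan) {
    if (p$type == "cassette_exon" &&
        identical(p$consequence, "truncating_frameshift")) {
      ex_len[p$exon_idx] <- ex_len[p$exon_idx] + 1L
    }
    if (p$type == "intron_retention" && !is.na(p$consequence %||% NA_character_)) {
      ii <- p$intron_idx
      if (identical(p$consequence, "truncating_frameshift")) {
        if (in_len[ii] %% 3L == 0L) in_len[ii] <- in_len[ii] + 1L
      } else {
        in_len[ii] <- in_len[ii] - (in_len[ii] %% 3L)
      }
    }
  }

  tx_end <- cumsum(ex_len); tx_start <- tx_end - ex_len + 1L
  tx_len <- tx_end[n_ex]
  cds_end_exon <- n_ex - cds_end_exon_back
  cds_start_tx <- tx_start[cds_start_exon] + 12L
  target_end <- tx_end[cds_end_exon] - 12L
  cds_len <- target_end - cds_start_tx + 1L
  cds_len <- cds_len - (cds_len %% 3L)
  cds_end_tx <- cds_start_tx + cds_len - 1L
  stopifnot(cds_end_tx >= tx_start[cds_end_exon] + 2L)

  seqs <- NULL
  if (cfg$emit_sequences) {
    n_cod <- cds_len / 3L
    mrna <- paste0(random_dna(cds_start_tx - 1L),
                   "ATG", paste(random_codons(n_cod - 2L), collapse = ""), "TAA",
                   random_dna(tx_len - cds_end_tx))
    exon_seq <- substring(mrna, tx_start, tx_end)
    intron_seq <- vapply(seq_len(n_ex - 1), function(i) {
      s <- random_dna(in_len[i], gc = reg$gc[i])
      substr(s, 1, 2) <- "GT"
      substr(s, in_len[i] - 1L, in_len[i]) <- "AG"
      m3 <- sample(names(cfg$minus3_probs), 1, prob = cfg$minus3_probs)
      substr(s, in_len[i] - 2L, in_len[i] - 2L) <- m3
      s
    }, character(1))
    seqs <- list(exon = exon_seq, intron = intron_seq)
  }

  # internal-exon motif classes; planted cassette exons get the class
  # matching their direction of change
  classes <- rep("constitutive", n_ex)
  for (p in event_plan) {
    if (p$type == "cassette_exon" && !is.na(p$delta_psi) && p$delta_psi != 0) {
      classes[p$exon_idx] <- if (p$delta_psi > 0) "included" else "skipped"
    }
  }
  if (cfg$emit_sequences && !is.null(cfg$motif)) {
    for (e in seq_len(n_ex)[-c(1, n_ex)]) {
      seqs$exon[e] <- plant_motifs(seqs$exon[e], classes[e], cfg$motif)
    }
    # repair any in-frame stop the motif planting may have created
    seqs <- repair_cds_stops(seqs, tx_start, tx_end, cds_start_tx, cds_end_tx)
  }

  # apply planted sequence edits (controlled inserts for alt sites / IR)
  events <- list(); truth <- list()
  for (p in event_plan) {
    built <- realize_event(cfg, p, gene_id, strand, n_ex, ex_len, in_len,
                           tx_start, tx_end, cds_start_tx, cds_end_tx, seqs)
    seqs <- built$seqs
    events[[length(events) + 1]] <- built$event
    truth[[length(truth) + 1]] <- built$truth
  }

  # assemble genomic coordinates (gene occupies its chromosome fully)
  chrom <- paste0("chr_", gene_id)
  glen <- tx_len + sum(in_len)
  sense_ex_start <- integer(n_ex); sense_ex_end <- integer(n_ex)
  pos <- 0L
  for (e in seq_len(n_ex)) {
    sense_ex_start[e] <- pos + 1L
    sense_ex_end[e] <- pos + ex_len[e]
    pos <- pos + ex_len[e] + if (e < n_ex) in_len[e] else 0L
  }
  s2g <- function(p) if (strand == "+") p else glen - p + 1L
  ex_gstart <- pmin(s2g(sense_ex_start), s2g(sense_ex_end))
  ex_gend <- pmax(s2g(sense_ex_start), s2g(sense_ex_end))

  tx_id <- paste0(gene_id, ".t1")
  exons <- tibble(gene_id = gene_id, transcript_id = tx_id,
                  exon_rank = seq_len(n_ex), start = ex_gstart, end = ex_gend)
  gene <- tibble(gene_id = gene_id, chrom = chrom, strand = strand)
  cds <- tibble(transcript_id = tx_id, cds_start = cds_start_tx, cds_end = cds_end_tx)

  genome <- NULL
  if (cfg$emit_sequences) {
    sense <- character(2 * n_ex - 1)
    sense[seq(1, 2 * n_ex - 1, by = 2)] <- seqs$exon
    if (n_ex > 1) sense[seq(2, 2 * n_ex - 2, by = 2)] <- seqs$intron
    sense <- paste(sense, collapse = "")
    genome <- setNames(if (strand == "+") sense else revcomp(sense), chrom)
  }

  # finalize event coordinate conversion (sense -> genomic) and keys
  ev_tbl <- list_rbind(map(events, function(ev) {
    finalize_event(ev, gene_id, tx_id, chrom, strand, glen,
                   sense_ex_start, sense_ex_end, ex_len, in_len)
  }))
  truth_tbl <- if (length(truth) > 0) {
    list_rbind(map2(truth, seq_along(truth), function(tr, i) {
      tr$event_id <- ev_tbl$event_id[i]
      tr
    }))
  } else {
    tibble()
  }

  exon_classes <- tibble(
    gene_id = gene_id, transcript_id = tx_id, exon_rank = seq_len(n_ex),
    class = classes,
    sequence = if (cfg$emit_sequences) seqs$exon else NA_character_
  )[-c(1, n_ex), ]

  intron_sense_start <- sense_ex_end[-n_ex] + 1L
  intron_sense_end <- sense_ex_start[-1L] - 1L
  intron_regime <- tibble(
    gene_id = gene_id, chrom = chrom, strand = strand,
    intron_rank = seq_len(n_ex - 1L),
    start = pmin(s2g(intron_sense_start), s2g(intron_sense_end)),
    end = pmax(s2g(intron_sense_start), s2g(intron_sense_end)),
    regime = regime_i
  )

  list(gene = gene, exons = exons, cds = cds, genome = genome,
       events = ev_tbl, truth = truth_tbl, exon_classes = exon_classes,
       intron_regime = intron_regime)
}

# decide which intron/exon slots host the planted + null events
plan_gene_events <- function(cfg, planted, conseq, n_ex, cds_start_exon,
                             n_null_here) {
  plans <- list()
  used_introns <- integer(0); used_exons <- integer(0)
  add_plan <- function(type, intron_idx = NA_integer_, exon_idx = NA_integer_,
                       row = NULL) {
    p <- list(type = type, intron_idx = intron_idx, exon_idx = exon_idx,
              group = if (!is.null(row)) row$group else NA_character_,
              baseline_psi = if (!is.null(row)) row$baseline_psi else
                runif(1, cfg$baseline_psi_range[1], cfg$baseline_psi_range[2]),
              delta_psi = if (!is.null(row)) row$delta_psi else 0,
              consequence = if (!is.null(row)) row$consequence else NA_character_,
              nmd_d = if (!is.null(row)) row$nmd_d else 1,
              expr_fc = if (!is.null(row)) row$expr_fc else 1)
    plans[[length(plans) + 1]] <<- p
  }
  if (!is.null(planted)) {
    if (planted$type %in% c("alt_3ss", "alt_5ss")) {
      # non_coding events sit on a 5'-UTR intron; others inside the CDS
      ii <- if (identical(conseq, "non_coding")) 1L else cds_start_exon + 1L
      used_introns <- c(used_introns, ii)
      add_plan(planted$type, intron_idx = ii, row = planted)
    } else if (planted$type == "intron_retention") {
      ii <- cds_start_exon + 1L
      used_introns <- c(used_introns, ii)
      add_plan("intron_retention", intron_idx = ii, row = planted)
    } else if (planted$type == "cassette_exon") {
      ei <- switch(conseq,
                   alt_first_coding_exon = cds_start_exon,
                   alt_last_coding_exon = n_ex - 1L,
                   cds_start_exon + 1L)
      ei <- max(2L, min(ei, n_ex - 1L))
      used_exons <- c(used_exons, ei)
      used_introns <- c(used_introns, ei - 1L, ei)
      add_plan("cassette_exon", exon_idx = ei, row = planted)
    } else {
      abort(paste0("unsupported planted event type: ", planted$type))
    }
  }
  if (n_null_here > 0) {
    free_introns <- setdiff(seq_len(n_ex - 1), used_introns)
    free_exons <- setdiff(seq(2, n_ex - 1), used_exons)
    for (k in seq_len(n_null_here)) {
      ty <- cfg$null_types[1 + (k - 1) %% length(cfg$null_types)]
      if (ty == "cassette_exon") {
        cand <- free_exons[(free_exons - 1) %in% free_introns &
                             free_exons %in% free_introns]
        if (length(cand) == 0) ty <- "intron_retention"
        else {
          ei <- cand[1]
          free_exons <- setdiff(free_exons, ei)
          free_introns <- setdiff(free_introns, c(ei - 1L, ei))
          add_plan("cassette_exon", exon_idx = ei)
          next
        }
      }
      if (length(free_introns) == 0) break
      ii <- free_introns[1]
      free_introns <- free_introns[-1]
      add_plan(ty, intron_idx = ii)
    }
  }
  plans
}

# Plant Poisson-placed motif occurrences at the configured per-quarter
# rates. Chance background matches are scrubbed first so the realized
# motif density is the planted rate, not rate + background.
plant_motifs <- function(seq, class, motif_cfg) {
  L <- nchar(seq)
  if (L < 16) return(seq)
  seq <- scrub_motifs(seq, names(motif_cfg$multipliers))
  chars <- strsplit(seq, "")[[1]]
  seg <- segment_bounds(L, 4)
  occupied <- rep(FALSE, L)
  planted_starts <- setNames(vector("list", length(motif_cfg$multipliers)),
                             names(motif_cfg$multipliers))
  for (m in names(motif_cfg$multipliers)) {
    pat <- strsplit(m, "")[[1]]
    w <- length(pat)
    mult <- motif_cfg$multipliers[[m]][class, ]
    for (q in 1:4) {
      rate <- motif_cfg$base_rate * mult[q]
      n_here <- rpois(1, rate * (seg$end[q] - seg$start[q] + 1))
      if (n_here == 0) next
      pos_max <- min(seg$end[q], L - w + 1)
      if (pos_max < seg$start[q]) next
      # place without overlapping an earlier planted occurrence, so the
      # realized density equals the planted rate
      cand <- sample(seg$start[q]:pos_max)
      placed <- 0L
      for (p in cand) {
        if (placed >= n_here) break
        if (any(occupied[p:(p + w - 1)])) next
        real <- vapply(pat, function(b) {
          switch(b, N = sample(bases, 1), S = sample(c("C", "G"), 1), b)
        }, character(1))
        chars[p:(p + w - 1)] <- real
        occupied[p:(p + w - 1)] <- TRUE
        planted_starts[[m]] <- c(planted_starts[[m]], p)
        placed <- placed + 1L
      }
    }
  }
  # Planting can create chance matches overlapping the planted
  # occurrences; destroy every non-planted match by mutating one of its
  # constrained (non-N) bases outside the planted footprints, so the
  # realized density equals the planted rate.
  motifs <- names(motif_cfg$multipliers)
  for (pass in 1:4) {
    s <- paste(chars, collapse = "")
    changed <- FALSE
    for (m in motifs) {
      mp <- strsplit(m, "")[[1]]
      fixed_off <- which(mp != "N") - 1L
      hits <- gregexpr(paste0("(?=", iupac_regex(m), ")"), s, perl = TRUE)[[1]]
      if (hits[1] == -1) next
      for (p in setdiff(hits, planted_starts[[m]])) {
        mut <- p + fixed_off
        mut <- mut[!occupied[mut]]
        if (length(mut) > 0) {
          chars[mut[1]] <- "T"
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  paste(chars, collapse = "")
}

# destroy chance IUPAC matches by mutating the second base to T
# (neither CCNG nor GGNG admits T there); iterate until clean
scrub_motifs <- function(seq, motifs) {
  pats <- vapply(motifs, iupac_regex, character(1))
  chars <- strsplit(seq, "")[[1]]
  for (pass in 1:6) {
    s <- paste(chars, collapse = "")
    at <- integer(0)
    for (p in pats) {
      # lookahead finds overlapping match starts
      hits <- gregexpr(paste0("(?=", p, ")"), s, perl = TRUE)[[1]]
      if (hits[1] != -1) at <- c(at, hits + 1L)
    }
    if (length(at) == 0) break
    chars[unique(at)] <- "T"
  }
  paste(chars, collapse = "")
}

iupac_regex <- function(motif) {
  map <- c(A = "A", C = "C", G = "G", T = "T", N = ".", S = "[CG]",
           W = "[AT]", R = "[AG]", Y = "[CT]")
  paste(map[strsplit(motif, "")[[1]]], collapse = "")
}
repair_cds_stops <- function(seqs, tx_start, tx_end, cds_start_tx, cds_end_tx) {
  mrna <- paste(seqs$exon, collapse = "")
  cds <- substr(mrna, cds_start_tx, cds_end_tx)
  cods <- codons_of(cds)
  bad <- which(cods %in% stop_codons)
  bad <- bad[bad < length(cods)]  # keep the terminal stop
  if (length(bad) > 0) {
    for (b in bad) {
      pos <- cds_start_tx + 3 * (b - 1)   # first base of the codon
      substr(mrna, pos + 2, pos + 2) <- "C"
    }
    seqs$exon <- substring(mrna, tx_start, tx_end)
  }
  seqs
}

# Apply one planned event to the gene: controlled sequence edits plus a
# sense-space event description (converted to genomic later).
realize_event <- function(cfg, p, gene_id, strand, n_ex, ex_len, in_len,
                          tx_start, tx_end, cds_start_tx, cds_end_tx, seqs) {
  truth <- tibble(
    gene_id = gene_id, type = p$type, group = p$group %||% NA_character_,
    baseline_psi = p$baseline_psi, delta_psi = p$delta_psi,
    consequence = p$consequence %||% NA_character_,
    nmd_d = p$nmd_d, expr_fc = p$expr_fc
  )
  if (p$type %in% c("alt_3ss", "alt_5ss")) {
    ii <- p$intron_idx
    kind <- switch(p$consequence %||% "non_truncating",
                   truncating_ptc = "ptc",
                   truncating_frameshift = "clean",
                   "clean")
    k <- if (identical(p$consequence, "truncating_frameshift")) 20L else 21L
    # phase of the reading frame at the insertion point
    jpos <- if (p$type == "alt_3ss") tx_end[ii] else tx_end[ii]
    phase <- if (is.na(cds_start_tx) || jpos < cds_start_tx) 0L
    else (jpos - cds_start_tx + 1L) %% 3L
    if (cfg$emit_sequences) {
      s <- seqs$intron[ii]; L <- nchar(s)
      if (p$type == "alt_3ss") {
        # retain the last k intronic bases; novel acceptor AG just upstream
        ins <- controlled_insert(k, phase, kind, fixed_tail = "AG")
        substr(s, L - k + 1L, L) <- ins
        substr(s, L - k - 1L, L - k) <- "AG"
      } else {
        # retain the first k intronic bases; insert starts with the
        # canonical GT, novel donor GT placed just downstream
        ins <- controlled_insert(k, phase, kind)
        substr(ins, 1, 2) <- "GT"
        substr(s, 1L, k) <- ins
        substr(s, k + 1L, k + 2L) <- "GT"
      }
      seqs$intron[ii] <- s
    }
    ev <- list(type = p$type, intron_idx = ii, offset = if (p$type == "alt_3ss") -k else k)
  } else if (p$type == "intron_retention") {
    ii <- p$intron_idx
    if (cfg$emit_sequences && !is.na(p$consequence %||% NA_character_)) {
      # control the retained intron's in-frame content
      s <- seqs$intron[ii]; L <- nchar(s)
      phase <- if (tx_end[ii] < cds_start_tx) 0L
      else (tx_end[ii] - cds_start_tx + 1L) %% 3L
      kind <- if (identical(p$consequence, "truncating_ptc")) "ptc" else "clean"
      if ((L %% 3L != 0L) && identical(p$consequence, "non_truncating")) {
        abort("non_truncating intron retention needs intron length % 3 == 0")
      }
      body <- controlled_insert(L, phase, kind, fixed_tail = "AG")
      substr(body, 1, 2) <- "GT"
      m3 <- substr(s, L - 2L, L - 2L)
      substr(body, L - 2L, L - 2L) <- m3
      seqs$intron[ii] <- body
    }
    ev <- list(type = "intron_retention", intron_idx = ii, offset = NA_integer_)
  } else if (p$type == "cassette_exon") {
    ev <- list(type = "cassette_exon", exon_idx = p$exon_idx, offset = NA_integer_)
  } else {
    abort(paste0("unknown event type: ", p$type))
  }
  list(seqs = seqs, event = ev, truth = truth)
}

# convert a sense-space event description to the genomic event record
finalize_event <- function(ev, gene_id, tx_id, chrom, strand, glen,
                           sense_ex_start, sense_ex_end, ex_len, in_len) {
  s2g <- function(p) if (strand == "+") p else glen - p + 1L
  grange <- function(a, b) c(min(s2g(a), s2g(b)), max(s2g(a), s2g(b)))
  n_ex <- length(sense_ex_start)
  intron_sense <- function(i) c(sense_ex_end[i] + 1L, sense_ex_start[i + 1L] - 1L)

  if (ev$type %in% c("alt_3ss", "alt_5ss")) {
    i <- ev$intron_idx
    anno <- intron_sense(i)
    k <- abs(ev$offset)
    novel <- if (ev$type == "alt_3ss") c(anno[1], anno[2] - k)
    else c(anno[1] + k, anno[2])
    ag <- grange(anno[1], anno[2]); ng <- grange(novel[1], novel[2])
    incl <- junction_key(chrom, ng[1], ng[2], strand)
    excl <- junction_key(chrom, ag[1], ag[2], strand)
    tibble(event_id = paste0(ev$type, "|", gene_id, "|", incl),
           type = ev$type, gene_id = gene_id, transcript_id = tx_id,
           chrom = chrom, strand = strand,
           inclusion = incl, exclusion = excl, offset = ev$offset,
           anno_start = ag[1], anno_end = ag[2],
           alt_start = ng[1], alt_end = ng[2])
  } else if (ev$type == "intron_retention") {
    i <- ev$intron_idx
    anno <- intron_sense(i)
    ag <- grange(anno[1], anno[2])
    jk <- junction_key(chrom, ag[1], ag[2], strand)
    incl <- paste0("B:", jk, ":", c("left", "right"))
    tibble(event_id = paste0("intron_retention|", gene_id, "|", jk),
           type = "intron_retention", gene_id = gene_id, transcript_id = tx_id,
           chrom = chrom, strand = strand,
           inclusion = join_keys(incl), exclusion = jk, offset = NA_integer_,
           anno_start = ag[1], anno_end = ag[2],
           alt_start = NA_integer_, alt_end = NA_integer_)
  } else { # cassette_exon (skip of annotated exon e)
    e <- ev$exon_idx
    up <- intron_sense(e - 1L); dn <- intron_sense(e)
    gu <- grange(up[1], up[2]); gd <- grange(dn[1], dn[2])
    skip <- grange(up[1], dn[2])
    exg <- grange(sense_ex_start[e], sense_ex_end[e])
    incl <- c(junction_key(chrom, gu[1], gu[2], strand),
              junction_key(chrom, gd[1], gd[2], strand))
    excl <- junction_key(chrom, skip[1], skip[2], strand)
    tibble(event_id = paste0("cassette_exon|", gene_id, "|", excl),
           type = "cassette_exon", gene_id = gene_id, transcript_id = tx_id,
           chrom = chrom, strand = strand,
           inclusion = join_keys(incl), exclusion = excl, offset = NA_integer_,
           anno_start = exg[1], anno_end = exg[2],
           alt_start = skip[1], alt_end = skip[2])
  }
}
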