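# Gene model container, GTF/FASTA/TSV readers and writers.

test_that("gene models derive introns and validate coordinates", {
  m <- toy_models("+")
  expect_equal(nrow(m$introns), 2)
  expect_equal(m$introns$start, c(31L, 161L))
  expect_equal(m$introns$end, c(130L, 260L))

  m2 <- toy_models("-")
  expect_equal(nrow(m2$introns), 2)
  # minus-strand intron 1 (5'-most in transcript direction) is the
  # genomically rightmost
  expect_equal(m2$introns$start[m2$introns$intron_rank == 1], 161L)

  expect_error(
    gene_model_set(
      genes = tibble(gene_id = "g", chrom = "c", strand = "+"),
      exons = tibble(gene_id = "g", transcript_id = "t", exon_rank = 1:2,
                     start = c(1L, 5L), end = c(10L, 20L))
    ),
    "overlapping"
  )
  expect_error(
    gene_model_set(
      genes = tibble(gene_id = "g", chrom = "c", strand = "+"),
      exons = tibble(gene_id = "g", transcript_id = "t", exon_rank = 1,
                     start = 10L, end = 30L),
      cds = tibble(transcript_id = "t", cds_start = 1L, cds_end = 40L)
    ),
    "exon union"
  )
})

test_that("GTF loading counts features and rejects malformed coordinates", {
  gtf <- tempfile(fileext = ".gtf")
  lines <- c(
    'chr1\ttest\texon\t1\t100\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\ttest\texon\t201\t300\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\ttest\texon\t401\t500\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'
  )
  writeLines(lines, gtf)
  m <- load_annotation(gtf)
  expect_equal(nrow(m$genes), 1)
  expect_equal(nrow(m$exons), 3)
  expect_equal(nrow(m$introns), 2)

  bad <- tempfile(fileext = ".gtf")
  writeLines('chr1\ttest\texon\t100\t50\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
             bad)
  expect_error(load_annotation(bad))
})

test_that("annotation and genome round-trip losslessly through GTF/FASTA", {
  cfg <- sim_config(seed = 3, n_genes = 8, effects = default_effects()[1:5, ],
                    n_null_events = 5)
  ref <- simulate_reference(cfg)
  gtf <- tempfile(fileext = ".gtf")
  fa <- tempfile(fileext = ".fa")
  write_annotation(ref$models, gtf)
  write_genome(ref$genome, fa)
  m2 <- load_annotation(gtf)
  g2 <- load_genome(fa)
  ord <- function(x) as.data.frame(arrange(as_tibble(x), across(everything())))
  expect_equal(ord(m2$genes), ord(ref$models$genes))
  expect_equal(ord(m2$exons), ord(ref$models$exons))
  expect_equal(ord(m2$cds), ord(ref$models$cds))
  expect_identical(g2[sort(names(g2))], ref$genome[sort(names(ref$genome))])
})

test_that("junction tables validate and load against the sample sheet", {
  sheet <- sample_sheet(c("s1", "s2"), "BMMNC", c("SF3B1:K700E", "none"))
  tsv <- tempfile(fileext = ".tsv")
  jx <- tibble(
    chrom = "chr1", intron_start = c(101L, 101L, 501L, 501L),
    intron_end = c(200L, 200L, 600L, 600L), strand = "+",
    sample_id = c("s1", "s2", "s1", "s2"), count = c(5L, 8L, 0L, 3L)
  )
  readr::write_tsv(jx, tsv)
  jt <- load_junction_table(tsv, sheet)
  expect_equal(nrow(jt$junctions), 4)
  expect_equal(length(unique(junction_key(jt$junctions$chrom,
                                          jt$junctions$intron_start,
                                          jt$junctions$intron_end,
                                          jt$junctions$strand))), 2)

  readr::write_tsv(jx %>% mutate(sample_id = c("s1", "s9", "s1", "s2")), tsv)
  expect_error(load_junction_table(tsv, sheet), "s9")

  expect_error(junction_table(jx %>% mutate(count = c(-1L, 1L, 1L, 1L))),
               "non-negative")
  expect_error(junction_table(bind_rows(jx, jx[1, ])), "duplicate")
  expect_error(junction_table(jx %>% mutate(intron_start = intron_end + 1L)),
               "intron_start")
})

test_that("simulator junction output loads losslessly", {
  st <- small_study(seed = 21)
  path <- tempfile(fileext = ".tsv")
  write_junction_table(st$sim$junctions, path)
  jt2 <- load_junction_table(path, st$sim$sheet,
                             boundaries_path = paste0(path, ".boundaries.tsv"))
  ord <- function(x) as.data.frame(arrange(as_tibble(x), across(everything())))
  expect_equal(ord(jt2$junctions), ord(st$sim$junctions$junctions))
  expect_equal(ord(jt2$boundaries), ord(st$sim$junctions$boundaries))
})

test_that("results tables are deterministic, re-loadable and idempotent", {
  path <- tempfile(fileext = ".tsv")
  write_results_table(tibble(a = character(), b = double()), path)
  expect_equal(readLines(path), "a\tb")

  d <- tibble(event_id = c("e1", "e2", "e3"), p = c(0.1234567890123, 1e-12, NA))
  write_results_table(d, path)
  expect_equal(length(readLines(path)), 4)
  back <- read_results_table(path)
  path2 <- tempfile(fileext = ".tsv")
  write_results_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("sample sheets enforce unique ids and CHX pairing", {
  expect_error(sample_sheet(c("a", "a"), "BMMNC", "none"), "duplicate")
  expect_error(
    sample_sheet(c("a", "b"), "BMMNC", "none",
                 chx_status = c("treated", "treated"),
                 pair_id = c("p1", "p1")),
    "exactly one untreated"
  )
  sh <- sample_sheet(c("a", "b"), "BMMNC", "SF3B1:K700E",
                     chx_status = c("untreated", "treated"),
                     pair_id = c("p1", "p1"))
  expect_s3_class(sh, "sample_sheet")
})

test_that("the 9-column junction dialect converts to the package dialect", {
  path <- tempfile(fileext = ".tab")
  writeLines(c("chr1\t101\t200\t1\t1\t1\t12\t3\t30",
               "chr1\t501\t600\t2\t2\t0\t7\t0\t25"), path)
  out <- read_sj_file(path, "s1")
  expect_equal(out$strand, c("+", "-"))
  expect_equal(out$count, c(12L, 7L))
  expect_equal(read_sj_file(path, "s1", use_multi = TRUE)$count, c(15L, 7L))
})
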