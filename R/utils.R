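# Shared helpers: junction keys, sequence utilities, validation.

#' Build a strand-qualified junction key
#'
#' Junctions are identified by the first and last intronic base
#' (1-based, inclusive) plus strand, e.g. `"chr1:101-200:+"`.
#'
#' @param chrom Chromosome name.
#' @param intron_start,intron_end First and last intronic base (1-based).
#' @param strand `"+"` or `"-"`.
#' @return Character vector of keys.
#' @export
junction_key <- function(chrom, intron_start, intron_end, strand) {
  paste0(chrom, ":", intron_start, "-", intron_end, ":", strand)
}

# parse "chr:start-end:strand" keys back into a tibble (chromosome
# names must not contain ":")
parse_junction_key <- function(key) {
  parts <- data.table::tstrsplit(key, ":", fixed = TRUE)
  if (length(parts) != 3 || !all(parts[[3]] %in% c("+", "-"))) {
    abort("malformed junction key(s)")
  }
  coords <- data.table::tstrsplit(parts[[2]], "-", fixed = TRUE)
  if (length(coords) != 2) abort("malformed junction key(s)")
  out <- tibble(
    chrom = parts[[1]],
    intron_start = suppressWarnings(as.integer(coords[[1]])),
    intron_end = suppressWarnings(as.integer(coords[[2]])),
    strand = parts[[3]]
  )
  if (anyNA(out$intron_start) || anyNA(out$intron_end)) {
    abort("malformed junction key(s)")
  }
  out
}

# ";"-joined set columns used in event tables
join_keys <- function(keys) paste(keys, collapse = ";")
split_keys <- function(x) stringr::str_split(x, ";")[[1]]

the_complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# reverse-complement for plain character vectors (Biostrings used for
# DNAStringSet workloads; this avoids repeated class round-trips)
revcomp <- function(x) {
  vapply(x, function(s) {
    chars <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    paste(the_complement[chars], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# extract [start, end] (1-based inclusive) from a named character genome,
# reverse-complementing for "-" strand so the result reads 5'->3'
fetch_seq <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) {
    abort(paste0("chromosome not in genome: ", chrom))
  }
  s <- genome[[chrom]]
  if (start < 1 || end > nchar(s)) {
    abort(paste0("window [", start, ",", end, "] out of bounds on ", chrom))
  }
  out <- substr(s, start, end)
  if (strand == "-") out <- revcomp(out) else out
}

gc_fraction <- function(seqs) {
  gc <- str_count(seqs, "[GCgc]")
  gc / nchar(seqs)
}

# coerce a DNAStringSet or character vector to named character
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    setNames(as.character(genome), names(genome))
  } else if (is.character(genome)) {
    if (is.null(names(genome))) abort("genome must be named by chromosome")
    genome
  } else {
    abort("genome must be a named character vector or DNAStringSet")
  }
}

stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0(what, " is missing column(s): ", paste(missing, collapse = ", ")))
  }
  invisible(df)
}

new_ss_tbl <- function(df, subclass) {
  class(df) <- c(subclass, class(tibble()))
  df
}
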