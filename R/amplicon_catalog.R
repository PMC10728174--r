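#' @title Primer pools of multiplexed DSB amplicons
#'
#' @description
#' A *primer pool* describes the multiplexed PCR that tiles endonuclease-cut
#' loci: for each amplicon it records the forward and reverse primers, the
#' full amplicon reference sequence, the genomic interval it came from, the
#' offset of the cut midpoint within the amplicon, and the repair class the
#' locus is prone to (`HR`, `NHEJ`, or `UNCUT` for undamaged controls).
#'
#' Pools are held as a `data.frame` of class `primer_pool` (one row per
#' locus) carrying the primer-matching policy (`match_len`, `max_mismatch`)
#' as attributes. All internal coordinates are 0-based half-open; `cut_offset`
#' is the 0-based offset of the first base 3' of the cut midpoint.
#'
#' @name primer_pool
NULL

POOL_COLUMNS <- c("locus_id", "repair_class", "chrom", "start", "end",
                  "cut_offset", "fwd_primer", "rev_primer", "ref_seq")

#' Load and validate a primer pool from TSV
#'
#' Reads a tab-separated pool table with columns `locus_id`, `repair_class`,
#' `chrom`, `start`, `end`, `cut_offset` (empty for `UNCUT` loci),
#' `fwd_primer`, `rev_primer`, `ref_seq`, and checks every pool invariant:
#' unique ids, reference length equal to `end - start`, reference beginning
#' with the forward primer and ending with the reverse complement of the
#' reverse primer, cut offsets present exactly for cut loci, and a
#' collision-free primer set (no two primers within `max_mismatch` of each
#' other over `match_len` bases), which is what guarantees that primer-based
#' read classification is unambiguous.
#'
#' @param path Path to the TSV file.
#' @param match_len Number of 5' bases over which primers are matched;
#'   `NULL` (default) means the full length of each primer.
#' @param max_mismatch Mismatches tolerated when matching a primer
#'   (default 1, one sequencing error).
#' @return A validated `primer_pool`.
#' @seealso [default_pool()], [write_primer_pool()], [write_reference_fasta()]
#' @export
load_primer_pool <- function(path, match_len = NULL, max_mismatch = 1L) {
  if (!file.exists(path)) stop("primer pool file not found: ", path)
  df <- read.delim(path, colClasses = "character", na.strings = NULL,
                   check.names = FALSE)
  missing <- setdiff(POOL_COLUMNS, names(df))
  if (length(missing))
    stop("primer pool format error: missing column(s) ",
         paste(missing, collapse = ", "))
  df <- df[POOL_COLUMNS]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$cut_offset <- suppressWarnings(as.integer(ifelse(df$cut_offset == "",
                                                      NA, df$cut_offset)))
  primer_pool(df, match_len = match_len, max_mismatch = max_mismatch)
}

#' Construct a primer pool from a data frame
#'
#' @param df Data frame with the pool columns (see [load_primer_pool()]).
#' @inheritParams load_primer_pool
#' @return A validated `primer_pool`.
#' @export
primer_pool <- function(df, match_len = NULL, max_mismatch = 1L) {
  pool <- as.data.frame(df, stringsAsFactors = FALSE)
  rownames(pool) <- NULL
  attr(pool, "match_len") <- if (is.null(match_len)) NULL else as.integer(match_len)
  attr(pool, "max_mismatch") <- as.integer(max_mismatch)
  class(pool) <- c("primer_pool", "data.frame")
  validate_pool(pool)
  pool
}

validate_pool <- function(pool) {
  df <- pool
  fail <- function(locus, rule)
    stop("primer pool validation error at locus '", locus, "': ", rule,
         call. = FALSE)
  if (anyDuplicated(df$locus_id))
    stop("primer pool validation error: duplicate locus_id '",
         df$locus_id[duplicated(df$locus_id)][1], "'", call. = FALSE)
  for (i in seq_len(nrow(df))) {
    id <- df$locus_id[i]
    if (!df$repair_class[i] %in% c("HR", "NHEJ", "UNCUT"))
      fail(id, paste0("repair_class must be HR, NHEJ or UNCUT, got '",
                      df$repair_class[i], "'"))
    for (col in c("fwd_primer", "rev_primer", "ref_seq"))
      if (!grepl("^[ACGT]+$", df[[col]][i]))
        fail(id, paste0(col, " is not an ACGT string"))
    if (nchar(df$ref_seq[i]) != df$end[i] - df$start[i])
      fail(id, "length(ref_seq) != end - start")
    if (substr(df$ref_seq[i], 1L, nchar(df$fwd_primer[i])) != df$fwd_primer[i])
      fail(id, "ref_seq does not begin with fwd_primer")
    rc <- revcomp(df$rev_primer[i])
    L <- nchar(df$ref_seq[i])
    if (substr(df$ref_seq[i], L - nchar(rc) + 1L, L) != rc)
      fail(id, "ref_seq does not end with reverse-complement(rev_primer)")
    uncut <- df$repair_class[i] == "UNCUT"
    if (uncut && !is.na(df$cut_offset[i]))
      fail(id, "UNCUT locus must have no cut_offset")
    if (!uncut && is.na(df$cut_offset[i]))
      fail(id, "cut locus must have a cut_offset")
    if (!uncut && (df$cut_offset[i] < 0 || df$cut_offset[i] >= L))
      fail(id, "cut_offset outside the amplicon")
  }
  check_primer_collisions(pool)
  invisible(pool)
}

# Primer table of a pool: one row per (locus, side), with the effective match
# length under the pool's match_len policy.
primer_table <- function(pool, match_len = NULL) {
  ml <- match_len %||% attr(pool, "match_len")
  tab <- data.frame(
    locus_id = rep(pool$locus_id, 2L),
    side = rep(c("fwd", "rev"), each = nrow(pool)),
    primer = c(pool$fwd_primer, pool$rev_primer),
    stringsAsFactors = FALSE)
  tab$match_len <- if (is.null(ml)) nchar(tab$primer)
                   else pmin(as.integer(ml), nchar(tab$primer))
  tab
}

# Collision-freeness: no primer prefix (over its match length) within
# max_mismatch Hamming distance of any other primer's prefix.
check_primer_collisions <- function(pool) {
  tab <- primer_table(pool)
  mm <- attr(pool, "max_mismatch") %||% 1L
  n <- nrow(tab)
  if (n < 2L) return(invisible(TRUE))
  pre <- substr(tab$primer, 1L, tab$match_len)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    len <- min(tab$match_len[i], tab$match_len[j])
    d <- hamming(substr(pre[i], 1L, len), substr(pre[j], 1L, len))
    if (d <= mm)
      stop("primer pool validation error: primers ", tab$locus_id[i], "/",
           tab$side[i], " and ", tab$locus_id[j], "/", tab$side[j],
           " are within ", mm, " mismatch(es) of each other (distance ", d,
           "); classification would be ambiguous", call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a primer pool back to TSV
#'
#' Inverse of [load_primer_pool()]; `load_primer_pool(write_primer_pool(pool))`
#' round-trips field-exactly. `cut_offset` is written empty for UNCUT loci.
#'
#' @param pool A `primer_pool`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_primer_pool <- function(pool, path) {
  df <- as.data.frame(pool)[POOL_COLUMNS]
  df$cut_offset <- ifelse(is.na(df$cut_offset), "", as.character(df$cut_offset))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The packaged synthetic 25-locus pool
#'
#' Loads the pool shipped with the package: 25 amplicons (10 HR-prone,
#' 10 NHEJ-prone, 5 uncut controls), each 250-290 bp with at least 100 bp of
#' primer-free sequence on either side of the cut and the AsiSI recognition
#' motif `GCGATCGC` centred on the cut midpoint at cut loci. The sequences
#' are synthetic (generated, not genomic) but satisfy every structural
#' constraint of the assay design, so they stand in for the real primer
#' panel in simulations and tests.
#'
#' @inheritParams load_primer_pool
#' @return A validated `primer_pool` of 25 loci.
#' @export
default_pool <- function(match_len = NULL, max_mismatch = 1L) {
  path <- system.file("extdata", "synthetic_pool_25loci.tsv",
                      package = "imutseq", mustWork = TRUE)
  load_primer_pool(path, match_len = match_len, max_mismatch = max_mismatch)
}

#' @export
print.primer_pool <- function(x, ...) {
  cat("primer_pool:", nrow(x), "loci (",
      sum(x$repair_class == "HR"), "HR,",
      sum(x$repair_class == "NHEJ"), "NHEJ,",
      sum(x$repair_class == "UNCUT"), "UNCUT )\n")
  cat("  amplicon lengths:", if (nrow(x)) paste0(min(nchar(x$ref_seq)), "-",
                                                 max(nchar(x$ref_seq)), " bp")
      else "-", "\n")
  cat("  max_mismatch:", attr(x, "max_mismatch") %||% 1L,
      " match_len:", attr(x, "match_len") %||% "full primer", "\n")
  invisible(x)
}

#' Extract one locus from a pool
#'
#' @param pool A `primer_pool`.
#' @param locus_id Locus identifier.
#' @return A one-row `amplicon_locus` list with the pool columns as fields.
#' @export
get_locus <- function(pool, locus_id) {
  i <- match(locus_id, pool$locus_id)
  if (is.na(i)) stop("unknown locus '", locus_id, "'")
  loc <- as.list(as.data.frame(pool)[i, , drop = FALSE])
  class(loc) <- "amplicon_locus"
  loc
}

#' Write the amplicon reference FASTA
#'
#' One record per locus, header equal to the locus id, sequence equal to the
#' full amplicon reference, wrapped at 80 columns. This is the alignment
#' target for the (external) aligner stage.
#'
#' @param pool A `primer_pool`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(pool, path) {
  seqs <- Biostrings::DNAStringSet(setNames(as.character(pool$ref_seq),
                                            pool$locus_id))
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Convert an amplicon offset to a cut-relative position
#'
#' Positions are signed distances from the cut midpoint: negative values lie
#' 5' (upstream) of the cut and 0 is the first base 3' of the cut midpoint.
#' Metagene profiles are drawn on this axis.
#'
#' @param locus An `amplicon_locus` (see [get_locus()]) or one-row pool slice.
#' @param abs_pos 0-based offset(s) within the amplicon.
#' @return `abs_pos - cut_offset` (vectorised).
#' @export
to_cut_relative <- function(locus, abs_pos) {
  co <- locus$cut_offset
  if (is.na(co))
    stop("locus '", locus$locus_id, "' is UNCUT: cut-relative coordinates ",
         "are undefined")
  L <- nchar(locus$ref_seq)
  if (any(abs_pos < 0 | abs_pos >= L))
    stop("abs_pos outside amplicon [0, ", L, ")")
  as.integer(abs_pos) - as.integer(co)
}
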