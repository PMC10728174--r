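#' @title Primer-identity classification of read pairs
#'
#' @description
#' In a multiplexed amplicon library every molecule was amplified by one
#' forward and one reverse primer, and both mates begin with the primer that
#' primed them. Matching each mate's 5' prefix against the pool therefore
#' reveals the molecule's origin: both primers from the same locus means a
#' correctly repaired (cis) molecule, primers from two different loci means
#' the two DSB ends were ligated together -- a translocation (trans).
#' Anything else (no primer hit, or two same-side primers, which is
#' indistinguishable from a primer artefact) is unmatched.
#'
#' @name translocapture
NULL

# Batch prefix-match against the pool primer table; returns row index into
# primer_table(pool) (0 = none, -1 = ambiguous).
match_primers_batch <- function(seqs, pool, max_mismatch) {
  tab <- primer_table(pool)
  idx <- match_primers_cpp(seqs, tab$primer, tab$match_len,
                           as.integer(max_mismatch))
  if (any(idx < 0L))
    stop("internal consistency error: a read prefix matches two pool ",
         "primers within ", max_mismatch, " mismatch(es); the pool ",
         "collision invariant is violated")
  idx
}

#' Identify the primer at the 5' end of a read
#'
#' @param seq Read sequence.
#' @param pool A `primer_pool`.
#' @param max_mismatch Hamming mismatches tolerated over the match length
#'   (default: the pool's policy).
#' @return `list(locus_id, side)` with `side` in `fwd`/`rev`, or `NULL` if
#'   no primer matches.
#' @export
match_primer <- function(seq, pool,
                         max_mismatch = attr(pool, "max_mismatch") %||% 1L) {
  idx <- match_primers_batch(seq, pool, max_mismatch)
  if (idx == 0L) return(NULL)
  tab <- primer_table(pool)
  list(locus_id = tab$locus_id[idx], side = tab$side[idx])
}

#' Classify one read pair by primer identity
#'
#' Each mate is matched against every primer (both sides, both mates, so
#' library orientation does not matter). A valid amplicon structure needs
#' one forward and one reverse primer.
#'
#' @param r1,r2 Mate sequences.
#' @inheritParams match_primer
#' @return A `read_origin`: `list(status, locus_fwd, locus_rev)` with
#'   `status` in `cis`/`trans`/`unmatched`.
#' @export
classify_read_pair <- function(r1, r2, pool,
                               max_mismatch = attr(pool, "max_mismatch") %||% 1L) {
  tab <- primer_table(pool)
  idx <- match_primers_batch(c(r1, r2), pool, max_mismatch)
  origin_from_idx(idx[1], idx[2], tab)
}

origin_from_idx <- function(i1, i2, tab) {
  out <- list(status = "unmatched", locus_fwd = NA_character_,
              locus_rev = NA_character_)
  class(out) <- "read_origin"
  if (i1 == 0L || i2 == 0L || tab$side[i1] == tab$side[i2]) return(out)
  fwd <- if (tab$side[i1] == "fwd") i1 else i2
  rev <- if (tab$side[i1] == "rev") i1 else i2
  out$locus_fwd <- tab$locus_id[fwd]
  out$locus_rev <- tab$locus_id[rev]
  out$status <- if (out$locus_fwd == out$locus_rev) "cis" else "trans"
  out
}

#' @export
print.read_origin <- function(x, ...) {
  cat("read_origin:", x$status,
      if (x$status != "unmatched") paste0("(", x$locus_fwd, " / ",
                                          x$locus_rev, ")"), "\n")
  invisible(x)
}

# --- streaming FASTQ scan -------------------------------------------------

open_fastq <- function(path, mode = "rt") {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

# Read up to n records from an open FASTQ connection; NULL at EOF.
read_fastq_chunk <- function(con, n, offset = 0L) {
  lines <- readLines(con, n * 4L)
  if (!length(lines)) return(NULL)
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ record at record index ",
         offset + length(lines) %/% 4L + 1L)
  id <- lines[c(TRUE, FALSE, FALSE, FALSE)]
  plus <- lines[c(FALSE, FALSE, TRUE, FALSE)]
  bad <- which(!startsWith(id, "@") | !startsWith(plus, "+"))
  if (length(bad))
    stop("malformed FASTQ record at record index ", offset + bad[1])
  list(id = sub("^@", "", sub("[/ ].*$", "", id)),
       raw_id = id,
       seq = lines[c(FALSE, TRUE, FALSE, FALSE)],
       plus = plus,
       qual = lines[c(FALSE, FALSE, FALSE, TRUE)])
}

write_fastq_chunk <- function(con, chunk, keep) {
  if (!any(keep)) return(invisible())
  writeLines(c(rbind(chunk$raw_id[keep], chunk$seq[keep],
                     chunk$plus[keep], chunk$qual[keep])), con)
}

#' Scan paired FASTQ files, count translocations, split the reads
#'
#' Streams synchronised mates in bounded memory, classifies every pair by
#' primer identity, accumulates the locus-by-locus translocation matrix
#' (diagonal = cis), and optionally writes cis and trans pairs to separate
#' FASTQ files (`<out_prefix>_cis_R1.fastq`, ... `_trans_R2.fastq`).
#' Translocated reads must be removed before alignment-based mutation
#' calling, so the cis output is the input of the downstream caller stage.
#'
#' @param r1_path,r2_path Paired FASTQ paths (gzipped allowed).
#' @param pool A `primer_pool`.
#' @param out_prefix Output prefix for split FASTQs; `NULL` skips writing.
#' @inheritParams match_primer
#' @param chunk_size Read pairs held in memory at a time.
#' @return A list: `matrix` (a `transloc_matrix`), `report` (data frame of
#'   totals per status), `files` (paths of the split FASTQs or `NULL`).
#' @export
scan_fastq <- function(r1_path, r2_path, pool, out_prefix = NULL,
                       max_mismatch = attr(pool, "max_mismatch") %||% 1L,
                       chunk_size = 20000L) {
  tab <- primer_table(pool)
  ids <- pool$locus_id
  counts <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  totals <- c(cis = 0L, trans = 0L, unmatched = 0L)

  con1 <- open_fastq(r1_path); on.exit(close(con1), add = TRUE)
  con2 <- open_fastq(r2_path); on.exit(close(con2), add = TRUE)
  outs <- NULL
  if (!is.null(out_prefix)) {
    paths <- paste0(out_prefix, c("_cis_R1.fastq", "_cis_R2.fastq",
                                  "_trans_R1.fastq", "_trans_R2.fastq"))
    outs <- lapply(paths, function(p) file(p, "wt"))
    on.exit(for (o in outs) close(o), add = TRUE)
  }

  done <- 0L
  repeat {
    c1 <- read_fastq_chunk(con1, chunk_size, done)
    c2 <- read_fastq_chunk(con2, chunk_size, done)
    if (is.null(c1) && is.null(c2)) break
    n1 <- length(c1$id) %||% 0L; n2 <- length(c2$id) %||% 0L
    if (is.null(c1) || is.null(c2) || n1 != n2) {
      bad <- done + min(n1, n2) + 1L
      stop("desynchronised mates: files differ in length at record index ", bad)
    }
    mism <- which(c1$id != c2$id)
    if (length(mism))
      stop("desynchronised mates: read ids differ at record index ",
           done + mism[1], " ('", c1$id[mism[1]], "' vs '",
           c2$id[mism[1]], "')")

    i1 <- match_primers_batch(c1$seq, pool, max_mismatch)
    i2 <- match_primers_batch(c2$seq, pool, max_mismatch)
    valid <- i1 > 0L & i2 > 0L & tab$side[pmax(i1, 1L)] != tab$side[pmax(i2, 1L)]
    lf <- lr <- rep(NA_character_, n1)
    s1_fwd <- tab$side[pmax(i1, 1L)] == "fwd"
    lf[valid] <- ifelse(s1_fwd[valid], tab$locus_id[i1[valid]],
                        tab$locus_id[i2[valid]])
    lr[valid] <- ifelse(s1_fwd[valid], tab$locus_id[i2[valid]],
                        tab$locus_id[i1[valid]])
    status <- rep("unmatched", n1)
    status[valid] <- ifelse(lf[valid] == lr[valid], "cis", "trans")
    if (any(valid)) {
      t2 <- table(factor(lf[valid], ids), factor(lr[valid], ids))
      counts <- counts + unclass(t2)
    }
    tt <- table(factor(status, names(totals)))
    totals <- totals + as.integer(tt)
    if (!is.null(outs)) {
      write_fastq_chunk(outs[[1]], c1, status == "cis")
      write_fastq_chunk(outs[[2]], c2, status == "cis")
      write_fastq_chunk(outs[[3]], c1, status == "trans")
      write_fastq_chunk(outs[[4]], c2, status == "trans")
    }
    done <- done + n1
  }

  res <- list(matrix = transloc_matrix(counts),
              report = data.frame(status = c(names(totals), "total"),
                                  count = c(as.integer(totals), done)),
              files = if (!is.null(outs)) setNames(as.list(paths),
                c("cis_r1", "cis_r2", "trans_r1", "trans_r2")) else NULL)
  res
}

#' Locus-by-locus translocation matrix
#'
#' Square count matrix over pool loci; rows are the forward-primer locus,
#' columns the reverse-primer locus; the diagonal holds correctly repaired
#' (cis) pairs. Rates are counts divided by the total of classified
#' (cis + trans) pairs, so all cells sum to 1.
#'
#' @param counts Square integer matrix with identical row/col names.
#' @return A `transloc_matrix` list: `locus_ids`, `counts`, `rates`,
#'   `total_classified`.
#' @export
transloc_matrix <- function(counts) {
  stopifnot(is.matrix(counts), nrow(counts) == ncol(counts),
            identical(rownames(counts), colnames(counts)),
            all(counts >= 0))
  total <- sum(counts)
  out <- list(locus_ids = rownames(counts), counts = counts,
              rates = if (total > 0) counts / total else counts * 0,
              total_classified = total)
  class(out) <- "transloc_matrix"
  out
}

#' @export
print.transloc_matrix <- function(x, ...) {
  cis <- sum(diag(x$counts)); trans <- x$total_classified - cis
  cat("transloc_matrix:", length(x$locus_ids), "loci,",
      x$total_classified, "classified pairs (", cis, "cis /", trans,
      "trans )\n")
  if (x$total_classified > 0)
    cat(sprintf("  aggregate translocation rate: %.4g\n",
                trans / x$total_classified))
  invisible(x)
}

#' Write a translocation matrix as CSV
#'
#' Emits `<prefix>_counts.csv` and `<prefix>_rates.csv` with locus ids as
#' header row and column.
#'
#' @param tm A `transloc_matrix`.
#' @param prefix Output path prefix.
#' @return The two paths, invisibly.
#' @export
write_transloc_matrix <- function(tm, prefix) {
  p1 <- paste0(prefix, "_counts.csv"); p2 <- paste0(prefix, "_rates.csv")
  write.csv(data.frame(locus_id = tm$locus_ids, tm$counts,
                       check.names = FALSE), p1, row.names = FALSE,
            quote = FALSE)
  write.csv(data.frame(locus_id = tm$locus_ids, tm$rates,
                       check.names = FALSE), p2, row.names = FALSE,
            quote = FALSE)
  invisible(c(p1, p2))
}

#' Read back a translocation count matrix written by [write_transloc_matrix()]
#'
#' @param path The `_counts.csv` file.
#' @return A `transloc_matrix`.
#' @export
read_transloc_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$locus_id
  storage.mode(m) <- "integer"
  transloc_matrix(m)
}

#' Partition read pairs by a marker subsequence
#'
#' A pair is positive when either mate contains the marker or its reverse
#' complement as an exact substring. This reproduces the marker-gated read
#' split used to separate successfully gene-corrected (HR-repaired)
#' molecules in reporter sequencing: the corrected allele carries a
#' diagnostic sequence absent from the broken allele.
#'
#' @param r1_path,r2_path Paired FASTQ paths.
#' @param marker DNA string (non-empty).
#' @param out_prefix Output prefix for `_pos_R1/_pos_R2/_neg_R1/_neg_R2`
#'   FASTQs; `NULL` skips writing.
#' @param chunk_size Read pairs per chunk.
#' @return `list(positive, negative, files)` with pair counts.
#' @export
partition_by_marker <- function(r1_path, r2_path, marker, out_prefix = NULL,
                                chunk_size = 20000L) {
  if (!nzchar(marker)) stop("marker must be non-empty")
  rc <- revcomp(marker)
  con1 <- open_fastq(r1_path); on.exit(close(con1), add = TRUE)
  con2 <- open_fastq(r2_path); on.exit(close(con2), add = TRUE)
  outs <- NULL
  if (!is.null(out_prefix)) {
    paths <- paste0(out_prefix, c("_pos_R1.fastq", "_pos_R2.fastq",
                                  "_neg_R1.fastq", "_neg_R2.fastq"))
    outs <- lapply(paths, function(p) file(p, "wt"))
    on.exit(for (o in outs) close(o), add = TRUE)
  }
  npos <- 0L; nneg <- 0L; done <- 0L
  repeat {
    c1 <- read_fastq_chunk(con1, chunk_size, done)
    c2 <- read_fastq_chunk(con2, chunk_size, done)
    if (is.null(c1) && is.null(c2)) break
    if (is.null(c1) || is.null(c2) || length(c1$id) != length(c2$id))
      stop("desynchronised mates at record index ",
           done + min(length(c1$id), length(c2$id)) + 1L)
    pos <- grepl(marker, c1$seq, fixed = TRUE) |
           grepl(rc, c1$seq, fixed = TRUE) |
           grepl(marker, c2$seq, fixed = TRUE) |
           grepl(rc, c2$seq, fixed = TRUE)
    npos <- npos + sum(pos); nneg <- nneg + sum(!pos)
    if (!is.null(outs)) {
      write_fastq_chunk(outs[[1]], c1, pos)
      write_fastq_chunk(outs[[2]], c2, pos)
      write_fastq_chunk(outs[[3]], c1, !pos)
      write_fastq_chunk(outs[[4]], c2, !pos)
    }
    done <- done + length(c1$id)
  }
  list(positive = npos, negative = nneg,
       files = if (!is.null(outs)) setNames(as.list(paths),
         c("pos_r1", "pos_r2", "neg_r1", "neg_r2")) else NULL)
}
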