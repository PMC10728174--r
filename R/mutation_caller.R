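#' @title Per-nucleotide mutation calling from pileup text
#'
#' @description
#' The caller turns samtools-dialect pileup text into an *mprofile*: a
#' per-locus, per-position table of depth, directional substitution counts,
#' insertion events, deletion coverage (`*` symbols) and deletion events by
#' size class, with per-position rates expressed as percent of reads
#' covering the position. Deletion events are additionally annotated with
#' break adjacency and junction microhomology, flagging likely
#' microhomology-mediated end-joining (MMEJ) products and polymerase
#' slippage at homopolymer runs.
#'
#' @name mutation_caller
NULL

#' Parse one pileup line
#'
#' Decodes the six tab-separated pileup columns and the full base-string
#' dialect: `.`/`,` reference match (case = strand), `ACGTacgt`
#' substitutions, `*` deletion coverage, `+N<seq>` insertion after this
#' position, `-N<seq>` deletion event anchored here spanning the next `N`
#' positions, `^X` read start (the mapping-quality byte is consumed), `$`
#' read end. The decoded read-symbol count must equal the depth column.
#'
#' @param line One pileup line.
#' @return A list: `ref_name`, `pos` (converted to 0-based), `ref_base`,
#'   `depth`, `n_ref`, `n_star`, `sub` (named counts over A/C/G/T/N,
#'   case-collapsed), `ins` and `del` data frames of decoded indel events
#'   (`length`, `seq`).
#' @export
parse_pileup_record <- function(line) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  # zero-depth lines legitimately end in empty base/quality fields, which
  # strsplit drops; restore them before validating
  if (length(f) %in% 4:5) f <- c(f, rep("", 6L - length(f)))
  if (length(f) < 6L)
    stop("pileup format error: expected 6 tab-separated fields, got ",
         length(f))
  depth <- suppressWarnings(as.integer(f[4]))
  if (is.na(depth)) stop("pileup format error: non-integer depth '", f[4], "'")
  dec <- decode_pileup_bases(f[5])
  if (dec$n_symbols != depth)
    stop("pileup format error at ", f[1], ":", f[2], ": decoded ",
         dec$n_symbols, " read symbols but depth is ", depth)
  list(ref_name = f[1],
       pos = as.integer(f[2]) - 1L,
       ref_base = toupper(f[3]),
       depth = depth,
       n_ref = dec$n_ref,
       n_star = dec$n_star,
       sub = dec$sub,
       ins = data.frame(length = dec$ins_len, seq = dec$ins_seq,
                        stringsAsFactors = FALSE),
       del = data.frame(length = dec$del_len, seq = dec$del_seq,
                        stringsAsFactors = FALSE))
}

#' Size class of a deletion
#'
#' 1 bp deletions are `small`, 2-5 bp `mid`, longer than 5 bp `large`.
#'
#' @param length Deletion length(s) in bp, >= 1.
#' @return Character vector over `small`/`mid`/`large`.
#' @export
classify_deletion_length <- function(length) {
  if (any(length < 1L)) stop("deletion length must be >= 1")
  ifelse(length == 1L, "small", ifelse(length <= 5L, "mid", "large"))
}

#' Junction microhomology of a deletion
#'
#' The junction-ambiguity length: the largest `k` not exceeding
#' `min(del_end - del_start, nchar(ref) - del_end)` such that the first `k`
#' bases of the deleted segment equal the first `k` bases following the
#' deletion. Microhomology of 2 bp or more on a large deletion is the
#' hallmark of MMEJ repair.
#'
#' @param ref Amplicon reference sequence.
#' @param del_start 0-based first deleted base.
#' @param del_end 0-based half-open end of the deletion.
#' @return Integer homology length.
#' @export
compute_microhomology <- function(ref, del_start, del_end) {
  L <- nchar(ref)
  if (del_start < 0L || del_start >= del_end || del_end > L)
    stop("invalid deletion interval [", del_start, ", ", del_end, ")")
  kmax <- min(del_end - del_start, L - del_end)
  k <- 0L
  while (k < kmax &&
         substr(ref, del_start + k + 1L, del_start + k + 1L) ==
         substr(ref, del_end + k + 1L, del_end + k + 1L))
    k <- k + 1L
  k
}

#' Annotate a deletion event
#'
#' Fills the size class, the signed cut-relative position of the nearest
#' deleted base, break adjacency (within `adjacency_bp` of the cut),
#' junction microhomology, and the MMEJ flag (large class with >= 2 bp
#' homology) and slippage flag (<= 2 bp deleted inside a homopolymer run of
#' >= 3). Deletions at UNCUT loci are `distant` by definition.
#'
#' @param locus An `amplicon_locus`.
#' @param start 0-based first deleted base; must lie in the primer-free
#'   interior of the amplicon.
#' @param length Deletion length in bp.
#' @param adjacency_bp Adjacency threshold in bp from the cut (default 10).
#' @return One-row data frame: `locus_id`, `start`, `length`, `class`,
#'   `rel_dist`, `adjacency`, `microhomology`, `mmej`, `slippage`.
#' @export
annotate_deletion <- function(locus, start, length, adjacency_bp = 10L) {
  L <- nchar(locus$ref_seq)
  fp <- nchar(locus$fwd_primer); rp <- nchar(locus$rev_primer)
  if (start < fp || start + length > L - rp)
    stop("deletion [", start, ", ", start + length,
         ") lies outside the primer-free interior of locus '",
         locus$locus_id, "'")
  cls <- classify_deletion_length(length)
  if (is.na(locus$cut_offset)) {
    rel_dist <- NA_integer_; adjacency <- "distant"
  } else {
    rel <- seq.int(start, start + length - 1L) - locus$cut_offset
    rel_dist <- rel[which.min(abs(rel))]
    adjacency <- if (abs(rel_dist) <= adjacency_bp) "adjacent" else "distant"
  }
  mh <- compute_microhomology(locus$ref_seq, start, start + length)
  seg <- substr(locus$ref_seq, start + 1L, start + length)
  segc <- strsplit(seg, "")[[1]]
  slip <- FALSE
  if (length <= 2L && all(segc == segc[1])) {
    b <- segc[1]; run <- length
    i <- start
    while (i >= 1L && substr(locus$ref_seq, i, i) == b) {
      run <- run + 1L; i <- i - 1L
    }
    i <- start + length + 1L
    while (i <= L && substr(locus$ref_seq, i, i) == b) {
      run <- run + 1L; i <- i + 1L
    }
    slip <- run >= 3L
  }
  data.frame(locus_id = locus$locus_id, start = start, length = length,
             class = cls, rel_dist = rel_dist, adjacency = adjacency,
             microhomology = mh,
             mmej = (cls == "large" && mh >= 2L), slippage = slip,
             stringsAsFactors = FALSE)
}

#' Aggregate pileup text into an mprofile
#'
#' Streams pileup lines (a character vector, file path or connection),
#' validates them against the pool, and aggregates per-position counts:
#' substitutions by alternate base, insertion events, deletion coverage
#' (`*`), and deletion events by size class counted at their anchoring
#' position. Per-position rates (percent of reads) are emitted only where
#' depth reaches `min_depth`; shallower positions keep their counts but
#' rates are `NA`. Distinct deletion events are collected, annotated with
#' [annotate_deletion()], and attached as the `"deletions"` attribute.
#'
#' @param pileup Character vector of pileup lines, or a path to a pileup
#'   file.
#' @param pool A `primer_pool`; pileup reference names must be pool locus
#'   ids.
#' @param min_depth Minimum depth for rate emission (default 100).
#' @param adjacency_bp Passed to [annotate_deletion()].
#' @return An `mprofile` data frame, one row per covered position, with
#'   count columns (`n_sub_A` ... `n_del_large`), the 12 directional
#'   substitution rate columns `sub_<X>to<Y>` in percent, `sub_total`,
#'   `ins_rate`, `del_cov_rate` and deletion event columns; deletion
#'   annotations in `attr(, "deletions")`.
#' @export
pileup_to_profile <- function(pileup, pool, min_depth = 100L,
                              adjacency_bp = 10L) {
  lines <- if (is.character(pileup) && length(pileup) == 1L &&
               !grepl("\t", pileup) && file.exists(pileup))
    readLines(pileup) else pileup
  loci <- setNames(lapply(pool$locus_id, function(id) get_locus(pool, id)),
                   pool$locus_id)
  rows <- vector("list", length(lines))
  del_key <- character(0); del_cnt <- integer(0)
  for (i in seq_along(lines)) {
    rec <- parse_pileup_record(lines[i])
    loc <- loci[[rec$ref_name]]
    if (is.null(loc))
      stop("pileup validation error: unknown reference '", rec$ref_name, "'")
    L <- nchar(loc$ref_seq)
    if (rec$pos < 0L || rec$pos >= L)
      stop("pileup validation error: position ", rec$pos + 1L,
           " outside amplicon '", rec$ref_name, "' (length ", L, ")")
    dl <- rec$del
    n_ev <- c(small = 0L, mid = 0L, large = 0L)
    if (nrow(dl)) {
      cls <- classify_deletion_length(dl$length)
      for (k in seq_len(nrow(dl))) {
        n_ev[cls[k]] <- n_ev[cls[k]] + 1L
        key <- paste(rec$ref_name, rec$pos + 1L, dl$length[k], sep = "|")
        j <- match(key, del_key)
        if (is.na(j)) {
          del_key <- c(del_key, key); del_cnt <- c(del_cnt, 1L)
        } else del_cnt[j] <- del_cnt[j] + 1L
      }
    }
    rows[[i]] <- data.frame(
      locus_id = rec$ref_name, pos = rec$pos,
      rel_pos = if (is.na(loc$cut_offset)) NA_integer_
                else rec$pos - loc$cut_offset,
      ref_base = rec$ref_base, depth = rec$depth,
      n_sub_A = rec$sub[["A"]], n_sub_C = rec$sub[["C"]],
      n_sub_G = rec$sub[["G"]], n_sub_T = rec$sub[["T"]],
      n_sub_N = rec$sub[["N"]],
      n_ins = nrow(rec$ins), n_star = rec$n_star,
      n_del_small = n_ev[["small"]], n_del_mid = n_ev[["mid"]],
      n_del_large = n_ev[["large"]],
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- utils::read.table(text = "", col.names = c(
      "locus_id", "pos", "rel_pos", "ref_base", "depth", "n_sub_A",
      "n_sub_C", "n_sub_G", "n_sub_T", "n_sub_N", "n_ins", "n_star",
      "n_del_small", "n_del_mid", "n_del_large"))
  df <- df[order(match(df$locus_id, pool$locus_id), df$pos), , drop = FALSE]
  rownames(df) <- NULL

  anns <- NULL
  if (length(del_key)) {
    parts <- strsplit(del_key, "|", fixed = TRUE)
    anns <- do.call(rbind, lapply(seq_along(parts), function(k) {
      p <- parts[[k]]
      a <- annotate_deletion(loci[[p[1]]], as.integer(p[2]),
                             as.integer(p[3]), adjacency_bp)
      a$count <- del_cnt[k]
      # depth at the anchoring position, for event-rate computation
      anchor <- as.integer(p[2]) - 1L
      j <- which(df$locus_id == p[1] & df$pos == anchor)
      a$anchor_depth <- if (length(j)) df$depth[j[1]] else NA_integer_
      a
    }))
    anns <- anns[order(match(anns$locus_id, pool$locus_id), anns$start), ,
                 drop = FALSE]
    rownames(anns) <- NULL
  }
  new_mprofile(df, anns, min_depth)
}

MPROFILE_SUB_COLS <- as.vector(outer(c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T"),
                                     function(a, b) paste0("sub_", a, "to", b)))
MPROFILE_SUB_COLS <- MPROFILE_SUB_COLS[substr(MPROFILE_SUB_COLS, 5, 5) !=
                                       substr(MPROFILE_SUB_COLS, 8, 8)]
MPROFILE_RATE_COLS <- c(MPROFILE_SUB_COLS, "sub_total", "ins_rate",
                        "del_cov_rate")

# Attach percent rate columns to a count frame and classify as mprofile.
new_mprofile <- function(df, deletions, min_depth) {
  ok <- df$depth >= min_depth
  denom <- ifelse(ok, df$depth, NA_real_)
  for (col in MPROFILE_SUB_COLS) df[[col]] <- 0
  for (rb in c("A", "C", "G", "T")) {
    sel <- df$ref_base == rb
    if (!any(sel)) next
    for (alt in setdiff(c("A", "C", "G", "T"), rb))
      df[[paste0("sub_", rb, "to", alt)]][sel] <-
        100 * df[[paste0("n_sub_", alt)]][sel] / denom[sel]
  }
  df$sub_total <- rowSums(df[MPROFILE_SUB_COLS])
  df$ins_rate <- 100 * df$n_ins / denom
  df$del_cov_rate <- 100 * df$n_star / denom
  structure(df, deletions = deletions, min_depth = min_depth,
            class = c("mprofile", "data.frame"))
}

#' @export
print.mprofile <- function(x, ...) {
  cat("mprofile:", nrow(x), "positions over",
      length(unique(x$locus_id)), "loci; min_depth",
      attr(x, "min_depth"), "\n")
  dels <- attr(x, "deletions")
  cat("  deletion events:", if (is.null(dels)) 0 else nrow(dels),
      "distinct\n")
  cat(sprintf("  mean substitution rate: %.4g%%\n",
              mean(x$sub_total, na.rm = TRUE)))
  invisible(x)
}

#' Deletion annotations of an mprofile
#'
#' @param profile An `mprofile`.
#' @return The annotated deletion-event data frame (or `NULL`).
#' @export
deletion_annotations <- function(profile) attr(profile, "deletions")

#' Write an mprofile (and companion deletion annotations) as TSV
#'
#' Emits the per-position table with the schema `locus_id, pos, rel_pos,
#' ref_base, depth, sub_<X>to<Y> (12 percent columns), sub_total, ins_rate,
#' del_cov_rate, del_small_events, del_mid_events, del_large_events`, and,
#' when annotations exist and `ann_path` is given, the deletion table.
#'
#' @param profile An `mprofile`.
#' @param path Output TSV path.
#' @param ann_path Optional path for the deletion-annotation TSV.
#' @return `path`, invisibly.
#' @export
write_mprofile <- function(profile, path, ann_path = NULL) {
  df <- as.data.frame(profile)
  out <- df[c("locus_id", "pos", "rel_pos", "ref_base", "depth",
              MPROFILE_RATE_COLS)]
  out$del_small_events <- df$n_del_small
  out$del_mid_events <- df$n_del_mid
  out$del_large_events <- df$n_del_large
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(ann_path)) {
    anns <- deletion_annotations(profile)
    if (is.null(anns))
      anns <- utils::read.table(text = "", col.names = c(
        "locus_id", "start", "length", "class", "rel_dist", "adjacency",
        "microhomology", "mmej", "slippage", "count", "anchor_depth"))
    write.table(anns, ann_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
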