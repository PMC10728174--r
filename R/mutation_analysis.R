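#' @title Delta profiles, metagenes and per-locus summaries
#'
#' @description
#' Background mutations (natural variants, PCR and sequencing error) are
#' removed by per-nucleotide subtraction: the undamaged (-DSB) sample's
#' rate of each mutation type at each position is subtracted from the
#' damaged (+DSB) sample's rate at the same position. Treatment effects are
#' isolated by chaining the same subtraction across conditions:
#' `(treat+ - treat-) - (ctrl+ - ctrl-)`. Metagene profiles average rates
#' across loci on the cut-relative axis; per-locus summaries total the
#' per-position percent rates over the profiled window ("per DSB" rates).
#'
#' @name mutation_analysis
NULL

#' Per-nucleotide difference of two mutation profiles
#'
#' Subtracts every rate column of `b` from `a` on an identical
#' `(locus, pos)` grid. A position missing a rate on either side (depth
#' below the caller's `min_depth`) stays missing; negative deltas are
#' retained.
#'
#' @param a,b `mprofile` or `delta_profile` objects on the same grid.
#' @return A `delta_profile` data frame with the same rate columns, signed.
#' @export
delta_profiles <- function(a, b) {
  ga <- paste(a$locus_id, a$pos); gb <- paste(b$locus_id, b$pos)
  if (!identical(ga, gb))
    stop("profile grids differ; deltas require identical (locus, pos) grids")
  out <- a[c("locus_id", "pos", "rel_pos", "ref_base")]
  for (col in MPROFILE_RATE_COLS) out[[col]] <- a[[col]] - b[[col]]
  structure(out, class = c("delta_profile", "data.frame"),
            provenance = c(attr(a, "provenance") %||% "a",
                           "-", attr(b, "provenance") %||% "b"))
}

#' Chained treatment-versus-control delta
#'
#' `(treat_plus - treat_minus) - (ctrl_plus - ctrl_minus)`: the
#' damaged-undamaged delta of the control condition is subtracted from the
#' damaged-undamaged delta of the treatment condition at each nucleotide,
#' leaving the treatment-specific DSB-induced signal.
#'
#' @param treat_plus,treat_minus,ctrl_plus,ctrl_minus `mprofile`s on one
#'   grid (`plus` = damaged, `minus` = undamaged).
#' @return A `delta_profile`.
#' @export
chained_treatment_delta <- function(treat_plus, treat_minus,
                                    ctrl_plus, ctrl_minus) {
  delta_profiles(delta_profiles(treat_plus, treat_minus),
                 delta_profiles(ctrl_plus, ctrl_minus))
}

#' @export
print.delta_profile <- function(x, ...) {
  cat("delta_profile:", nrow(x), "positions over",
      length(unique(x$locus_id)), "loci\n")
  cat(sprintf("  sub_total delta range: [%.4g, %.4g]%%\n",
              suppressWarnings(min(x$sub_total, na.rm = TRUE)),
              suppressWarnings(max(x$sub_total, na.rm = TRUE))))
  invisible(x)
}

#' Write a delta profile as TSV
#'
#' Same positional schema as the mprofile TSV, signed rates.
#'
#' @param delta A `delta_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_delta_profile <- function(delta, path) {
  write.table(as.data.frame(delta), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Metagene profile on the cut-relative axis
#'
#' Aligns the per-locus rows of one rate measure at cut-relative position 0
#' and averages them, unweighted, across the loci of a group over
#' `-window .. +window`. Group loci must have a cut site; the default
#' window of 100 bp matches the guaranteed primer-free flank of the assay
#' design, giving 201 positions.
#'
#' @param profile An `mprofile` or `delta_profile`.
#' @param pool The `primer_pool`.
#' @param group `"HR"`, `"NHEJ"`, or a character vector of locus ids.
#' @param window Half-width in bp (default 100).
#' @param measure Rate column to profile (default `"sub_total"`).
#' @return A `metagene` list: `group`, `measure`, `rel` (positions),
#'   `mean` (average rate per position), `per_locus` (locus x position
#'   matrix).
#' @export
metagene_profile <- function(profile, pool, group, window = 100L,
                             measure = "sub_total") {
  ids <- if (length(group) == 1L && group %in% c("HR", "NHEJ"))
    pool$locus_id[pool$repair_class == group] else group
  if (!all(ids %in% pool$locus_id))
    stop("unknown loci: ", paste(setdiff(ids, pool$locus_id), collapse = ", "))
  if (!measure %in% names(profile)) stop("unknown measure '", measure, "'")
  rel <- seq.int(-window, window)
  per_locus <- matrix(NA_real_, length(ids), length(rel),
                      dimnames = list(ids, rel))
  for (id in ids) {
    loc <- get_locus(pool, id)
    if (is.na(loc$cut_offset))
      stop("locus '", id, "' is UNCUT: cut-relative alignment is undefined")
    fp <- nchar(loc$fwd_primer); rp <- nchar(loc$rev_primer)
    L <- nchar(loc$ref_seq)
    if (loc$cut_offset - window < fp || loc$cut_offset + window > L - rp - 1L)
      stop("window ", window, " bp exceeds the primer-free interior of ",
           "locus '", id, "'")
    sel <- profile$locus_id == id & profile$rel_pos >= -window &
      profile$rel_pos <= window
    per_locus[id, as.character(profile$rel_pos[sel])] <-
      profile[[measure]][sel]
  }
  structure(list(group = paste(group, collapse = ","), measure = measure,
                 rel = rel, mean = colMeans(per_locus),
                 per_locus = per_locus),
            class = "metagene")
}

#' @export
print.metagene <- function(x, ...) {
  cat("metagene:", x$measure, "over group", x$group, "(",
      nrow(x$per_locus), "loci,", length(x$rel), "positions )\n")
  pk <- which.max(abs(x$mean))
  cat(sprintf("  extreme mean rate %.4g%% at %+d bp\n", x$mean[pk],
              x$rel[pk]))
  invisible(x)
}

#' Write a metagene as TSV (`group, rel_pos, mean_rate`)
#'
#' @param mg A `metagene`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metagene <- function(mg, path) {
  write.table(data.frame(group = mg$group, rel_pos = mg$rel,
                         mean_rate = as.numeric(mg$mean)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Collapse a 12-direction substitution rate row block onto the 6
# pyrimidine classes (purine-reference changes are reverse-complemented).
COLLAPSE_MAP <- c("sub_CtoA" = "C>A", "sub_GtoT" = "C>A",
                  "sub_CtoG" = "C>G", "sub_GtoC" = "C>G",
                  "sub_CtoT" = "C>T", "sub_GtoA" = "C>T",
                  "sub_TtoA" = "T>A", "sub_AtoT" = "T>A",
                  "sub_TtoC" = "T>C", "sub_AtoG" = "T>C",
                  "sub_TtoG" = "T>G", "sub_AtoC" = "T>G")

#' Per-locus mutation summary ("per DSB" rates)
#'
#' Totals the per-position percent rates of a profile over the profiled
#' window around each cut (the full primer-free interior for UNCUT loci):
#' total substitutions, insertions, deletion coverage, deletion events by
#' size class split by break adjacency, the MMEJ event rate, and the
#' 6-class pyrimidine-collapsed substitution signature (which conserves the
#' total 12-direction substitution mass). With `per_position = "mean"` the
#' totals are means instead of sums.
#'
#' @param profile An `mprofile` (deletion annotations are taken from it
#'   unless supplied).
#' @param pool The `primer_pool`.
#' @param annotations Optional deletion-annotation frame (defaults to the
#'   profile's own).
#' @param window Half-width in bp around the cut (default 100).
#' @param per_position `"sum"` (default) or `"mean"` aggregation.
#' @return A data frame, one row per locus present in the profile.
#' @export
locus_summary <- function(profile, pool, annotations = NULL,
                          window = 100L, per_position = c("sum", "mean")) {
  per_position <- match.arg(per_position)
  agg <- if (per_position == "sum") function(v) sum(v, na.rm = TRUE)
         else function(v) mean(v, na.rm = TRUE)
  annotations <- annotations %||% deletion_annotations(profile)
  ids <- unique(profile$locus_id)
  if (!all(ids %in% pool$locus_id))
    stop("profile names loci absent from the pool: ",
         paste(setdiff(ids, pool$locus_id), collapse = ", "))
  ids <- pool$locus_id[pool$locus_id %in% ids]
  out <- lapply(ids, function(id) {
    loc <- get_locus(pool, id)
    sel <- profile$locus_id == id
    if (!is.na(loc$cut_offset))
      sel <- sel & !is.na(profile$rel_pos) & abs(profile$rel_pos) <= window
    p <- profile[sel, , drop = FALSE]
    sig <- vapply(split(names(COLLAPSE_MAP), COLLAPSE_MAP),
                  function(cols) agg(unlist(p[cols])), 0)
    row <- data.frame(locus_id = id, repair_class = loc$repair_class,
                      n_positions = nrow(p),
                      sub_total = agg(p$sub_total),
                      ins_total = agg(p$ins_rate),
                      del_cov_total = agg(p$del_cov_rate),
                      stringsAsFactors = FALSE)
    # deletion events by class x adjacency, as percent of anchor depth
    a <- annotations
    a <- if (is.null(a)) a else a[a$locus_id == id, , drop = FALSE]
    for (cl in c("small", "mid", "large")) for (ad in c("adjacent", "distant")) {
      v <- 0
      if (!is.null(a) && nrow(a)) {
        s <- a$class == cl & a$adjacency == ad & !is.na(a$anchor_depth)
        if (any(s)) v <- sum(100 * a$count[s] / a$anchor_depth[s])
      }
      row[[paste0("del_", cl, "_", ad)]] <- v
    }
    row$mmej_rate <- if (!is.null(a) && nrow(a)) {
      s <- a$mmej & !is.na(a$anchor_depth)
      if (any(s)) sum(100 * a$count[s] / a$anchor_depth[s]) else 0
    } else 0
    for (cls in names(sig)) row[[paste0("sig_", sub(">", "to", cls))]] <-
      sig[[cls]]
    row
  })
  do.call(rbind, out)
}

#' Translocation summary by repair-class pair
#'
#' Collapses a translocation matrix to unordered locus pairs (summing
#' `(i,j)` and `(j,i)`) and averages pair rates within and between repair
#' classes: HR-HR, NHEJ-NHEJ, HR-NHEJ and UNCUT-any. Also returns the
#' per-pair map table used for heatmap export.
#'
#' @param tm A `transloc_matrix`.
#' @param pool The `primer_pool` (must contain all matrix loci).
#' @return `list(class_summary, pair_map)`.
#' @export
translocation_summary <- function(tm, pool) {
  if (!all(tm$locus_ids %in% pool$locus_id))
    stop("matrix names loci absent from the pool: ",
         paste(setdiff(tm$locus_ids, pool$locus_id), collapse = ", "))
  ids <- tm$locus_ids
  cls <- pool$repair_class[match(ids, pool$locus_id)]
  pairs <- which(upper.tri(tm$rates), arr.ind = TRUE)
  pair_map <- data.frame(
    locus_a = ids[pairs[, 1]], locus_b = ids[pairs[, 2]],
    class_a = cls[pairs[, 1]], class_b = cls[pairs[, 2]],
    count = tm$counts[pairs] + t(tm$counts)[pairs],
    rate = tm$rates[pairs] + t(tm$rates)[pairs],
    stringsAsFactors = FALSE)
  pair_class <- ifelse(
    pair_map$class_a == "UNCUT" | pair_map$class_b == "UNCUT", "UNCUT-any",
    ifelse(pair_map$class_a == pair_map$class_b,
           paste0(pair_map$class_a, "-", pair_map$class_a), "HR-NHEJ"))
  pair_map$pair_class <- pair_class
  lv <- c("HR-HR", "NHEJ-NHEJ", "HR-NHEJ", "UNCUT-any")
  means <- vapply(lv, function(l) {
    s <- pair_class == l
    if (any(s)) mean(pair_map$rate[s]) else NA_real_
  }, 0)
  list(class_summary = data.frame(pair_class = lv, mean_rate = means,
                                  n_pairs = as.integer(table(
                                    factor(pair_class, lv))),
                                  row.names = NULL),
       pair_map = pair_map)
}
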