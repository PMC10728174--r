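#' @title Synthetic amplicon sequencing under a DSB mutation spectrum
#'
#' @description
#' Two simulators share one generative model. [simulate_sample()] emits
#' paired FASTQ reads (150 bp, primer-anchored, with translocation chimeras)
#' plus a machine-readable truth table; [simulate_pileup()] emits
#' samtools-dialect pileup text directly, bypassing alignment, so the
#' mutation caller can be tested without an external aligner. Event
#' placement is driven by deterministic per-locus candidate sets, so the
#' spectrum implies the same per-position probabilities in both simulators.
#'
#' @name synthetic_sequencing
NULL

DNA_BASES <- c("A", "C", "G", "T")

# --- deterministic event-candidate sets -----------------------------------

# 0-based homopolymer runs of a sequence.
homopolymer_runs <- function(ref) {
  r <- rle(strsplit(ref, "")[[1]])
  end <- cumsum(r$lengths)
  data.frame(start = end - r$lengths, len = r$lengths, base = r$values,
             stringsAsFactors = FALSE)
}

# Per-locus candidate events and their per-read probabilities under a
# spectrum. Purely deterministic given (locus, spectrum).
#   $sub: pos (0-based, interior), w  (per-read per-position probability)
#   $ins: anchor (0-based), p
#   $del: start, len, kind in {small, mid, large, slip, mmej}, p
event_candidates <- function(locus, spectrum, slip_min_dist = 16L) {
  L <- nchar(locus$ref_seq)
  fp <- nchar(locus$fwd_primer); rp <- nchar(locus$rev_primer)
  interior <- seq.int(fp, L - rp - 1L)
  cut <- locus$cut_offset

  if (is.na(cut)) {
    w <- rep(spectrum$sub_floor, length(interior))
  } else {
    rel <- interior - cut
    w <- spectrum$sub_rate_peak * exp(-abs(rel) / spectrum$sub_decay_bp) +
      spectrum$sub_floor
  }
  sub <- data.frame(pos = interior, w = w)

  ins <- data.frame(anchor = integer(0), p = numeric(0))
  del <- data.frame(start = integer(0), len = integer(0),
                    kind = character(0), p = numeric(0),
                    stringsAsFactors = FALSE)
  if (!is.na(cut)) {
    add <- function(start, len, kind, rate) {
      keep <- start >= fp & (start + len - 1L) <= (L - rp - 1L)
      start <- start[keep]; len <- len[keep]
      if (!length(start) || rate <= 0) return(NULL)
      data.frame(start = start, len = len, kind = kind,
                 p = rate / length(start), stringsAsFactors = FALSE)
    }
    small <- add(cut + (-5:4), rep(1L, 10L), "small", spectrum$del_small_rate)
    grid <- do.call(rbind, lapply(2:5, function(l)
      data.frame(start = cut + seq.int(-l - 2L, 2L), len = l)))
    mid <- add(grid$start, grid$len, "mid", spectrum$del_mid_rate)
    grid <- do.call(rbind, lapply(6:30, function(l)
      data.frame(start = cut - seq.int(l - 1L, 0L), len = l)))
    large <- add(grid$start, grid$len, "large", spectrum$del_large_rate)

    runs <- homopolymer_runs(locus$ref_seq)
    runs <- runs[runs$len >= 3L & runs$start >= fp &
                 (runs$start + runs$len) <= (L - rp), , drop = FALSE]
    dist <- pmin(abs(runs$start - cut), abs(runs$start + runs$len - 1L - cut))
    runs <- runs[dist >= slip_min_dist, , drop = FALSE]
    slip <- add(runs$start, rep(1L, nrow(runs)), "slip",
                spectrum$distant_slip_rate)

    mmej <- NULL
    if (spectrum$mmej_rate > 0) {
      cds <- mmej_candidates(locus$ref_seq, cut, fp, rp)
      if (nrow(cds))
        mmej <- data.frame(start = cds$start, len = cds$len, kind = "mmej",
                           p = spectrum$mmej_rate / nrow(cds),
                           stringsAsFactors = FALSE)
    }
    del <- do.call(rbind, Filter(Negate(is.null),
                                 list(small, mid, large, slip, mmej)))
    if (is.null(del))
      del <- data.frame(start = integer(0), len = integer(0),
                        kind = character(0), p = numeric(0))
    if (spectrum$ins_rate > 0)
      ins <- data.frame(anchor = cut + (-3:3),
                        p = spectrum$ins_rate / 7)
  }
  list(sub = sub, ins = ins, del = del,
       p_class = c(sub = sum(sub$w),
                   ins = sum(ins$p),
                   vapply(split(del$p, factor(del$kind,
                          c("small", "mid", "large", "slip", "mmej"))),
                          sum, 0)))
}

# Cut-spanning deletions of 6-70 bp whose junction carries 2-7 bp
# microhomology; the MMEJ candidate set of a locus.
mmej_candidates <- function(ref, cut, fp, rp) {
  L <- nchar(ref)
  out <- list()
  for (s in seq.int(max(fp, cut - 69L), cut)) {
    e_max <- min(L - rp, s + 70L)
    if (e_max < cut + 1L) next
    for (e in seq.int(cut + 1L, e_max)) {
      if (e - s < 6L) next
      k <- compute_microhomology(ref, s, e)
      if (k >= 2L && k <= 7L)
        out[[length(out) + 1L]] <- c(s, e - s)
    }
  }
  if (!length(out)) return(data.frame(start = integer(0), len = integer(0)))
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], len = m[, 2])
}

# --- deterministic event application --------------------------------------

#' Apply mutation events to a reference sequence
#'
#' Events are applied right-to-left so that earlier anchors stay valid.
#' `events` is a data frame with columns `kind` (`sub`, `ins`, `del`),
#' `start` (0-based), `length`, and `seq` (the replacement bases for `sub`,
#' the inserted bases for `ins`, ignored for `del`). Substitutions and
#' deletions occupy `[start, start + length)`; insertions fall between
#' `start` and `start + 1`.
#'
#' @param ref_seq DNA string.
#' @param events Ordered, non-overlapping event data frame.
#' @return The mutated DNA string, of length
#'   `nchar(ref_seq) + sum(ins lengths) - sum(del lengths)`.
#' @export
apply_events <- function(ref_seq, events) {
  if (is.null(events) || nrow(events) == 0L) return(ref_seq)
  L <- nchar(ref_seq)
  ends <- ifelse(events$kind == "ins", events$start + 1L,
                 events$start + events$length)
  if (any(events$start < 0L) || any(ends > L))
    stop("event anchors outside the sequence")
  o <- order(events$start)
  if (any(events$start[o][-1] < ends[o][-nrow(events)]))
    stop("overlapping events")
  for (i in rev(o)) {
    s <- events$start[i]
    switch(events$kind[i],
      sub = substr(ref_seq, s + 1L, s + events$length[i]) <- events$seq[i],
      del = ref_seq <- paste0(substr(ref_seq, 1L, s),
                              substr(ref_seq, s + events$length[i] + 1L, L)),
      ins = ref_seq <- paste0(substr(ref_seq, 1L, s + 1L), events$seq[i],
                              substr(ref_seq, s + 2L, L)),
      stop("unknown event kind '", events$kind[i], "'"))
    L <- nchar(ref_seq)
  }
  ref_seq
}

# Sample an alternate base for a substitution at a reference base, following
# the pyrimidine-collapsed signature (purine references are handled on the
# complementary strand).
sample_sub_alt <- function(ref_base, sig) {
  pyr <- ref_base %in% c("C", "T")
  rb <- if (pyr) ref_base else chartr("AG", "TC", ref_base)
  cls <- SIGNATURE_CLASSES[substr(SIGNATURE_CLASSES, 1, 1) == rb]
  w <- sig[cls]
  if (sum(w) <= 0) w <- rep(1, 3)
  alt <- substr(sample(cls, 1L, prob = w), 3L, 3L)
  if (!pyr) alt <- chartr("ACGT", "TGCA", alt)
  alt
}

# Alternate-base probability split for pileup simulation: named vector over
# the three non-reference bases, proportional to the signature.
alt_split <- function(ref_base, sig) {
  pyr <- ref_base %in% c("C", "T")
  rb <- if (pyr) ref_base else chartr("AG", "TC", ref_base)
  cls <- SIGNATURE_CLASSES[substr(SIGNATURE_CLASSES, 1, 1) == rb]
  w <- sig[cls]
  if (sum(w) <= 0) w <- rep(1, 3) / 3 else w <- w / sum(w)
  alts <- substr(cls, 3L, 3L)
  if (!pyr) alts <- chartr("ACGT", "TGCA", alts)
  setNames(as.numeric(w), alts)
}

# --- paired-read simulator ------------------------------------------------

#' Simulate a paired-end amplicon sequencing sample
#'
#' Draws `n_pairs` read pairs from a primer pool under a
#' [mutation_spectrum()]. Each pair originates from one amplicon (cis) or,
#' with probability `transloc_rate`, from a chimera joining the forward side
#' of one cut locus to the reverse side of another (trans). At most one
#' mutational event is injected per molecule (the default; independent
#' per-class draws with `multi_event = TRUE`), then uniform sequencing error
#' is applied to both mates. R1 is the first `read_len` bases of the
#' molecule; R2 the reverse complement of its last `read_len` bases, so R1
#' begins with a forward primer and R2 with a reverse primer. Identical
#' `(pool, spectrum, n_pairs, seed)` give byte-identical outputs.
#'
#' @param pool A `primer_pool`.
#' @param spectrum A `mutation_spectrum`.
#' @param n_pairs Number of read pairs.
#' @param seed RNG seed (defaults to the spectrum's).
#' @param r1_path,r2_path Output FASTQ paths (`.gz` suffix gzips).
#' @param truth_path Optional TSV path for the truth table.
#' @param read_len Read length (150 by default, as in 2x150 sequencing;
#'   molecules shorter than this yield shorter reads, unpadded).
#' @param multi_event Allow more than one event per molecule.
#' @return Invisibly, `list(r1, r2, truth)` where `truth` is a data frame
#'   with one row per pair: `read_id`, `locus_id`, `kind` (`none`, `sub`,
#'   `ins`, `del`, `transloc`), `rel_pos` (cut-relative anchor; absolute
#'   offset at UNCUT loci, which have no cut), `length`,
#'   `detail` (e.g. `"C>T"`, inserted/deleted bases, or `"fwd:rev"` locus
#'   pair for translocations).
#' @export
simulate_sample <- function(pool, spectrum, n_pairs, seed = spectrum$seed,
                            r1_path = tempfile(fileext = "_R1.fastq"),
                            r2_path = tempfile(fileext = "_R2.fastq"),
                            truth_path = NULL, read_len = 150L,
                            multi_event = FALSE) {
  if (n_pairs < 0) stop("n_pairs must be >= 0")
  if (is.na(seed)) stop("a seed is required for reproducible simulation")
  set.seed(seed)
  n_loci <- nrow(pool)
  loci <- lapply(pool$locus_id, function(id) get_locus(pool, id))
  names(loci) <- pool$locus_id
  cand <- lapply(loci, event_candidates, spectrum = spectrum)

  read_id <- sprintf("pair%06d", seq_len(n_pairs))
  truth <- data.frame(read_id = read_id,
                      locus_id = rep(NA_character_, n_pairs),
                      kind = rep("none", n_pairs),
                      rel_pos = rep(NA_integer_, n_pairs),
                      length = rep(NA_integer_, n_pairs),
                      detail = rep("", n_pairs),
                      stringsAsFactors = FALSE)
  molecules <- character(n_pairs)

  # translocation chimeras
  W <- transloc_weight_table(pool, spectrum$transloc_weights)
  is_trans <- if (nrow(W) && spectrum$transloc_rate > 0)
    runif(n_pairs) < spectrum$transloc_rate else rep(FALSE, n_pairs)
  if (any(is_trans)) {
    pick <- sample.int(nrow(W), sum(is_trans), replace = TRUE, prob = W$w)
    fwd <- W$fwd[pick]; rev <- W$rev[pick]
    chim <- vapply(seq_along(pick), function(k) {
      a <- loci[[fwd[k]]]; b <- loci[[rev[k]]]
      paste0(substr(a$ref_seq, 1L, a$cut_offset),
             substr(b$ref_seq, b$cut_offset + 1L, nchar(b$ref_seq)))
    }, character(1))
    molecules[is_trans] <- chim
    truth$locus_id[is_trans] <- fwd
    truth$kind[is_trans] <- "transloc"
    truth$detail[is_trans] <- paste0(fwd, ":", rev)
  }

  # cis molecules, one per remaining pair
  cis <- which(!is_trans)
  locus_idx <- sample.int(n_loci, length(cis), replace = TRUE)
  truth$locus_id[cis] <- pool$locus_id[locus_idx]
  classes <- c("sub", "ins", "small", "mid", "large", "slip", "mmej")
  for (l in seq_len(n_loci)) {
    rows <- cis[locus_idx == l]
    if (!length(rows)) next
    loc <- loci[[l]]; cd <- cand[[l]]
    molecules[rows] <- loc$ref_seq
    pc <- cd$p_class[classes]
    pc[is.na(pc)] <- 0
    if (multi_event) {
      hits <- matrix(runif(length(rows) * length(classes)), ncol =
                       length(classes)) < rep(pc, each = length(rows))
    } else {
      draw <- sample(c(classes, "none"), length(rows), replace = TRUE,
                     prob = c(pc, max(0, 1 - sum(pc))))
      hits <- outer(draw, classes, "==")
    }
    for (k in which(rowSums(hits) > 0)) {
      i <- rows[k]
      evs <- sample_locus_events(loc, cd, classes[hits[k, ]], spectrum)
      if (is.null(evs)) next
      molecules[i] <- apply_events(loc$ref_seq, evs)
      # truth keeps the first (only, by default) event
      truth$kind[i] <- evs$truth_kind[1]
      truth$rel_pos[i] <- if (!is.na(loc$cut_offset))
        evs$start[1] - loc$cut_offset else evs$start[1]
      truth$length[i] <- evs$length[1]
      truth$detail[i] <- evs$detail[1]
    }
  }

  # sequencing error and mate extraction
  L <- nchar(molecules)
  r1 <- substr(molecules, 1L, pmin(read_len, L))
  r2 <- revcomp(substr(molecules, pmax(1L, L - read_len + 1L), L))
  r1 <- inject_errors(r1, spectrum$seq_error_rate)
  r2 <- inject_errors(r2, spectrum$seq_error_rate)

  write_fastq(read_id, r1, r1_path, mate = 1L)
  write_fastq(read_id, r2, r2_path, mate = 2L)
  if (!is.null(truth_path))
    write.table(truth, truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(list(r1 = r1_path, r2 = r2_path, truth = truth))
}

# Ordered-pair translocation weight table over cut loci.
transloc_weight_table <- function(pool, weights = NULL) {
  cut_ids <- pool$locus_id[pool$repair_class != "UNCUT"]
  if (length(cut_ids) < 2L)
    return(data.frame(fwd = character(0), rev = character(0), w = numeric(0)))
  if (is.null(weights)) {
    g <- expand.grid(fwd = cut_ids, rev = cut_ids, stringsAsFactors = FALSE)
    g <- g[g$fwd != g$rev, ]
    g$w <- 1 / nrow(g)
  } else {
    stopifnot(is.matrix(weights))
    g <- expand.grid(fwd = rownames(weights), rev = colnames(weights),
                     stringsAsFactors = FALSE)
    g$w <- as.vector(weights)
    g <- g[g$w > 0 & g$fwd != g$rev, ]
    if (!all(c(g$fwd, g$rev) %in% pool$locus_id))
      stop("transloc_weights name loci absent from the pool")
    g$w <- g$w / sum(g$w)
  }
  rownames(g) <- NULL
  g
}

# Draw concrete events for one molecule given its hit classes. Returns an
# ordered non-overlapping event frame (extra overlapping events dropped),
# with truth metadata columns.
sample_locus_events <- function(loc, cd, hit_classes, spectrum) {
  ref <- loc$ref_seq
  evs <- list()
  for (cl in hit_classes) {
    ev <- switch(cl,
      sub = {
        pos <- cd$sub$pos[sample.int(nrow(cd$sub), 1L, prob = cd$sub$w)]
        rb <- substr(ref, pos + 1L, pos + 1L)
        alt <- sample_sub_alt(rb, spectrum$sub_signature)
        data.frame(kind = "sub", start = pos, length = 1L, seq = alt,
                   truth_kind = "sub", detail = paste0(rb, ">", alt))
      },
      ins = {
        a <- cd$ins$anchor[sample.int(nrow(cd$ins), 1L)]
        len <- sample(1:3, 1L)
        s <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
        data.frame(kind = "ins", start = a, length = len, seq = s,
                   truth_kind = "ins", detail = s)
      },
      {
        rows <- which(cd$del$kind == cl)
        if (!length(rows)) NULL else {
          r <- rows[sample.int(length(rows), 1L,
                               prob = cd$del$p[rows])]
          st <- cd$del$start[r]; len <- cd$del$len[r]
          data.frame(kind = "del", start = st, length = len,
                     seq = "", truth_kind = "del",
                     detail = substr(ref, st + 1L, st + len))
        }
      })
    if (!is.null(ev)) evs[[length(evs) + 1L]] <- ev
  }
  if (!length(evs)) return(NULL)
  evs <- do.call(rbind, evs)
  evs <- evs[order(evs$start), , drop = FALSE]
  # drop events overlapping an earlier-kept one
  keep <- rep(TRUE, nrow(evs))
  last_end <- -1L
  for (i in seq_len(nrow(evs))) {
    e <- if (evs$kind[i] == "ins") evs$start[i] + 1L
         else evs$start[i] + evs$length[i]
    if (evs$start[i] < last_end) keep[i] <- FALSE else last_end <- e
  }
  evs[keep, , drop = FALSE]
}

# Uniform per-base substitution error on a vector of reads.
inject_errors <- function(reads, e) {
  if (e <= 0 || !length(reads)) return(reads)
  w <- nchar(reads)
  k <- rbinom(length(reads), w, e)
  for (i in which(k > 0L)) {
    s <- strsplit(reads[i], "")[[1]]
    pos <- sample.int(w[i], k[i])
    for (p in pos) s[p] <- sample(setdiff(DNA_BASES, s[p]), 1L)
    reads[i] <- paste(s, collapse = "")
  }
  reads
}

# 4-line FASTQ writer; constant Q30 qualities; gzip by file suffix.
write_fastq <- function(ids, seqs, path, mate = 1L) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (length(ids)) {
    qual <- strrep("?", nchar(seqs))   # Phred+33 Q30
    writeLines(c(rbind(paste0("@", ids, "/", mate), seqs, "+", qual)), con)
  } else writeLines(character(0), con)
  invisible(path)
}

# --- pileup simulator -----------------------------------------------------

#' Simulate samtools-dialect pileup text directly
#'
#' Emits one pileup line per amplicon position at constant depth, with
#' alternate-read counts drawn binomially from the per-position
#' probabilities the spectrum implies: substitutions follow the spatial
#' decay model split across alternate bases by the signature (plus uniform
#' sequencing error), deletion events are drawn per candidate
#' `(start, length)` and encoded as `-N<seq>` on the anchoring position with
#' `*` over every deleted position, insertions as `+N<seq>`. Because it
#' bypasses read simulation and alignment entirely, its output feeds
#' [pileup_to_profile()] for aligner-free testing.
#'
#' @inheritParams simulate_sample
#' @param depth Reads per position.
#' @param path Optional output path for the pileup text.
#' @return Invisibly, `list(pileup, truth)`: `pileup` is the character
#'   vector of pileup lines (also written to `path` if given); `truth` has
#'   `$positions` (per-position true alternate probabilities) and `$events`
#'   (each drawn indel candidate with its probability and drawn count).
#' @export
simulate_pileup <- function(pool, spectrum, depth, seed = spectrum$seed,
                            path = NULL) {
  if (depth < 0) stop("depth must be >= 0")
  if (is.na(seed)) stop("a seed is required for reproducible simulation")
  set.seed(seed)
  out <- vector("list", nrow(pool))
  pos_truth <- vector("list", nrow(pool))
  ev_truth <- vector("list", nrow(pool))
  for (l in seq_len(nrow(pool))) {
    loc <- get_locus(pool, pool$locus_id[l])
    cd <- event_candidates(loc, spectrum)
    L <- nchar(loc$ref_seq)
    refc <- strsplit(loc$ref_seq, "")[[1]]
    e3 <- spectrum$seq_error_rate / 3

    # per-position alternate probabilities (rows A,C,G,T)
    palt <- matrix(e3, nrow = 4L, ncol = L,
                   dimnames = list(DNA_BASES, NULL))
    for (j in seq_len(L)) palt[refc[j], j] <- 0
    if (nrow(cd$sub)) for (r in seq_len(nrow(cd$sub))) {
      j <- cd$sub$pos[r] + 1L
      split <- alt_split(refc[j], spectrum$sub_signature)
      palt[names(split), j] <- palt[names(split), j] + cd$sub$w[r] * split
    }
    nalt <- matrix(rbinom(4L * L, depth, as.vector(palt)), nrow = 4L,
                   dimnames = list(DNA_BASES, NULL))
    for (j in seq_len(L)) nalt[refc[j], j] <- 0L

    # indel events
    star <- integer(L)
    del_tok <- vector("list", L)   # tokens attached at anchor (0-based start-1)
    ins_tok <- vector("list", L)
    ev <- NULL
    if (nrow(cd$del)) {
      cnt <- rbinom(nrow(cd$del), depth, cd$del$p)
      for (r in which(cnt > 0L)) {
        st <- cd$del$start[r]; len <- cd$del$len[r]
        seqr <- substr(loc$ref_seq, st + 1L, st + len)
        star[seq.int(st + 1L, st + len)] <-
          star[seq.int(st + 1L, st + len)] + cnt[r]
        del_tok[[st]] <- c(del_tok[[st]],
                           setNames(cnt[r], paste0("-", len, seqr)))
      }
      ev <- data.frame(locus_id = loc$locus_id, kind = cd$del$kind,
                       start = cd$del$start, length = cd$del$len,
                       p = cd$del$p, count = cnt,
                       stringsAsFactors = FALSE)
    }
    if (nrow(cd$ins)) {
      cnt <- rbinom(nrow(cd$ins), depth, cd$ins$p)
      ilen <- sample(1:3, nrow(cd$ins), replace = TRUE)
      for (r in which(cnt > 0L)) {
        a <- cd$ins$anchor[r]
        seqr <- paste(sample(DNA_BASES, ilen[r], replace = TRUE),
                      collapse = "")
        ins_tok[[a + 1L]] <- c(ins_tok[[a + 1L]],
                               setNames(cnt[r], paste0("+", ilen[r], seqr)))
      }
      ev <- rbind(ev, data.frame(locus_id = loc$locus_id, kind = "ins",
                                 start = cd$ins$anchor, length = ilen,
                                 p = cd$ins$p, count = cnt,
                                 stringsAsFactors = FALSE))
    }

    lines <- character(L)
    for (j in seq_len(L)) {
      ns <- star[j]; na <- sum(nalt[, j])
      n_ref <- depth - ns - na
      toks <- c(del_tok[j][[1]], ins_tok[j][[1]])
      n_anchored <- sum(toks)
      if (n_ref < n_anchored)
        stop("internal: event probabilities too high for depth ", depth)
      bases <- paste0(strrep(".", n_ref - n_anchored),
                      paste0(strrep(paste0(".", names(toks)), toks),
                             collapse = ""),
                      paste0(strrep(DNA_BASES, nalt[, j]), collapse = ""),
                      strrep("*", ns))
      lines[j] <- paste(loc$locus_id, j, refc[j], depth, bases,
                        strrep("I", depth), sep = "\t")
    }
    out[[l]] <- lines
    rel <- if (is.na(loc$cut_offset)) rep(NA_integer_, L)
           else seq_len(L) - 1L - loc$cut_offset
    pos_truth[[l]] <- data.frame(locus_id = loc$locus_id,
                                 pos = seq_len(L) - 1L, rel_pos = rel,
                                 p_alt = colSums(palt),
                                 n_alt = colSums(nalt),
                                 stringsAsFactors = FALSE)
    ev_truth[[l]] <- ev
  }
  lines <- unlist(out)
  if (!is.null(path)) writeLines(lines, path)
  invisible(list(pileup = lines,
                 truth = list(positions = do.call(rbind, pos_truth),
                              events = do.call(rbind, ev_truth))))
}
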