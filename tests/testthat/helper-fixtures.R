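# In-code fixtures shared across the suite.

rc_str <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

# Deterministic small pool: 2 cut loci (1 HR, 1 NHEJ) + 1 UNCUT control.
# Amplicons ~250 bp with the AsiSI motif centred on the cut, a homopolymer
# run planted 60 bp upstream for slippage simulation, 20 bp primers.
tiny_pool <- function(max_mismatch = 1L) {
  set.seed(424242)
  mk_ref <- function(len, cut) {
    s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    if (!is.na(cut)) {
      s[(cut - 4):(cut + 3)] <- strsplit("GCGATCGC", "")[[1]]
      s[(cut - 59):(cut - 55)] <- "A"
      s[(cut + 56):(cut + 60)] <- "T"
    }
    paste(s, collapse = "")
  }
  rows <- list(
    list(id = "HRA",  cls = "HR",    len = 256L, cut = 128L),
    list(id = "NHEB", cls = "NHEJ",  len = 250L, cut = 125L),
    list(id = "CTRC", cls = "UNCUT", len = 260L, cut = NA_integer_))
  df <- do.call(rbind, lapply(rows, function(r) {
    ref <- mk_ref(r$len, r$cut)
    data.frame(locus_id = r$id, repair_class = r$cls, chrom = "chrT",
               start = 1000L, end = 1000L + r$len,
               cut_offset = if (is.na(r$cut)) NA_integer_ else r$cut - 1L,
               fwd_primer = substr(ref, 1, 20),
               rev_primer = rc_str(substr(ref, r$len - 19, r$len)),
               ref_seq = ref, stringsAsFactors = FALSE)
  }))
  primer_pool(df, max_mismatch = max_mismatch)
}

# Minimal two-locus pool with short amplicons for hand-checkable reads.
micro_pool <- function() {
  mk <- function(id, cls, core, cut) {
    ref <- core
    data.frame(locus_id = id, repair_class = cls, chrom = "chrT",
               start = 0L, end = nchar(ref), cut_offset = cut,
               fwd_primer = substr(ref, 1, 10),
               rev_primer = rc_str(substr(ref, nchar(ref) - 9, nchar(ref))),
               ref_seq = ref, stringsAsFactors = FALSE)
  }
  set.seed(99)
  base <- function() paste(sample(c("A", "C", "G", "T"), 60, TRUE),
                           collapse = "")
  primer_pool(rbind(mk("A", "HR", base(), 30L),
                    mk("B", "NHEJ", base(), 30L)))
}

# Write a paired FASTQ from sequence vectors; returns c(r1, r2).
write_pair_fastq <- function(seq1, seq2, dir = NULL,
                             ids = sprintf("p%04d", seq_along(seq1))) {
  if (is.null(dir)) {
    dir <- tempfile("fq")
    dir.create(dir)
  }
  r1 <- file.path(dir, "r1.fastq"); r2 <- file.path(dir, "r2.fastq")
  fq <- function(path, seqs, mate) writeLines(
    c(rbind(paste0("@", ids, "/", mate), seqs, "+",
            strrep("I", nchar(seqs)))), path)
  fq(r1, seq1, 1); fq(r2, seq2, 2)
  c(r1, r2)
}

# Perfect cis mates for a locus: R1 = 5' prefix, R2 = revcomp 3' suffix.
cis_mates <- function(loc, read_len = 150L) {
  L <- nchar(loc$ref_seq)
  list(r1 = substr(loc$ref_seq, 1, min(read_len, L)),
       r2 = rc_str(substr(loc$ref_seq, max(1, L - read_len + 1), L)))
}

# Brute-force reference classifier for scan_fastq oracle tests: tests every
# primer prefix against every read end, independent of the C++ matcher.
brute_classify <- function(r1, r2, pool, max_mismatch = 1L) {
  tab <- data.frame(locus = rep(pool$locus_id, 2),
                    side = rep(c("fwd", "rev"), each = nrow(pool)),
                    primer = c(pool$fwd_primer, pool$rev_primer),
                    stringsAsFactors = FALSE)
  one <- function(s) {
    hit <- NULL
    for (k in seq_len(nrow(tab))) {
      p <- tab$primer[k]
      if (nchar(s) < nchar(p)) next
      d <- sum(strsplit(substr(s, 1, nchar(p)), "")[[1]] !=
               strsplit(p, "")[[1]])
      if (d <= max_mismatch) hit <- rbind(hit, tab[k, ])
    }
    hit
  }
  vapply(seq_along(r1), function(i) {
    h1 <- one(r1[i]); h2 <- one(r2[i])
    if (is.null(h1) || is.null(h2) || nrow(h1) != 1 || nrow(h2) != 1 ||
        h1$side == h2$side) return("unmatched")
    if (h1$locus == h2$locus) "cis" else "trans"
  }, "")
}

# Independent brute-force microhomology honouring the cap
# min(del_end - del_start, nchar(ref) - del_end): try every k exhaustively.
brute_microhomology <- function(ref, s, e) {
  kmax <- min(e - s, nchar(ref) - e)
  best <- 0L
  for (k in seq_len(kmax)) {
    if (substr(ref, s + 1, s + k) == substr(ref, e + 1, e + k)) best <- k
  }
  best
}
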