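test_that("pileup records decode exactly as hand-parsed", {
  r <- parse_pileup_record("ampA\t101\tA\t5\t.,Tt.\tIIIII")
  expect_equal(r$depth, 5L)
  expect_equal(r$sub[["T"]], 2L)
  expect_equal(r$n_ref, 3L)
  expect_equal(r$pos, 100L)  # converted to 0-based

  r <- parse_pileup_record("ampA\t50\tG\t4\t.+2TA.,.\tIIII")
  expect_equal(r$depth, 4L)
  expect_equal(nrow(r$ins), 1L)
  expect_equal(r$ins$seq, "TA")
  expect_equal(sum(r$sub), 0L)

  r <- parse_pileup_record("ampA\t60\tC\t6\t..-2AT..,,\tIIIIII")
  expect_equal(r$depth, 6L)
  expect_equal(nrow(r$del), 1L)
  expect_equal(r$del$length, 2L)
  expect_equal(r$del$seq, "AT")

  # ^] consumes the mapping-quality byte even when it looks like a symbol
  r <- parse_pileup_record("ampA\t10\tT\t2\t.^],\t II")
  expect_equal(r$depth, 2L)
  expect_equal(sum(r$sub) + r$n_star + nrow(r$ins) + nrow(r$del), 0L)

  # read ends and deletion coverage
  r <- parse_pileup_record("ampA\t7\tC\t4\t.$*,a\tIIII")
  expect_equal(r$n_star, 1L)
  expect_equal(r$sub[["A"]], 1L)
})

test_that("malformed pileup lines raise named format errors", {
  expect_error(parse_pileup_record("ampA\t1\tA\t5\t.,Tt.,,\tIII"),
               "decoded 7 read symbols but depth is 5")
  expect_error(parse_pileup_record("ampA\t1\tA\t2\t.+T.\tII"),
               "not followed by a length")
  expect_error(parse_pileup_record("ampA\t1\tA\t2\t.+9TA\tII"), "dangling")
  expect_error(parse_pileup_record("ampA\t1\tA\t2\t.!\tII"),
               "unknown pileup symbol '!'")
  expect_error(parse_pileup_record("too\tfew"), "6 tab-separated fields")
})

test_that("profiles aggregate counts into per-position percent rates", {
  pool <- micro_pool()
  loc <- get_locus(pool, "A")
  rb <- function(i) substr(loc$ref_seq, i, i)
  # a 1-in-200,000 alternate at depth 400,000: rate 0.0005%
  depth <- 400000L
  alt <- if (rb(31) == "T") "G" else "T"
  line <- paste("A", 31, rb(31), depth,
                paste0(strrep(".", depth - 2L), strrep(alt, 2L)),
                strrep("I", depth), sep = "\t")
  prof <- pileup_to_profile(line, pool)
  expect_equal(prof$sub_total, 100 * 2 / depth)  # 0.0005%
  expect_equal(prof$depth, depth)

  # all-reference pileup: all rates exactly zero
  lines <- vapply(25:30, function(i) paste("A", i, rb(i), 100L,
                                           strrep(".", 100), strrep("I", 100),
                                           sep = "\t"), "")
  prof <- pileup_to_profile(lines, pool)
  expect_true(all(prof$sub_total == 0 & prof$ins_rate == 0 &
                  prof$del_cov_rate == 0))

  # rates below min_depth are missing, counts retained
  line <- paste("A", 31, rb(31), 10L, paste0(strrep(".", 9), alt),
                strrep("I", 10), sep = "\t")
  prof <- pileup_to_profile(line, pool, min_depth = 100)
  expect_true(is.na(prof$sub_total))
  expect_equal(prof[[paste0("n_sub_", alt)]], 1L)

  expect_error(pileup_to_profile("nope\t1\tA\t1\t.\tI", pool),
               "unknown reference")
  expect_error(pileup_to_profile(paste("A", 99, "A", 1L, ".", "I",
                                       sep = "\t"), pool),
               "outside amplicon")
})

test_that("a length-3 deletion spans coverage and anchors one mid event", {
  pool <- micro_pool()
  loc <- get_locus(pool, "A")
  rb <- function(i) substr(loc$ref_seq, i, i)
  p <- 30L  # 1-based anchor
  dseq <- substr(loc$ref_seq, p + 1, p + 3)
  lines <- c(
    paste("A", p, rb(p), 50L, paste0(strrep(".", 49), ".-3", dseq),
          strrep("I", 50), sep = "\t"),
    vapply(p + 1:3, function(i) paste("A", i, rb(i), 50L,
                                      paste0(strrep(".", 49), "*"),
                                      strrep("I", 50), sep = "\t"), ""))
  prof <- pileup_to_profile(lines, pool, min_depth = 10)
  expect_equal(prof$n_del_mid[prof$pos == p - 1L], 1L)
  expect_equal(prof$n_star[prof$pos %in% (p + 0:2)], rep(1L, 3))
  expect_equal(prof$del_cov_rate[prof$pos %in% (p + 0:2)], rep(2, 3))
  anns <- deletion_annotations(prof)
  expect_equal(nrow(anns), 1L)
  expect_equal(anns$start, p)        # first deleted base, 0-based
  expect_equal(anns$length, 3L)
  expect_equal(anns$class, "mid")
})

test_that("deletion size classes split at 1 bp and 5 bp", {
  expect_equal(classify_deletion_length(c(1, 2, 5, 6, 40)),
               c("small", "mid", "mid", "large", "large"))
  expect_error(classify_deletion_length(0), ">= 1")
})

test_that("microhomology equals the frozen hand-derived cases", {
  expect_equal(compute_microhomology("ATCACGTACGTTT", 3, 7), 4L)
  expect_equal(compute_microhomology("AAAATTTT", 2, 4), 0L)
  # capped by the remaining deletion length: a 1 bp deletion can carry at
  # most 1 bp of junction homology under the cap rule
  expect_equal(compute_microhomology("CCAAAAACC", 2, 3), 1L)
  expect_error(compute_microhomology("ACGT", 2, 2), "invalid deletion")
  expect_error(compute_microhomology("ACGT", -1, 2), "invalid deletion")
})

test_that("microhomology matches an exhaustive scan on random instances", {
  set.seed(1234)
  for (i in 1:1000) {
    L <- sample(20:60, 1)
    ref <- paste(sample(c("A", "C", "G", "T"), L, TRUE,
                        prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
    s <- sample(0:(L - 2), 1)
    e <- sample((s + 1):min(L, s + 15), 1)
    expect_identical(compute_microhomology(ref, s, e),
                     brute_microhomology(ref, s, e))
  }
})

test_that("deletion annotation fills class, adjacency, MMEJ and slippage", {
  pool <- tiny_pool()
  loc <- get_locus(pool, "HRA")
  cut <- loc$cut_offset
  # 1 bp deletion in the planted A-run ~57 bp upstream: small, distant, slip
  run_start <- cut - 59L
  a <- annotate_deletion(loc, run_start, 1L)
  expect_equal(a$class, "small")
  expect_equal(a$adjacency, "distant")
  expect_true(a$slippage)
  expect_false(a$mmej)
  # cut-spanning deletion with known junction homology: mmej iff homology >= 2
  cand <- NULL
  for (s in (cut - 30):(cut - 6)) for (e in (cut + 1):(cut + 30)) {
    if (e - s >= 6 && brute_microhomology(loc$ref_seq, s, e) >= 2) {
      cand <- c(s, e); break
    }
  }
  expect_false(is.null(cand))
  a <- annotate_deletion(loc, cand[1], cand[2] - cand[1])
  expect_equal(a$class, "large")
  expect_equal(a$adjacency, "adjacent")
  expect_true(a$mmej)
  expect_equal(a$microhomology,
               brute_microhomology(loc$ref_seq, cand[1], cand[2]))
  # 2 bp deletion at the cut: mid, adjacent, never MMEJ
  a <- annotate_deletion(loc, cut, 2L)
  expect_equal(a$class, "mid")
  expect_equal(a$adjacency, "adjacent")
  expect_false(a$mmej)
  # deletions reaching into primers are rejected
  expect_error(annotate_deletion(loc, 5L, 3L), "primer-free interior")
})

test_that("caller recovers simulated truth exactly on error-free pileups", {
  pool <- tiny_pool()
  sp <- mutation_spectrum(seq_error_rate = 0, sub_rate_peak = 5e-3,
                          sub_floor = 0, del_small_rate = 0.01,
                          del_mid_rate = 0.01, del_large_rate = 0.01,
                          distant_slip_rate = 0.01, mmej_rate = 0.01,
                          ins_rate = 0.01, transloc_rate = 0)
  sim <- simulate_pileup(pool, sp, depth = 3000, seed = 41)
  prof <- pileup_to_profile(sim$pileup, pool, min_depth = 10)
  # per-position alternate counts match the generator's own draws exactly
  tp <- sim$truth$positions
  merged <- merge(as.data.frame(prof)[c("locus_id", "pos", "n_sub_A",
                                        "n_sub_C", "n_sub_G", "n_sub_T")],
                  tp, by = c("locus_id", "pos"))
  expect_equal(merged$n_sub_A + merged$n_sub_C + merged$n_sub_G +
               merged$n_sub_T, merged$n_alt)
  # deletion events: recovered counts equal drawn counts per (start, len)
  ev <- sim$truth$events
  ev <- ev[ev$kind != "ins" & ev$count > 0, ]
  anns <- deletion_annotations(prof)
  ev_agg <- aggregate(count ~ locus_id + start + length, ev, sum)
  m <- merge(anns, ev_agg, by = c("locus_id", "start", "length"),
             suffixes = c("_called", "_true"))
  expect_equal(nrow(m), nrow(ev_agg))
  expect_equal(m$count_called, m$count_true)
  # class partition: total deletion events == sum over size classes
  expect_equal(sum(prof$n_del_small + prof$n_del_mid + prof$n_del_large),
               sum(anns$count))
})

test_that("halving depth at most doubles the relative standard error", {
  pool <- micro_pool()
  sp <- mutation_spectrum(sub_rate_peak = 0.02, sub_floor = 0,
                          del_small_rate = 0, del_mid_rate = 0,
                          del_large_rate = 0, distant_slip_rate = 0,
                          mmej_rate = 0, ins_rate = 0, transloc_rate = 0,
                          seq_error_rate = 0)
  rate_at_cut <- function(depth, seed) {
    sim <- simulate_pileup(pool[pool$locus_id == "A", ], sp, depth, seed)
    prof <- pileup_to_profile(sim$pileup, pool, min_depth = 10)
    prof$sub_total[prof$rel_pos == 0]
  }
  seeds <- 1:24
  hi <- vapply(seeds, function(s) rate_at_cut(4000L, s), 0)
  lo <- vapply(seeds, function(s) rate_at_cut(2000L, s + 1000), 0)
  rse <- function(x) sd(x) / mean(x)
  # binomial: rse scales as 1/sqrt(depth); allow slack for sampling noise
  expect_lt(rse(lo), 2.5 * rse(hi))
  expect_gt(rse(lo), rse(hi) / 2.5)
})
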