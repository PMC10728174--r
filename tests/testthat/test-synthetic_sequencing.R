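test_that("apply_events performs exact edits and rejects overlap", {
  expect_identical(apply_events("ACGT", NULL), "ACGT")
  ev <- data.frame(kind = "del", start = 1L, length = 2L, seq = "")
  expect_identical(apply_events("ACGT", ev), "AT")
  ev <- data.frame(kind = "del", start = 3L, length = 4L, seq = "")
  expect_identical(apply_events("ATCACGTACGTTT", ev), "ATCACGTTT")
  ev <- data.frame(kind = c("sub", "ins"), start = c(0L, 2L),
                   length = c(1L, 2L), seq = c("G", "TT"))
  expect_identical(apply_events("ACGT", ev), "GCGTTT")
  bad <- data.frame(kind = c("del", "sub"), start = c(1L, 2L),
                    length = c(2L, 1L), seq = c("", "A"))
  expect_error(apply_events("ACGT", bad), "overlapping")
  expect_error(apply_events("ACGT",
    data.frame(kind = "del", start = 3L, length = 2L, seq = "")),
    "outside")
})

test_that("null spectrum reads are exact reference prefixes/suffixes", {
  pool <- tiny_pool()
  res <- simulate_sample(pool, null_spectrum(seq_error_rate = 0), 500,
                         seed = 11)
  expect_true(all(res$truth$kind == "none"))
  lines1 <- readLines(res$r1); lines2 <- readLines(res$r2)
  expect_equal(length(lines1), 500 * 4)
  for (i in seq_len(50)) {  # spot-check structure on a sample
    loc <- get_locus(pool, res$truth$locus_id[i])
    exp <- cis_mates(loc)
    expect_identical(lines1[4 * i - 2], exp$r1)
    expect_identical(lines2[4 * i - 2], exp$r2)
  }
})

test_that("simulation is byte-identical under a fixed seed", {
  pool <- tiny_pool()
  sp <- mutation_spectrum()
  d <- withr::local_tempdir()
  a <- simulate_sample(pool, sp, 300, seed = 5,
                       r1_path = file.path(d, "a1.fq"),
                       r2_path = file.path(d, "a2.fq"))
  b <- simulate_sample(pool, sp, 300, seed = 5,
                       r1_path = file.path(d, "b1.fq"),
                       r2_path = file.path(d, "b2.fq"))
  expect_identical(readLines(a$r1), readLines(b$r1))
  expect_identical(readLines(a$r2), readLines(b$r2))
  expect_identical(a$truth, b$truth)
  # and n_pairs = 0 gives empty outputs
  z <- simulate_sample(pool, sp, 0, seed = 1,
                       r1_path = file.path(d, "z1.fq"),
                       r2_path = file.path(d, "z2.fq"))
  expect_equal(length(readLines(z$r1)), 0L)
  expect_equal(nrow(z$truth), 0L)
  expect_error(simulate_sample(pool, sp, -1, seed = 1), ">= 0")
})

test_that("degenerate translocation rate forces all-trans truth", {
  pool <- micro_pool()
  sp <- mutation_spectrum(transloc_rate = 1, seq_error_rate = 0)
  res <- simulate_sample(pool, sp, 100, seed = 3)
  expect_true(all(res$truth$kind == "transloc"))
  expect_true(all(res$truth$detail %in% c("A:B", "B:A")))
  # chimeric molecules start with one locus fwd primer and end on the
  # other locus rev primer
  seqs <- readLines(res$r1)[c(FALSE, TRUE, FALSE, FALSE)]
  pa <- get_locus(pool, "A")$fwd_primer
  pb <- get_locus(pool, "B")$fwd_primer
  expect_true(all(startsWith(seqs, pa) | startsWith(seqs, pb)))
})

test_that("truth table counts match exhaustive read-vs-reference diffing", {
  pool <- tiny_pool()
  sp <- mutation_spectrum(sub_rate_peak = 2e-3, del_small_rate = 0.05,
                          del_mid_rate = 0.05, del_large_rate = 0.05,
                          distant_slip_rate = 0.05, mmej_rate = 0.05,
                          ins_rate = 0.05, transloc_rate = 0,
                          seq_error_rate = 0)
  res <- simulate_sample(pool, sp, 400, seed = 21)
  seqs1 <- readLines(res$r1)[c(FALSE, TRUE, FALSE, FALSE)]
  seqs2 <- readLines(res$r2)[c(FALSE, TRUE, FALSE, FALSE)]
  # independent oracle: rebuild each molecule from its truth record alone
  # and check both emitted mates are its exact 150 bp ends
  for (i in seq_along(seqs1)) {
    tr <- res$truth[i, ]
    loc <- get_locus(pool, tr$locus_id)
    mol <- loc$ref_seq
    if (tr$kind != "none") {
      start <- tr$rel_pos + (if (is.na(loc$cut_offset)) 0L
                             else loc$cut_offset)
      ev <- switch(tr$kind,
        sub = data.frame(kind = "sub", start = start, length = 1L,
                         seq = sub(".*>", "", tr$detail)),
        ins = data.frame(kind = "ins", start = start,
                         length = nchar(tr$detail), seq = tr$detail),
        del = data.frame(kind = "del", start = start, length = tr$length,
                         seq = ""))
      mol <- apply_events(mol, ev)
    }
    L <- nchar(mol)
    expect_identical(seqs1[i], substr(mol, 1, min(150L, L)))
    expect_identical(seqs2[i], rc_str(substr(mol, max(1L, L - 149L), L)))
  }
  # every emitted pair has exactly one truth record
  expect_equal(nrow(res$truth), 400L)
  expect_false(anyDuplicated(res$truth$read_id) > 0)
})

test_that("deletion truth classes match their constructed geometry", {
  pool <- tiny_pool()
  sp <- mutation_spectrum(sub_rate_peak = 0, sub_floor = 0,
                          del_small_rate = 0.2, del_mid_rate = 0.2,
                          del_large_rate = 0.2, distant_slip_rate = 0.2,
                          mmej_rate = 0.2, ins_rate = 0, transloc_rate = 0,
                          seq_error_rate = 0)
  res <- simulate_sample(pool, sp, 300, seed = 31)
  tr <- res$truth[res$truth$kind == "del", ]
  expect_gt(nrow(tr), 200)
  expect_true(all(tr$length >= 1 & tr$length <= 70))
  # deleted detail string matches the reference at the recorded anchor
  for (i in seq_len(nrow(tr))) {
    loc <- get_locus(pool, tr$locus_id[i])
    s <- tr$rel_pos[i] + loc$cut_offset
    expect_identical(tr$detail[i], substr(loc$ref_seq, s + 1, s + tr$length[i]))
  }
})

test_that("pileup simulation obeys the binomial law at a known probability", {
  pool <- micro_pool()
  # fix one position's true alternate probability via the spatial model:
  # at the cut, rate = sub_rate_peak + sub_floor
  sp <- mutation_spectrum(sub_rate_peak = 0.1, sub_floor = 0,
                          sub_decay_bp = 1e-9 + 20,
                          del_small_rate = 0, del_mid_rate = 0,
                          del_large_rate = 0, distant_slip_rate = 0,
                          mmej_rate = 0, ins_rate = 0, transloc_rate = 0,
                          seq_error_rate = 0)
  depth <- 10000L
  counts <- vapply(1:20, function(s) {
    sim <- simulate_pileup(pool[pool$locus_id == "A", ], sp, depth, seed = s)
    tp <- sim$truth$positions
    tp$n_alt[tp$rel_pos == 0][1]
  }, 0)
  p <- 0.1
  se <- sqrt(p * (1 - p) * depth / 20)
  expect_lt(abs(mean(counts) - depth * p), 3 * se)
})

test_that("pileup text is well-formed at degenerate depths and spectra", {
  pool <- micro_pool()
  sim0 <- simulate_pileup(pool, null_spectrum(seq_error_rate = 0), 0,
                          seed = 1)
  rec <- parse_pileup_record(sim0$pileup[1])
  expect_equal(rec$depth, 0L)
  expect_equal(rec$n_ref + rec$n_star + sum(rec$sub), 0L)
  sim <- simulate_pileup(pool, null_spectrum(seq_error_rate = 0), 100,
                         seed = 1)
  bases <- vapply(strsplit(sim$pileup, "\t"), `[`, "", 5)
  expect_true(all(bases == strrep(".", 100)))
  # determinism
  sim2 <- simulate_pileup(pool, mutation_spectrum(), 500, seed = 9)
  sim3 <- simulate_pileup(pool, mutation_spectrum(), 500, seed = 9)
  expect_identical(sim2$pileup, sim3$pileup)
})
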