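# Shared small profiles for delta / metagene tests, built once per file.
ana_pool <- tiny_pool()
prof_of <- function(sp, seed) pileup_to_profile(
  simulate_pileup(ana_pool, sp, 3000L, seed)$pileup, ana_pool,
  min_depth = 10)
prof_plus <- prof_of(mutation_spectrum(sub_rate_peak = 0.01, sub_floor = 0,
                                       seq_error_rate = 0.002), 61)
prof_minus <- prof_of(null_spectrum(seq_error_rate = 0.002), 62)

test_that("delta of a profile with itself is identically zero", {
  d <- delta_profiles(prof_plus, prof_plus)
  expect_true(all(d$sub_total == 0, na.rm = TRUE))
  expect_true(all(d$ins_rate == 0, na.rm = TRUE))
})

test_that("deltas subtract per nucleotide, keep sign, propagate missing", {
  d <- delta_profiles(prof_plus, prof_minus)
  i <- which(!is.na(d$sub_total))[1]
  expect_equal(d$sub_total[i],
               prof_plus$sub_total[i] - prof_minus$sub_total[i])
  expect_true(any(d$sub_total < 0, na.rm = TRUE))  # noise goes both ways
  # grids must match
  expect_error(delta_profiles(prof_plus,
                              prof_minus[-1, ]), "grids differ")
  # a position missing on one side is missing in the delta
  pm <- prof_minus
  pm$sub_total[5] <- NA_real_
  expect_true(is.na(delta_profiles(prof_plus, pm)$sub_total[5]))
})

test_that("delta linearity: d(a,b) + d(b,c) == d(a,c) pointwise", {
  a <- prof_plus; b <- prof_minus
  cc <- prof_plus  # reuse as third grid-compatible profile
  lhs <- delta_profiles(a, b)$sub_total + delta_profiles(b, cc)$sub_total
  rhs <- delta_profiles(a, cc)$sub_total
  expect_equal(lhs, rhs)
})

test_that("chained treatment delta isolates a treatment-specific signal", {
  expect_equal(
    chained_treatment_delta(prof_plus, prof_plus, prof_plus,
                            prof_plus)$sub_total,
    rep(0, nrow(prof_plus)))
  ch <- chained_treatment_delta(prof_plus, prof_minus, prof_plus, prof_minus)
  expect_true(all(abs(ch$sub_total) < 1e-12, na.rm = TRUE))
})

test_that("treatment doubling distant slippage shows in the chained delta", {
  pool <- ana_pool
  depth <- 20000L
  base_slip <- 0.004
  mk <- function(slip, err, seed) pileup_to_profile(simulate_pileup(
    pool, mutation_spectrum(sub_rate_peak = 0, sub_floor = 0,
                            del_small_rate = 0, del_mid_rate = 0,
                            del_large_rate = 0, distant_slip_rate = slip,
                            mmej_rate = 0, ins_rate = 0, transloc_rate = 0,
                            seq_error_rate = err),
    depth, seed)$pileup, pool, min_depth = 10)
  tp <- mk(2 * base_slip, 0.001, 71); tm <- mk(0, 0.001, 72)
  cp <- mk(base_slip, 0.001, 73);     cm <- mk(0, 0.001, 74)
  ch <- chained_treatment_delta(tp, tm, cp, cm)
  # summed distant deletion-coverage delta is positive and near the
  # injected extra rate; substitution delta stays near zero
  hra <- ch[ch$locus_id == "HRA", ]
  expect_gt(sum(hra$del_cov_rate), 100 * base_slip / 2)
  expect_lt(abs(sum(hra$sub_total)), 100 * base_slip / 2)
})

test_that("metagene aligns loci at the cut and averages unweighted", {
  pool <- ana_pool
  W <- 60L
  mg1 <- metagene_profile(prof_plus, pool, "HR", window = W)
  expect_equal(length(mg1$rel), 2L * W + 1L)
  # single-locus group: the metagene equals that locus's own row
  hra <- prof_plus[prof_plus$locus_id == "HRA" &
                   !is.na(prof_plus$rel_pos) &
                   abs(prof_plus$rel_pos) <= W, ]
  expect_equal(as.numeric(mg1$mean),
               hra$sub_total[match(mg1$rel, hra$rel_pos)])
  # two-locus group: pointwise arithmetic mean of the rows
  mg2 <- metagene_profile(prof_plus, pool, c("HRA", "NHEB"), window = W)
  expect_equal(as.numeric(mg2$mean),
               as.numeric(colMeans(mg2$per_locus)))
  expect_equal(mg2$per_locus["HRA", ], mg1$per_locus["HRA", ])
  # default window is 100 bp -> 201 positions
  mg3 <- metagene_profile(prof_plus, pool, "HR")
  expect_equal(length(mg3$rel), 201L)
  expect_error(metagene_profile(prof_plus, pool, c("CTRC"), window = W),
               "UNCUT")
  expect_error(metagene_profile(prof_plus, pool, "HR", window = 1000L),
               "exceeds the primer-free interior")
})

test_that("the damage peak sits at the cut in the metagene delta", {
  d <- delta_profiles(prof_plus, prof_minus)
  mg <- metagene_profile(d, ana_pool, c("HRA", "NHEB"), window = 80L)
  pk <- mg$rel[which.max(mg$mean)]
  expect_lte(abs(pk), 10L)  # peak within 10 bp of the cut
  # and the peak rate is near the injected 1% per-read-per-position rate
  expect_gt(max(mg$mean), 0.3)
})

test_that("locus summaries total rates and collapse the signature", {
  pool <- ana_pool
  # all-zero profile -> all-zero summary
  zero <- pileup_to_profile(simulate_pileup(
    pool, null_spectrum(seq_error_rate = 0), 500, seed = 81)$pileup,
    pool, min_depth = 10)
  s <- locus_summary(zero, pool, window = 60L)
  expect_equal(nrow(s), 3L)
  num <- vapply(s, is.numeric, TRUE)
  expect_true(all(abs(as.matrix(s[, num & names(num) != "n_positions"]))
                  < 1e-12))
  # a single A>G alternate lands entirely in the T>C collapsed class
  loc <- get_locus(pool, "HRA")
  apos <- which(strsplit(loc$ref_seq, "")[[1]] == "A")
  apos <- apos[apos > 30 & abs(apos - 1 - loc$cut_offset) <= 50][1]
  line <- paste("HRA", apos, "A", 200L,
                paste0(strrep(".", 199), "G"), strrep("I", 200), sep = "\t")
  prof1 <- pileup_to_profile(line, pool, min_depth = 10)
  s1 <- locus_summary(prof1, pool, window = 60L)
  expect_equal(s1$sig_TtoC, 100 / 200)
  expect_equal(s1$sig_CtoT + s1$sig_CtoA + s1$sig_CtoG + s1$sig_TtoA +
               s1$sig_TtoG, 0)
  # collapse conserves total substitution mass
  s2 <- locus_summary(prof_plus, pool, window = 60L)
  sig_cols <- grep("^sig_", names(s2), value = TRUE)
  expect_equal(rowSums(s2[sig_cols]), s2$sub_total, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("a C>T-dominated spectrum is recovered as C>T argmax per seed", {
  pool <- ana_pool
  sp <- mutation_spectrum(sub_rate_peak = 0.01, sub_floor = 0,
                          sub_signature = c("C>A" = 0.05, "C>G" = 0.05,
                                            "C>T" = 0.7, "T>A" = 0.05,
                                            "T>C" = 0.1, "T>G" = 0.05),
                          seq_error_rate = 0)
  for (seed in 1:10) {
    prof <- pileup_to_profile(simulate_pileup(pool, sp, 2000,
                                              seed = seed)$pileup,
                              pool, min_depth = 10)
    s <- locus_summary(prof, pool, window = 80L)
    sig <- colSums(s[grep("^sig_", names(s))])
    expect_equal(names(which.max(sig)), "sig_CtoT")
  }
})

test_that("translocation summaries average unordered class pairs", {
  pool <- default_pool()
  ids <- pool$locus_id
  z <- matrix(0L, 25, 25, dimnames = list(ids, ids))
  s0 <- translocation_summary(transloc_matrix(z), pool)
  expect_true(all(is.na(s0$class_summary$mean_rate) |
                  s0$class_summary$mean_rate == 0))
  # 99 cis + 1 trans between two HR loci: only HR-HR mean is positive
  m <- z
  diag(m)[1:25] <- 4L  # 100 cis spread over loci (99 + 1 adjusted below)
  diag(m)[1] <- 3L
  m["HR01", "HR02"] <- 1L
  tm <- transloc_matrix(m)
  expect_equal(tm$total_classified, 100L)
  ts <- translocation_summary(tm, pool)
  cs <- ts$class_summary
  expect_gt(cs$mean_rate[cs$pair_class == "HR-HR"], 0)
  expect_equal(cs$mean_rate[cs$pair_class == "NHEJ-NHEJ"], 0)
  expect_equal(cs$mean_rate[cs$pair_class == "HR-NHEJ"], 0)
  expect_equal(cs$mean_rate[cs$pair_class == "UNCUT-any"], 0)
  expect_equal(ts$pair_map$rate[ts$pair_map$locus_a == "HR01" &
                                ts$pair_map$locus_b == "HR02"], 1 / 100)
  # symmetry: transposing counts leaves the summary unchanged
  ts_t <- translocation_summary(transloc_matrix(t(m)), pool)
  expect_equal(ts_t$class_summary, ts$class_summary)
  expect_error(translocation_summary(
    transloc_matrix(matrix(0L, 2, 2, dimnames = list(c("x", "y"),
                                                     c("x", "y")))), pool),
    "absent from the pool")
})
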