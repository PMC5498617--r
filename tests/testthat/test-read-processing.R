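test_that("sliding-window trimming follows the documented rule", {
  # uniform high quality: untouched
  r <- make_reads(random_seq(50), q = 40L)
  expect_identical(trim_reads(r), r)
  # 30 good bases then poor tail: the first failing window starts at 30,
  # so the 30-base prefix is kept
  r <- make_reads(random_seq(50), quals = qual_string(c(rep(40, 30), rep(2, 20))))
  out <- trim_reads(r, window = 4, min_mean_quality = 15, min_length = 30)
  expect_identical(nchar(out$sequence), 30L)
  expect_identical(out$sequence, substr(r$sequence, 1, 30))
  expect_identical(out$quality, substr(r$quality, 1, 30))
  # 29 good bases -> trimmed to 29 -> dropped by the length filter
  r <- make_reads(random_seq(50), quals = qual_string(c(rep(40, 29), rep(2, 21))))
  expect_identical(nrow(trim_reads(r, min_length = 30)), 0L)
  expect_error(trim_reads(r, window = 0), "window")
})

test_that("scanning requires a perfect match on either strand", {
  ps <- rice_probe_sets()$rc
  word <- ps$alt_forward
  mism <- paste0("A", substr(word, 2, 30))
  if (mism == word) mism <- paste0("C", substr(word, 2, 30))
  ev <- scan_reads(make_reads(c(word, mism, reverse_complement(word))), ps)
  expect_identical(ev$raw_alt_hits, 2L) # exact + revcomp, not the mismatch
  expect_identical(ev$raw_ref_hits, 0L)
  # N never matches a probe base
  nread <- paste0(substr(word, 1, 10), "N", substr(word, 12, 30))
  expect_identical(scan_reads(make_reads(nread), ps)$raw_alt_hits, 0L)
  # multiple occurrences in one read count once
  ev2 <- scan_reads(make_reads(paste0(word, "ACGT", word)), ps)
  expect_identical(ev2$raw_alt_hits, 1L)
})

test_that("scanning is strand-symmetric and agrees with a naive oracle", {
  set.seed(21)
  loc <- rice_loci()$laba1
  ps <- design_probes(loc, left_flank_ref = 16, left_flank_alt = 16)
  words <- c(ps$ref_forward, ps$ref_revcomp, ps$alt_forward, ps$alt_revcomp)
  seqs <- c(replicate(30, random_seq(60)),
            vapply(1:10, function(i) {
              w <- sample(words, 1)
              paste0(random_seq(sample(0:20, 1)), w, random_seq(sample(0:20, 1)))
            }, character(1)))
  reads <- make_reads(sample(seqs))
  ev <- scan_reads(reads, ps)
  # oracle: per read, any of the four words as exact substring
  n_ref <- sum(vapply(reads$sequence, function(s) {
    oracle_contains(s, ps$ref_forward) || oracle_contains(s, ps$ref_revcomp)
  }, logical(1)))
  n_alt <- sum(vapply(reads$sequence, function(s) {
    oracle_contains(s, ps$alt_forward) || oracle_contains(s, ps$alt_revcomp)
  }, logical(1)))
  expect_identical(ev$raw_ref_hits, n_ref)
  expect_identical(ev$raw_alt_hits, n_alt)
  # strand symmetry
  flipped <- reads
  flipped$sequence <- reverse_complement(reads$sequence)
  ev2 <- scan_reads(flipped, ps)
  expect_identical(ev2$raw_ref_hits, ev$raw_ref_hits)
  expect_identical(ev2$raw_alt_hits, ev$raw_alt_hits)
  # monotonicity: a superset of reads never has fewer hits
  ev_sub <- scan_reads(reads[1:20, ], ps)
  expect_lte(ev_sub$raw_ref_hits, ev$raw_ref_hits)
  expect_lte(ev_sub$raw_alt_hits, ev$raw_alt_hits)
})

test_that("align_pair scores match an independent overlap aligner", {
  expect_identical(align_pair("ACGT", "ACGT")$score, 4)
  expect_identical(length(unlist(align_pair("ACGT", "ACGT")$internal_gap_lengths)), 0L)
  expect_identical(align_pair("ACGT", "ACGA")$score, 2)
  expect_error(align_pair("", "ACGT"), "non-empty")
  set.seed(22)
  for (i in 1:60) {
    a <- random_seq(sample(4:50, 1))
    b <- random_seq(sample(4:50, 1))
    expect_equal(align_pair(a, b)$score, oracle_overlap_score(a, b))
  }
})

test_that("stripping gaps from an alignment recovers the inputs", {
  set.seed(23)
  for (i in 1:15) {
    a <- random_seq(sample(4:40, 1))
    b <- random_seq(sample(4:40, 1))
    al <- align_pair(a, b)
    expect_identical(gsub("-", "", al$aligned_a), a)
    expect_identical(gsub("-", "", al$aligned_b), b)
    expect_identical(nchar(al$aligned_a), nchar(al$aligned_b))
  }
})

test_that("indel length inference recovers the documented deletions", {
  ps <- rice_probe_sets()
  # LABA1 pair: one internal 1 bp gap in the deletion-allele word
  al <- align_pair(ps$laba1$alt_forward, ps$laba1$ref_forward)
  expect_identical(al$internal_gap_lengths$a, 1L)
  expect_identical(length(al$internal_gap_lengths$b), 0L)
  expect_identical(infer_indel_length(ps$laba1$ref_forward,
                                      ps$laba1$alt_forward), 1L)
  expect_identical(infer_indel_length(ps$rc$ref_forward,
                                      ps$rc$alt_forward), 14L)
  expect_identical(infer_indel_length("ACGTACGT", "ACGTACGT"), 0L)
  expect_identical(infer_indel_length("ACGTAAGT", "ACGTACGT"), 0L)
})

test_that("verification assigns reads to the better-aligning allele", {
  loc <- rice_loci()$rc
  ps <- design_probes(loc)
  # error-free read spanning the junction of the deletion allele
  junction <- regexpr("TGCCATCC", loc$alt_allele_seq, fixed = TRUE)
  read_alt <- substr(loc$alt_allele_seq, junction - 40, junction + 34)
  reads <- make_reads(read_alt, ids = "alt1")
  ev <- verify_matches(scan_reads(reads, ps, "acc1"), reads, loc)
  expect_identical(ev$verified_alt_hits, 1L)
  expect_identical(ev$verified_ref_hits, 0L)
  # read equal to the wild-type word: verified ref with a clear margin
  reads <- make_reads(ps$ref_forward, ids = "ref1")
  ev <- verify_matches(scan_reads(reads, ps, "acc2"), reads, loc)
  expect_identical(ev$verified_ref_hits, 1L)
  # under the verification scoring the 14 bp indel costs the wrong allele
  # at least the gap penalty 1 + 13 * 0.5 (doubled integer scale)
  vargs <- list(match = 2L, mismatch = -2L, gap = -2L, gap_extend = -1L)
  a_ref <- do.call(align_pair, c(list(ps$ref_forward, loc$ref_allele_seq), vargs))
  a_alt <- do.call(align_pair, c(list(ps$ref_forward, loc$alt_allele_seq), vargs))
  expect_gte((a_ref$score - a_alt$score) / 2, 1 + 13 * 0.5)
  # missing read id is a consistency error
  ev_raw <- scan_reads(make_reads(ps$ref_forward, ids = "gone"), ps)
  expect_error(verify_matches(ev_raw, make_reads("ACGTACGT"), loc),
               "not in the read set")
})

test_that("a chimeric read matching the alt word is not verified for alt", {
  # toy locus with a 16 bp divergent block of equal length on both alleles
  set.seed(24)
  p <- random_seq(40); q <- random_seq(40)
  ref_div <- "AAAATTTTGGGGCCCC"
  alt_div <- "TGCATGCATGCATGCA"
  loc <- locus("blk", "1", 50, paste0(p, ref_div, q), paste0(p, alt_div, q))
  ps <- design_probes(loc, word_length = 18, left_flank_ref = 1,
                      left_flank_alt = 1)
  # chimera: the alt word followed by the ref divergent block plus flank
  chimera <- paste0(ps$alt_forward, ref_div, substr(q, 1, 30))
  reads <- make_reads(chimera, ids = "chi")
  ev_raw <- scan_reads(reads, ps, "accX")
  expect_identical(ev_raw$raw_alt_hits, 1L)
  # brute-force check that it aligns better to the ref allele
  expect_gt(oracle_overlap_score(chimera, loc$ref_allele_seq),
            oracle_overlap_score(chimera, loc$alt_allele_seq))
  ev <- verify_matches(ev_raw, reads, loc)
  expect_identical(ev$verified_alt_hits, 0L)
  expect_true("chi" %in% ev$dropped_read_ids)
})

test_that("with zero sequencing error verified counts equal raw counts", {
  loc <- rice_loci()$rc
  ps <- design_probes(loc)
  cfg <- sim_config(seed = 5, group_sizes = c(wild = 12L),
                    allele_freqs = data.frame(group = "wild", locus = "Rc",
                                              alt_freq = 0.5),
                    het_rate = 0, error_rate = 0, coverage = c(wild = 4))
  cohort <- simulate_cohort(cfg, loci = list(rc = loc))
  reads_by_acc <- simulate_reads(cohort$truth, loc, cfg)
  for (acc in names(reads_by_acc)) {
    ev <- scan_reads(reads_by_acc[[acc]], ps, acc)
    ev <- verify_matches(ev, reads_by_acc[[acc]], loc)
    expect_identical(ev$verified_ref_hits, ev$raw_ref_hits)
    expect_identical(ev$verified_alt_hits, ev$raw_alt_hits)
  }
})
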