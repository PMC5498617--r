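test_that("SNP matrices round-trip through TSV with missing data", {
  m <- toy_snp_matrix(list(a1 = c("A", "C"), a2 = c(NA, "T")),
                      c("7:2872361", "7:2872911"))
  path <- tempfile(fileext = ".tsv")
  write_snp_matrix(m, path)
  back <- read_snp_matrix(path)
  expect_identical(back$calls, m$calls)
  expect_identical(back$sites, m$sites)
  unlink(path)
})

test_that("matrix ingest validates calls, headers and site order", {
  expect_error(toy_snp_matrix(list(a1 = c("A", "R")), c("1:10", "1:20")),
               "ambiguity")
  expect_error(toy_snp_matrix(list(a1 = c("A", "C")), c("1:10", "1:10")),
               "duplicate site")
  expect_error(toy_snp_matrix(list(a1 = c("A", "C")), c("1:10", "badheader")),
               "chrom:pos")
  expect_error(toy_snp_matrix(list(a1 = c("A", "C")), c("1:10", "1:pos")),
               "unsortable")
  # "7:2872361" parses into chromosome 7, position 2,872,361; sites sorted
  m <- toy_snp_matrix(list(a1 = c("C", "T")), c("7:2872911", "7:2872361"))
  expect_identical(m$sites$chrom, c("7", "7"))
  expect_identical(m$sites$pos, c(2872361, 2872911))
  expect_identical(colnames(m$calls)[1], "7:2872361")
  # N and - are missing
  m2 <- toy_snp_matrix(list(a1 = c("N", "-")), c("1:1", "1:2"))
  expect_true(all(is.na(m2$calls)))
})

japonica_column <- function() {
  # 46 C + 21 A with data, rest of 482 japonica-like accessions missing
  calls <- c(rep("C", 46), rep("A", 21), rep(NA, 415))
  ids <- sprintf("j%04d", seq_along(calls))
  toy_snp_matrix(setNames(as.list(calls), ids), "4:34628688",
                 groups = setNames(rep("japonica", length(ids)), ids))
}

test_that("site frequencies are computed over non-missing calls only", {
  sf <- site_allele_frequencies(japonica_column(), "4:34628688",
                                group = "japonica")
  expect_identical(sf$n_nonmissing, 67L)
  expect_identical(unname(sf$frequencies["C"]), 68.7)
  expect_identical(unname(sf$counts["C"]), 46L)
  # uniform column
  m <- toy_snp_matrix(setNames(as.list(c(rep("C", 127), rep(NA, 100))),
                               sprintf("i%04d", 1:227)), "7:2872361")
  sf <- site_allele_frequencies(m, "7:2872361")
  expect_identical(unname(sf$frequencies["C"]), 100.0)
  expect_false(sf$no_call)
  # all-missing column is NO-CALL, not an error
  m <- toy_snp_matrix(list(a = NA_character_, b = NA_character_), "1:5")
  expect_true(site_allele_frequencies(m, "1:5")$no_call)
  expect_error(site_allele_frequencies(m, "1:999"), "unknown site")
})

test_that("site frequencies ignore accession order and all-missing rows", {
  m <- japonica_column()
  sf <- site_allele_frequencies(m, "4:34628688", group = "japonica")
  shuffled <- m$calls[sample(nrow(m$calls)), , drop = FALSE]
  m2 <- snp_matrix(shuffled, groups = m$groups)
  sf2 <- site_allele_frequencies(m2, "4:34628688", group = "japonica")
  expect_identical(sf$counts, sf2$counts)
  expect_identical(sf$frequencies, sf2$frequencies)
})

test_that("haplotype assignment concatenates calls in caller order", {
  ids <- sprintf("h%02d", 1:5)
  m <- toy_snp_matrix(
    list(h01 = c("C", "A"), h02 = c("C", "C"), h03 = c("T", "C"),
         h04 = c(NA, "C"), h05 = c("C", "A")),
    c("7:2872361", "7:2872911"))
  # prog1 convention: position 2,872,911 first, then 2,872,361
  hap <- assign_haplotypes(m, c("7:2872911", "7:2872361"))
  a <- hap$assignments
  expect_identical(a$haplotype[a$accession_id == "h01"], "AC")
  expect_identical(a$haplotype[a$accession_id == "h03"], "CT")
  expect_true(is.na(a$haplotype[a$accession_id == "h04"]))
  expect_false(a$complete[a$accession_id == "h04"])
  # counts match exhaustive enumeration over complete accessions
  expect_identical(sum(hap$counts$count), 4L)
  expect_identical(hap$counts$count[hap$counts$haplotype == "AC"], 2L)
  expect_identical(hap$counts$count[hap$counts$haplotype == "CC"], 1L)
  expect_error(assign_haplotypes(m, "9:1"), "unknown site")
})

test_that("haplotype counts sum to the complete-call accessions", {
  set.seed(41)
  for (i in 1:5) {
    n <- sample(8:30, 1)
    rows <- lapply(seq_len(n), function(j) {
      v <- sample(c("A", "C", "G", "T", NA), 3, replace = TRUE)
      v
    })
    names(rows) <- sprintf("x%03d", seq_len(n))
    m <- toy_snp_matrix(rows, c("1:10", "1:20", "1:30"))
    hap <- assign_haplotypes(m, c("1:30", "1:10"))
    n_complete <- sum(!is.na(m$calls[, "1:30"]) & !is.na(m$calls[, "1:10"]))
    expect_identical(sum(hap$counts$count), n_complete)
    expect_identical(sum(hap$assignments$complete), n_complete)
  }
})

test_that("parsimony-informative filter matches its definition", {
  aln <- c("AAGT", "AAGA", "CAGT", "CAGA") # cols 1 and 4 informative
  out <- parsimony_informative_sites(aln)
  expect_identical(as.character(out), c("AT", "AA", "CT", "CA"))
  expect_identical(attr(out, "kept_columns"), c(1L, 4L))
  # column 1 {A:2, C:2} retained; column 2 {A:3, C:1} is a singleton variant
  aln <- c("AA", "AA", "CC", "CA")
  out <- parsimony_informative_sites(aln)
  expect_identical(attr(out, "kept_columns"), 1L)
  expect_error(parsimony_informative_sites(c("AA", "AC", "AA")), "4 sequences")
  expect_error(parsimony_informative_sites(c("AAA", "AC", "AAA", "AAA")),
               "unequal")
})

test_that("informative filter agrees with a brute-force oracle, idempotent", {
  set.seed(42)
  for (i in 1:8) {
    aln <- replicate(6, random_seq(20, alphabet = c("A", "C", "G", "-")))
    mat <- do.call(rbind, strsplit(aln, ""))
    keep <- which(apply(mat, 2, oracle_informative))
    out <- parsimony_informative_sites(aln)
    expect_identical(attr(out, "kept_columns"), keep)
    twice <- parsimony_informative_sites(out)
    expect_identical(as.character(twice), as.character(out))
  }
})

test_that("gap recoding collapses shared multi-base runs to single events", {
  aln <- c("AC---GT", "AC---GT", "ACTTAGT", "ACTTCGT")
  out <- recode_gaps(aln)
  expect_identical(as.character(out), c("ACGT1", "ACGT1", "ACGT0", "ACGT0"))
  expect_identical(attr(out, "indel_events"),
                   data.frame(start = 3L, end = 5L))
  # 1 bp gaps are left in place (strictly >1 bp runs are events)
  aln1 <- c("AC-GT", "ACTGT", "ACTGT", "ACAGT")
  out1 <- recode_gaps(aln1)
  expect_identical(as.character(out1), aln1)
  # two disjoint runs (lengths 2 and 4) produce exactly two binary columns:
  # columns 2-3 and 6-9 are dropped, leaving cols 1,4,5,10 plus two events
  aln2 <- c("A--CGTTTTA", "AGGCG----A", "AGGCGTTTTA", "A--CG----A")
  out2 <- recode_gaps(aln2)
  expect_identical(as.character(out2), c("ACGA10", "ACGA01", "ACGA00", "ACGA11"))
  expect_identical(nrow(attr(out2, "indel_events")), 2L)
  # ragged (overlapping, non-identical) runs cannot be recoded
  aln3 <- c("A--CCGT", "AC--CGT", "ACCCCGT", "ACCCCGT")
  expect_error(recode_gaps(aln3), "ambiguous gap recoding")
})
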