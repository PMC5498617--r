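# In-code fixtures and independent oracles shared across test files.

make_reads <- function(seqs, q = 40L, quals = NULL, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(seqs))
  if (is.null(quals)) quals <- strrep(intToUtf8(q + 33L), nchar(seqs))
  data.frame(id = ids, sequence = seqs, quality = quals,
             stringsAsFactors = FALSE)
}

qual_string <- function(scores) intToUtf8(scores + 33L, multiple = FALSE)

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# table-driven reverse-complement oracle, independent of the implementation
oracle_revcomp <- function(s) {
  tab <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(tab[strsplit(s, "")[[1]]])), collapse = "")
}

# naive O(n*m) substring oracle
oracle_contains <- function(text, word) {
  n <- nchar(text); m <- nchar(word)
  if (m > n) return(FALSE)
  any(vapply(seq_len(n - m + 1L),
             function(i) substr(text, i, i + m - 1L) == word, logical(1)))
}

# independent overlap-alignment score via Biostrings (same scoring scheme:
# +1/-1, one point per gap run)
oracle_overlap_score <- function(a, b) {
  Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, type = "overlap",
    substitutionMatrix =
      Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = TRUE),
    gapOpening = 1, gapExtension = 0))
}

# brute-force parsimony-informative test for one column
oracle_informative <- function(col) {
  tab <- table(col)
  sum(tab >= 2L) >= 2L
}

# build a snp_matrix from a list of per-accession call vectors
toy_snp_matrix <- function(rows, sites, groups = NULL) {
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- sites
  snp_matrix(m, groups = groups)
}
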