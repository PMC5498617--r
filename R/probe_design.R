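# Locate the divergent region between the two allele references.
# Longest common prefix / suffix, with the suffix clamped so that prefix and
# suffix never overlap on the shorter allele (a 1 bp indel next to an
# identical base makes the placement ambiguous; clamping fixes it
# deterministically at the leftmost position).
divergent_region <- function(ref, alt) {
  a <- strsplit(ref, "")[[1]]
  b <- strsplit(alt, "")[[1]]
  n <- length(a); m <- length(b); k <- min(n, m)
  lcp <- 0L
  while (lcp < k && a[lcp + 1L] == b[lcp + 1L]) lcp <- lcp + 1L
  lcs <- 0L
  while (lcs < k && a[n - lcs] == b[m - lcs]) lcs <- lcs + 1L
  lcs <- min(lcs, k - lcp)
  list(ref = c(start = lcp + 1L, end = n - lcs),
       alt = c(start = lcp + 1L, end = m - lcs))
}

word_at <- function(seq, div, left_flank, word_length, allele, locus_name) {
  start <- div[["start"]] - left_flank
  end <- start + word_length - 1L
  div_len <- div[["end"]] - div[["start"]] + 1L
  # the word must reach at least one base beyond the divergent region (or,
  # for a zero-length junction, cover both junction-adjacent bases)
  lo <- if (div_len > 0L) div[["start"]] - 1L else div[["start"]] - 1L
  hi <- if (div_len > 0L) div[["end"]] + 1L else div[["start"]]
  if (start < 1L || end > nchar(seq) || start > lo || end < hi) {
    stop("flank too short: a ", word_length, " bp word with left flank ",
         left_flank, " cannot span the discriminating site of the ",
         allele, " allele of locus ", locus_name)
  }
  substr(seq, start, end)
}

word_exclusive <- function(word, other_seq) {
  !grepl(word, other_seq, fixed = TRUE) &&
    !grepl(reverse_complement(word), other_seq, fixed = TRUE)
}

#' Design allele-diagnostic exact-match probe words
#'
#' Cuts one word of `word_length` from each allele reference, spanning the
#' discriminating site (the indel junction, or the variant base for a SNP),
#' and returns the four exact-match words (2 alleles x 2 strands). By
#' default the site is centred in the word; explicit `left_flank_*`
#' arguments (bases retained left of the site) reproduce particular
#' published words. When flanks are left unspecified and the centred word is
#' not allele-exclusive, nearby offsets are tried in order of distance from
#' the centre.
#'
#' @param locus A [locus] object.
#' @param word_length Word length in bp (default 30, as used for the Rc and
#'   LABA1 screens).
#' @param left_flank_ref,left_flank_alt Optional explicit left flanks.
#' @return An object of class `probe_set` with fields `locus_name`,
#'   `word_length`, `ref_forward`, `ref_revcomp`, `alt_forward`,
#'   `alt_revcomp`.
#' @examples
#' ps <- design_probes(rice_loci()$rc)
#' ps$alt_forward # the published deletion-allele word
#' @export
design_probes <- function(locus, word_length = 30L,
                          left_flank_ref = NULL, left_flank_alt = NULL) {
  stopifnot(inherits(locus, "locus"))
  word_length <- as.integer(word_length)
  if (word_length < 3L) stop("word_length must be at least 3")
  div <- divergent_region(locus$ref_allele_seq, locus$alt_allele_seq)
  if (locus$ref_allele_seq == locus$alt_allele_seq) {
    stop("undesignable locus ", locus$name,
         ": identical alleles cannot be discriminated")
  }

  pick <- function(seq, other, d, flank, allele) {
    div_len <- d[["end"]] - d[["start"]] + 1L
    if (!is.null(flank)) {
      w <- word_at(seq, d, as.integer(flank), word_length, allele, locus$name)
      if (!word_exclusive(w, other)) {
        stop("exclusivity violated for the ", allele, " word of locus ",
             locus$name, " at left flank ", flank)
      }
      return(w)
    }
    centre <- max(1L, (word_length - max(div_len, 0L)) %/% 2L)
    lo <- 1L
    hi <- word_length - max(div_len, 1L)
    cand <- unique(pmin(pmax(
      centre + c(0L, as.vector(rbind(seq_len(word_length), -seq_len(word_length)))),
      lo), hi))
    tried <- integer()
    for (f in cand) {
      w <- tryCatch(word_at(seq, d, f, word_length, allele, locus$name),
                    error = function(e) NULL)
      if (is.null(w)) next
      tried <- c(tried, f)
      if (word_exclusive(w, other)) return(w)
    }
    stop("undesignable locus ", locus$name, ": exclusivity violated for the ",
         allele, " allele at every admissible left flank (tried: ",
         toString(tried), ")")
  }

  ref_fwd <- pick(locus$ref_allele_seq, locus$alt_allele_seq, div$ref,
                  left_flank_ref, "ref")
  alt_fwd <- pick(locus$alt_allele_seq, locus$ref_allele_seq, div$alt,
                  left_flank_alt, "alt")
  ps <- structure(
    list(locus_name = locus$name, word_length = word_length,
         ref_forward = ref_fwd, ref_revcomp = reverse_complement(ref_fwd),
         alt_forward = alt_fwd, alt_revcomp = reverse_complement(alt_fwd)),
    class = "probe_set")
  stopifnot(nrow(check_exclusivity(ps, locus)) == 0L)
  ps
}

#' @export
print.probe_set <- function(x, ...) {
  cat("<probe_set>", x$locus_name, " (", x$word_length, " bp words)\n",
      "  ref+ ", x$ref_forward, "\n  ref- ", x$ref_revcomp, "\n",
      "  alt+ ", x$alt_forward, "\n  alt- ", x$alt_revcomp, "\n", sep = "")
  invisible(x)
}

#' Report cross-allele probe-word hits
#'
#' Brute-force substring scan of every word (both strands) against the other
#' allele's local reference. An empty report means the words are
#' allele-diagnostic with respect to the supplied references; genome-wide
#' uniqueness is the user's responsibility (matches are in any case verified
#' by alignment downstream).
#'
#' @param probe_set A `probe_set`.
#' @param locus The [locus] the words were designed on.
#' @return Data frame with columns `word_role`, `strand`, `offending_allele`;
#'   zero rows when exclusivity holds.
#' @export
check_exclusivity <- function(probe_set, locus) {
  stopifnot(inherits(probe_set, "probe_set"), inherits(locus, "locus"))
  words <- list(
    list("ref", "+", probe_set$ref_forward, locus$alt_allele_seq, "alt"),
    list("ref", "-", probe_set$ref_revcomp, locus$alt_allele_seq, "alt"),
    list("alt", "+", probe_set$alt_forward, locus$ref_allele_seq, "ref"),
    list("alt", "-", probe_set$alt_revcomp, locus$ref_allele_seq, "ref"))
  hits <- Filter(function(w) {
    grepl(w[[3]], w[[4]], fixed = TRUE) ||
      grepl(w[[3]], reverse_complement(w[[4]]), fixed = TRUE)
  }, words)
  data.frame(
    word_role = vapply(hits, `[[`, character(1), 1L),
    strand = vapply(hits, `[[`, character(1), 2L),
    offending_allele = vapply(hits, `[[`, character(1), 5L),
    stringsAsFactors = FALSE)
}

#' Serialise probe sets
#'
#' Five-column TSV (`locus`, `role`, `strand`, `word`, `word_length`) or
#' FASTA export for interoperability with external screening tools.
#'
#' @param probe_sets A `probe_set` or list of them.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_probes_tsv <- function(probe_sets, path) {
  if (inherits(probe_sets, "probe_set")) probe_sets <- list(probe_sets)
  rows <- do.call(rbind, lapply(probe_sets, function(ps) {
    data.frame(
      locus = ps$locus_name,
      role = c("ref", "ref", "alt", "alt"),
      strand = c("+", "-", "+", "-"),
      word = c(ps$ref_forward, ps$ref_revcomp, ps$alt_forward, ps$alt_revcomp),
      word_length = ps$word_length, stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probes_tsv
#' @export
read_probes_tsv <- function(path) {
  tab <- read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  need <- c("locus", "role", "strand", "word", "word_length")
  if (!all(need %in% names(tab))) {
    stop("probe TSV must have columns: ", toString(need))
  }
  lapply(split(tab, tab$locus), function(d) {
    get1 <- function(role, strand) d$word[d$role == role & d$strand == strand]
    structure(
      list(locus_name = d$locus[1], word_length = d$word_length[1],
           ref_forward = get1("ref", "+"), ref_revcomp = get1("ref", "-"),
           alt_forward = get1("alt", "+"), alt_revcomp = get1("alt", "-")),
      class = "probe_set")
  })
}

#' @rdname write_probes_tsv
#' @export
write_probes_fasta <- function(probe_sets, path) {
  if (inherits(probe_sets, "probe_set")) probe_sets <- list(probe_sets)
  seqs <- unlist(lapply(probe_sets, function(ps) {
    setNames(c(ps$ref_forward, ps$ref_revcomp, ps$alt_forward, ps$alt_revcomp),
             paste0(ps$locus_name, "_", c("ref_fwd", "ref_rev",
                                          "alt_fwd", "alt_rev")))
  }))
  write_fasta(seqs, path)
}
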