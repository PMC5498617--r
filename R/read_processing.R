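#' Sliding-window quality trimming
#'
#' Scans each read from the 5' end with a sliding window of `window` bases;
#' at the first window whose mean Phred quality falls below
#' `min_mean_quality` the read is truncated at that window's start position
#' (i.e. bases up to and including the window start are kept). Reads shorter
#' than `min_length` after trimming are dropped. Quality strings are trimmed
#' in step with the sequence.
#'
#' @param reads Data frame of reads (see [read_fastq()]).
#' @param window Window width in bases (>= 1).
#' @param min_mean_quality Mean-quality threshold.
#' @param min_length Minimum retained read length.
#' @param quality_offset Phred encoding offset (33 or 64).
#' @return Data frame of trimmed reads.
#' @export
trim_reads <- function(reads, window = 4L, min_mean_quality = 15,
                       min_length = 30L, quality_offset = 33L) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("window must be >= 1")
  if (nrow(reads) == 0L) return(reads)
  keep_len <- vapply(reads$quality, function(qstr) {
    q <- utf8ToInt(qstr) - as.integer(quality_offset)
    L <- length(q)
    if (L < window) return(L)
    means <- (cumsum(q)[window:L] -
                c(0, cumsum(q)[seq_len(L - window)])) / window
    fail <- which(means < min_mean_quality)
    if (length(fail) == 0L) L else fail[1]
  }, integer(1), USE.NAMES = FALSE)
  out <- reads
  out$sequence <- substr(reads$sequence, 1L, keep_len)
  out$quality <- substr(reads$quality, 1L, keep_len)
  out <- out[nchar(out$sequence) >= min_length, , drop = FALSE]
  rownames(out) <- NULL
  out
}

new_match_evidence <- function(accession_id, locus_name) {
  structure(
    list(accession_id = accession_id, locus_name = locus_name,
         raw_ref_hits = 0L, raw_alt_hits = 0L,
         verified_ref_hits = NA_integer_, verified_alt_hits = NA_integer_,
         ref_read_ids = character(), alt_read_ids = character(),
         ambiguous_read_ids = character(),
         verified_ref_read_ids = character(),
         verified_alt_read_ids = character(),
         dropped_read_ids = character(),
         n_reads_scanned = 0L),
    class = "match_evidence")
}

#' Scan reads for perfect probe-word matches
#'
#' A read counts for an allele when the allele's forward word or its reverse
#' complement occurs in the read as an exact substring (grep-style perfect
#' match: one substituted base means no hit, and `N` never matches a probe
#' base). Multiple occurrences within one read count once. A read matching
#' words of both alleles is recorded in each raw count but routed to the
#' ambiguous set for alignment verification instead of being attributed to
#' either allele.
#'
#' @param reads Data frame of reads.
#' @param probe_set A `probe_set` from [design_probes()].
#' @param accession_id Accession the reads belong to.
#' @return An object of class `match_evidence` with raw counts and matching
#'   read ids; verified counts stay `NA` until [verify_matches()].
#' @export
scan_reads <- function(reads, probe_set, accession_id = "unknown") {
  stopifnot(inherits(probe_set, "probe_set"))
  ev <- new_match_evidence(accession_id, probe_set$locus_name)
  ev$n_reads_scanned <- nrow(reads)
  if (nrow(reads) == 0L) return(ev)
  s <- reads$sequence
  ref_hit <- grepl(probe_set$ref_forward, s, fixed = TRUE) |
    grepl(probe_set$ref_revcomp, s, fixed = TRUE)
  alt_hit <- grepl(probe_set$alt_forward, s, fixed = TRUE) |
    grepl(probe_set$alt_revcomp, s, fixed = TRUE)
  ev$raw_ref_hits <- sum(ref_hit)
  ev$raw_alt_hits <- sum(alt_hit)
  ev$ref_read_ids <- reads$id[ref_hit & !alt_hit]
  ev$alt_read_ids <- reads$id[alt_hit & !ref_hit]
  ev$ambiguous_read_ids <- reads$id[ref_hit & alt_hit]
  ev
}

#' @export
print.match_evidence <- function(x, ...) {
  cat("<match_evidence> ", x$accession_id, " @ ", x$locus_name,
      ": raw ref/alt ", x$raw_ref_hits, "/", x$raw_alt_hits,
      ", verified ", x$verified_ref_hits, "/", x$verified_alt_hits,
      " (", x$n_reads_scanned, " reads scanned)\n", sep = "")
  invisible(x)
}

#' Verify probe matches by alignment to both allele references
#'
#' Each candidate read (raw probe hit) is aligned with free end gaps to both
#' allele references, scoring match +1, mismatch -1, gap open -1 and -0.5
#' per additional gap base (run internally at doubled integer scale). The
#' affine extension term matters here: against a full-length reference a
#' run-cost-only scheme would chain cheap gaps between coincidental motif
#' matches and flatten the score difference between alleles. The read is
#' verified for the higher-scoring allele iff the identity fraction over the
#' aligned region is at least `min_identity` and the score margin (in match
#' units) over the other allele is at least `min_margin`;
#' reads with a smaller margin, or whose winning allele is not one they
#' matched a probe word for, are discarded and recorded in
#' `dropped_read_ids`. After verification a read id is attributed to at most
#' one allele.
#'
#' @param evidence A `match_evidence` from [scan_reads()].
#' @param reads The read set the evidence refers to.
#' @param locus The [locus] with both allele references.
#' @param min_identity Minimum identity fraction for the winning alignment.
#' @param min_margin Minimum score margin between the two alignments.
#' @return The `match_evidence` with verified counts and id sets filled in.
#' @export
verify_matches <- function(evidence, reads, locus,
                           min_identity = 0.9, min_margin = 1) {
  stopifnot(inherits(evidence, "match_evidence"), inherits(locus, "locus"))
  cand <- c(evidence$ref_read_ids, evidence$alt_read_ids,
            evidence$ambiguous_read_ids)
  missing <- setdiff(cand, reads$id)
  if (length(missing)) {
    stop("read id(s) in evidence but not in the read set: ",
         toString(utils::head(missing, 3)))
  }
  eligible <- c(setNames(rep("ref", length(evidence$ref_read_ids)),
                         evidence$ref_read_ids),
                setNames(rep("alt", length(evidence$alt_read_ids)),
                         evidence$alt_read_ids),
                setNames(rep("both", length(evidence$ambiguous_read_ids)),
                         evidence$ambiguous_read_ids))
  ver_ref <- character(); ver_alt <- character(); dropped <- character()
  best_orient <- function(seq, ref) {
    # reads are unstranded: align both orientations, keep the better
    fwd <- align_pair(seq, ref, match = 2L, mismatch = -2L, gap = -2L,
                      gap_extend = -1L)
    rev <- align_pair(reverse_complement(seq), ref, match = 2L,
                      mismatch = -2L, gap = -2L, gap_extend = -1L)
    if (fwd$score >= rev$score) fwd else rev
  }
  for (id in cand) {
    seq <- reads$sequence[match(id, reads$id)]
    a_ref <- best_orient(seq, locus$ref_allele_seq)
    a_alt <- best_orient(seq, locus$alt_allele_seq)
    margin <- abs(a_ref$score - a_alt$score) / 2
    winner <- if (a_ref$score >= a_alt$score) "ref" else "alt"
    ident <- if (winner == "ref") a_ref$identity_fraction else
      a_alt$identity_fraction
    ok <- margin >= min_margin && ident >= min_identity &&
      eligible[[id]] %in% c(winner, "both")
    if (!ok) dropped <- c(dropped, id)
    else if (winner == "ref") ver_ref <- c(ver_ref, id)
    else ver_alt <- c(ver_alt, id)
  }
  evidence$verified_ref_hits <- length(ver_ref)
  evidence$verified_alt_hits <- length(ver_alt)
  evidence$verified_ref_read_ids <- ver_ref
  evidence$verified_alt_read_ids <- ver_alt
  evidence$dropped_read_ids <- dropped
  evidence
}

#' Flatten match evidence into a table
#'
#' @param evidence A `match_evidence` or list of them.
#' @return Data frame with one row per (accession, locus).
#' @export
evidence_table <- function(evidence) {
  if (inherits(evidence, "match_evidence")) evidence <- list(evidence)
  do.call(rbind, lapply(evidence, function(e) {
    data.frame(accession_id = e$accession_id, locus = e$locus_name,
               raw_ref = e$raw_ref_hits, raw_alt = e$raw_alt_hits,
               verified_ref = e$verified_ref_hits,
               verified_alt = e$verified_alt_hits,
               n_reads_scanned = e$n_reads_scanned,
               stringsAsFactors = FALSE)
  }))
}

#' @rdname evidence_table
#' @param path Output TSV path.
#' @export
write_evidence_tsv <- function(evidence, path) {
  write.table(evidence_table(evidence), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname evidence_table
#' @export
read_evidence_tsv <- function(path) {
  read.delim(path, sep = "\t", comment.char = "#", stringsAsFactors = FALSE)
}
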