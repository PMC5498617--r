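#' Classify an accession at a locus from verified evidence
#'
#' A single verified read suffices by default (`min_reads = 1`): `ALT_ONLY`
#' when only deletion-allele reads were verified, `REF_ONLY` symmetric,
#' `HET` when both alleles reach `min_reads` (an accession with reads
#' matching both alleles), `NO_DATA` otherwise.
#'
#' @param evidence A `match_evidence` with verified counts, or anything with
#'   `verified_ref_hits`/`verified_alt_hits` fields.
#' @param min_reads Minimum verified reads per allele.
#' @return One-row data frame: `accession_id`, `locus`, `call`,
#'   `verified_ref`, `verified_alt`.
#' @export
classify_accession <- function(evidence, min_reads = 1L) {
  vr <- evidence$verified_ref_hits
  va <- evidence$verified_alt_hits
  if (is.na(vr) || is.na(va)) {
    stop("verified counts missing; run verify_matches() first")
  }
  if (vr < 0 || va < 0) stop("negative verified counts")
  call <- if (vr >= min_reads && va >= min_reads) "HET"
  else if (va >= min_reads && vr == 0) "ALT_ONLY"
  else if (vr >= min_reads && va == 0) "REF_ONLY"
  else "NO_DATA"
  data.frame(accession_id = evidence$accession_id,
             locus = evidence$locus_name, call = call,
             verified_ref = vr, verified_alt = va, stringsAsFactors = FALSE)
}

#' @rdname classify_accession
#' @param evidence_df Evidence table ([evidence_table()]) with columns
#'   `accession_id`, `locus`, `verified_ref`, `verified_alt`.
#' @return `classify_calls()`: data frame of calls, one row per
#'   (accession, locus).
#' @export
classify_calls <- function(evidence_df, min_reads = 1L) {
  vr <- evidence_df$verified_ref
  va <- evidence_df$verified_alt
  if (any(is.na(vr) | is.na(va))) stop("verified counts missing")
  if (any(vr < 0 | va < 0)) stop("negative verified counts")
  call <- rep("NO_DATA", nrow(evidence_df))
  call[vr >= min_reads & va == 0] <- "REF_ONLY"
  call[va >= min_reads & vr == 0] <- "ALT_ONLY"
  call[vr >= min_reads & va >= min_reads] <- "HET"
  data.frame(accession_id = evidence_df$accession_id,
             locus = evidence_df$locus, call = call,
             verified_ref = vr, verified_alt = va, stringsAsFactors = FALSE)
}

#' Heterozygote-aware group allele table
#'
#' Reproduces the summary-table convention for accession-level indel
#' screens: the denominator is the number of distinct informative accessions
#' (any verified read at the locus), and a heterozygote is counted as a
#' carrier of *both* alleles, so `n_ref_carriers + n_alt_carriers - n_het ==
#' n_informative` and the two percentages sum to at least 100. Percentages
#' are rounded half-up to one decimal, matching printed tables.
#'
#' @param calls Calls data frame from [classify_calls()].
#' @param metadata Accession metadata ([read_metadata_tsv()]); every called
#'   accession must be present.
#' @return Data frame per (group, locus): `n_ref_carriers`,
#'   `n_alt_carriers`, `n_het`, `n_informative`, `pct_ref`, `pct_alt`.
#' @examples
#' calls <- data.frame(
#'   accession_id = sprintf("a%03d", 1:228), locus = "Rc",
#'   call = rep(c("ALT_ONLY", "HET", "REF_ONLY"), c(61, 4, 163)))
#' meta <- data.frame(accession_id = calls$accession_id, group = "indica")
#' tabulate_groups(calls, meta) # 28.5% alt, 73.2% ref
#' @export
tabulate_groups <- function(calls, metadata) {
  idx <- match(calls$accession_id, metadata$accession_id)
  if (anyNA(idx)) {
    stop("accession with a call but no metadata group: ",
         calls$accession_id[which(is.na(idx))[1]])
  }
  grp <- metadata$group[idx]
  key <- split(seq_len(nrow(calls)), list(grp, calls$locus), drop = TRUE)
  rows <- lapply(names(key), function(k) {
    i <- key[[k]]
    cc <- calls$call[i]
    n_het <- sum(cc == "HET")
    n_alt <- sum(cc == "ALT_ONLY") + n_het
    n_ref <- sum(cc == "REF_ONLY") + n_het
    n_inf <- sum(cc != "NO_DATA")
    data.frame(group = grp[i][1], locus = calls$locus[i][1],
               n_ref_carriers = n_ref, n_alt_carriers = n_alt,
               n_het = n_het, n_informative = n_inf,
               pct_ref = if (n_inf > 0) round_half_up(100 * n_ref / n_inf) else NA_real_,
               pct_alt = if (n_inf > 0) round_half_up(100 * n_alt / n_inf) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$locus, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Carrier percentage over a caller-supplied denominator
#'
#' The companion to [tabulate_groups()] for prose-style figures where the
#' denominator is quoted directly (e.g. carriers over all accessions with
#' any match, heterozygotes included once). Rounded half-up to one decimal.
#'
#' @param n_carriers,denominator Non-negative counts.
#' @return Percentage, one decimal.
#' @examples
#' carrier_percentage(33, 255) # 12.9
#' carrier_percentage(33, 250) # 13.2
#' @export
carrier_percentage <- function(n_carriers, denominator) {
  if (denominator <= 0) stop("denominator must be positive")
  round_half_up(100 * n_carriers / denominator)
}

#' @rdname tabulate_groups
#' @param table Group allele table.
#' @param path Output TSV path.
#' @export
write_group_table_tsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
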