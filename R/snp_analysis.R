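#' Construct a SNP matrix
#'
#' Accessions x sites call table over `{A,C,G,T}` with `NA` for missing.
#' Column names are `"chrom:pos"` (1-based positions); columns are sorted by
#' chromosome then position and must be unique. Heterozygous/IUPAC ambiguity
#' codes are rejected outright: the source matrices this emulates are
#' haploid-coded, and silent reinterpretation would corrupt frequencies.
#'
#' @param calls Character matrix (rownames = accession ids, colnames =
#'   `"chrom:pos"`), `NA`, `"N"` or `"-"` meaning missing.
#' @param groups Optional named character vector mapping accession id to
#'   group/class label.
#' @return An object of class `snp_matrix` with fields `calls`, `sites`
#'   (data frame `chrom`, `pos`), `groups`.
#' @export
snp_matrix <- function(calls, groups = NULL) {
  if (!is.matrix(calls)) stop("calls must be a matrix")
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    stop("calls must have accession rownames and 'chrom:pos' colnames")
  }
  calls[calls %in% c("N", "-", "")] <- NA_character_
  bad <- !is.na(calls) & !(calls %in% c("A", "C", "G", "T"))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop("invalid call ", sQuote(calls[bad][1]), " (accession ",
         rownames(calls)[w[1]], ", site ", colnames(calls)[w[2]],
         "); heterozygous/ambiguity codes are not supported")
  }
  if (anyDuplicated(colnames(calls))) {
    stop("duplicate site column: ",
         colnames(calls)[duplicated(colnames(calls))][1])
  }
  parts <- strsplit(colnames(calls), ":", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("site columns must be 'chrom:pos', got ",
         sQuote(colnames(calls)[lengths(parts) != 2L][1]))
  }
  chrom <- vapply(parts, `[`, character(1), 1L)
  pos <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2L)))
  if (anyNA(pos)) {
    stop("unsortable position in site column ",
         sQuote(colnames(calls)[is.na(pos)][1]))
  }
  ord <- order(chrom, pos)
  structure(
    list(calls = calls[, ord, drop = FALSE],
         sites = data.frame(chrom = chrom[ord], pos = pos[ord],
                            stringsAsFactors = FALSE),
         groups = groups),
    class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat("<snp_matrix> ", nrow(x$calls), " accessions x ", ncol(x$calls),
      " sites (", sum(is.na(x$calls)), " missing calls)\n", sep = "")
  invisible(x)
}

#' Read and write SNP matrices
#'
#' TSV with first column `accession_id` and remaining columns `"chrom:pos"`;
#' cells in `{A,C,G,T,N,-}` where `N`/`-` mean missing. Lines starting with
#' `#` are skipped. Optional metadata attaches group labels.
#'
#' @param path TSV path.
#' @param metadata Optional metadata data frame with `accession_id`, `group`.
#' @return A `snp_matrix`.
#' @export
read_snp_matrix <- function(path, metadata = NULL) {
  tab <- read.delim(path, sep = "\t", comment.char = "#", check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  if (names(tab)[1] != "accession_id") {
    stop("first column must be 'accession_id', got ", sQuote(names(tab)[1]))
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$accession_id
  groups <- NULL
  if (!is.null(metadata)) {
    groups <- setNames(metadata$group, metadata$accession_id)[tab$accession_id]
    names(groups) <- tab$accession_id
  }
  snp_matrix(m, groups = groups)
}

#' @rdname read_snp_matrix
#' @param matrix A `snp_matrix`.
#' @export
write_snp_matrix <- function(matrix, path) {
  m <- matrix$calls
  m[is.na(m)] <- "N"
  df <- data.frame(accession_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

site_key <- function(site) {
  if (length(site) == 2L) paste0(site[1], ":", as.numeric(site[2])) else site
}

resolve_accessions <- function(matrix, group = NULL, accessions = NULL) {
  ids <- rownames(matrix$calls)
  if (!is.null(accessions)) {
    missing <- setdiff(accessions, ids)
    if (length(missing)) {
      stop("unknown accession(s): ", toString(utils::head(missing, 3)))
    }
    return(accessions)
  }
  if (is.null(group)) return(ids)
  if (is.null(matrix$groups)) stop("matrix has no group labels attached")
  sel <- ids[!is.na(matrix$groups[ids]) & matrix$groups[ids] == group]
  if (length(sel) == 0L) stop("unknown or empty group: ", group)
  sel
}

#' Per-site per-group allele frequencies
#'
#' Base counts and percentages over non-missing calls only, rounded half-up
#' to one decimal. An all-missing column gives a NO-CALL result (flag, not
#' an error).
#'
#' @param matrix A `snp_matrix`.
#' @param site `"chrom:pos"` string or `c(chrom, pos)`.
#' @param group Group label (requires group labels on the matrix).
#' @param accessions Alternatively, an explicit accession id subset.
#' @return List of class `site_freq_summary`: `site`, `group`, `counts`
#'   (named, non-missing only), `n_nonmissing`, `frequencies` (percent,
#'   one decimal), `no_call`.
#' @export
site_allele_frequencies <- function(matrix, site, group = NULL,
                                    accessions = NULL) {
  stopifnot(inherits(matrix, "snp_matrix"))
  key <- site_key(site)
  if (!(key %in% colnames(matrix$calls))) stop("unknown site: ", key)
  ids <- resolve_accessions(matrix, group, accessions)
  calls <- matrix$calls[ids, key]
  calls <- calls[!is.na(calls)]
  counts <- table(calls)
  n <- length(calls)
  structure(
    list(site = key, group = if (is.null(group)) "all" else group,
         counts = setNames(as.integer(counts), names(counts)),
         n_nonmissing = n,
         frequencies = if (n > 0)
           setNames(round_half_up(100 * as.integer(counts) / n),
                    names(counts)) else numeric(),
         no_call = n == 0L),
    class = "site_freq_summary")
}

#' @export
print.site_freq_summary <- function(x, ...) {
  if (x$no_call) {
    cat("<site_freq_summary>", x$site, x$group, ": NO-CALL (all missing)\n")
  } else {
    cat("<site_freq_summary> ", x$site, " ", x$group, " (n=",
        x$n_nonmissing, "): ",
        paste0(names(x$frequencies), " ", x$frequencies, "%",
               collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Diagnostic-SNP haplotype assignment
#'
#' Concatenates each accession's calls at the listed sites, in caller order
#' (for the *prog1* pair the convention is position 2,872,911 first, then
#' 2,872,361, which makes the published names TC/CC/CA read off directly).
#' Accessions with any missing call at the listed sites are `INCOMPLETE` and
#' excluded from the counts.
#'
#' @param matrix A `snp_matrix`.
#' @param sites Ordered list/vector of sites (`"chrom:pos"` strings).
#' @param group Optional group label; `accessions` as an alternative subset.
#' @param accessions Explicit accession ids.
#' @return List: `assignments` (data frame `accession_id`, `haplotype`,
#'   `complete`) and `counts` (data frame `haplotype`, `count`,
#'   `frequency_pct` over complete accessions).
#' @export
assign_haplotypes <- function(matrix, sites, group = NULL, accessions = NULL) {
  stopifnot(inherits(matrix, "snp_matrix"), length(sites) >= 1L)
  keys <- vapply(sites, site_key, character(1))
  unknown <- setdiff(keys, colnames(matrix$calls))
  if (length(unknown)) stop("unknown site: ", unknown[1])
  ids <- resolve_accessions(matrix, group, accessions)
  sub <- matrix$calls[ids, keys, drop = FALSE]
  complete <- rowSums(is.na(sub)) == 0L
  hap <- ifelse(complete, apply(sub, 1L, paste, collapse = ""), NA_character_)
  counts <- sort(table(hap[complete]), decreasing = TRUE)
  n <- sum(complete)
  list(
    assignments = data.frame(accession_id = ids, haplotype = unname(hap),
                             complete = unname(complete),
                             stringsAsFactors = FALSE),
    counts = data.frame(
      haplotype = names(counts), count = as.integer(counts),
      frequency_pct = if (n > 0) round_half_up(100 * as.integer(counts) / n)
                      else numeric(),
      stringsAsFactors = FALSE))
}

as_alignment_matrix <- function(alignment) {
  if (is.matrix(alignment)) return(alignment)
  if (!is.character(alignment)) stop("alignment must be character or matrix")
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L) {
    stop("alignment sequences have unequal lengths: ",
         toString(unique(lens)))
  }
  do.call(rbind, strsplit(toupper(alignment), ""))
}

alignment_from_matrix <- function(mat, template) {
  if (is.matrix(template)) return(mat)
  out <- apply(mat, 1L, paste, collapse = "")
  names(out) <- names(template)
  out
}

#' Filter an alignment to its parsimony-informative columns
#'
#' Retains exactly the columns with at least two distinct states each
#' present in at least two sequences (the standard definition; the gap
#' character counts as a state here — recode multi-base gap runs first with
#' [recode_gaps()] if they should be single events). Idempotent.
#'
#' @param alignment Character vector of equal-length sequences (or a
#'   character matrix, one column per site); at least 4 sequences.
#' @return Filtered alignment of the same type, with the retained column
#'   indices in attribute `kept_columns`.
#' @export
parsimony_informative_sites <- function(alignment) {
  mat <- as_alignment_matrix(alignment)
  if (nrow(mat) < 4L) {
    stop("at least 4 sequences are required (no column can be ",
         "parsimony-informative otherwise)")
  }
  keep <- which(apply(mat, 2L, function(col) {
    tab <- table(col)
    sum(tab >= 2L) >= 2L
  }))
  out <- alignment_from_matrix(mat[, keep, drop = FALSE], alignment)
  attr(out, "kept_columns") <- unname(keep)
  out
}

gap_runs_of <- function(row) {
  r <- rle(row == "-")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Recode multi-base gap runs as single presence/absence characters
#'
#' Each maximal gap run of length > 1 (same start and end across the
#' sequences that carry it) is treated as one mutational event: its columns
#' are dropped and a single binary column (`"1"` gap present / `"0"`
#' absent) is appended, in order of run start. 1 bp gaps are left in place.
#' Runs that overlap but do not share identical boundaries are ambiguous to
#' recode and raise an error listing them.
#'
#' @param alignment Character vector of equal-length sequences or character
#'   matrix, with `-` as the gap character.
#' @return Recoded alignment of the same type; attributes `dropped_columns`
#'   and `indel_events` (data frame `start`, `end`) describe the recoding.
#' @export
recode_gaps <- function(alignment) {
  mat <- as_alignment_matrix(alignment)
  runs <- unique(do.call(rbind, lapply(seq_len(nrow(mat)), function(i) {
    r <- gap_runs_of(mat[i, ])
    r[r[, "end"] - r[, "start"] + 1L > 1L, , drop = FALSE]
  })))
  if (is.null(runs) || nrow(runs) == 0L) {
    attr(alignment, "dropped_columns") <- integer()
    attr(alignment, "indel_events") <-
      data.frame(start = integer(), end = integer())
    return(alignment)
  }
  runs <- runs[order(runs[, "start"], runs[, "end"]), , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in seq_len(nrow(runs) - 1L)) {
      for (j in (i + 1L):nrow(runs)) {
        if (runs[j, "start"] <= runs[i, "end"] &&
            !all(runs[i, ] == runs[j, ])) {
          stop("ambiguous gap recoding: runs [", runs[i, "start"], "-",
               runs[i, "end"], "] and [", runs[j, "start"], "-",
               runs[j, "end"], "] overlap with different boundaries")
        }
      }
    }
  }
  drop_cols <- unlist(lapply(seq_len(nrow(runs)),
                             function(i) runs[i, "start"]:runs[i, "end"]))
  new_cols <- vapply(seq_len(nrow(runs)), function(i) {
    apply(mat[, runs[i, "start"]:runs[i, "end"], drop = FALSE], 1L,
          function(row) if (all(row == "-")) "1" else "0")
  }, character(nrow(mat)))
  if (is.null(dim(new_cols))) new_cols <- matrix(new_cols, nrow = nrow(mat))
  out_mat <- cbind(mat[, -drop_cols, drop = FALSE], new_cols)
  colnames(out_mat) <- NULL
  out <- alignment_from_matrix(out_mat, alignment)
  attr(out, "dropped_columns") <- sort(unique(drop_cols))
  attr(out, "indel_events") <- data.frame(start = unname(runs[, "start"]),
                                          end = unname(runs[, "end"]),
                                          row.names = NULL)
  out
}
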