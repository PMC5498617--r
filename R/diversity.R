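#' Missing-data-weighted polymorphism density in a window
#'
#' The diversity statistic computed here is `D = S / (n * c)` where `S` is
#' the number of polymorphic sites (>= 2 distinct non-missing calls,
#' singletons included) within the window among the chosen accession class,
#' `n` the number of class accessions, and `c` the mean per-accession
#' proportion of non-missing calls over the window sites. With complete
#' data `D = S/n` exactly; halving the call rate doubles `D`. This is the
#' package's single, fixed operationalisation of "polymorphic sites per
#' examined accession, weighted by the proportion of non-missing data";
#' per-site weighting and pairwise-difference statistics are deliberately
#' not implemented.
#'
#' The window is centred: `[position - window_bp/2, position + window_bp/2
#' - 1]`, 1-based inclusive. A window reaching below position 1 is clipped
#' and flagged `truncated`.
#'
#' @param matrix A `snp_matrix`.
#' @param focal `c(chrom, pos)` or `"chrom:pos"` of the causative mutation.
#' @param window_bp Window width in bp (default 10000).
#' @param accessions Accession ids of the allele class; alternatively
#'   `group` (a label in the matrix's group vector).
#' @param group Optional group/class label.
#' @param class_label Free-text label stored in the result.
#' @param locus_name Free-text locus label stored in the result.
#' @return Object of class `diversity_result`: `locus`, `class_label`,
#'   `chrom`, `window_start`, `window_end`, `S`, `n`, `mean_callrate`, `D`,
#'   `undefined`, `truncated`. `undefined` is `TRUE` (and `D` is `NA`) when
#'   the class is empty, there are no window sites, or the call rate is 0.
#' @export
window_diversity <- function(matrix, focal, window_bp = 10000L,
                             accessions = NULL, group = NULL,
                             class_label = NULL, locus_name = NA_character_) {
  stopifnot(inherits(matrix, "snp_matrix"))
  if (is.character(focal) && length(focal) == 1L) {
    focal <- strsplit(focal, ":", fixed = TRUE)[[1]]
  }
  chrom <- as.character(focal[1])
  pos <- as.numeric(focal[2])
  if (!(chrom %in% matrix$sites$chrom)) {
    stop("chromosome ", chrom, " not present in the matrix")
  }
  half <- floor(window_bp / 2)
  start <- pos - half
  end <- pos + half - 1
  truncated <- start < 1
  start <- max(1, start)

  ids <- if (is.null(accessions) && is.null(group)) character() else
    resolve_accessions(matrix, group, accessions)
  if (is.null(class_label)) {
    class_label <- if (!is.null(group)) group else "custom"
  }

  in_win <- matrix$sites$chrom == chrom &
    matrix$sites$pos >= start & matrix$sites$pos <= end
  res <- structure(
    list(locus = locus_name, class_label = class_label, chrom = chrom,
         window_start = start, window_end = end,
         S = 0L, n = length(ids), mean_callrate = NA_real_, D = NA_real_,
         undefined = TRUE, truncated = truncated),
    class = "diversity_result")
  if (length(ids) == 0L || !any(in_win)) return(res)

  sub <- matrix$calls[ids, in_win, drop = FALSE]
  res$S <- sum(apply(sub, 2L, function(col) {
    length(unique(col[!is.na(col)])) >= 2L
  }))
  res$mean_callrate <- mean(rowMeans(!is.na(sub)))
  if (res$mean_callrate > 0) {
    res$D <- res$S / (res$n * res$mean_callrate)
    res$undefined <- FALSE
  }
  res
}

#' @export
print.diversity_result <- function(x, ...) {
  cat("<diversity_result> ", x$class_label, " @ chr", x$chrom, ":",
      x$window_start, "-", x$window_end,
      if (x$truncated) " (truncated)", "\n  S = ", x$S, ", n = ", x$n,
      ", mean call rate = ",
      if (is.na(x$mean_callrate)) "NA" else sprintf("%.3f", x$mean_callrate),
      ", D = ", if (x$undefined) "undefined" else sprintf("%.3g", x$D),
      "\n", sep = "")
  invisible(x)
}

#' Flatten diversity results to a table
#'
#' @param results A `diversity_result` or list of them.
#' @return Data frame, one row per result.
#' @export
diversity_table <- function(results) {
  if (inherits(results, "diversity_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    data.frame(locus = r$locus, class = r$class_label, S = r$S, n = r$n,
               mean_callrate = r$mean_callrate, D = r$D,
               window_start = r$window_start, window_end = r$window_end,
               truncated = r$truncated, stringsAsFactors = FALSE)
  }))
}

#' @rdname diversity_table
#' @param path Output TSV path.
#' @export
write_diversity_tsv <- function(results, path) {
  write.table(diversity_table(results), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
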