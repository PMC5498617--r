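#' Closed vocabulary of rice accession groups
#'
#' Group labels follow the usual population-structure split of Asian rice:
#' the wild progenitor *Oryza rufipogon* plus the cultivated groups
#' *indica*, tropical and temperate *japonica*, *aus* and *aromatic*.
#'
#' @return Character vector of admissible group labels.
#' @export
rice_groups <- function() {
  c("wild", "indica", "japonica_tropical", "japonica_temperate",
    "aus", "aromatic", "other")
}

validate_dna <- function(seq, allow_n = FALSE, what = "sequence") {
  if (!is.character(seq)) stop(what, " must be a character vector")
  seq <- toupper(seq)
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, seq)
  if (any(bad)) {
    stop("invalid ", what, ": characters outside {A,C,G,T",
         if (allow_n) ",N", "} in ", sQuote(substr(seq[bad][1], 1, 40)))
  }
  seq
}

#' Define a locus with two local allele references
#'
#' A locus bundles the two local reference sequences (wild-type and derived
#' allele) around a causative variant, e.g. the 14 bp deletion in the *Rc*
#' coding sequence or the 1 bp deletion in *LABA1*. The indel length is the
#' length difference between the two allele references (0 for a SNP).
#'
#' @param name Short locus label, e.g. `"Rc"`.
#' @param chromosome Chromosome label.
#' @param causative_position 1-based genomic coordinate of the causative
#'   variant.
#' @param ref_allele_seq,alt_allele_seq DNA strings over `{A,C,G,T}`: local
#'   references for the wild-type and derived allele respectively.
#' @return An object of class `locus`.
#' @examples
#' snp <- locus("toy", "1", 100, "ACGTA", "ACTTA")
#' snp$indel_length # 0
#' @export
locus <- function(name, chromosome, causative_position,
                  ref_allele_seq, alt_allele_seq) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  ref_allele_seq <- validate_dna(ref_allele_seq, what = "ref_allele_seq")
  alt_allele_seq <- validate_dna(alt_allele_seq, what = "alt_allele_seq")
  if (!nzchar(ref_allele_seq) || !nzchar(alt_allele_seq)) {
    stop("allele sequences must be non-empty")
  }
  causative_position <- as.numeric(causative_position)
  if (length(causative_position) != 1L || causative_position < 1) {
    stop("causative_position must be a single 1-based coordinate")
  }
  structure(
    list(name = name,
         chromosome = as.character(chromosome),
         causative_position = causative_position,
         ref_allele_seq = ref_allele_seq,
         alt_allele_seq = alt_allele_seq,
         indel_length = abs(nchar(ref_allele_seq) - nchar(alt_allele_seq))),
    class = "locus")
}

#' @export
print.locus <- function(x, ...) {
  cat("<locus>", x$name, " chr", x$chromosome, ":", x$causative_position,
      "  ref ", nchar(x$ref_allele_seq), " bp / alt ",
      nchar(x$alt_allele_seq), " bp (indel ", x$indel_length, " bp)\n",
      sep = "")
  invisible(x)
}

#' Reverse complement of DNA sequences
#'
#' Vectorised base complement plus reversal; `N` maps to `N`. Lower-case
#' input is upper-cased; any other character is an error rather than being
#' silently masked.
#'
#' @param seq Character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("AAAGGCGCAAGTGGATGCCATCCAAGGTGA")
#' @export
reverse_complement <- function(seq) {
  seq <- validate_dna(seq, allow_n = TRUE)
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Read and write FASTQ files
#'
#' Minimal strict four-line FASTQ I/O. Reads are returned as a data frame
#' with columns `id`, `sequence` and `quality` (ASCII-encoded string, one
#' symbol per base). Gzipped input is handled transparently; a path ending
#' in `.gz` is written compressed. Parse errors name the offending line.
#'
#' @param path File path (plain or gzipped FASTQ).
#' @param reads Data frame with columns `id`, `sequence`, `quality`.
#' @return `read_fastq()`: data frame of reads; `write_fastq()`: the path,
#'   invisibly.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ record at line ", length(lines) + 1L, " in ", path)
  }
  n <- length(lines) / 4L
  if (n == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  }
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- toupper(lines[seq(2L, by = 4L, length.out = n)])
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) stop("missing '@' header at line ", (bad[1] - 1L) * 4L + 1L)
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) stop("missing '+' separator at line ", (bad[1] - 1L) * 4L + 3L)
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad)) {
    stop("sequence/quality length mismatch at line ", (bad[1] - 1L) * 4L + 2L)
  }
  bad <- which(!grepl("^[ACGTN]*$", seq))
  if (length(bad)) {
    stop("non-nucleotide character at line ", (bad[1] - 1L) * 4L + 2L)
  }
  data.frame(id = sub("^@", "", sub("\\s.*$", "", hdr)),
             sequence = seq, quality = qual, stringsAsFactors = FALSE)
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
  if (any(nchar(reads$sequence) != nchar(reads$quality))) {
    stop("sequence/quality length mismatch")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  out <- rbind(paste0("@", reads$id), reads$sequence, "+", reads$quality)
  writeLines(as.vector(out), con)
  invisible(path)
}

#' Decode ASCII quality strings to integer Phred scores
#'
#' @param quality Character vector of ASCII quality strings.
#' @param offset Encoding offset: 33 (Sanger/Illumina 1.8+, default) or 64.
#' @return List of integer vectors, one per input string.
#' @export
quality_scores <- function(quality, offset = 33L) {
  lapply(quality, function(q) utf8ToInt(q) - as.integer(offset))
}

#' Read a FASTA file of named sequences
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]; sequences are
#' upper-cased and returned as a named character vector.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(ss)), sub("\\s.*$", "", names(ss)))
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), filepath = path)
  invisible(path)
}

#' Read accession metadata
#'
#' Tab-separated, header row, UTF-8. Required columns: `accession_id`,
#' `group`; optional `latitude`, `longitude`, `fastq_path`. Group labels are
#' validated against [rice_groups()] and accession ids must be unique.
#' Lines starting with `#` are ignored (provenance headers).
#'
#' @param path TSV file path.
#' @return Data frame of accession records.
#' @export
read_metadata_tsv <- function(path) {
  md <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  need <- c("accession_id", "group")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata missing column(s): ", toString(miss))
  bad <- !(md$group %in% rice_groups())
  if (any(bad)) {
    stop("unknown group label ", sQuote(md$group[bad][1]),
         " at metadata row ", which(bad)[1],
         " (admissible: ", toString(rice_groups()), ")")
  }
  if (anyDuplicated(md$accession_id)) {
    stop("duplicate accession_id: ",
         md$accession_id[duplicated(md$accession_id)][1])
  }
  for (col in c("latitude", "longitude", "fastq_path")) {
    if (is.null(md[[col]])) md[[col]] <- NA
  }
  md
}

#' @rdname read_metadata_tsv
#' @param metadata Data frame of accession records.
#' @export
write_metadata_tsv <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
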