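default_allele_freqs <- function() {
  rbind(
    data.frame(group = c("wild", "indica", "japonica_tropical",
                         "japonica_temperate", "aus", "aromatic", "other"),
               locus = "Rc",
               alt_freq = c(0.132, 0.285, 0.318, 0.116, 1.0, 0.0, 0.15),
               stringsAsFactors = FALSE),
    data.frame(group = c("wild", "indica", "japonica_tropical",
                         "japonica_temperate", "aus", "aromatic", "other"),
               locus = "LABA1",
               alt_freq = c(0.153, 0.023, 0.0, 0.581, 0.667, 0.0, 0.15),
               stringsAsFactors = FALSE))
}

#' Configuration of a synthetic rice cohort
#'
#' Defaults emulate the structure of the published 1543-accession screen at
#' one tenth of its size: group sizes scaled from 460 wild / 519 indica /
#' 482 japonica / 30 aus / 5 aromatic / 47 other, mean sequencing depth 2x
#' for wild and 1x for cultivated accessions, and derived-allele carrier
#' frequencies set to the reported group frequencies. Carrier frequencies
#' are accession-level (haploid-style), matching how the screen scores
#' accessions rather than diploid dosage.
#'
#' @param seed Integer seed; all downstream simulation is deterministic
#'   given the seed.
#' @param group_sizes Named integer vector (names from [rice_groups()]).
#' @param allele_freqs Data frame `group`, `locus`, `alt_freq` in `[0,1]`.
#' @param het_rate Probability an accession carries both alleles.
#' @param coverage Named mean depth per group; groups not named fall back to
#'   the `"cultivated"` entry.
#' @param read_length Simulated read length in bp.
#' @param error_rate Per-base substitution probability.
#' @param base_quality Constant Phred quality written for simulated bases.
#' @param snp_missing_rate Per-call missingness of simulated SNP matrices.
#' @param polymorphism_density Named per-bp segregating-site probability per
#'   accession class (used by [simulate_snp_matrix()]); the default 4:1
#'   wild-carrier : cultivated ratio mirrors the observed excess of
#'   polymorphism around the causative deletions in wild carriers.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       group_sizes = c(wild = 46L, indica = 52L,
                                       japonica_tropical = 24L,
                                       japonica_temperate = 24L,
                                       aus = 3L, aromatic = 1L, other = 5L),
                       allele_freqs = default_allele_freqs(),
                       het_rate = 0.005,
                       coverage = c(wild = 2, cultivated = 1),
                       read_length = 75L,
                       error_rate = 0.002,
                       base_quality = 35L,
                       snp_missing_rate = 0.3,
                       polymorphism_density = c(wild_carrier = 0.004,
                                                cultivated = 0.001)) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (is.null(names(group_sizes)) ||
      !all(names(group_sizes) %in% rice_groups())) {
    stop("group_sizes must be named with labels from rice_groups()")
  }
  if (any(group_sizes < 0)) stop("group sizes must be >= 0")
  probs <- c(allele_freqs$alt_freq, het_rate, error_rate, snp_missing_rate,
             polymorphism_density)
  if (any(probs < 0 | probs > 1)) {
    stop("frequencies, rates and densities must lie in [0, 1]")
  }
  if (any(coverage < 0)) stop("coverage must be >= 0")
  structure(
    list(seed = as.integer(seed), group_sizes = group_sizes,
         allele_freqs = allele_freqs, het_rate = het_rate,
         coverage = coverage, read_length = as.integer(read_length),
         error_rate = error_rate, base_quality = as.integer(base_quality),
         snp_missing_rate = snp_missing_rate,
         polymorphism_density = polymorphism_density),
    class = "sim_config")
}

group_coverage <- function(config, group) {
  cov <- config$coverage
  if (group %in% names(cov)) unname(cov[[group]])
  else if ("cultivated" %in% names(cov)) unname(cov[["cultivated"]])
  else stop("no coverage entry for group ", group)
}

#' Simulate cohort metadata and truth alleles
#'
#' Draws, per accession and locus, the true carried allele: `HET` with
#' probability `het_rate`, otherwise `ALT` with the configured (group,
#' locus) carrier frequency, else `REF`. Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @param loci List of [locus] objects (default [rice_loci()]).
#' @return List: `metadata` (accession table) and `truth` (data frame
#'   `accession_id`, `group`, `locus`, `genotype` in REF/ALT/HET).
#' @export
simulate_cohort <- function(config, loci = rice_loci()) {
  stopifnot(inherits(config, "sim_config"))
  sizes <- config$group_sizes[config$group_sizes > 0]
  groups <- rep(names(sizes), sizes)
  n <- length(groups)
  metadata <- data.frame(
    accession_id = sprintf("acc%04d", seq_len(n)),
    group = groups, latitude = NA_real_, longitude = NA_real_,
    fastq_path = NA_character_, stringsAsFactors = FALSE)
  truth <- with_seed(config$seed, {
    do.call(rbind, lapply(loci, function(loc) {
      f <- config$allele_freqs
      freq <- setNames(f$alt_freq[f$locus == loc$name],
                       f$group[f$locus == loc$name])
      missing_groups <- setdiff(unique(groups), names(freq))
      if (length(missing_groups)) {
        stop("no allele frequency configured for locus ", loc$name,
             ", group(s) ", toString(missing_groups))
      }
      is_het <- runif(n) < config$het_rate
      is_alt <- runif(n) < freq[groups]
      data.frame(accession_id = metadata$accession_id, group = groups,
                 locus = loc$name,
                 genotype = ifelse(is_het, "HET",
                                   ifelse(is_alt, "ALT", "REF")),
                 stringsAsFactors = FALSE)
    }))
  })
  rownames(truth) <- NULL
  list(metadata = metadata, truth = truth)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_bases <- function(seq, error_rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < error_rate)
  if (length(hit)) {
    for (i in hit) {
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    }
  }
  paste(ch, collapse = "")
}

#' Simulate low-coverage reads for a locus
#'
#' Per accession the read count is Poisson with mean `coverage *
#' region_length / read_length`; start positions are uniform over the
#' carried allele's local reference (heterozygotes draw each read's allele
#' with probability 1/2); bases are substituted independently at
#' `error_rate`; qualities are a constant configurable value. About half
#' the reads are emitted as the reverse complement, as in real unstranded
#' sequencing. Deterministic given the config seed (offset per locus so
#' different loci get independent streams).
#'
#' @param truth Truth table from [simulate_cohort()].
#' @param locus A [locus]; its allele references must exceed the read
#'   length.
#' @param config A [sim_config()].
#' @return Named list (by accession id) of read data frames.
#' @export
simulate_reads <- function(truth, locus, config) {
  stopifnot(inherits(config, "sim_config"), inherits(locus, "locus"))
  refs <- c(REF = locus$ref_allele_seq, ALT = locus$alt_allele_seq)
  if (any(nchar(refs) <= config$read_length)) {
    stop("read_length (", config$read_length,
         ") must be smaller than both allele references of ", locus$name)
  }
  rows <- truth[truth$locus == locus$name, , drop = FALSE]
  if (nrow(rows) == 0L) stop("truth table has no rows for locus ", locus$name)
  rl <- config$read_length
  seed <- (config$seed + sum(utf8ToInt(locus$name))) %% 2147483647L
  with_seed(seed, {
    out <- lapply(seq_len(nrow(rows)), function(i) {
      acc <- rows$accession_id[i]
      depth <- group_coverage(config, rows$group[i])
      lambda <- depth * nchar(refs[["REF"]]) / rl
      n_reads <- rpois(1L, lambda)
      if (n_reads == 0L) {
        return(data.frame(id = character(), sequence = character(),
                          quality = character(), stringsAsFactors = FALSE))
      }
      alleles <- switch(rows$genotype[i],
        REF = rep("REF", n_reads),
        ALT = rep("ALT", n_reads),
        HET = sample(c("REF", "ALT"), n_reads, replace = TRUE))
      seqs <- vapply(alleles, function(al) {
        src <- refs[[al]]
        start <- sample.int(nchar(src) - rl + 1L, 1L)
        read <- substr(src, start, start + rl - 1L)
        read <- mutate_bases(read, config$error_rate)
        if (runif(1) < 0.5) reverse_complement(read) else read
      }, character(1), USE.NAMES = FALSE)
      data.frame(
        id = sprintf("%s_%s_r%04d", acc, locus$name, seq_len(n_reads)),
        sequence = seqs,
        quality = strrep(intToUtf8(config$base_quality + 33L), rl),
        stringsAsFactors = FALSE)
    })
    names(out) <- rows$accession_id
    out
  })
}

#' Simulate a SNP matrix with class-specific polymorphism density
#'
#' Places polymorphic sites along a window by independent per-bp Bernoulli
#' draws with a class-specific density, gives class members a 50:50 draw
#' between the site's two alleles, all other accessions the reference base,
#' and finally masks calls to missing at `snp_missing_rate`. Deterministic
#' given the config seed.
#'
#' @param config A [sim_config()]; densities come from
#'   `config$polymorphism_density` (one entry per class name).
#' @param focal `c(chrom, pos)` centre of the window.
#' @param window_bp Window width in bp.
#' @param classes Named list of accession id vectors; names must match
#'   density entries.
#' @return List: `matrix` (a `snp_matrix` with class labels attached as
#'   groups) and `classes` (as supplied).
#' @export
simulate_snp_matrix <- function(config, focal = c("4", 34631527),
                                window_bp = 10000L, classes) {
  stopifnot(inherits(config, "sim_config"), is.list(classes),
            !is.null(names(classes)))
  miss <- setdiff(names(classes), names(config$polymorphism_density))
  if (length(miss)) {
    stop("no polymorphism density configured for class(es): ",
         toString(miss))
  }
  chrom <- as.character(focal[1])
  centre <- as.numeric(focal[2])
  half <- floor(window_bp / 2)
  w_start <- max(1, centre - half)
  w_end <- centre + half - 1
  ids <- unique(unlist(classes))
  with_seed(config$seed + 7L, {
    site_pos <- list()
    for (cl in names(classes)) {
      dens <- config$polymorphism_density[[cl]]
      offs <- which(runif(w_end - w_start + 1) < dens)
      site_pos[[cl]] <- w_start + offs - 1
    }
    all_pos <- sort(unique(unlist(site_pos)))
    if (length(all_pos) == 0L) {
      # degenerate but valid: one invariant anchor site so the matrix is
      # well-formed; it is monomorphic and contributes S = 0
      all_pos <- centre
    }
    calls <- matrix(NA_character_, length(ids), length(all_pos),
                    dimnames = list(ids, paste0(chrom, ":", all_pos)))
    for (j in seq_along(all_pos)) {
      bases <- sample(c("A", "C", "G", "T"), 2L)
      calls[, j] <- bases[1]
      for (cl in names(classes)) {
        if (all_pos[j] %in% site_pos[[cl]]) {
          members <- classes[[cl]]
          calls[members, j] <- ifelse(runif(length(members)) < 0.5,
                                      bases[2], bases[1])
        }
      }
    }
    mask <- matrix(runif(length(calls)) < config$snp_missing_rate,
                   nrow(calls), ncol(calls))
    calls[mask] <- NA_character_
    group_vec <- setNames(rep(NA_character_, length(ids)), ids)
    for (cl in names(classes)) group_vec[classes[[cl]]] <- cl
    list(matrix = snp_matrix(calls, groups = group_vec), classes = classes)
  })
}
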