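# cli module: run_pipeline() is the chained entry point; a thin Rscript
# dispatcher over the same functions ships in inst/scripts/wildallele.R.

read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML path or a list")
  if (is.null(config$seed)) stop("config must set a seed")
  if (is.null(config$outdir)) stop("config must set an outdir")
  config
}

validate_run_config <- function(config) {
  locus_paths <- if (is.list(config$loci)) {
    unlist(lapply(config$loci, function(l) c(l$ref_fasta, l$alt_fasta)))
  }
  for (p in c(config$metadata, config$snp_matrix, locus_paths)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("validation failure: referenced file does not exist: ", p)
    }
  }
  invisible(config)
}

pipeline_loci <- function(config) {
  if (is.null(config$loci) || identical(config$loci, "builtin")) {
    return(rice_loci())
  }
  loci <- lapply(config$loci, function(l) {
    ref <- read_fasta(l$ref_fasta)[[1]]
    alt <- read_fasta(l$alt_fasta)[[1]]
    locus(l$name, l$chromosome %||% "NA", l$causative_position %||% 1,
          ref, alt)
  })
  setNames(loci, vapply(loci, `[[`, character(1), "name"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

provenance_header <- function(config, seed) {
  # hash the analysis-relevant configuration: where the outputs go must not
  # change what they contain
  hashed <- config[setdiff(names(config), "outdir")]
  c(paste0("# wildallele ", as.character(packageVersion("wildallele"))),
    paste0("# seed: ", seed),
    paste0("# config_hash: ", rlang::hash(hashed)))
}

prepend_header <- function(path, header) {
  writeLines(c(header, readLines(path)), path)
  path
}

write_stage_tsv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full synthetic screen pipeline
#'
#' Chains simulate -> design-probes -> trim -> scan -> verify -> classify ->
#' tabulate -> diversity from a single YAML (or list) configuration. Every
#' stage writes a TSV under `outdir` with a provenance header (`# wildallele
#' <version>`, `# seed`, `# config_hash`), and a final `manifest.tsv` lists
#' each output with its md5 checksum, so runs with identical config and seed
#' produce identical manifests. Any stage error aborts with the stage name.
#'
#' Config keys: `seed`, `outdir`; optional `sim` (overrides for
#' [sim_config()]), `loci` (`"builtin"` or a list with `name`,
#' `ref_fasta`, `alt_fasta`, ...), `thresholds` (`min_reads`,
#' `min_identity`, `min_margin`), `diversity` (`window_bp`), `trim`
#' (`window`, `min_mean_quality`, `min_length`), `write_fastq` (logical),
#' `stop_after_simulate` (write only metadata, truth and per-accession
#' FASTQ, then the manifest).
#'
#' @param config YAML file path or list.
#' @return Invisibly, the manifest data frame (file, md5).
#' @export
run_pipeline <- function(config) {
  config <- read_run_config(config)
  validate_run_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hdr <- provenance_header(config, config$seed)
  thr <- config$thresholds %||% list()
  trim_cfg <- config$trim %||% list()

  cfg <- run_stage("config", {
    sim_args <- config$sim %||% list()
    sim_args$seed <- config$seed
    # YAML maps come in as lists; sim_config wants named vectors
    for (f in c("group_sizes", "coverage", "polymorphism_density")) {
      if (!is.null(sim_args[[f]])) sim_args[[f]] <- unlist(sim_args[[f]])
    }
    if (!is.null(sim_args$allele_freqs)) {
      sim_args$allele_freqs <-
        do.call(rbind, lapply(sim_args$allele_freqs, as.data.frame))
    }
    do.call(sim_config, sim_args)
  })
  loci <- run_stage("loci", pipeline_loci(config))

  cohort <- run_stage("simulate", simulate_cohort(cfg, loci))
  write_stage_tsv(cohort$metadata, file.path(outdir, "metadata.tsv"), hdr)
  write_stage_tsv(cohort$truth, file.path(outdir, "truth.tsv"), hdr)

  finish <- function() {
    files <- sort(list.files(outdir, recursive = TRUE, full.names = FALSE))
    files <- setdiff(files, "manifest.tsv")
    manifest <- data.frame(
      file = files,
      md5 = unname(tools::md5sum(file.path(outdir, files))),
      stringsAsFactors = FALSE)
    write_stage_tsv(manifest, file.path(outdir, "manifest.tsv"), hdr)
    invisible(manifest)
  }
  if (isTRUE(config$stop_after_simulate)) {
    run_stage("simulate", {
      fq_dir <- file.path(outdir, "fastq")
      dir.create(fq_dir, showWarnings = FALSE)
      for (loc in loci) {
        reads_by_acc <- simulate_reads(cohort$truth, loc, cfg)
        for (acc in names(reads_by_acc)) {
          write_fastq(reads_by_acc[[acc]],
                      file.path(fq_dir, paste0(acc, "_", loc$name, ".fastq")))
        }
      }
    })
    return(finish())
  }

  probes <- run_stage("design-probes", {
    flanks <- config$probe_flanks %||% list()
    ps <- lapply(loci, function(loc) {
      f <- flanks[[loc$name]] %||% list()
      design_probes(loc, word_length = config$word_length %||% 30L,
                    left_flank_ref = f$ref, left_flank_alt = f$alt)
    })
    setNames(ps, vapply(loci, `[[`, character(1), "name"))
  })
  write_probes_tsv(probes, file.path(outdir, "probes.tsv"))
  prepend_header(file.path(outdir, "probes.tsv"), hdr)

  evidence <- run_stage("scan", {
    evs <- list()
    for (loc in loci) {
      reads_by_acc <- simulate_reads(cohort$truth, loc, cfg)
      if (isTRUE(config$write_fastq)) {
        fq_dir <- file.path(outdir, "fastq")
        dir.create(fq_dir, showWarnings = FALSE)
        for (acc in names(reads_by_acc)) {
          write_fastq(reads_by_acc[[acc]],
                      file.path(fq_dir, paste0(acc, "_", loc$name, ".fastq")))
        }
      }
      for (acc in names(reads_by_acc)) {
        reads <- trim_reads(reads_by_acc[[acc]],
                            window = trim_cfg$window %||% 4L,
                            min_mean_quality = trim_cfg$min_mean_quality %||% 15,
                            min_length = trim_cfg$min_length %||% 30L)
        ev <- scan_reads(reads, probes[[loc$name]], accession_id = acc)
        ev <- verify_matches(ev, reads, loc,
                             min_identity = thr$min_identity %||% 0.9,
                             min_margin = thr$min_margin %||% 1)
        evs[[length(evs) + 1L]] <- ev
      }
    }
    evs
  })
  ev_df <- evidence_table(evidence)
  write_stage_tsv(ev_df, file.path(outdir, "evidence.tsv"), hdr)

  calls <- run_stage("genotype",
                     classify_calls(ev_df, min_reads = thr$min_reads %||% 1L))
  write_stage_tsv(calls, file.path(outdir, "calls.tsv"), hdr)
  table <- run_stage("tabulate", tabulate_groups(calls, cohort$metadata))
  write_stage_tsv(table, file.path(outdir, "group_table.tsv"), hdr)

  div <- run_stage("diversity", {
    wbp <- (config$diversity %||% list())$window_bp %||% 10000L
    res <- list()
    for (loc in loci) {
      carrier <- calls$accession_id[calls$locus == loc$name &
                                      calls$call %in% c("ALT_ONLY", "HET")]
      grp <- setNames(cohort$metadata$group, cohort$metadata$accession_id)
      classes <- list(
        wild_carrier = carrier[grp[carrier] == "wild"],
        cultivated = cohort$metadata$accession_id[
          cohort$metadata$group != "wild"])
      classes <- classes[lengths(classes) > 0]
      if (length(classes) == 0L) next
      sim <- simulate_snp_matrix(
        cfg, focal = c(loc$chromosome, loc$causative_position),
        window_bp = wbp, classes = classes)
      snp_path <- file.path(outdir, paste0("snp_matrix_", loc$name, ".tsv"))
      write_snp_matrix(sim$matrix, snp_path)
      prepend_header(snp_path, hdr)
      for (cl in names(classes)) {
        res[[length(res) + 1L]] <- window_diversity(
          sim$matrix, focal = c(loc$chromosome, loc$causative_position),
          window_bp = wbp, accessions = classes[[cl]],
          class_label = cl, locus_name = loc$name)
      }
    }
    res
  })
  if (length(div)) {
    write_stage_tsv(diversity_table(div), file.path(outdir, "diversity.tsv"),
                    hdr)
  }

  finish()
}
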