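# Example configuration for `run_pipeline()` / `wildallele run`.
#
# Every source of randomness flows from this one seed; it is recorded in the
# provenance header of every output TSV together with a hash of this config.
seed: 42

# All stage outputs (metadata, truth, probes, evidence, calls, group table,
# SNP matrices, diversity, manifest) are written here.
outdir: wildallele_run

# Loci: "builtin" uses the packaged Rc / LABA1 reconstructions. To supply
# your own locus, replace with a list of entries like:
#   - name: Rc
#     chromosome: "7"
#     causative_position: 6069568
#     ref_fasta: rc_wildtype.fa   # local reference WITH the 14 bp segment
#     alt_fasta: rc_deletion.fa   # local reference with the deletion
loci: builtin

# Synthetic cohort: overrides for sim_config(). Sizes here are deliberately
# small so the example finishes in seconds; drop the block to get the
# package defaults (a ~1/10-scale cohort with study-like frequencies).
sim:
  group_sizes:
    wild: 10
    indica: 8
    japonica_tropical: 4
  coverage:          # mean sequencing depth per group
    wild: 2
    cultivated: 1
  read_length: 75
  error_rate: 0.002  # per-base substitution probability
  snp_missing_rate: 0.3

# The published LABA1 words are offset 16 bases left of the junction on both
# alleles; Rc uses the default centred placement.
probe_flanks:
  LABA1:
    ref: 16
    alt: 16

# Quality trimming applied before scanning (sliding window, mean Phred).
trim:
  window: 4
  min_mean_quality: 15
  min_length: 30

# Evidence thresholds: one verified read suffices for a call; alignment
# verification needs >= 90% identity and a score margin of >= 1 over the
# other allele.
thresholds:
  min_reads: 1
  min_identity: 0.9
  min_margin: 1

# Diversity windows around each locus's causative position.
diversity:
  window_bp: 10000

# Set true to also write per-accession FASTQ files under outdir/fastq/.
write_fastq: false
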