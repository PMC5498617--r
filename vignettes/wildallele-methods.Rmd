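---
title: "Probe-word genotyping of rice domestication alleles: methods and design notes"
author: "wildallele"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probe-word genotyping of rice domestication alleles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wildallele)
```

## The problem

Several "domestication genes" of Asian rice carry recessive alleles whose
causative variants are small and sharply defined: a 14 bp deletion in the
*Rc* coding sequence (white vs red pericarp), a 1 bp deletion in *LABA1*
(barbless awns), a G→T substitution in *Sh4* (non-shattering rachis) and
candidate polymorphisms upstream of *PROG1* (erect growth). Whether these
alleles occur naturally in wild *Oryza rufipogon* matters for models of rice
domestication, and it can be asked directly of public low-coverage
resequencing data: at a mean depth of 1–2× per accession no gene can be
assembled, but a known indel can be *scored* in whatever subset of
accessions happens to have a read across the site.

`wildallele` implements that screen as a reusable, tested pipeline:

1. design four exact-match **probe words** per locus (2 alleles × 2
   strands) spanning the discriminating site;
2. quality-trim reads and scan them for perfect word matches;
3. verify candidate reads by pairwise alignment against both allele
   references;
4. call each accession (`REF_ONLY` / `ALT_ONLY` / `HET` / `NO_DATA`) and
   tabulate per-group carrier frequencies with the heterozygote convention
   used in accession-level screens;
5. quantify polymorphism around the causative site with a
   missing-data-weighted window statistic, and classify diagnostic-SNP
   haplotypes from a haploid-coded SNP matrix;
6. generate synthetic cohorts with the statistical structure of the real
   study, so that every stage is testable without terabyte-scale archives.

## Probe-word design

A `locus` holds two local allele references. The divergent region between
them is located by longest-common-prefix/suffix comparison; the common
suffix is clamped so that prefix and suffix never overlap on the shorter
allele, which resolves the placement ambiguity a 1 bp indel has next to an
identical base (deleting either `C` of a `CC` gives the same sequence; the
junction is fixed deterministically at the leftmost position). Each probe
word must include at least one base beyond the divergent region on each
side; by default the site is centred in the word, and explicit
`left_flank_*` parameters reproduce particular published words (the Rc pair
falls out of the centred default; the LABA1 pair is offset 16 bases left of
the junction on both alleles). Word length defaults to 30 bp.

Design enforces **cross-allele exclusivity**: no word (in either
orientation) may occur in the other allele's local reference, otherwise a
perfect match would not be diagnostic. Exclusivity is checked only against
the supplied local references — genome-wide uniqueness is the user's
responsibility, which is why every raw match is verified by alignment
rather than trusted. Words containing `N` are rejected because `N` never
participates in a perfect match.

```{r probes}
ps <- rice_probe_sets()$rc
ps
```

The packaged Rc/LABA1 loci are *reconstructions*: the 30–60 bp around each
junction is the genuine diagnostic core, the outer flanks are synthetic
padding so simulated reads can start on either side. They are adequate for
probe design, simulation and verification, not for genome-coordinate work.

## Scanning and alignment verification

Scanning is exact substring search (grep-style): a read counts for an
allele if the allele's forward word or its reverse complement occurs in it;
one substituted base means no hit; multiple occurrences in one read count
once (evidence is per read). A read matching words of both alleles — only
possible if exclusivity was deliberately overridden — is recorded in both
raw counts but routed to verification rather than attributed.

Verification aligns each candidate read, in both orientations, to both
allele references with free-end-gap (semi-global) alignment and assigns it
to the higher-scoring allele iff

* identity over the aligned region ≥ `min_identity` (default 0.9), and
* the score margin over the other allele ≥ `min_margin` (default 1 match
  unit), and
* the winning allele is one whose probe the read actually matched.

Everything else is discarded and logged. These thresholds are deliberate,
documented configuration: the screen's published description verifies
matches by alignment but does not state an acceptance rule, so the package
exposes the simplest rule that separates alleles differing by at least 1 bp.

### Two gap-scoring regimes, and why

The aligner (`align_pair()`, an Rcpp Gotoh implementation) scores match +1,
mismatch −1 and a **gap run** −1 by default, with `gap_extend = 0`: an
indel is one mutational event regardless of length. This is the same
single-event view of indels used when multi-base gap runs are recoded as
single characters for parsimony analysis (`recode_gaps()`), and it is what
makes `infer_indel_length()` meaningful for a word pair spanning one indel:
with any per-base gap cost comparable to the match score, the optimal
alignment of the two published Rc words is *not* the biologically correct
one — the 14 bp gap (16 matches − 14) loses to alignments that exploit
local similarity between the words. Under per-event scoring the canonical
single-gap alignment is optimal, and two further determinism rules make it
unique: among score-equal alignments the one with the fewest gap runs wins
(parsimony over events, resolved exactly via a lexicographic integer
objective, not an epsilon), and remaining traceback ties prefer the
diagonal, then a gap in the second sequence, then a gap in the first.

```{r indel}
align_pair(rice_probe_sets()$rc$alt_forward, rice_probe_sets()$rc$ref_forward)
infer_indel_length(ps$ref_forward, ps$alt_forward)
```

Verification uses the *other* regime: match +1, mismatch −1, gap open −1
and −0.5 per additional gap base (run internally at doubled integer scale
so the lexicographic objective stays exact). Against a 250 bp reference a
run-cost-only scheme lets the aligner chain cheap gaps between coincidental
motif matches, which flattens the score difference between alleles; the
affine extension term makes long reference skips expensive and restores a
clean margin (≥ 7.5 match units for an error-free read across the 14 bp
junction). Each regime is the default for the operation it serves; both are
plain arguments.

### Quality trimming

`trim_reads()` is a minimal sliding-window trimmer, not a Trimmomatic
clone: scanning 5′→3′ with a `window` of 4 bases, the read is truncated at
the start position of the first window whose mean Phred quality falls below
`min_mean_quality` (15), keeping bases up to and including that position;
reads shorter than `min_length` (30, one probe word) are dropped. The rule
is exercised base-by-base in the tests.

## Genotyping conventions

One verified read suffices for a call (`min_reads = 1`): at 1–2× depth
demanding more would discard most of the cohort. `HET` means both alleles
reached `min_reads`. Group tables count a heterozygote as a carrier of
*both* alleles over a denominator of distinct informative accessions, so

```
n_ref_carriers + n_alt_carriers − n_het == n_informative
```

and the two percentages sum to ≥ 100. This is the only convention
consistent with accession-level summary tables of this kind of screen
(65/228 = 28.5 and 167/228 = 73.2 for a group with 4 heterozygotes among
228 informative accessions). Percentages are rounded half-up to one decimal
— base R's `round()` is round-half-even and reproduces printed tables
incorrectly at ties.

Prose-style figures sometimes use a different denominator (all accessions
with any match, heterozygotes counted once: 33/255 = 12.9 vs the
table-style 33/250 = 13.2). Both computations are exposed —
`tabulate_groups()` for the table convention, `carrier_percentage()` for a
caller-supplied denominator — rather than silently choosing one.

## The windowed diversity statistic

For an allele class (e.g. wild accessions carrying the deletion), within a
centred window of `window_bp` (default 10 000) around the causative
position:

$$D = \frac{S}{n \cdot \bar c}$$

where $S$ is the number of polymorphic sites (≥ 2 distinct non-missing
calls among the class; singletons count, since no minor-allele threshold is
part of the statistic), $n$ the number of class accessions and $\bar c$ the
mean per-accession call rate over the window sites. With complete data
$D = S/n$; halving the call rate doubles $D$. "Polymorphic sites per
examined accession weighted by the proportion of non-missing data" admits
several readings (per-site weighting, pairwise differences); this package
fixes exactly one and computes nothing else, because a single auditable
definition beats a silent choice among readings. Degenerate inputs (empty
class, no window sites, call rate 0) yield a flagged undefined result, not
an error; a window clipped at position 1 is flagged truncated.

## SNP-matrix operations

The SNP matrix is haploid-coded (`A/C/G/T`, `N`/`-` missing). Heterozygous
or IUPAC ambiguity codes are a hard error on ingest, not reinterpreted as
missing: silent reinterpretation would corrupt frequencies, and failing
loudly is the safer contract. Site columns are `chrom:pos` (1-based),
deduplicated and sorted.

`site_allele_frequencies()` counts over non-missing calls only (an
all-missing column is a flagged NO-CALL). `assign_haplotypes()`
concatenates calls at caller-ordered sites — order is an argument, not a
constant, because the naming convention of the *PROG1* upstream pair (TC /
CC / CA) corresponds to position 2,872,911 first, then 2,872,361 — and
excludes accessions with any missing call at the listed sites as
`INCOMPLETE`.

For parsimony pre-processing, `parsimony_informative_sites()` keeps exactly
the columns with ≥ 2 states each carried by ≥ 2 sequences (gap counts as a
state; the filter is idempotent), and `recode_gaps()` replaces each maximal
gap run longer than 1 bp (identical start and end across the sequences that
carry it) by one binary presence/absence character, dropping the run's
columns; 1 bp gaps stay in place. Runs that overlap with different
boundaries are an error listing the runs — how ragged runs should be
recoded is genuinely ambiguous, and guessing silently would change tree
topologies. Tree search itself (dnapars-style) is out of scope; only its
input pre-processing is provided.

## The synthetic cohort generator

The generator's defaults are the study conditions, scaled to desk size:

| parameter | default | rationale |
|---|---|---|
| group sizes | wild 46, indica 52, japonica 24+24, aus 3, aromatic 1, other 5 | ~1/10 of the 1543-accession cohort (460/519/482/30/5/47) |
| coverage | wild 2×, cultivated 1× | the depths of the underlying datasets |
| carrier frequencies | per (group, locus), e.g. wild Rc 0.132, wild LABA1 0.153 | the reported group frequencies |
| read length | 75 bp | typical 2012-era Illumina; unstated in the source, so configurable |
| error rate | 0.002/base | typical Illumina substitution error |
| base quality | constant Q35 | flat profile; see limitations |
| SNP missing rate | 0.3 | heavy but not extreme missingness |
| polymorphism density | 0.004 vs 0.001 /bp | the observed ~4× excess around the deletions in wild carriers |

Truth alleles are drawn per accession (`HET` with `het_rate`, else `ALT`
with the configured frequency) — carrier state is accession-level
(haploid-style), matching how the screen scores accessions, not diploid
dosage. Read counts are Poisson(coverage × region length / read length),
starts uniform, bases substituted independently, and about half the reads
are emitted reverse-complemented as in unstranded sequencing. Errors are
substitution-only: the detection method is exact-match, so indel errors
in reads would only lower sensitivity, and modelling them would not change
any decision boundary the package has. SNP matrices place sites by per-bp
Bernoulli draws with class-specific density, give class members a 50:50
draw between two alleles, others the reference base, then mask missingness.

Everything is deterministic given the seed (per-locus offsets keep loci
independent); the same seed yields byte-identical FASTQ and matrix output.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: realistic quality profiles and error spectra
(no quality/position dependence, no indel errors), PCR duplicates,
coalescent haplotype structure and linkage (window sites are independent),
reference bias, and contamination. Parameter-recovery results on synthetic
cohorts demonstrate that the pipeline's logic is unbiased under its own
model, not that the model captures every failure mode of SRA data.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline on cohorts
of 250 accessions over 20–40 seeds (local references ~250 bp, so ~6–7
reads per accession at 2×), which gives the recovered carrier percentage a
standard error of ~0.2–0.5 points — small against the ~13% signal while
keeping a complete run in tens of seconds. The windowed-diversity ratio
check pools polymorphic-site counts across 20 seeds before taking the
ratio: with only ~10 expected cultivated sites per window, the per-seed
ratio is noisy and upward-biased, and the pooled estimator is the
consistent one.

Other fixed numerical choices: percentages round half-up to one decimal;
window arithmetic is half-open internally and reported 1-based inclusive
(`[pos − w/2, pos + w/2 − 1]`); alignment tie-breaks are as above;
`with_seed()` restores the caller's RNG state so library calls never
perturb user randomness.

## Known limitations

* Exclusivity is local, not genome-wide; paralogous perfect matches would
  inflate raw counts (verification against the local references mitigates
  but cannot fully resolve this without a genome).
* The packaged loci are reconstructions with synthetic flanks.
* `HET` calls at 1–2× coverage are rare-event observations; the simulator's
  `het_rate` is a phenomenological knob, not a population-genetic model.
* The diversity statistic is a polymorphism density, not π or θ; values are
  comparable between classes within one matrix, not across matrices with
  different site ascertainment.
* The trimmer is deliberately minimal and will not reproduce Trimmomatic
  output parameter-for-parameter.
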