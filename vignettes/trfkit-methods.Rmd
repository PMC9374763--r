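---
title: "Quantifying a 31-nt tRNA-iMet fragment from small-RNA-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying a 31-nt tRNA-iMet fragment from small-RNA-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trfkit)
```

## The problem

tRNA-derived fragments (tRFs) are small non-coding RNAs released by
cleavage of mature or precursor tRNAs. One such fragment -- a 31-nt
piece from the 5' end of initiator methionine tRNA, here called
tRiMetF31 -- rises dose-dependently in breast cancer cells induced to
express miR-34a, and silences the glycolytic activator PFKFB3 through a
complementary site in its 3'UTR. trfkit re-implements the computational
side of that analysis as a tested, reusable pipeline:

1. **Trimming** 3' adapter read-through from 50-cycle single-end reads
   and splitting a library into small-RNA inserts versus adapter-free
   full-length candidates (`partition_library()`).
2. **Hierarchical classification** of inserts into genomic categories
   with count-and-remove precedence
   (miRNA, piRNA, snoRNA, rRNA, tRNA, CDS, Promoters, 5'UTR, 3'UTR,
   Introns, repeats; `classify_reads()`).
3. **Fragment quantification** by mismatch-bounded ungapped matching
   against tRNA references, scaled to library size as a percent
   (`quantify_fragment()`), full-length tRNA counting
   (`quantify_full_length()`), and RPM length profiles
   (`length_profile()`).
4. **Duplex scanning** of the fragment against 3'UTR/reporter sequences
   and provenance checks of the assay oligos (`find_duplex_sites()`,
   `derive_reporter_inserts()`, `check_oligo_provenance()`).
5. **Odds-ratio meta-analysis** with the I²-driven fixed/random model
   switch (`select_and_pool()`).

No sequencing accession accompanies the original libraries, so the
package ships a synthetic-data generator (`simulate_library()`,
`simulate_dose_series()`) that emulates their statistical structure and
carries ground truth for every read.

## The matching model

Reads map as substrings of references (a fragment lives inside its
parent tRNA), ungapped, at a Hamming distance of at most *k*
mismatches, on both strands. This mirrors short-read alignment of
15-51 nt inserts, where indels are not a realistic error mode at desk
scale. `"best"` mode keeps only placements achieving the minimum
mismatch count, with a deterministic tie order: reference input order,
then smaller offset, then '+' before '-'. Read-level counting
increments one reference per read (the first best-tied one), because
library composition is a partition of reads, not of alignments. An `N`
in a read can never match and is charged as a mismatch; references must
be N-free.

Defaults follow the two sub-analyses they serve: fragment counting uses
*k* = 0 (counts at *k* = 1 or 2 should move only slightly, which the
test suite checks as monotonicity on synthetic data), while the genome
prefilter, category mapping and full-length counting use *k* = 1 with
best-mode placement.

The scan kernels are small C++ loops (Rcpp) verified in the test suite
against two independent routes: a pure-R all-offsets Hamming scan and
`Biostrings::matchPattern`.

## Trimming rule

Read-through happens because inserts are shorter than the 50-cycle
read: the sequencer continues into the 3' adapter (and, for very short
inserts, beyond it). `trim_read_3prime()` takes the *leftmost* offset
at which an adapter prefix of length at least `min_overlap = 3`
(shorter only because the read ends) aligns with a mismatch fraction at
most `max_error_rate = 0.1`, and removes everything from that offset
on. Leftmost-first matters: a global minimum-error rule would prefer a
chance, error-free 3-mer near the read tail over the true 21-nt overlap
carrying one sequencing error. Adapter-free reads of 50-51 nt are
full-length transcript candidates; adapter-free reads outside that
window are tallied and dropped (the 50-51 window is taken from the
original analysis as stated; why 51 nt can appear among 50-cycle reads
is not explained there, and we keep the window verbatim). An adapter at
offset 0 leaves a zero-length insert, which is retained in the trimmed
set for accounting but excluded from all matching.

## Classification semantics

Classification is sequential with count-and-remove semantics. Step 0
maps each insert to a concatenated genome; failures are counted
`unmapped` and removed. Survivors are then tested category by category
in precedence order and assigned to the first category with any valid
placement. The arrow notation of the original description is read as
left-first precedence (miRNA claims reads first); its prose ("remaining
reads were mapped to the next dataset") supports this reading.
Categories are explicit sequence sets, not genome intervals, matching
how the original reference sets were downloaded per category.
Percent shares use the total of non-empty trimmed reads as denominator.
Three invariants are property-tested: conservation
(`unmapped + categories + residual = total`), permutation invariance,
and precedence dominance (removing a later category never changes
earlier counts).

## What the generator emulates -- and what it does not

`simulate_library()` produces reads of the form
`insert + adapter`, truncated to the read length and padded with random
bases when insert plus adapter run short -- the read-through geometry
that makes trimming necessary. Inserts are 5'-anchored prefixes of
their source references: the fragment of interest is a 5' tRF, mature
small RNAs are whole references, and anchoring keeps the set of
distinct read sequences small enough that deduplicated classification
of a 100,000-read library runs in seconds. Insert lengths are uniform
on 18-35 nt (the small-RNA size range retained after gel selection);
a configurable share of tRNA reads carries the whole tRNA instead,
producing adapter-free reads for the full-length branch. Quality is a
constant 'I' because nothing downstream reads it.

The tRNA-iMet-like reference is assembled entirely from published
sequences: the printed 31-nt fragment, then the reverse complement of
the printed FISH detection probe (a probe is antisense to its target,
so its reverse complement is tRNA sequence), then a fixed 10-nt tail --
73 nt in all. This keeps every fixture derivable from printed material
while giving the pipeline the only structure it relies on: the fragment
is an exact 5' prefix of a tRNA reference.

Deliberately not modelled: sequencing errors, quality-score variation,
5' adapters, paired ends, isomiR-style end heterogeneity, and genomic
multi-mapping structure. A green recovery test therefore establishes
that the pipeline's accounting and matching are correct under clean
read-through geometry -- not that the pipeline is robust to platform
error modes.

Two conditioning details matter when comparing recovered shares with
intended fractions. First, recovery experiments simulate with
`full_length_fraction = 0`: full-length reads are adapter-free, leave
the trimmed library, and would shrink the percent denominator by about
1% relative -- a bookkeeping artifact, not an error. Second, the
measured fragment percent includes a small background of ordinary tRNA
reads that draw the iMet-like reference at insert length 31 and are
then sequence-identical to the fragment; under the defaults this
background is 0.25 x 1/15 x 1/18 ~ 9.3e-4 of reads, derived in closed
form from the generative model and accounted for in the recovery test's
expectation.

## Duplex model and oligo checks

The binding-site model is the simplest one consistent with the
published reporter data: a contiguous, perfectly complementary
antiparallel stretch, G:U wobble off by default, reported when at least
`min_length = 8` bases long and maximal (extendable in neither
direction). On the printed sequences this recovers a unique 10-bp site
pairing fragment positions 1-10 with `CCACUCUGCU` in the wild-type
reporter, and nothing of 8+ bp on the deletion mutant or the scrambled
control -- `min_length = 8` is the shortest threshold separating those
outcomes with margin. The original target prediction tool is unnamed in
the source, so no thermodynamic scoring is attempted; conclusions are
limited to what contiguous complementarity supports.

Reporter oligo pairs are validated by their cloning geometry: a `CTAG`
(XbaI) 5' overhang on the top strand, `AATT` (EcoRI) on the bottom, and
exact reverse-complementarity of the remainder. Assay oligos are traced
to their parents after stripping a declared synthesis decoration
(3' poly(A) tail for the tailing-qPCR primers, UU overhang for siRNA
strands), with the longest-core interpretation winning.

## Meta-analysis

Per-study odds ratios use `(a d)/(b c)` with Wald CIs from
`sqrt(1/a + 1/b + 1/c + 1/d)`; any study containing a zero cell gets
0.5 added to all four cells first (Haldane), and the same corrected
cells feed the pooled sums so weights and estimates stay consistent.
The fixed-effect default is Mantel-Haenszel with the
Robins-Breslow-Greenland variance -- the default estimator of the
meta-analysis software named in the source, which does not print its
estimator choice; inverse-variance pooling is provided alongside for
testability. Random effects use DerSimonian-Laird. Model choice follows
the published rule literally: random effects when I² is *strictly*
greater than 50%, fixed otherwise (I² = 50 exactly pools fixed). The
z-quantile is fixed at 1.96. When the fixed model is selected, `tau2`
is reported as 0 -- the fixed model's assumption -- even though the
method-of-moments estimate from `heterogeneity()` may be positive.

The identities and extracted counts behind the original forest plot are
not printed, so the published pooled values are not reproducible;
what is reproducible, and tested, is the machinery: exact identities
for single and identical studies, the strict threshold switch,
simulation recovery of a known log odds ratio, and ~95% fixed-effect CI
coverage at tau = 0.

`spearman_rho()` (average ranks, t approximation on n - 2 df for
n >= 4, p = 1 below) serves the ordinal 0-3 staining-score
correlations; `students_t()` is the pooled-variance two-sample test
used throughout the original comparisons, with Welch's form available.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; every report is 1-based
  inclusive (`hits_to_tsv()` converts).
* Sequences are uppercased on ingest; ids kept verbatim; a record never
  mixes T and U.
* Empty libraries: `composition_report()` returns all-zero percents
  with a warning; `quantify_fragment()` refuses a zero denominator.
* Fraction sums are validated to 1e-9; normalized meta-analysis weights
  sum to 1 by construction.
* Per-dose child seeds derive from the master seed by one
  `sample.int()` draw, giving independent, reproducible streams below
  2^31.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(seed = 1, out_dir = tempfile("run_"),
                       n_reads = 50000)
manifest <- run_pipeline(cfg)
vapply(manifest$libraries, `[[`, numeric(1), "trimet_percent")
#>    dose01    dose02    dose03
#> 0.6377 2.0816 5.2619   (percent of trimmed reads; intended
#>                          fractions 0.005 / 0.02 / 0.05 plus background)
manifest$dose_correlation$rho
#> [1] 1
```

With three dose points a rank correlation has no t-approximate p-value
(`p` reports 1); the monotone trend and `rho = 1` carry the
dose-response claim, as in the original three-dose design.

## Known limitations

* The duplex model is sequence-only; free-energy or seed-rule models
  could rank sites differently.
* Classification needs explicit per-category sequence sets; GFF/BED
  interval annotation is out of scope.
* The matcher is a direct scan, adequate for reference sets up to a few
  hundred kilobases; genome-scale mapping would need an index, which
  changes no contract.
* The generator's clean-read world means recovery tests bound
  accounting errors, not robustness to sequencing noise.
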