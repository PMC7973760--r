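---
title: "Methods: fine-tuning a ddRAD-seq platform with ddradtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fine-tuning a ddRAD-seq platform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddradtools)
```

## The problem

Double-digest RAD sequencing reduces a genome to the fragments produced by
two restriction enzymes and a fragment-size selection step, so that many
individuals can be genotyped on one sequencing lane. Whether the platform
works for a given species hinges on a handful of quantitative choices made
*before* any sequencing: which enzyme pair, which size window, and how much
yield per sample; and on diagnostics made *after* sequencing: did the
multiplexed libraries actually sample the same loci, and how usable is the
resulting genotype matrix. `ddradtools` implements that whole arithmetic as
a tested pipeline.

## In silico digestion

A `restriction_enzyme` is a name, an IUPAC motif, and the offset of the
top-strand cut from the motif start. Recognition sequences are not usually
printed in platform papers, so the package ships standard REBASE
definitions (PstI `CTGCA^G`, MboI `^GATC`, MspI `C^CGG`, EcoRI `G^AATTC`,
SphI `GCATG^C`, ApeKI `G^CWGC`) and lets the user override them — silent
hard-coding would make digestion counts irreproducible across REBASE
interpretations.

Coordinates are 0-based half-open throughout and a cut position is a
between-base index, so fragments tile each chromosome exactly and
`length = end − start` without off-by-one ambiguity. Matching is
case-insensitive; IUPAC codes in the *motif* are expanded, while letters in
the *genome* are taken literally (`fixed = "subject"` in Biostrings), so an
`N` run never matches a real motif. All six built-in enzymes are
palindromic and scanned on the top strand only; a non-palindromic user
enzyme is additionally scanned as its reverse complement with the cut
mapped back to top-strand coordinates.

Fragment ends are labeled by the enzyme that produced the cut, or
`CHROM_END` at chromosome termini. Classes are mutually exclusive —
`has_chrom_end` takes precedence, then `AB+BA` (two distinct enzymes, either
order), then `AA`/`BB` — and always partition the fragment set, which the
test suite asserts as an invariant. When both enzymes cut at the same
position, one boundary is kept, labeled with the lexicographically smaller
enzyme name, and the event is counted in a `coincident_cuts` diagnostic:
deterministic and observable rather than silently resolved.

Window bounds are inclusive on both ends; "between 300 and 400 bp" is
ambiguous in prose and the inclusive reading was fixed once. Enzyme pairs
are ranked by the windowed AB+BA count — the fragments a ddRAD library
actually sequences — with ties broken lexicographically by pair name so
ranking is reproducible.

Methylation sensitivity is carried as metadata only. The wet-lab rationale
for methylation-sensitive enzymes (avoiding repetitive regions) is real,
but the in silico digestion does not model methylation state, and
pretending otherwise would require a methylome the user rarely has.

## Sequencing-design arithmetic

`target_bp_range(n, [ℓ, u]) = (n·ℓ, n·u)` and
`expected_depth(Y, (t_min, t_max)) = (Y/t_max, Y/t_min)`, reported to one
decimal. Depth is deliberately a *pair*: for the peach numbers
(63,730 loci, 300–400 bp, 250 Mb yield) the low end is 9.8×, which is what
"at least 10×" rounds to — reporting a single number would hide that the
guarantee holds only at the window's short edge.

Quoted yields are often ambiguous about whether both mates of a read pair
are counted. `yield_to_reads()` implements both conventions; the default is
`one_mate` because the platform equates 250 Mb with 1 M 2×250 bp pairs,
which is internally inconsistent with `both_mates` (1 M pairs × 500 b =
500 Mb). Both are exposed rather than guessing intent.

## Coverage-overlap diagnostics

Alignments are ingested with the platform's `MAPQ > 3` filter (the
threshold is configurable), and paired mates are counted as independent
segments everywhere — a mate is a mate regardless of its partner's fate.

*Breadth* is the fraction of genome positions with depth at or above a
threshold (default 1); *mean depth* is averaged over covered positions
only, matching the threshold-based phrasing such platforms use
("breadth … with a minimum depth of …").

The bin-count matrix assigns each segment to exactly one bin — the bin
containing its leftmost aligned base. The alternative (counting a segment
in every bin it overlaps) would make row sums exceed read counts and
double-weight bin boundaries; with leftmost assignment each sample's row
sum equals its retained segment count, an invariant the tests check.

Correlations default to Spearman because per-sample yields vary severalfold
and rank correlation is insensitive to that scale; Pearson is available.
Samples with constant bin counts have no defined correlation: they are
flagged, `NA`-masked, and excluded from the average-linkage clustering used
for display order. The PCA uses `log1p` counts, bin-centered and unscaled:
unscaled because bins are on a common scale and scaling would inflate
empty-bin noise; `log1p` because raw counts are dominated by a few
high-coverage bins.

*Common sites* are positions covered at least once (configurable) in every
sample of a group — the loci genotypable across that group. The
batch-effect estimator compares experimental pools with *artificial* pools
built by drawing `k` samples from each experimental pool without
replacement, so each sample is used exactly once and the artificial pools
are exchangeable across batches. Significance uses a paired two-sided
t-test at α = 0.01 across pools; the platform literature reports
"α < 0.01, n = 8" without naming a test, and the paired t-test is the
natural choice for n paired pool-level counts.

## Variant summarization

Microsatellite detection follows the MISA thresholds: minimum 10 repeat
units for mononucleotides, 6 for dinucleotides, 5 for motif lengths 3–6.
Motifs are required to be irreducible (no `ATAT` unit — it is `AT`), which
also suppresses longer-motif calls wholly explained by a shorter motif.
Imperfect (Weber-style interrupted) repeats are formed by merging runs of
the same motif separated by at most 4 bp of called sequence — the cited
criterion has no single operational rule, so this default is configurable
and flagged in the output. Two guards keep the merge rule from
manufacturing repeats: each merged run must carry at least half the
threshold on its own (otherwise the two-copy `AA` inside every `AACCT`
unit would chain into a spurious poly-A), and a gap containing `N` breaks
the chain. Motifs are reported as found, without reverse-complement
merging, because published motif tables list `AG` and `CT` separately.

InDels are labeled microsatellite-associated by embedding each allele in
its flanking genomic context (default 50 bp), scanning with the same
detector, and checking for a repeat overlapping the allele. The published
pipelines feed called InDels to a microsatellite finder without describing
the exact sequence context; flank-embedding is one defensible reading and
is documented as such.

Filtering mirrors the conventional phrasing exactly: missingness is a
*strict* upper bound ("< 5% missing") and MAF an *inclusive* lower bound
("MAF ≥ 1%"). Missing fractions are computed over all samples from the
missing count directly (not as `1 − called/n`, which perturbs exact
boundary fractions in floating point). MAF defaults to the frequency of
the second-most-frequent allele among called alleles, with
`one_minus_major` available for multiallelic sites. Half-calls are treated
as missing. Deletions and insertions are classified per alternative
allele, so a triallelic InDel can contribute one of each — matching how
alternative-allele accounting is done in the platform literature.

## The synthetic world

The generator's defaults are the platform's stated conditions wherever they
are stated: 8 pools × 24 samples, per-sample read-pair yields with a 28.14%
coefficient of variation, 225-b post-trim reads, a 300–400 bp window, and a
pool-level batch effect. Where a value is not stated, it was chosen once on
realism grounds and not revisited:

* **Genome 1 Mb, 2 chromosomes** (not 230 Mb): the synthetic module exists
  to make analyses testable at desk scale; locus and variant counts are
  scaled per Mb (280 loci/Mb is the density implied by 63,730 loci on
  230 Mb) and the per-sample yield default (4,500 pairs) preserves the real
  platform's ~16 read pairs per windowed locus.
* **Gamma-distributed yields**: positive, right-skewed, and parameterized
  directly by mean and CV, the two quantities actually reported.
* **Batch effect as a size-window shift** (+20 bp for the second batch of
  pools): the platform's hypothesized mechanism — manual versus automatic
  size selection between experiments — made concrete. Planted locus lengths
  extend 100 bp beyond the window on each side so a shift genuinely changes
  the captured locus set; with shift 0 samples are exchangeable across
  pools, which is what gives the pool test its type-I control.
* **Hotspot as a tandem-repeated insert** whose reads are all placed at the
  first copy's coordinates: a multi-mapping proxy for an organellar-homolog
  region that accumulates ~10× the average bin count, without simulating an
  organellar genome or an aligner.
* **SNP transitions drawn with probability 0.571**, giving Ts/Tv ≈ 1.33,
  the ratio typical of peach SNP sets; MAF from `0.5·Beta(0.8, 2.5)` (many
  rare alleles, some common); missingness Bernoulli at 1.33% per genotype,
  optionally scaled inversely to realized yield.

Background sequence is scrubbed of all accidental recognition sites before
features are planted, and the planted site table is verified against the
package's own site finder before the genome is returned — the truth tables
are exact by construction, not approximately true.

What the generator does **not** emulate: sequencing error and quality
scores, adapter/barcode structure, alignment ambiguity (beyond the hotspot
collapse), linkage between variants, and population structure among
samples. A green test therefore establishes that the *analysis* code is
correct on data with the assumed statistical structure — not that the
wet-lab protocol will reproduce that structure.

## Numerical choices and degenerate inputs

Ratios (Ts/Tv, Del/Ins) are rounded to two decimals as conventionally
printed; zero-transversion and zero-insertion inputs yield a flagged `NA`
rather than `Inf`. A chromosome with no cuts digests to a single
`CHROM_END`/`CHROM_END` fragment. The degenerate enzyme pair (E, E)
reproduces the single digest with E, and all its internal fragments are
class `AA`. All-missing variants are excluded from filtering and counted
separately. Sites-per-variant uses floor division, matching how the
published worked example (2,026,509 / 6,819 = 297) was computed. All
generator randomness flows from one design seed through fixed per-stage
offsets (genome +0, reads +1, genotypes +2), and the read/genotype stages
accept a seed override so replicate studies can redraw data over one fixed
genome.

## Known limitations

* Star activity, partial digestion, and methylation-dependent site masking
  are out of scope by design.
* The genome-scale check against the published in silico locus count
  (63,730 on GCF_000346465.2) requires the reference FASTA locally; whether
  that figure was computed on chromosomes only or including unplaced
  scaffolds is unstated, so `rank_pairs()` can be run on either selection
  and both should be reported when the assembly is available.
* Whether published bin-count correlations used raw or normalized counts is
  unstated; the package computes them on raw counts, with Spearman as the
  default precisely so the answer is insensitive to per-sample scale.
* The range reported for merged mean depth ("7× to 27×") has no stated
  unit; `coverage_summary()` returns per-chromosome rows so users can take
  either reading.
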