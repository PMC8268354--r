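---
title: "Mapping a WZ/ZZ sex-determination candidate from gene-copy mixtures"
author: "wzkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a WZ/ZZ sex-determination candidate from gene-copy mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wzkit)
```

## The inference problem

In female-heterogametic (WZ/ZZ) fish, a candidate master sex-determining
gene is often an extra, structurally divergent copy of an ordinary gene that
resides only on the W chromosome. The *banf2* locus of *Oreochromis* cichlids
is the motivating case: females carry a W-linked copy (*banf2w*) with a
one-residue deletion and a handful of substitutions, alongside two to four
standard copies. Establishing such a candidate requires a chain of
inferences, each of which this package implements as a tested, reusable
operation:

1. **Copy-number proportions from composite Sanger chromatograms.** PCR over
   a multi-copy locus superimposes the traces of all copies; the peak-height
   mixture at sites where copies differ reveals their relative copy numbers.
2. **Integer copy-ratio models.** A ~25% W-specific signal reads as a 3:1
   standard-to-W configuration, ~33% as 2:1, ~20% as 4:1.
3. **Exact marker–sex association.** Genotype-by-sex tables are tested with
   Fisher's exact test (2×2) or its Freeman–Halton generalization (r×2),
   and the critical region is delimited by the flanking markers around the
   maximally associated block.
4. **Inheritance-model goodness of fit.** The observed all-heterozygote
   female distribution is compared against autosomal Hardy–Weinberg,
   lethal-WW, and female-determining-W expectations.
5. **Gene-structure validation** (exon/intron arithmetic, GT..AG splice
   sites, CDS translation, polyadenylation signals) and **windowed
   divergence** between W-copy orthologs.
6. **Expression quantification** by exact 32-mer probe matching with an
   FPKM transform and a minimum-read detection threshold.

A seeded synthetic-data generator produces every input the chain consumes,
so the whole pipeline is testable without any external download.

## The trace-decomposition model

A chromatogram window is a matrix $H \in \mathbb{R}_{\ge 0}^{L \times 4}$ of
peak heights over $L$ positions and the four base channels. Under the linear
mixture model, a set of candidate haplotypes with copy numbers $w_h$
generates

$$H_{ic} \;=\; g \sum_h w_h\, \mathbb{1}[\text{haplotype } h \text{ has base } c
\text{ at position } i] \,(1 + \varepsilon_{ich}),$$

with gain $g$ and multiplicative noise $\varepsilon$. Haplotypes are
anchored at the window start *in their own coordinates*: an internal
deletion shifts every downstream base of that haplotype, so all
post-deletion positions become informative mixed peaks. This is precisely
the mechanism that makes decomposition of a deletion-bearing W copy
powerful — a single 3-base deletion turns the whole downstream window into
signal.

`build_signatures()` encodes the candidates as a binary design matrix $S$
over (position, channel) rows; `decompose_trace()` fits $H$ (flattened) on
$S$ by non-negative least squares and normalizes the weights to mixture
proportions, in the style of trace-decomposition tools of the TIDE family.
Fit quality is $R^2 = 1 - \mathrm{SSR}/\mathrm{SST}$ (SST about the mean
height, clamped to $[0,1]$); decompositions below an $R^2$ of 0.9 (the
`r2_threshold` pipeline default) should be treated as unusable. Haplotypes
identical over the window (e.g. the standard Z-linked copies away from
their diagnostic SNP) yield identical columns; they are merged by
`collapse_signatures()` and reported as one group, since only the group
proportion is identifiable. Forward and reverse sequencing orientations are
decomposed separately and combined by an unweighted mean (the conservative
minimum is kept for $R^2$); `peak_ratio()` provides the complementary
single-site estimator used at diagnostic SNPs.

For a noiseless trace from identifiable signatures NNLS recovery is exact
to machine precision (a property the test suite asserts, together with
scale invariance and agreement with an exhaustive simplex grid search on
small instances).

## Integer copy models

`infer_copy_ratio()` maps an estimated W-specific fraction $f$ to the
integer pair $(\mathrm{major}, \mathrm{minor})$, $\mathrm{major} +
\mathrm{minor} \le 5$, minimizing $|\mathrm{minor}/(\mathrm{major}+
\mathrm{minor}) - f|$; ties resolve toward the smaller total, then the
smaller minor count. The bound of five copies reflects the observed range
of two to five copies per diploid genome at this locus. Note that reducible
ratios are returned in reduced form (a fraction of 0.5 reads as 1:1, never
2:2). `enumerate_models()` expands a ratio into per-chromosome gene
configurations: the W chromosome carries the W-specific roles (*banf2w*
and, when present, *banf2c*), and each Z carries the standard copy with an
optional duplication (*banf2b*). `classify_individual()` glues estimation,
ratio inference and enumeration, flagging individuals whose W-specific
signal contradicts their phenotypic sex (threshold 0.10, chosen halfway
between noise level and the smallest true W fraction of 0.20).

## Exact association and inheritance statistics

`fisher_exact_2x2()` and `fisher_exact_rxc()` implement the two-sided
point-probability method: all tables with both margins fixed are
enumerated, and the p-value sums the probabilities of tables no more
probable than the observed one, with a relative tie tolerance of $10^{-7}$.
Enumeration is exact and feasible for the r×2 tables that occur in
marker-association scans (up to eight genotype rows). The test suite checks
the implementation against an independent brute-force enumeration and
against `stats::fisher.test`.

`association_scan()` assembles per-marker genotype-by-sex tables (dominant
markers collapse to presence/absence first), applies the matching exact
test and reports a critical interval: the span between the nearest markers
that flank, on either side, the block of maximally associated markers. We
chose the *nearest-flanking* rule rather than "outermost significant
marker" because a distant marker can be strongly yet imperfectly associated
(long-range linkage) without delimiting the candidate region; the flanking
markers with measurably weaker association are what bound it.

Inheritance models for the female genotype distribution use allele
frequencies $p$ (Z) and $q$ (W), by default $0.5$ each, as the design
implies for a WZ mother:

| model | ZZ | WZ | WW |
|---|---|---|---|
| autosomal (HWE) | $np^2$ | $2npq$ | $nq^2$ |
| lethal WW | $np^2/(1-q^2)$ | $2npq/(1-q^2)$ | 0 |
| female-determining W | 0 | $n$ | 0 |

`gof_pearson()` computes the Pearson statistic over cells with positive
expectation; observed counts in a zero-expectation cell reject the model
outright ($p = 0$), and the degrees of freedom count only supported cells
minus one. `hwe_deviation_test()` estimates $q$ from the counts and uses
one degree of freedom (three classes, one estimated parameter) — the
standard convention. The published lethal-WW goodness-of-fit value is not
recoverable from the stated expectations under any Pearson convention we
examined; the package reports the defined Pearson value ($\chi^2 = 24$,
df 1) and the discrepancy is documented here rather than hidden.

## The synthetic-data generator

`sim_config()` fixes the study conditions: 48 phenotypic females and 48
males sampled case-control style by sex; a sex-reversal rate of $1/96$
(about one discordant individual expected per cohort of 96, matching the
single-mismatch association tables the design anticipates); chromatogram
noise with a 5% coefficient of variation (no empirical noise magnitude is
available for these instruments, so 5% was fixed once as a realistic
capillary-trace figure and downstream tolerances treat trace-derived
targets as stochastic); gain 100 signal units per copy. Markers are
inherited through the maternal W or Z with a per-marker recombination
fraction; the paternal allele is always Z-linked.

What the generator emulates: multi-copy mixtures with W fractions near 1/3,
1/4 and 1/5; deletion-induced downstream peak mixing; cohorts under a WZ/ZZ
model with recombination leakage and rare sex reversal; read libraries with
exactly planted 32-mer probe occurrences (background reads are
rejection-sampled to exclude every probe in both orientations, so planted
counts are exact ground truth). What it does not emulate: electrophoresis
physics (dye blobs, mobility shifts), base-calling error profiles,
sequencing quality decay, real genome context around the locus, or linked
marker–marker correlation beyond shared descent from the SD locus. Passing
tests therefore demonstrate correctness of the inference chain under the
linear mixture model and the stated sampling design, not robustness to
instrument artifacts.

All generators draw from deterministic sub-streams derived from (seed,
operation), so identical configurations are byte-identical across runs and
call orders, and the caller's RNG state is never disturbed.

## Numerical choices and degenerate inputs

- Coordinates are 1-based inclusive throughout; an alignment window of
  2261–2438 spans 178 columns.
- Windowed divergence counts substitution columns plus maximal gap runs
  (an indel of any length is one event); columns gapped in both sequences
  are padding and count as nothing. The utility aligner scores match +1,
  mismatch −1, linear gap −2; under linear gap penalties optimal alignments
  can tie, so supplied (fixed) alignments are preferred for reproducible
  divergence values.
- Overlapping polyadenylation-motif hits are counted; the count is
  invariant under appending non-matching sequence.
- Exact tests: empty margins are untestable and return $p = 1$ with a
  warning; r×2 enumeration beyond eight rows raises a capability error
  rather than approximating.
- Decomposition: an all-zero trace, a window past a haplotype's shifted
  end, and unmerged identical signature columns are all explicit errors
  (the latter instructing to call `collapse_signatures()`).
- FPKM uses the probe length (32 bp) as the feature length — the only
  length available under probe-based counting. Absolute values therefore
  differ from transcript-length FPKM by a constant factor per probe;
  within-probe comparisons across libraries, and the detection threshold
  of three reads, are unaffected.
- No multiple-testing correction is applied in association scans; raw
  exact p-values are reported, as is conventional when a handful of
  physically clustered candidate markers is tested.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic data
at deliberately modest sizes chosen once for statistical adequacy: 297-bp
decomposition windows, cohorts of 96 (with 2,000 for recombination-recovery
checks), 200-replicate Monte-Carlo loops for unbiasedness and model
recovery, 400-replicate null calibrations, and read libraries of a few
hundred reads with planted counts below ten.

## Known limitations

- Proportions of haplotypes indistinguishable in the window are only
  identifiable as a group; choosing a window that covers a diagnostic site
  is the user's responsibility (`build_signatures()` flags the problem).
- The classifier resolves ZZ copy number only when an informative-site
  ratio is supplied; without it, two copies are assumed.
- The Freeman–Halton implementation is limited to two-column tables, the
  shape that arises in sex-association scans.
- Physical ordering and orientation of gene copies on a chromosome are not
  modelled, only their counts and chromosome of residence.
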