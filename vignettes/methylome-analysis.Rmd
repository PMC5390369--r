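---
title: "Sliding-window methylome analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sliding-window methylome analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(methwind)
library(dplyr)
```

`methwind` analyses whole-genome bisulfite sequencing (WGBS) data starting
from per-cytosine count tables — the Bismark-style cytosine report with a
methylated and an unmethylated read count per reference cytosine. This
vignette explains the statistical model behind each stage, the parameters
that matter and their defaults, what the built-in simulator does and does
not emulate, and the design decisions taken where the methodology is
genuinely open.

## The count model

Bisulfite treatment converts unmethylated cytosines to uracil (read as T)
while 5-methylcytosine resists conversion. After alignment, each reference
cytosine *i* carries a methylated count $S^+_i$ and an unmethylated count
$S^-_i$. The package models the methylated count as a binomial random
variable,

$$S^+_i \sim \mathrm{Bin}(S^+_i + S^-_i,\; r_i),$$

with $r_i$ the per-site methylated-read rate. The *methylation level* of a
site is the observed fraction

$$\mathrm{ML} = \frac{S^+}{S^+ + S^-},$$

undefined (not zero) when coverage is zero; uncovered sites are excluded
from every summary.

### Contexts

Plant methylation is context-stratified: CG, CHG and CHH (H = A, C or T),
determined by the two bases downstream of the cytosine in its strand's
5'→3' direction. `classify_contexts()` scans both strands — every C on the
plus strand, and every G on the plus strand read as a C on the reverse
complement — and emits the trinucleotide and context per site. Sites whose
downstream bases run off the chromosome or contain an ambiguity code get
context `"unknown"` and are excluded downstream. CG sites are reported per
strand because the two strands of a CpG dyad are sequenced independently;
`merge_cg_strands()` pools the symmetric pair when a dyad-level view is
wanted, but nothing in the pipeline assumes pooling.

### Non-conversion correction

A fraction $r$ of truly unmethylated cytosines escapes conversion and
reads as methylated. $r$ is estimated from the unmethylated lambda phage
spike-in as the pooled methylated fraction over all lambda cytosines
(`estimate_nonconversion()`). Under the one-parameter contamination model
the observed level of a site with true level $p$ has expectation
$p + (1 - p)\,r$, and

$$\mathrm{ML}_{\mathrm{corr}} = \frac{\mathrm{ML} - r}{1 - r}$$

inverts it exactly in expectation; values are clamped to $[0, 1]$. The
clamp introduces a tiny upward bias at sites whose raw level falls below
$r$, negligible at the coverages used here (the acceptance suite verifies
recovery of the true rates to within three standard errors at 30×).

### Calling methylated sites

The null hypothesis for a site is "fully unmethylated, every
methylated-looking read is a conversion failure": $S^+ \sim
\mathrm{Bin}(S^+ + S^-, r)$. `call_methylated_sites()` computes the
one-sided tail $P[X \ge S^+]$, adjusts across sites with
Benjamini–Hochberg, and calls a site methylated at $q \le \alpha$
(default 0.05). The literature this pipeline follows does not state the
null rate, the sidedness or the multiple-testing method for the site test;
taking the global non-conversion rate as the null rate with a one-sided
tail and BH correction is the standard Lister-style choice, and all three
are exposed as arguments rather than hard-coded.

## Sliding windows

Methylation levels are noisy at single sites, so counts are pooled in
sliding windows: **3,000 bp windows stepped by 600 bp** for
methylation-level tracks (`window_ml()`), and **1,000 bp windows stepped
by 100 bp** for differential testing (`window_pair_counts()`,
`detect_dmrs()`). Pooled window ML is the ratio of summed counts — exactly
`compute_ml()` applied to the sums, a property the tests assert. Windows
are 0-based half-open internally; the cytosine-report interface stays
1-based (Bismark dialect).

## DMR detection

For two conditions A and B, each window and context scope yields a 2×2
table of pooled counts $[[S^+_A, S^-_A], [S^+_B, S^-_B]]$, tested with the
**two-sided Fisher exact test**. The implementation enumerates the
hypergeometric distribution directly (summing all tables with probability
at most the observed one, with the conventional $1 + 10^{-7}$ tie guard)
so that tens of thousands of windows can be tested without per-window
overhead; the test suite checks it against `stats::fisher.test()` to
$10^{-12}$. Windows with fewer than 10 pooled reads in either condition
are skipped — a test on near-empty windows is vacuous.

Window p-values are BH-adjusted; significant windows ($q \le 0.05$) of the
same scope that overlap (or sit within `max_gap` bases; default 0) merge
into a DMR. The merged region re-pools counts over its whole interval and
recomputes the Fisher p-value, the per-condition levels, the signed
difference $\Delta\mathrm{ML} = \mathrm{ML}_B - \mathrm{ML}_A$ and the
direction (hyper = B above A, so swapping the condition order flips every
label — also asserted by the tests). The merging rule is the package's own
choice: the sliding-window DMR tools this follows do not document their
merge internals, so the simplest reproducible rule (union of significant
windows) was adopted and exposed as configuration. Because windows
overlap by 900 bp at the default step, a called DMR extends beyond a true
differential interval by up to roughly one window width on either side;
with 2 kb planted DMRs this still yields reciprocal overlap above 50%,
which is the recovery criterion the acceptance suite uses.

A note on screening direction: the source literature's text mentions
screening DMRs "with a corrected p-value ≥ 0.05" in one passage; that
contradicts standard significance screening and is treated as a typo —
selection here is $q \le \alpha$.

## Gene-element metaprofiles

Each instance of a gene element (promoter, exon, intron) is scaled to
**20 equal bins** in the gene's 5'→3' orientation; minus-strand instances
are reversed so bin 1 is always the TSS-proximal end. A site's single-base
position is distributed over the bins it overlaps with fractional weights
(for elements shorter than 20 bp a base spans several bins; the weights of
all positions always sum to the element length). The bin value is the
weighted mean corrected ML of covered sites of the requested context; the
profile is the mean over instances. Promoters are defined as **2,000 bp
upstream of the TSS**, strand-aware — the convention in plant epigenomics;
the span is configurable because the source methodology never defines it.

Expression is normalised per gene as
$\mathrm{FPKM}_{\mathrm{log\_ratio}} =
\log_{10}(\mathrm{FPKM}) / \log_{10}(\max \mathrm{FPKM})$, which maps the
most expressed gene to 1 and FPKM = 1 to 0; it requires
$\max(\mathrm{FPKM}) > 1$ and leaves non-positive FPKM undefined.

## Sequence preference

`split_high_low()` classifies sites as high-methylation by **strict**
thresholds — ML > 0.75 in CG context, ML > 0.25 in CHG/CHH — applied to
the corrected ML (whether raw or corrected levels feed the thresholds is
unstated in the source methodology; corrected is used here and the column
is an argument). `extract_flanks()` returns the $2k+1$-mer centred on each
cytosine in its strand's orientation, and `build_pfm()` tabulates
per-offset base frequencies and information content $2 - H$ bits (offset 0
is C by construction, IC = 2). The pseudocount defaults to 0: raw
frequencies are reported, and logo rendering (`autoplot()`) is cosmetic,
not part of the tested core.

`predict_cpg_islands()` mirrors the classic Gardiner–Garden criteria —
size > 100 bp, GC > 50%, observed/expected CpG > 0.6 with
$\mathrm{O/E} = \#\mathrm{CG} \cdot L / (\#\mathrm{C} \cdot \#\mathrm{G})$
— using a 200 bp scanning window whose passing positions merge into
maximal runs; the criteria are stated in the source, the scan procedure is
not, so the classic one is used.

## The simulator, and what passing tests mean

`simulate_methylome()` generates the study the tests run on: i.i.d. bases
at a configurable GC fraction, a lambda contig simulated fully
unmethylated, non-overlapping gene models with strand-aware promoters and
exon/intron structure, and per-cytosine counts drawn from the exact model
the pipeline assumes — Poisson coverage (mean 30 by default, matching a
typical WGBS design; uncovered sites are emitted with 0/0 counts), true
rates per context (defaults CG/CHG/CHH = 0.6/0.5/0.2, in the range
reported for symmetric vs asymmetric contexts in plant leaf tissue),
planted DMR intervals that shift the rate by a signed delta in the
stressed condition only (giving unambiguous hyper/hypo truth), and
non-conversion as a per-read false-methylation event on unmethylated
cytosines at rate 0.005 by default (a typical spike-in figure; the source
does not report its own). Optional knobs plant a promoter CHH elevation
and a TSS→TES gradient to validate metaprofile orientation.

This means passing tests show *internal consistency*: the estimator
inverts the generator. Real WGBS data violate the generator in known ways
— coverage is overdispersed and GC-biased, methylation is spatially
autocorrelated beyond planted blocks, contexts cluster in repeats,
sequencing and mapping errors are absent, and true DMRs have soft edges.
Recovery rates measured here are therefore upper bounds on real-data
performance, not estimates of it.

## Null calibration design

Two different window designs measure type-I behaviour, deliberately:

* the raw Fisher type-I fraction is measured on **non-overlapping** 1 kb
  windows (2,000+ of them, pooled over four 500 kb chromosomes at 10×),
  because the binomial 3-s.d. band around 0.05 is only valid for
  independent tests — overlapping windows share 90% of their counts;
* the end-to-end false-positive check (no DMRs after BH on identical-rate
  conditions) runs the **default overlapping** design over 20 seeded
  replicates, since that is what users run; the window correlation makes
  BH conservative there.

Fisher's exact test is discrete and slightly conservative, so the raw
fraction sits a little below 0.05; both effects are visible in the
acceptance output. The replicate check is itself a Bernoulli experiment
whose expected zero-DMR fraction is about $1 - \alpha$; individual seeds
can land at 18–20 of 20.

## Numerical and degenerate-input conventions

Zero-coverage sites are `NA`, never 0. Empty chromosomes emit zero
windows. `correct_ml()` refuses $r \ge 1$; `estimate_nonconversion()`
refuses zero total coverage; `fisher_window_test()` refuses negative
cells and returns 1 for degenerate margins. All randomness in the
simulator flows from a single integer seed and the RNG state of the caller
is restored, so identical configurations give byte-identical tables and
files. Reported percentages are rounded half-up to two decimals (the
convention of the summary tables this mirrors) with unrounded values kept
alongside.

## Problem sizes used in the checks

The test and acceptance suites simulate 50 kb–2 Mb genomes at 10–30×
coverage: large enough that pooled fractions sit within three binomial
standard deviations of truth and that a 1 Mb genome yields ~10,000 DMR
windows, small enough that the whole suite runs in a few minutes on one
core. These sizes are the package's validation design, chosen once.

## A worked run

```{r example, fig.width = 6, fig.height = 3.5}
cfg0 <- sim_config(genome_length = 100000, n_chromosomes = 1,
                   coverage_mean = 20, seed = 7)
genome <- simulate_genome(cfg0)
planted <- plant_dmrs(genome, 2, width = 2000, context = "CG",
                      delta = c(0.3, -0.3), seed = 8)
cfg <- sim_config(genome_length = 100000, n_chromosomes = 1,
                  coverage_mean = 20, planted_dmrs = planted, seed = 7)
sim <- simulate_methylome(cfg, n_genes = 8)

report <- run_methylome_pipeline(sim$counts, annotation = sim$annotation)
report
glance(report)
tidy(report$dmrs[[1]]) |> select(chrom:scope, delta_ml, direction, qvalue)
autoplot(report$profiles$control)
```

## Known limitations

The simulator's independence assumptions (above) are the main one. The
DMR caller tests each context scope separately and does not model
spatial smoothing within windows; boundary precision is limited to the
window step. The site caller's null uses a single global non-conversion
rate, not per-sample per-strand rates. GO/KEGG interpretation of DMR gene
lists, read-level processing and alignment are out of scope: the package
starts from count tables.
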