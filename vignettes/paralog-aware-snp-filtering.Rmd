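---
title: "Paralog-aware SNP filtering: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paralog-aware SNP filtering: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralogsift)
```

## The problem

In a genome with residual tetraploidy, a fraction of loci exists in two
near-identical copies. Short reads from both copies co-align, so a fixed
difference between the copies looks like a heterozygous SNP — in *every*
individual. Two classes of such artifacts matter here:

* a **PSV** (paralogous sequence variant): a fixed difference between the two
  copies; the collapsed locus shows a roughly 50/50 allele mixture in all
  samples;
* an **MSV** (multisite variant): a variant segregating on one of the copies;
  carriers show a mixture whose alternate fraction depends on their genotype
  at that copy (about 1/4 for heterozygotes, 1/2 for homozygotes of the
  variant copy).

A **doubled haploid** (DH) individual carries a doubled single gamete and is
homozygous at every single-copy locus, so called heterozygosity in DH lines is
a direct read-out of collapsed duplication. Rare **residual maternal
heterozygosity** (retained maternal chromatin in an otherwise doubled paternal
genome) means a *single* DH heterozygote is not conclusive; requiring at
least two DH heterozygotes (`Het > 1`) is the operating point this package
defaults to.

## The filter cascade

`apply_filter_cascade()` applies four site filters in a fixed order, with
per-stage accounting; `dh_screen()` is the fifth stage. All five are pure
per-site predicates given fixed masks and indel positions, so the surviving
*set* does not depend on the order — only the ledger's per-stage attribution
does.

| stage | rule | default |
|---|---|---|
| QUAL | bi-allelic SNP, `QUAL > min_qual`, no indel anchor within `indel_distance` bp | 30; 4 bp |
| LC   | site not in a low-complexity mask | DUST window 64, threshold 2 |
| DP   | summed read depth over samples `<= max_depth` | 1,500 |
| NS   | callable genotypes in `>= min_samples` samples | 58 of 61, i.e. `ceiling(0.95 n)` |
| DH   | fewer than `threshold` DH heterozygotes | 2 |

Boundary conventions that matter and are pinned by tests: `QUAL = 30` fails
(strict inequality); an indel exactly 4 bp away disqualifies (inclusive
distance on the indel's VCF anchor position); depth exactly 1,500 passes;
57 callable samples fail. The indel-proximity test uses the anchor base
rather than the full REF span — the conservative reading was *not* chosen
here because anchors are what both callers report uniformly; the width of the
exclusion window is configurable.

**Genotype rule.** A heterozygote needs at least two alternate-supporting
reads and one reference read. Only the heterozygote rule is externally
specified; homozygotes are defined symmetrically (at least two reads of the
observed allele and zero of the other) so the function is total: anything
else is missing. Whether the callers' own GT fields are kept or re-called
from AD is a flag (`recall` in `apply_filter_cascade()`); re-calling is the
default because it makes the NS stage independent of caller-specific GT
heuristics.

**Low-complexity masking.** `dust_mask()` scores every 64-base window by its
trinucleotide composition, `sum(c_i (c_i - 1) / 2) / (w - 3)`: 0 for a
perfectly triplet-diverse window, ~0.5 for random sequence, 15.25 for a
dinucleotide repeat, 31 for a homopolymer. The threshold of 2 sits an order
of magnitude above random sequence and far below any simple repeat, and with
the simulator's default repeat-tract load it masks about 10% of the genome —
the share the filter is meant to remove in a salmonid assembly. Windows are
merged, and `N` runs are always masked. This is a DUST-*style* scorer, not a
reimplementation of any specific masking binary; its role (deterministic,
composition-based masking) is what the LC filter needs, and an external BED
mask can be supplied instead.

## Two-caller concordance

Call sets are keyed by (chromosome, position). Shared positions with equal
ALT form the trusted core; unequal ALT (including the rare REF-representation
mismatch) is `same_site_diff_alt`. Two percentages are reported with fixed
denominators: the same-ALT share of the *combined* set (all four categories)
and the different-ALT share of the *shared* sites. Both use round-half-even
at the conventional precisions (integer; three decimals). `run_pipeline()`
intersects first and then filters; per-caller filtering before comparison is
available by running `apply_filter_cascade()` on each set and then
`classify_sites()`, since each stage is exposed as a plain function.

## The Hardy–Weinberg exact test

With 4–12 fish per population, a chi-square HWE test is useless, so the
package implements the conditional exact test: given the minor allele count,
heterozygote counts of the same parity are enumerated, their probabilities
computed by the standard mode-anchored recurrence
`P(h+2)/P(h) = 4 hom_r hom_c / ((h+1)(h+2))` and normalised, and the
two-sided p-value sums all outcomes no more probable than the observed one
(with a `1e-7` relative tolerance absorbing floating-point ties between
symmetric configurations). `hwe_het_distribution()` exposes the conditional
distribution; the test suite verifies both against a direct log-factorial
multinomial enumeration for every genotype table with up to 200 individuals.

## The threshold sweep

`threshold_sweep()` reports, for every minimum DH heterozygote count `k`, the
flagged-locus count, the mean observed heterozygosity among the 50 outbred
fish, and the percentage of flagged loci with exact-test `p < 0.05`. On both
real and simulated data the pattern is: counts fall with `k`, outbred
heterozygosity and HWE deviation rise — high thresholds isolate the cleanest
PSVs but miss most of them, which is why the default stays at 2.

## The synthetic study

`sim_config()` defaults define the study conditions:

* **Genome**: two chromosomes, four arms (70 + 80 and 70 + 60 kb, 280 kb
  total), with the two p-arms a duplicated pair diverged at 0.005/bp — those
  fixed differences *are* the planted PSVs, mirrored at both copies.
  Low-complexity tracts (rate `3e-4`/bp, mean 200 bp) cover ~6% of the
  genome directly and ~10% after the masking window's flank extension.
  Indels at `2e-4`/bp exercise the proximity filter.
* **Samples**: 11 DH lines, seven populations of four fish, one of ten, and a
  12-fish aquaculture population (61 total). Outbred genotypes are
  Hardy–Weinberg draws at population frequencies obtained from a
  Balding–Nichols Beta around the ancestral frequency (`Fst = 0.1`);
  ancestral frequencies are Beta(0.4, 0.4); DH lines are doubled gametes with
  residual heterozygosity 0.005 per line per site.
* **Reads**: per-sample mean coverage is 8 + Gamma (mean 15, minimum 8,
  matching the sequencing design); site depths are Poisson; allele counts are
  binomial. The per-read miscall rate defaults to `5e-4` — a
  post-base-quality-filtering figure (callers here require base quality >= 20
  and most retained bases are better) — and a miscall lands on one specific
  other base a third of the time. This matters because the genotype rule
  calls a heterozygote from a *single* stray reference read on a hom-alt
  background plus two alternate reads; an error model that funnels all
  miscalls into the reference allele would overstate DH false flags several-fold.
* **Collapsed loci**: at PSV/MSV sites, reads split between the two reference
  copies (depth stays ~1x) and a per-locus cross-mapping fraction
  `m ~ Beta(2, 2)` sets the mixture: alternate fraction `m` at PSVs, `m g2/2`
  at MSVs with copy-2 genotype `g2`. The broad Beta matters: real flagged
  loci are heterogeneous (their observed heterozygosity climbs smoothly with
  the DH threshold rather than jumping), and the heterogeneity is what
  spreads DH heterozygote counts over the whole 0..11 range. MSV allele
  frequencies are Beta(3, 1): variants segregating at low frequency on a
  duplicated copy are essentially invisible to a 61-sample panel, so the
  generator concentrates on the detectable class.
* **Callers**: each caller independently drops 8% of sites, adds false unique
  sites at 3.2% of the truth count, and caller B swaps the ALT at 0.2% of its
  sites; 5% of QUAL draws fall below 30. These defaults were derived
  analytically from the target concordance: the expected same-site-same-ALT
  share of the combined set is `(1-d)^2 (1-a) / ((1-d^2) + 2f) = 0.80`.

With a fixed seed the whole simulation is byte-deterministic, including the
files `simulate_study(..., outdir = )` writes.

**What the simulator does not model**: real read alignment (mismapping is
summarised by the cross-mapping fraction, not simulated), base-quality
structure, linkage between sites, copy number above two, demographic history,
and reference errors. Passing recovery tests therefore demonstrates that the
*filters and statistics* behave correctly under the study's assumptions, not
that those assumptions hold in any particular real data set.

## Numerical and reporting conventions

* VCF positions are 1-based; BED masks 0-based half-open; a site at position
  `p` is masked iff `start <= p - 1 < end`.
* Integer SNP spacing is truncated, `floor(length / n)` — rounding is ruled
  out by standard published tables where a ratio of 52.79 prints as 52 — and
  the SNPs-per-kb figure is `round(1000 / rate, 1)`.
* Percentages use round-half-even (base `round()`): integer percents for
  table shares, three decimals for the small different-ALT share, two
  decimals for MAF/heterozygosity means.
* Windowed nucleotide diversity uses the unbiased per-site estimator
  `(n/(n-1)) 2p(1-p)` with `n` the called allele count, accumulated per
  window and divided by the window width; trailing partial windows are
  normalised by their true width; empty windows contribute 0 to the genome
  mean.
* Monomorphic HWE input gives `p = 1`; sites with no called genotypes give
  `NaN` heterozygosity and are dropped from means via `na.rm`.

## Problem sizes used in the tests

The test suite runs the full pipeline on the default 280-kb genome with 61
samples (a few thousand candidate sites, seconds per run) and uses a 105-kb
variant of the same layout for unit tests. The exhaustive HWE verification
covers all genotype tables with up to 200 individuals by sweeping every
(sample count, minor-allele count) configuration. The diversity-recovery
check compares the windowed estimate from read-called genotypes against the
planted truth's per-bp diversity on the *complete* planted site set: the
cascade necessarily removes sites (caller intersection, masking), so post-QC
diversity understates the simulated value by construction in any pipeline,
and the recovery property is about the estimator and genotype calling, not
about the cascade's site loss.

## Effect annotation defaults

The annotator emits the 20-term Sequence Ontology scheme with fixed impact
tiers. Conventions the upstream annotation tools leave configurable are set
to: upstream/downstream distance 5 kb; splice donor/acceptor = first/last two
intronic bases; splice region = intronic bases 3–8 or exonic bases 1–3 from a
junction (emitted *in addition* to the coding consequence for exonic cases);
`splice_region_variant` is reported with LOW impact; alternative start codons
ATG/CTG/TTG are recognised, so a substitution converting one start to another
is `initiator_codon_variant` while any other change in the initiator is
`start_lost`. A 5'-UTR substitution that creates an ATG on the coding strand
within the UTR is a premature-start gain. One record is emitted per (SNP,
transcript feature), so effect counts exceed site counts, and
`intergenic_region` is the fallback ensuring every SNP has at least one
record.

## Known limitations

* The DH screen cannot separate PSVs from MSVs from higher-copy collapses;
  they are flagged as one class, as the screen's logic only sees DH
  heterozygosity.
* Multi-allelic records are carried through I/O but removed at the QUAL
  stage; no decomposition is attempted.
* The concordance module does not normalise haplotype representations across
  callers; representation differences surface as `same_site_diff_alt`.
* `missingness_accumulation()` attributes the intersection's callable-sample
  count using caller A's genotypes.
* The annotator handles single-base substitutions only.
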