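---
title: "Methods: population-scale SV merging, differentiation scans and phenotype bridging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-scale SV merging, differentiation scans and phenotype bridging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svpopscan)
```

svpopscan implements the analysis stack used in population surveys of
structural variants (SVs) called from long-read sequencing of two human
populations: turning noisy per-sample, per-caller call sets into one
nonredundant cohort call set, characterising the cohort SV landscape, and
scanning for population-differentiated variants with downstream
regulatory and phenotype context.  Because real cohorts of this kind are
controlled-access, the package ships a fully specified synthetic cohort
generator so that every stage is testable end to end against a known
truth table.

## Coordinates and containers

All internal coordinates are 0-based half-open; conversion to and from
the 1-based conventions of VCF happens only in the readers and writers
(BED is already half-open).  Insertions are points (`end == start`) with
the insert size carried in `length`; records of spanned types
(DEL/DUP/INV) keeps `length == end - start` as an invariant.  SV calls
are plain tibbles; genotypes live in a `genotype_matrix` (samples x
variants dosages 0/1/2 with `NA` for missing).  Two views of that matrix
coexist deliberately:

* **presence** (0/1, missing treated as absence) drives carrier
  frequencies, the frequency spectrum, saturation curves, PCA, trees and
  hotspots — the N x M presence matrix of the field's population
  analyses;
* **dosage** (with missing dropped pairwise) drives Hardy–Weinberg
  tests, F_ST and LD, matching how VCFtools/PLINK-style tools treat
  missing genotypes.

Partially genotyped calls (`./1`) are treated as missing.

## Consensus and nonredundant merging

Two SVs *match* when (i) they are the same type, (ii) every breakpoint
distance is below 1 kb (both breakpoints for spanned types, the
insertion point for insertions; a start-only mode is available), (iii)
spanned records overlap reciprocally by at least 40% of each span
(an either-span mode is available), and (iv) insertion lengths differ by
less than twice the shorter insertion.  The literal reading
`|L1 - L2| < 2 min(L1, L2)` is the default; because it is permissive, a
length-ratio alternative (`ins_rule = "ratio"`) is provided.  The
distance and overlap rules are applied conjunctively at every size.

Within one sample, calls from the three supported long-read callers are
clustered under this relation; a cluster is kept if two distinct callers
support it or if it contains a cuteSV call flagged high-quality, and the
emitted coordinates/genotype come from the highest-priority caller
(cuteSV > sniffles > nanovar).  Before consensus, raw calls are filtered
to read-support fraction > 0.3, depth < 2x the sample mean, and lengths
in [50 bp, 50 kb].

Across samples, merging is single-linkage (transitive) clustering over a
per-(chromosome, type) sweep sorted by start; the sweep window equal to
the 1 kb distance bound is sound because every match implies a start
distance below it.  Single linkage was chosen over greedy alternatives
because it makes the output an exact function of the match relation:
the partition provably equals the transitive closure of the all-pairs
match graph, which the test suite verifies against an independent
brute-force oracle (all pairs + connected components), and it is
invariant to sample and call order.  The cluster representative is the
member with the most caller support, ties broken by caller priority,
then smallest start, then record id; genotype conflicts within a cluster
resolve by caller priority, then the more-alternate genotype.  Merging
the merged representatives is a fixed point.

## Landscape statistics

Carrier ("SV") frequency is the proportion of samples carrying at least
one copy.  The spectrum uses the frequency levels (0, 0.1], (0.1, 0.4],
(0.4, 1) and the fixed class {1}, plus singleton counts.  Saturation
curves accumulate distinct SVs over random sample orderings.  GC content
is computed over the SV span (insertions: a +-150 bp flanking window)
with ambiguous bases excluded, and a >= 55% threshold defines high-GC
loci.  PCA is an SVD of the column-centred presence matrix with signs
fixed by the largest-magnitude loading, so scores are fully
deterministic; trees use Manhattan distance on presence rows with
average (or complete) linkage and are serialised as Newick.

The power-law fit of the frequency spectrum follows the
Clauset–Shalizi–Newman recipe: continuous maximum likelihood for the
tail exponent at each candidate cutoff, cutoff chosen by minimal
Kolmogorov–Smirnov distance, and a semi-parametric bootstrap
goodness-of-fit p (the fraction of synthetic data sets fitting worse
than observed; a large p means the power law is not rejected).  Candidate
cutoffs are thinned to at most 60 quantiles, which leaves the estimate
essentially unchanged while keeping the bootstrap affordable; the
discrete (zeta-style) estimator is available for count data.

Hardy–Weinberg testing uses the closed-form 1-df chi-square on genotype
counts without continuity correction — the chi-square approach named for
this analysis family — with Bonferroni correction across tested
(polymorphic) variants.  Its type-I error is verified to sit in
[0.03, 0.07] at nominal 0.05 in simulation.

## Weir–Cockerham F_ST

For two populations the per-site variance components are

$$a = \frac{\bar n}{n_c}\Big[s^2 - \tfrac{1}{\bar n - 1}\big(\bar p(1-\bar p) - \tfrac{r-1}{r}s^2 - \tfrac{\bar h}{4}\big)\Big],\qquad
b = \frac{\bar n}{\bar n - 1}\Big[\bar p(1-\bar p) - \tfrac{r-1}{r}s^2 - \tfrac{2\bar n - 1}{4\bar n}\bar h\Big],\qquad
c = \bar h/2,$$

with $\hat\theta = a/(a+b+c)$ per site and the cohort-wide **weighted**
estimate $\sum a / \sum(a+b+c)$ over defined sites — the headline
statistic, matching the "weighted" output of the standard VCFtools
implementation.  Monomorphic or under-genotyped sites (fewer than two
genotyped individuals in either population) are flagged undefined and
excluded from the sums.  A fixed difference between populations of ten
individuals each gives exactly $a = 0.5$, $b = c = 0$, $\hat\theta = 1$.
Note that a verbal description of F_ST as
$(H_T - \bar H_S)/H_T$ differs numerically from the Weir–Cockerham
estimator; the package defaults to Weir–Cockerham and offers the
Hudson-style form via `method = "hudson"` rather than guessing intent.

Population-specific SVs require three criteria in one direction: focal
carrier frequency at least 0.2, at least twice the other population's
frequency (a zero denominator counts as satisfied), and F_ST strictly
greater than 0.1.  "Population frequency" here is carrier frequency —
the package's SV-frequency definition — not allele frequency.

## Hotspots, density and enrichment

Binned density counts SV midpoints (insertion points for INS) in 500 kb
bins, per type and per annotation track, keeping the last partial bin.
Hotspot detection evaluates a Gaussian kernel density (bandwidth
200 kb, the hotspotter-style setting) of midpoints on a 10 kb grid per
chromosome, scaled to events per bp.  The null re-places the same number
of midpoints uniformly on the chromosome 1,000 times (200 in the fast
presets); the threshold is the 95th percentile of the null per-trial
*maximum* density, a family-wise choice made because the original tool's
null is not fully described — a pointwise-quantile mode is provided.
Correction is per chromosome.  Hotspots are maximal grid runs above
threshold with an empirical p of $(1 + \#\{\text{null max} \ge
\text{peak}\})/(\text{trials}+1)$.  Under a uniform null the family-wise
false-positive rate stays at or below the nominal 5%, and an implanted
50-event/100 kb cluster is found in over 90% of seeds.

Track enrichment compares the observed fraction of SVs overlapping a
track with the mean fraction under length- and chromosome-preserving
uniform re-placement (the genome-fraction shortcut is reported
alongside, since "expected" is sometimes quoted that way).

## LD and the phenotype bridge

r² is the squared Pearson correlation of unphased dosages over
pairwise-complete samples — the composite allele-count measure standard
LD tools compute on unphased genotypes; haplotype-EM r² is out of scope.
Constant vectors or fewer than three complete pairs yield a flagged
undefined value, never silently 0.  The scan tests SNPs within 1 Mb of
the nearer SV breakpoint, reports pairs with r² >= 0.2, and the bridge
keeps pairs with r² >= 0.8 (inclusive) whose SNP appears in a
GWAS-catalog-style table, emitting one association per
(SV, SNP, phenotype) triple.

## Regulatory overlap

Candidate SVs (those above the F_ST reporting threshold) are padded by
+-100 bp and intersected half-open with each annotation track.  Padding
extends the outer hull of the SV span; for spanned SVs the hull and the
two-breakpoint-window interpretations coincide for overlap detection, and
a `mode = "breakpoints"` option covers very large SVs where they do not.
Overlap is monotone in the pad and reduces to plain intersection at
pad 0.

## The synthetic cohort generator

The generator defines the study conditions rather than adapting to them:
119 samples in population A and 201 in population B (the cohort sizes of
the motivating survey), Balding–Nichols differentiation with
$F = 0.1$ — per-population allele frequencies drawn from
$\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$ around an ancestral
$p \sim \mathrm{Beta}(0.5, 1.5)$ (a rare-skewed spectrum), genotypes as
two independent haploid draws (HWE within population, no inbreeding).
Twenty selected loci are overridden to carrier frequencies 0.6 vs 0.05.
The default toy genome is two chromosomes totalling 100 Mb with 2,000 SV
loci (log-uniform lengths in [50 bp, 50 kb]; type mix 45/45/5/5
DEL/INS/DUP/INV): large enough to populate every statistic, small enough
that a full pipeline run takes seconds.  The W&C estimator recovers the
$F$ parameter from this generator to within 0.02 on average.

Caller noise: each carried SV is emitted per caller with sensitivity
0.95/0.92/0.85 (cuteSV/sniffles/nanovar), rounded-Gaussian breakpoint
and length jitter (sd 30/15 bp), and Poisson false calls (0.5 per Mb per
sample per caller) of which half are drawn to fail the raw AF/depth
filter.  Independent false calls are constructed never to agree across
callers (chance collisions are resolved at generation time), so the
two-caller rule removes all of them; a `correlated_fp` mode shares false
calls across callers to exercise the high-quality-flag pathway instead.

Tag SNPs copy the SV allele per haplotype with a swap probability solved
numerically from the target r² — the naive closed form
$q = (1-\sqrt{r^2})/2$ assumes allele frequencies are preserved and is
attenuation-biased at skewed frequencies, so the generator corrects for
the realized tag-allele frequency and restricts tagging to
intermediate-frequency SVs.  Realized mean r² hits targets
{0.5, 0.8, 1.0} within 0.05 at n = 300.  One caveat the tests make
explicit: a bridge implanted exactly at the 0.8 cutoff sits on the
decision boundary, and the extra genotype noise of the caller ->
consensus -> merge path attenuates post-merge r² by roughly 0.03–0.09,
so boundary tags bridge only ~75–80% of the time after the full noisy
pipeline while tags at r² = 1 always bridge; recall of the bridge
machinery itself (on truth genotypes) is complete.

What the generator does *not* emulate: read-level evidence, sequence
content of variants, reference bias, segmental-duplication artifacts,
relatedness/kinship structure, and demographic history beyond the single
differentiation parameter.  Green tests therefore validate the
algorithms and their calibration, not performance on any particular real
cohort.

## Orchestration and reproducibility

`pipeline_config()` validates every parameter block before any stage
runs; `run_pipeline()` executes simulate -> filter -> consensus ->
merge -> landscape -> selection -> hotspots -> LD bridge -> regulatory
overlap, records every threshold actually applied in the report's
parameter block, and is byte-identical under a fixed config.  A single
global seed fans out to per-stage seeds through a deterministic counter,
so each stage is reproducible independently of the others.  Problem
sizes used by the validation suite are the ones quoted above (2,000 loci
x 100+100 samples x 20 seeds for estimator recovery; 500 SVs on 10 Mb x
200 trials x 50 seeds for hotspot calibration; n = 5,000 x 50 seeds for
the power-law fit; a 5,000-call cohort for merge order-invariance) — the
package's own choices for a thorough desk-scale validation.

## Known limitations

* Breakpoints are taken at face value; no re-genotyping or breakpoint
  refinement from reads.
* The insertion match rule compares lengths only, not inserted sequence.
* F_ST is the two-population estimator; multi-population scans are out
  of scope.
* The hotspot null is uniform per chromosome; real genomes have
  alignability and gap structure the null ignores (accepting annotation
  tracks as BED lets users mask accordingly).
* LD uses genotype-dosage correlation, which underestimates haplotype r²
  when phase matters.
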