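---
title: "Methods: low-level somatic SNV filtering, validation and joint gene-set analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: low-level somatic SNV filtering, validation and joint gene-set analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicSNV)
```

# Scope and model

mosaicSNV implements the post-calling stages of a case-control analysis
of low-level brain somatic SNVs (variant allele fractions down to a few
tenths of a percent) detected by high-depth multi-region exome
sequencing, and their joint assessment with damaging germline SNVs.
Everything upstream — alignment, the somatic and germline callers, the
empirical-Bayes artifact score, consequence annotation and CADD scoring —
is consumed as input columns; the package owns the filtering, validation,
burden, gene-set and enrichment logic.

## Post-call filtering

Candidate calls from paired (brain + peripheral) subjects survive iff

* VAF < 20 % — higher fractions in a somatic candidate are more
  consistent with germline contamination or copy-number effects;
* EBscore > 5 — at or below 5 the site's error profile across a panel of
  reference samples explains the observation (the cutoff is exclusive on
  both rules);
* supporting reads are not confined to read ends, the reads carry no
  other base changes, and, when a BLAT re-alignment summary is present,
  the average second-highest alignment score of supporting reads is
  below 900 (higher values indicate multi-mapping artifacts). A missing
  BLAT score passes: the check only fires when evidence of ambiguity
  exists.

Brain-only (unpaired) subjects lack the peripheral subtraction, so two
stricter rules are prepended: depth ≥ 300 and VAF < 10 %. Rejections are
attributed to the first failing rule in the documented order; since the
rules are a pure conjunction, the surviving set is independent of rule
order, which the test suite asserts.

One upstream manual-inspection rule ("more than 50% of supporting reads
(at least three reads)") has no unambiguous machine reading; it is not
guessed at. The `clean_support` flag column is the hook through which a
user can supply any additional per-call manual decision.

## Pseudoreplicate rescue and barcode concordance

Low-VAF variants fall under the single-sample detection limit, but a
genuine early-developmental mutation recurs across brain regions of the
same individual. Treating regions as pseudoreplicates, a variant
(subject, chromosome, position, ref, alt — exact matching, no fuzz) is
*rescued* when called in at least two distinct unordered region pairs,
i.e. at least three distinct regions, and absent from the subject's
peripheral call set (presence there would indicate a germline or shared
artifact origin). Barcode-tagged deep sequencing confirms rescued calls:
in *every* contributing region the variant needs more than 4 supporting
barcodes, WES/BCDseq VAF agreement within 10-fold and within an absolute
5 %. A zero VAF on exactly one platform leaves the fold change undefined
and conservatively fails concordance; zero on both platforms carries no
discordance signal and passes the fold rule (the variant still cannot
pass overall without barcodes).

## Amplicon validation

The validation test asks whether the observed alternate count could be
produced by platform error alone. With class-specific background
alternate-allele fractions (T>A 0.00312, T>C 0.00797, T>G 0.000758,
C>T 0.00407, C>G 0.000765, C>A 0.00185; purine-reference substitutions
are strand-collapsed onto these six), the p-value is the one-sided exact
binomial upper tail `P(X >= alt | depth, rate)`, validated at p < 0.05.
The exact test was chosen over a Poisson or normal approximation to stay
correct at low depth and tiny rates; the suite checks agreement with
direct summation of the binomial mass to 1e-12 for depths up to 2,000.
Whether the original protocol used a one- or two-sided test is not
stated; one-sided is the natural reading of "more alternate reads than
error would produce" and is what is implemented. Replicate observations
of one candidate are pooled (depths and alternate counts summed) before
testing, as no per-replicate combination rule is specified upstream.
Zero-depth observations yield p = 1 with a warning rather than an error.

## Burden and extrapolation

"Per single brain region" averages weight subject-region pairs, not
subjects — each sequenced region is one observation; zero-count regions
are materialised explicitly so that denominators are honest. The genome
extrapolation is deliberately naive linear scaling (default 75 Mb exome
footprint to 3 Gb genome), exact and configurable. Transcript-length
normalisation divides per-gene category counts by canonical-transcript
length supplied as an input table; genes lacking a length are a hard
error rather than a silent drop.

## Merged gene sets and risk

Damaging somatic genes require a validated call with LOF/missense
consequence and CADD > 20 (strict). Damaging germline genes require
depth ≥ 100, within-sample allele fraction ≥ 30 % (a heterozygous-call
heuristic — this is a read fraction, not a population frequency),
ExAC frequency < 0.02 % with missing treated as zero (novelty cannot
make a variant common), CADD > 20, SFARI class 1–3 membership and a
LOF/missense consequence. Per-group merged sets are unions of distinct
gene symbols across subjects and sources, each gene annotated with its
source(s). Risk is assessed on the carrier 2×2 with the two-sided Fisher
exact test; the reported odds ratio is the conditional maximum-likelihood
estimate with its exact confidence interval — the estimator paired with
Fisher's test, and the convention that reproduces a published 3.92
(CI 1.121–14.794) from the carrier table [[14,10],[8,23]], whereas the
cross-product estimator gives 4.025 and is reported alongside for
transparency. A zero margin leaves the odds ratio undefined and p = 1.

## Spatiotemporal signatures

For gene *i*, stage *s*, region *r*:

$$z_i^s = \frac{e_i^{sr} - m_i^s}{1.4826\,\mathrm{MAD}_i^s},\qquad
  z_i^r = \frac{e_i^{sr} - m_i^r}{1.4826\,\mathrm{MAD}_i^r},\qquad
  z_i^{sr} = \frac{z_i^s + z_i^r}{\sqrt2}$$

where `m_i^s`/`MAD_i^s` are taken across all regions at stage *s* and
`m_i^r`/`MAD_i^r` across all stages at region *r*. (The surrounding prose
of the source method swaps the two superscripts once; the displayed
definitions above are internally consistent and the meta-z is symmetric
in its components, so membership is unaffected.) A window's signature is
the genes with meta-z ≥ 1.5 and *both* components defined; a zero MAD
makes the robust scale uninformative, so the affected component is
undefined and the gene is excluded from that window rather than given an
infinite score. Scale invariance (multiplying the tensor by c > 0) and
per-gene shift covariance are asserted as properties. Enrichment per
window is the one-sided Fisher exact (hypergeometric upper-tail) test of
the overlap over the tensor's gene universe; gene-set members outside
the universe are dropped with a reported count; the 150 windows of one
gene set form a single Benjamini–Hochberg family, flagged at q < 0.05.

## Permutation overlap test and PPI degrees

The overlap null resamples gene *subsets* (without replacement — a draw
is a set) of size k (default 18, the merged ASD set) from the cohort
pool (default 60) and counts overlaps with a reference list. The
empirical p uses the add-one estimator `(1 + #(null >= obs))/(n_perm+1)`
so it can never be exactly zero; the protocol's "5 % cutoff" is reported
as the null's 95th-percentile order statistic. For small pools the
empirical p converges to the exact hypergeometric tail, which the suite
verifies by full subset enumeration. Because the null overlap
distribution is discrete, the test is conservative: across many
configurations the analytic rejection probability at α = 0.05 is
0.02–0.03, so the calibration property asserted is one-sided validity
(type-I rate ≤ α within Monte-Carlo error, and not vacuously zero)
rather than a two-sided band around α.

Weighted PPI degree sums each protein's interaction reliability scores;
each edge contributes to both endpoints, self-loops once. Group
comparisons are two-sided Wilcoxon rank-sum tests.

# The synthetic-data generators

The generators define the study conditions under which the pipeline is
exercised; their defaults are fixed once:

* **Cohort** — 24 cases / 31 controls, five brain regions (BA9, BA21,
  BA22, BA17, CB), 13 of 24 cases and all controls with matched
  peripheral tissue; sex Bernoulli(0.5).
* **Mutations** — 2.4 true somatic SNVs per exome per region; true VAFs
  follow a Beta(1.2, 3.53) rescaled to (0.003, 0.2), giving a lower edge
  of 0.3 % and mean ≈ 5.3 %. The VAF family itself is a modelling choice:
  the empirical distribution of such cohorts is right-skewed with a hard
  detection floor, which a rescaled Beta reproduces with two parameters.
  A 20 % sharing fraction sends mutations to ≥ 3 regions (mimicking
  early cell-division epochs: region span is drawn uniformly from 3 to
  all regions, rather than from an explicit lineage tree). Per-region
  observations are binomially resampled at Poisson(559) depth, the
  cohort's average sequencing depth; observations with zero sampled
  alternate reads are uncallable and are counted in an attribute rather
  than silently lost.
* **Artifacts** — 2 artifact candidates per region with VAF 0.5–8 %, of
  which 30 % carry EBscore > 5 and therefore survive filtering. These
  two numbers set the residual false-positive rate of the post-filter
  candidate set so that its amplicon-validation precision emulates the
  ~80 % observed in the motivating validation experiment; they are the
  generator's only deliberately calibrated pair.
* **Expression** — per-gene log-normal baselines (sdlog 1 across genes)
  with cell-wise log-normal noise (sdlog 0.5), i.e. independent cells.
  Planted genes are raised at one (region, stage) cell until both robust
  z components reach the target effect. Real developmental expression is
  smooth across adjacent stages and correlated across regions; the
  generator makes no attempt at that, so passing recovery tests shows
  the signature machinery works, not that real tensors have recoverable
  planted structure.
* **PPI** — Erdős–Rényi background at mean degree 4 with Beta(2, 2) edge
  reliabilities; planted hubs accumulate edges to 10× mean degree.
  No degree-distribution realism (no scale-free tail) is attempted.
* **Reference lists** — uniform draws from a universe, with one list
  forced to share exactly k genes with a target set.

Identical seeds give identical outputs for every generator; seeds are
applied to a local RNG scope so callers' RNG streams are untouched.

# Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen to
keep Monte-Carlo standard errors well inside the asserted tolerances:
100–200 simulated subjects (1,000 subject-regions) for rate recovery,
10,000–20,000 draws for distributional checks, 10,000 permutations
against exact enumeration on pools of 6–12 genes, 10,000 null amplicon
sites for type-I control, and 100 seeds of a 500-gene × 15-region ×
10-stage tensor for planted-signal recovery and specificity. Exactness
of the binomial tail is asserted to 1e-12; Fisher p transposition
invariance to 1e-12; everything stochastic uses fixed seeds.

Degenerate inputs are defined rather than left to chance: empty call
tables filter to empty outputs with zero rejection counts; an empty gene
set yields p = 1 in every window; a signature equal to the universe
yields p = 1 (no enrichment is possible); zero variance on either side
of a correlation gives NA with a warning; groups with zero variance and
equal means compare at p = 1.

# Limitations

* The package starts at the call/count level; no read-level evidence is
  re-examined, so alignment-induced artifact classes are only as
  detectable as the input flags make them.
* The binomial validation model treats amplicon reads as independent
  draws; UMI-free amplicon data with PCR jackpotting would be
  overdispersed relative to this model, making the test anti-conservative
  at extreme depths.
* The cohort-level biological findings of the motivating study
  (specific GO/phenotype terms, published PPI medians) depend on the
  real external gene lists, interaction databases and expression
  compendium, and are not reproduced here; the synthetic suites
  demonstrate the machinery's statistical behaviour instead.
* The conditional-MLE odds ratio is reported because it pairs with the
  exact test; readers comparing against logistic-regression output
  should expect the cross-product estimate (also reported) instead.
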