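---
title: "Methods: quantifying epigenetic potential from CpG gain/loss variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying epigenetic potential from CpG gain/loss variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical and algorithmic choices behind
`epipotential`: what each stage computes, which parameters matter, what the
synthetic-data generator does and does not emulate, and where the design was
genuinely open.

## Site classification

A biallelic SNP at position $p$ with reference allele $r$, alternative $a$
and *reference* flanking bases $\ell = \mathrm{base}(p-1)$,
$\rho = \mathrm{base}(p+1)$ is classified by two independent flags:

$$
\text{loss} \iff (r = C \wedge \rho = G)\ \vee\ (r = G \wedge \ell = C),
\qquad
\text{gain} \iff (a = C \wedge \rho = G)\ \vee\ (a = G \wedge \ell = C).
$$

Because a substitution changes one base inside a trinucleotide, the two
overlapping dinucleotide windows $(p-1,p)$ and $(p,p+1)$ must be inspected
separately: `C>G` in a `C_G` context destroys the right-hand CpG *and*
creates a new one with the left flank. A net CG-count would call this "no
change"; the flag pair calls it `both`. The test suite checks the rule
against an exhaustive trinucleotide string oracle over all 192
(left, right, ref, alt) combinations, and for strand symmetry (CpG context
is self-complementary, so one forward-strand rule covers both strands).

Flanks are the *immediate* neighbours only, and always come from the
reference: adjacent variants are classified independently, with no
haplotype-aware joint context. The `N` sentinel (chromosome ends, ambiguity
codes) satisfies neither clause. The synthetic generator enforces a minimum
spacing of 3 bp between planted variants precisely so that the reference
flanks of one variant are never altered by another; on real data, tightly
linked adjacent variants are a known approximation of this site-independent
treatment.

## Presence, EP and total CpG

Per individual, a loss-type CpG is *present* when the genotype carries at
least one reference allele, and a gain-type CpG when it carries at least
one alternative allele; heterozygotes count as present on the rationale
that one CpG-bearing haplotype suffices as methylation substrate. An
allele-dosage alternative (0/1/2 per site, `dosage = TRUE`) is provided
because presence/absence versus dosage is a genuinely open choice; the
default is presence/absence. `both`-class sites contribute to *both* the
CpG and polyCpG tallies (and so can add 2 to one individual's EP); a
precedence scheme would discard real information about the two distinct
dinucleotides involved.

Missing genotypes are excluded from EP counts — they contribute neither
presence nor absence — and the resulting per-sample missingness fraction
is carried into the group models as a weight. The whole-genome total CpG
count (the robustness response) is defined for every sample as

$$
\text{total} = \#\{\text{reference CpGs on included chromosomes}\}
 - \#\{\text{loss sites, hom-alt}\} + \#\{\text{gain sites, present}\},
$$

with missing genotypes contributing the reference state, so the total is
never undefined; the weighting compensates for the extra reference-biased
uncertainty of high-missingness samples. The suite validates both EP and
total CpG against a brute-force oracle that rebuilds each individual's two
haplotype sequences and counts CG pairs directly.

## Filtering

Filters run in a fixed order, and the order is part of the contract
because it decides which rule a multiply-offending site is tallied under:

1. drop records on excluded (sex) chromosomes;
2. drop sites with QUAL < 30 (Phred);
3. mask genotypes with depth outside 5–15× (set to missing);
4. drop sites called in < 80% of individuals *after* masking;
5. drop sites whose mean depth over called genotypes is < 8×.

Two conventions for the depth rules were genuinely open. The 5–15× window is
applied per genotype (masking) rather than to a site-level mean, matching
common `vcftools --minDP/--maxDP` practice and making the 80% rule
meaningful; and the ≥ 8× rule is read as a site-mean over called
genotypes, since a per-genotype ≥ 8 floor would make the 5–15 window
largely redundant. Multiallelic records are decomposed into per-alternate
pseudo-records (other-alt alleles masked), non-SNP alternates dropped with
a count, and half-calls treated as missing. Filtering is idempotent — a
second pass removes nothing — and removed-per-rule counts plus retained
always equal the input count; both are asserted on randomized fixtures.

## Annotation

Gene models come from 12-column BED (0-based half-open, converted to
1-based inclusive internally; variant coordinates dominate the code, so
VCF conventions win). Features are built per class and unioned across
transcripts before precedence: promoters are strand-aware TSS ± flank
windows clipped at chromosome ends, exons the union of exon blocks,
introns the union of transcript spans minus exons. A position gets exactly
one category by precedence promoter > exon > intron > intergenic. The
position annotated for any CpG is its C position — a 1-bp query keeps the
partition unambiguous.

The promoter flank defaults to 1000 bp on each side (a 2001-bp window),
the customary default of transcript-feature annotation tools; it is a
parameter (`promoter_flank`) because the appropriate window is
organism- and question-dependent. A flank of 0 disables the promoter class
entirely rather than degenerating to a 1-bp feature, so shrinking the
flank can only move positions *out* of the promoter class (a monotonicity
the tests assert).

## Enrichment

For each variant type and category, the observed category count $k$ out of
$n$ variants is compared with the background proportion $p$ by a two-sided
exact binomial test using the minimum-likelihood convention (sum of all
outcome probabilities no larger than that of $k$; ties at the standard
$1 + 10^{-7}$ relative tolerance). The computation is delegated to
`stats::binom.test()` and verified in the tests against an independent
full-pmf enumeration to $10^{-10}$, including mode-inclusion ($k$ at the
mode gives $p = 1$) and super-uniformity of null p-values. Tests are
marginal per (type × category) cell, and raw p-values are reported without
multiple-testing correction — the effect measure of interest is the signed
proportion difference (expected − observed; negative = over-represented).

The background defaults to the union of all reference CpG C-positions on
included chromosomes and all gain-variant positions, so one background
serves both variant types; a reference-CpGs-only mode
(`background = "reference"`) is provided because the exact background
composition is a live analytical choice. Degenerate cells (empty variant
set, expected proportion of 0 or 1) yield `NA` p-values rather than
errors.

## Group-comparison models

Three pairwise comparisons against the philopatric reference group:
patch switching (1 vs 2), immigrants (1 vs 3), colonisation (1 vs 4). The
model is `response ~ group * sex`, weighted by $w = 1 - \text{missingness}$
(floored at $10^{-3}$): the design requirement fixes only the *direction*
of the weighting — lower missingness earns more weight — and $1 - m$ is
the simplest bounded transform with that direction ($1/m$ was rejected as
unbounded). For the spatial comparisons a
sampling-year random intercept is estimated by REML (`lmerTest`), with
Satterthwaite denominator degrees of freedom for the term F tests; when
the random effect is inestimable (single year, singular fit) the model
falls back to weighted least squares with exact F tests and a warning —
the colonisation comparison never includes year because its groups are
single-year by design. Term tests are marginal (type III-style) under
sum-to-zero contrasts so the interaction F is invariant to factor-level
order; reported *estimates* use treatment coding with the philopatric
group and males as references, so signs read as disperser-minus-reference
and female-minus-male. Sex-stratified follow-up fits (the same model
without sex terms, within one sex) are produced by the pipeline whenever
the interaction p < 0.07, probing interactions near the significance
boundary.

The WLS path is checked against the closed-form weighted normal equations
to $10^{-8}$; calibration is checked by simulation at the study's group
sizes (21/19/14/20): type-I error of the group term within [0.03, 0.07]
at $\alpha = 0.05$ over 1000 null replicates, and recovery of a planted
1-SD group effect with bias below 10% over 200 replicates. Exact
numerical parity with any particular mixed-model implementation is not
claimed — the contract is agreement with this package's own oracles and
calibration properties.

## The synthetic-data generator

`sim_config()` fixes the study conditions: two 100-kb autosomes plus a
50-kb sex chromosome (emitted with variants and then excluded by the
filters); GC content 0.42 and CpG density 0.01 per base (CpG-depleted,
vertebrate-like — the generator plants CG pairs at alternate positions
after breaking accidental ones, so the CpG count is exactly binomial and
analytically checkable); 12 multi-exon transcripts with 100–300-bp exons
and 500–3000-bp introns, giving intron/intergenic-dominated category
proportions as in real genomes; 300 loss, 300 gain and 400 non-CpG
variants; four groups of 21/19/14/20 with the study's sex ratios and
years (1998 for the colonisation group, 2015–2019 otherwise);
negative-binomial per-genotype depth with mean 8× (size 25, mild
overdispersion, exercising both the 5–15× mask and the ≥ 8× mean rule);
Gaussian site QUAL (mean 60, sd 20) putting a realistic minority of sites
below the QUAL 30 cut; and per-sample missingness rates uniform on
0–10%. A group's EP effect is planted by shifting the CpG-allele frequency
of every CpG variant by `ep_effect[g]` (clamped to [0.02, 0.98]);
genotypes are then unphased Hardy–Weinberg draws within group.

One seed drives everything, with per-stage sub-seeds so reference, gene
models and cohort can be regenerated independently; equal seeds give
byte-identical files. The ground truth records every planted class and
category and the per-sample counts implied by the emitted genotypes, so a
clean configuration (no missingness, constant depth 10, QUAL 60) must be
recovered by the pipeline *exactly* — class labels, categories, and
per-sample counts — which the acceptance-style tests assert.

The generator deliberately does **not** emulate linkage disequilibrium,
demography, selection, mutation-rate heterogeneity, indels or C/G
insertions/deletions (one reason the total-CpG robustness response exists),
genotype-calling error correlated with depth, or related individuals.
Passing tests therefore demonstrate correctness of the counting,
annotation and inference machinery under the declared sampling model — not
robustness to those real-data complications.

## Problem sizes and numerical conventions

The test suite runs at deliberately small scales chosen as the package's
own verification sizes: 10–30-kb toy chromosomes for oracle comparisons
(50 variants × 12 samples for the haplotype-reconstruction check), a
100-site fixture for filter tallies, n ≤ 50 grids for the exact binomial
test, 100 replicates of 2000 planted gain variants for enrichment
recovery, and 1000/200 replicates for model calibration. Numerical
conventions: WLS agreement asserted to $10^{-8}$, binomial p-values to
$10^{-10}$, probability ties resolved at relative $1 + 10^{-7}$, singular
mixed fits detected at `lme4::isSingular(tol = 1e-5)` and resolved by
fixed-effects fallback, weights floored at $10^{-3}$, and empty retained
sets after filtering treated as an explicit pipeline error rather than a
silent zero-row result.

## Known limitations

- Classification against reference flanks ignores haplotype context of
  tightly linked variants.
- The EP definition counts sites, not methylation states; it measures
  capacity, not usage.
- The union background for enrichment includes the gain variants
  themselves, slightly shrinking measured gain-type enrichment relative to
  a reference-only background (both modes are available).
- Satterthwaite F tests are approximations at small year counts; the
  package prefers an honest fallback to exact WLS over forcing a singular
  random effect.
- BED12 is the only gene-model input; GTF/GFF conversion is left to
  standard external tools.
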