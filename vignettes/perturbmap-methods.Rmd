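---
title: "Models and methods behind perturbmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind perturbmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

perturbmap analyses pooled CRISPRi screens run across a panel of barcoded
haploid cross progeny (segregants). Each cell carries a double barcode — a
20-nt segregant tag next to a 20-nt guide tag — so a single amplicon read
pair identifies both the genetic background and the knockdown it carries.
Competing the pool over ~10 generations with and without guide induction,
and sequencing the barcodes at several time points, yields a fitness value
for every segregant x guide combination. From those the package asks: which
guides have fitness effects at all, which effects depend on the genetic
background, which loci drive that dependence, and do a few "hub" loci
interact with many different perturbations.

This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic-data generator does
and does not emulate.

## The generative model

The simulator draws a biallelic cross (alleles coded BY = 0, 3S = 1) as an
independent two-state Markov chain per chromosome with a per-interval
switch probability (default 0.08 between markers ~18 kb apart). There is no
interference and no genetic-map calibration; all that downstream mapping
needs is realistic linkage-disequilibrium decay.

Fitness is per generation on the natural-log scale. For segregant *s*
carrying guide *g*:

$$
w_{s,g} = b_s + I\,\big( m_g + \kappa b_s + \textstyle\sum_\ell
\beta_{g,\ell} x_{s,\ell} + \varepsilon_{s,g} \big) + e
$$

* `b_s` — baseline fitness: a handful of additive QTL (default 3, allele
  effects 0.02–0.05) plus a residual (SD 0.02), centred to mean 0.
* `I` — induction indicator (the CON assay has `I = 0`; "leaky" guides,
  off by default, keep their effect in CON).
* `m_g` — mean guide effect. All targets are essential genes, so
  efficacious guides (a third of targets by default) draw negative effects,
  uniform in magnitude over 0.05–0.35; controls and non-efficacious guides
  have `m = 0`.
* `kappa` (default −0.3) couples the induced deviation to baseline fitness:
  the same knockdown costs more in a fitter background. It applies only to
  guides that do something (non-zero `m` or interactions); an inert control
  does not acquire an effect merely because inducer was added.
* `beta_{g,l}` — hub interactions. An *amplifying* hub is not a fitness
  locus; its 3S allele becomes beneficial under interacting guides, with
  |beta| = 0.4 |m_g|. A *masking* hub **is** a major baseline fitness locus
  (anchor allele effect 0.065) whose effect is attenuated under induction:
  the realized induced allele contrast is `a * max(0, 1 - 3 |m_g|)`, i.e.
  fully masked at the severe end of the mean-effect range. The stored
  `beta` compensates the `kappa` contribution so that this closed form is
  exactly what an allele contrast measures.
* `epsilon_{s,g}` — combination-level dispersion with SD `tau |m_g|`
  (default tau 0.25). It is drawn once per segregant-guide pair and shared
  by replicate barcodes and by both induced assays: it represents
  *repeatable* residual interaction (a stand-in for higher-order epistasis),
  which is why broad-sense heritability is high while the additive share is
  not. Had it been drawn per lineage, barcode averaging would shrink the
  dispersion-versus-effect slope by 1/sqrt(n barcodes) and the two induced
  replicates would decorrelate.
* `e` — independent per-lineage noise (SD 0.01).

Hub sizes default to 18 interacting guides — the smallest hub membership
the assay design is intended to resolve; masking hubs are anchored on
major fitness loci because a locus that is too weak to reach the baseline
scan threshold could not plausibly be discovered as a masking hub. The
amplifying hub is placed on a chromosome without baseline QTL so that
baseline-coupling signal cannot shadow it.

Lineages grow deterministically, `f_i(t+Δ) ∝ f_i(t) exp(s_i Δ)`
(renormalised each transfer — equivalently growth at `s_i − s̄(t)`), with
multinomial read sampling of the configured depth at each sequenced time
point (generations 0, 2, 4, 6, 10). T0 abundances are log-normal with CV
0.5, standing in for the post-transformation spread, which is not reported;
a finite bottleneck between transfers can be enabled but is off by default
so sequencing remains the only sampling noise. About 65% of segregant x
guide combinations are present, matching a pool in which each guide is
observed in roughly two-thirds of backgrounds — the absent combinations are
what PCR-chimera detection keys on — and each present combination carries
~1.4 distinct barcode-pair lineages (one or two per combination), the
recovery rate pooled integration typically achieves. Replicate assays
share the identical lineage set.

What the generator does **not** emulate: diploid genetics, de-novo
mutation within lineages, tetrad structure, flocculation artifacts,
index/lane structure, and position-specific sequencing error. Passing
recovery tests on these simulations therefore demonstrates the estimators'
correctness under the stated model, not robustness to every artifact of
real sequencing data.

## From reads to counts

Barcodes are extracted from fixed read positions and validated by anchor
sequences (`CCCGAGTCGCGATAA` after the guide barcode, `TACCGTTCGTATAGG`
after the segregant barcode; exact match by default, one mismatch
configurable). Read pairs are dropped when the mean phred quality of the
first 35 bases of either read is below 30. Observed barcodes are matched
against the reference lists with a similarity score
`100 (1 − edit/max(len))`, accepting scores ≥ 90 — about 1–2 nt for a
20-mer; ties go to the lexicographically smallest reference.

PCR chimeras pair barcodes that never co-occurred in a cell. Pairs whose
segregant-guide combination is absent from the library are treated as known
chimeras, and their frequencies are regressed on the marginal frequencies
of the two barcodes (OLS, fitted separately in the four early time points,
coefficients averaged). Every pair's frequency is then reduced by its
prediction and floored at zero. Counts are finally rescaled so each time
point sums to a common constant, so that all time points carry equal
weight in fitness estimation. The constant should sit near the true
per-time-point depth (450,000,000 — roughly a full lane — for a
production experiment; the simulated depth for a desk-scale run), because
fitness estimation reads the normalised counts as Poisson observations
and a scale far above the real depth would overstate their precision.

## Fitness inference

Each lineage has one fitness `s_i`, constant over the assay, while the
population mean `s̄(t)` moves as fast lineages expand. A whole trajectory
is projected per lineage, `n̂_i(t+Δ) = n̂_i(t) exp((s_i − s̄(t)) Δ)`,
anchored at a *fitted* starting abundance: the T0 count is itself one
noisy Poisson draw, and conditioning on it as if exact costs real
accuracy for low-coverage lineages, so the log-anchor enters the fit as a
per-lineage nuisance parameter. Each (anchor, fitness) pair is updated by
joint Newton steps to minimise the Poisson deviance between the projected
and observed trajectory (T0 included); `s̄(t)` is then recomputed as the
frequency-weighted mean of the current estimates. Initialisation is the
observed T0 count and the least-squares slope of log frequency
(pseudocount 0.5 on zeros); iteration stops when no estimate moves by
more than 1e-6 (cap 200 iterations). Because only fitness *differences*
are identified, the gauge is pinned by re-centring each iteration so the
T0-frequency-weighted mean is zero; a halving step guards the deviance
against overshoot, and the iteration stops if no step can decrease it.
A lineage that crashes to zero counts has its maximum-likelihood fitness
at −∞, so estimates are floored at the least-extreme value that leaves
half a read by the end of the assay — the assay's resolution limit for
that lineage. The per-lineage fit score is the total Poisson
log-likelihood of its trajectory.

QC removes lineages whose score falls below Q1 − 1·IQR ("one interquartile
range below the first quartile" taken literally, not 1.5·IQR), lineages
with fewer than 5 T0 reads, then — iterated to a fixed point — segregants
with < 100 distinct guides and guides with < 2 distinct segregants. Removal
is by flag; nothing is dropped silently.

Fitness values are relative to each assay's own mean, so assays are aligned
on control guides (intergenic/noncoding targets): control guides whose
average fitness is negative and inconsistent between induced and control
assays (|difference| beyond 2 SD of all control differences — an explicit,
configurable reading of "inconsistent") are dropped; induced
assays are shifted by the difference of control medians; and a final global
shift makes the mean CON lineage fitness exactly zero.

## Guide effects and deviation values

For each guide, lineages from CON (indicator 0) and one induced assay
(indicator 1) enter a mixed model with a random segregant intercept and
fixed guide effect; the interaction model adds a per-segregant guide term
as a random slope. A likelihood-ratio test (α = 0.05) decides whether the
interaction model is warranted; the guide coefficient and its Satterthwaite
p-value are read from the selected model, and the interaction p-value from
the LRT. Benjamini–Hochberg correction is applied separately to the
mean-effect family (all guides) and the interaction family (only guides
with significant mean effects, following the source analysis's wording).
Because effects are CON-vs-induced contrasts, a guide that is equally leaky
in both conditions cancels out by construction.

Significance alone is too permissive for efficacy, so a conservative
threshold is added: the effects at or above the centre of the distribution
are treated as the upper half of the null, reflected about the centre, and
their SD taken as the null SD; efficacious guides must fall at least 3 SD
below the centre. The centre is the median by default (the mean is
available via an argument; the two conventions differ negligibly for a
symmetric null, and the median is robust to the deleterious tail).

Per-segregant deviation values are the predicted segregant-specific guide
effects minus the mean effect, re-centred to average exactly zero. The
default extracts random-slope BLUPs (shrinkage estimates, as model-based
prediction implies); a fixed-effects mode (per-segregant induced-minus-
control contrast, no shrinkage) is provided and used wherever a
hand-computable oracle is wanted. Guides with deviations for fewer than 35
segregants are dropped. Guides whose 20-nt binding window overlaps a
BY/3S variant are excluded up front — an allele-specific binding site
masquerades as a background effect.

## Heritability

Broad-sense heritability of a guide's effect is the between-segregant share
of the total sum of squares in a one-way ANOVA over replicate lineages,
with the per-lineage guide effect defined as induced lineage fitness minus
the segregant's control baseline (by default the mean over that segregant's
CON lineages carrying control guides; an all-CON-lineage option exists).
Narrow-sense heritability comes from the additive relationship matrix of
standardised marker genotypes (haploid coding: centred by allele frequency,
scaled by sqrt(p(1−p)), averaged over markers). The variance-component
model `y = μ + g + e`, `g ~ N(0, σ²_A A)`, is fitted by exact restricted
maximum likelihood on the eigendecomposition of A — the profile restricted
likelihood is optimised in the single heritability parameter — and h² is
clipped to [0, 1]. Genotypes, not deviations, build A. The higher-order
epistasis share is `1 − h²/H²`, floored at zero, reported only when
H² > 0. At 169 segregants the null sampling spread of the REML estimate is
real: purely environmental traits average below 0.1 but their 95th
percentile sits near 0.14, which the tests assert as measured.

## Linkage mapping and hubs

Deviation values are traits: each marker is tested by simple linear
regression (`deviations ~ locus`; slope is the 3S-minus-BY contrast),
p-values floored at 1e-300 before −log10. The genome-wide threshold comes
from 1000 permutations, each drawing a random guide, shuffling its
deviations across segregants (genotypes intact, preserving LD), and saving
the minimum p; the 5th percentile of those minima is the cutoff. Peaks are
local maxima above the cutoff, taken greedily in significance order; each
carries a 2-unit −log10 p drop interval (the run of markers within 2 units
of the peak — boundary markers are the last still within 2), and intervals
closer than 100 kb on a chromosome are suppressed (interval-to-interval,
which is how "away from any other drop" reads). Peaks within 10 kb of the
guide's binding site are flagged cis and excluded from trans analyses.
Baseline fitness is mapped with the same machinery applied to segregant
mean CON fitness.

Hubs are loci whose alleles modify many different perturbations. Counting,
at each marker, the trans intervals that cover it, a Poisson null with
rate λ = (total interval length)/(genome length) and a per-bin level of
0.05/(number of 20-kb bins) gives the minimum significant overlap count k —
the smallest k with P(X ≥ k) strictly below the per-bin level. Runs of
adjacent markers at or above k become hubs; the hub marker is the highest
count (ties resolve to the tied marker closest to their mean position), and
members are the guides whose intervals overlap that marker. Per member, the
mean induced fitness by allele (replicate barcodes averaged within a
segregant first) and the deviation contrast are reported; regressing
|allele fitness difference| on |mean effect| across members classifies the
hub — positive slope (p < 0.05): amplifying; negative slope at a
baseline-fitness locus: masking. A sign-epistasis flag notes members whose
allele contrast flips sign relative to the uninduced contrast.

## Problem sizes and orchestration

The default synthetic study is 169 segregants x 16 chromosomes x 40
markers, 200 guides (20 controls) with 1–3 barcodes each, five time points,
and read depths of 1e5–1e6 per time point — a desk-scale stand-in for the
millions of lineages of a full experiment. The package-level calibration
studies (`hub_recovery_study()`, the test suite, `scripts/acceptance.R`)
run tens to a hundred replicates of the effect-level generator, which skips
the sequencing layer; the sequencing layer itself is validated end-to-end
by the read round-trip, chimera-recovery and fitness-recovery checks.
`run_pipeline()` strings every stage together from one config with one
master seed and writes plain-text TSV/JSON artifacts; `write_report()`
summarises counts of efficacious and background guides, mapped loci, hubs,
the heritability decomposition, and between-assay correlations.

## Known limitations

* The fitness model holds each lineage's fitness constant over the assay;
  slow equilibration after induction biases mean effects toward zero, and
  no time-varying alternative is fitted.
* BLUP deviations are shrunk toward zero by design; slope-style summaries
  computed from them underestimate the generative coupling, which is why
  calibration studies use the fixed-effects mode.
* The chimera model is frequency-linear with pooled per-assay marginals;
  lane-specific chimera rates are not modelled.
* The permutation threshold is shared across guides (one random guide per
  permutation), as in the source procedure — per-guide thresholds would be
  more conservative for guides with unusual missingness.
* Classification of a hub needs enough members (≥ 3 to fit anything,
  realistically ≥ 10) and both alleles observed among phenotyped
  segregants.
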