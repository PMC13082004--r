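---
title: "Methods: haplotype-aware variant effect prediction with pvep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype-aware variant effect prediction with pvep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A variant effect predictor maps a sequence to a prediction — per-residue
amino-acid log-probabilities for a protein language model, per-position
acceptor/donor probabilities for a splice model, per-position coverage
tracks for a regulatory model. The conventional VEP score is the delta
between the reference sequence with and without the variant. `pvep`
replaces the single reference background with the set of personalized
haplotypes observed in a phased cohort: for each focal variant $v$ and
haplotype $h$, the wild-type sequence is the personalized background,
the mutant adds $v$, and

$$\mathrm{VEP}_{v,h,m} = \Delta\big(m(s^{\mathrm{mut}}),\,
   m(s^{\mathrm{wt}})\big)$$

yields one score per background. Both phased copies of a diploid
individual are scored independently and treated as independent haplotype
observations. Scores are oriented so that negative values indicate
reduced predicted fitness (more pathogenic).

Three delta conventions are implemented for protein scorers.
*Masked marginals* (the default): at each differing position $i$,
$\log p(\mathrm{mt}_i \mid s^{\mathrm{wt}}_{\setminus i}) - \log
p(\mathrm{wt}_i \mid s^{\mathrm{wt}}_{\setminus i})$, both read from one
pass over the wild-type haplotype masked at $i$, summed over differing
positions. *WT marginals*: the same sum from the unmasked forward pass.
*Pseudo-perplexity*: the full pseudo-log-likelihood difference between
mutant and wild type. The contract is substitution-only: the alignment
convention for unequal-length deltas is undefined, so indel-bearing
haplotype pairs are rejected by `protein_delta()` and indel-bearing
haplotypes (including length-neutral insertion/deletion pairs, which
shift residue coordinates) are excluded from protein scoring by default
and logged with reason `indel_background`. Truncated (premature-stop)
and frameshifted haplotypes are likewise retained but flagged and
excluded by default.

Splice deltas use an odd scoring window (101 nt by default, inside a
10,101 nt model window) centered on the focal position: acceptor gain is
$\max_w (P^{\mathrm{mut}}_{\mathrm{acc}} - P^{\mathrm{wt}}_{\mathrm{acc}})$
clipped at 0, likewise acceptor loss and the donor analogues; the VEP
score is the maximum of the four and the effect class its argmax, with
ties broken in the fixed order acceptor gain, acceptor loss, donor gain,
donor loss so that entropy computations are deterministic. The coverage
ratio is the signed maximum
$\mathrm{COVR} = \max_{p,t} \log_2\!\big((C_{\mathrm{mut}} +
\varepsilon)/(C_{\mathrm{wt}} + \varepsilon)\big)$ with
$\varepsilon = 10^{-6}$; an `absolute = TRUE` switch returns the
largest-magnitude fold-change with its sign, since "maximum fold-change"
is ambiguous when coverage drops.

## Haplotype construction

Phased cohorts carry biallelic records with an INFO quality score;
records below 0.9 are ignored everywhere. Coordinates are 0-based
half-open internally; VCF/GFF3 I/O converts. DNA windows are extracted
per (sample, ploid) with substitutions preserving length and indels
shifting downstream offsets through a monotone coordinate map;
windows extending past a contig edge are N-padded with the padding
recorded. A variant straddling the window boundary is skipped with
reason `boundary`. Injection is compatibility-checked: if a background
variant occupies or deleted the focal site, the pair is recorded as
incompatible (`allele_mismatch` / `site_deleted`), never silently
scored. Protein haplotypes apply coding variants to the CDS on the
transcript strand, translate, and deduplicate identical amino-acid
sequences; per-superpopulation frequency is carrier chromosomes over
$2 \times$ group size. Residue maps are built from a per-base coordinate
map of the personalized CDS, so in-frame indel shifts are exact and
deleted or frame-disrupted residues map to `NA`.

Every focal × haplotype pair is accounted for as scored, incompatible
(with reason), or filtered (with reason); `audit_store()` verifies the
three counts sum to the total.

## Distribution characterization

The representativeness percentile uses mid-ranks,
$100\,(\#\{x < r\} + \tfrac12 \#\{x = r\})/n$, with the reference score
not appended to the distribution (the convention is invariant under
strictly monotone transforms). Normality uses the D'Agostino–Pearson
omnibus $K^2 = Z_1(\sqrt{b_1})^2 + Z_2(b_2)^2$ against $\chi^2_2$,
reported untestable below $n = 20$ or at zero variance; downstream
q-values are Benjamini–Hochberg.

Modality fits a one-dimensional variational-Bayes Gaussian mixture
(coordinate-ascent; Dirichlet concentration $1/K$ with $K = 50$,
Normal–Gamma priors centered on the sample moments, tolerance $10^{-3}$
on mixing-weight change, 500 iterations, one deterministic
quantile-spread initialization jittered by the seed). Components with
posterior weight below 1% are discarded; the reported number of modes is
the count of local maxima of the retained mixture density. Counting
density maxima rather than retained components is deliberate: we
verified empirically that the reference variational implementation with
identical settings keeps two or more components at weight ≥ 1% on
unimodal Gaussian samples in roughly half of random seeds — component
counts measure how the optimizer tiles the density, not how many humps
the data has. The same logic gates the empirical benign/pathogenic
boundary: a 2-component fit whose density is unimodal (or whose means
collapse within a tenth of the pooled standard deviation) yields no
boundary; otherwise the boundary is the point between the two density
modes where the weighted component densities are equal.

## Sensitization maps and the non-additivity test

The surrogate model regresses per-haplotype scores on binary
background-variant presence, one ridge fit per clinical target with
centered columns, an unpenalized intercept, and $\alpha = 1$
(deterministic SVD solver; the test suite checks it against the
normal-equations closed form to $10^{-8}$). Missing cells (incompatible
injections) are dropped pairwise per target; constant columns are
flagged and receive zero coefficients. Marginal effects are mean
absolute coefficients across the other axis. The splicing variant of the
model is a single-target fit restricted to background variants within
±5 kb of the focal position (inclusive).

The non-additivity test asks, for a pair (background $i$, clinical $j$),
whether carriers of $i$ deviate from the additive expectation. Its
construction was genuinely open and three candidate readings fail:

* using the observed deviation $d_h = y_h - (\mu + e_i g_h)$ as a
  regressor puts the carriers' own noise on both sides, so the
  interaction model fits carriers exactly and the F-test rejects always;
* a per-pair scalar $d$ makes $g \cdot d$ collinear with $g$
  (untestable always);
* comparing raw carrier/non-carrier group means has essentially no power
  once the other background variants' additive effects dominate the
  residual variance (measured power ≈ 0.03 at the acceptance scale).

The implemented test is the classical fixed-value coefficient test on
the full-design least-squares fit: per target $j$, regress $y$ on all
background columns (constant/collinear columns dropped); the additive
null fixes variant $i$'s coefficient at its individual effect $e_i$
while the interaction model frees it, giving

$$F = \frac{(\hat\beta_{ij} - e_i)^2}{v_i\,\hat\sigma^2_j},
  \qquad F \sim F(1,\, n - p) \text{ under } H_0,$$

with $v_i$ the coefficient's variance factor. Other background variants
act as covariates in both models — that is what makes the planted
interactions detectable. Individual effects $e_i$ are summarized across
clinical targets from a near-unpenalized ($\alpha \approx 0$) surrogate
fit: ordinary least squares is required for calibration (ridge
coefficients are shrunk by a factor of order $\alpha/(n \cdot
\mathrm{var}(X_i))$, which leaves systematic deviations for rarer
variants; we measured a 0.34 null rejection rate at $\alpha = 1$ versus
0.05 at $\alpha \approx 0$). The cross-target summary is the median
rather than the mean: a mean is contaminated by the variant's own strong
interactions (bias $\beta_{\mathrm{int}}/m$), which measurably inflates
the realized false discovery proportion past 0.1. Pairs are untestable
below 10 scored haplotypes, with an empty carrier group, when the
carrier column is collinear with the covariates, or at zero residual
(exactly additive scores); untestable rows carry reason codes. BH
q-values are reported alongside p-values.

## Structure analyses

Contacts are residue pairs at distance strictly below 8 Å, excluding the
diagonal; no further sequence-separation filter is applied. Haplotype
contact maps are compared to the reference as gained/lost sets over
$i < j$ pairs; indel-bearing haplotypes (residue count mismatch) are
excluded with an error that names the cause. Enrichment at threshold $t$
is $E(t) = \hat p_{\mathrm{obs}}(t)/p_{\mathrm{exp}}$ with
$p_{\mathrm{exp}}$ the overall contact frequency among mapped pairs and
an exact binomial tail per threshold; the default grid is 20 quantiles
of $|\beta|$, and pairs without a residue mapping are excluded with a
logged count. Superpopulation-weighted maps are
$W = \sum_h f_h C_h \in [0,1]$ with group calls at strict $W > 0.5$
(majority of chromosome mass; a 50/50 split is deliberately not called).
Per-residue contact variance (averaged over partners) is
Pearson-correlated with per-residue confidence scores; identical maps
yield an undefined, flagged correlation.

## The synthetic world

The generators are a stated world for testing the machinery, not a
population-genetics claim. Contigs are uniform-random nucleotides with
valid coding transcripts written in (ATG start, no internal stop, 1–3
coding exons, alternating strands). Variant positions follow a Poisson
process at the target density with a ≥ 4 bp spacing guard (so
overlapping records never occur); 85% SNVs and 15% short (1–3 bp)
indels; allele frequencies are Beta(0.3, 3) — rare-variant-skewed, so
most haplotypes differ from the reference by few variants; genotypes are
independent Bernoulli draws per chromosome (no linkage disequilibrium,
no demography, by design). INFO scores place roughly 15% of records
below the 0.9 filter so the quality-filter path is always exercised.
Superpopulation labels default to five groups with largest-remainder
rounding.

Planted ground truth selects background variants among nonsynonymous
coding SNVs already segregating in the cohort (one per residue; stop
gains excluded), invents clinical missense variants at background-free
residues with negative (pathogenic-leaning) effects, and plants
interactions of fixed magnitude and random sign. Interactions are
planted only on background variants with at least 10 carrier and 10
non-carrier chromosomes — the downstream testability filter — because
power against unobservable pairs is undefined. The epistatic toy scorer
realizes this truth through haplotype-conditional log-probabilities: the
shift at clinical site $j$ is $\mathrm{clin}_j + \sum_i
(\mathrm{add}_i + \mathrm{int}_{ij})\,X_{hi}$ (plus optional
deterministic sequence-keyed noise), so the stored delta equals the
ground-truth sum to machine precision at zero noise. Background additive
terms are kept inside the clinical-site shift deliberately: real
nonlinear models retain background sensitivity in their deltas, and
without that additive signal the surrogate fit of a rare-variant design
cannot reach the required explained variance. What a green planted-
recovery test establishes is therefore that the surrogate and the
interaction test recover effects *of the form the toy scorer emits*; it
says nothing about any real model's inductive biases, calibration, or
long-range context handling.

The replicated power/FDP/type-I analyses run at the chromosome-
observation level (two rows per diploid sample) through
`simulate_planted_scores()`, the documented matrix-level equivalent of
the sequence route; the sequence route itself is verified exactly
against the same function at zero noise.

## Numerical and interface choices

* All generators are pure functions of (seed, parameters); pipeline
  stages derive sub-seeds from one root seed. Re-running any stage with
  the same config and seed is byte-identical.
* The logistic allele-frequency fit uses nonlinear least squares with
  five deterministic starts built from the data range, slope sign and
  median predictor (`scaleOffset = 1` so noiseless data converge), Wald
  95% intervals from the estimate covariance, and an overall regression
  F-test. Raw frequencies are the default; `log10_af = TRUE` is
  available since the transformation convention is unstated upstream.
* Win rates use strict inequality on $|r|$; exact ties count as neither
  win nor loss. Eligibility is both correlations significant at an
  uncorrected 0.05.
* Storage: DNA results as per-contig site × sample × ploid × metric
  arrays rendered as plain TSV + JSON metadata; protein tables under
  `{cohort}/vep/{model}/{protein}/{haplotype}/{variant_source}/
  {strategy}.tsv`. Missing cells round-trip as NA; a schema version
  mismatch is a hard error. Plain text keeps every artifact diffable and
  no binary dependency load-bearing.
* Configuration is JSON (`run_config()`/`save_config()`/`load_config()`
  round-trip exactly); window sizes default to the standard model
  contexts (10,101 nt splice, 524,288 bp coverage) and the CLI clamps
  them to the simulated contig so desk-scale runs do not score padding.
* Missing genotypes are rejected at VCF read time (the synthetic cohorts
  are fully phased); multiallelic records must be pre-split.
* DNA windows are reported on the forward genomic strand; strand-aware
  scorers can reverse-complement at the adapter boundary.

## Known limitations

* No linkage disequilibrium or demographic structure in the synthetic
  cohort; carrier correlations that real cohorts exhibit are absent, so
  collinearity handling sees only chance correlation.
* The protein pipeline is substitution-only by default; scoring
  indel-bearing haplotypes requires an alignment convention the delta
  definitions do not pin down.
* The non-additivity test's conditional F distribution treats the
  individual effect $e_i$ as fixed; its cross-target estimation noise is
  small but not zero (the measured null rejection rate, 0.050 over 2,000+
  pairs, absorbs this).
* Toy scorers are purely local (motif indicators, per-position tables);
  they cannot emulate long-range context effects, saturation, or
  model-specific calibration.
* The variational mixture is one-dimensional and mode counting depends
  on the 1% weight floor and the density grid; heavily skewed unimodal
  data with $n \ll 500$ can still split.
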