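---
title: "Models and methods behind methylaccel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methylaccel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylaccel)
```

This vignette is the package's own account of its science: the models it
fits, the knobs that matter, what the synthetic cohort does and does not
emulate, and the numerical and design choices made where the design was
genuinely open.

# The measurement model

A methylation array reports, per sample and CpG probe, a *beta value* — the
methylated fraction of the signal, in $[0,1]$ — together with a detection
p-value (probability the signal is background) and a beadcount (number of
beads supporting the measurement). The `MethylationSet` class carries all
three as assays of a `SummarizedExperiment`, probes as rows.

## Quality control

Four exclusion rules run in a fixed order, and their boundary semantics are
pinned deliberately (tests assert every edge):

1. a **sample** is removed when the fraction of its probes with detection
   $p > 0.05$ (strict) is $\ge 1\%$ (inclusive);
2. a **probe** is removed when its beadcount is $< 3$ (strict) in $> 5$
   samples (strict);
3. a **probe** is removed when the fraction of samples with detection
   $p > 0.05$ is $\ge 0.5\%$ (inclusive);
4. a **sample** is removed when the sex predicted from mean chrX beta
   disagrees with the recorded sex.

Whether probe-level fractions should be computed before or after the sample
exclusions is ambiguous in general; `runQC()` evaluates them on the samples
surviving step 1 (the order the rules are listed in), and a property test
checks this against an explicit two-pass oracle. The consequence worth
knowing: QC is idempotent, and relaxing any threshold never excludes more.
When no beadcount matrix is available rule 2 is skipped with a warning
rather than an error, since beadcounts rarely survive export pipelines.

The sex check replaces a visual log-intensity inspection with a
deterministic rule: predicted female iff mean chrX beta exceeds the
midpoint of the female-like (0.5) and male-like (0.2) archetypes. Both
archetypes and the threshold are arguments.

# Epigenetic age and acceleration

A clock is a linear model $F(\text{age}) = c + \sum_j w_j \beta_j$ with an
optional log-linear calibration
$F(a) = \log(a+1) - \log(a_{\mathrm{adult}}+1)$ for $a \le
a_{\mathrm{adult}}$, linear beyond — continuous, strictly increasing, and
exactly invertible. Coefficient tables are user-supplied CSVs; published
clock coefficient sets are deliberately not redistributed, and the bundled
`makeToyClock()`/`fitClockModel()` clocks exist so that every test is
self-contained. Missing clock probes are mean-imputed up to 20% of the
panel, refusal beyond — mirroring common calculator behaviour; the
threshold is pinned by a test.

## Cell deconvolution

Proportions of the seven leukocyte types (naive and exhausted CD8+ T,
plasmablast, CD4+ T, NK, monocyte, granulocyte) are estimated per sample by
constrained least squares against reference profiles: minimise
$\lVert Rp - b\rVert^2$ subject to $p \ge 0$, $\sum p = 1$. With seven cell
types the convex program is solved *exactly* by enumerating support sets
(127 equality-constrained KKT solves per sample, with a one-solve fast path
when the interior solution is already feasible). This avoids an external
quadratic-programming dependency and guarantees the global optimum; the
trade-off is exponential cost in the number of cell types, which is fixed
at seven here.

## IEAA and EEAA

*Intrinsic* epigenetic age acceleration is the residual of clock age
regressed on chronological age plus six free cell proportions; granulocytes
are dropped as the reference category because the proportions sum to one
(the choice of dropped category does not change the residual, which is a
projection; the choice is nonetheless pinned by a test). When the cell
proportions are themselves exactly collinear with age — which happens in
the noiseless synthetic limit — the design is rank-deficient; the residual
is still the unique projection onto the column space, so `computeIEAA()`
warns and uses the pivoted least-squares projection rather than refusing.

*Extrinsic* acceleration combines a Hannum-style clock age with the three
age-varying immune measures (naive CD8+ T, exhausted CD8+ T, plasmablast)
into a Klemera–Doubal biological age

$$\mathrm{BA} = \frac{\sum_j (x_j - q_j)\,k_j/s_j^2}{\sum_j k_j^2/s_j^2},$$

where $(k_j, q_j, s_j)$ are the slope, intercept and residual SD of
biomarker $j$ regressed on chronological age; EEAA is the residual of BA on
chronological age. Two open choices were resolved as follows:

- **Estimator form.** The weighted-average form above (no
  chronological-age anchor term) is the default because the combination is
  described in the literature as a weighted average of the biomarkers' own
  implied ages; the anchored variant — chronological age as an $(m+1)$-th
  pseudo-biomarker with unit slope and a configurable residual SD — is
  available via `kdmCombine(..., anchorAge=)`.
- **Training anchor.** The $(k, q, s)$ weights are fitted on the analysis
  cohort itself. Reference implementations hosted online carry internal
  gold-standard anchors that are not recoverable; cohort-fitting is the
  self-contained choice and is stated openly here.

A numerical guard: an exactly-linear biomarker has $s_j = 0$ and would
receive infinite weight, so residual SDs are floored at $10^{-6}$ biomarker
units. When *all* biomarkers imply the same age the floor cancels and the
combination returns that age exactly.

# The pedigree association model

Each risk factor is the **outcome**; chronological age, sex and the
acceleration exposure are fixed effects; the pedigree enters as a random
effect with covariance $\sigma^2_a A$, where $A$ is the additive
relationship matrix from the tabular recursion
($A_{ii} = 1 + \tfrac12 A_{s_i d_i}$,
$A_{ij} = \tfrac12 (A_{j s_i} + A_{j d_i})$). Continuous outcomes and the
exposures are z-scored (denominator $n-1$), so effects are in SD units;
binary outcomes keep their 0/1 coding.

The reference analysis this mirrors used a Bayesian MCMC sampler for all
outcomes. Here the inferential targets are kept identical but the default
machinery differs by outcome family, trading fidelity of mechanism for
determinism where that is free:

- **Continuous outcomes: REML.** After one eigendecomposition
  $A = UDU^\top$ the model is diagonal in $\lambda = \sigma^2_a /
  \sigma^2_e$; the restricted likelihood is profiled over $\sigma^2_e$ and
  optimised over $\log \lambda$ on $[-12, 12]$ (the lower bound doubling as
  the $\lambda \to 0$ boundary candidate). Wald tests use a $t$ reference
  with $n - p$ degrees of freedom, which keeps the test calibrated at the
  cohort sizes used here (the normal reference is visibly liberal at
  $n \approx 300$). A dense $O(n^3)$ evaluation of the restricted
  likelihood exists solely as a test oracle, and a conjugate Gaussian Gibbs
  sampler (`fitGaussianGibbs()`) is available behind a flag for fidelity
  runs.
- **Binary outcomes: probit Gibbs.** Latent-liability augmentation with
  residual variance fixed at 1, flat priors on fixed effects, and a weakly
  informative inverse-gamma prior (shape and rate $10^{-3}$) on
  $\sigma^2_a$ — configurable, since the reference analysis states none.
  The random-effect update reuses the eigenbasis of $A$, making each sweep
  $O(n^2)$. Effects are reported on the latent (liability) scale; no
  numeric equivalence with published unspecified-scale binary coefficients
  is claimed. The reported "p" is the two-sided posterior tail probability
  floored at one over the number of kept draws; a separation heuristic
  (posterior mean or SD of a fixed effect exceeding 8) triggers a warning.

Bonferroni correction is applied separately per exposure with $m = 12$
fixed — the roster size — even when the user subsets the roster, unless
they override `m`; the significance threshold is reported as
$\alpha/m = 0.05/12 = .0042$ (4 decimals). Education is an ordinal 0–10
variable and is z-scored like the other numeric factors by default; a
per-unit option exists because ordinal scales are sometimes reported per
unit.

# Polygenic scores

Greedy clumping by ascending GWAS p-value: keep the most significant
unprocessed SNP, drop unprocessed SNPs on the same chromosome within 250 kb
whose dosage $r^2 > 0.25$, repeat. Ties on p are broken by position then
id, so the retained set is invariant to input order (tested against a
brute-force pair-by-pair oracle). LD comes from the sample dosages
themselves, not an external reference panel — the self-contained choice.
Region exclusion (e.g. the *APOE* locus) removes SNPs in
$[\mathrm{start} - f,\ \mathrm{end} + f)$ with flank $f$ defaulting to
500 kb: "a 500-kb region" is ambiguous between total span and flank, so
the flank reading was adopted as the conservative one, closed-left/
open-right, and pinned by tests. No p-value threshold is applied by default
(all post-clumping SNPs are scored); `pThreshold` exists as an option.
Swapped effect/other alleles are reconciled by flipping dosage to
$2 - d$; irreconcilable SNPs are dropped and counted.

# What the synthetic cohort emulates

The generator's defaults describe the study conditions it stands in for: a
family-structured adult cohort (40 families of three generations,
$\approx 320$ people, ages uniform on 18–80), latent intrinsic and
extrinsic acceleration as independent Gaussians with SD 4.5 years, trait
heritability 0.4, array noise SD 0.02 on the beta scale, and a handful of
injected QC failures (2 failing samples, 2 failing probes by detection, 2
by beadcount, 1 recorded-sex swap).

Risk factors are generated *conditional on* the latent acceleration —
matching the direction of the association model — as unit-variance
liabilities $z = \beta_I z_I + \beta_E z_E + g + e$, with $g$ an additive
genetic value following the pedigree (mid-parent plus Mendelian sampling)
and the default $(\beta_I, \beta_E)$ set to effect magnitudes typical of
large adult cohorts (e.g. 0.089 SD of BMI per SD of intrinsic
acceleration). Continuous liabilities are mapped to natural units (BMI
$27.0 \pm 5.4$ kg/m², HDL $1.49 \pm 0.42$ mmol/L, total cholesterol
$5.13 \pm 1.09$ mmol/L, a deprivation rank on 1–6505, an ordinal education
level with median 4, zero-inflated pack years with 48% ever-smokers);
binary traits are thresholded at realistic prevalences (type-2 diabetes
3.4%, high blood pressure 13.7%, family history 16.7%, ε4 carriage 27.7%).
The total:HDL ratio is **derived** as `total_chol / hdl` exactly, so its
effect-table row is informational only.

Methylation is built in five probe blocks: a Horvath-style clock block
encoding $\text{age} + \text{accel}_I$, a Hannum-style block encoding
$\text{age} + \text{accel}_E$, the cell-reference probes carrying each
sample's mixture, a chrX block with sex-dependent means, and filler. Clock
betas are $0.5 + (w_j / \sum w^2)(t - 50)$, so at zero noise prediction is
*exact* — the identifiability anchor of the whole test suite. Cell mixtures
drift linearly with $\text{age} + \text{accel}_E$ (naive CD8+ T down ~0.08
percentage points/year, exhausted CD8+ T up ~0.1 pp/year), which is what
makes EEAA — but not IEAA — track composition; at nonzero noise the mixture
is drawn from a Dirichlet with precision 300 around that mean.

Deliberately **not** emulated: probe-specific mean/variance structure and
spatial correlation of real arrays, batch and chip effects, the second
normalization pass applied by online calculators, assortative mating and
shared-household environment (family resemblance is purely additive
genetic), linkage between the genotype panel and the methylation signal.
Passing tests therefore demonstrate correctness of the *algorithms* under a
known generative model, not robustness to real-array artefacts.

# Problem sizes and runtimes in the tests

The suite exercises parameter recovery at the smallest sizes that make the
checks sharp: REML bias over 100 phenotype replicates on one $n \approx
600$ pedigree (bias $< 0.02$ on a true 0.1 SD effect), probit recovery of a
0.5 liability-scale effect at $n \approx 500$ ($\pm 0.15$), and null
calibration over 500 cohorts of $n \approx 300$ with 12 Gaussian outcomes
each (per-test rejection inside the exact binomial 95% interval around
0.05; family-wise error under Bonferroni within its binomial bound; KS
uniformity of null p-values). Calibration is run through the REML path: the
probit sampler's calibration is checked by symmetry and recovery tests
rather than 6 000 chain runs. Random-pedigree relationship matrices are
verified against a recursive kinship oracle to $10^{-12}$ on 50 pedigrees.

# Known limitations

- The probit sampler uses a single chain and no formal convergence
  diagnostic beyond the separation heuristic; chain settings are exposed.
- Cell deconvolution assumes the reference spans the sample's composition;
  profiles outside the simplex of references are projected onto it.
- `ldClump()` computes dosage correlations pairwise per index SNP; for
  panels orders of magnitude larger than the tested sizes a blocked
  implementation would be preferable.
- The acceleration measures are fitted on the analysis cohort, so they are
  relative to it: adding or removing samples changes everyone's IEAA/EEAA
  slightly. This matches the definitions used in cohort studies but means
  values are not comparable across cohorts.
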