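---
title: "Methods: family-based variance components for DNA methylation"
author: "methfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-based variance components for DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
generative model behind the synthetic cohort, the estimators, the numerical
choices, and the places where the design was genuinely open and a choice had
to be made. Nothing here reports an empirical number that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The study design and the generative model

The cohort emulated throughout is a twin-family design: nuclear families of
two unrelated founder parents and at least two children, exactly one pair
of which is a twin pair, monozygotic with probability 67/178 (the MZ:DZ
ratio of a typical adolescent twin registry). The default family-size
distribution (0–3 extra siblings with probabilities 0.25/0.35/0.30/0.10)
gives a mean family of 5.25, so 117 families average about 614 individuals.
Parents' ages are uniform on 35–55 years and offsprings' on 10–20 years
(an adolescent cohort); twins share one age draw, MZ twins also one sex
draw. These are generator defaults, not fitted values.

Methylation is generated on a latent log-odds (logit) scale and mapped to
beta values by the inverse logit. For probe $p$ and individual $i$:

$$\eta_{pi} = \beta_0 + \mathbf{x}_i'\boldsymbol\gamma + \beta_{QTL} g_i
  + a_i + f_i + e_i,\qquad
  \mathbf a \sim N(0, V_a A),\; f \sim N(0, V_f H),\; e \sim N(0, V_e I)$$

with $A$ the additive relationship matrix (MZ co-twin entries 1) and $H$
the nuclear-family indicator (parents included — the household covers the
whole family; an option restricts it to offspring). Covariates
$\mathbf{x}$ can carry sex, age, chip and chip-position offsets, and a
cell-composition signature weighted by per-sample cell proportions. Type II
probes are linearly compressed toward 0.5, $\beta' = 0.5 + (1-s)(\beta -
0.5)$ with default $s = 0.2$, reflecting the flatter dynamic range of that
chemistry. The latent scale is a modelling choice: it keeps beta in [0,1]
by construction and matches the logistic-link normalisation that the
analysis applies, so covariate effects removed during normalisation are the
same objects the generator injects.

Default variances put the total latent variance at 0.25 (SD 0.5), which at
a hemimethylated site corresponds to a beta-scale SD of roughly 0.12 — a
typical variable probe. At this scale the logistic transform is nearly
affine, so latent correlations survive to the beta scale almost undistorted
(a fraction of a percent); probes simulated far from hemimethylation
(intercepts of ±2 and beyond) are visibly attenuated on the response
scale, which is why the calibration slope of estimated on true heritability
in the `analysis/` pipeline (which draws intercepts from N(0, 1.2²)) sits
below the slope obtained at hemimethylated probes. This is a property of
analysing bounded data on the response scale, not an estimator defect; the
`residual_scale = "link"` option of the normaliser avoids it where the
log-odds scale is preferred (the mQTL stage uses it so effects read as
log-odds per allele).

Blood cell proportions are Dirichlet draws (concentration 100, granulocyte
dominated). Because cellular composition is itself partly familial, the
sample-sheet generator can blend a family-level Dirichlet draw into each
individual's proportions (`cell_family_weight`); without that sharing, a
cell signature acts as independent noise and cannot inflate heritability,
which would miss the confounding mechanism the adjustment exists for.

Missingness is completely random at a configurable rate; detection
p-values are uniform on (0, 10⁻⁴) for passing entries and (10⁻³, 1) for
failing ones — thresholds at 0.01/0.001 then behave as in practice, though
no claim is made that real detection p-values follow these laws.

What the generator does *not* emulate: raw two-channel intensities and
their artefacts, bisulfite conversion variability, probe cross-hybridisation
(multi-mapping is an annotation flag, not a sequence phenomenon), SNPs
physically disrupting probe binding (SNP counts are annotation consumed by
a filter), linkage disequilibrium between SNPs (gene dropping is per-SNP
independent), and assortative mating (a spouse-correlation knob exists,
default 0, since the mechanism behind small observed spouse correlations is
unresolved — household effects, assortment and collection-time artefacts
are all candidates). Passing tests therefore demonstrate correctness of the
estimators under the stated model, not robustness to those artefacts.

## 2. Quality control and normalisation

Probe filters: sex-chromosome probes, multi-mapping probes, zero-CpG
probes, then binomial thresholds for missingness and detection failures.
The threshold is the smallest integer $k$ with
$P(\mathrm{Bin}(n, \bar r) > k) < 0.05 / n_{\text{probes}}$, with the rate
$\bar r$ pooled over all probes and samples; exceeding $k$ flags a probe as
deviating from random missingness. The filter is sequential and idempotent;
a per-rule tally is returned. An optional rule keeps only probes with no
annotated SNP (`n_snp == 0`), an annotation filter guarding real-data
heritability against allele-specific array binding.

Each probe is normalised across samples by a quasi-binomial GLM with
logistic link on chip, chip position, sex, age, age², sex×age and
sex×age² — no global normalisation, and no between-probe-type correction,
since within-probe variance partitioning is unaffected by the type II
compression. Response-scale residuals (observed − fitted beta) are the
default analysis quantity; because the logit link is canonical, they sum
to zero per probe. A `residual_scale = "link"` flag yields log-odds
residuals instead. If the GLM separates or fails to converge, the probe
falls back to a linear model on logit-transformed values (clipped to
[10⁻⁶, 1−10⁻⁶]) with a warning — a documented fallback, chosen here, not a
behaviour taken from anywhere.

Outliers: anything strictly beyond five interquartile ranges from its
nearest quartile is set missing. Quartiles are type-7 (linear
interpolation), computed once on the pre-mask values; the pass is single
shot, because iterating the rule could cascade. With zero IQR the strict
inequality still governs: exact ties survive, any deviation is masked.

Cell composition is estimated per sample by least squares against a
reference panel of six leukocyte profiles under non-negativity and
sum-to-one constraints. With only six cell types the constrained optimum is
found exactly by solving the equality-constrained problem on every support
and keeping the best feasible solution — no iterative solver, no tolerance.
The bundled reference panel is synthetic (generated from a fixed seed) and
stands in for a sorted-cell reference data set.

## 3. Relative-pair correlations

Pairs are enumerated within families (MZ, DZ, sibling — including
twin-to-non-twin pairs — parent-offspring with the parent's sex retained,
spouse) and optionally across families (all unrelated combinations). The
per-probe, per-class statistic is the one-way ANOVA intraclass correlation
$(MS_B - MS_W)/(MS_B + MS_W)$ with the pair as the grouping factor; it is
order-invariant within pairs, so no double entry is applied, and probes are
averaged unweighted. Under the additive model the class means follow $h^2$,
$h^2/2$, 0.

Two small-sample properties of this estimator matter and are verified by
the test suite rather than assumed. First, with all-pairs enumeration the
same individual appears in many pairs, which biases class means slightly
downward — most visibly for the unrelated class, whose mean comes out
around −0.002 rather than 0. The `disjoint_pairs()` helper subsamples to
member-disjoint pairs, where the bias vanishes; the acceptance checks of
the expected-correlation structure run on disjoint pairs (a calibrated
experiment), while the all-pairs table is reported as the published-table
analogue, slight negative unrelated mean included. Second, the ANOVA ICC
has an $O(1/n_{\text{pairs}})$ negative bias even on independent pairs
(about −0.0014 at 117 pairs and correlation 0.1), small against the
Monte-Carlo error of the pooled checks.

## 4. Variance-component estimation

Per probe, the model $y \sim N(X\beta,\; V_aA + V_fH + V_eI)$ is fitted by
maximum likelihood (ML throughout, not REML) with $\beta$ profiled by GLS —
intercept only by default, since covariates were removed upstream; cell
proportions enter here as fixed effects when adjustment is requested (one
cell type dropped, as proportions sum to one). Both relationship matrices
are block-diagonal over families, so the likelihood factors per family.

For the AE model the likelihood is rotated by a per-family
eigendecomposition of $A$, making each evaluation $O(n)$; $V_e$ is profiled
analytically and the maximisation runs over the single ratio
$\lambda = V_a/V_e$. The boundary $\hat V_a = 0$ is decided exactly by the
sign of the profile score at $\lambda = 0$ (the derivative is
$\tfrac12(\sum d_i r_{0i}^2/\hat v_0 - \sum d_i)$ with $d$ the eigenvalues
and $r_0$ the rotated OLS residuals); an interior candidate is located by
golden-section search on $\log\lambda$ over [10⁻⁸, 10⁸] and compared
against the boundary. This makes boundary estimates exact zeros, which the
zero-fraction statistic needs, and removes the optimizer-dependent ~1%
boundary inflation a generic bound-constrained quasi-Newton run exhibits
at loose tolerances. The AFE model is maximised over the two ratios
$(V_a, V_f)/V_e$ by L-BFGS-B from three starts (the AE solution, a
null-heavy and a genetic-heavy point), with one Cholesky per *distinct
family composition* per evaluation, batched across identical families.
Inputs are standardised internally so tolerances are scale-free.

Significance: a likelihood-ratio test of the model's focal component ($V_a$
for AE against E, $V_f$ for AFE against AE), referred to an equal mixture
of a point mass at zero and $\chi^2_1$ — the null distribution of a
variance tested on the boundary of its parameter space. Genome-wide
significance uses Benjamini–Hochberg at 5% (`stats::p.adjust`).

Zero-fraction bound: with $V_a \ge 0$ enforced, a truly null probe lands on
the boundary with probability ½ *asymptotically*; an observed boundary
fraction $p_0$ therefore bounds the proportion of probes with a genetic
component below by $100 - 200\,p_0$ percent. Exact zeros are detected at
$\hat h^2 < 10^{-6}$. A caveat the package quantifies rather than hides:
at 117 families the exact boundary probability under the null is not 0.5
but about 0.53 — the boundary event is $r_0'(A - I)r_0 \le 0$, a skewed
quadratic form, and the test suite verifies both that the fitter's boundary
decisions match this oracle probe-by-probe and that the simulated fraction
sits where the oracle puts it. The corresponding acceptance check against
the asymptotic 50% band is therefore expected to sit on the band's edge at
this design size; the lower-bound formula itself is unaffected (it only
becomes slightly conservative-to-liberal in proportion to the same
finite-sample excess).

Missing individuals are handled by subsetting $A$ and $H$ per probe, never
by imputation; eigen-structures are cached per missingness pattern, so a
screen over a complete matrix pays for one decomposition. Probes whose
subset covariance is not positive semi-definite are rejected with a flag.

## 5. mQTL scanning

SNP QC drops, in order: MAF strictly below 0.05 (computed from all
non-missing dosages), Hardy–Weinberg exact-test p below 10⁻⁶ computed on
*founders only* (offspring genotypes depart from HWE by construction in
families), and missingness strictly above 10%.

Association uses the measured-genotype model: per probe, $(V_a, V_e)$ are
estimated once under the no-SNP AE null; each SNP's allelic-dosage effect
is then a GLS fit with that covariance held fixed, with a Wald test against
the standard normal. Holding the null components fixed keeps the scan
linear in SNPs and is slightly conservative for very large effects (the
alternative's variance decomposition is not refitted per SNP). On unrelated
subsets the machinery collapses to OLS exactly. Monomorphic-after-subset
SNPs are skipped with a flag; fewer than 30 informative individuals is an
error. Regional profiling tests one lead SNP against every probe whose CpG
lies within half the window span on either side (the window is the full
8 Mb span, centred), flags Bonferroni-significant probes (0.05 over the
number of probes in the analysis by default) and reports signed effects,
since regional mQTL act in both directions.

## 6. Problem sizes and determinism

Every stochastic test fixes its seed and states its scale: the acceptance
suite uses a 117-family cohort with 2,000-probe simulations for the
boundary-zero and expected-correlation checks (the latter pooled over
three replicate cohorts), 500-probe recovery panels, 10,000 Gaussian
probes for LRT calibration, 2,000 SNPs for null-scan uniformity and 100
replicates for power; module tests use smaller designs (15–200 families)
chosen so each check's Monte-Carlo error is well inside its tolerance.
The AFE property checks run at 200 families and 50 probes. These sizes are
the package's chosen experiment scales; the generator and estimators
accept arbitrary sizes.

## 7. Known limitations

* ML variance components are biased at small family counts (the 53% vs 50%
  boundary phenomenon above is one face of this); REML is deliberately out
  of scope.
* Common environment and any sequence-independent transgenerational
  transmission are confounded in nuclear families; the AFE model's $V_f$
  absorbs both, and no explicit epigenetic-transmission model is fitted.
* The response-scale analysis attenuates signals at probes near full or
  zero methylation; the link-scale flag is the escape hatch.
* The mQTL scan accepts real-valued dosages but performs no imputation,
  phasing or LD-aware analysis.
* The cell-reference panel is synthetic; with a real sorted-cell panel the
  deconvolution accuracy claims would need re-validation.
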