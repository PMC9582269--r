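---
title: "Two-sample Mendelian randomization with summr: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with summr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(summr)
```

## The causal model

Mendelian randomization treats genetic variants as natural randomizers
for an exposure. A variant $j$ is a valid instrument when it satisfies
three assumptions: it associates with the exposure (*relevance*), it is
independent of confounders of the exposure–outcome relation
(*independence*), and it affects the outcome only through the exposure
(*exclusion restriction*). Under these assumptions the per-SNP Wald
ratio

$$\hat\theta_j = \frac{\hat\beta_{Y,j}}{\hat\beta_{X,j}}$$

estimates the causal effect $\theta$ of the exposure $X$ on the outcome
$Y$, where $\hat\beta_{X,j}$ and $\hat\beta_{Y,j}$ are the SNP–exposure
and SNP–outcome associations taken from two *non-overlapping* GWAS. For
binary traits both associations are per-allele log-odds, so $\theta$ is
a log-odds ratio and $e^\theta$ an odds ratio per unit increase in the
log-odds (liability) of the exposure.

The first-order Delta-method standard error of the ratio is
$se_j = se_{Y,j}/|\hat\beta_{X,j}|$, the convention of the standard
two-sample MR software; the second-order form
$\sqrt{se_{Y,j}^2/\hat\beta_{X,j}^2 +
\hat\beta_{Y,j}^2 se_{X,j}^2/\hat\beta_{X,j}^4}$ is available via
`se_mode = "second_order"`. The default is first order because it
reproduces the numeric conventions of the widely used implementations
and because, at the instrument strengths the pipeline enforces
(F ≥ 10, typically much more), the second term is negligible.

## Instrument selection

Instruments are selected by a p-value threshold and greedy LD clumping:
repeatedly take the smallest-p SNP below the threshold and discard all
remaining SNPs on the same chromosome within the distance window whose
r² with it is at or above the LD cut. Defaults are p < 5×10⁻⁷
(genome-wide-suggestive, appropriate for exposures whose GWAS yield few
genome-wide-significant hits), r² < 0.01 and a 10,000 kb window. The
window is interpreted *pairwise from the index SNP*, i.e. a candidate is
tested against each already-retained index within the window; this is
one of two defensible readings of "clump window" and is documented here
because the choice changes nothing for panels whose retained SNPs are
far apart, the typical case. Ties in p are broken by ascending position
and then rsid so selection is deterministic. SNPs absent from the LD
matrix are treated as unlinked with a warning — permissive clumping
against an incomplete reference panel — because silently dropping them
would discard instruments for lack of reference data, the worse error.

Per-SNP instrument strength uses
$R^2 = \frac{2f(1-f)\beta^2}{2f(1-f)\beta^2 + 2f(1-f)N\,se^2}$ (which
algebraically reduces to $\beta^2/(\beta^2 + N\,se^2)$, but is computed
as written) and $F = R^2(N-2)/(1-R^2)$. A-priori power for a binary
outcome uses the non-centrality approximation
$\lambda = N\,R^2\,\phi(1-\phi)\,\ln(OR)^2$ with case fraction $\phi$,
power $= 1 - \Phi(z_{1-\alpha/2} - \sqrt\lambda) +
\Phi(-z_{1-\alpha/2} - \sqrt\lambda)$. This matches the published
binary-outcome approximation used by the standard online calculators; it
is an approximation, accurate for the small per-unit effects typical of
this design (the package's tests verify it against individual-level
logistic simulation to within 0.02).

## Harmonization

Outcome effects are aligned to the exposure's effect allele. Identical
allele pairs are kept; swapped pairs have the outcome beta negated and
the outcome allele frequency reflected; pairs that match only after
complementing the outcome alleles are treated as strand flips. Allele
pairs irreconcilable after complementing are dropped with reason
`allele_mismatch`, never silently kept.

Palindromic variants (A/T, C/G) carry no strand information in their
allele labels. The package drops them when the exposure allele frequency
is within `palindrome_eaf_window` (default **0.08**) of 0.5, and
otherwise infers orientation from agreement of the allele frequencies
on the two sides; when the outcome frequency is missing they are dropped
unconditionally. The 0.08 half-width is a conservative, widely used
default — at frequencies closer to 0.5 the two orientations are
empirically indistinguishable. This policy (and its window) is a design
choice of this package, made explicitly configurable because published
analyses are frequently silent about theirs.

Instruments missing from an outcome study may be substituted by an LD
proxy (r² > 0.60, validated at load; weaker entries are rejected).
Proxy effect sizes are used **as-is**, without attenuation by r²,
matching standard proxy substitution; users who prefer attenuated
effects can pre-scale the proxy map. Unproxied instruments are reported
and the analysis proceeds on the reduced panel.

## Estimators

**IVW (multiplicative random effects).** With weights $w_j = 1/se_j^2$
on the ratio scale, $\hat\theta = \sum w_j \hat\theta_j / \sum w_j$,
fixed-effect $se_F = (\sum w_j)^{-1/2}$, and residual dispersion
$Q = \sum w_j(\hat\theta_j - \hat\theta)^2$. The reported SE is
$se_F \cdot \max(1, \sqrt{Q/(k-1)})$: over-dispersion from invalid
instruments widens the interval, but under-dispersion never narrows it
below the fixed-effect SE (the conservative convention). p-values use
the normal reference.

**Medians.** The simple median of the ratios is consistent when at
least half the *instruments* are valid; the weighted median —
interpolating the ordered ratios at standardized cumulative
inverse-variance weight 0.5 — when at least half the *weight* is valid.
Their SEs come from a seeded parametric bootstrap
($\hat\theta_j^* \sim N(\hat\theta_j, se_j)$, default 1,000
replicates; the seed is mandatory so runs are reproducible). Under
equal weights the weighted median reduces exactly to the simple median,
which the tests assert.

**MR-Egger.** Weighted least squares of outcome betas on exposure betas
with an unconstrained intercept (weights $1/se_{Y,j}^2$), after
orienting all exposure effects positive. A nonzero intercept estimates
the average directional pleiotropic effect; the slope is the
pleiotropy-adjusted causal estimate under the InSIDE assumption
(instrument strength independent of direct effects). SEs are inflated
by the residual standard deviation when it exceeds 1, and p-values use
$t_{k-2}$ because $k$ is small.

Confidence bounds throughout are $\hat\theta \pm 1.96\,se$ — the
multiplier is the fixed conventional constant rather than
`qnorm(0.975)`; the difference (4×10⁻⁶) is far below reporting
precision, and the fixed constant makes the interval contract exact and
testable.

## Heterogeneity, MR-PRESSO, leave-one-out

Cochran's $Q$ is referred to $\chi^2_{k-1}$;
$I^2 = \max(0, (Q - df)/Q) \times 100\%$ is banded low (≤ 25%),
moderate (25–50%] and high (> 50%). The two common band definitions
overlap at exactly 50%; the package assigns the boundary to *moderate*
(ties resolve toward the lower band) — a documented convention, not a
claim about anyone else's intent.

MR-PRESSO simulates the null distribution of the
leave-one-out-predicted residual sum of squares
$RSS = \sum_j w_j(\hat\beta_{Y,j} - \hat\theta_{(-j)}\hat\beta_{X,j})^2$
by drawing outcome effects from their leave-one-out predictions with the
observed SEs and recomputing the statistic on each draw (default 1,000
draws; the empirical p is floored at $1/(n_{sim}+1)$). Per-SNP outlier
tests use the same construction per observation with Bonferroni
correction across instruments — the convention of the reference
implementation of this test. Flagged outliers are removed and IVW
recomputed; the distortion test (raw-vs-corrected displacement against
random same-size removals) is reported as exploratory. The test is
designed for panels of more than 10 SNPs and warns below that.

Leave-one-out re-estimates IVW $k$ times; a row is flagged influential
when its interval and the full-panel interval disagree about excluding
the null — the operational form of "no single SNP drives the
inference".

## Multivariable MR and mediation

`mvmr_ivw()` regresses outcome betas on two exposures' betas jointly
(no intercept, weights $1/se_{Y}^2$), giving each exposure's *direct*
effect. The reporting unit is one covariate at a time — pairwise
models, mirroring how adjusted analyses of this design are tabulated —
rather than one saturated model. The MVMR panel is built from the
**union** of the two instrument sets, jointly re-clumped with the same
configuration as univariable selection (each SNP entering with its best
p across the exposures); the alternative — keeping only the primary
exposure's instruments and attaching covariate betas — is a stricter
subset of the same computation and can be obtained by passing the
primary instrument list as both sets. Residual degrees of freedom are
$k - p$ ($k-2$ for the two-exposure case). Rank-deficient designs raise
an error naming the offending exposure; observed exposure-beta
correlation above 0.95 triggers a near-collinearity warning.
Conditional instrument strength is reported for transparency but weak
conditional instruments are *not* pruned, since pruning rules are not
part of the standard reporting of this design.

Mediation is decomposed both ways: the **product** method multiplies
the exposure→mediator estimate by the mediator→outcome direct effect
(Delta-method SE $\sqrt{a^2 se_b^2 + b^2 se_a^2}$), and the
**difference** method subtracts the adjusted direct effect from the
total effect, so direct + indirect recomposes the total exactly. The
difference SE uses the independence approximation
$\sqrt{se_{total}^2 + se_{direct}^2}$, flagged as approximate: the
covariance between the two estimates is not estimable from two-sample
summary data. Proportions mediated outside [0, 1] (inconsistent
mediation, e.g. suppression) are reported as-is with a warning, never
truncated; the proportion is undefined when the total effect is zero.

## FDR control and orchestration

The primary IVW p-values across the outcome family (seven outcomes per
direction in the default design) are adjusted by Benjamini–Hochberg;
sensitivity methods would be corrected within their own family. The
pipeline (`run_pipeline()`) runs selection → harmonization → estimation
→ diagnostics → FDR, optionally in the reverse direction (each outcome
as exposure, probing reverse causation). A fatal error in one pair
yields an explicit NA row and the run continues. All stage seeds derive
deterministically from the configuration seed, so a run is
bit-reproducible from its configuration object; per-run provenance
(version, thresholds, instrument counts, failures) is returned as a
manifest. Differently configured runs (e.g. different palindrome
windows or SE modes) legitimately give different estimates for the same
pair; the package reports exactly one estimate per configuration and
leaves reconciliation of configuration differences to the analyst.

## The synthetic-data generator

`generate_gwas()` simulates directly on the summary scale:
$maf_j \sim U(0.05, 0.45)$;
$se_{X,j} = (2 maf_j(1-maf_j) N_X)^{-1/2}$;
$se_{Y,j} = (2 maf_j(1-maf_j) N_Y \phi(1-\phi))^{-1/2}$ with outcome
case fraction $\phi$; true effects $\gamma_j$ rejection-sampled from
$N(0, 0.02^2)$ until genome-wide-suggestive at $N_X$ and oriented to
the exposure-increasing allele; observed betas are truth plus
independent Gaussian noise at the analytic SEs, with outcome mean
$\theta\gamma_j + \alpha_j$. The pleiotropy law sets $\alpha_j = 0$
with probability $1 - $`frac_invalid`, else
$N(\mu_\alpha, sd_\alpha^2)$ (balanced: $\mu_\alpha = 0$).

Default conditions — 12 instruments, $N_X = 350{,}000$,
$N_Y = 500{,}000$, $\phi = 0.1$, $\theta = \ln 1.1$ — are the
validation conditions of the whole package: a suggestive-threshold
panel for a binary psychiatric exposure against large binary
cardiovascular outcomes. `gamma_scale = 0.02` and the MAF range were
chosen once as realistic for common variants at these sample sizes;
they yield instrument F statistics from the mid-twenties to low
hundreds, the range such panels actually show.

What the generator *does* emulate: two-sample independence (separate
noise draws), binary-trait SE structure, instrument selection pressure,
configurable exclusion-restriction violations, exact analytic SEs. What
it does *not*: LD between instruments (post-clumping panels are modeled
as independent), winner's curse (selection acts on true effects, not
observed ones — observed p-values can drift above the threshold, so a
12-instrument design occasionally yields 10–11 selected instruments),
sample overlap, allele-frequency differences between studies, and
indels. Passing tests therefore demonstrate correctness of the
estimators under the model's assumptions, not robustness to every
pathology of real summary files — which is why harmonization and I/O
carry their own adversarial tests.

Two consequences observed in validation and worth knowing: first,
because exposure betas carry sampling noise, Wald denominators are
noisy and IVW shows a small regression-dilution bias toward the null
(≈ −5% of $\theta$ at the default instrument strengths); it stays
within Monte-Carlo error of the recovery checks but is a real,
documented property of ratio estimators with finite-strength
instruments. Second, the multiplicative random-effects floor makes
interval coverage slightly conservative (≈ 95.6% measured over 2,000
replicates).

## Validation scales and numerical choices

The stochastic validation suite uses: 500 replicates for parameter
recovery and for the pleiotropy bias contrast, 1,000 for interval
coverage and type-I error, 200 for the familywise BH discovery rate and
the MR-PRESSO detection rate (1,000 null simulations per run), and 200
panels for the uniformity of the PRESSO global p. These sizes put
Monte-Carlo error well below the effect sizes being checked while
keeping the default suite in minutes on one CPU.

The directional-pleiotropy robustness contrast uses
$\mu_\alpha = 0.03$, $sd_\alpha = 0.01$, 40% invalid instruments: a
pleiotropic Wald-ratio shift of ≈ 1.2, comfortably above per-instrument
sampling noise (≈ 0.3). With shifts far below instrument noise the
median and the mean behave alike and the contrast is uninformative;
this setting places the violation in the regime the weighted-median
estimator is designed for, where IVW bias is roughly 4× its own.

Other numerical choices: p-values of exactly zero in input files are
replaced by the smallest positive double (and flagged) so downstream
log transforms stay finite; floats are written with 17 significant
digits so write/read round-trips are bit-exact; empirical p-values are
floored at $1/(n_{sim}+1)$; the bootstrap and PRESSO seeds are
mandatory arguments rather than defaults so no silent global-RNG state
leaks between stages.

## Known limitations

- LD proxies substitute effects unattenuated; with r² near the 0.60
  floor this overstates the proxy's information.
- The difference-method mediation SE assumes independence of total and
  direct estimates; it is conservative in typical positive-correlation
  settings but is an approximation either way.
- MR-Egger at k ≈ 12 has low power against modest directional
  pleiotropy (measured ≈ 10% at an intercept of 0.0032); a null
  intercept is weak evidence of absence.
- Binary-exposure MR estimates are interpretable as effects of
  *genetic liability* to the exposure, not of the exposure itself;
  nothing in the arithmetic rescues that interpretation.
- Positions are treated as opaque coordinates within one analysis; the
  package never lifts over or mixes genome builds.
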