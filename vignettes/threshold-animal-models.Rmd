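---
title: "Threshold animal models for binary disqualifying traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold animal models for binary disqualifying traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedliab)
```

## The model

Morphological defects in beef cattle — problems of feet and legs, mouth,
chamfer, racial characterization, depigmentation, umbilical hernia,
testicular hypoplasia and navel — are recorded at the yearling evaluation
as binary scores (1 = defect present). `pedliab` estimates their genetic
parameters under the liability-threshold animal model: each record is the
discretization of a latent continuous liability

$$ l = X\beta + Za + e, \qquad a \sim N(0,\, A\sigma^2_a), \quad
   e \sim N(0,\, I\sigma^2_e), $$

with the observed score $y_i = 1$ exactly when $l_i$ exceeds a fixed
threshold $t_1$. $X$ carries the fixed effects (contemporary group, region,
optionally a lineage factor, and for feet-and-legs the centered yearling
weight and its square), $Z$ maps records to animals, and $A$ is the
numerator relationship matrix built from the pedigree. Because the
liability scale of a binary trait is unidentified, the standard
identification is used: $t_1 = 0$ and $\sigma^2_e = 1$, so the liability
heritability is $h^2 = \sigma^2_a/(\sigma^2_a + 1)$. For a continuous
trait (yearling weight) the same machinery runs as a plain linear animal
model with $\sigma^2_e$ sampled.

Inference is by single-site Gibbs sampling: truncated-normal draws of the
liabilities (inverse CDF in log space, exact in the far tails), Gauss–
Seidel-with-noise updates of $\beta$ and $a$ under the mixed-model
equations with $\lambda = \sigma^2_e/\sigma^2_a$ weighting the sparse
$A^{-1}$, and scaled inverse chi-square draws of the variances. The
genetic correlation between a binary and a continuous trait is estimated
by a two-trait linear–threshold model whose residual covariance is sampled
in the conditional-regression parameterization, which keeps the threshold
trait's residual variance pinned at 1 in every stored sample.

## Pedigree algebra

`build_a_inverse()` constructs $A^{-1}$ directly from the pedigree by
Henderson's rules with Mendelian-sampling variances
$d_i = 0.5 - 0.25(F_s + F_d)$; the inbreeding coefficients $F$ come from
the Meuwissen–Luo algorithm, which is exact and fast at the pedigree sizes
involved. The dense tabular relationship matrix
(`relationship_matrix_tabular()`) is retained purely as an independent
oracle: the test suite verifies, on randomized pedigrees of up to 500
animals, that the sparse inverse times the tabular matrix is the identity
to $10^{-8}$ and that $\mathrm{diag}(A) = 1 + F$. Unknown parents are
treated as unrelated, non-inbred founders; no genetic groups are fitted.
Both an inbreeding-aware and a classical non-inbred $A^{-1}$ are exposed,
since analyses in the field report either.

## Record preparation

Contemporary groups are the composite of birth year, farm, birth season,
sex, weaning and yearling farm, and the two management groups; sex is
dropped from the key for testicular hypoplasia, which is recorded in
males only. Seasons default to trimesters of the birth month. The filters
— yearling age window of 340–670 days, minimum group size 10, and removal
of binary-trait groups without phenotypic variability — are iterated to a
fixpoint, so their result does not depend on the order in which the rules
are applied, and re-filtering a filtered data set is a no-op. Fixed
effects use reference (drop-first-level) coding with an intercept;
estimable contrasts are unaffected by this choice. The yearling-weight
covariates are centered at their post-filter means for numerical
conditioning.

## Priors, and why the threshold default is proper

For linear traits the default variance prior is the improper flat prior
(`variance_prior(-2, 0)`), under which the full conditionals are the usual
scaled inverse chi-squares. For threshold traits the default is the
weakly informative proper prior `variance_prior(4, 0.2)`. This is not a
cosmetic choice. With a binary trait each phenotyped animal carries a
single record and its own breeding value, so the marginal likelihood of
$\sigma^2_a$ does not vanish as $\sigma^2_a \to \infty$: in that limit the
model approaches the heritability-one regime in which family-structured
liabilities reproduce the observed scores almost perfectly ("complete
separation"). With a few hundred affected animals the likelihood therefore
flattens rather than decays, improper priors yield an effectively improper
posterior, and chains under flat priors drift without bound — behavior we
verified against exact posteriors (see below) rather than assumed. The
proper default bounds that tail while contributing only four prior degrees
of freedom against thousands of animals.

## Verification against exact posteriors

For paternal half-sib designs the threshold animal model's marginal
likelihood factorizes into one-dimensional integrals per sire family
(offspring are conditionally independent given the sire's breeding value,
with the Mendelian-sampling variance folded into the probit scale). This
yields an *exact* posterior by quadrature at full study scale, with no
MCMC. The sampler reproduces these exact posteriors: on a 30-sire,
2,100-offspring design at 5% incidence and true $h^2 = 0.16$ the exact
posterior mean is 0.18 and the Gibbs chains (20,000 and 100,000 cycles)
give 0.18 as well. The same oracle exposed that a much stronger prior
(df 10) would systematically over-shrink high-heritability traits, which
is why the default stays at df 4.

## Mixing: the interweaving move

The classical alternation between $a \mid \sigma^2_a$ and
$\sigma^2_a \mid a$ mixes very slowly when individual records are weakly
informative. After each centered variance draw the sampler therefore
performs an ancillarity–sufficiency interweaving (ASIS) step: the
breeding values are mapped to the non-centered parameterization
$\tilde a = a/\sigma_a$ (whose prior does not involve $\sigma_a$), the
genetic standard deviation is redrawn from its one-dimensional full
conditional — a truncated Gaussian tilted by the prior, sampled by inverse
CDF on a grid — and $a$ is rescaled. On the quadrature-verified designs
this raises the effective sample size of $\sigma^2_a$ by roughly two
orders of magnitude while leaving the invariant distribution unchanged
(the move is an exact Gibbs step in the alternative parameterization).
The bivariate sampler applies the same move to the threshold channel,
with the prior term adapted to the inverse-Wishart scale.

## Chain configuration

`gibbs_config()` defaults mirror a production run: 1,000,000 cycles,
250,000 burn-in (300,000 for the bivariate analysis), storage interval 25
— 30,000 stored samples. `scale_factor` shrinks chain length and burn-in
proportionally while keeping the thin interval; the recovery suites run at
`scale_factor = 0.02` (20,000 cycles, 5,000 burn-in), which the
quadrature-verified designs show is adequate when the posterior is
well-identified. Identical seed and configuration produce bit-identical
chains; all randomness flows through R's RNG from the single seed.

Convergence is never assumed: `summarize_posterior()` and
`diagnostic_report()` attach Geweke $z$ (batch-means spectral estimator
with $\lceil\sqrt n\rceil$ batches, windows 10%/50%), Heidelberger–Welch
stationarity (Cramér–von Mises against the Brownian-bridge null, critical
value 0.46136 at $\alpha = 0.05$, progressive 10% discards down to 50%
retention) and halfwidth tests, and the initial-positive-sequence
effective sample size. The conventional $|z| < 1.96$ plus stationarity
pass is reported as "converged"; non-convergence flags the estimate rather
than erroring.

## The synthetic herd generator

`simulate_herd()` creates the data the analysis assumes: a discrete
three-generation pedigree (300 founders, a pool of 10 sires per
generation, three offspring per dam — progeny groups of 70–100, matching
the heavy use of elite young sires in breeding programs of this kind),
Mendelian-sampled breeding values with variance
$\tfrac12\sigma^2_a(1-(F_s+F_d)/2)$, iid contemporary-group effects
(SD 0.3 liability units across ~20 groups), two regions (SD 0.1), and
liabilities thresholded so the *marginal* incidence hits its target — the
threshold is placed by the inverse normal CDF on the total liability
variance $\sigma^2_a + \sigma^2_{cg} + \sigma^2_{region} + 1$, not the
residual alone. Yearling weight can be generated alone or jointly with
the defect under a 2×2 genetic covariance with the residual constraint
$R[1,1] = 1$; the default residual cross-covariance is zero, so any
phenotypic association between the traits flows through the genetic
covariance. Ages are uniform on the 340–670-day window. An optional
truncation-selection rule on true breeding values produces declining
genetic trends for trend testing.

What the generator does not emulate: overlapping generations, maternal
effects, non-random mating, farm geography, and selective recording. A
recovery test passing here shows the estimator is consistent with its own
assumptions — not that real field data meet them.

### A caveat on desk-scale recovery of low-heritability binary traits

At ~2,000 phenotyped animals and 5% incidence (roughly 100 affected), the
posterior for a true liability $h^2$ of 0.16 is honest but wide (95%
intervals typically 0.07–0.5), and for a minority of simulated herds the
multi-generation likelihood places real mass near the separation mode, so
posterior means scatter above the truth more often than below. The exact
quadrature oracle shows this is a property of the posterior at this data
size, not of the sampler. Production-scale data (hundreds of thousands of
records, as in the motivating application) do not have this problem; at
desk scale the convergence flags and the interval — not the point
estimate — are the meaningful outputs.

## Trends, lineages, reports

Genetic trends regress the per-birth-year mean EBV of animals with known
sire, standardized by the posterior mean genetic standard deviation, on
birth year; the default uses annual means (a cumulative-means variant is
provided, as the "subsequent means" phrasing common in this literature is
ambiguous), and $R^2$ is defined as 0 for a zero-variance response.
Paternal lineages collect each animal's male-line ancestors within three
generations — sire, both grandsires, all four great-grandsires — count
defect-affected descendants per candidate ancestor, found lineages on the
top-ranked ancestors, and assign each animal to the founder with the most
affected descendants (ties to the lower pedigree code), so memberships are
disjoint and reproducible under input permutation. Defect percentages use
phenotyped members as the denominator. `render_reports()` assembles the
occurrence, variance-component and lineage tables in a fixed trait order
with a JSON twin; the headline heritability is the posterior mean of the
per-sample $h^2$, with the ratio-of-posterior-means variant also reported
since published tables are often consistent with the latter.

## Worked example

```{r example, eval = FALSE}
herd <- simulate_herd(sim_config(seed = 1))
fit <- fit_animal_model(herd$records, herd$pedigree, "FL",
                        config = gibbs_config(scale_factor = 0.02, seed = 1))
summary(fit)
trend <- genetic_trend(ebv_by_birth_year(ebv(fit), herd$pedigree),
                       genetic_sd = sqrt(mean(fit$samples$sigma2_a)))
trend
```

The chunk is not evaluated during package build (a 20,000-cycle chain
takes ~10 s); the README shows the printed output of exactly this code.
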