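---
title: "Two-sample Mendelian randomization with mrpipe: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

## The causal model

Mendelian randomization (MR) uses genetic variants as instrumental
variables for a modifiable exposure. A variant $j$ is a valid instrument
for exposure $X$ on outcome $Y$ under three assumptions: it is robustly
associated with $X$ (relevance); it is independent of confounders of the
$X$–$Y$ relationship (independence); and it affects $Y$ only through $X$
(exclusion restriction). In the two-sample summary-statistics setting the
data per SNP are $(\hat\beta_{Xj}, \sigma_{Xj})$ from an exposure GWAS and
$(\hat\beta_{Yj}, \sigma_{Yj})$ from a separate outcome GWAS, with

$$\hat\beta_{Yj} \approx \theta\,\beta_{Xj} + \alpha_j + \varepsilon_j,$$

where $\theta$ is the causal effect (log-odds per SD of exposure for a
binary outcome) and $\alpha_j$ is a possible direct (horizontally
pleiotropic) effect. Each estimator in the package corresponds to a
different assumption about the $\alpha_j$:

* **Wald ratio**: $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$, with
  first-order SE $\sigma_{Yj}/|\hat\beta_{Xj}|$. The first-order SE
  ignores exposure-side noise, the standard default when all instruments
  have $F = \beta^2/\sigma^2 > 10$; `wald_ratio(second_order = TRUE)`
  adds the exposure-side term for weak-instrument settings.
* **IVW** (`mr_ivw()`): the inverse-variance weighted mean of the Wald
  ratios, identical to weighted least squares of $\hat\beta_Y$ on
  $\hat\beta_X$ through the origin with weights $1/\sigma_Y^2$. Unbiased
  when pleiotropy is absent or balanced. The multiplicative
  random-effects mode scales the fixed-effect SE by $\sqrt{Q/(J-1)}$ and
  deliberately does **not** truncate the factor below 1 (the pure
  multiplicative-regression convention; some implementations truncate,
  which can only enlarge the SE). Both modes share the point estimate.
* **MR-Egger** (`mr_egger()`): the same regression with a free intercept,
  after orienting every SNP so the exposure effect is non-negative. Under
  the InSIDE assumption (pleiotropy independent of instrument strength)
  the slope is a consistent causal estimate even under directional
  pleiotropy, and the intercept estimates the mean pleiotropic effect;
  an intercept p-value above 0.05 is the usual no-pleiotropy criterion.
  Coefficient SEs carry the analogous untruncated $\sqrt{Q_E/(J-2)}$
  scale.
* **Weighted median** (`mr_weighted_median()`): the inverse-variance
  weighted median of the ratios, consistent while instruments carrying
  at least half of the total weight are valid. The point estimate
  interpolates linearly in cumulative normalized weight (so equal weights
  reduce it to the ordinary median); the SE comes from a seeded
  parametric bootstrap (default 1000 draws) that redraws both beta
  vectors from their sampling distributions.

All p-values are two-sided normal on $\hat\theta/\widehat{se}$, the
summary-data MR convention, and every estimate is reported on the
log-odds scale and as an odds ratio per SD with a 95% CI.

Heterogeneity among ratios is quantified by Cochran's
$Q = \sum_j w_j(\hat\theta_j - \hat\theta)^2$ against $\chi^2_{J-1}$
(`cochran_q()`; $J-2$ when the reference is an Egger fit), and
`mr_leave_one_out()` ranks instruments by how far the IVW estimate moves
when each is omitted.

## MR-PRESSO

`mr_presso()` implements the residual-sum-and-outlier battery. The
observed statistic is $RSS = \sum_j w_j(\hat\beta_{Yj} -
\hat\beta_{Xj}\hat\theta_{(-j)})^2$ with leave-one-out IVW slopes
$\hat\theta_{(-j)}$ and $w_j = 1/\sigma_{Yj}^2$; its null distribution is
simulated by redrawing $\beta_X^* \sim N(\hat\beta_X, \sigma_X^2)$ and
$\beta_Y^* \sim N(\hat\beta_X\hat\theta_{(-j)}, \sigma_Y^2)$. Empirical
p-values use the add-one rule $(1 + \#\{RSS^* \ge RSS\})/(n_{sim}+1)$, so
they can never be exactly zero. Per-SNP outliers are flagged when their
empirical residual p-value falls below $\alpha/J$; Bonferroni is the
default because $J$ per-SNP tests are performed, with
`multiplicity = "none"` available for the unadjusted 0.05 rule. The
distortion test compares the relative shift of the IVW estimate after
removing the flagged SNPs against shifts from removing equally many
random SNPs (1000 seeded draws without replacement), and the corrected
estimate is exactly the IVW fit on the retained instruments — one round
of removal, no iterated re-testing. The simulation count defaults to
1000 and the seed is a required argument: identical inputs, seed and
`n_sim` reproduce the result bit for bit.

## Multivariable MR and mediation

`mr_mvmr()` regresses outcome effects jointly on $K$ exposure-effect
columns without an intercept (weights $1/\sigma_Y^2$), giving each
exposure's **direct** effect adjusted for the co-exposures; with $K = 1$
it reduces exactly to random-effects IVW. The conditional heterogeneity
$Q_{cond}$ has $J - K$ degrees of freedom and supplies the untruncated
multiplicative SE scale. Instruments significant for *any* included
exposure enter the fit (the union rule, which maximizes $J$; a
primary-exposure-only subset can be passed explicitly). Because a strong
marginal instrument can be conditionally weak, the package reports a
per-exposure conditional-strength approximation — the mean weighted
squared residual of that exposure's effects after projecting out the
co-exposures — and warns below the conventional bar of 10. Exposure
columns that are identically zero are dropped with a warning rather than
aborting; genuine collinearity is a fatal error naming the offending
exposures.

Two-step mediation (`mr_mediation()`) decomposes a total effect: step 1
estimates exposure→mediator ($a$) by univariable IVW using the
exposure's instruments; step 2 estimates mediator→outcome adjusted for
the exposure ($b$) from the joint multivariable fit. The indirect effect
is $ab$ with delta-method SE $\sqrt{a^2\sigma_b^2 + b^2\sigma_a^2}$ —
the $a$–$b$ covariance is set to zero because the two coefficients come
from separate regressions against separate outcome datasets — and the
proportion mediated is $ab/\theta_{total}$. The proportion SE propagates
both the indirect and the total variance by default
(`total_fixed = TRUE` conditions on the total), and intervals are
symmetric normal intervals on the computed scale; asymmetric intervals
(e.g. bootstrap percentile) are not implemented. The total effect used
in the proportion is the univariable IVW on the full instrument set,
before any outlier removal; the outlier-corrected total can be supplied
instead since all three inputs are plain estimates. A candidate only
proceeds to the decomposition when the step-1 estimate is significant
(`mediation_gate()`, strict inequality at $\alpha = 0.05$).

```{r mediation}
z <- qnorm(0.975)
total <- mr_estimate("ivw_fe", log(1.19), (log(1.35) - log(1.04)) / (2 * z), 229)
a <- mr_estimate("ivw_fe", 0.05, (0.09 - 0.01) / (2 * z), 229, outcome = "BMI")
b <- mr_estimate("mvmr", log(1.70), (log(2.07) - log(1.39)) / (2 * z), 240,
                 exposure = "BMI")
mr_mediation(total, a, b)
```

## Power for a binary outcome

`mr_power_binary()` implements the closed-form normal approximation for
an IVW-style test against a binary outcome. With case fraction $K$, the
attenuated risk-scale association of the instrument score is
$b = K\left(\frac{OR}{1 + K(OR - 1)} - 1\right)$, its variance is
$v = (K(1-K) - b^2)/(N R^2)$ with $R^2$ the exposure variance explained
by the instruments, and power is $\Phi(|b|/\sqrt{v} - z_{1-\alpha/2})$.
This is a linearization of the logistic risk: it is accurate for modest
odds ratios (the package's Monte-Carlo agreement check runs at OR 1.2,
where formula and simulation agree within simulation error; by OR 1.5
the formula is optimistic by several points). At the null OR = 1 the
one-tail-of-two-sided construction returns $\alpha/2$.

```{r power}
mr_power_binary(n_total = 213746, case_fraction = 3283 / 213746,
                odds_ratio = 1.36, r2 = 0.0476)
```

## Instrument selection and harmonization

Selection keeps SNPs with association p-value strictly below the
threshold (5e-8 by convention; a relaxed per-trait threshold such as
1e-5 is supported for traits with few genome-wide hits). Greedy clumping
sorts by p-value (ties broken by rsID for determinism) and accepts a SNP
unless it lies within the ±1 Mb window of an accepted SNP on the same
chromosome with LD $r^2 \ge 0.001$. Pairs **absent** from the supplied
LD table but inside the window are treated as dependent: the artifact
does not ship a reference panel, and silently keeping a possibly
correlated instrument is the worse error.

Harmonization aligns every trait to the primary exposure's effect
allele, negating betas and mirroring allele frequencies on swaps. All
palindromic (A/T, C/G) SNPs are dropped unconditionally — no
frequency-based rescue, since strand cannot be resolved from labels.
Instruments missing from the outcome may be replaced by an
outcome-present proxy with LD $r^2 > 0.8$ (ties broken by rsID); the
proxy's effect allele is assumed concordant with the index SNP's
exposure-increasing allele, an assumption that true phase data would be
needed to verify — a documented limitation. SNPs associated with the
outcome below 5e-8 are excluded to protect the exclusion restriction;
the threshold is configurable because "significant" admits several
conventions. Every removal is logged with exactly one reason code, so
input SNP counts are conserved.

Instrument strength is summarized by per-SNP $F = \beta^2/\sigma^2$ and
$R^2 = 2\,\text{EAF}(1-\text{EAF})\beta^2$; the per-exposure headline F
is the arithmetic mean (minimum and median are also reported, since
aggregation conventions vary), with a warning below 10.

## The synthetic-data generator

`simulate_two_sample()` draws summary statistics directly at the summary
level — no individual genotypes. Its defaults emulate the study design
the package targets: a continuous biomarker from a large biobank GWAS
($N = 361{,}194$), a rare binary kidney-disease outcome from a second
biobank ($N = 213{,}746$, case fraction $3283/213746$), 234 independent
instruments jointly explaining about 9.6% of exposure variance (the
per-SNP effect SD is calibrated from the target $R^2$ via
$E[2p(1-p)] = 0.365$ for $p \sim U(0.05, 0.95)$), and a true odds ratio
of 1.19 per SD. Standard errors follow the standard GWAS approximations
$\sigma_X = (2p(1-p)N)^{-1/2}$ and, for a logistic outcome,
$\sigma_Y = (2p(1-p)NK(1-K))^{-1/2}$.

Two conventions deserve note:

* **Pleiotropy is defined on the exposure-increasing allele**: the
  direct effect enters the outcome as $\mathrm{sign}(\gamma_j)\alpha_j$
  with $\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)$ drawn
  independently of $\gamma_j$ (so InSIDE holds in the oriented frame).
  With symmetric $\gamma_j$ and Egger's orientation to positive exposure
  effects, a frame-fixed directional offset would average to zero and
  "directional pleiotropy" would be undetectable by construction;
  anchoring the offset to the exposure-raising allele is the standard
  simulation convention and makes the Egger intercept estimand equal
  $\mu_\alpha$. Even so, the identity is asymptotic in instrument
  strength: when an instrument's observed effect sign is misclassified,
  its pleiotropy flips in the oriented frame, attenuating the intercept
  by roughly $2\,P(\text{flip})\,\mu_\alpha$. The package's intercept
  recovery experiment therefore uses a large exposure GWAS
  ($N = 5\times 10^6$), where sign errors are negligible.
* **Planted outliers** add $\mathrm{sign}(\gamma_j)\,m\,\sigma_{Yj}$ to
  the true outcome association ($m$ = `outlier_magnitude`, default 10),
  producing the directional, null-ward-or-away biases that the
  MR-PRESSO battery is designed to catch.

`simulate_mediation()` adds a mediator pathway ($M = a\gamma + \delta$,
$Y = c\gamma + bM + \dots$) plus mediator-specific instruments so the
joint multivariable fit is identified; the exposure's total effect is
$c + ab$ by construction, and the default paths ($a = 0.05$,
$b = \ln 1.70$, $c$ derived so the total is $\ln 1.19$) put the true
proportion mediated at about 15%. What the generator does **not**
emulate: LD between instruments (they are post-clumping by
construction), population stratification, sample overlap between the
two GWAS, and winner's curse from selecting on the discovery sample.
Passing tests therefore certify the estimators and the plumbing, not
robustness to those real-data complications.

## Numerical choices and problem sizes

Ties in clumping order and proxy choice break lexicographically by
rsID. Simulated p-values are floored at 1e-300 so extreme associations
stay inside $(0, 1]$. The weighted-median bootstrap, MR-PRESSO draws,
distortion resampling and the generator all require explicit seeds; the
pipeline derives its stage seeds from the single config seed, and two
runs with the same config produce byte-identical reports (the report's
provenance block records the config's MD5 and the seed). Statistical
recovery experiments in the test suite use 200–2000 replicates at
$J = 20$–100 instruments — sizes chosen so Monte-Carlo error is small
relative to the effects under test while the whole suite stays
desk-scale — and recovery is asserted within two Monte-Carlo standard
errors against the generator's closed-form truth. The mediation and
multivariable recovery experiments use a balanced case-control outcome
($K = 0.5$, $N = 5\times10^5$) so that the ratio estimator's denominator
noise does not swamp the quantity being checked.

## Known limitations

Proxy alignment assumes allele concordance (above); the weighted-median
SE is bootstrap-based and hence seed-dependent; MVMR-Egger,
mode-based estimators, Steiger directionality filtering and multi-mediator
decompositions are out of scope; and the power formula's accuracy
degrades for large odds ratios. The pipeline's confounder/mediator list
is configuration — choosing biologically sensible confounders remains a
human step.
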