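---
title: "Models and methods in meiorec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in meiorec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

meiorec analyses meiotic crossover data along three axes: per-meiosis
recombination phenotypes and their genotype association, crossover
interference under the Housworth–Stahl two-pathway model, and fixed-effects
meta-analysis of case-control association summary statistics. Because
individual-level crossover and disease data of the kind that motivates these
analyses are not publicly distributable, the package ships a fully seeded
synthetic-data generator that emulates each data type, and every analysis
stage is validated against it. This vignette records the models, the
numerical choices, and what the simulations do and do not establish.

## The Housworth–Stahl crossover model

Crossovers on a transmitted chromatid arise from two independent pathways on
the genetic scale (Morgans):

* **Interference pathway.** Chiasmata on the four-strand bundle follow a
  stationary gamma renewal process with shape $\nu > 0$ and rate
  $2\nu(1-p)$ per Morgan, so inter-chiasma gaps have mean $1/(2(1-p))$.
  Each chiasma involves the transmitted chromatid with probability $1/2$
  (thinning). The gap between successive *retained* crossovers is therefore a
  geometric mixture of gamma sums,
  $$f(x) = \sum_{k\ge1} 2^{-k}\,\mathrm{Gamma}\!\left(x;\, k\nu,\, 2\nu(1-p)\right),$$
  with mean $1/(1-p)$ Morgans.
* **Escape pathway.** An interference-free Poisson process with rate $p$ per
  Morgan.

The combined intensity is exactly 1 crossover per Morgan for every
$(\nu, p)$ — the genetic map calibrates itself. $\nu = 1$ with $p = 0$
collapses to a homogeneous Poisson process; $\nu > 1$ spaces crossovers more
evenly than Poisson.

### Likelihood

For an interval of genetic length $L$ carrying observed crossovers
$y_1 < \dots < y_n$, the likelihood sums over all $2^n$ assignments of points
to the interference pathway. A subset $S = \{s_1 < \dots < s_m\}$ assigned to
the interference pathway contributes
$$p^{\,n-m} e^{-pL}\; h(s_1) \prod_{j=1}^{m-1} f(s_{j+1}-s_j)\,\big(1 - F(L - s_m)\big),$$
with the stationary first-point density $h(x) = (1-p)(1 - F(x))$ and, for
$S = \varnothing$, the empty-interval probability
$P_0(L) = 1 - (1-p)\int_0^L (1-F)$. Meioses with *no* crossover on a
chromosome still carry information through $P_0$ and must be included; the
`stahl_data()` container therefore tracks the full meiosis set.

Two useful exact reductions anchor the implementation:

* at $\nu = 1$ the subset sum telescopes and the total log-likelihood equals
  $-\sum L$ — minus the total Morgans scored — independent of the positions
  and of $p$;
* the empty-interval probability can be checked against the simulated
  frequency of empty intervals.

### Numerical choices

* The series for $f$, $F$, and $\int_0^L(1-F)$ is truncated at $K = 34$
  terms ($2^{-K} < 10^{-10}$); the tail of the survival mixture is absorbed
  as $+2^{-K}$, which is also the correct limit of the large-$k$ components
  at any argument of interest. The CDF and its integral use exact `pgamma`
  identities ($\int_0^L F_k = L F_k(L) - (k\nu/\beta) F_{k\nu+1}(L)$) rather
  than quadrature, so normalization holds to near machine precision.
* Gamma log-densities are combined by log-sum-exp; the subset sum is
  evaluated through a precomputed index structure (one pass per dataset) and
  `rowsum`, with a per-row log-sum-exp fallback if a row underflows.
* The per-interval crossover count is guarded at $n \le 25$ (the enumeration
  is $2^n$); simulated human-scale chromosomes stay far below this.
* The optimizer works on $(\log\nu, \mathrm{logit}\,p)$: a coarse
  $5\times5$ grid start followed by Nelder–Mead, with the $p$ boundary
  handled by flooring $\mathrm{logit}\,p$ at $-12$. Inside the optimizer the
  density and survival are interpolated from a cached grid (2048 points by
  default); we verified on simulated data at $\nu = 6.59$ that the
  grid-interpolated MLE coincides with the exactly evaluated one to three
  decimals in $\nu$, while coarser grids (512 points) shift $\hat\nu$ by a
  few percent — hence the conservative default. `stahl_loglik()` itself
  defaults to exact evaluation.
* Standard errors, when requested, come from the numerically differentiated
  observed information on the transformed scale and the delta method.

The carrier/noncarrier comparison (`carrier_lrt()`) fits pooled and
group-specific models and refers $2(\ell_1 + \ell_2 - \ell_{pooled})$ to
$\chi^2_2$ (Wilks). Group fits are warm-started at the pooled optimum, which
saves roughly half the likelihood evaluations without changing the optimum.

### Simulator

`simulate_stahl_process()` realizes the chiasma renewal process by burn-in:
gamma gaps are accumulated from $20$ mean inter-chiasma gaps to the left of
the interval (about 10 Morgans), which makes the start effectively
stationary; retained chiasmata are thinned at $1/2$ and the Poisson escape
points superimposed. The burn-in alternative to sampling the
forward-recurrence density was chosen for simplicity; the Poisson closed
forms (count distribution, empty-interval frequency) are used in the tests
to confirm the bias is below Monte-Carlo resolution.

## Recombination phenotypes

Five per-meiosis phenotypes are computed genome-wide and per chromosome:
crossover count (RR), hotspot usage (RH: fraction of crossovers in intervals
whose local rate is at least 10 times the genome-average cM/Mb), telomere
distance (TD), GC content (GC) and replication timing (RT) around the
crossovers. Conventions the package fixes where the field's descriptions are
loose:

* **TD normalization** divides the distance to the nearest chromosome end by
  the full chromosome length, so TD lies in $[0, 0.5]$ and equals $0.25$ in
  expectation for uniformly placed crossovers. Normalizing by half-length
  would double all values; only the carrier/noncarrier contrast matters
  downstream, but the constant is fixed and documented here.
* **GC/RT windows** are 1,000 bp centered on the crossover point, clipped at
  chromosome ends, averaged length-weighted over the track bins.
* **Hotspot calling** scans fixed-width bins (10 kb default, configurable)
  of the genetic map and merges adjacent bins at or above the fold
  threshold; the bin width used upstream of the published 10× definition is
  not documented anywhere we could find, so it is a parameter.
* Meioses with no crossover in scope have RR = 0 and missing location
  phenotypes; missing values are dropped per phenotype before rank
  normalization.
* **Rank-inverse-normal transform** uses offset ranks $(r - 1/2)/m$ with
  average ranks for ties. The Blom offset $(r - 3/8)/(m + 1/4)$ differs
  negligibly at cohort sizes; the choice is stated for reproducibility.

## Association and the chromosome-length interaction

Genotype association is ordinary least squares of the rank-normalized
phenotype on allele dosage (additive model), with optional covariates;
effects are in s.d. units and are converted to native units by multiplying
with the raw per-scope phenotype SD. Per-chromosome effects feed a weighted
linear regression of effect on physical chromosome length (Mb) with weights
equal to the inverse variance of each effect estimate — the natural reading
of "effect estimates and their variance used as input into a linear
regression" with `lm`. With equal weights this reduces exactly to unweighted
OLS, which the tests assert.

## Case-control meta-analysis

Per-cohort logistic regression (IRLS via `glm`) yields log-OR estimates that
are pooled by fixed-effects inverse variance:
$w_i = 1/\mathrm{se}_i^2$, $\hat\beta = \sum w_i\beta_i / \sum w_i$,
$\mathrm{se} = (\sum w_i)^{-1/2}$, with Cochran's
$Q = \sum w_i(\beta_i - \hat\beta)^2 \sim \chi^2_{k-1}$ for heterogeneity.
No random-effects model is offered — the target design is fixed-effects.
Multiplicity uses class-based weighted Bonferroni thresholds
$t_c = \alpha w_c / \sum_{c'} n_{c'} w_{c'}$, which satisfy
$\sum_c n_c t_c = \alpha$ exactly; the published five-class threshold ladder
(ratios roughly 330:66:6:3:1) is reproducible by choosing the weights
accordingly, which are configuration, not constants, since the exact class
weights are not published. The binomial enrichment helper defaults to the
one-sided upper tail $P(X \ge k)$ with sidedness as a flag, because the
sidedness convention behind published enrichment values of this kind is not
always stated.

The cohort simulator draws genotypes under Hardy–Weinberg and case status
from $\mathrm{logit}\,P = \alpha_c + d\log\mathrm{OR}$ with $\alpha_c$
calibrated by `uniroot` to the requested case fraction, so the realized
2×2 carrier odds ratio and the per-cohort case fractions are testable
against their targets.

## The synthetic-data generator as a study stand-in

The generator reproduces the *mechanisms* the analyses assume: a stationary
renewal interference process with escape, Hardy–Weinberg parent genotypes,
dosage-additive parameter interpolation (heterozygote midway between
homozygotes), an optional monotone "distal shift" warp of the genetic map
toward the chromosome ends (strength $a + b\,l$ per chromosome of length
$l$ Mb, scaled by dosage/2, endpoints and total map length preserved) that
induces known-sign telomere-distance and length-interaction effects, and
case-control cohorts with a known odds ratio. It deliberately does **not**
emulate: interval-resolved (marker-censored) crossover calls — positions are
exact points; genotyping or imputation error; relatedness or population
structure; covariate confounding; paternal meioses. Passing tests therefore
establish correctness of the estimators under the generating model, not
robustness to those real-data complications.

Default simulation scales were chosen once as the smallest sizes at which
the quantities of interest are statistically stable: parameter recovery uses
3,000 meioses over 5 chromosomes of 1–3 Morgans (MLE scatter in $\nu$ about
±2% there); null-calibration suites use 200 seeds of a few hundred meioses
with interior parameters ($\nu = 3$, $p = 0.15$) so that Wilks asymptotics
are not distorted by the $p \ge 0$ boundary; meta-analysis recovery uses
4 cohorts totalling 20,000 cases / 80,000 controls at risk-allele
frequencies 0.2–1.3%.

## Known limitations

* The exact subset-sum likelihood is exponential in the per-interval
  crossover count; it is intended for human-scale chromosomes (a few
  Morgans), not for organisms or intervals with tens of crossovers.
* `p` near its boundary makes its standard error asymmetric; use the LRT
  rather than Wald intervals for hypotheses about `p`.
* The distal-shift warp is a phenomenological device for producing
  length-graded positional effects; it is not a mechanistic model of where
  carrier crossovers relocate.
* Genetic maps are treated as error-free inputs; map uncertainty is not
  propagated.
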