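---
title: "Multi-stage randomized response: model, estimation, privacy and design comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-stage randomized response: model, estimation, privacy and design comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrstage)
```

## The problem

Asking people directly whether they carry a stigmatizing attribute — drug
use, psychiatric illness, infidelity — produces evasive-answer bias.
Randomized-response techniques interpose a chance device between the
question and the answer: because the interviewer cannot know which question
a respondent actually answered, individual answers are uninformative enough
to protect, while the population prevalence $\pi$ remains estimable from the
aggregate.

`rrstage` implements a family of such devices with $j$ stages. At stage $g$
(visited in order, stage 1 first) the respondent privately draws one of two
options: with probability $p_g$ the direct sensitive question, otherwise
(probability $q_g = 1 - p_g$) they continue to the next stage. The last
stage is a Warner draw — its continuation branch asks the *complement*
question, so a carrier answers "no" there. Taking $j = 1, 2, 3$ recovers
the classical Warner, Mangat–Singh and three-stage designs as special
cases; all four families share one code path here.

## Estimation

Conditioning on carrier status shows the answer depends on the design only
through $Q = \prod_g q_g$:
$P(\text{yes}\mid D) = 1 - Q$, $P(\text{yes}\mid \bar D) = Q$, hence
$$\alpha = P(\text{yes}) = (1 - 2Q)\,\pi + Q .$$
`alpha_of_pi()` evaluates both this closed form and the literal stage
recursion (the nested sum over where the walk terminates); their agreement
to $10^{-12}$ over randomized designs is a standing test, and the recursion
is the reference implementation.

Inverting the affine map at the sample yes-fraction $\hat\alpha$ gives the
unbiased estimator and its variance,
$$\hat\pi = \frac{\hat\alpha - Q}{1 - 2Q}, \qquad
V(\hat\pi) = \frac{\pi(1-\pi) + Q(1-Q)(1-2Q)^{-2}}{n},$$
and the unbiased variance estimator
$\hat V = \hat\alpha(1-\hat\alpha)(1-2Q)^{-2}/(n-1)$. The $n-1$ divisor is
essential: $E[\hat\alpha(1-\hat\alpha)] = \alpha(1-\alpha)(n-1)/n$, so
dividing by $n-1$ (not $n$) is exactly what makes $E[\hat V] = V$. The key
algebraic step is the factorization
$\alpha(1-\alpha) = \pi(1-\pi)(1-2Q)^2 + Q(1-Q)$, also identity-tested.

### Raw versus truncated estimates

$\hat\pi$ can fall outside $[0,1]$ (e.g. $\hat\alpha < Q$ in a small
sample). The package reports both the raw and the clamped value. All
internal statistics — Monte-Carlo bias, variance, coverage — use the *raw*
estimator, because unbiasedness and the variance theory hold only for it;
the truncated copy is what a practitioner would quote as a prevalence.
This dual report is a deliberate design choice where the theory is silent.

### Intervals

`wald_interval()` builds a normal-approximation interval on the raw scale,
$\hat\pi \pm z_{(1+\ell)/2}\sqrt{\hat V}$, clamped to $[0,1]$ afterwards.
A Wald interval was chosen because $n\hat\alpha$ is binomial and the
estimator is a linear transform of $\hat\alpha$; exact or bootstrap
intervals are out of scope. At $n = 1000$, $Q = 0.1$, $\pi = 0.3$ the
Monte-Carlo coverage sits near 0.946 — the usual mild Wald undercoverage.

## The singular point and degenerate designs

At $Q = 0.5$ the answer distribution does not depend on $\pi$: maximal
privacy, no information, and the estimator's denominator vanishes. Designs
with $|Q - 0.5| < 10^{-9}$ are constructible (probability evaluation still
works) but flagged, and every estimation or comparison routine refuses them
with a typed error. The hard tolerance makes the contract testable; the
variance blows up continuously as $Q \to 0.5$, so no useful design lives
near the excluded band anyway. Endpoint stage probabilities 0 and 1 are
allowed: they produce well-defined degenerate devices (e.g. $Q = 0$ is
direct questioning), and keeping them total simplifies the simulator. At
$Q \in \{0, 1\}$ the privacy measure is infinite; serialized output carries
an `unbounded` flag rather than a float infinity.

## Privacy and its exact trade-off with efficiency

The likelihood ratios of the two answers are $\tau_y = (1-Q)/Q$ and
$\tau_n = Q/(1-Q)$; the scalar privacy-protection measure is
$$M = \frac{\tau_y + \tau_n}{2} - 1 = \frac{(1-2Q)^2}{2Q(1-Q)} ,$$
zero at $Q = 0.5$ (answers reveal nothing) and unbounded at $Q \in \{0,1\}$
(answers reveal status deterministically). The variance decomposes exactly
as
$$V(\hat\pi) = \frac{\pi(1-\pi)}{n} + \frac{1}{2nM},$$
which the package verifies against the direct variance formula to
$10^{-12}$; smaller $M$ (more privacy) means larger variance, with nothing
in between. This identity also settles an ambiguity in the measure's
printed form: $(1-2Q)^2$ in the numerator is the unique reading under which
the decomposition holds.

## Comparing designs

Because the sampling term $\pi(1-\pi)/n$ is common to all same-$n$ designs,
every efficiency comparison reduces to the design component
$f(Q) = Q(1-Q)/(1-2Q)^2$: `compare_designs()` reports
$\text{diff} = f(Q_b) - f(Q_a) = n(V_b - V_a)$, free of $\pi$ and $n$, so
surfaces and dominance claims need no assumed prevalence or sample size —
the formulation preserves every sign and monotonicity statement one could
make at any fixed $\pi, n$. $f$ is symmetric about $0.5$ and strictly
increasing in $Q(1-Q)^{-1}$-distance from the endpoints, which yields the
closed-form dominance rule for nested designs: a $j$-stage device beats its
own first $j-g$ stages iff the trailing continuation product is below
$(1-Q_{j-g})/(1-Q_j)$ — equivalent to $Q_j(1-Q_j) < Q_{j-g}(1-Q_{j-g})$,
and property-tested against brute-force variance comparison on $10^4$
random nested pairs.

Two indexing conventions exist for multi-stage devices (stage-of-visit
versus distance-from-the-end). This package takes user input in visit
order throughout; since every quantity of interest depends on the design
only through continuation products, the two conventions are observationally
identical, and the nested rule is stated for visit-order prefixes.

### Matched designs

`matched_single_stage_q()` and `matched_leading_q()` solve $f(q) = f(Q)$
for the classical design with identical efficiency, by `uniroot` on the
sub-0.5 branch cross-checked against the closed form $\min(Q, 1-Q)$. For
the four-stage device with continuation probabilities
$(0.8, 0.5, 0.5, 0.5)$ ($Q = 0.1$) the matches are Warner at $q_1 = 0.1$,
the two-stage design at $q_1 = 0.2$ (trailing 0.5) and the three-stage
design at $q_1 = 0.4$ (trailing 0.5, 0.5); the permutation
$(0.5, 0.5, 0.5, 0.8)$ has the same $Q$, and the Warner design with
$p_1 = 0.9$ matches it in *both* privacy and efficiency. These four values
are what `scripts/acceptance.R` recomputes.

A practical reading: many weakly-protecting stages with low sensitive-
question probability per stage buy the same efficiency as one aggressive
Warner draw, while looking far less threatening to the respondent.

### Surfaces and curves

`efficiency_surface()` tabulates diff over a Cartesian grid of the four
continuation probabilities against the Warner / two-stage / three-stage
baselines built from the same leading probabilities. On the practicable
grid ($q_i \in \{0.1, \dots, 0.4\}$ — values below 0.5 being the regime
respondents find credible) the four-stage device wins at every grid point,
and its advantage over the three-stage baseline strictly grows as $q_4$
decreases. Grid resolution defaults to 0.1 steps; singular grid points are
flagged, never silently dropped. `variance_curves()` draws the four nested
variance curves at fixed $\pi, n$; with all trailing probabilities at 0.5
the four-stage curve lies below the two- and three-stage baselines for
every leading $q_1$, and below Warner exactly where the nested dominance
condition holds (it fails for $q_1$ near 1, where Warner's own $Q$ is close
to an endpoint).

## The simulator

`simulate_survey()` draws $n$ latent carrier statuses
$\mathrm{Bernoulli}(\pi)$ and walks each respondent through the device with
one seeded Mersenne–Twister stream consumed in respondent order (the
caller's RNG state is untouched; identical seeds give byte-identical CSV
output). The simulator emulates the full protocol — per-stage branch
draws, terminal stage, truthful answering — and its stage-occupancy
distribution and conditional answer rates are tested against the theory.
By default the output table contains only what a real interviewer would
see (`respondent_id`, `answer`); latent truth and terminal stage are
retained only under `keep_truth = TRUE`.

What it does *not* emulate: untruthful or non-complying respondents (the
model assumes complete honesty; extending to partial truthfulness is
future work), finite-population corrections, and any respondent
heterogeneity in how the device is operated. Passing Monte-Carlo checks
therefore validates the estimator theory under the model's own
assumptions, not robustness to their violation.

`monte_carlo_study()` validates the theory: by default it draws each
replicate's yes-count directly from $\mathrm{Binomial}(n, \alpha)$ — the
exact marginal law of the yes-count, since respondents are i.i.d. — which
makes $2\times10^4$ replicates essentially instant; a `respondent` method
walks every respondent instead, and a two-sample proportion test confirms
the two routes are statistically indistinguishable. The standard
validation run here uses $Q = 0.1$, $\pi = 0.3$, $n = 1000$ with
$2\times10^4$ replicates: bias within three Monte-Carlo standard errors of
zero, and both the empirical-variance and mean-$\hat V$ ratios to the
theoretical variance within $[0.95, 1.05]$.

## Numerical choices

* Singular band $|Q - 0.5| < 10^{-9}$; root-finding tolerance $10^{-12}$
  with brackets $(10^{-12},\, 0.5 - 10^{-9})$ for matched designs.
* Identities (recursion vs closed form, variance factorization, privacy
  decomposition) asserted at $10^{-12}$ over 1000 randomized designs with
  up to 8 stages.
* JSON/TSV artifacts are written at 12 significant digits so outputs diff
  cleanly across runs.
* Property-test problem sizes — 1000-design identity sweeps, $10^4$ nested
  dominance pairs, $10^5$-respondent marginal checks, $2\times10^4$
  Monte-Carlo replicates — were chosen to make three-standard-error bounds
  decisive for the effects under test while keeping the whole suite in
  well under a minute.

## Limitations

The estimator is undefined at $Q = 0.5$ and unstable near it; the Wald
interval mildly undercovers at moderate $n$; truncation to $[0,1]$
introduces bias exactly when the raw estimator leaves the unit interval
(small $n\pi$); and all guarantees assume truthful, independent
respondents. Alternative privacy measures and lying models are outside the
package's scope.
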