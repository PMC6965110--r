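---
title: "Fixation dynamics and the accumulation of adaptive steps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixation dynamics and the accumulation of adaptive steps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(fixstep)
```

`fixstep` asks a quantitative question about the origin of a complex trait:
given a finite population and a fixed window of time, is the trait more
likely to have arisen through a single mutation of very large effect (a
*macro-mutation*) or through an adaptive walk of several mutations of
smaller effect? The package separates the question into the two factors
that govern any such scenario — the *a priori* probability that a mutation
of a given fitness effect occurs at all, and the conditional probability
that it then spreads to fixation — and provides tested machinery for each
factor plus the Monte-Carlo experiment that combines them.

This vignette is the package's methods account: the models, their
assumptions, the numerical choices, and what the synthetic data do and do
not establish.

## The selection model

The wild type has fitness 1. A mutant allele $A$ confers fitness $1 +
s_{aA}$ on heterozygotes and $1 + s_{AA}$ on homozygotes. Three standard
dominance patterns are built in — dominant ($s_{AA} = s_{aA}$),
semidominant ($s_{AA} = 2 s_{aA}$, equivalent to a haploid model) and
recessive ($s_{aA} = 0$) — plus a linearly frequency-dependent mode
$s_{aA}(p) = k_{het}\,p$, $s_{AA}(p) = k_{hom}\,p$, which models an
advantage (say, communication) that only materialises once carriers are
common. Selection coefficients are dimensionless; $s = 1$ already means
carriers leave on average twice the offspring of the wild type, which is
why the constructors warn above 1 — for a slowly reproducing vertebrate,
larger values are not biologically credible.

Population size enters twice: the census size $N$ (diploid individuals,
$2N$ alleles, a single new mutant starts at $p_0 = 1/(2N)$) and the
effective size $N_e$ driving drift, which defaults to $N$. The working
values in the shipped analyses — $N$ from 100 to 15 000 with 1500 as the
focal case — bracket hunter-gatherer band sizes and upper estimates of
ancestral human effective population size.

## Fixation probabilities: two diffusion routes and their disagreement

The diffusion approximation summarises one generation by the mean change
$M(p)$ and variance $V(p)$ of the allele frequency. The package implements
two classical pairs:

* the **haploid** pair
  $M = p(1-p)\,s/(1+sp)$, $V = \tfrac{p(1-p)}{2N}\,\tfrac{2+s}{1+sp}$,
  which admits the closed form
  $p_{fix}(p_0) = \bigl(1 - e^{-4N\frac{s}{2+s}p_0}\bigr) /
  \bigl(1 - e^{-4N\frac{s}{2+s}}\bigr)$
  (`fixation_probability_closed()`); and
* the **Kimura diploid** pair
  $M = p(1-p)\,(s_{aA} + (s_{AA} - 2s_{aA})p)$, $V = p(1-p)/(2N_e)$,
  which keeps both genotype coefficients and so covers recessive and
  frequency-dependent schemes.

For any pair, the fixation probability is the stationary absorption
solution $u(p_0) = \int_0^{p_0} G \,/\, \int_0^1 G$ with $G(x) =
\exp(-\int_0^x 2M/V)$, computed by `fixation_probability_quadrature()`.

The two routes do **not** agree, and the package is explicit about this
rather than papering over it. The haploid variance above is that of $N$
haploid individuals, while the initial frequency $1/(2N)$ counts $2N$
alleles; the net effect is that the closed form gives $p_{fix} \approx s$
for a single weakly selected semidominant mutant, where the Kimura route —
and an exactly solved Wright–Fisher Markov chain, and Haldane's classical
branching-process result — give $\approx 2s$. The test suite therefore
pairs the closed form with haploid-mode quadrature (an exact identity,
asserted to < 1% over $s \in [0.01, 1]$, $N \in [10^2, 1.5\times10^4]$),
and validates the Kimura route against the exact chain and the forward
simulator. Users comparing absolute fixation probabilities against
simulation should use `model = "kimura"` (the default for non-semidominant
schemes).

Accuracy of the Kimura route degrades as selection strengthens: against
the exact chain at $N = 100$ the error is $\sim$2% at $s = 0.05$ but +9%
at dominant $s = 0.5$ (diffusion overestimates; the strongest-selection
entries in the shipped tables are upper bounds in that sense). Conclusions
drawn in the analyses are ratio and order-of-magnitude statements, which
are robust to this bias.

### Numerics of the quadrature

$2M/V$ is formed with the shared $p(1-p)$ factor cancelled analytically,
so the integrand of $H(x) = \int_0^x 2M/V$ is a smooth bounded function
with no $0/0$ at the absorbing boundaries, and the $s = 0$ limit is
returned analytically (neutral fixation probability is exactly $p_0$;
coefficients below $10^{-12}$ in magnitude are treated as zero). Segment
integrals of $e^{-H}$ use an exponential-fitted rule that is exact when
$2M/V$ is locally constant, so the boundary layer that forms when
$N s \gg 1$ (width $\sim 1/(4Ns)$) is integrated accurately even on coarse
meshes, and only *differences* of $H$ are exponentiated — no overflow for
any $N s$. The mesh is doubled until successive answers agree to
`rel_tol` (default $10^{-8}$), starting from 2048 intervals with the
requested evaluation points inserted as nodes.

## Fixation times

The probability-weighted mean fixation time $\vartheta(p)$ — fixation
probability times mean time to fixation — solves the boundary-value
problem

$$M(p)\,\vartheta'(p) + \tfrac12 V(p)\,\vartheta''(p) = -p_{fix}(p),
\qquad \vartheta(0) = \vartheta(1) = 0,$$

and the mean time among lineages that fix is $\tau(p_0) =
\vartheta(p_0)/p_{fix}(p_0)$ (`conditional_fixation_time()`). The Kimura
drift/variance pair is the default here: treating the population as
haploid implicitly doubles the homozygote advantage, which is tolerable
for probabilities but visibly wrong for times.

Discretisation is second-order finite differences with the singular
endpoints excluded and the boundary values imposed exactly. The mesh is
uniform with 2000 interior nodes by default, with two refinements the
solver applies automatically:

* the evaluation point $p_0 = 1/(2N)$ is inserted as a node (it generally
  falls far below the uniform spacing), and
* a geometric cascade of nodes is added next to both boundaries
  (`boundary_refine = TRUE`). Without it, cells with $N s \gtrsim 2500$
  (e.g. $N = 15\,000$, $s \ge 0.1$) are unresolved: the linear system
  returns a boundary-layer artefact and the solver refuses to report a
  time. With the cascade, every cell of the shipped grids computes, and
  halving the mesh spacing moves $\vartheta(p_0)$ by well under 1%.

Sanity anchors: in the drift limit ($N s \to 0$) the solution reproduces
the classical $\tau \approx 4N_e$ generations within a fraction of a
percent; under weak selection ($s = 0.05$, $N \le 200$) it matches the
exact-chain conditional time within $\sim$3%. Under strong or strongly
nonlinear selection the continuous approximation is again the weak link:
recessive and frequency-dependent conditional times at $N = 100$ are
biased by $-7\%$ and $-20\%$ respectively relative to the exact chain.
The package reports these numbers; it does not claim simulation-grade
accuracy for them.

Calendar conversions multiply generations by a generation time of 25–30
years (`generations_to_years()`), the conventional range for humans.

```{r drift-limit}
conditional_fixation_time(scheme_dominant(1e-6), population(1500))
```

## The Wright–Fisher oracle

`wf_fixation_stats()` is a forward-time diploid simulator used throughout
the tests as the independent check on the analytics. Its definition *is*
the model: Hardy–Weinberg random mating each generation, the
selection-weighted expected frequency

$$p^* = \frac{p^2(1+s_{AA}) + p(1-p)(1+s_{aA})}
             {p^2(1+s_{AA}) + 2p(1-p)(1+s_{aA}) + (1-p)^2},$$

then a binomial draw of $2N$ alleles — the standard Wright–Fisher kernel.
Genotypes are not tracked individually, matching the assumptions of the
diffusion it validates, and each generation is $O(1)$ per replicate.
Replicates are vectorised, runs that hit the generation cap (default
$100N$, where neutral censoring is $<0.1\%$) are flagged censored rather
than silently counted as losses, and a run with no fixations reports its
time estimate as unavailable rather than zero. The semantics of $s$ can
be measured directly in the kernel: `wf_fitness_ratio()` confirms that at
$s = 1$ (full dominance) rare carriers leave twice the per-capita
offspring of the wild type, the strongest case admitted by the model.

A second, fully deterministic oracle lives in the test helpers: the exact
absorbing-Markov-chain solution of the same kernel (dense linear solves
over the $2N+1$ allele-count states), feasible up to a few hundred
individuals. Monte-Carlo agreement tests are run at fixed seeds against
cells chosen so that the genuine diffusion bias sits well inside three
standard errors at $10^5$ replicates; the chain oracle pins down the bias
itself without noise.

## The sizes of beneficial mutations

For a genome already near a local fitness optimum, extreme value theory
gives an exponential density for beneficial effect sizes, $p(s) = \alpha
e^{-\alpha s}$ with $\alpha = 1/E[\Delta_1]$, where $E[\Delta_1]$ is the
expected fitness gap between the best and second-best mutant. Empirical
viral estimates put $E[\Delta_1]$ between $1/53$ (maximum likelihood) and
$1/37$ (least squares); the shipped analyses use $1/30$, deliberately
generous to large-effect mutations so that the case against the
macro-mutation scenario is not built on a biased parameter.

An *improvement* is a mutation that occurs **and** fixes; its size
distribution is proportional to $\alpha e^{-\alpha s} \cdot
p_{fix}(1/(2N); s, N)$. The package uses the closed-form CDF

$$\mathrm{CDF}(s) = 1 - \frac{e^{-\alpha s}}{\beta}\left[\frac{1}{\alpha}
 - \frac{e^{-2s}}{2+\alpha}
 + \frac{e^{-(N+1)s}}{N(N+\alpha+1)}\right],$$

with $\beta$ fixed by $\mathrm{CDF}(0) = 0$, i.e. $\beta = 1/\alpha -
1/(2+\alpha) + 1/(N(N+\alpha+1))$. Both identifications ($\alpha$ as the
exponential rate, $\beta$ as above) are verified in the test suite against
the numerically integrated, normalised product density: the maximum CDF
discrepancy at $\alpha = 30$, $N = 1500$ is $5.5\times10^{-4}$, far
inside the 0.02 the tests allow. An `N = Inf` mode drops the last term
for effectively very large populations, the appropriate mode when fitting
pooled viral data. Sampling inverts the closed-form CDF: a monotone
interpolation seed followed by Newton iterations on the analytic density,
converged to $10^{-8}$ in CDF units or the sampler refuses.

### Fitting

`fit_exponential_mle()` is the closed-form MLE — the sample mean of
"random" (occurrence) effects, with large-sample standard error
$\bar s/\sqrt n$; a single observation flags its SE as unavailable. It
refuses "preobserved" samples, which would conflate occurrence with
fixation. `fit_exponential_lsq()` minimises squared deviations between
observed bin *frequencies* and exponential bin probabilities (density
fitting at bin midpoints is available behind `target = "density"`); the
objective is flat in $\alpha$ far above the truth, so the optimiser
brackets the basin on a 400-point logarithmic grid before golden-section
refinement — deterministic given the data. Uncertainty for the
least-squares estimate comes from a bootstrap in the tests, where both
fitters hold nominal coverage on synthetic samples of the sizes a viral
assay would provide (n = 100).

## The accumulation experiment

`accumulation_experiment()` draws improvement sizes until their sum
reaches a target total gain $m$, recording every step. The defaults *are*
the focal study conditions: $m = 1$ (the gain a single $s = 1$
macro-mutation would deliver at once), $\alpha = 30$, $N = 1500$, 10 000
replicates (1000 in the quick acceptance run), all seed-recorded.
Histograms use unit-width integer bins for the step count and width-0.05
bins for the largest step per run — the granularity at which the results
are read, with edges configurable.

```{r accumulation}
acc <- accumulation_experiment(m = 1, alpha = 30, N = 1500,
                               replicates = 1000, seed = 1)
acc$summary
```

Two facts carry the scientific conclusion, and both are asserted in the
acceptance tests: the mean number of improvements is far above one (a
single-step run essentially never occurs), and nearly every run contains a
step of effect 0.1–0.4 — the walk is short and dominated by moderately
large steps, not a diffuse accumulation of micro-mutations and not one
macro-mutation. An independent rejection sampler (exponential proposals
thinned by the fixation filter) reproduces the step-count distribution,
guarding the production inverse-CDF sampler.

## Synthetic data: what it does and does not show

`generate_random_effects()` and `generate_preobserved_effects()` emulate
the *statistical structure* of viral fitness-assay data — exponential
occurrence effects, and fixation-filtered effects following the
improvement distribution — as pure functions of a spec and a seed. They
exist so that every fitting and accumulation path is testable offline;
default sizes (hundreds of observations) mirror what such assays yield.
They do not simulate viral replication, measurement error, detection
thresholds, or the particular binning of any published data set, so
passing recovery tests establishes estimator correctness under the model's
own assumptions, not robustness to real-data artefacts. Real measurements
can be supplied as a delimited table (`read_effects_table()`: header row,
`effect` column, optional `count`, `#` comments) and fitted identically.

## Degenerate inputs and tie-breaks

Absorbing boundaries are handled explicitly everywhere: $p_0 = 0$ or $1$
return their trivial fixation results, a zero fixation probability makes
the conditional time an error rather than a 0/0, `m = 0` is a zero-step
run, an empty effect sample refuses to fit, and binning requires strictly
increasing edges with out-of-range effects either an error or an explicit
open overflow bin. Seeds: every stochastic entry point either takes a
seed argument recorded in its metadata or documents its use of the global
R stream; seeded generators restore the caller's stream.

## Known limitations

* The diffusion routes carry $O(s)$ bias relative to the exact process;
  above $s \approx 0.2$ treat probabilities as approximations good to a
  few percent and strong-selection recessive/frequency-dependent *times*
  as order-of-magnitude.
* The improvement distribution inherits the haploid closed form for
  $p_{fix}$ inside its derivation; its absolute scale shares that form's
  factor-of-two conservatism for rare semidominant mutants. Step *counts*
  in the accumulation experiment are insensitive to this (the shape, not
  the absolute fixation rate, drives them).
* Improvements are assumed additive and independent — successive
  mutations neither interact epistatically nor segregate simultaneously.
* Problem sizes in the shipped tests (chain oracles at $N \le 100$,
  $10^5$-replicate simulator cells, 1000-replicate walks) were chosen so
  the whole suite runs in well under a minute on one core; all are
  configurable upward.
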