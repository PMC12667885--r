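---
title: "Mean fitness under stabilizing selection: model, simulator, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mean fitness under stabilizing selection: model, simulator, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabsel)
```

## The model

stabsel studies a single additive quantitative trait under Gaussian
stabilizing selection in a finite diploid population. An individual with
trait value $p$ has relative fitness

$$w(p) = \exp\!\left(-\frac{(p - \mathrm{opt})^2}{2 V_S}\right),$$

so an individual at the optimum has fitness one, and $V_S$ (trait
units$^2$) is the *inverse* strength of selection: larger $V_S$ means a
wider, more forgiving fitness surface. Throughout we set the optimum to
zero.

With many loci of small effect, phenotypic values in the population are
approximately normal with mean $\bar p$ and variance $V_P$, giving the
closed-form population mean fitness

$$\bar w(\bar p) = \sqrt{\frac{V_S}{V_P + V_S}}\,
  \exp\!\left(-\frac{\bar p^2}{2 (V_P + V_S)}\right)$$

(`mean_fitness_at()`). In a finite population of effective size $N_e$, the
mean phenotype itself drifts around the optimum; its displacement is
approximately normal with variance $V_S / (2 N_e)$. Averaging $\bar w$ over
that distribution yields the expectation of mean fitness
(`expected_mean_fitness_given_vp()`):

$$E[\bar w] = \left[\frac{2 N_e V_S}{V_S + 2 N_e (V_P + V_S)}\right]^{1/2},
\qquad
E[\bar w] \xrightarrow{N_e \to \infty} \sqrt{\frac{V_S}{V_P + V_S}}.$$

### Equilibrium genetic variance

At mutation–selection–drift balance the genetic variance $V_G$ depends on
the total per-gamete mutation rate $U$ over trait-affecting loci
($U = \mu L$ for per-base rate $\mu$ and target size $L$), the variance
$V_M$ of the effect-size distribution of new mutations (assumed
$\mathcal{N}(0, V_M)$), and $V_S$. Two classical regimes bracket the
answer: the house-of-cards limit $V_G \approx 4 U V_S$ for strong effects,
and the drift-dominated limit $V_G \approx 4 N_e U V_M$ for weak effects.
The stochastic house-of-cards (SHOC) interpolation,

$$V_G \approx \frac{4 U V_S}{1 + \dfrac{V_S}{N_e V_M}},$$

joins them smoothly (`vg_shoc()`). Substituting it for $V_P$ gives the
package's central prediction (`expected_mean_fitness()`):

$$E[\bar w] = \left[\frac{2 N_e}
  {1 + 2 N_e \left(1 + \dfrac{4 N_e U V_M}{N_e V_M + V_S}\right)}\right]^{1/2}.$$

A first-order expansion of the load $1 - E[\bar w]$ (`load_approx()`) makes
the limits legible: the load tends to roughly $2U$ as $N_e$ grows — an
overestimate, the exact limit being $1 - (1 + 4U)^{-1/2} < 2U$ — and to the
drift load $1/(4 N_e)$ as $U \to 0$. We expose this
truncation as a load rather than a fitness because those two limits are
what it is for; the exact expression above remains the primary prediction,
and we only check the truncation loosely against it (its accuracy away from
the limits is not sharply characterized).

### When is mean fitness maximized at a finite size?

The two ingredients pull in opposite directions: a larger population keeps
$\bar p$ closer to the optimum (less drift load) but maintains more genetic
variance (more segregating load). Setting the derivative of $E[\bar w]$
with respect to $N_e$ to zero gives a finite maximizer

$$N_e^{*} = \frac{V_S\left(1 + \sqrt{8 U V_S / V_M}\right)}{8 U V_S - V_M}$$

exactly when $8 U V_S > V_M$, i.e. when

$$U > \frac{V_M}{8 (V_S + V_E)}$$

once environmental variance is accounted for (`optimal_ne()`,
`finite_optimum_condition()`). Equivalently, in terms of target size,
$L > V_M / (8 \mu (V_S + V_E))$. At the boundary
$8 U V_S = V_M$ the denominator vanishes and the optimum recedes to
infinity; because the condition is a strict inequality we report "no finite
optimum" there.

### Environmental variance

Uncorrelated environmental noise of variance $V_E$, redrawn independently
each generation, can be absorbed into the width of the fitness function:
averaging $w(g + e)$ over $e \sim \mathcal{N}(0, V_E)$ is, up to a constant
factor that cancels from relative fitness, a Gaussian fitness function of
the genotypic value with width $V_S + V_E$. The package applies this single
substitution uniformly — in the fitness kernel (on request), the SHOC
variance, the central prediction, the optimum, and the condition — because
it is mathematically equivalent everywhere the model is defined, even
though it is usually stated only for the condition. The identity
`expected_mean_fitness(vs, ve) == expected_mean_fitness(vs + ve, 0)` is
exact and tested.

## Numerical oracles

Every closed form above is paired with an independent numerical check:

* `mean_fitness_numeric()` integrates $w(p) f(p)$ by adaptive quadrature
  (`stats::integrate`) over $\bar p \pm 12$ phenotypic standard deviations;
* `expected_mean_fitness_numeric()` nests two adaptive quadratures (outer
  over the $\bar p$ displacement, inner over phenotypes), relative
  tolerance $10^{-10}$, so oracle error is negligible against the
  $10^{-8}$ test tolerance;
* `optimal_ne_numeric()` maximizes the central prediction over
  $\log N_e$ with a 241-point log-spaced bracketing scan on
  $N_e \in [10^{-2}, 10^{10}]$ followed by golden-section refinement.
  $N_e$ is treated as continuous, matching the derivative-based derivation
  of $N_e^*$.

The $\pm 12\sigma$ bounds truncate a Gaussian tail of mass
$\sim 10^{-33}$; the quadrature tolerances were chosen so that oracle error
is orders of magnitude below every tolerance the tests assert.

## The Wright–Fisher simulator

`run_simulation()` validates the theory with an individual-based
forward simulation that realizes exactly the assumptions of the analytic
model:

* **diploid, monoecious Wright–Fisher** reproduction with discrete
  generations: each of $N$ offspring draws two parents independently with
  probability proportional to fitness (selfing allowed) — the simplest
  scheme consistent with the diploid factor 4 in the variance formulas;
* **infinite sites**: every new mutation is a new site, with effect drawn
  fresh from $\mathcal{N}(0, V_M)$ — the house-of-cards assumption;
* **free recombination**: each heterozygous mutation is transmitted
  independently with probability 1/2, implementing linkage equilibrium
  directly (no genetic map, no tracked chromosomes);
* **fixations are folded into a phenotype offset**, not discarded: fixed
  mutations displace the population mean relative to the optimum, and
  silently dropping them would bias mean fitness upward;
* **environmental noise** (when $V_E > 0$) is redrawn independently every
  generation and added to the genetic value before fitness is computed.

Defaults are `burn_in = 10 * n` generations from a mutation-free
population and one recorded sample every `n / 10` generations — standard
practice for reaching mutation–selection–drift equilibrium, comfortably
exceeding both the coalescent timescale and the mutation–selection
timescale $V_S / V_M$ for the architectures studied here (for very small
populations, where $10 n$ would undercut $V_S/V_M$, we raise the burn-in
explicitly, as in the small-population comparison below). Uncertainty is
summarized by normal-approximation 95% confidence intervals over replicate
means (`summarize_replicates()`); replicate seeds derive deterministically
from the configuration seed (`derive_seed()`), so identical configurations
reproduce bit-identical results.

Two implementations of the same model are provided: a compiled core
(`engine = "cpp"`, the default — sparse per-site bookkeeping, cost
proportional to the number of segregating copies) and a pure-R reference
engine built from the exported step operations `mutate_population()`,
`phenotypes_and_fitness()`, `reproduce_population()` and `prune_fixed()`.
The two engines consume random numbers in different orders and so produce
different streams from the same seed, but they sample the same process;
the test suite checks them against each other statistically. The compiled
engine draws the generation's total mutation count once from
$\text{Poisson}(2 N U)$ and scatters it over uniformly chosen gametes,
which is distributionally identical to the per-gamete
$\text{Poisson}(U)$ draws that the reference engine performs literally.

### What the simulator does and does not emulate

The simulator generates data under precisely the model the closed forms
assume — a single trait, additive effects, Gaussian effect-size
distribution, Gaussian fitness, panmixia, equilibrium demography. Passing
validation therefore shows that the *derivations* are sound, not that the
model describes any particular natural population: pleiotropy, dominance,
epistasis, linkage, non-Gaussian effects and changing optima are all
outside scope. Two breakdowns expected on theoretical grounds are
diagnosed rather than hidden (`breakdown_diagnostics()`): in very small
populations (order 100 and below) the normal approximation for the
fluctuation of $\bar p$ degrades, and for strong mutational effects with
high mutation rates the SHOC formula underestimates $V_G$.

## Validation experiments and problem sizes

`run_sweep()` reproduces the standard validation surface: simulated mean
fitness (points with 95% CIs) overlaid on the predicted curves across a
factorial grid of $(N_e, U, V_M)$ at $V_S = 1$. The package's own checks
use desk-scale grids chosen to finish in minutes on one core while keeping
every qualitative regime represented:

* **coverage grid**: $N = 500$, $U \in \{0.005, 0.01\}$,
  $V_M \in \{10^{-4}, 10^{-3}\}$, 20 replicates per cell, 20 samples per
  replicate — 8 coverage checks (4 mean-fitness, 4 genetic-variance);
* **reference cells** at $N = 1000$, $U = 0.01$,
  $V_M \in \{10^{-4}, 10^{-3}\}$, 20 replicates, for the genetic-variance
  recovery and the $\mathrm{Var}(\bar p) = V_S/(2N)$ fluctuation law;
* **small-vs-large comparison**: $U = 0.2$, $V_M = 0.02$ gives
  $N_e^* \approx 6.3$, so we compare $N = 6$ against $N = 600$ (100×
  larger), 6 replicates each. The expected gap in mean fitness is large
  (about 0.92 vs 0.76 analytically, and larger still in simulation where
  SHOC underestimates $V_G$ at these strong effects), so few replicates
  suffice. The $N = 6$ run uses a 1000-generation burn-in since
  $10 N = 60$ would be shorter than $V_S / V_M = 50$ generations.

With the coverage construction used here (does the simulated CI contain
the prediction?), occasional single-cell misses are expected behaviour for
an interpolation formula — SHOC is accurate but not exact in the
mid-regime $N_e V_M \approx V_S$ — which is why the acceptance check asks
for 7 of 8 rather than 8 of 8.

## Numerical and design choices

* $V_S = \infty$ is accepted by the simulator and switches selection off
  (every fitness is one); the neutral equilibrium $V_G = 4 N U V_M$ then
  provides an exact external check of the mutation and drift machinery.
* Fitness underflow (all individuals at $w = 0$, possible when $V_M \gg
  V_S$) raises an error advising larger `vs` or smaller `vm` rather than
  silently renormalizing.
* The genetic variance reported is the census variance of genetic values
  (denominator $N$), i.e. the whole-population quantity the theory
  predicts, not a sample estimate.
* `pbar` records the mean *genetic* value; with $V_E > 0$ the mean
  environmental deviation ($O(\sqrt{V_E/N})$) would only add noise to the
  fluctuation diagnostics, while fitness is always computed from the full
  phenotype.
* Ties and boundaries: the condition $U > V_M / (8(V_S+V_E))$ is strict;
  at equality no finite optimum is reported.
* Sweep-cell seeds are derived as a Lehmer step of (base seed, cell
  index), so adding or reordering grid cells never changes another cell's
  result.

## A worked condition check

For human-scale quantitative traits, mutational target sizes of order
$L \sim 10^6$ bases and per-base rates $\mu \sim 10^{-8}$ give
$U \sim 0.01$, and the strength of stabilizing selection relative to
phenotypic variance has been estimated around $V_S / V_P \approx 60$.
Scaling the condition by $V_P$:

```{r}
p <- model_params(ne = 1000, mu = 1e-8, l = 1e6, vm = 1, vs = 60)
8 * p$u * p$vs / p$vm
finite_optimum_condition(p)
```

The quantity $8 U V_S / V_P = 4.8$ exceeds 1, so as long as
$V_M / V_P < 1$ (mutational variance below standing phenotypic variance,
as expected), such architectures satisfy the finite-optimum condition —
the regime where mean fitness is maximized at a finite, often small,
population size.

## Known limitations

* Single trait, no pleiotropy or multivariate fitness surfaces; no
  dominance, epistasis or linkage; Gaussian effects only; equilibrium
  demography with a fixed optimum.
* The SHOC interpolation inherits known error in the crossover regime and
  underestimates $V_G$ for strong effects at high $U$; the diagnostics
  flag, but do not correct, these regimes.
* The normal approximation for $\bar p$ fluctuations degrades for very
  small $N$; predictions near $N \lesssim 100$ should be read
  qualitatively.
* Census size and effective size are identified ($N = N_e$), as
  appropriate for the idealized Wright–Fisher scheme simulated here.
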