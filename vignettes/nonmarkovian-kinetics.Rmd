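---
title: "Non-Markovian stochastic kinetics: model, sampler and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-Markovian stochastic kinetics: model, sampler and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmsim)
```

## The model

A discrete-state stochastic reaction system is a set of channels
`a1 X1 + ... -> b1 Y1 + ...`, each annotated with the probability
density of its waiting time. When every density is exponential the
system is a continuous-time Markov jump process and Gillespie's SSA
simulates it exactly. `nmsim` generalises the waiting-time law per
channel, which matters whenever a mesoscopic event lumps several hidden
elementary steps.

The motivating case is enzyme catalysis. For a single enzyme cycling
through binding, dissociation and catalysis, the turnover time — the
interval between consecutive product formations — has the exact density

$$f(\tau) = \alpha\,(e^{\beta\tau} - e^{\gamma\tau}),$$

with $B = -(k_1 S + k_{-1} + k_2)/2 < 0$,
$A = \sqrt{B^2 - k_1 k_2 S} \in (0, |B|)$,
$\alpha = k_1 k_2 S/(2A)$, $\beta = A + B$, $\gamma = B - A$. Both
exponents are negative and $\beta > \gamma$, so $F(\tau) = r$ has
exactly one solution for every $r \in (0,1)$ — the property the sampler
relies on. The density vanishes at $\tau = 0$: immediately after a
turnover the enzyme must re-bind substrate before it can produce again,
which is precisely what the memoryless exponential cannot express. The
distribution is a two-phase hypoexponential in disguise (phases
$|\beta|$ and $|\gamma|$), and its mean obeys the single-molecule
Michaelis–Menten equation

$$\frac{1}{\langle\tau\rangle} = \frac{k_2 S}{S + K_M}, \qquad
  K_M = \frac{k_{-1}+k_2}{k_1},$$

the ergodic consistency between single-molecule and ensemble kinetics
that justifies feeding bulk-measured constants into single-molecule
simulations. The package verifies this identity numerically
(`1/\int \tau f(\tau)\,d\tau` against `mm_mean_rate()`, relative
tolerance 1e-6) for every fixture and for randomly drawn parameter sets.

Two assumptions are inherited from the underlying single-molecule
theory: no *dynamic disorder* (the rate constants do not fluctuate over
time), and a fixed substrate level during one waiting time (the engine
re-evaluates $S$ from the live state at every sampling, so $S$ is
piecewise constant between firings).

The derived quantities fail to be real exactly when $k_{-1} = 0$ and
$k_1 S = k_2$ (double root, $A = 0$). This measure-zero boundary is
rejected with a dedicated error rather than implementing the
$\alpha\tau e^{B\tau}$ limiting density; the error is distinct from
ordinary positivity violations so callers can tell a degenerate
parameter set from a typo.

Besides the Michaelis–Menten family the package ships exponential,
Erlang and hyperexponential (finite mixture of exponentials) laws; the
latter covers over-dispersed waiting times and is defined as the
standard mixture since only the family name, not a formula, is fixed by
convention. Units are the caller's responsibility: $k_1$ and $S$ must
merely be mutually consistent (M with M⁻¹s⁻¹, µM with µM⁻¹s⁻¹); the
bundled fixture sets record their units in an attribute.

## Sampling by guaranteed-bracketing inversion

Inverse transform sampling draws $r \sim U(0,1)$ and solves
$F(\tau) = r$. A closed-form inverse exists only in special cases, so
`invert_cdf()` solves the equation numerically under an interval
contract: it returns an *enclosure* $[\ell, u]$ with
$u - \ell \le \texttt{precision}$ and $F(\ell) \le r \le F(u)$, and
reports the midpoint. The procedure is

1. initial bracket $[0, \tau_0]$ with $\tau_0 = $ the distribution mean;
2. geometric expansion (doubling) of the upper end until $F \ge r$
   (capped by `max_bracket_expansions`, default 200);
3. bisection until the width drops below `precision` (capped by
   `max_bisections`, default 5000).

Because $F$ is continuous and strictly increasing with range $(0,1)$,
step 2 always terminates for admissible $r$ and bisection never loses
the root: the method is complete in the same sense as exhaustive
interval search, without interval-arithmetic machinery. Bisection was
chosen over derivative-based polishing as the default because its
enclosure guarantee is unconditional; a Newton polish could be layered
on but must never leave the verified bracket, and profiling showed the
CDF evaluations are cheap enough that the gain would be marginal.

Numerical choices:

* **precision** defaults to `1e-9 * wt_mean(dist)`, floored at `1e-15`
  absolute — relative to the channel's natural time scale, so fast and
  slow reactions are resolved equally well. About 30–60 CDF evaluations
  reach it from the initial bracket.
* $r$ is drawn on the **open** interval: exact 0 (possible with R's
  generator) is rejected and redrawn; $r = 1$ cannot occur. This avoids
  $\tau = 0$ (which would stall the clock) and the divergent upper tail.
* When bisection hits the floating-point floor (midpoint equal to an
  endpoint) it stops: the enclosure is then the tightest representable.
* The exponential and Erlang families use their closed-form quantiles
  (`qexp`, `qgamma`) on the default sampling path; the numeric inverter
  remains available (`method = "numeric"`) and is exercised by the test
  suite for every family.

Randomness comes from R's session RNG; every simulation entry point
accepts a `seed` argument, and identical (system, state, seed, config)
yield byte-for-byte identical trajectory files.

## The race engine

Per iteration the engine samples one waiting time for every fireable
reaction from its distribution *evaluated at the current state*, fires
the channel with the smallest $\tau$ (ties — measure-zero but possible
in floating point — go to the lowest reaction index, for determinism),
applies the stoichiometry, advances the clock by the winning $\tau$ and
starts over. Losing samples are discarded, not carried as residual
clocks. This resampling loop is deliberate: it is the simplest
semi-Markov race consistent with state-dependent densities, and for
exponential waiting times it reduces *exactly* to the Markov jump
process (memorylessness makes resampling and clock persistence
equivalent) — the test suite verifies distributional agreement with the
Direct Method on a three-channel network. For genuinely non-exponential
densities, resampling and persistent-clock ("race with memory")
semantics differ; the persistent variant is out of scope and the
documentation flags the distinction.

Channels whose live parameters are invalid at the current state (e.g. a
Michaelis–Menten channel at $S = 0$) are treated as not fireable for
that iteration rather than raising, so competing channels can drain the
system cleanly.

Two interpretation knobs exist because copy numbers and concentrations
are mixed freely in this modelling style:

* `engine_config(scale=)` converts a copy number into the concentration
  fed to live parameters (default 1: counts used directly).
* A lumped Michaelis–Menten channel samples **one** waiting time per
  channel regardless of how many enzyme copies exist — reproducing the
  benchmark behaviour where 500 products always take 500 iterations.
  The physically motivated alternative for $E > 1$ (minimum of $E$
  independent draws, i.e. the first of $E$ enzymes to finish) is
  available as `engine_config(first_of_n = "E")` but off by default,
  since the single-channel reading is the one the benchmark protocol
  defines and the $E > 1$ interpretation is genuinely open.

The Gillespie reference simulator shares the reaction grammar
(`dist=mass_action; c=...` for elementary channels with the standard
combinatorial propensities, `dist=mm_lumped` for the Markovian
Michaelis–Menten rate law $v = k_2[S]/([S]+K_M)$) so the same system
file can be pushed through both engines.

## What the validation emulates — and what it does not

All validation inputs are generated in code: printed kinetic parameter
sets (`mm_fixture("A1")` … `"B3"`), a two-channel demonstration network
(`example_network()`), and a log-uniform random-parameter generator
(`random_mm_params()`, ranges $k_1, k_2, S \in [10^{-1}, 10^2]$,
$k_{-1} \in [10^{-2}, 10^2]$, chosen to span stiff and non-stiff
regimes while keeping quadrature well-conditioned; degenerate-boundary
draws are rejected). The A sets are molar-unit single-molecule
parameters at $S = 5\,\mu M$; the B sets are µM-unit ensemble constants
for a β-lactamase/benzylpenicillin system. The saturation-curve check
sweeps $S$ over 20 log-spaced points in $[10^{-3}, 200]$ µM (the range
is stated without units in the source literature; µM matches the B
sets' rate-constant units, and log spacing resolves the rising limb) —
with 100 draws per point, every reciprocal-mean estimate must fall
within 5 delta-method standard errors of the analytic law, and the
plateau is checked against $k_2$ at saturating $S$.

Statistical checks and their design:

* **Histogram vs density**: Pearson χ² with 20 equal-probability bins
  (CDF-quantile edges), adjacent bins merged until every expected count
  is ≥ 5, no fitted parameters (df = bins − 1). "Pass" means
  p > α for a true-null check — note that for a goodness-of-fit test a
  *small* p-value indicates misfit, so a "p < 0.005 means good fit"
  reading would be inverted; the report always carries the statistic,
  df and p-value so the caller can judge.
* **Sampler correctness**: Kolmogorov–Smirnov distance of $10^4$ seeded
  draws against the analytic CDF below the asymptotic 1% critical
  value, per family; the numeric inverter is additionally checked
  against $-\ln(1-r)/\lambda$ to $10^{-9}$ at 1000 quantiles.
* **Markov limit**: the race engine with exponential channels against
  the Direct Method — 2000 runs of a three-channel first-order network
  to a fixed horizon, final-state contingency χ² (p > 0.01).
* **Lumping accuracy**: in a low-copy regime with $k_{-1} \ll k_2$
  ($k_1 = 1, k_2 = 20, k_{-1} = 0.1, S_0 = 20, E_0 = 1$, 800 runs per
  model, horizon 0.6), the mean product-formation curve of the lumped
  non-Markovian model tracks the full elementary scheme within
  Monte-Carlo bands at every grid point, while the lumped *Markovian*
  model overshoots the early transient by several standard errors —
  the exponential density overweights near-zero waiting times that the
  true turnover density forbids. With a single enzyme the lumped
  non-Markovian model is not an approximation at all: the turnover
  density is exactly the product inter-arrival law of the full scheme.

These problem sizes (1000–10⁴ draws, 800–2000 replicate runs) were
chosen so each check has comfortable statistical power against the
effect it targets while the whole suite stays quick to run routinely.

Synthetic validation of this kind establishes *self-consistency*: the
sampler draws from the density it claims, the engine's bookkeeping is
exact, and the Markovian/non-Markovian contrast behaves as the theory
predicts. It cannot establish that any particular real enzyme follows
the two-phase density — dynamic disorder, conformational states and
crowding are outside the model class.

## Known limitations

* No dynamic disorder or time-varying rate constants.
* No persistent-clock semi-Markov semantics (see above).
* No spatial or compartmental structure; well-stirred volume assumed.
* No approximate accelerations (tau-leaping); the engine is exact and
  its cost is one CDF inversion per fireable channel per iteration.
* Empirical-histogram densities are not supported; waiting-time laws
  must come from the four parametric families.
* Iteration counts of elementary-scheme benchmarks from other toolkits
  are not reproduced here, since their full parameterisation is not
  fixed; the engine's own invariant — iterations equal to the product
  target for the lumped channel, at every stiffness — is what
  `scripts/acceptance.R` measures.
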