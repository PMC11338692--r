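---
title: "A life-history model of paternal-care elaboration under sexual selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A life-history model of paternal-care elaboration under sexual selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carescape)
```

## The question and the model

Paternal care is widespread yet puzzling: why do males of some species invest
in offspring rather than in traits that win matings? This package implements
a male-fitness model for a system in which egg care by males has *already*
originated, and asks when sexual selection favors elaborating that care
(additional care $c$) versus investing in a non-care mating trait ($m$) that
females may prefer. Both investments vary continuously on $[0, 1]$.

The life history is deliberately minimal. A male's baseline egg mortality
$d_{E0}$ doubles as an inverse proxy for his baseline care level: well-cared
eggs die rarely. Care and the mating trait are costly to adult survival and
beneficial through different channels:

$$d_A = 1 - (1 - d_{A0})\, e^{-\left((1 - d_{E0}) + c \,[+\, m]\right)},
\qquad d_E = d_{E0}\, e^{-c},$$

with the $m$ cost present only when the trait is exhibited. Whatever females
prefer raises fertilization success through a shared saturating form,

$$r = 1 - (1 - r_0)\, e^{-x},$$

where the exponent $x$ is $0$, $c$, $m$, or $c + m$ depending on the
preference scenario. Per-episode reproductive success is $R = r\,b\,(1 -
d_E)$ for $b$ available female gametes, and lifetime fitness assumes a
guaranteed first reproductive episode plus a truncated-geometric expectation
of future ones:

$$W = R\left(1 + \sum_{i=0}^{n} i\, d_A (1 - d_A)^i\right).$$

Four scenarios span the preference structure (S1 none, S2 care preferred,
S3 trait exhibited and preferred, S4 both preferred), crossed with two
investment regimes: *unconstrained*, where each expressed trait is invested
at 0.5 independently, and *constrained*, where $c + m$ is capped at a 0.5
budget (all to care in S1/S2, split 0.25/0.25 in S3/S4). The constrained
regime encodes a direct tradeoff between care and ornamentation; the
unconstrained regime removes the tradeoff but keeps both survival costs.

Out of scope by design: female fitness and co-evolutionary feedback,
frequency dependence, paternity uncertainty, competing males, care beyond
the egg stage, and any offspring size–number tradeoff.

## Parameters and defaults

| parameter | meaning | default | domain |
|---|---|---|---|
| `d_E0` | baseline egg mortality (inverse proxy for baseline care) | 0.5 | $[0,1]$ |
| `d_A0` | baseline adult male mortality | 0.5 | $[0,1]$ |
| `r_0`  | baseline fertilization success | 0.5 | $[0,1]$ |
| `b`    | female gametes per episode | 100 | $\ge 0$ (integer for simulation) |
| `n`    | future episodes in the truncated sum | 5 | nonnegative integer |
| `c`, `m` | additional care, mating trait | regime defaults | $[0,1]$ |

The defaults are the reference parameter set used by every figure panel.
`n` is treated as the integer 5 (it indexes a discrete sum over episodes,
so fractional horizons have no interpretation here). All probabilities are
validated to the closed interval $[0, 1]$; violations raise errors naming
the offending field rather than silently clamping.

## The truncated lifetime sum

The future-episode expectation $\sum_{i=0}^{n} i\, d_A (1-d_A)^i$ truncates
the geometric lifespan distribution at the horizon $n$ *without*
renormalizing or crediting longer lifespans: a male whose drawn lifespan
exceeds $n$ contributes zero future episodes. We implement this literal
reading exactly, because it is the quantity the analytic results are built
on, and we expose a clearly flagged `capped = TRUE` variant (lifespans beyond
$n$ count as $n$ episodes, adding $n(1-d_A)^{n+1}$ to the sum) for
sensitivity analysis only — no reference reproduction uses it. A useful
internal consistency check falls out at $d_A = 0$: the analytic sum is zero
(every term carries a factor $d_A$) and, generatively, the lifespan almost
surely exceeds any finite horizon, which the truncation also maps to zero.
The simulator honors this by treating $d_A = 0$ as a lifespan beyond the
horizon rather than attempting a geometric draw with success probability
zero.

Whether $n$ counts total or future episodes is ambiguous in the verbal
description; we take it as the upper index of the future-episode sum (the
first episode is always additional to it), which is the only reading
consistent with $W = R$ at $d_A = 1$.

## Analysis layer

`sweep_fitness()` grids one baseline parameter and evaluates all scenarios
at their regime defaults. Sweep ranges are $[0.01, 0.99]$ for the
probability parameters and $[1, 200]$ for $b$, on 99-point grids: the open
probability interval avoids the degenerate endpoints where fitness is
identically zero or scenarios tie exactly, while covering everything the
comparative claims concern. Comparative line plots of the egg-mortality
panels use $\log W$ (the fitness curves span orders of magnitude and the
reported "negative fitness" at low fertilization success is only consistent
with a log scale); CSV output always carries both $W$ and $\log W$ so either
convention can be plotted. $\log 0$ is represented by the sentinel `-Inf`,
never an error — a male with zero fitness is a valid model state.

`rank_scenarios()` orders scenarios at each grid point with an absolute tie
tolerance of $10^{-9}$ on $W$: far below any biologically meaningful
difference, comfortably above double-precision noise at these magnitudes
($W \sim 10$–$10^2$). Ties are reported as ties and broken by scenario index
only for display.

`find_crossovers()` detects sign changes of pairwise fitness differences
between adjacent grid points and refines each by bisection on the continuous
difference function to a location tolerance of $10^{-6}$. Bisection is
derivative-free and guaranteed to converge on a bracketed sign change, which
is exactly the certificate the grid provides; no gradient method is needed
or used. Sweeps over $b$ can never produce crossovers because $W$ is exactly
linear in $b$ — this is asserted, not assumed, in the test suite.

`classify_monotonicity()` classifies $W$ as a function of one trait on a
1001-point grid over $[0, 1]$ from the sign pattern of finite differences:
steps with $|\Delta W| \le 10^{-9}$ count as flat, and a verdict is
*non-monotone* when both strictly positive and strictly negative steps
occur. The dense grid makes the classification robust to the model's gentle
curvature at these parameter magnitudes.

One classification deserves comment. At low baseline adult mortality with
no preferences (S1, $d_{A0} \lesssim 0.15$, other parameters at defaults),
the net effect of care is negative — $W(c{=}1) < W(c{=}0)$ — but the exact
curve first rises a few percent to an interior maximum near $c \approx 0.2$
before declining. A coarse visual reading calls this "fitness increases as
care decreases"; the sign-pattern classifier reports it, correctly, as
non-monotone. We keep the exact verdict: the classifier's job is the sign
structure, and flattening a genuine interior maximum into "decreasing"
would require a tolerance far above anything defensible.

## The individual-based validator

`simulate_male()` and `estimate_fitness_mc()` simulate what the closed form
claims to average: each male gets a guaranteed first episode; his future
episode count is geometric, $P(L = i) = d_A (1 - d_A)^i$, with draws beyond
$n$ contributing zero further episodes (the literal truncation); each
episode fertilizes each of $b$ gametes independently at rate $r$ and each
fertilized egg survives at rate $1 - d_E$ (a two-stage binomial). The
generator therefore emulates exactly the model's own assumptions — *not*
real data: there is no male–male competition, no female choice among
discrete males, no inheritance of $c$ and $m$, and no overdispersion beyond
the binomial. Passing validation shows the algebra and the simulation agree,
not that either describes a natural population.

Simulation uses R's Mersenne-Twister generator, which is platform-stable,
with explicit integer seeds recorded in every output header;
`generate_cohort_table()` is byte-for-byte reproducible given a seed. At the
reference parameters, $10^5$ replicates give standard errors near 0.07 on
$W \approx 40$–$75$, so the 3-standard-error agreement band is a sub-percent
check while remaining cheap (seconds per scenario–regime cell). A
chi-squared goodness-of-fit test on the binned lifespans (tail pooled beyond
$n$) guards the geometric draw itself.

`b` must be an integer for simulation (it is a count of gametes); the
analytic core accepts real `b`, where it acts as a rate multiplier.

## Design choices where the design was open

* **Scenarios are closed-world.** Exactly four canonical preference
  patterns exist; other flag combinations are accepted by the core (they are
  well-defined mathematically) but marked non-canonical so reports cannot
  silently mix them with the reference set.
* **Constrained S1/S2 males do not "reallocate" the unused trait budget.**
  The reference investment levels put the whole 0.5 budget into care for
  care-only scenarios, which coincides with the unconstrained default; both
  regimes are encoded through one `default_allocation()` so the coincidence
  cannot drift.
* **Validation is strict, conversion is not attempted.** Parameters outside
  their domains raise immediately; nothing is clamped or warned-and-fixed.
  No tolerance is applied inside the model core — all tolerances live in the
  analysis layer where they are stated per operation.
* **Config files are YAML** with sections `params`, `regime`, `sweep`;
  unknown keys are rejected so typos fail loudly, and CLI flags override
  file values. (YAML 1.1 parses a bare `n:` key as a boolean; the reader
  maps it back, and the shipped config quotes the key.)

## Problem sizes

The reference reproductions use 99-point sweep grids, 1001-point
monotonicity grids, a $10^4$-point brute-force grid as the crossover oracle,
and $10^5$ Monte-Carlo replicates per scenario–regime cell; the whole
analysis suite runs in about a minute on one CPU.

## Known limitations

The model is a single-male fitness surface, not population dynamics: no
frequency dependence, no co-evolution of preferences, no paternity
uncertainty. The literal truncation of the lifetime sum discards survival
mass beyond the horizon, which slightly depresses $W$ at low adult mortality
relative to the capped variant; conclusions that depend on very low
$d_{A0}$ should be checked against `capped = TRUE`. Fitness is exactly
linear in $b$, so gamete number can never reorder scenarios — a feature of
the model (no size–number tradeoff), not a finding about real clutches.
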