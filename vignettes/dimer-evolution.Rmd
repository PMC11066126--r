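---
title: "Modeling the fate of homodimers after gene duplication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the fate of homodimers after gene duplication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimerevol)
```

Most proteins work as complexes, and many of those complexes are homodimers.
When the gene encoding a homodimeric protein is duplicated, the two paralogous
proteins A and B are initially identical and assemble indiscriminately into
two homodimers (AA, BB) and a heterodimer (AB).  What happens next — whether
the heterodimer is lost, takes over, or coexists with the homodimers — is a
long-standing question in molecular evolution.  `dimerevol` implements a
biophysical model of this system and origin-fixation simulations of its
evolution, so that the contribution of *mutational biases* (as opposed to
selection) to heterodimer retention can be quantified.

## The biophysical model

Each gene is described by a synthesis rate $s$ (units·h⁻¹), a folding free
energy $\Delta G_{fold}$ (kcal/mol), and binding free energies
$\Delta G_{bind}$ (kcal/mol) for every dimer it participates in.  The
fraction of properly folded protein follows the Boltzmann form

$$w = \frac{1}{1 + e^{\Delta G_{fold}}},$$

so the synthesis rate of *folded* subunits is $s\,w$; misfolded copies are
degraded and never enter complexes.  Folded monomers and dimers decay with
first-order rates (all 1.3 h⁻¹ by default, a typical value for yeast protein
turnover).  Dimerization is at binding equilibrium with association constants

$$K = e^{-\Delta G_{bind} / RT}, \qquad R = 1.987\times10^{-3}\
\mathrm{kcal\,K^{-1}mol^{-1}},\ T = 298\ \mathrm{K},$$

and the heterodimer's association constant carries an additional statistical
factor of 2 that corrects for mixing entropy.  This placement of the factor
is what makes two *identical* paralogs settle at the binomial 1:2:1
(AA:AB:BB) ratio — 50% heterodimer among dimers — which is the natural
starting point of every simulation:

```{r}
conc <- solve_post_duplication(reference_state(duplicated = TRUE))
round(conc, 3)
het_share_dimers(conc)
```

Before duplication the monomer concentration has a closed form (the positive
root of a quadratic mass balance).  After duplication, steady state requires
solving a quartic polynomial in the concentration of monomer A; the other
four species follow by back-substitution, and the physically meaningful
solution is the unique root with all five concentrations positive.  Two
numerical safeguards matter in practice:

* all four roots are extracted (companion-matrix solver in the compiled
  path, `polyroot()` in the R path) and every admissible root is polished by
  a damped Newton iteration on the two per-subunit flux balances.  The naive
  back-substitution $c_B = (s_A/c_A - 2 d_{AA} K_{AA} c_A - d_A)/(d_{AB}
  K_{AB})$ cancels catastrophically when binding is strong, and root
  extraction itself loses precision when the two paralogs' folded synthesis
  rates differ by hundreds of orders of magnitude (which happens in
  selection-free control runs); the Newton polish restores full double
  precision in both regimes, and its Jacobian is an M-matrix so the
  iteration is globally convergent.  Zero or several *distinct* all-positive
  roots raise an error rather than being silently resolved;
* when the heterodimer association constant underflows (below $10^{-12}$)
  the system is solved as two independent single-gene systems with
  $c_{AB}=0$, the continuous limit.

Both solvers are validated in the test suite against integration of the full
five-species mass-action ODE system to steady state, to a relative tolerance
of $10^{-6}$ over randomized states (binding energies in $[-15,-2]$
kcal/mol, synthesis rates in $[10, 500]$ units/h), and per-subunit flux
balance is checked to $10^{-8}$.

## Activity and fitness

Selection acts on a single quantity, the total activity: the
specific-activity-weighted sum of concentrations, with weight 0.1 for
monomers and 1 for all dimers by default.  With the reference parameters
($s = 100$, $\Delta G_{fold} = -5$, $\Delta G_{bind} = -10$, decay 1.3 h⁻¹)
total activity is 38.2 h⁻¹ before duplication and 76.4 h⁻¹ after:

```{r}
total_activity(solve_pre_duplication(reference_state()))
total_activity(solve_post_duplication(reference_state(duplicated = TRUE)))
```

Fitness is a lognormal function of activity with an optimum `alpha` and a
width parameter `beta`: fitness 1 at `alpha` and fitness `beta` at half or
twice `alpha`.  Only those two properties are fixed by the model
description, so the package implements the unique log-symmetric
Gaussian-in-log form satisfying them,

$$f(a) = \beta^{\left(\log_2 (a/\alpha)\right)^2},$$

exposed as a replaceable strategy in the grid-evaluation API.  Simulations
use `alpha = 80` h⁻¹ by default (the post-duplication activity slightly
undershoots the optimum, favoring fixation of the duplication) or
`alpha = 60` h⁻¹ (the duplication overshoots); `beta = 0.5` throughout.
Non-positive activity maps to fitness 0 — a system producing nothing is
treated as inviable.

## Mutational effects

Coding mutations perturb three quantities at once: the target paralog's
folding energy, the target paralog's homodimer binding energy, and the
shared heterodimer binding energy (the *other* homodimer is untouched).  The
default parametric source is a trivariate normal with marginals
$\Delta\Delta G_{fold} \sim N(2.6, 4.6)$,
$\Delta\Delta G_{bind,HM} \sim N(0.4, 2.4)$ and
$\Delta\Delta G_{bind,HET} \sim N(0.2, 1.2)$ (kcal/mol), correlation 0.9
between the two binding effects and 0.3 between folding and each binding
effect — moments matching structure-based mutational scans of homodimers.
Mutations are destabilizing on average, and heterodimer effects are about
half the homodimer effects because a mutation changes only one of the two
interface sides of the heterodimer.

The deviation of a mutation from that half-slope expectation is its
*residual*,

$$\mathrm{residual} = \Delta\Delta G_{bind,HET} - 0.5\,\Delta\Delta
G_{bind,HM},$$

negative values favoring the heterodimer.  A mutational spectrum is
summarized by its *enrichment score*: the fraction of residuals below
$-0.2$ kcal/mol minus the fraction above $+0.2$ kcal/mol (the threshold is
configurable; 0.1–0.4 give the same qualitative picture).

Empirical per-substitution tables (the kind produced by FoldX/MutateX-style
pipelines: one row per substitution with the three $\Delta\Delta G$ values)
can be used instead of the parametric model; sampling is uniform over rows,
and fixed substitutions are replayed onto each paralog's sequence so that
sequence divergence can be reported.  Effects are applied additively to the
current state while the underlying distribution stays constant — the model
deliberately ignores epistasis and any dependence of the available mutation
spectrum on the current sequence, a simplification that keeps replicates
comparable but means the late phase of long trajectories should be read
qualitatively.

`generate_synthetic_structure()` emulates such a table: all 19 substitutions
at every position of a random sequence, effects drawn from a parametric
model, and a `residual_bias` term that shifts every heterodimer effect
relative to the half-slope diagonal.  It generates test fixtures with a
*known* mutational bias, which the simulations should (and, in the test
suite, do) recover in their outcomes.  What the generator does not emulate:
position-specific effect distributions (buried vs. interface residues),
outliers beyond normality, and correlations varying along the sequence —
conclusions about real structural data rest on the empirical-table mode, not
on passing tests against the generator.

Expression mutations, drawn with probability `p_exp` per event, multiply the
target gene's synthesis rate by $1+\varepsilon$ with $\varepsilon$
skew-normal distributed (mean 0, SD 0.025, skewness $-0.125$, following
measured promoter-mutation effect distributions).  The moment parameters are
converted to the skew-normal's location/scale/shape in closed form, reading
the stated skew as the distribution's standardized skewness.  The
$1+\varepsilon$ form keeps the mean-zero effect distribution meaningful:
effects are measured relative to the current rate, and applying a mean-zero
multiplier directly would annihilate synthesis.

## Origin-fixation simulation

Evolution is simulated in the weak-mutation regime: one mutation at a time,
fixed or lost before the next arises.  The model description leaves the
fixation kernel open, so the package defaults to Kimura's diffusion
approximation for a new semidominant mutation,

$$p_{fix} = \frac{1 - e^{-2s}}{1 - e^{-2Ns}}, \qquad s =
\frac{f_{new}}{f_{old}} - 1,$$

with effective population size $N = 1000$; a Metropolis-style ratio rule is
available behind the same interface, and `neutral = TRUE` switches selection
off entirely (every proposal fixes with probability $1/N$), which separates
the contribution of mutational bias from that of selection.  The Kimura
kernel is validated against a brute-force Wright–Fisher simulation in the
test suite.

Each replicate starts from the pre-duplication reference state.  The
duplication itself is proposed repeatedly until it fixes (it is beneficial
under both `alpha` settings) and is recorded as fixation #1; no further
duplications are sampled.  Afterwards each proposal picks an expression
event with probability `p_exp`, otherwise a coding event; the affected
paralog is chosen uniformly; the equilibrium, activity and fitness are
recomputed from scratch; and the proposal fixes with its fixation
probability.  A replicate ends after `n_fixed` mutations (200 by default,
duplication included); rejected proposals are counted but never part of that
budget.  Runs with biased specific activities (`het_activity_bias`) apply
the bias from the start of the replicate and never mutate it.

```{r}
cfg <- simulation_config(n_fixed = 60, n_replicates = 4, p_exp = 0.3,
                         seed = 42)
sim <- run_simulation(cfg, parametric_effect_model())
sim
round(sim$replicates[, c("p_AA", "p_AB", "p_BB", "het_pct_dimers")], 1)
```

Outcomes are classified from the final relative concentrations
($p_X = 100\,c_X/\sum c$): heterodimer dominant at $p_{AB} \ge 70$,
homodimer dominant at $p_{AA}+p_{BB} \ge 70$, "both" when dimers jointly
reach 70 with neither class alone at 70, monomers at $p_A+p_B \ge 70$,
otherwise ambiguous — evaluated in that order of precedence, on each
replicate's final state.  Headline heterodimer percentages are reported
among dimers only ($100\,c_{AB}/(c_{AA}+c_{AB}+c_{BB})$, which starts at
exactly 50%); the all-species variant is emitted alongside, and the two
differ negligibly whenever dimers dominate the mixture.

## Reproducibility and problem sizes

All randomness flows from one seed: `run_simulation()` derives one
sub-seed per replicate, so batches are reproducible file-for-file and
replicates are independent.  The compiled inner loop draws from R's own
random number generator, which keeps trajectories identical across the
compiled and interpreted entry points.

The test suite runs the full study condition (50 replicates × 200
fixations, `p_exp = 0.9`) for the expression-mutation regime, and
deliberately smaller designs for property-style checks (e.g. 8–20
replicates of 80–100 fixations across 5–11 bias levels for the
bias-recovery experiments, and 30–100 randomized states for the
ODE-equivalence battery); these sizes give the statistics involved
comfortable margins while keeping the suite quick to run.

## Known limitations

* No epistasis and no sequence-dependent redrawing of the effect
  distribution (see above).
* Folding and binding are independent: binding does not stabilize folding,
  and there are no higher-order oligomers, no cotranslational assembly, no
  dominant-negative effects.
* Specific activities are fixed per run; the model does not let one dimer
  evolve a new function.
* Explicit association/dissociation rate constants are not user-facing
  parameters: association constants come directly from binding free
  energies, which is exact at binding equilibrium but means kinetic
  competition between dimer decay and dissociation is not modeled as a
  separate degree of freedom (the ODE oracle in the tests uses explicit
  on/off rates chosen to reproduce the same constants).
* The pre-duplication phase is not evolved: the duplication is always the
  first fixation.  Coding drift before duplication would only decorrelate
  the starting point across replicates.
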