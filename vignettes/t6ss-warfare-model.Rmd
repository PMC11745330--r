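---
title: "Modelling T6SS warfare and the evolution of toxin resistance"
author: "T6SSim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling T6SS warfare and the evolution of toxin resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(T6SSim)
```

## The biological question

Many bacteria kill their neighbours with the type VI secretion system
(T6SS), a contractile nanomachine that stabs adjacent cells and injects a
cocktail of protein toxins (effectors). Unlike diffusible antibiotics, a
T6SS hit delivers *several different toxins at once*. This package asks the
evolutionary question that follows: when can a susceptible lineage evolve
resistance to T6SS attack, and how does the size of the attacker's toxin
arsenal change the answer? The package provides (i) a 2-D agent-based
engine for contact-dependent intoxication between rod-shaped cells, (ii) a
mutate–select–replace trajectory engine with two selection backends, and
(iii) the summary statistics — phenotypic resistance $N_{hits}$,
competitive advantage, absolute fitness — used to decide when resistance is
under positive selection.

## The toxin-response model

Each cell carries a scaled integrity variable $I$, set to 1 at birth. A hit
from an attacker translocates a dose vector $d$ (one entry per toxin); the
target accumulates intracellular amounts $x_i$ and its integrity is

$$I = 1 - \sum_i a_i x_i - \sum_i \sum_j B_{ij} x_i x_j,$$

where $a_i \in [0,1]$ is the target's sensitivity to toxin $i$ (1 = one
unit is lethal, 0 = immune) and $B$ is a toxin-interaction matrix: positive
entries model synergy, negative entries antagonism, and diagonal entries a
nonlinear single-toxin dose response. The double sum runs over *ordered*
pairs, so a symmetric off-diagonal pair contributes twice. The cell dies
when $I$ reaches zero; death is implemented as $I \le 0$ because the fully
sensitive case ($a = 1$, unit dose) must die on exactly its first hit.
Toxin activity is constant over a simulation: knowing the accumulated doses
$\{x_i\}$ is sufficient to know whether a cell has died, so there is no
intracellular decay or repair.

With purely additive toxins ($B = 0$) the number of hits a target can
sustain — its *phenotypic resistance* — is closed-form:

$$N_{hits} = \left\lceil \left(\sum_i a_i d_i\right)^{-1} \right\rceil,$$

with $N_{hits} = \infty$ when the sum vanishes (full immunity; attackers
are perfectly immune to their own arsenal). The ceiling follows from the
death rule: `nHits(0.7, 1)` is 2, not 1.43. With $B \neq 0$ the formula no
longer holds and `hitsToDeath()` counts doses directly.

Resistance may carry a growth cost, assumed proportional to total toxin
insensitivity. Only the proportionality is biologically motivated; the
functional form is our choice: the linear, clipped multiplier
$\max(0,\, 1 - c\sum_i(1-a_i))$ applied to the growth rate, with $c = 0$
(cost-free) the default everywhere.

## The spatial engine

Cells are spherocylinders of fixed radius $R = 0.5\ \mu m$ and variable
segment length $L$ on an unbounded plane (no periodic boundary; colonies
expand freely). In 2-D we take "volume" to be the capsule footprint area
$V = 2RL + \pi R^2$, which makes the $V \leftrightarrow L$ conversion
closed-form. Each timestep:

1. **Growth.** $V \to V e^{k\,\Delta t}$ per living cell, with
   $k = k_{grow} \times$ the cost multiplier. The default
   $k_{grow} = \ln 2 / 2.5\ h^{-1}$ gives four doublings over a 10 h
   competition.
2. **Division.** At $V \ge 2V_0 + \eta$ ($V_0$ = birth volume, $\eta$
   uniform on $\pm 0.1 V_0$ — the noise width is our choice, configurable)
   the rod splits into two equal-volume daughters placed end-to-end along
   the parent axis, outer caps coinciding with the parent's extent.
   Daughters inherit the parent's accumulated toxins and integrity
   unchanged (no dilution, no healing); whether real daughters share
   sub-lethal damage is unknown, and this is the conservative bookkeeping
   choice.
3. **Relaxation.** Growth and division create overlaps; damped pairwise
   translations and rotations (position-based iteration over
   grid-selected neighbour pairs) remove them to a tolerance of
   $0.01\ \mu m$, capped at 100 sweeps per step. In a large crowded colony
   the interior is slightly compressed and the cap can be reached — the
   residual is a pressure-like artefact a local iterative scheme cannot
   remove in bounded sweeps; it is reported as a warning and does not
   affect lengths, volumes or life status.
4. **Firing.** Each living attacker fires $N \sim Poisson(k_{fire}\Delta t)$
   needles from uniform-random membrane points. Needles have length one
   cell radius and point along the outward surface normal (a
   uniform-random outward direction is available as a config flag; the
   normal convention is the package default since the needle reach of one
   radius beyond the membrane is the geometrically meaningful quantity).
5. **Hit resolution.** Cells and needles are binned on an infinite square
   grid of $10\ \mu m$ elements; each needle strikes the first cell whose
   capsule it enters (smallest entry distance), never its own firer.
   Dead-but-unlysed cells absorb hits ("corpse barrier").
6. **Intoxication.** Each hit applies the firer strain's dose vector to
   the struck cell, except that kin (same strain) are immune. Cells whose
   integrity reaches zero stop growing ($k_{grow} = 0$) and become
   corpses.
7. **Lysis.** Corpses are physically removed $1/k_{lysis}$ hours after
   death ($k_{lysis} = 2\ h^{-1}$ by default, i.e. 0.5 h persistence).

The step order (grow, divide, relax, fire, resolve, intoxicate, lyse) is
fixed. The default timestep is $\Delta t = 0.025$ h. All randomness flows
through R's RNG from a single top-level seed; substreams for replicates,
trajectories and trajectory steps derive deterministically via
`deriveSeed()`, so every run replays bit-for-bit and results are
independent of scheduling.

### Calibration of the firing rate

There is no canonical measured value for $k_{fire}$ or $k_{lysis}$ at this
level of abstraction, so these defaults are calibrated against the
qualitative structure of the selection map they produce: competitions seeded
attacker:susceptible:mutant must yield a finite competitive advantage in
most replicates (the susceptible strain decimated but not universally
exterminated), with CA $\approx 1$ for a neutral mutant and CA $\gg 1$ for
a fully resistant one. At $k_{fire} = 50$ firings cell$^{-1}$h$^{-1}$ the
susceptible strain is exterminated in essentially every desk-scale
replicate (CA degenerate everywhere); $k_{fire} = 10$ reproduces the
expected structure and is the package default. Both rates are explicit
config fields and every headline analysis can be re-run at other values.

## Competition experiments

`tripartiteConfig()` builds the canonical selection experiment: an
attacker (immune to its own toxins), a fully susceptible target
($a = (1,1)$) and a rare mutant, seeded uniformly at random in a disc —
500:90:10 cells in a 50 µm radius by default — and run for 10 h across 20
replicates. Two statistics summarise a run:

$$\mathrm{CA} = \frac{(N_{mut}/N_{sus})_{final}}{(N_{mut}/N_{sus})_{initial}},
\qquad
\mathrm{Fitness} = \frac{1}{t_f - t_i}\log_2\frac{N(t_f)}{N(t_i)}.$$

Degenerate outcomes are encoded, not dropped: CA is 0 if the mutant went
extinct, $\infty$ if only the susceptible did, `NA` if both did; maps of
selection then average over the surviving (finite, positive) replicates,
optionally on the log scale (`meanCompetitiveAdvantage()`). A run
terminates early once every non-attacker strain is extinct, recorded as an
outcome rather than an error. `protectionSweep()` wraps paired
resistant-mutant vs susceptible-control conditions over a grid of seeding
densities and flags cross-protection when the susceptible strain's mean
fitness is significantly higher with the resistant mutant present (Welch
one-sided test across replicates).

## Evolutionary trajectories

The adaptive walk iterates three steps from a fully susceptible resident
($a = (1, \dots, 1)$): (i) propose a mutant by perturbing every
sensitivity with independent $\mathcal N(0, \sigma^2)$ draws
($\sigma = 0.1$ by default; whole-vector redraw if any component leaves
$[0,1]$); (ii) subject resident and mutant to selection; (iii) replace the
resident if the mutant wins. Two backends implement step (ii):

* **`abm`** — a full spatial competition seeded 500:90:10
  attacker:resident:mutant for 1.5 h; the mutant fixes iff its competitive
  advantage over the resident exceeds 1 (strictly — exact ties are
  rejected, and drift enters only through stochastic CA), and total
  elimination of the target cells terminates the walk as an extinction.
* **`simplified`** — the competition is replaced by the analytic
  comparison $\Delta = N_{hits}^{mut} - N_{hits}^{res} > 0$. This removes
  spatial structure, drift and extinction but reproduces the qualitative
  predictions at a tiny fraction of the cost. With $B \neq 0$ fixation
  compares brute-force hits-to-death instead of the ceiling formula, which
  assumes additivity. With a growth cost the comparison uses an
  expected-divisions-before-death proxy, growth multiplier × hits-to-death
  (a cell's expected reproductive output before dying under steady attack
  is proportional to both its lifespan in hits and its division rate);
  this reduces exactly to the $\Delta > 0$ rule at zero cost.

The central predictions, reproduced by the test suite and acceptance
script: against a single-toxin attacker every simplified walk at least
doubles its resistance within 30 mutations (any accepted decrease of
$a_A$ below 1 yields $N_{hits} \ge 2$), and arena walks frequently pick up
resistance to the *unused* toxin B through drift; against a two-toxin
attacker no phenotypic resistance evolves at $\sigma = 0.1$ (a fixation
would require a single $\approx 7\sigma$ joint jump across the
$a_A + a_B < 1$ lethality plateau), and arena lineages go extinct more
often because the attacker stays lethal across the whole sensitivity
range. Larger arsenals, synergistic interactions and resistance costs all
suppress resistance evolution further; antagonistic interactions relax the
plateau and re-open stepwise escape routes.

## Problem sizes and what the tests show

Full-resolution versions of these experiments (21×21 sensitivity grids ×
20 replicates × 10 h each, and 30-step arena walks at 500:90:10) call for
cluster-scale compute. The package targets desk-side use, so its shipped
analyses use proportional reductions chosen once: competitions seeded
250:45:5 (or smaller) at the *same cell density* (disc radius scaled by
$\sqrt{N/600}$), 5–10 h horizons, around 10 replicates; arena walks at
100:18:2 with 12–15 mutations. The generator emulates random well-mixed
seeding, exponential rod growth and contact killing; it does not emulate
nutrient gradients, within-population heterogeneity, macroscale structure
or clonal interference, so passing tests support the model's qualitative
logic, not quantitative predictions for any particular real community.
Numerical conventions worth knowing: `nHits()` pins the ceiling to the
exact death rule ($n \sum a_i d_i \ge 1$) to avoid floating-point
off-by-one; the hit detector exploits convexity of point-to-capsule
distance along the needle (ternary search + bisection, deterministic
tie-break toward the lower cell index); relaxation corrections are damped
(factor 0.7, rotation gain 0.3) to keep shallow-angle rod contacts from
oscillating.

## A worked example

```{r example, eval = FALSE}
cfg <- tripartiteConfig(attackerD = c(1, 0), mutantA = c(0, 1),
                        counts = c(250, 45, 5),
                        arenaRadius = 50 * sqrt(300 / 600), duration = 5)
res <- runCompetition(cfg, seed = 1, replicates = 10)
meanCompetitiveAdvantage(res)

walks <- runTrajectories(30, seed = 1, backend = "simplified",
                         attackerD = c(1, 1), sigma = 0.1, maxSteps = 30)
trajectorySummary(walks)$counts
```

## Known limitations

Two-dimensional mechanics only; no adhesion, friction anisotropy or
substrate interaction beyond overlap repulsion; no retaliatory
("tit-for-tat") firing, no effector-specific intracellular kinetics, no
immunity-protein exchange; the simplified backend removes frequency
dependence and drift by construction; and the crowded-colony relaxation
residual noted above. Strong antagonistic interactions
($d^\top B d \le -\sum a_i d_i$ scale) can make integrity non-decreasing
in dose, i.e. an unkillable target — mathematically consistent, but a sign
the quadratic interaction form is being pushed beyond its sensible range.
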