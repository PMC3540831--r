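---
title: "Evolving gap-gene circuits: model, operators and design choices"
author: "grnEvolve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving gap-gene circuits: model, operators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnEvolve)
```

# The model

grnEvolve simulates the early patterning of the *Drosophila* trunk by the gap
genes, and the evolution of the regulatory network that performs it. The
embryo is reduced to a 1-D row of nuclei spanning 34-82 percent egg length
(%EL) at one nucleus per %EL (49 nuclei), the region where terminal-system
inputs can be neglected. Each zygotic gene product $a$ obeys the gene-circuit
reaction-diffusion equation

$$\frac{\partial v^a_i}{\partial t} =
  R_a\, g(u^a_i) + D_a \Delta v^a_i - \lambda_a v^a_i, \qquad
  u^a_i = \sum_b W^{ab} v^b_i + h^a,$$

where the regulator sum runs over the maternal inputs (Bcd, optionally Cad)
and all zygotic products. $W^{ab} > 0$ is activation of gene $a$ by product
$b$, $W^{ab} < 0$ repression, and $h^a$ a ubiquitous input. The genotype that
evolves is the matrix $W$; the kinetic parameters $R$, $D$, $\lambda$, $h$
are fixed.

Several numerical details are deliberate choices, since a range of
conventions exists for this model family:

* **Sigmoid.** The regulation-expression function must approach 0 below
  $u = -1.5$ and 1 above $1.5$. We use the algebraic form
  $g(u) = \tfrac12\,(1 + u/\sqrt{1+u^2})$, the classic gene-circuit choice
  ($g(-1.5) \approx 0.084$); a logistic form is selectable
  (`simParams(sigmoidForm = "logistic")`).
* **Boundaries.** The discrete Laplacian uses zero-flux ends, with the ghost
  node copying the boundary value. This variant conserves total
  concentration exactly (to rounding), which the test suite checks at a
  relative drift below $10^{-10}$.
* **Integration.** Explicit Euler with
  $dt \le 1/(\max\lambda + 2\max D/h^2)$; the default is half of this bound
  (1 time unit with the default kinetics). Within the bound the update
  preserves nonnegativity. Convergence is first order in $dt$, verified by
  step halving.
* **Initial conditions.** Zygotic concentrations start at zero; maternal
  profiles are constant in time within one "embryo".
* **Kinetics.** Defaults $R = \lambda = 0.1$, $D = 0.2$, $h = -2.5$ in
  arbitrary units: $R/\lambda = 1$ puts steady states in $(0,1)$, matching
  targets normalised to $[0,1]$, the slowest relaxation time is
  $1/\lambda = 10$ and the default horizon $T = 100$ comfortably
  equilibrates the pattern. Genes are silent by default ($h = -2.5$), so a
  freshly introduced gene stays inert until mutation wires it in. Each
  kinetic field accepts a per-gene vector; genes beyond its length take the
  last element (the template for recruits, which the search never alters).

# Fitness

A circuit is scored by the summed squared difference between its final
obligatory-gene output and the target profiles (`costE`). Only the
obligatory genes (Kr and kni in the 2-gene scenarios; gt, hb, Kr, kni in the
coevolution scenario) are ever scored; recruits act on the score only
through the dynamics. The success threshold `EThreshold` defaults to 0.5,
calibrated on the synthetic Kr/kni targets: it corresponds to a mean
deviation of about 0.07 concentration units per nucleus over the 98 scored
values, at which the domains are visually correct.

# The evolutionary engine

One generation is: score all unscored individuals; replace every
worse-than-average individual by a copy of a random at-or-better-than-average
one; reproduce the truncation-selected best `Reprod` fraction; apply the
cooption and transposon operators. Defaults are the full-scale settings
(`Popul = 8000`, `Reprod = 0.4`, `Mut = 0.32`, `Cross = 0.08`,
`Power = EvalSum = 10^6`); all experiments in the tests run scaled-down
versions (`Popul` 100-300, up to 500 generations), chosen so each experiment
completes in minutes on one CPU while preserving the qualitative regimes.

Two points were genuinely open and are decided as follows:

* **Offspring versus in-place reproduction.** `Reprod` is the quota of the
  population *replaced by offspring* each generation, so the default
  (`reproduction = "offspring"`) copies the selected parents, applies
  crossover and mutation to the copies, and writes them over the worst
  `Reprod` fraction; parents persist. The alternative
  (`reproduction = "inplace"`) mutates the selected fraction directly; it
  destroys every copy of the current best genotype each generation (the
  best-so-far record then no longer exists in the population) and
  measurably stalls the search, which is why it is not the default.
* **Elitism.** No explicit elitism is implemented; offspring-mode
  reproduction already never overwrites the best individual.

The mutation operator perturbs each element independently with probability
`Mut` by $\pm\ln u$, $u$ uniform on $\{1,\dots,\mathrm{Power}\}$ (a
continuous draw is selectable). Note the consequence: with
$\mathrm{Power} = 10^6$, 99% of steps have magnitude between 11.5 and 13.8,
so mutation is a long-jump operator; fine adjustment of $W$ comes from
recombining values present in the population, not from small mutations.
This matters for interpreting convergence: populations reliably reach the
correct domain structure, but the residual cost floors at a few percent of
the initial-population best rather than converging indefinitely (see the
recovery experiment in `tests/testthat/test-acceptance.R`).

One-point crossover picks one homologous chromosome (one gene's row of $W$,
maternal columns included) and one cut point, and swaps the tails between
the two parents; transposon marks travel with their elements. Whole-set
recombination is intentionally not performed per event. Parents of unequal
gene count skip crossover. Ties in truncation selection break by index
order, and all randomness flows from a single seed, so a run is exactly
reproducible from its echoed configuration.

# Gene cooption

`introduceGene` appends one all-zero row and column to $W$ (an inert
recruit: the obligatory dynamics, and hence the fitness, are unchanged
until mutation connects it). `withdrawGene` removes the last-added gene and
never shrinks the network below the obligatory count. In dynamic mode a
`ToRecruitingProc` fraction of the population undergoes the procedure each
generation, each selected individual withdrawing with probability
`WithdrAdd` and introducing otherwise. The effective introduction rate is
`ToRecruitingProc * (1 - WithdrAdd)` — 10% per generation with the package
defaults; both effective rates are echoed in the configuration object, and
never summarised as a bare ratio (the two orientations are easy to
confuse).

For the introduction-withdrawal *ratio* experiment, the probabilities
(introduction 25%, withdrawal 75%) are per *solution* and sum to one, i.e.
in that experiment every solution undergoes the procedure
(`ToRecruitingProc = 1`). The distinction matters: with slow churn
(`ToRecruitingProc = 0.1`) selection protects recruits that mutation has
already wired in, and networks keep growing even at 3:1 withdrawal; with
per-solution churn the withdrawal hazard outpaces wiring-in and recruitment
stalls at the neutral birth-death excess of about 0.5 recruits. We measure
"recruitment shut off" as a population-mean gain of less than one full gene
over a run, against gains of several genes in the introduction-only arm.

`functionalInvolvement` quantifies a recruit's contribution by re-scoring
the circuit with that gene's row *and* column zeroed; the relative increase
$r = (E_{\mathrm{zeroed}} - E_{\mathrm{full}})/E_{\mathrm{full}}$ is
compared against the 10% and 33% thresholds. When $E_{\mathrm{full}}$ is
numerically zero, $r$ is reported as $\infty$ if zeroing changes the fit at
all and 0 otherwise.

# Artificial transposons

A transposon is a contiguous cluster of marks on the binary string aligned
with each chromosome. Four operators act on it:

* **Static column** (`staticColumnValues`, `applyStaticColumn`): the Bcd
  column of $W$ is held at integers evenly spaced on $[0, 100]$ and
  re-imposed after every operator pass, a permanent restriction of the
  search space.
* **Mutator** (`teMutator`): each marked element decays by the factor 1/2
  with probability `teAction` per generation; at `teAction = 1` this is
  exact halving, which cuts the infected regulatory connection to below
  $10^{-15}$ of its value within 50 generations.
* **Spread** (`teSpread`): each cluster extends by at most one element per
  generation along its column, with probability `teGrowth`, up to the
  per-lineage maximum length (sampled once as 2 + (1 or 2) when not fixed).
  The growth direction along the column is not fixed by the construction;
  we default to increasing row index, configurable.
* **Transmission** (`teTransmit`): for each event a random host pair is
  drawn; if the donor carries marks they are replicated at the same
  coordinates in the partner, regardless of the partner's values there
  (marks never move along a chromosome). The event count per generation is
  `ceiling(transmissionRate * Popul)`, expressing the rate as a fraction of
  the population so it scales across population sizes.

The coevolution experiment (`coevolutionExperiment`) makes all four gap
genes obligatory, allows a single recruit (R1), seeds every founder with a
length-4 cluster spanning the Bcd column, caps cluster length at 5 (so
length-5 transposons exist only in 5-gene hosts), and replenishes the
population each generation with uninfected 4-gene individuals from an
external reservoir (default 5% of the population, replacing the worst
individuals; the reservoir size is a free choice of this implementation).
The per-generation log tracks the abundances of 4-gene and R1 networks and
of length-4 and length-5 clusters; at desk scale (population 300, 500
generations) the strain series oscillate through repeated invasion-escape
cycles.

# Robustness to maternal variability

`perturbBcd` rescales the whole Bcd profile by $1 + s\,\varepsilon$ with
random sign and $\varepsilon$ uniform on $[0, 0.2]$ by default — one draw
per embryo, modelling embryo-to-embryo dosage variation, which is the
biological question being asked; independent per-nucleus noise is available
as a mode switch. `robustnessScore` compares perturbed against unperturbed
*model* output (not data) over the obligatory genes, averaging the squared
difference $E'$ over 100 draws by default.

Expression-domain borders are defined operationally as the half-maximum
crossings of a profile, linearly interpolated between nuclei; a monotone
profile has a single border, and flat or multimodal profiles are flagged
with the border reported missing rather than guessed. `borderRobustness`
reports the standard deviation of each border position (in %EL) across
perturbation draws, which is how per-border precision differences (e.g. a
soft anterior Kr border with a firm posterior one) become visible.

# Synthetic data

All tests and examples run on generated data. `makeBcd` is a normalised
exponential with a 20 %EL decay length (the classic Bcd length scale);
`makeCad` a posterior-high logistic; `makeGapTargets` places Gaussian bumps
for Kr (centre 52 %EL, sd 6) and kni (centre 66 %EL, sd 5) with amplitude
0.9. These emulate the *shape* of mid-cycle-14 FlyEx profiles — anterior-high
Bcd, central Kr, posterior kni — not their measured values; nothing numeric
is claimed from data. Real quantitative profiles can be supplied through the
generic table reader (`readProfileTable`) in the same format.

`defaultTeacherCircuit` is a fixed 3-gene circuit (Kr, kni and one hb-like
Bcd-activated anterior repressor) whose output forms a central Kr domain
(about 46-58 %EL) and a posterior kni domain. Teacher-generated targets
guarantee that a perfect-fitness solution exists, which makes them the right
substrate for recovery experiments; recovery runs fix the kinetics at the
teacher's own values, since only $W$ evolves.

What passing on synthetic data does *not* show: the generator has no
measurement noise model, no embryo-to-embryo registration error, single-bump
domains only (real gt and hb have two domains), and unit-free
concentrations. Conclusions about fit quality on real FlyEx data do not
follow.

# Known limitations

* The long-jump mutation law sets a floor on achievable cost at small
  population sizes (see above); quantitative convergence claims should be
  made relative to that floor.
* One spatial dimension, no nuclear divisions, no stochastic gene
  expression, no terminal-system inputs.
* Whether Cad should itself be dynamic is unresolved in the source
  material; it is implemented as a static profile.
* Transposon excision and relocation do not exist; mark counts can only
  grow or stay constant, so long runs with active spread saturate at the
  length cap.

# Reproducing a run

```{r, eval = FALSE}
grid <- spatialGrid()
inputs <- maternalInputs(grid, makeBcd(grid))
problem <- evolutionProblem(inputs, makeGapTargets(grid))
cfg <- engineConfig(Popul = 200, seed = 1, maxGenerations = 100)
res <- runEvolution(problem, cfg,
                    cooption = cooptionConfig(mode = "dynamic"))
res
writeResults(res, problem, "run01")   # re-runnable archive
```
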