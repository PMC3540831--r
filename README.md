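# grnEvolve

In silico evolution of the *Drosophila* gap-gene network: a 1-D gene-circuit
reaction–diffusion model of trunk gap genes under maternal gradients, evolved
by a genetic algorithm extended with gene-cooption operators and artificial
transposons, with robustness analysis against maternal Bcd variability.

The package is for computational/systems biologists studying how gene
regulatory networks (GRNs) grow by recruiting existing genes — how fast
cooption happens, how it affects evolvability, and whether it buys
developmental robustness — and for evolutionary-computation researchers
interested in transposon-inspired operators and host–parasite dynamics in
GAs.

## The model

Each zygotic gene product *a* in nucleus *i* (1 nucleus per %EL, modelled
region 34–82 %EL) follows

    dv[a,i]/dt = R_a g(u[a,i]) + D_a Δv[a,i] − λ_a v[a,i],
    u[a,i]     = Σ_b W[a,b] v[b,i] + h_a,

with g the gene-circuit sigmoid ½(1 + u/√(1+u²)), Δ the zero-flux 1-D
Laplacian, and the regulator sum running over the maternal inputs (Bcd,
optionally Cad) and all zygotic products. The genotype is the
interconnectivity matrix W (activation > 0, repression < 0); kinetics are
fixed. Circuits are scored by the cost

    E = Σ_{a∈obligatory} Σ_i (v[a,i]_model − v[a,i]_target)²,

with only the obligatory genes (Kr, kni) fitted; all other genes are
potential recruits. The GA uses replacement of below-average chromosome
sets, truncation selection (Reprod = 0.4), one-point crossover, and the
logarithmic point mutation W ← W ± ln(u), u uniform on {1..10⁶}. Gene
Introduction/Withdrawal operators grow and shrink W during the search;
artificial transposons are mark clusters that halve infected W elements,
spread along columns and transmit between hosts. Robustness is measured as
E′, the squared deviation of perturbed-Bcd output from unperturbed output,
averaged over ±20% dosage draws, plus the per-border standard deviation of
half-maximum domain border positions.

Everything runs on synthetic FlyEx-like profiles generated in code; a
delimited-table reader accepts real quantitative profiles in the same
format.

## Worked example

Evolve networks for the synthetic Kr/kni targets under Bcd alone, with
dynamic gene cooption (up to 8 recruits):

```r
library(grnEvolve)
grid    <- spatialGrid()                       # 49 nuclei, 34-82 %EL
inputs  <- maternalInputs(grid, makeBcd(grid))
problem <- evolutionProblem(inputs, makeGapTargets(grid))
cfg     <- engineConfig(Popul = 200, seed = 1, maxGenerations = 100)
res     <- runEvolution(problem, cfg, cooption = cooptionConfig(mode = "dynamic"))
res
#> EvolutionResult: stopped after 100 generations, 8112 evaluations (best E = 3.5768)
```

The cost of the best network falls from ≈20 (random circuits) to 3.58, and
the population coopts essentially every available gene — the log's
`mean_genes` column rises from 2 to 9.97 of a possible 10, the package's
desk-scale version of the finding that evolving GRNs tend to coopt all
available genes:

```r
tail(runLog(res)[, c("generation", "evaluations", "best_E", "mean_genes")], 1)
#>     generation evaluations   best_E mean_genes
#> 101        100        8112 3.576772       9.97
```

Which recruits matter? Zeroing each recruit's W entries and re-scoring
(`functionalInvolvement`) shows one load-bearing recruit — removing r1
raises E tenfold (rel_change 10.11, flagged at both the 10% and 33%
thresholds) — while the rest are passengers in this particular solution:

```r
best <- individualCircuit(bestIndividual(res), problem)
functionalInvolvement(best, inputs, makeGapTargets(grid))[, c("gene", "rel_change")]
#>   gene rel_change
#> 1   r1      10.11    # functional at 10% and 33%
#> 2   r2       0.02
#> ...
```

Robustness of the same network to ±20% Bcd dosage variation: the mean E′ is
0.594 over 100 draws, and the surviving domain borders move with a standard
deviation of ≈2.3 %EL — this Bcd-only solution transmits maternal
variability rather than filtering it (the anterior Kr border is lost
entirely in some draws, reported as `NA`):

```r
set.seed(1)
robustnessScore(best, inputs, amplitude = 0.2, nDraws = 100)$meanEprime
#> [1] 0.5942822
set.seed(1)
borderRobustness(best, inputs, amplitude = 0.2, nDraws = 100)$spread
#>     anterior posterior
#> Kr        NA      2.26
#> kni     2.29      2.27
```

A shell front end wrapping the same functions is installed at
`inst/scripts/grnevolve` (subcommands `synth`, `evolve`, `evolve-te`,
`robustness`, `coevolve`, `benchmark`); every run echoes its seed and
resolved configuration so it can be reproduced exactly.

See `vignettes/gene-circuit-evolution.Rmd` for the model assumptions,
operator semantics and the design decisions behind them.

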