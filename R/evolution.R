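#' Engine configuration for evolutionary runs
#'
#' Defaults are the full-scale settings of the standard runs: population
#' Popul = 8000, truncation fraction Reprod = 0.4, per-element mutation
#' probability Mut = 0.32, per-pair crossover probability Cross = 0.08,
#' mutation magnitude parameter Power = 1e6 and evaluation budget
#' EvalSum = 1e6. Desk-scale experiments override Popul, EvalSum and
#' maxGenerations.
#'
#' @param Popul population size
#' @param Reprod fraction of the population (best by E) reproduced each
#'   generation by truncation selection
#' @param Mut per-element mutation probability
#' @param Cross per-pair crossover probability
#' @param Power mutation magnitude parameter; mutated elements move by
#'   \code{+/- log(u)} with u uniform on 1..Power
#' @param EvalSum maximum number of circuit evaluations
#' @param EThreshold success threshold on the cost E; the default 0.5 is
#'   calibrated on the synthetic Kr/kni targets so that visually correct
#'   domains pass (mean deviation of about 0.07 concentration units per
#'   nucleus over 2 x 49 scored values)
#' @param seed RNG seed for the run
#' @param initRange range of the uniform law for initial W entries
#' @param maxGenerations optional cap on generations (Inf = none)
#' @param mutationLaw "integer" draws u as a uniform integer on 1..Power;
#'   "continuous" draws u uniformly on (1, Power)
#' @param reproduction "offspring" (default): mutated/recombined copies of
#'   the truncation-selected parents replace the worst Reprod fraction, so
#'   parents persist unchanged; "inplace": the selected fraction is mutated
#'   and recombined in place
#' @return a validated configuration list
#' @export
engineConfig <- function(Popul = 8000, Reprod = 0.4, Mut = 0.32, Cross = 0.08,
                         Power = 1e6, EvalSum = 1e6, EThreshold = 0.5,
                         seed = 1L, initRange = c(-5, 5),
                         maxGenerations = Inf,
                         mutationLaw = c("integer", "continuous"),
                         reproduction = c("offspring", "inplace")) {
  stopifnot(Popul >= 2, Reprod >= 0, Reprod <= 1, Mut >= 0, Mut <= 1,
            Cross >= 0, Cross <= 1, Power >= 2, EvalSum >= 1,
            length(initRange) == 2, initRange[1] < initRange[2])
  list(Popul = as.integer(Popul), Reprod = Reprod, Mut = Mut, Cross = Cross,
       Power = Power, EvalSum = EvalSum, EThreshold = EThreshold,
       seed = as.integer(seed), initRange = initRange,
       maxGenerations = maxGenerations,
       mutationLaw = match.arg(mutationLaw),
       reproduction = match.arg(reproduction))
}

#' Kinetic parameter template
#'
#' Fixed per-gene kinetics shared by all genes, including genes added during
#' evolution (only W evolves). Units are arbitrary concentration/time units;
#' with R/lam = 1 steady-state concentrations lie in (0, 1), matching the
#' normalised targets, and the slowest relaxation time is 1/lam = 10.
#'
#' Each field may be a scalar (shared by every gene) or a per-gene vector;
#' genes beyond the vector's length (recruits added during evolution) take
#' its last element as their template value.
#'
#' @param R synthesis rate
#' @param D diffusion coefficient
#' @param lam decay rate
#' @param h ubiquitous regulatory input (negative = off by default)
#' @return list of kinetic parameters
#' @export
kineticTemplate <- function(R = 0.1, D = 0.2, lam = 0.1, h = -2.5) {
  stopifnot(all(R >= 0), all(D >= 0), all(lam >= 0))
  list(R = R, D = D, lam = lam, h = h)
}

# scalar-or-vector kinetic field expanded to ng genes; extra genes take the
# last (template) value
.kinVec <- function(x, ng) {
  if (length(x) >= ng) x[seq_len(ng)]
  else c(x, rep(x[length(x)], ng - length(x)))
}

#' Define an evolution problem
#'
#' Bundles the maternal inputs, the target patterns for the obligatory genes,
#' the fixed kinetics and the simulation settings into the problem object the
#' engine optimises over.
#'
#' @param inputs \linkS4class{MaternalInputs}
#' @param targets \linkS4class{TargetPatterns}; its profile names define the
#'   obligatory genes (scored in this order)
#' @param kinetics \code{\link{kineticTemplate}}
#' @param sim \code{\link{simParams}}
#' @return an evolutionProblem list
#' @export
evolutionProblem <- function(inputs, targets, kinetics = kineticTemplate(),
                             sim = simParams()) {
  oblNames <- names(profiles(targets))
  nMaternal <- if (length(inputs@cad)) 2L else 1L
  spacing <- gridSpacing(inputs@positions)
  bound <- 1 / (max(kinetics$lam) + 2 * max(kinetics$D) / spacing^2)
  dt <- if (is.null(sim$dt)) 0.5 * bound else sim$dt
  if (dt > bound + 1e-12)
    stop("evolutionProblem: sim dt violates the stability bound")
  m <- if (nMaternal == 1L) matrix(inputs@bcd, 1L) else
    rbind(inputs@bcd, inputs@cad)
  structure(list(
    inputs = inputs, targets = targets, oblNames = oblNames,
    obligatory = length(oblNames), nMaternal = nMaternal,
    kinetics = kinetics, sim = sim,
    prep = list(m = m, spacing = spacing, dt = dt,
                nsteps = as.integer(ceiling(sim$T / dt)),
                sigCode = .sigmoidCode(sim$sigmoidForm),
                targetMat = do.call(rbind, profiles(targets)),
                nNuclei = length(inputs@positions))),
    class = "evolutionProblem")
}

# -- individuals -------------------------------------------------------------

.newIndividual <- function(nGenes, nMaternal, initRange) {
  nc <- nMaternal + nGenes
  list(W = matrix(runif(nGenes * nc, initRange[1], initRange[2]), nGenes, nc),
       marks = matrix(0L, nGenes, nc), E = NA_real_, maxTE = NA_integer_)
}

#' Build the GeneCircuit encoded by a population individual
#'
#' @param individual a population member (list with W and marks)
#' @param problem an \code{\link{evolutionProblem}}
#' @return a \linkS4class{GeneCircuit}
#' @export
individualCircuit <- function(individual, problem) {
  ng <- nrow(individual$W)
  kin <- problem$kinetics
  nm <- problem$nMaternal
  geneCircuit(individual$W, h = .kinVec(kin$h, ng), R = .kinVec(kin$R, ng),
              D = .kinVec(kin$D, ng), lam = .kinVec(kin$lam, ng),
              nMaternal = nm, obligatory = problem$obligatory,
              geneNames = c(problem$oblNames,
                            if (ng > problem$obligatory)
                              paste0("r", seq_len(ng - problem$obligatory))))
}

# fast path used inside the GA loop; semantics identical to
# evaluateCircuit(individualCircuit(ind, prob), ...)
.evalIndividual <- function(ind, prob) {
  ng <- nrow(ind$W)
  kin <- prob$kinetics
  p <- prob$prep
  v <- simulate_circuit_cpp(ind$W, .kinVec(kin$h, ng), .kinVec(kin$R, ng),
                            .kinVec(kin$D, ng), .kinVec(kin$lam, ng), p$m,
                            matrix(0, ng, p$nNuclei), p$dt, p$nsteps,
                            p$spacing, p$sigCode)
  sum((v[seq_len(prob$obligatory), , drop = FALSE] - p$targetMat)^2)
}

.scorePopulation <- function(pop, prob, counter) {
  for (i in seq_along(pop)) {
    if (is.na(pop[[i]]$E)) {
      pop[[i]]$E <- .evalIndividual(pop[[i]], prob)
      counter$evaluations <- counter$evaluations + 1L
    }
  }
  pop
}

# -- operators ---------------------------------------------------------------

#' Initialise a population of random W matrices
#'
#' Each individual carries one floating-point chromosome per gene (the rows
#' of W, including the maternal columns), an aligned all-zero transposon-mark
#' string, and an unset fitness.
#'
#' @param config \code{\link{engineConfig}}
#' @param nGenes genes per individual (>= 2)
#' @param nMaternal maternal input columns (1 or 2)
#' @return list of \code{Popul} individuals
#' @export
initPopulation <- function(config, nGenes, nMaternal = 1L) {
  if (nGenes < 2L) stop("initPopulation: at least 2 genes are required")
  replicate(config$Popul,
            .newIndividual(nGenes, nMaternal, config$initRange),
            simplify = FALSE)
}

#' Logarithmic point mutation
#'
#' Each W element is changed independently with probability \code{Mut} by
#' \code{W <- W +/- log(u)}, sign equiprobable and u a uniform integer on
#' 1..Power (so the step never exceeds log(Power)). If any element is hit the
#' fitness is invalidated.
#'
#' @param individual a population member
#' @param Mut per-element mutation probability
#' @param Power magnitude parameter (>= 2)
#' @param law "integer" (default) or "continuous" u draw
#' @return the mutated individual
#' @export
mutateIndividual <- function(individual, Mut, Power = 1e6,
                             law = c("integer", "continuous")) {
  law <- match.arg(law)
  if (Power < 2) stop("mutateIndividual: Power must be >= 2")
  if (Mut <= 0) return(individual)
  n <- length(individual$W)
  hit <- which(runif(n) < Mut)
  if (!length(hit)) return(individual)
  u <- if (law == "integer") sample.int(Power, length(hit), replace = TRUE)
       else runif(length(hit), 1, Power)
  s <- sample(c(-1, 1), length(hit), replace = TRUE)
  individual$W[hit] <- individual$W[hit] + s * log(u)
  individual$E <- NA_real_
  individual
}

#' One-point crossover between two individuals
#'
#' Picks one homologous chromosome (one gene row of W) and a cut point on it;
#' the tails beyond the cut are exchanged between the two parents. Transposon
#' marks travel with their elements, so the multiset of (value, mark) pairs
#' across the pair is preserved.
#'
#' @param parent1,parent2 individuals of identical shape
#' @return list of the two offspring
#' @export
onePointCrossover <- function(parent1, parent2) {
  if (!identical(dim(parent1$W), dim(parent2$W)))
    stop("onePointCrossover: parents must have identical shapes")
  row <- sample.int(nrow(parent1$W), 1L)
  len <- ncol(parent1$W)
  cut <- sample.int(len - 1L, 1L)          # swap elements (cut+1)..len
  tail <- (cut + 1L):len
  w1 <- parent1$W[row, tail]; m1 <- parent1$marks[row, tail]
  w2 <- parent2$W[row, tail]; m2 <- parent2$marks[row, tail]
  if (!identical(w1, w2) || !identical(m1, m2)) {
    parent1$W[row, tail] <- w2; parent1$marks[row, tail] <- m2
    parent2$W[row, tail] <- w1; parent2$marks[row, tail] <- m1
    parent1$E <- NA_real_; parent2$E <- NA_real_
  }
  list(parent1, parent2)
}

#' Replace worse-than-average individuals
#'
#' Every individual scoring worse than the population mean E is replaced by a
#' copy of a uniformly chosen individual scoring at or below the mean.
#' Population size is unchanged.
#'
#' @param population fully scored population
#' @return the population after replacement
#' @export
replaceBelowAverage <- function(population) {
  E <- vapply(population, function(x) x$E, numeric(1))
  if (any(is.na(E))) stop("replaceBelowAverage: population must be scored")
  m <- mean(E)
  bad <- which(E > m)
  if (!length(bad)) return(population)
  good <- which(E <= m)
  population[bad] <-
    population[good[sample.int(length(good), length(bad), replace = TRUE)]]
  population
}

#' One reproduction pass (truncation selection, crossover, mutation)
#'
#' The best \code{Reprod} fraction by E (ties broken by index order) is the
#' parent pool of the generation. In the default \code{"offspring"} mode,
#' copies of the parents undergo one-point crossover in random pairs (with
#' probability \code{Cross} per pair; pairs of unequal gene count are
#' skipped) and per-element mutation, and the resulting offspring replace the
#' worst \code{Reprod} fraction of the population, so parents persist
#' unchanged. In \code{"inplace"} mode the selected individuals are
#' recombined and mutated in place instead. Fitness of modified individuals
#' is invalidated.
#'
#' @param population fully scored population
#' @param config \code{\link{engineConfig}}
#' @return the population after reproduction
#' @export
reproduceGeneration <- function(population, config) {
  k <- floor(config$Reprod * length(population))
  if (k < 1L) return(population)
  E <- vapply(population, function(x) x$E, numeric(1))
  if (any(is.na(E))) stop("reproduceGeneration: population must be scored")
  ord <- order(E)
  sel <- ord[seq_len(k)]

  .operate <- function(group) {
    if (length(group) >= 2L && config$Cross > 0) {
      perm <- sample.int(length(group))
      for (p in seq_len(length(group) %/% 2L)) {
        i <- perm[2L * p - 1L]; j <- perm[2L * p]
        if (runif(1) < config$Cross &&
            identical(dim(group[[i]]$W), dim(group[[j]]$W))) {
          ch <- onePointCrossover(group[[i]], group[[j]])
          group[[i]] <- ch[[1L]]; group[[j]] <- ch[[2L]]
        }
      }
    }
    if (config$Mut > 0)
      group <- lapply(group, mutateIndividual, Mut = config$Mut,
                      Power = config$Power, law = config$mutationLaw)
    group
  }

  if (config$reproduction == "offspring") {
    offspring <- .operate(population[sel])
    worst <- rev(ord)[seq_len(k)]
    population[worst] <- offspring
  } else {
    population[sel] <- .operate(population[sel])
  }
  population
}

# -- run loop ----------------------------------------------------------------

.meanTELength <- function(pop) {
  mean(vapply(pop, function(ind) {
    if (!any(ind$marks == 1L)) return(0)
    max(unlist(lapply(seq_len(ncol(ind$marks)), function(j)
      with(rle(ind$marks[, j]), lengths[values == 1L])), use.names = FALSE), 0)
  }, numeric(1)))
}

.clusterLengthCounts <- function(pop, lengths) {
  all <- unlist(lapply(pop, function(ind)
    unlist(lapply(seq_len(ncol(ind$marks)), function(j)
      with(rle(ind$marks[, j]), lengths[values == 1L])), use.names = FALSE)),
    use.names = FALSE)
  vapply(lengths, function(L) sum(all == L), integer(1))
}

#' Run an evolutionary search
#'
#' The generation cycle is: score all unscored individuals (counting
#' evaluations), record the log row, test the stopping rules, then
#' replacement of below-average individuals, truncation
#' reproduction (crossover + mutation), optional cooption operators, optional
#' transposon operators (spread, mark decay, transmission), re-application of
#' a frozen maternal column, and optional reservoir influx. The run succeeds
#' when the best E falls below \code{EThreshold}; it stops unsuccessfully when
#' the evaluation budget \code{EvalSum} or \code{maxGenerations} is exhausted.
#'
#' @param problem \code{\link{evolutionProblem}}
#' @param config \code{\link{engineConfig}}
#' @param cooption \code{\link{cooptionConfig}}
#' @param te \code{\link{teConfig}} or NULL for no transposons
#' @param staticColumn optional integer vector frozen into the Bcd column of
#'   every individual after every operator pass (static transposon forcing)
#' @param reservoir optional list(count =) giving a per-generation influx of
#'   fresh, uninfected, obligatory-size individuals replacing the worst ones
#' @param nGenesInit genes per individual at initialisation (default: the
#'   obligatory count, or obligatory + maxRecruits in static cooption mode)
#' @param trackInvolvement also log, per generation, how many recruits of the
#'   current best individual pass the 10% and 33% involvement thresholds
#'   (extra simulations, not counted against EvalSum)
#' @param strainLog also log counts of minimal vs recruited networks and of
#'   transposon clusters of length 4 and 5 (coevolution bookkeeping)
#' @return an \linkS4class{EvolutionResult}
#' @examples
#' \donttest{
#' inp <- maternalInputs(spatialGrid(), makeBcd())
#' prob <- evolutionProblem(inp, makeGapTargets())
#' cfg <- engineConfig(Popul = 30, EvalSum = 300, maxGenerations = 5, seed = 1)
#' res <- runEvolution(prob, cfg, nGenesInit = 3)
#' runLog(res)
#' }
#' @export
runEvolution <- function(problem, config = engineConfig(),
                         cooption = cooptionConfig(mode = "off"), te = NULL,
                         staticColumn = NULL, reservoir = NULL,
                         nGenesInit = NULL, trackInvolvement = FALSE,
                         strainLog = FALSE) {
  set.seed(config$seed)
  obl <- problem$obligatory
  if (is.null(nGenesInit))
    nGenesInit <- if (cooption$mode == "static")
      obl + cooption$maxRecruits else obl
  pop <- initPopulation(config, nGenesInit, problem$nMaternal)
  if (!is.null(staticColumn))
    pop <- lapply(pop, applyStaticColumn, values = staticColumn)
  if (!is.null(te)) pop <- lapply(pop, .initialInfection, te = te)

  counter <- fitnessCounter()
  best <- NULL
  gen <- 0L
  rows <- list()
  success <- FALSE

  repeat {
    pop <- .scorePopulation(pop, problem, counter)
    E <- vapply(pop, function(x) x$E, numeric(1))
    ib <- which.min(E)
    if (is.null(best) || E[ib] < best$E) best <- pop[[ib]]

    inv <- c(NA_integer_, NA_integer_)
    if (trackInvolvement && nrow(best$W) > obl) {
      rep <- functionalInvolvement(individualCircuit(best, problem),
                                   problem$inputs, problem$targets,
                                   sim = problem$sim,
                                   thresholds = cooption$involvementThresholds)
      inv <- c(sum(rep$functional_lo), sum(rep$functional_hi))
    }
    row <- data.frame(
      generation = gen, evaluations = counter$evaluations,
      best_E = best$E, mean_E = mean(E),
      mean_genes = mean(vapply(pop, function(x) nrow(x$W), numeric(1))),
      mean_TE_length = if (is.null(te)) 0 else .meanTELength(pop),
      functional_recruits_10 = inv[1], functional_recruits_33 = inv[2])
    if (strainLog) {
      ng <- vapply(pop, function(x) nrow(x$W), integer(1))
      cl <- .clusterLengthCounts(pop, c(4L, 5L))
      row$grn_base <- sum(ng == obl)
      row$grn_recruit <- sum(ng > obl)
      row$te_len4 <- cl[1]; row$te_len5 <- cl[2]
    }
    rows[[length(rows) + 1L]] <- row

    if (best$E < config$EThreshold) { success <- TRUE; break }
    if (counter$evaluations >= config$EvalSum) break
    if (gen >= config$maxGenerations) break

    pop <- replaceBelowAverage(pop)
    pop <- reproduceGeneration(pop, config)
    if (cooption$mode == "dynamic") pop <- applyCooption(pop, cooption, obl)
    if (!is.null(te)) {
      pop <- lapply(pop, teSpread, teGrowth = te$teGrowth,
                    direction = te$spreadDirection)
      pop <- lapply(pop, teMutator, teAction = te$teAction,
                    decayFactor = te$decayFactor)
      pop <- teTransmit(pop, te$transmissionRate)
    }
    if (!is.null(staticColumn))
      pop <- lapply(pop, applyStaticColumn, values = staticColumn)
    if (!is.null(reservoir) && reservoir$count > 0L) {
      Enow <- vapply(pop, function(x) x$E, numeric(1))
      Enow[is.na(Enow)] <- -Inf        # freshly modified: keep
      worst <- order(Enow, decreasing = TRUE)[seq_len(reservoir$count)]
      for (i in worst) {
        ind <- .newIndividual(obl, problem$nMaternal, config$initRange)
        if (!is.null(te)) ind$maxTE <- .sampleMaxTE(te)
        pop[[i]] <- ind
      }
    }
    gen <- gen + 1L
  }

  new("EvolutionResult", best = best, log = do.call(rbind, rows),
      success = success, evaluations = counter$evaluations,
      generations = gen,
      config = list(engine = config, cooption = cooption, te = te,
                    staticColumn = staticColumn, reservoir = reservoir,
                    nGenesInit = nGenesInit))
}

#' Success rate and speed of evolution over repeated runs
#'
#' Repeats \code{\link{runEvolution}} with distinct sub-seeds derived from
#' \code{config$seed}. Success rate is the fraction of runs whose best E
#' reached the threshold; evolvability is measured as the mean number of
#' evaluations spent by the successful runs (lower = faster evolution).
#'
#' @inheritParams runEvolution
#' @param nRuns number of independent runs (>= 1)
#' @param ... further arguments passed to \code{\link{runEvolution}}
#' @return list with success_rate, mean_evaluations (NA if no successes), and
#'   the individual \linkS4class{EvolutionResult}s
#' @export
benchmarkEvolvability <- function(problem, config, nRuns, ...) {
  if (nRuns < 1L) stop("benchmarkEvolvability: nRuns must be >= 1")
  runs <- lapply(seq_len(nRuns), function(i) {
    cfg <- config
    cfg$seed <- as.integer((config$seed + 1009 * i) %% .Machine$integer.max)
    runEvolution(problem, cfg, ...)
  })
  ok <- vapply(runs, succeeded, logical(1))
  list(success_rate = mean(ok),
       mean_evaluations = if (any(ok))
         mean(vapply(runs[ok], evaluationsUsed, integer(1))) else NA_real_,
       runs = runs)
}
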