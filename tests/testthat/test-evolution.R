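test_that("initPopulation draws consistent, reproducible uniform genotypes", {
  cfg <- engineConfig(Popul = 10, seed = 1)
  set.seed(1)
  pop <- initPopulation(cfg, 3, 1)
  expect_length(pop, 10)
  expect_true(all(vapply(pop, function(x)
    identical(dim(x$W), c(3L, 4L)) && identical(dim(x$marks), c(3L, 4L)) &&
      all(x$marks == 0L) && is.na(x$E), logical(1))))
  set.seed(1)
  pop2 <- initPopulation(cfg, 3, 1)
  expect_identical(pop, pop2)
  expect_error(initPopulation(cfg, 1, 1), "at least 2")

  # uniform law: mean of all entries ~ 0 within 3 sigma
  cfgBig <- engineConfig(Popul = 500, seed = 1)
  set.seed(2)
  w <- unlist(lapply(initPopulation(cfgBig, 3, 1), function(x) x$W))
  se <- sqrt(10^2 / 12 / length(w))
  expect_lt(abs(mean(w)), 3 * se)
})

test_that("mutation respects its probability, magnitude bound and identity", {
  set.seed(3)
  ind <- mkInd(matrix(runif(12, -5, 5), 3, 4))
  ind$E <- 1.23
  expect_identical(mutateIndividual(ind, Mut = 0), ind)

  # Mut = 1: essentially every element changes, each by at most log(Power)
  deltas <- c()
  for (i in 1:50) {
    mut <- mutateIndividual(ind, Mut = 1, Power = 1e6)
    expect_true(is.na(mut$E))
    deltas <- c(deltas, abs(mut$W - ind$W))
  }
  expect_true(all(deltas <= log(1e6) + 1e-12))
  expect_gt(mean(deltas > 0), 0.999)      # u = 1 (delta 0) has prob 1e-6
  expect_error(mutateIndividual(ind, Mut = 0.5, Power = 1), "Power")
})

test_that("one-point crossover swaps a tail and preserves the value multiset", {
  p1 <- mkInd(matrix(1:4, 1, 4)); p2 <- mkInd(matrix(5:8, 1, 4))
  p1$E <- 0.5; p2$E <- 0.7
  set.seed(4)
  for (i in 1:20) {
    ch <- onePointCrossover(p1, p2)
    expect_setequal(c(ch[[1]]$W, ch[[2]]$W), 1:8)
    # children are prefix-of-one + suffix-of-other for some cut
    ok <- any(vapply(1:3, function(k)
      identical(ch[[1]]$W[1, ], c(p1$W[1, 1:k], p2$W[1, (k + 1):4])) &&
      identical(ch[[2]]$W[1, ], c(p2$W[1, 1:k], p1$W[1, (k + 1):4])),
      logical(1)))
    expect_true(ok)
    expect_true(is.na(ch[[1]]$E) && is.na(ch[[2]]$E))
  }
  # identical parents give identical children with fitness retained
  ch <- onePointCrossover(p1, p1)
  expect_identical(ch[[1]], p1)
  expect_error(onePointCrossover(p1, mkInd(matrix(0, 2, 3))), "shape")
})

test_that("marks travel with their elements in crossover", {
  p1 <- mkInd(matrix(1:4, 1, 4), marks = matrix(c(1L, 1L, 1L, 1L), 1, 4))
  p2 <- mkInd(matrix(5:8, 1, 4), marks = matrix(0L, 1, 4))
  set.seed(9)
  ch <- onePointCrossover(p1, p2)
  for (child in ch)
    for (j in 1:4)
      expect_identical(child$marks[1, j],
                       if (child$W[1, j] %in% 1:4) 1L else 0L)
})

test_that("replaceBelowAverage culls strictly-worse-than-mean individuals", {
  mk <- function(E) { i <- mkInd(matrix(E, 2, 3)); i$E <- E; i }
  # all equal: nobody is below average
  popEq <- lapply(c(2, 2, 2), mk)
  expect_identical(replaceBelowAverage(popEq), popEq)
  # scores {1, 3}: mean 2, the 3-scorer is replaced by the 1-scorer
  set.seed(5)
  pop <- replaceBelowAverage(list(mk(1), mk(3)))
  expect_identical(vapply(pop, function(x) x$E, numeric(1)), c(1, 1))
  # post-condition: max E never exceeds the previous mean
  set.seed(6)
  for (i in 1:10) {
    pop <- lapply(runif(20, 0, 10), mk)
    m <- mean(vapply(pop, function(x) x$E, numeric(1)))
    post <- replaceBelowAverage(pop)
    expect_lte(max(vapply(post, function(x) x$E, numeric(1))), m)
    expect_length(post, 20)
  }
  expect_error(replaceBelowAverage(list(mkInd(matrix(0, 2, 3)))), "scored")
})

test_that("reproduceGeneration applies operators to the right slots", {
  mk <- function(E) { i <- mkInd(matrix(E, 2, 3)); i$E <- E; i }
  pop <- lapply(1:10, mk)

  cfg0 <- engineConfig(Popul = 10, Reprod = 0)
  expect_identical(reproduceGeneration(pop, cfg0), pop)

  cfgNoop <- engineConfig(Popul = 10, Reprod = 0.4, Mut = 0, Cross = 0)
  set.seed(7)
  post <- reproduceGeneration(pop, cfgNoop)
  # offspring are unmutated copies of the 4 parents replacing the worst 4;
  # everything keeps a valid fitness value
  expect_identical(sort(vapply(post, function(x) x$E, numeric(1))),
                   c(1, 1, 2, 2, 3, 3, 4, 4, 5, 6))

  set.seed(8)
  post <- reproduceGeneration(pop, engineConfig(Popul = 10, Reprod = 0.4,
                                                Mut = 1, Cross = 0))
  changed <- vapply(post, function(x) is.na(x$E), logical(1))
  expect_identical(sum(changed), 4L)                 # floor(0.4 * 10)
  expect_false(any(changed[1:4]))                    # parents persist
  # in-place mode instead mutates the selected best
  set.seed(8)
  post <- reproduceGeneration(pop, engineConfig(Popul = 10, Reprod = 0.4,
                                                Mut = 1, Cross = 0,
                                                reproduction = "inplace"))
  changed <- vapply(post, function(x) is.na(x$E), logical(1))
  expect_identical(which(changed), 1:4)
})

test_that("runEvolution stopping rules and budget accounting work", {
  prob <- recoveryProblem()
  # infinite threshold: success at generation 0
  cfg <- engineConfig(Popul = 10, EThreshold = Inf, seed = 1)
  res <- runEvolution(prob, cfg, nGenesInit = 3)
  expect_true(succeeded(res))
  expect_identical(res@generations, 0L)
  # EvalSum = Popul: exactly one scoring pass
  cfg <- engineConfig(Popul = 10, EThreshold = -1, EvalSum = 10, seed = 1)
  res <- runEvolution(prob, cfg, nGenesInit = 3)
  expect_false(succeeded(res))
  expect_identical(evaluationsUsed(res), 10L)
  expect_identical(nrow(runLog(res)), 1L)
})

test_that("runEvolution is deterministic and best-so-far is nonincreasing", {
  prob <- recoveryProblem()
  cfg <- engineConfig(Popul = 24, EThreshold = 1e-6, seed = 42,
                      maxGenerations = 15)
  r1 <- runEvolution(prob, cfg, nGenesInit = 3)
  r2 <- runEvolution(prob, cfg, nGenesInit = 3)
  expect_identical(runLog(r1), runLog(r2))
  expect_identical(bestIndividual(r1)$W, bestIndividual(r2)$W)
  expect_true(all(diff(runLog(r1)$best_E) <= 0))
  # the budget is never exceeded by more than one scoring pass
  expect_lte(evaluationsUsed(r1), cfg$EvalSum + cfg$Popul)
  # population size is constant: mean_genes recorded for full population
  expect_identical(nrow(runLog(r1)), r1@generations + 1L)
})

test_that("benchmarkEvolvability aggregates runs correctly", {
  prob <- recoveryProblem()
  cfg <- engineConfig(Popul = 10, EThreshold = Inf, seed = 1)
  b <- benchmarkEvolvability(prob, cfg, nRuns = 3, nGenesInit = 3)
  expect_identical(b$success_rate, 1)
  expect_identical(b$mean_evaluations, 10)
  expect_error(benchmarkEvolvability(prob, cfg, nRuns = 0), "nRuns")
  # tightening the threshold cannot increase the success rate (same seeds)
  cfgT <- engineConfig(Popul = 10, EThreshold = -1, EvalSum = 20, seed = 1)
  bT <- benchmarkEvolvability(prob, cfgT, nRuns = 3, nGenesInit = 3)
  expect_lte(bT$success_rate, b$success_rate)
})
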