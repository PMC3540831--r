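test_that("gene introduction appends an inert zero gene", {
  set.seed(10)
  ind <- mkInd(matrix(runif(6, -5, 5), 2, 3))
  prob <- recoveryProblem()
  big <- introduceGene(ind, obligatory = 2L)
  expect_identical(dim(big$W), c(3L, 4L))
  expect_identical(dim(big$marks), c(3L, 4L))
  expect_true(all(big$W[3, ] == 0) && all(big$W[, 4] == 0))
  bigger <- introduceGene(big, obligatory = 2L)
  expect_identical(dim(bigger$W), c(4L, 5L))
  # the recruit cap makes the operator a no-op
  expect_identical(introduceGene(big, maxRecruits = 1, obligatory = 2L), big)

  # obligatory dynamics are unchanged immediately after introduction
  e2 <- evaluateCircuit(individualCircuit(ind, prob), inpBcd, teacherTg)
  e3 <- evaluateCircuit(individualCircuit(big, prob), inpBcd, teacherTg)
  expect_equal(e2, e3, tolerance = 1e-12)
})

test_that("gene withdrawal removes the last gene and respects the minimum", {
  set.seed(11)
  ind3 <- mkInd(matrix(runif(12, -5, 5), 3, 4))
  out <- withdrawGene(ind3, obligatory = 2L)
  expect_identical(dim(out$W), c(2L, 3L))
  expect_identical(out$W, ind3$W[-3, -4])
  # at the minimal network size the operator does not operate
  ind2 <- mkInd(matrix(runif(6, -5, 5), 2, 3))
  expect_identical(withdrawGene(ind2, obligatory = 2L), ind2)
  # introduce-then-withdraw of an inert recruit recovers the genotype
  expect_identical(withdrawGene(introduceGene(ind2, obligatory = 2L), 2L)$W,
                   ind2$W)
  # withdrawing an inert recruit keeps the fitness, an active one does not
  ind3b <- introduceGene(ind2, obligatory = 2L); ind3b$E <- 1
  expect_identical(withdrawGene(ind3b, 2L)$E, 1)
  ind3b$W[1, 4] <- 2
  expect_true(is.na(withdrawGene(ind3b, 2L)$E))
})

test_that("applyCooption follows ToRecruitingProc and WithdrAdd", {
  set.seed(12)
  pop <- replicate(20, mkInd(matrix(runif(12, -5, 5), 3, 4)),
                   simplify = FALSE)
  cfg0 <- cooptionConfig(mode = "dynamic", ToRecruitingProc = 0)
  expect_identical(applyCooption(pop, cfg0, 2L), pop)

  ng <- function(p) vapply(p, function(x) nrow(x$W), integer(1))
  cfgIntro <- cooptionConfig(mode = "dynamic", ToRecruitingProc = 1,
                             WithdrAdd = 0, maxRecruits = 8)
  expect_true(all(ng(applyCooption(pop, cfgIntro, 2L)) == 4L))
  cfgWd <- cooptionConfig(mode = "dynamic", ToRecruitingProc = 1,
                          WithdrAdd = 1)
  expect_true(all(ng(applyCooption(pop, cfgWd, 2L)) == 2L))
  # off mode is a no-op regardless
  expect_identical(applyCooption(pop, cooptionConfig(mode = "off"), 2L), pop)
})

test_that("gene counts stay within bounds during dynamic cooption", {
  prob <- evolutionProblem(inpBcd, makeGapTargets(gridEL))
  cfg <- engineConfig(Popul = 20, EThreshold = 0, seed = 2,
                      maxGenerations = 25)
  co <- cooptionConfig(mode = "dynamic", ToRecruitingProc = 0.3,
                       WithdrAdd = 0.3, maxRecruits = 3)
  res <- runEvolution(prob, cfg, cooption = co)
  lg <- runLog(res)
  expect_true(all(lg$mean_genes >= 2 & lg$mean_genes <= 5))
  # with WithdrAdd = 0 there is a net upward drift in gene count (selection
  # copying can lower it transiently, but introduction dominates)
  co0 <- cooptionConfig(mode = "dynamic", ToRecruitingProc = 0.3,
                        WithdrAdd = 0, maxRecruits = 3)
  lg0 <- runLog(runEvolution(prob, cfg, cooption = co0))
  expect_gt(lg0$mean_genes[nrow(lg0)], lg0$mean_genes[1])
})

test_that("functional involvement flags essential recruits, not inert ones", {
  prob <- recoveryProblem()
  # inert recruit: all-zero W entries -> r = 0, never functional
  set.seed(13)
  ind <- mkInd(matrix(runif(6, -5, 5), 2, 3))
  ind3 <- introduceGene(ind, obligatory = 2L)
  rep0 <- functionalInvolvement(individualCircuit(ind3, prob), inpBcd,
                                teacherTg)
  expect_identical(nrow(rep0), 1L)
  expect_identical(rep0$rel_change, 0)
  expect_false(rep0$functional_lo); expect_false(rep0$functional_hi)

  # the teacher's recruit r1 is essential: E_full = 0, zeroing it breaks the
  # fit -> infinite relative change, flagged at both thresholds
  repT <- functionalInvolvement(teacher, inpBcd, teacherTg)
  expect_identical(repT$rel_change, Inf)
  expect_true(repT$functional_lo && repT$functional_hi)

  # perturbed teacher: E_full > 0 and zeroing r1 raises E by far more than
  # 50% -> flagged at both 10% and 33%
  pert <- teacher
  pert@W[1, 1] <- pert@W[1, 1] + 1
  repP <- functionalInvolvement(pert, inpBcd, teacherTg)
  expect_gt(repP$E_full, 0)
  expect_gt(repP$rel_change, 0.5)
  expect_true(repP$functional_lo && repP$functional_hi)

  # flags are monotone in the threshold
  expect_true(all(!repP$functional_hi | repP$functional_lo))

  # no recruits -> empty report
  cc2 <- geneCircuit(matrix(0, 2, 3), geneNames = c("Kr", "kni"))
  expect_identical(nrow(functionalInvolvement(cc2, inpBcd, teacherTg)), 0L)
})
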