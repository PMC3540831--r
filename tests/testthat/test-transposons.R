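test_that("the static maternal column reproduces the printed tables", {
  expect_identical(staticColumnValues(4), c(0L, 33L, 67L, 100L))
  expect_identical(staticColumnValues(6), c(0L, 20L, 40L, 60L, 80L, 100L))
  expect_identical(staticColumnValues(8),
                   c(0L, 14L, 29L, 43L, 57L, 71L, 86L, 100L))
  expect_identical(staticColumnValues(10),
                   c(0L, 11L, 22L, 33L, 44L, 56L, 67L, 78L, 89L, 100L))
  expect_identical(staticColumnValues(2), c(0L, 100L))
  expect_error(staticColumnValues(1), "dimension")
})

test_that("a frozen Bcd column survives mutation", {
  vals <- staticColumnValues(3)
  set.seed(14)
  ind <- applyStaticColumn(mkInd(matrix(runif(12, -5, 5), 3, 4)), vals)
  mut <- mutateIndividual(ind, Mut = 1)
  fixed <- applyStaticColumn(mut, vals)
  expect_identical(fixed$W[, 1], as.numeric(vals))
  # non-maternal entries are exactly the mutated values
  expect_identical(fixed$W[, 2:4], mut$W[, 2:4])
  expect_error(applyStaticColumn(ind, 1:2), "length")
})

test_that("the mutator halves marked elements and cuts the connection", {
  marks <- matrix(0L, 2, 3); marks[1, 1] <- 1L
  W <- matrix(0, 2, 3); W[1, 1] <- 8
  ind <- mkInd(W, marks)
  for (g in 1:3) ind <- teMutator(ind, teAction = 1)
  expect_identical(ind$W[1, 1], 1)          # 8 -> 4 -> 2 -> 1
  expect_true(all(ind$W[-1] == 0))          # unmarked elements untouched
  ind2 <- mkInd(W, marks)
  for (g in 1:50) ind2 <- teMutator(ind2, teAction = 1)
  expect_identical(ind2$W[1, 1], 8 * 2^-50)
  expect_lt(abs(ind2$W[1, 1]), 1e-15 * 8)
  # a decayed value flags the fitness as stale
  ind3 <- mkInd(W, marks); ind3$E <- 1
  expect_true(is.na(teMutator(ind3, teAction = 1)$E))
  # teAction = 0 is a no-op
  ind4 <- mkInd(W, marks); ind4$E <- 1
  expect_identical(teMutator(ind4, teAction = 0), ind4)
})

test_that("spread grows clusters one element at a time up to the cap", {
  marks <- matrix(0L, 6, 3); marks[2, 1] <- 1L
  ind <- mkInd(matrix(1, 6, 3), marks)
  g1 <- teSpread(ind, teGrowth = 1, maxLength = 4)
  expect_identical(sum(g1$marks), 2L)
  expect_identical(g1$marks[2:3, 1], c(1L, 1L))   # grows downward
  # repeated spread: at most one new mark per call, contiguous, capped at 4
  cur <- ind
  for (i in 1:10) {
    nxt <- teSpread(cur, teGrowth = 1, maxLength = 4)
    expect_lte(sum(nxt$marks) - sum(cur$marks), 1L)
    runs <- rle(nxt$marks[, 1])
    expect_lte(max(runs$lengths[runs$values == 1L]), 4L)
    cur <- nxt
  }
  expect_identical(sum(cur$marks), 4L)
  # upward direction
  gu <- teSpread(ind, teGrowth = 1, maxLength = 4, direction = "up")
  expect_identical(gu$marks[1:2, 1], c(1L, 1L))
  # teGrowth = 0 is a no-op
  expect_identical(teSpread(ind, teGrowth = 0), ind)
  # values are never modified by spread
  expect_identical(g1$W, ind$W)
})

test_that("transmission copies marks at fixed coordinates", {
  set.seed(15)
  donor <- mkInd(matrix(1, 3, 4)); donor$marks[1:2, 1] <- 1L
  blank <- mkInd(matrix(2, 3, 4))
  # force the donor/recipient roles by trying until transmission happened
  pop <- list(donor, blank)
  for (i in 1:20) pop <- teTransmit(pop, transmissionRate = 1)
  m1 <- pop[[1]]$marks; m2 <- pop[[2]]$marks
  expect_identical(m1, donor$marks)               # donor unchanged
  expect_identical(m2, donor$marks)               # same coordinates only
  # values at newly marked coordinates are untouched
  expect_identical(pop[[2]]$W, blank$W)
  # a markless population transmits nothing
  p2 <- list(mkInd(matrix(1, 2, 3)), mkInd(matrix(2, 2, 3)))
  expect_identical(teTransmit(p2, transmissionRate = 1), p2)
})

test_that("mark count never decreases under spread plus transmission", {
  set.seed(16)
  pop <- replicate(6, {
    ind <- mkInd(matrix(runif(12), 3, 4))
    if (runif(1) < 0.7) ind$marks[sample(3, 1), sample(4, 1)] <- 1L
    ind
  }, simplify = FALSE)
  count <- function(p) sum(vapply(p, function(x) sum(x$marks), integer(1)))
  n0 <- count(pop)
  for (i in 1:15) {
    pop <- lapply(pop, teSpread, teGrowth = 0.5, maxLength = 3)
    pop <- teTransmit(pop, transmissionRate = 0.5)
    n1 <- count(pop)
    expect_gte(n1, n0)
    n0 <- n1
  }
})

test_that("the coevolution bookkeeping is consistent", {
  res <- coevolutionExperiment(Popul = 24, generations = 12, seed = 3,
                               influx = 2)
  lg <- runLog(res)
  expect_identical(nrow(lg), 13L)
  expect_true(all(lg$grn_base + lg$grn_recruit == 24))
  expect_true(all(lg$te_len4 >= 0 & lg$te_len5 >= 0))
  # TE_5 clusters require a 5-gene host: they never exceed recruit count
  expect_true(all(lg$te_len5 <= lg$grn_recruit * 6))
  # without reservoir, transposons and cooption the strain counts are frozen
  res0 <- coevolutionExperiment(Popul = 12, generations = 6, seed = 4,
                                influx = 0, te = NULL,
                                cooption = cooptionConfig(mode = "off"))
  lg0 <- runLog(res0)
  expect_true(all(lg0$grn_base == 12) && all(lg0$grn_recruit == 0))
})
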