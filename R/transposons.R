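#' Transposon (TE) configuration
#'
#' Controls the artificial-transposon operators: per-generation cluster
#' growth probability (\code{teGrowth}), per-generation probability that each
#' marked W element decays by \code{decayFactor} (\code{teAction};
#' \code{teAction = 1} with the default factor 1/2 halves every marked
#' element every generation), host-to-host transmission intensity, and the
#' maximum cluster length. When \code{maxLength} is NULL it is sampled once
#' per lineage as 2 + (1 or 2), i.e. 3 or 4 with equal probability.
#'
#' @param teGrowth cluster growth probability per generation
#' @param teAction decay probability per marked element per generation
#' @param decayFactor multiplicative decay of marked elements (default 1/2)
#' @param maxLength fixed maximum cluster length, or NULL to sample 3 or 4
#'   per individual
#' @param initialLength length of the initial mark cluster seeded in the Bcd
#'   column of every individual at the start of a run
#' @param transmissionRate transmission events per generation, expressed as a
#'   fraction of the population size (ceiling(rate * Popul) random host pairs)
#' @param spreadDirection "down" (increasing target-gene row, default) or "up"
#' @return a validated configuration list
#' @export
teConfig <- function(teGrowth = 0.5, teAction = 0.5, decayFactor = 0.5,
                     maxLength = NULL, initialLength = 1L,
                     transmissionRate = 0.05,
                     spreadDirection = c("down", "up")) {
  stopifnot(teGrowth >= 0, teGrowth <= 1, teAction >= 0, teAction <= 1,
            decayFactor > 0, decayFactor < 1, initialLength >= 1,
            transmissionRate >= 0)
  list(teGrowth = teGrowth, teAction = teAction, decayFactor = decayFactor,
       maxLength = if (is.null(maxLength)) NULL else as.integer(maxLength),
       initialLength = as.integer(initialLength),
       transmissionRate = transmissionRate,
       spreadDirection = match.arg(spreadDirection))
}

.sampleMaxTE <- function(te) {
  if (is.null(te$maxLength)) 2L + sample.int(2L, 1L) else te$maxLength
}

# seed every individual with one mark cluster at the top of the Bcd column
.initialInfection <- function(ind, te) {
  ind$maxTE <- .sampleMaxTE(te)
  L <- min(te$initialLength, nrow(ind$marks))
  ind$marks[seq_len(L), 1L] <- 1L
  ind
}

#' Constant maternal-regulation column for static transposon tests
#'
#' The Bcd column of W is held at \code{dimension} integers evenly spaced on
#' [0, 100], rounded to the nearest integer, while the rest of the matrix is
#' free to evolve.
#'
#' @param dimension number of genes (>= 2)
#' @return integer vector of length \code{dimension}
#' @examples
#' staticColumnValues(4)   # 0 33 67 100
#' @export
staticColumnValues <- function(dimension) {
  if (!is.numeric(dimension) || dimension < 2)
    stop("staticColumnValues: dimension must be >= 2")
  as.integer(round(seq(0, 100, length.out = dimension)))
}

#' Freeze the maternal (Bcd) column of an individual
#'
#' Overwrites the first column of W with \code{values}. The engine re-applies
#' this after every mutation/crossover pass so the column is effectively
#' frozen during evolution.
#'
#' @param individual a population member
#' @param values numeric vector, one value per gene
#' @return the individual with the frozen column
#' @export
applyStaticColumn <- function(individual, values) {
  if (length(values) != nrow(individual$W))
    stop("applyStaticColumn: values length must equal the gene count")
  if (!isTRUE(all.equal(individual$W[, 1L], as.numeric(values),
                        check.attributes = FALSE))) {
    individual$W[, 1L] <- as.numeric(values)
    individual$E <- NA_real_
  }
  individual
}

#' Transposon mutator: decay of marked W elements
#'
#' Each marked element is multiplied by \code{decayFactor} with probability
#' \code{teAction} per generation. At \code{teAction = 1} and factor 1/2 this
#' is exact halving every generation, which quickly cuts the infected
#' regulatory connection.
#'
#' @param individual a population member with aligned marks
#' @param teAction per-element decay probability
#' @param decayFactor multiplicative factor in (0, 1)
#' @return the individual after decay (fitness invalidated if any value
#'   changed)
#' @export
teMutator <- function(individual, teAction, decayFactor = 0.5) {
  marked <- which(individual$marks == 1L)
  if (!length(marked) || teAction <= 0) return(individual)
  sel <- marked[runif(length(marked)) < teAction]
  if (!length(sel)) return(individual)
  old <- individual$W[sel]
  individual$W[sel] <- old * decayFactor
  if (any(old != individual$W[sel])) individual$E <- NA_real_
  individual
}

#' Transposon spread: cluster growth along a W column
#'
#' Each contiguous mark cluster in each column extends, with probability
#' \code{teGrowth}, by exactly one element onto the adjacent unmarked row
#' (downward in row index by default), unless the cluster already has the
#' maximum length. Marks only are changed; element values are untouched.
#'
#' @param individual a population member
#' @param teGrowth growth probability per cluster per generation
#' @param maxLength cluster length cap; defaults to the individual's own
#'   sampled cap, or unlimited if none was assigned
#' @param direction "down" or "up"
#' @return the individual with possibly extended marks
#' @export
teSpread <- function(individual, teGrowth, maxLength = NULL,
                     direction = c("down", "up")) {
  direction <- match.arg(direction)
  if (teGrowth <= 0 || !any(individual$marks == 1L)) return(individual)
  if (is.null(maxLength))
    maxLength <- if (is.na(individual$maxTE)) Inf else individual$maxTE
  m <- individual$marks
  nr <- nrow(m)
  for (j in seq_len(ncol(m))) {
    if (!any(m[, j] == 1L)) next
    r <- rle(m[, j])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values == 1L)) {
      if (r$lengths[k] >= maxLength) next
      if (runif(1) >= teGrowth) next
      target <- if (direction == "down") ends[k] + 1L else starts[k] - 1L
      if (target >= 1L && target <= nr && m[target, j] == 0L &&
          individual$marks[target, j] == 0L)
        individual$marks[target, j] <- 1L
    }
  }
  individual
}

#' Transposon transmission between hosts
#'
#' For each transmission event a random pair of hosts is chosen and one of
#' the two is the donor. If the donor carries transposon marks, they are
#' replicated at the same W coordinates in the partner, regardless of the
#' partner's values there (coordinates outside the partner's matrix are
#' dropped). Values at newly marked coordinates are untouched until the
#' mutator acts, so fitness is retained.
#'
#' @param population list of individuals
#' @param transmissionRate events per generation as a fraction of the
#'   population size
#' @return the population after transmission
#' @export
teTransmit <- function(population, transmissionRate) {
  n <- length(population)
  if (transmissionRate <= 0 || n < 2L) return(population)
  for (ev in seq_len(ceiling(transmissionRate * n))) {
    pair <- sample.int(n, 2L)
    don <- population[[pair[1L]]]
    if (!any(don$marks == 1L)) next
    rec <- population[[pair[2L]]]
    nr <- min(nrow(don$marks), nrow(rec$marks))
    nc <- min(ncol(don$marks), ncol(rec$marks))
    sub <- rec$marks[seq_len(nr), seq_len(nc), drop = FALSE]
    rec$marks[seq_len(nr), seq_len(nc)] <-
      pmax(sub, don$marks[seq_len(nr), seq_len(nc), drop = FALSE])
    population[[pair[2L]]] <- rec
  }
  population
}

#' Default target patterns for the four-gap-gene coevolution scenario
#'
#' Gaussian stand-ins for all four trunk gap domains (gt, hb, Kr, kni in
#' anterior-posterior order) on the default grid.
#'
#' @param positions grid positions in %EL
#' @return a \linkS4class{TargetPatterns}
#' @export
coevolutionTargets <- function(positions = spatialGrid()) {
  makeGapTargets(positions, genes = list(
    gt  = list(center = 40, width = 4, amplitude = 0.9),
    hb  = list(center = 46, width = 5, amplitude = 0.9),
    Kr  = list(center = 54, width = 5, amplitude = 0.9),
    kni = list(center = 66, width = 5, amplitude = 0.9)))
}

#' Host-transposon coevolution experiment
#'
#' Runs the full engine with four obligatory gap genes, a single allowed
#' recruit (R1), growing and transmitting transposons, and a per-generation
#' influx of fresh uninfected 4-gene individuals from an external reservoir
#' replacing the worst ones. Every founder is infected with a transposon
#' cluster spanning the Bcd column (length 4); the per-lineage maximum
#' cluster length is 5, so length-5 transposons can only exist in 5-gene
#' (R1) hosts. The run logs per generation the abundances of 4-gene and R1
#' networks and the counts of mark clusters of lengths 4 and 5.
#'
#' @param Popul population size
#' @param generations generations to run
#' @param seed RNG seed
#' @param influx reservoir individuals per generation (0 = no reservoir)
#' @param te \code{\link{teConfig}}; NULL disables transposons
#' @param cooption \code{\link{cooptionConfig}}
#' @param inputs \linkS4class{MaternalInputs}
#' @param targets \linkS4class{TargetPatterns} for the four obligatory genes
#' @return an \linkS4class{EvolutionResult} whose log has columns grn_base,
#'   grn_recruit, te_len4 and te_len5
#' @export
coevolutionExperiment <- function(Popul = 300, generations = 500, seed = 1L,
                                  influx = ceiling(0.05 * Popul),
                                  te = teConfig(teGrowth = 0.1,
                                                teAction = 0.2,
                                                transmissionRate = 0.05,
                                                initialLength = 4L,
                                                maxLength = 5L),
                                  cooption = cooptionConfig(
                                    mode = "dynamic", ToRecruitingProc = 0.1,
                                    WithdrAdd = 0.25, maxRecruits = 1L),
                                  inputs = maternalInputs(spatialGrid(),
                                                          makeBcd()),
                                  targets = coevolutionTargets()) {
  problem <- evolutionProblem(inputs, targets)
  cfg <- engineConfig(Popul = Popul, EThreshold = 0, seed = seed,
                      maxGenerations = generations)
  runEvolution(problem, cfg, cooption = cooption, te = te,
               reservoir = if (influx > 0) list(count = as.integer(influx)),
               strainLog = TRUE)
}
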