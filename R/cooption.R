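#' Cooption (gene Introduction/Withdrawal) configuration
#'
#' In \code{dynamic} mode, each generation a \code{ToRecruitingProc} fraction
#' of the population is selected; each selected individual undergoes Gene
#' Withdrawal with probability \code{WithdrAdd} and Gene Introduction
#' otherwise. The effective per-generation Introduction rate is therefore
#' \code{ToRecruitingProc * (1 - WithdrAdd)} (0.1 with the defaults, within
#' the standard 5-10% range) and the Withdrawal rate
#' \code{ToRecruitingProc * WithdrAdd}; both are echoed in the returned
#' object, and never reported as a bare ratio. In \code{static} mode the
#' population is initialised with \code{maxRecruits} recruits already present
#' and the gene count never changes.
#'
#' @param mode "off", "static" or "dynamic"
#' @param ToRecruitingProc fraction of the population subjected to the
#'   procedure per generation
#' @param WithdrAdd probability that a selected individual undergoes
#'   Withdrawal rather than Introduction
#' @param maxRecruits cap on recruits beyond the obligatory genes
#' @param involvementThresholds the two relative-E thresholds used to flag
#'   functionally involved recruits
#' @return a validated configuration list
#' @export
cooptionConfig <- function(mode = c("off", "static", "dynamic"),
                           ToRecruitingProc = 0.1, WithdrAdd = 0,
                           maxRecruits = 8L,
                           involvementThresholds = c(0.10, 0.33)) {
  stopifnot(ToRecruitingProc >= 0, ToRecruitingProc <= 1,
            WithdrAdd >= 0, WithdrAdd <= 1, maxRecruits >= 0,
            length(involvementThresholds) == 2)
  list(mode = match.arg(mode), ToRecruitingProc = ToRecruitingProc,
       WithdrAdd = WithdrAdd, maxRecruits = as.integer(maxRecruits),
       introductionRate = ToRecruitingProc * (1 - WithdrAdd),
       withdrawalRate = ToRecruitingProc * WithdrAdd,
       involvementThresholds = sort(involvementThresholds))
}

#' Gene Introduction operator
#'
#' Appends one gene to an individual's network: a new bottom row and
#' right-most column of W, all entries zero, with aligned zero transposon
#' marks. A freshly introduced gene is inert (its regulatory output is zero),
#' so the fitness of the individual is unchanged and retained; mutation and
#' crossover subsequently adapt the new weights. Kinetic parameters of the
#' new gene come from the problem's kinetic template at circuit build time.
#' If the recruit cap is reached the operator is a no-op.
#'
#' @param individual a population member
#' @param maxRecruits recruit cap (Inf = uncapped)
#' @param obligatory obligatory gene count
#' @return the individual, possibly enlarged
#' @export
introduceGene <- function(individual, maxRecruits = Inf, obligatory = 2L) {
  ng <- nrow(individual$W)
  if (is.finite(maxRecruits) && ng - obligatory >= maxRecruits)
    return(individual)
  individual$W <- rbind(cbind(individual$W, 0), 0)
  individual$marks <- rbind(cbind(individual$marks, 0L), 0L)
  individual
}

#' Gene Withdrawal operator
#'
#' Removes the last-added gene (bottom row and right-most column of W, with
#' its marks). Does not operate on a minimal network (gene count equal to the
#' obligatory count). The fitness is retained when the removed gene was inert
#' (zero regulatory output onto the remaining genes) and invalidated
#' otherwise.
#'
#' @param individual a population member
#' @param obligatory obligatory gene count
#' @return the individual, possibly shrunk
#' @export
withdrawGene <- function(individual, obligatory = 2L) {
  ng <- nrow(individual$W)
  if (ng <= obligatory) return(individual)
  outCol <- individual$W[-ng, ncol(individual$W)]
  individual$W <- individual$W[-ng, -ncol(individual$W), drop = FALSE]
  individual$marks <- individual$marks[-ng, -ncol(individual$marks),
                                       drop = FALSE]
  if (any(outCol != 0)) individual$E <- NA_real_
  individual
}

#' Apply dynamic cooption to a population
#'
#' @param population list of individuals
#' @param config \code{\link{cooptionConfig}} with mode "dynamic"
#' @param obligatory obligatory gene count
#' @return the population after Introduction/Withdrawal events
#' @export
applyCooption <- function(population, config, obligatory = 2L) {
  if (config$mode != "dynamic") return(population)
  n <- length(population)
  k <- round(config$ToRecruitingProc * n)
  if (k < 1L) return(population)
  for (i in sample.int(n, k)) {
    population[[i]] <-
      if (runif(1) < config$WithdrAdd)
        withdrawGene(population[[i]], obligatory)
      else
        introduceGene(population[[i]], config$maxRecruits, obligatory)
  }
  population
}

#' Functional involvement of recruited genes
#'
#' For each recruit (gene beyond the obligatory set), the fit to the data is
#' re-evaluated with that gene's W elements zeroed out (both its row - the
#' inputs it receives - and its column - its regulatory output). The relative
#' fitness drop \code{r = (E_zeroed - E_full) / E_full} is compared against
#' the two thresholds (default 10% and 33%); a recruit is functionally
#' involved at threshold theta when \code{r > theta}. When \code{E_full} is
#' numerically zero, \code{r} is reported as \code{Inf} if zeroing changes the
#' fit at all and 0 otherwise.
#'
#' @param circuit a \linkS4class{GeneCircuit} with recruits
#' @param inputs \linkS4class{MaternalInputs}
#' @param targets \linkS4class{TargetPatterns}
#' @param sim \code{\link{simParams}}
#' @param thresholds two increasing fractions
#' @return data.frame with one row per recruit: gene, E_full, E_zeroed,
#'   rel_change, functional_lo, functional_hi (flags at the lower and higher
#'   threshold; thresholds stored as an attribute)
#' @export
functionalInvolvement <- function(circuit, inputs, targets, sim = simParams(),
                                  thresholds = c(0.10, 0.33)) {
  thresholds <- sort(thresholds)
  ng <- nGenes(circuit)
  obl <- circuit@obligatory
  if (ng <= obl) {
    out <- data.frame(gene = character(), E_full = numeric(),
                      E_zeroed = numeric(), rel_change = numeric(),
                      functional_lo = logical(), functional_hi = logical())
    attr(out, "thresholds") <- thresholds
    return(out)
  }
  eFull <- evaluateCircuit(circuit, inputs, targets, sim)
  eps <- .Machine$double.eps^0.5
  rows <- lapply((obl + 1L):ng, function(g) {
    cz <- circuit
    cz@W[g, ] <- 0
    cz@W[, circuit@nMaternal + g] <- 0
    ez <- evaluateCircuit(cz, inputs, targets, sim)
    r <- if (eFull > eps) (ez - eFull) / eFull
         else if (ez > eps) Inf else 0
    data.frame(gene = circuit@geneNames[g], E_full = eFull, E_zeroed = ez,
               rel_change = r, functional_lo = r > thresholds[1],
               functional_hi = r > thresholds[2])
  })
  out <- do.call(rbind, rows)
  attr(out, "thresholds") <- thresholds
  out
}
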