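#' Evaluation counter
#'
#' A small mutable record of how many circuit evaluations have been spent,
#' used to enforce the evaluation budget (EvalSum) of evolutionary runs.
#'
#' @return an environment with an integer field \code{evaluations}
#' @export
fitnessCounter <- function() {
  e <- new.env(parent = emptyenv())
  e$evaluations <- 0L
  e
}

#' Cost of a model solution against target patterns
#'
#' Sum of squared differences between model output and target data over the
#' scored genes and all nuclei:
#' \deqn{E = \sum_{a \in scored} \sum_i (v^a_i\,\mathrm{model} -
#'   v^a_i\,\mathrm{data})^2.}
#' Genes outside \code{scoredGenes} (recruits) never enter the sum; their
#' influence on E is only through the dynamics of the scored genes.
#'
#' @param state final \linkS4class{ExpressionState} (gene names as rownames)
#' @param targets \linkS4class{TargetPatterns}
#' @param scoredGenes character vector of gene names to score
#' @return nonnegative scalar, 0 iff the scored genes match exactly
#' @examples
#' tg <- targetPatterns(1:3, list(Kr = c(0, 0, 0)))
#' st <- expressionState(matrix(c(1, 2, 0), 1, 3, dimnames = list("Kr", NULL)))
#' costE(st, tg, "Kr")  # 5
#' @export
costE <- function(state, targets, scoredGenes) {
  v <- state@v
  missing <- setdiff(scoredGenes, rownames(v))
  if (length(missing))
    stop("costE: genes absent from the model state: ",
         paste(missing, collapse = ", "))
  missing <- setdiff(scoredGenes, names(targets@profiles))
  if (length(missing))
    stop("costE: genes absent from the targets: ",
         paste(missing, collapse = ", "))
  if (ncol(v) != length(targets@positions))
    stop("costE: model state and targets differ in grid length")
  sum(vapply(scoredGenes,
             function(g) sum((v[g, ] - targets@profiles[[g]])^2),
             numeric(1)))
}

#' Simulate a circuit and score it
#'
#' Runs \code{\link{simulateCircuit}} and evaluates \code{\link{costE}} on the
#' circuit's obligatory genes, incrementing the evaluation counter by one.
#'
#' @param circuit a \linkS4class{GeneCircuit}
#' @param inputs \linkS4class{MaternalInputs}
#' @param targets \linkS4class{TargetPatterns}
#' @param sim simulation parameters (\code{\link{simParams}})
#' @param counter optional \code{\link{fitnessCounter}}
#' @return the cost E
#' @export
evaluateCircuit <- function(circuit, inputs, targets, sim = simParams(),
                            counter = NULL) {
  st <- simulateCircuit(circuit, inputs, T = sim$T, dt = sim$dt,
                        sigmoidForm = sim$sigmoidForm)
  if (!is.null(counter)) counter$evaluations <- counter$evaluations + 1L
  costE(st, targets, circuit@geneNames[seq_len(circuit@obligatory)])
}
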