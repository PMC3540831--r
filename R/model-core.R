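#' Sigmoid regulation-expression function
#'
#' Maps the total regulatory input \code{u} of a gene onto its fractional
#' synthesis activity in (0, 1). The default is the algebraic gene-circuit
#' sigmoid \deqn{g(u) = \frac{1}{2}\left(1 + \frac{u}{\sqrt{1+u^2}}\right),}
#' which rapidly approaches 0 below u = -1.5 and 1 above u = 1.5. A logistic
#' form is available as an alternative.
#'
#' @param u regulatory input (finite numeric, vectorised)
#' @param form "algebraic" (default) or "logistic"
#' @return values in (0, 1), strictly increasing in \code{u}
#' @examples
#' sigmoid(0)      # 0.5
#' sigmoid(1.5)    # ~0.916
#' @export
sigmoid <- function(u, form = c("algebraic", "logistic")) {
  form <- match.arg(form)
  if (any(!is.finite(u))) stop("sigmoid: input must be finite")
  if (form == "logistic") 1 / (1 + exp(-u))
  else 0.5 * (1 + u / sqrt(1 + u * u))
}

.sigmoidCode <- function(form) match(match.arg(form, c("algebraic", "logistic")),
                                     c("algebraic", "logistic")) - 1L

# maternal profiles as an nMaternal x nNuclei matrix matching the circuit
.maternalMatrix <- function(circuit, inputs) {
  nn <- length(inputs@positions)
  if (circuit@nMaternal == 1L) {
    matrix(inputs@bcd, nrow = 1L, ncol = nn)
  } else {
    if (!length(inputs@cad))
      stop("circuit expects two maternal inputs but Cad is missing")
    rbind(inputs@bcd, inputs@cad)
  }
}

#' Regulatory input u of one gene in one nucleus
#'
#' Computes \eqn{u^a = \sum_b W^{ab} v^b_i + h^a}, where the regulator vector
#' concatenates the maternal concentrations and the zygotic gene products in
#' nucleus \code{nucleus}.
#'
#' @param circuit a \linkS4class{GeneCircuit}
#' @param state an \linkS4class{ExpressionState}
#' @param inputs a \linkS4class{MaternalInputs}
#' @param gene,nucleus 1-based indices
#' @return scalar regulatory input
#' @export
regulatoryInput <- function(circuit, state, inputs, gene, nucleus) {
  ng <- nGenes(circuit)
  nn <- length(inputs@positions)
  if (gene < 1L || gene > ng || nucleus < 1L || nucleus > nn)
    stop("regulatoryInput: index out of range")
  if (ncol(state@v) != nn || nrow(state@v) != ng)
    stop("regulatoryInput: state shape does not match circuit/inputs")
  m <- .maternalMatrix(circuit, inputs)
  sum(circuit@W[gene, ] * c(m[, nucleus], state@v[, nucleus])) +
    circuit@h[gene]
}

#' Euler-stability bound on the integration step
#'
#' Explicit Euler is nonnegativity- and stability-safe for
#' \code{dt <= 1 / (max(lam) + 2 * max(D) / spacing^2)}.
#'
#' @param circuit a \linkS4class{GeneCircuit}
#' @param spacing grid spacing (%EL per nucleus)
#' @return the maximum admissible dt
#' @export
stabilityBound <- function(circuit, spacing = 1) {
  1 / (max(circuit@lam) + 2 * max(circuit@D) / spacing^2)
}

#' One explicit-Euler step of the gene-circuit equations
#'
#' Advances every gene in every nucleus by
#' \code{v <- v + dt * (R * g(u) + D * Lap(v) - lam * v)} where \code{Lap} is
#' the discrete 1-D Laplacian with zero-flux (reflecting) boundaries. This is
#' the reference R implementation; \code{\link{simulateCircuit}} uses a
#' compiled loop with identical semantics.
#'
#' @inheritParams regulatoryInput
#' @param dt time step, must satisfy \code{\link{stabilityBound}}
#' @param sigmoidForm "algebraic" or "logistic"
#' @return the advanced \linkS4class{ExpressionState}
#' @export
eulerStep <- function(circuit, state, inputs, dt,
                      sigmoidForm = c("algebraic", "logistic")) {
  sigmoidForm <- match.arg(sigmoidForm)
  spacing <- gridSpacing(inputs@positions)
  if (dt <= 0 || dt > stabilityBound(circuit, spacing) + 1e-12)
    stop("eulerStep: dt must be positive and within the stability bound")
  v <- state@v
  nn <- ncol(v)
  m <- .maternalMatrix(circuit, inputs)
  u <- circuit@W %*% rbind(m, v) + circuit@h
  lap <- (v[, c(1L, seq_len(nn - 1L)), drop = FALSE] +
          v[, c(seq_len(nn - 1L) + 1L, nn), drop = FALSE] - 2 * v) /
    spacing^2
  vnew <- v + dt * (circuit@R * sigmoid(u, sigmoidForm) + circuit@D * lap -
                    circuit@lam * v)
  expressionState(vnew, state@t + dt)
}

#' Simulation parameters
#'
#' @param T integration horizon (time units); the default 100 comfortably
#'   exceeds the slowest relaxation time of the default kinetics (1/lam = 10)
#' @param dt Euler step; \code{NULL} picks half the stability bound
#' @param sigmoidForm "algebraic" or "logistic"
#' @return list of simulation parameters
#' @export
simParams <- function(T = 100, dt = NULL,
                      sigmoidForm = c("algebraic", "logistic")) {
  list(T = T, dt = dt, sigmoidForm = match.arg(sigmoidForm))
}

#' Integrate a gene circuit to time T
#'
#' Runs \code{ceiling(T / dt)} explicit-Euler steps of the reaction-diffusion
#' system from the given initial state (default: all zygotic concentrations
#' zero). Deterministic given its inputs.
#'
#' @inheritParams eulerStep
#' @param T integration horizon (> 0, or 0 to return the initial state)
#' @param initial optional initial \linkS4class{ExpressionState}
#' @param useCpp use the compiled integrator (default); the pure-R path is
#'   retained for verification
#' @return final \linkS4class{ExpressionState}
#' @examples
#' inp <- maternalInputs(spatialGrid(), makeBcd())
#' cc <- geneCircuit(matrix(c(2, 1, 0, -1, 1, 0), 2, 3))
#' out <- simulateCircuit(cc, inp)
#' @export
simulateCircuit <- function(circuit, inputs, T = 100, dt = NULL,
                            initial = NULL,
                            sigmoidForm = c("algebraic", "logistic"),
                            useCpp = TRUE) {
  sigmoidForm <- match.arg(sigmoidForm)
  spacing <- gridSpacing(inputs@positions)
  nn <- length(inputs@positions)
  ng <- nGenes(circuit)
  if (is.null(dt)) dt <- 0.5 * stabilityBound(circuit, spacing)
  if (is.null(initial))
    initial <- expressionState(matrix(0, ng, nn,
                                      dimnames = list(circuit@geneNames, NULL)))
  if (nrow(initial@v) != ng || ncol(initial@v) != nn)
    stop("simulateCircuit: initial state shape mismatch")
  if (T < 0) stop("simulateCircuit: T must be >= 0")
  if (T == 0) return(initial)
  nsteps <- as.integer(ceiling(T / dt))
  if (dt > stabilityBound(circuit, spacing) + 1e-12)
    stop("simulateCircuit: dt violates the stability bound")
  m <- .maternalMatrix(circuit, inputs)
  if (useCpp) {
    v <- simulate_circuit_cpp(circuit@W, circuit@h, circuit@R, circuit@D,
                              circuit@lam, m, initial@v, dt, nsteps, spacing,
                              .sigmoidCode(sigmoidForm))
    rownames(v) <- circuit@geneNames
    expressionState(v, initial@t + nsteps * dt)
  } else {
    st <- initial
    for (i in seq_len(nsteps)) st <- eulerStep(circuit, st, inputs, dt,
                                               sigmoidForm)
    rownames(st@v) <- circuit@geneNames
    st
  }
}
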