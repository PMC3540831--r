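#' Synthetic maternal Bcd gradient
#'
#' Anterior-high exponential profile
#' \eqn{\exp(-(x - x_{ant}) / \ell)} normalised to maximum 1 on the grid,
#' emulating the shape of the Bicoid gradient at mid cleavage cycle 14. The
#' default decay length of 20 %EL is the classic Bcd length scale.
#'
#' @param positions grid positions in %EL
#' @param decayLength exponential decay length ell in %EL (> 0)
#' @return nonnegative, strictly decreasing profile with max 1
#' @export
makeBcd <- function(positions = spatialGrid(), decayLength = 20) {
  if (!is.numeric(decayLength) || decayLength <= 0)
    stop("makeBcd: decayLength must be positive")
  .checkGrid(positions)
  p <- exp(-(positions - positions[1L]) / decayLength)
  p / max(p)
}

#' Synthetic maternal Cad gradient
#'
#' Posterior-high logistic profile normalised to maximum 1, emulating the
#' Caudal protein gradient.
#'
#' @param positions grid positions in %EL
#' @param midpoint %EL at which the profile reaches half of its plateau
#' @param steepness logistic scale in %EL (> 0); smaller is steeper
#' @return nondecreasing profile with max 1
#' @export
makeCad <- function(positions = spatialGrid(), midpoint = 60, steepness = 6) {
  if (steepness <= 0) stop("makeCad: steepness must be positive")
  .checkGrid(positions)
  p <- 1 / (1 + exp(-(positions - midpoint) / steepness))
  p / max(p)
}

#' Synthetic gap-gene target patterns
#'
#' Gaussian-bump stand-ins for the quantitative Kr and kni expression domains
#' (central and posterior, respectively) used to score circuits. Domain
#' centres, widths and amplitudes are configuration choices emulating the
#' qualitative shape of mid-cycle-14 gap domains; none are measured values.
#' Optional additive Gaussian noise is clipped at zero.
#'
#' @param positions grid positions in %EL
#' @param genes named list; each element a list with \code{center},
#'   \code{width} (Gaussian sd, %EL) and \code{amplitude} (in [0, 1])
#' @param noise sd of additive noise (0 = none)
#' @return a \linkS4class{TargetPatterns}
#' @examples
#' tg <- makeGapTargets()
#' names(profiles(tg))
#' @export
makeGapTargets <- function(positions = spatialGrid(),
                           genes = list(
                             Kr  = list(center = 52, width = 6, amplitude = 0.9),
                             kni = list(center = 66, width = 5, amplitude = 0.9)),
                           noise = 0) {
  .checkGrid(positions)
  prof <- lapply(genes, function(g) {
    stopifnot(g$amplitude >= 0, g$amplitude <= 1,
              g$center >= min(positions), g$center <= max(positions))
    p <- g$amplitude * exp(-0.5 * ((positions - g$center) / g$width)^2)
    if (noise > 0) p <- pmax(0, p + stats::rnorm(length(p), 0, noise))
    p
  })
  targetPatterns(positions, prof)
}

#' Targets generated by a teacher circuit
#'
#' Simulates a known "teacher" circuit and returns its obligatory-gene output
#' as target patterns, guaranteeing by construction that a perfect-fitness
#' solution exists. Used for parameter-recovery experiments.
#'
#' @param circuit the teacher \linkS4class{GeneCircuit}
#' @param inputs \linkS4class{MaternalInputs}
#' @param sim simulation parameters from \code{\link{simParams}}
#' @return a \linkS4class{TargetPatterns} over the obligatory genes
#' @export
teacherTargets <- function(circuit, inputs, sim = simParams()) {
  st <- simulateCircuit(circuit, inputs, T = sim$T, dt = sim$dt,
                        sigmoidForm = sim$sigmoidForm)
  obl <- seq_len(circuit@obligatory)
  targetPatterns(inputs@positions,
                 setNames(lapply(obl, function(a) st@v[a, ]),
                          circuit@geneNames[obl]))
}

#' Default teacher circuit for recovery experiments
#'
#' A fixed 3-gene circuit (obligatory Kr and kni plus one hb-like recruit)
#' under a single Bcd input, whose output forms unimodal central Kr and
#' posterior kni domains. The recruit is strongly Bcd-activated and represses
#' Kr and kni anteriorly, which positions their anterior borders; mutual
#' Kr-kni repression sharpens the posterior borders. Weights are round values
#' on the scale reachable by the logarithmic mutation operator.
#'
#' @param nMaternal 1 (Bcd) or 2 (Bcd + Cad; the Cad column is zero so the
#'   output is unchanged, but the search space matches two-gradient runs)
#' @return a \linkS4class{GeneCircuit}
#' @export
defaultTeacherCircuit <- function(nMaternal = 1L) {
  #            Bcd    Kr   kni    r1
  W <- rbind(
    Kr  = c(  14,     0,   -3,  -12),
    kni = c(   0,   -12,    0,  -10),
    r1  = c(  24,     0,    0,    0))
  if (nMaternal == 2L) W <- cbind(W[, 1L], Cad = 0, W[, -1L])
  geneCircuit(W, h = c(-4, 1.5, -14), nMaternal = nMaternal,
              obligatory = 2L, geneNames = c("Kr", "kni", "r1"))
}
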