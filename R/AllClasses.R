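#' Spatial grid of nuclei along the anterior-posterior axis
#'
#' Builds the 1-D row of nuclei on which all simulations run. Positions are
#' in percent egg length (%EL, anterior pole = 0). The default grid spans the
#' trunk region 34-82 %EL at one nucleus per %EL (49 nuclei).
#'
#' @param from,to anterior and posterior limits in %EL
#' @param spacing grid spacing in %EL per nucleus
#' @return numeric vector of nucleus positions
#' @examples
#' g <- spatialGrid()
#' length(g)  # 49
#' @export
spatialGrid <- function(from = 34, to = 82, spacing = 1) {
  if (!is.finite(from) || !is.finite(to) || !is.finite(spacing) ||
      spacing <= 0 || to <= from)
    stop("spatialGrid: need finite from < to and spacing > 0")
  seq(from, to, by = spacing)
}

#' Grid spacing of a position vector
#'
#' @param positions strictly increasing, uniformly spaced numeric vector
#' @return the (uniform) spacing
#' @export
gridSpacing <- function(positions) {
  .checkGrid(positions)
  positions[2L] - positions[1L]
}

.checkGrid <- function(positions) {
  if (length(positions) < 2L || any(!is.finite(positions)))
    stop("grid must have at least two finite positions")
  d <- diff(positions)
  if (any(d <= 0)) stop("grid positions must be strictly increasing")
  if (max(abs(d - d[1L])) > 1e-8 * abs(d[1L]))
    stop("grid positions must be uniformly spaced")
  invisible(positions)
}

# ---------------------------------------------------------------------------

#' GeneCircuit: genotype and kinetics of a gene-circuit model
#'
#' A gene circuit couples a genetic interconnectivity matrix \code{W} with
#' per-gene kinetic parameters. Row \code{a} of \code{W} holds the regulatory
#' weights acting on zygotic gene \code{a}; the left-most \code{nMaternal}
#' columns are the maternal inputs (Bcd, optionally Cad) followed by one
#' column per zygotic gene. Positive entries are activation, negative
#' repression. \code{h} is the ubiquitous regulatory input, \code{R} the
#' maximum synthesis rate, \code{D} the diffusion coefficient and \code{lam}
#' the first-order decay rate of each gene product.
#'
#' @slot W numeric matrix, nGenes x (nMaternal + nGenes)
#' @slot h,R,D,lam numeric vectors of length nGenes
#' @slot nMaternal integer, number of maternal input columns (1 or 2)
#' @slot obligatory integer, number of leading genes scored against data
#' @slot geneNames character vector of zygotic gene names
#' @export
setClass("GeneCircuit",
  representation(W = "matrix", h = "numeric", R = "numeric", D = "numeric",
                 lam = "numeric", nMaternal = "integer",
                 obligatory = "integer", geneNames = "character"),
  validity = function(object) {
    ng <- nrow(object@W)
    msg <- character()
    if (object@nMaternal < 1L || object@nMaternal > 2L)
      msg <- c(msg, "nMaternal must be 1 or 2")
    if (ncol(object@W) != object@nMaternal + ng)
      msg <- c(msg, "W must have nMaternal + nGenes columns")
    for (s in c("h", "R", "D", "lam"))
      if (length(slot(object, s)) != ng)
        msg <- c(msg, sprintf("%s must have one entry per gene", s))
    if (any(object@R < 0) || any(object@D < 0) || any(object@lam < 0))
      msg <- c(msg, "R, D and lam must be nonnegative")
    if (object@obligatory < 1L || object@obligatory > ng)
      msg <- c(msg, "obligatory count out of range")
    if (length(object@geneNames) != ng)
      msg <- c(msg, "geneNames must have one entry per gene")
    if (!all(is.finite(object@W)))
      msg <- c(msg, "W must be finite")
    if (length(msg)) msg else TRUE
  })

#' Construct a GeneCircuit
#'
#' @param W interaction matrix (nGenes x (nMaternal + nGenes)); maternal
#'   columns left-most
#' @param h,R,D,lam per-gene kinetics, recycled to the gene count
#' @param nMaternal number of maternal inputs (1 = Bcd, 2 = Bcd + Cad)
#' @param obligatory number of leading genes scored against target data
#' @param geneNames optional gene names; defaults to Kr, kni, r1, r2, ...
#' @return a \linkS4class{GeneCircuit}
#' @examples
#' cc <- geneCircuit(W = matrix(0, 2, 3))
#' nGenes(cc)
#' @export
geneCircuit <- function(W, h = -2.5, R = 0.1, D = 0.2, lam = 0.1,
                        nMaternal = 1L, obligatory = min(2L, nrow(W)),
                        geneNames = NULL) {
  W <- as.matrix(W)
  ng <- nrow(W)
  if (is.null(geneNames)) geneNames <- defaultGeneNames(ng)
  new("GeneCircuit", W = W,
      h = rep_len(as.numeric(h), ng), R = rep_len(as.numeric(R), ng),
      D = rep_len(as.numeric(D), ng), lam = rep_len(as.numeric(lam), ng),
      nMaternal = as.integer(nMaternal), obligatory = as.integer(obligatory),
      geneNames = geneNames)
}

defaultGeneNames <- function(ng, obligatory = min(2L, ng)) {
  obl <- c("Kr", "kni", "gt", "hb")[seq_len(min(obligatory, 4L))]
  if (obligatory > 4L) obl <- c(obl, paste0("g", seq_len(obligatory - 4L)))
  c(obl, if (ng > obligatory) paste0("r", seq_len(ng - obligatory)))[seq_len(ng)]
}

# ---------------------------------------------------------------------------

#' MaternalInputs: time-constant maternal gradients on the grid
#'
#' Holds the maternal protein profiles that act as external inputs to the
#' circuit: anterior-high Bcd and, optionally, posterior-high Cad. Profiles
#' are treated as constant in time during one simulation.
#'
#' @slot positions grid positions in %EL
#' @slot bcd nonnegative Bcd profile
#' @slot cad nonnegative Cad profile, or length 0 for Bcd-only models
#' @export
setClass("MaternalInputs",
  representation(positions = "numeric", bcd = "numeric", cad = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@bcd) != length(object@positions))
      msg <- c(msg, "bcd must match the grid length")
    if (length(object@cad) && length(object@cad) != length(object@positions))
      msg <- c(msg, "cad must be empty or match the grid length")
    if (any(object@bcd < 0) || any(object@cad < 0))
      msg <- c(msg, "maternal profiles must be nonnegative")
    ok <- tryCatch({ .checkGrid(object@positions); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) msg <- c(msg, ok)
    if (length(msg)) msg else TRUE
  })

#' Construct MaternalInputs
#' @param positions grid positions (%EL)
#' @param bcd Bcd profile over the grid
#' @param cad optional Cad profile; NULL for Bcd-only models
#' @return a \linkS4class{MaternalInputs}
#' @export
maternalInputs <- function(positions, bcd, cad = NULL) {
  new("MaternalInputs", positions = as.numeric(positions),
      bcd = as.numeric(bcd),
      cad = if (is.null(cad)) numeric(0) else as.numeric(cad))
}

# ---------------------------------------------------------------------------

#' TargetPatterns: target expression profiles for the scored genes
#'
#' @slot positions grid positions in %EL
#' @slot profiles named list of nonnegative numeric profiles (one per gene)
#' @export
setClass("TargetPatterns",
  representation(positions = "numeric", profiles = "list"),
  validity = function(object) {
    msg <- character()
    if (is.null(names(object@profiles)) || any(names(object@profiles) == ""))
      msg <- c(msg, "profiles must be a named list")
    bad <- vapply(object@profiles, function(p)
      length(p) != length(object@positions) || any(!is.finite(p)) || any(p < 0),
      logical(1))
    if (any(bad))
      msg <- c(msg, "each profile must be nonnegative, finite and grid-length")
    if (length(msg)) msg else TRUE
  })

#' Construct TargetPatterns
#' @param positions grid positions (%EL)
#' @param profiles named list of target profiles
#' @return a \linkS4class{TargetPatterns}
#' @export
targetPatterns <- function(positions, profiles) {
  new("TargetPatterns", positions = as.numeric(positions),
      profiles = lapply(profiles, as.numeric))
}

# ---------------------------------------------------------------------------

#' ExpressionState: gene product concentrations at one time point
#'
#' @slot v numeric matrix, nGenes x nNuclei, with gene names as rownames
#' @slot t simulation time (arbitrary units)
#' @export
setClass("ExpressionState",
  representation(v = "matrix", t = "numeric"),
  validity = function(object) {
    if (any(!is.finite(object@v))) "concentrations must be finite"
    else if (length(object@t) != 1L) "t must be a scalar" else TRUE
  })

#' Construct an ExpressionState
#' @param v concentration matrix (genes in rows, nuclei in columns)
#' @param t simulation time
#' @return an \linkS4class{ExpressionState}
#' @export
expressionState <- function(v, t = 0) new("ExpressionState", v = as.matrix(v),
                                          t = as.numeric(t))

# ---------------------------------------------------------------------------

#' EvolutionResult: outcome of one evolutionary run
#'
#' @slot best the best individual seen (list with W, marks, E)
#' @slot log per-generation data.frame (generation, evaluations, best_E,
#'   mean_E, mean_genes, mean_TE_length, functional_recruits_10,
#'   functional_recruits_33)
#' @slot success logical, TRUE if best E fell below the threshold
#' @slot evaluations total circuit evaluations used
#' @slot generations generations executed
#' @slot config the resolved configuration of the run
#' @export
setClass("EvolutionResult",
  representation(best = "list", log = "data.frame", success = "logical",
                 evaluations = "integer", generations = "integer",
                 config = "list"))
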