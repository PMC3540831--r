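#' Read a delimited profile table
#'
#' Expects tab-delimited text with a header row starting with \code{position}
#' followed by gene names, one row per nucleus, positions in %EL (strictly
#' increasing, uniformly spaced).
#'
#' @param path file path
#' @return list with \code{positions} (numeric) and \code{profiles} (named
#'   list of numeric vectors)
#' @export
readProfileTable <- function(path) {
  tab <- read.delim(path, check.names = FALSE)
  if (!"position" %in% names(tab))
    stop("readProfileTable: missing 'position' column in ", path)
  if (!all(vapply(tab, is.numeric, logical(1))))
    stop("readProfileTable: non-numeric cells in ", path)
  pos <- tab$position
  .checkGrid(pos)
  list(positions = pos,
       profiles = as.list(tab[setdiff(names(tab), "position")]))
}

#' Write a delimited profile table
#'
#' @param positions grid positions in %EL
#' @param profiles named list of numeric profiles
#' @param path destination file
#' @return the path, invisibly
#' @export
writeProfileTable <- function(positions, profiles, path) {
  tab <- data.frame(position = positions, profiles, check.names = FALSE)
  write.table(.fullPrecision(tab), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# doubles serialised at 17 significant digits round-trip bitwise through text
.fullPrecision <- function(tab) {
  for (j in seq_along(tab))
    if (is.double(tab[[j]])) tab[[j]] <- sprintf("%.17g", tab[[j]])
  tab
}

#' Read/write a labelled W matrix
#'
#' Tab-delimited table with regulator names as the column header and target
#' gene names as row labels.
#'
#' @param path file path
#' @return \code{readWMatrix}: a numeric matrix with dimnames
#' @export
readWMatrix <- function(path) {
  tab <- read.delim(path, row.names = 1L, check.names = FALSE)
  as.matrix(tab)
}

#' @rdname readWMatrix
#' @param W matrix with dimnames (e.g. from \code{\link{wMatrix}})
#' @return \code{writeWMatrix}: the path, invisibly
#' @export
writeWMatrix <- function(W, path) {
  tab <- .fullPrecision(as.data.frame(W, check.names = FALSE))
  write.table(data.frame(target = rownames(W), tab, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the artefacts of an evolutionary run
#'
#' Writes, into \code{outDir}: the best W matrix (\code{best_W.tsv}), the
#' per-generation log (\code{log.tsv}), the final obligatory-gene profiles of
#' the best circuit (\code{final_profiles.tsv}), and the resolved
#' configuration with its seed (\code{config.yaml}). All files are re-readable
#' by the package's own readers.
#'
#' @param result an \linkS4class{EvolutionResult}
#' @param problem the \code{\link{evolutionProblem}} of the run
#' @param outDir destination directory (created if needed)
#' @return the output directory, invisibly
#' @export
writeResults <- function(result, problem, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  circ <- individualCircuit(bestIndividual(result), problem)
  writeWMatrix(wMatrix(circ), file.path(outDir, "best_W.tsv"))
  write.table(runLog(result), file.path(outDir, "log.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  st <- simulateCircuit(circ, problem$inputs, T = problem$sim$T,
                        dt = problem$sim$dt,
                        sigmoidForm = problem$sim$sigmoidForm)
  obl <- seq_len(problem$obligatory)
  writeProfileTable(problem$inputs@positions,
                    setNames(lapply(obl, function(a) st@v[a, ]),
                             problem$oblNames),
                    file.path(outDir, "final_profiles.tsv"))
  cfg <- result@config
  cfg$success <- succeeded(result)
  cfg$evaluations <- evaluationsUsed(result)
  yaml::write_yaml(.configForYaml(cfg), file.path(outDir, "config.yaml"))
  invisible(outDir)
}

.configForYaml <- function(x) {
  if (is.list(x)) lapply(x, .configForYaml)
  else if (is.numeric(x) && any(is.infinite(x)))
    ifelse(is.infinite(x), paste0(ifelse(x > 0, "", "-"), ".inf"), x)
  else x
}

#' Default run configuration
#'
#' The fully resolved, nested default configuration covering the engine,
#' model, cooption, transposon, robustness and data sections. Unknown keys in
#' a user file are rejected.
#'
#' @return nested named list
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    engine = engineConfig(),
    model = list(gridFrom = 34, gridTo = 82, gridSpacing = 1,
                 kinetics = kineticTemplate(),
                 sigmoidForm = "algebraic", T = 100, dt = NULL),
    cooption = cooptionConfig(mode = "off"),
    transposons = c(list(enabled = FALSE), teConfig()),
    robustness = list(amplitude = 0.2, nDraws = 100, mode = "embryo"),
    data = list(bcdDecayLength = 20, cadMidpoint = 60, cadSteepness = 6,
                useCad = FALSE, noise = 0,
                targets = "synthetic", profileFile = NULL))
}

#' Read and resolve a run configuration file
#'
#' YAML file whose keys must be a subset of \code{\link{defaultRunConfig}};
#' missing keys take their defaults, unknown keys are an error.
#'
#' @param path YAML file path
#' @return resolved configuration list
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  def <- defaultRunConfig()
  .mergeStrict <- function(def, user, where = "") {
    unknown <- setdiff(names(user), names(def))
    if (length(unknown))
      stop("readRunConfig: unknown key(s) ", where,
           paste(unknown, collapse = ", "))
    for (k in names(user)) {
      def[[k]] <- if (is.list(def[[k]]) && is.list(user[[k]]))
        .mergeStrict(def[[k]], user[[k]], paste0(where, k, "$"))
      else user[[k]]
    }
    def
  }
  .mergeStrict(def, user)
}
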