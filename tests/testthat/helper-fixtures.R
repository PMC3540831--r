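# shared desk-scale fixtures, all generated in code

gridEL <- spatialGrid()                       # 34..82 %EL, 49 nuclei
inpBcd <- maternalInputs(gridEL, makeBcd(gridEL))
teacher <- defaultTeacherCircuit()
teacherTg <- teacherTargets(teacher, inpBcd)

# recovery problem: kinetics fixed at the teacher's own values
recoveryProblem <- function()
  evolutionProblem(inpBcd, teacherTg, kinetics = kineticTemplate(h = teacher@h))

# bare individual for operator-level tests
mkInd <- function(W, marks = NULL) {
  W <- as.matrix(W)
  list(W = W,
       marks = if (is.null(marks)) matrix(0L, nrow(W), ncol(W))
               else as.matrix(marks),
       E = NA_real_, maxTE = NA_integer_)
}

# 2-gene circuit whose obligatory genes ignore Bcd (zero maternal column)
bcdBlindCircuit <- function() {
  W <- matrix(0, 2, 3)
  W[, 2:3] <- c(1, 0.5, -0.5, 1)
  geneCircuit(W, geneNames = c("Kr", "kni"))
}
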