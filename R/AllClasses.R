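#' @import methods
NULL

#' The six canonical RNA base-pair types
#'
#' Ordered pair codes used throughout the package to index stack and triplet
#' tables: Watson-Crick AU, UA, GC, CG and wobble GU, UG.  A pair type is
#' read 5' to 3' on the strand carrying the first nucleotide, i.e. the pair
#' (i, j) with s[i] = G, s[j] = C has type \code{"GC"}.
#'
#' @return Character vector of the six pair codes, in table order.
#' @examples
#' pairTypes()
#' @export
pairTypes <- function() c("AU", "UA", "GC", "CG", "GU", "UG")

## reversal (read the duplex from the opposite strand): AU<->UA, GC<->CG, GU<->UG
.PAIR_REV <- c(AU = "UA", UA = "AU", GC = "CG", CG = "GC", GU = "UG", UG = "GU")

#' Energy parameter bundle for the nearest-neighbor model
#'
#' Holds a Turner-style parameter set: the 6x6 base-stack free energies and
#' enthalpies, loop initiation tables for hairpins, bulges and internal loops
#' (sizes 1..30, \code{NA} where a size is not realizable), the affine
#' multiloop coefficients, the terminal non-GC (AU/GU closing pair) penalty
#' and optional tetraloop bonus tables.  All free energies are kcal/mol at
#' the reference temperature 310.15 K; enthalpies are kcal/mol.
#'
#' @slot name parameter-set name, e.g. \code{"turner1999"}
#' @slot stackDG,stackDH 6x6 matrices indexed (outer pair, inner pair) in
#'   \code{pairTypes()} order; outer pair (i,j), inner pair (i+1,j-1)
#' @slot hairpinDG,hairpinDH,bulgeDG,bulgeDH,internalDG,internalDH
#'   length-30 vectors indexed by loop size
#' @slot multiloop named vector \code{a,b,c,a_dH,b_dH,c_dH}: closing penalty,
#'   per-branch cost (the closing pair counts as a branch) and
#'   per-unpaired-base cost
#' @slot terminalNonGC named vector \code{dG37,dH}
#' @slot lxc Jacobson-Stockmayer coefficient for loop sizes beyond 30
#' @slot tetraloopDG,tetraloopDH named vectors keyed by the 6-mer
#'   closing-pair-plus-loop sequence
#' @export
setClass("EnergyParams",
  representation(
    name = "character",
    stackDG = "matrix", stackDH = "matrix",
    hairpinDG = "numeric", hairpinDH = "numeric",
    bulgeDG = "numeric", bulgeDH = "numeric",
    internalDG = "numeric", internalDH = "numeric",
    multiloop = "numeric",
    terminalNonGC = "numeric",
    lxc = "numeric",
    tetraloopDG = "numeric", tetraloopDH = "numeric"
  )
)

setValidity("EnergyParams", function(object) {
  msg <- character()
  for (nm in c("stackDG", "stackDH")) {
    m <- slot(object, nm)
    if (!all(dim(m) == c(6L, 6L))) msg <- c(msg, paste(nm, "must be 6x6"))
    else if (any(!is.finite(m))) msg <- c(msg, paste(nm, "has non-finite cells"))
  }
  for (nm in c("hairpinDG", "bulgeDG", "internalDG"))
    if (length(slot(object, nm)) != 30L)
      msg <- c(msg, paste(nm, "must cover loop sizes 1..30"))
  if (any(is.na(slot(object, "hairpinDG")[3:30])))
    msg <- c(msg, "hairpin energies must be defined for sizes 3..30")
  if (any(is.na(slot(object, "bulgeDG"))))
    msg <- c(msg, "bulge energies must be defined for sizes 1..30")
  if (any(is.na(slot(object, "internalDG")[2:30])))
    msg <- c(msg, "internal-loop energies must be defined for sizes 2..30")
  if (!all(c("a", "b", "c", "a_dH", "b_dH", "c_dH") %in% names(object@multiloop)))
    msg <- c(msg, "multiloop must name a, b, c and their enthalpies")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EnergyParams", function(object) {
  cat("EnergyParams '", object@name, "'\n", sep = "")
  cat("  stack dG37 range: [", min(object@stackDG), ", ", max(object@stackDG),
      "] kcal/mol\n", sep = "")
  ml <- object@multiloop
  cat(sprintf("  multiloop a=%.2f b=%.2f c=%.2f; terminal non-GC %.2f kcal/mol\n",
              ml["a"], ml["b"], ml["c"], object@terminalNonGC["dG37"]))
  cat("  tetraloop bonuses:", length(object@tetraloopDG), "entries\n")
})

#' Triplet stacking free-energy table
#'
#' The 6x6x6 table of extended nearest-neighbor energies, indexed
#' (outer, middle, inner) pair type, inferred from a stack table by the
#' maximum-entropy procedure (see \code{\link{inferTripletTable}}).
#'
#' @slot dG 6x6x6 array, kcal/mol at \code{temperature}
#' @slot temperature Kelvin at which the table was derived
#' @slot calibration additive-constant mode used
#'   (\code{"mean_avg_stacks"} or \code{"none"})
#' @slot source name of the stack-parameter set
#' @export
setClass("TripletTable",
  representation(dG = "array", temperature = "numeric",
                 calibration = "character", source = "character")
)

setValidity("TripletTable", function(object) {
  if (!all(dim(object@dG) == c(6L, 6L, 6L))) return("dG must be 6x6x6")
  if (any(!is.finite(object@dG))) return("all 216 cells must be finite")
  TRUE
})

setMethod("show", "TripletTable", function(object) {
  cat(sprintf("TripletTable (%s, %.2f K, calibration '%s')\n",
              object@source, object@temperature, object@calibration))
  cat(sprintf("  dG range [%.3f, %.3f] kcal/mol, mean %.3f\n",
              min(object@dG), max(object@dG), mean(object@dG)))
})

#' Model configuration
#'
#' Collects the knobs shared by the folding, ensemble and inference code.
#'
#' @slot model \code{"nn"} (nearest-neighbor stacks) or \code{"enn"}
#'   (extended nearest-neighbor triplets)
#' @slot theta minimum number of unpaired bases in a hairpin loop
#' @slot maxInternal largest internal-loop/bulge size enumerated by the DP
#' @slot temperature Kelvin
#' @slot gasConstant kcal/(mol K)
#' @slot calibration triplet additive-constant mode
#' @slot useTerminalNonGC apply the AU/GU helix-end closing penalty
#' @slot useTetraloop apply sequence-specific tetraloop bonuses
#' @slot reinferTriplets re-derive the triplet table at each working
#'   temperature (otherwise the 310.15 K table is reused unchanged)
#' @slot seed integer seed for stochastic operations (NA = leave RNG alone)
#' @export
setClass("ModelConfig",
  representation(
    model = "character", theta = "integer", maxInternal = "integer",
    temperature = "numeric", gasConstant = "numeric",
    calibration = "character", useTerminalNonGC = "logical",
    useTetraloop = "logical", reinferTriplets = "logical", seed = "integer"
  )
)

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (!object@model %in% c("nn", "enn")) msg <- c(msg, "model must be 'nn' or 'enn'")
  if (object@theta < 0L) msg <- c(msg, "theta must be >= 0")
  if (object@maxInternal < 2L) msg <- c(msg, "maxInternal must be >= 2")
  if (object@temperature <= 0) msg <- c(msg, "temperature must be positive (Kelvin)")
  if (!object@calibration %in% c("avg_stacks", "mean_avg_stacks", "none"))
    msg <- c(msg, "calibration must be 'avg_stacks', 'mean_avg_stacks' or 'none'")
  if (length(msg)) msg else TRUE
})

#' Create a model configuration
#'
#' @param model energy model, \code{"nn"} or \code{"enn"}
#' @param theta minimum unpaired bases in a hairpin (steric default 3)
#' @param maxInternal internal-loop size cap in the DP (Vienna convention, 30)
#' @param temperature working temperature in Kelvin (310.15 = 37 C)
#' @param gasConstant kcal/(mol K)
#' @param calibration additive-constant mode for triplet inference
#' @param useTerminalNonGC apply the terminal AU/GU closing penalty
#' @param useTetraloop apply tetraloop bonus tables
#' @param reinferTriplets re-infer the triplet table at each temperature
#' @param seed integer seed for stochastic operations
#' @return A \linkS4class{ModelConfig} object.
#' @examples
#' modelConfig("enn", temperature = 310.15)
#' @export
modelConfig <- function(model = c("nn", "enn"), theta = 3L, maxInternal = 30L,
                        temperature = 310.15, gasConstant = 0.0019872,
                        calibration = c("avg_stacks", "mean_avg_stacks", "none"),
                        useTerminalNonGC = TRUE, useTetraloop = FALSE,
                        reinferTriplets = TRUE, seed = NA_integer_) {
  new("ModelConfig", model = match.arg(model), theta = as.integer(theta),
      maxInternal = as.integer(maxInternal), temperature = temperature,
      gasConstant = gasConstant, calibration = match.arg(calibration),
      useTerminalNonGC = useTerminalNonGC, useTetraloop = useTetraloop,
      reinferTriplets = reinferTriplets, seed = as.integer(seed))
}

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf("ModelConfig: model=%s T=%.2fK theta=%d maxInternal=%d\n",
              object@model, object@temperature, object@theta, object@maxInternal))
  cat(sprintf("  calibration=%s terminalNonGC=%s tetraloop=%s reinferTriplets=%s\n",
              object@calibration, object@useTerminalNonGC, object@useTetraloop,
              object@reinferTriplets))
})

#' RNA secondary structure
#'
#' A pseudoknot-free set of canonical base pairs on a concrete sequence.
#' Pairs are stored as a two-column integer matrix (i, j), 1-based, i < j,
#' sorted by i.  Validity enforces: canonical pairing partners, each base in
#' at most one pair, and no crossing pairs.
#'
#' @slot seq the RNA sequence (A/C/G/U)
#' @slot pairs integer matrix with columns i, j
#' @export
setClass("SecondaryStructure",
  representation(seq = "character", pairs = "matrix")
)

setValidity("SecondaryStructure", function(object) {
  n <- nchar(object@seq)
  p <- object@pairs
  if (ncol(p) != 2L) return("pairs must have two columns (i, j)")
  if (nrow(p) == 0L) return(TRUE)
  if (any(p < 1L | p > n)) return("pair index out of range")
  if (any(p[, 1] >= p[, 2])) return("pairs must satisfy i < j")
  if (anyDuplicated(as.vector(p))) return("a base takes part in two pairs")
  s <- strsplit(object@seq, "")[[1]]
  tp <- .pairTypeCode(s[p[, 1]], s[p[, 2]])
  if (any(is.na(tp))) {
    bad <- which(is.na(tp))[1]
    return(sprintf("non-canonical pair (%d, %d): %s-%s", p[bad, 1], p[bad, 2],
                   s[p[bad, 1]], s[p[bad, 2]]))
  }
  ## crossing check: sort by i, every open pair must nest
  o <- order(p[, 1])
  p <- p[o, , drop = FALSE]
  for (r in seq_len(nrow(p) - 1L)) {
    later <- p[(r + 1L):nrow(p), , drop = FALSE]
    inside <- later[, 1] < p[r, 2]
    if (any(inside & later[, 2] > p[r, 2]))
      return(sprintf("pseudoknot: pair (%d, %d) crosses another pair",
                     p[r, 1], p[r, 2]))
  }
  TRUE
})

setMethod("show", "SecondaryStructure", function(object) {
  n <- nchar(object@seq)
  cat(sprintf("SecondaryStructure: %d nt, %d base pairs\n", n, nrow(object@pairs)))
  if (n <= 120) {
    cat(" ", object@seq, "\n")
    cat(" ", dotBracket(object), "\n")
  }
})

#' Filled dynamic-programming arrays
#'
#' The constrained folding arrays on all subintervals, in one of two
#' semirings: \code{"min-plus"} entries are minimum free energies (kcal/mol),
#' \code{"sum-product"} entries are natural logarithms of the restricted
#' partition functions.  Upper-triangular matrices; impossible cells are
#' +Inf (min-plus) or -Inf (log scale).
#'
#' @slot seq the folded sequence
#' @slot semiring \code{"min-plus"} or \code{"sum-product"}
#' @slot arrays named list: Z, Zb, Zbb, Zbl, Zbr, Zm, Zm1 (plus the helper
#'   Znt, the non-triplet-continuation part of Zb)
#' @slot config the \linkS4class{ModelConfig} used
#' @slot tables internal energy tables handed to the compiled engine
#' @export
setClass("FoldArrays",
  representation(seq = "character", semiring = "character",
                 arrays = "list", config = "ModelConfig", tables = "list")
)

setMethod("show", "FoldArrays", function(object) {
  cat(sprintf("FoldArrays (%s): %d nt, model %s\n", object@semiring,
              nchar(object@seq), object@config@model))
})

#' Folding result
#'
#' @slot model \code{"nn"} or \code{"enn"}
#' @slot energy minimum free energy (kcal/mol) in MFE mode
#' @slot logZ natural log of the partition function (NA in MFE mode)
#' @slot structure the MFE \linkS4class{SecondaryStructure} (or NULL)
#' @slot config the \linkS4class{ModelConfig} used
#' @export
setClass("FoldResult",
  representation(model = "character", energy = "numeric", logZ = "numeric",
                 structure = "ANY", config = "ModelConfig")
)

setMethod("show", "FoldResult", function(object) {
  cat(sprintf("FoldResult (%s model)\n", object@model))
  if (!is.na(object@energy))
    cat(sprintf("  MFE: %.2f kcal/mol\n", object@energy))
  if (!is.na(object@logZ)) {
    RT <- object@config@gasConstant * object@config@temperature
    cat(sprintf("  log Z: %.4f   ensemble free energy: %.2f kcal/mol\n",
                object@logZ, -RT * object@logZ))
  }
  if (is(object@structure, "SecondaryStructure")) show(object@structure)
})

#' Base-pair probability matrix
#'
#' Sparse map of (i, j) base-pair probabilities for one sequence, either
#' estimated from stochastic traceback samples or computed exactly by
#' structure enumeration (small sequences).
#'
#' @slot n sequence length
#' @slot prob data.frame with columns i, j, p
#' @slot method \code{"sample"} or \code{"exact_small"}
#' @export
setClass("BasePairProb",
  representation(n = "integer", prob = "data.frame", method = "character")
)

setValidity("BasePairProb", function(object) {
  pr <- object@prob
  if (!all(c("i", "j", "p") %in% names(pr))) return("prob needs columns i, j, p")
  if (nrow(pr) && (any(pr$p < -1e-12) || any(pr$p > 1 + 1e-12)))
    return("probabilities must lie in [0, 1]")
  TRUE
})

setMethod("show", "BasePairProb", function(object) {
  cat(sprintf("BasePairProb (%s): %d nt, %d pairs with p > 0, sum %.3f\n",
              object@method, object@n, nrow(object@prob), sum(object@prob$p)))
})
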