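## R-side folding interface over the compiled engine.

.tripletCache <- new.env(parent = emptyenv())

## triplet table for a parameter bundle at the configured temperature,
## memoized (the IPF inference is deterministic)
.tripletFor <- function(params, config) {
  key <- paste(params@name, format(config@temperature, digits = 12),
               config@calibration,
               paste(format(params@stackDG, digits = 12), collapse = ","),
               sep = "|")
  hit <- .tripletCache[[key]]
  if (!is.null(hit)) return(hit)
  tt <- inferTripletTable(params, config)
  assign(key, tt, envir = .tripletCache)
  tt
}

## assemble the numeric tables handed to the compiled engine, all at the
## configured temperature; n is the sequence length (loop tables must reach it)
.modelTables <- function(n, params, config, triplet = NULL, zeroEnergies = FALSE) {
  T <- config@temperature
  if (zeroEnergies) {
    return(list(
      stack = matrix(0, 6, 6), junction = array(0, c(6, 6, 6)),
      tau = rep(0, 6), hairpin = rep(0, n), bulge = rep(0, n),
      internal = rep(0, n), mlA = 0, mlB = 0, mlC = 0,
      RT = config@gasConstant * T, theta = config@theta,
      maxInternal = as.integer(n)
    ))
  }
  stackT <- rescaleToTemperature(params@stackDG, params@stackDH, T)
  if (config@model == "enn") {
    if (is.null(triplet)) triplet <- .tripletFor(params, config)
    junction <- triplet@dG
  } else {
    junction <- array(rep(stackT, 6), c(6, 6, 6))
  }
  tl <- list(
    stack = unname(stackT),
    junction = unname(junction),
    tau = .terminalTau(params, config),
    hairpin = .loopVector(params@hairpinDG, params@hairpinDH, T, n, params@lxc),
    bulge = .loopVector(params@bulgeDG, params@bulgeDH, T, n, params@lxc),
    internal = .loopVector(params@internalDG, params@internalDH, T, n, params@lxc),
    mlA = rescaleToTemperature(params@multiloop[["a"]], params@multiloop[["a_dH"]], T),
    mlB = rescaleToTemperature(params@multiloop[["b"]], params@multiloop[["b_dH"]], T),
    mlC = rescaleToTemperature(params@multiloop[["c"]], params@multiloop[["c_dH"]], T),
    RT = config@gasConstant * T,
    theta = config@theta,
    maxInternal = config@maxInternal
  )
  if (config@useTetraloop && length(params@tetraloopDG)) {
    keys <- names(params@tetraloopDG)
    codes <- vapply(keys, function(k) {
      v <- match(strsplit(k, "")[[1]], .BASES) - 1L
      sum(v * 4L^(5:0))
    }, integer(1))
    tl$tetraCodes <- unname(codes)
    tl$tetraE <- unname(rescaleToTemperature(params@tetraloopDG,
                                             params@tetraloopDH, T))
  }
  tl
}

.resolveInputs <- function(seq, params, config) {
  seq <- normalizeSequence(seq)
  params <- loadParameters(params)
  list(seq = seq, iseq = .encodeSeq(seq), params = params, config = config)
}

#' Fill the constrained folding arrays
#'
#' Runs the dynamic-programming fill over all subintervals in the requested
#' semiring.  In \code{"min-plus"} mode entries are minimum free energies
#' (kcal/mol, +Inf for impossible cells); in \code{"sum-product"} mode
#' entries are natural logs of the restricted partition functions (-Inf for
#' empty cells), which keeps sequences of several hundred nucleotides free
#' of overflow.
#'
#' @param seq RNA sequence
#' @param params an \linkS4class{EnergyParams} or parameter-set name
#' @param config a \linkS4class{ModelConfig}
#' @param semiring \code{"sum-product"} or \code{"min-plus"}
#' @return A \linkS4class{FoldArrays} object.
#' @examples
#' fa <- fillFoldArrays("GGGAAACCC", "turner99", modelConfig("nn"))
#' exp(fa@arrays$Z[1, 9])  # partition function
#' @export
fillFoldArrays <- function(seq, params = "turner99", config = modelConfig(),
                           semiring = c("sum-product", "min-plus")) {
  semiring <- match.arg(semiring)
  inp <- .resolveInputs(seq, params, config)
  tl <- .modelTables(nchar(inp$seq), inp$params, config)
  arrays <- .cpp_fill(inp$iseq, tl, semiring)
  new("FoldArrays", seq = inp$seq, semiring = semiring, arrays = arrays,
      config = config, tables = tl)
}

#' Minimum free energy structure
#'
#' Fills the min-plus arrays and traces back one optimal structure under the
#' deterministic tie-break order (hairpin, triplet extension, size-1 bulges,
#' stem-end stack, internal loops by size, multiloop; leftmost first).
#'
#' @param seq RNA sequence
#' @param params an \linkS4class{EnergyParams} or parameter-set name
#' @param config a \linkS4class{ModelConfig}; \code{config@model} selects
#'   the NN or ENN energy model
#' @return A \linkS4class{FoldResult} with the structure and its energy.
#' @examples
#' fr <- mfeFold("GGGGAAAACCCC", "turner99", modelConfig("nn"))
#' dotBracket(fr)
#' @export
mfeFold <- function(seq, params = "turner99", config = modelConfig()) {
  inp <- .resolveInputs(seq, params, config)
  tl <- .modelTables(nchar(inp$seq), inp$params, config)
  res <- .cpp_mfe(inp$iseq, tl, FALSE)
  struct <- secondaryStructure(inp$seq, pairs = res$pairs, theta = config@theta)
  new("FoldResult", model = config@model, energy = res$energy,
      logZ = NA_real_, structure = struct, config = config)
}

#' Partition function
#'
#' Boltzmann sum over all secondary structures, from the sum-product fill.
#'
#' @inheritParams mfeFold
#' @return list with \code{logZ} (natural log), \code{Z} (NA when it would
#'   overflow a double) and \code{ensembleFreeEnergy} = -RT log Z (kcal/mol).
#' @examples
#' partitionFunction("GGGAAACCC", "turner99", modelConfig("nn"))$logZ
#' @export
partitionFunction <- function(seq, params = "turner99", config = modelConfig()) {
  fa <- fillFoldArrays(seq, params, config, "sum-product")
  n <- nchar(fa@seq)
  logZ <- fa@arrays$Z[1, n]
  RT <- config@gasConstant * config@temperature
  list(logZ = logZ,
       Z = if (logZ < log(.Machine$double.xmax)) exp(logZ) else NA_real_,
       ensembleFreeEnergy = -RT * logZ)
}

#' Count secondary structures exactly
#'
#' Runs the folding engine with every free energy set to zero in the
#' counting semiring, so the "partition function" is the exact number of
#' secondary structures (canonical pairs, no sharing, no crossing, hairpins
#' of at least \code{theta} unpaired bases).  Counts are exact as long as
#' they fit an IEEE double (up to 2^53).
#'
#' @param seq RNA sequence
#' @param theta minimum unpaired bases in a hairpin
#' @return the structure count as a double.
#' @examples
#' countStructures("GGAAACC")  # 6
#' @export
countStructures <- function(seq, theta = 3L) {
  seq <- normalizeSequence(seq)
  n <- nchar(seq)
  cfg <- modelConfig(theta = as.integer(theta), temperature = 310.15)
  tl <- .modelTables(n, NULL, cfg, zeroEnergies = TRUE)
  arrays <- .cpp_fill(.encodeSeq(seq), tl, "count")
  cnt <- arrays$Z[1, n]
  if (cnt >= 2^53) warning("structure count exceeds exact double range")
  cnt
}
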