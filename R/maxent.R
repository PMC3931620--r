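## Inference of triplet stacking free energies from a stack table:
## Boltzmann conversion, marginalization, maximum-entropy iterative
## proportional fitting, and inverse-Boltzmann calibration.

.tripletDimnames <- function() list(outer = pairTypes(), middle = pairTypes(),
                                    inner = pairTypes())

## sum of the two constituent stacks for every (outer, middle, inner) triple
.stackSums <- function(stacks) {
  out <- array(0, dim = c(6, 6, 6), dimnames = .tripletDimnames())
  for (z in 1:6) out[, , z] <- stacks + matrix(stacks[, z], 6, 6, byrow = TRUE)
  out
}

#' Boltzmann joint distribution over triplet stacks
#'
#' A triplet stack (outer x, middle y, inner z) is assigned probability
#' proportional to exp(-(stack(x,y) + stack(y,z)) / RT): motif frequencies in
#' a representative ensemble are Boltzmann distributed in the motif energy.
#'
#' @param stacks 6x6 stack free-energy matrix (kcal/mol), pair order
#'   \code{pairTypes()}
#' @param RT gas constant times temperature (kcal/mol)
#' @return 6x6x6 probability array summing to one.
#' @examples
#' j <- boltzmannJointFromStacks(matrix(0, 6, 6), RT = 0.61)
#' all.equal(max(j), 1 / 216)
#' @export
boltzmannJointFromStacks <- function(stacks, RT) {
  stopifnot(RT > 0, all(dim(stacks) == c(6, 6)), all(is.finite(stacks)))
  w <- exp(-.stackSums(stacks) / RT)
  w / sum(w)
}

#' Positional marginals of a triplet joint distribution
#'
#' @param joint 6x6x6 probability array over (outer, middle, inner)
#' @return list with 6x6 matrices \code{left} (over middle, inner; outer
#'   summed out), \code{middle} (over outer, inner) and \code{right}
#'   (over outer, middle).
#' @export
marginalsOf <- function(joint) {
  stopifnot(all(dim(joint) == c(6, 6, 6)))
  list(left = apply(joint, c(2, 3), sum),
       middle = apply(joint, c(1, 3), sum),
       right = apply(joint, c(1, 2), sum))
}

#' Maximum-entropy joint distribution by iterative proportional fitting
#'
#' Starting from the uniform distribution, repeatedly rescales the joint so
#' that it reproduces, in turn, the left, middle and right target marginals,
#' until every marginal cell agrees within \code{epsilon}.  The fixed point
#' is the maximum-entropy distribution consistent with the targets.
#'
#' @param targets list with matrices \code{left}, \code{middle},
#'   \code{right} as returned by \code{\link{marginalsOf}}; each must sum
#'   to one and the three must be mutually consistent
#' @param epsilon convergence tolerance, L-infinity over all marginal cells
#' @param maxCycles iteration cap
#' @return the fitted 6x6x6 joint, with attributes \code{cycles} and
#'   \code{residual}.
#' @examples
#' tg <- marginalsOf(boltzmannJointFromStacks(matrix(0, 6, 6), 0.61))
#' fit <- ipfMaxent(tg)
#' @export
ipfMaxent <- function(targets, epsilon = 1e-9, maxCycles = 100000L) {
  stopifnot(epsilon > 0, maxCycles >= 1)
  for (nm in c("left", "middle", "right")) {
    m <- targets[[nm]]
    if (is.null(m) || !all(dim(m) == c(6, 6)))
      stop("targets$", nm, " must be a 6x6 matrix")
    if (any(m < 0)) stop("targets$", nm, " has negative cells")
    if (abs(sum(m) - 1) > 1e-8)
      stop("targets$", nm, " must sum to 1 (got ", format(sum(m)), ")")
  }
  p <- array(1 / 216, dim = c(6, 6, 6), dimnames = .tripletDimnames())
  safeRatio <- function(target, current) {
    r <- target / current
    r[target == 0] <- 0
    r
  }
  residual <- Inf
  for (cycle in seq_len(maxCycles)) {
    cur <- apply(p, c(2, 3), sum)
    p <- p * rep(safeRatio(targets$left, cur), each = 6)
    cur <- apply(p, c(1, 3), sum)
    p <- p * aperm(array(safeRatio(targets$middle, cur), c(6, 6, 6)), c(1, 3, 2))
    cur <- apply(p, c(1, 2), sum)
    p <- p * array(safeRatio(targets$right, cur), c(6, 6, 6))
    m <- marginalsOf(p)
    residual <- max(abs(m$left - targets$left), abs(m$middle - targets$middle),
                    abs(m$right - targets$right))
    if (residual <= epsilon) {
      p <- p / sum(p)
      attr(p, "cycles") <- cycle
      attr(p, "residual") <- residual
      return(p)
    }
  }
  stop(sprintf("IPF did not converge within %d cycles (residual %.3g > %.3g)",
               maxCycles, residual, epsilon))
}

#' Convert a joint distribution back to triplet free energies
#'
#' Inverse Boltzmann with a configurable calibration.  Raw energies
#' -RT log p are always positive for a normalized distribution, so a
#' calibration maps them onto the stacking free-energy scale:
#' \describe{
#'   \item{\code{"avg_stacks"} (default)}{half-RT inverse Boltzmann,
#'     -RT/2 log p, shifted so the table mean equals the mean of
#'     (stack(x,y) + stack(y,z)) / 2 over all 216 triples.  Consecutive
#'     triplet windows along a helix overlap in one stack, so each interior
#'     stack is covered by two windows; the factor 1/2 corrects that double
#'     counting and anchors the triplet energy to the average of its two
#'     constituent stacks.}
#'   \item{\code{"mean_avg_stacks"}}{-RT log p with a single additive shift
#'     so the table mean equals the mean stack average.  Each window then
#'     carries the full sum of its two stacks (strong windows become
#'     stronger, weak windows weaker than under the NN model): a markedly
#'     more cooperative, but also more distorted, energy surface.}
#'   \item{\code{"none"}}{-RT log p unshifted.}
#' }
#'
#' @param joint 6x6x6 probability array
#' @param RT kcal/mol
#' @param stacks 6x6 stack matrix used for calibration
#' @param calibration calibration mode, see Details
#' @param floorProb optional small probability substituted for empty cells;
#'   by default a zero cell is an error (infinite energy)
#' @return 6x6x6 array of triplet free energies (kcal/mol).
#' @export
energiesFromDistribution <- function(joint, RT, stacks,
                                     calibration = c("avg_stacks",
                                                     "mean_avg_stacks", "none"),
                                     floorProb = NULL) {
  calibration <- match.arg(calibration)
  stopifnot(RT > 0, all(dim(joint) == c(6, 6, 6)))
  if (any(joint <= 0)) {
    if (is.null(floorProb))
      stop("joint distribution has a zero cell: infinite energy ",
           "(set floorProb to floor instead)")
    joint <- pmax(joint, floorProb)
    joint <- joint / sum(joint)
  }
  raw <- -RT * log(joint)
  out <- switch(calibration,
    avg_stacks = {
      half <- raw / 2
      half + (mean(.stackSums(stacks) / 2) - mean(half))
    },
    mean_avg_stacks = raw + (mean(.stackSums(stacks) / 2) - mean(raw)),
    none = raw)
  dimnames(out) <- .tripletDimnames()
  out
}

#' Infer the triplet stacking table from a stack table
#'
#' End-to-end pipeline: rescale the stack table to the working temperature,
#' convert to a Boltzmann joint over triplet stacks, take its positional
#' marginals, fit the maximum-entropy joint by iterative proportional
#' fitting, and convert back to calibrated free energies.
#'
#' @param params an \linkS4class{EnergyParams} (or set name), or a bare 6x6
#'   stack matrix already at the working temperature
#' @param config a \linkS4class{ModelConfig}; sets temperature, gas
#'   constant and calibration mode
#' @param epsilon,maxCycles IPF controls
#' @return A \linkS4class{TripletTable}.
#' @examples
#' tt <- inferTripletTable("turner99", modelConfig("enn"))
#' tt
#' @export
inferTripletTable <- function(params, config = modelConfig("enn"),
                              epsilon = 1e-9, maxCycles = 100000L) {
  if (is.matrix(params)) {
    stacks <- params
    src <- "custom"
  } else {
    params <- loadParameters(params)
    stacks <- rescaleToTemperature(params@stackDG, params@stackDH,
                                   config@temperature)
    src <- params@name
  }
  RT <- config@gasConstant * config@temperature
  joint <- boltzmannJointFromStacks(stacks, RT)
  fit <- ipfMaxent(marginalsOf(joint), epsilon = epsilon, maxCycles = maxCycles)
  dG <- energiesFromDistribution(fit, RT, stacks, calibration = config@calibration)
  new("TripletTable", dG = dG, temperature = config@temperature,
      calibration = config@calibration, source = src)
}
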