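## Boltzmann-ensemble quantities: stochastic traceback sampling, base-pair
## probabilities, expected pair counts, and temperature melting curves.

#' Sample structures from the Boltzmann ensemble
#'
#' Stochastic traceback through the sum-product arrays: each structure S is
#' drawn with probability exp(-E(S)/RT) / Z under the same recursion
#' contract the arrays were filled with.
#'
#' @param arrays a \linkS4class{FoldArrays} filled in sum-product mode
#' @param m number of samples
#' @param seed integer seed (NA = leave the RNG state alone)
#' @return list of \linkS4class{SecondaryStructure} objects.
#' @examples
#' fa <- fillFoldArrays("GGGGAAAACCCC", "turner99", modelConfig("nn"))
#' samp <- sampleStructures(fa, 10, seed = 1)
#' @export
sampleStructures <- function(arrays, m, seed = NA_integer_) {
  stopifnot(is(arrays, "FoldArrays"), m >= 1)
  if (arrays@semiring != "sum-product")
    stop("sampleStructures needs sum-product arrays, got ", arrays@semiring)
  if (!is.na(seed)) set.seed(as.integer(seed))
  iseq <- .encodeSeq(arrays@seq)
  raw <- .cpp_sample(iseq, arrays@tables, arrays@arrays, as.integer(m))
  lapply(raw, function(p)
    secondaryStructure(arrays@seq, pairs = p, theta = arrays@config@theta))
}

#' Base-pair probabilities
#'
#' Either the empirical pair frequencies over \code{m} stochastic traceback
#' samples (default), or exact probabilities by weighted enumeration for
#' short sequences (\code{method = "exact_small"}, n <= 30).
#'
#' @param seq RNA sequence
#' @param params an \linkS4class{EnergyParams} or set name
#' @param config a \linkS4class{ModelConfig}
#' @param method \code{"sample"} or \code{"exact_small"}
#' @param m sample count for the sampling method
#' @param seed integer seed for the sampling method
#' @return A \linkS4class{BasePairProb}.
#' @examples
#' basePairProbabilities("GAAAC", "turner99", modelConfig("nn"),
#'                       method = "exact_small")
#' @export
basePairProbabilities <- function(seq, params = "turner99",
                                  config = modelConfig(),
                                  method = c("sample", "exact_small"),
                                  m = 10000L, seed = NA_integer_) {
  method <- match.arg(method)
  seq <- normalizeSequence(seq)
  n <- nchar(seq)
  if (method == "exact_small") {
    if (n > 30L)
      stop("exact_small enumeration is limited to sequences of at most 30 nt")
    bpp <- bruteBPP(seq, params, config, maxLen = 30L)
    return(bpp)
  }
  fa <- fillFoldArrays(seq, params, config, "sum-product")
  if (!is.na(seed)) set.seed(as.integer(seed))
  raw <- .cpp_sample(.encodeSeq(seq), fa@tables, fa@arrays, as.integer(m))
  counts <- new.env(parent = emptyenv())
  for (p in raw) {
    if (!nrow(p)) next
    for (r in seq_len(nrow(p))) {
      key <- paste0(p[r, 1], ",", p[r, 2])
      counts[[key]] <- (counts[[key]] %||% 0) + 1
    }
  }
  keys <- ls(counts)
  if (length(keys)) {
    ij <- do.call(rbind, strsplit(keys, ","))
    prob <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                       p = vapply(keys, function(k) counts[[k]], numeric(1)) / m)
    prob <- prob[order(prob$i, prob$j), ]
    rownames(prob) <- NULL
  } else {
    prob <- data.frame(i = integer(), j = integer(), p = numeric())
  }
  new("BasePairProb", n = n, prob = prob, method = "sample")
}

#' Expected number of base pairs
#'
#' Sum of all base-pair probabilities.
#'
#' @param bpp a \linkS4class{BasePairProb}
#' @return expected pair count.
#' @export
expectedBasePairs <- function(bpp) {
  stopifnot(is(bpp, "BasePairProb"))
  sum(bpp@prob$p)
}

#' Temperature melting curve
#'
#' For each temperature on the grid, every energy parameter is rescaled via
#' its enthalpy, the triplet table is re-inferred at that temperature in ENN
#' mode (unless \code{config@reinferTriplets} is FALSE, in which case the
#' 310.15 K table is reused), the sum-product arrays are filled and the
#' expected number of base pairs is estimated from \code{m} stochastic
#' traceback samples.
#'
#' @param seq RNA sequence
#' @param params an \linkS4class{EnergyParams} or set name
#' @param config a \linkS4class{ModelConfig}
#' @param tGrid temperatures in Celsius, strictly increasing
#' @param m samples per temperature
#' @param seed integer master seed (the whole curve is reproducible)
#' @return data.frame with columns \code{temperature_C},
#'   \code{expected_bp}, \code{expected_bp_per_nt}.
#' @examples
#' mc <- meltingCurve("GGGGAAAACCCC", "turner99", modelConfig("nn"),
#'                    tGrid = c(0, 50, 100), m = 200, seed = 1)
#' @export
meltingCurve <- function(seq, params = "turner99", config = modelConfig(),
                         tGrid = seq(0, 120, by = 1), m = 2000L,
                         seed = NA_integer_) {
  stopifnot(length(tGrid) >= 1, !is.unsorted(tGrid, strictly = TRUE))
  seq <- normalizeSequence(seq)
  params <- loadParameters(params)
  n <- nchar(seq)
  if (!is.na(seed)) set.seed(as.integer(seed))
  frozen <- NULL
  if (config@model == "enn" && !config@reinferTriplets) {
    cfg37 <- config; cfg37@temperature <- 310.15
    frozen <- .tripletFor(params, cfg37)
  }
  ebp <- vapply(tGrid, function(tc) {
    cfg <- config
    cfg@temperature <- tc + 273.15
    triplet <- frozen
    tl <- .modelTables(n, params, cfg, triplet = triplet)
    arrays <- .cpp_fill(.encodeSeq(seq), tl, "sum-product")
    raw <- .cpp_sample(.encodeSeq(seq), tl, arrays, as.integer(m))
    mean(vapply(raw, nrow, integer(1)))
  }, numeric(1))
  data.frame(temperature_C = tGrid, expected_bp = ebp,
             expected_bp_per_nt = ebp / n)
}
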