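## Brute-force reference implementations: exhaustive enumeration of all
## secondary structures, Boltzmann sums, optimal-energy search and exact
## pair probabilities.  Deliberately naive; guarded by a length cap.  They
## serve as the independent oracle for every claim the DP engine makes, and
## let users verify custom parameter files at small scale.

.ENUM_MAX_LEN <- 25L

## list of pair matrices for the interval [i, j] (1-based), memoized
.enumRec <- function(iseq, theta, memo, i, j) {
  if (j - i < theta + 1L) return(list(matrix(integer(), 0L, 2L)))
  key <- paste0(i, ":", j)
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  out <- .enumRec(iseq, theta, memo, i, j - 1L)              # j unpaired
  for (k in i:(j - theta - 1L)) {                            # j paired with k
    if (is.na(.PT_LOOKUP[cbind(.BASES[iseq[k] + 1L], .BASES[iseq[j] + 1L])]))
      next
    before <- .enumRec(iseq, theta, memo, i, k - 1L)
    inside <- .enumRec(iseq, theta, memo, k + 1L, j - 1L)
    for (b in before)
      for (ins in inside)
        out[[length(out) + 1L]] <- rbind(b, c(k, j), ins)
  }
  assign(key, out, envir = memo)
  out
}

#' Enumerate all secondary structures of a sequence
#'
#' Exhaustively generates every pseudoknot-free set of canonical base pairs
#' with hairpins of at least \code{theta} unpaired bases.  Intended as a
#' test oracle; refuses sequences longer than \code{maxLen}.
#'
#' @param seq RNA sequence
#' @param theta minimum hairpin size
#' @param maxLen refusal threshold for exhaustive work
#' @return list of two-column pair matrices (the empty structure included).
#' @examples
#' length(enumerateStructures("GGAAACC"))  # 6
#' @export
enumerateStructures <- function(seq, theta = 3L, maxLen = .ENUM_MAX_LEN) {
  seq <- normalizeSequence(seq)
  n <- nchar(seq)
  if (n > maxLen)
    stop("enumerateStructures: sequence longer than maxLen = ", maxLen)
  iseq <- .encodeSeq(seq)
  memo <- new.env(parent = emptyenv())
  structs <- .enumRec(iseq, as.integer(theta), memo, 1L, n)
  lapply(structs, function(p) {
    if (nrow(p)) p[order(p[, 1]), , drop = FALSE] else p
  })
}

#' Independent structure count by the classical recursion
#'
#' Counts secondary structures via C(i,j) = C(i,j-1) + sum over canonical
#' partners k of j of C(i,k-1) * C(k+1,j-1) - a second, independent counting
#' route used to cross-check both the enumeration and the zero-energy DP.
#'
#' @inheritParams enumerateStructures
#' @return the count as a double.
#' @export
countStructuresRecursion <- function(seq, theta = 3L) {
  seq <- normalizeSequence(seq)
  n <- nchar(seq)
  iseq <- .encodeSeq(seq)
  memo <- new.env(parent = emptyenv())
  cnt <- function(i, j) {
    if (j - i < theta + 1L) return(1)
    key <- paste0(i, ":", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    v <- cnt(i, j - 1L)
    for (k in i:(j - theta - 1L)) {
      if (is.na(.PT_LOOKUP[cbind(.BASES[iseq[k] + 1L], .BASES[iseq[j] + 1L])]))
        next
      v <- v + cnt(i, k - 1L) * cnt(k + 1L, j - 1L)
    }
    assign(key, v, envir = memo)
    v
  }
  cnt(1L, n)
}

## shared enumeration + per-structure energies
.bruteEnsemble <- function(seq, params, config, maxLen = .ENUM_MAX_LEN) {
  seq <- normalizeSequence(seq)
  params <- loadParameters(params)
  structs <- enumerateStructures(seq, theta = config@theta, maxLen = maxLen)
  iseq <- .encodeSeq(seq)
  tl <- .modelTables(length(iseq), params, config)
  energies <- vapply(structs, .evalEnergyTables, numeric(1),
                     iseq = iseq, tl = tl, model = config@model)
  list(seq = seq, structs = structs, energies = energies,
       RT = config@gasConstant * config@temperature)
}

#' Brute-force folding oracles
#'
#' \code{bruteMFE} returns the minimum of \code{\link{evaluateEnergy}} over
#' every enumerated structure (with one argmin structure);
#' \code{brutePartition} the exact Boltzmann sum; \code{bruteBPP} exact
#' base-pair probabilities by weighted enumeration.
#'
#' @param seq RNA sequence (length-capped)
#' @param params an \linkS4class{EnergyParams} or set name
#' @param config a \linkS4class{ModelConfig}
#' @param maxLen enumeration length cap
#' @return \code{bruteMFE}: list(energy, structure); \code{brutePartition}:
#'   list(Z, logZ); \code{bruteBPP}: a \linkS4class{BasePairProb}.
#' @examples
#' bruteMFE("GGGGAAAACCCC", "turner99", modelConfig("nn"))$energy
#' @export
bruteMFE <- function(seq, params = "turner99", config = modelConfig(),
                     maxLen = .ENUM_MAX_LEN) {
  be <- .bruteEnsemble(seq, params, config, maxLen)
  best <- which.min(be$energies)
  list(energy = be$energies[best],
       structure = secondaryStructure(be$seq, pairs = be$structs[[best]],
                                      theta = config@theta))
}

#' @rdname bruteMFE
#' @export
brutePartition <- function(seq, params = "turner99", config = modelConfig(),
                           maxLen = .ENUM_MAX_LEN) {
  be <- .bruteEnsemble(seq, params, config, maxLen)
  ## stable log-sum-exp
  s <- -be$energies / be$RT
  m <- max(s)
  logZ <- m + log(sum(exp(s - m)))
  list(Z = exp(logZ), logZ = logZ)
}

#' @rdname bruteMFE
#' @export
bruteBPP <- function(seq, params = "turner99", config = modelConfig(),
                     maxLen = .ENUM_MAX_LEN) {
  be <- .bruteEnsemble(seq, params, config, maxLen)
  s <- -be$energies / be$RT
  wts <- exp(s - max(s))
  wts <- wts / sum(wts)
  acc <- new.env(parent = emptyenv())
  for (idx in seq_along(be$structs)) {
    p <- be$structs[[idx]]
    if (!nrow(p)) next
    for (r in seq_len(nrow(p))) {
      key <- paste0(p[r, 1], ",", p[r, 2])
      acc[[key]] <- (acc[[key]] %||% 0) + wts[idx]
    }
  }
  keys <- ls(acc)
  if (length(keys)) {
    ij <- do.call(rbind, strsplit(keys, ","))
    prob <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                       p = vapply(keys, function(k) acc[[k]], numeric(1)))
    prob <- prob[order(prob$i, prob$j), ]
    rownames(prob) <- NULL
  } else {
    prob <- data.frame(i = integer(), j = integer(), p = numeric())
  }
  new("BasePairProb", n = nchar(be$seq), prob = prob, method = "exact_small")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
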