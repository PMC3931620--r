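## Reference (whole-structure) energy evaluator.  Implements the same loop
## decomposition and helix contract as the compiled DP fill, but by direct
## decomposition of a given structure; the two are cross-checked against
## each other in the test suite via exhaustive enumeration.

## pairs: integer matrix; iseq: 0-based codes; tl: tables from .modelTables;
## model: "nn" or "enn".  Returns energy in kcal/mol.
.evalEnergyTables <- function(pairs, iseq, tl, model) {
  n <- length(iseq)
  np <- nrow(pairs)
  pt <- function(i, j) .PT_LOOKUP[cbind(.BASES[iseq[i] + 1L], .BASES[iseq[j] + 1L])]
  if (np == 0L) return(0)
  tree <- .structureTree(pairs)
  tau <- tl$tau
  e <- 0
  ## exterior: penalty on the outer end of every external helix
  for (r in tree$top) e <- e + tau[pt(pairs[r, 1], pairs[r, 2])]
  ## pairedWith lookup for O(1) adjacency queries
  partner <- integer(n)
  partner[pairs[, 1]] <- pairs[, 2]
  partner[pairs[, 2]] <- pairs[, 1]
  hairpinE <- function(i, j) {
    size <- j - i - 1L
    he <- tl$hairpin[size] + tau[pt(i, j)]
    if (!is.null(tl$tetraCodes) && size == 4L) {
      code <- sum(iseq[i:j] * 4L^(5:0))
      hit <- match(code, tl$tetraCodes)
      if (!is.na(hit)) he <- he + tl$tetraE[hit]
    }
    he
  }
  for (r in seq_len(np)) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    kids <- tree$kids[[r]]
    if (length(kids) == 0L) {           # hairpin
      e <- e + hairpinE(i, j)
    } else if (length(kids) == 1L) {    # stacked pair, bulge, or internal loop
      k <- pairs[kids, 1]; l <- pairs[kids, 2]
      n1 <- k - i - 1L; n2 <- j - l - 1L
      if (n1 == 0L && n2 == 0L) {
        ## direct stack: triplet window if the inner pair stacks directly
        ## onward (ENN), NN stack if it terminates the helix
        inner3 <- (k + 1L <= l - 1L) && partner[k + 1L] == l - 1L &&
          (l - 1L) > (k + 1L)
        if (model == "enn" && inner3) {
          e <- e + tl$junction[pt(i, j), pt(k, l), pt(k + 1L, l - 1L)]
        } else {
          e <- e + tl$stack[pt(i, j), pt(k, l)]
        }
      } else if (n1 + n2 == 1L) {       # size-1 bulge: helix continues
        e <- e + tl$bulge[1] + tl$stack[pt(i, j), pt(k, l)]
      } else {
        eloop <- if (n1 == 0L || n2 == 0L) tl$bulge[n1 + n2] else tl$internal[n1 + n2]
        e <- e + eloop + tau[pt(i, j)] + tau[pt(k, l)]
      }
    } else {                            # multiloop
      u <- (j - i - 1L) - sum(pairs[kids, 2] - pairs[kids, 1] + 1L)
      m <- length(kids) + 1L
      e <- e + tl$mlA + tl$mlB * m + tl$mlC * u + tau[pt(i, j)]
      for (kk in kids) e <- e + tau[pt(pairs[kk, 1], pairs[kk, 2])]
    }
  }
  e
}

#' Evaluate the free energy of a structure
#'
#' Decomposes a secondary structure into its loops (hairpins, bulges,
#' internal loops, multiloops, exterior) and helix junctions and sums the
#' model energies: under the NN model every directly stacked pair of pairs
#' contributes a stack term; under the ENN model each window of three
#' contiguous stacked pairs contributes a triplet term and each helix keeps
#' a single NN stack at its loop-terminating end.  Size-1 bulges contribute
#' the bulge penalty plus the NN stack across the bulge and interrupt
#' triplet windows.  This evaluator and the DP engine assign identical
#' energies to every structure.
#'
#' @param structure a \linkS4class{SecondaryStructure}
#' @param params an \linkS4class{EnergyParams} or parameter-set name
#' @param config a \linkS4class{ModelConfig}
#' @return energy in kcal/mol.
#' @examples
#' ss <- secondaryStructure("GGGAAACCC", dotbracket = "(((...)))")
#' evaluateEnergy(ss, "turner99", modelConfig("nn"))
#' @export
evaluateEnergy <- function(structure, params = "turner99", config = modelConfig()) {
  stopifnot(is(structure, "SecondaryStructure"))
  validObject(structure)
  params <- loadParameters(params)
  iseq <- .encodeSeq(structure@seq)
  if (nrow(structure@pairs) &&
      any(structure@pairs[, 2] - structure@pairs[, 1] <= config@theta))
    stop("structure violates the hairpin constraint (theta = ", config@theta, ")")
  tl <- .modelTables(length(iseq), params, config)
  .evalEnergyTables(structure@pairs, iseq, tl, config@model)
}
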