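#' Base pairs of a structure-bearing object
#'
#' @param x a \linkS4class{SecondaryStructure} or \linkS4class{FoldResult}
#' @return two-column integer matrix of (i, j) pairs
#' @export
setGeneric("basePairs", function(x) standardGeneric("basePairs"))

#' Dot-bracket rendering
#'
#' @param x a \linkS4class{SecondaryStructure} or \linkS4class{FoldResult}
#' @return Vienna-style dot-bracket string
#' @export
setGeneric("dotBracket", function(x) standardGeneric("dotBracket"))

#' Free energy of a fold result
#'
#' @param x a \linkS4class{FoldResult}
#' @return energy in kcal/mol
#' @export
setGeneric("foldEnergy", function(x) standardGeneric("foldEnergy"))
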