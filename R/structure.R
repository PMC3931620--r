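## Sequence and structure primitives.

.BASES <- c("A", "C", "G", "U")

## canonical pair type lookup: rows/cols A C G U -> code into pairTypes(), NA otherwise
.PT_LOOKUP <- local({
  m <- matrix(NA_integer_, 4, 4, dimnames = list(.BASES, .BASES))
  m["A", "U"] <- 1L; m["U", "A"] <- 2L; m["G", "C"] <- 3L
  m["C", "G"] <- 4L; m["G", "U"] <- 5L; m["U", "G"] <- 6L
  m
})

.pairTypeCode <- function(x, y) .PT_LOOKUP[cbind(x, y)]

#' Normalize an RNA sequence string
#'
#' Upper-cases, converts DNA T to U, and rejects any other character.
#'
#' @param seq character scalar
#' @param notify emit a message when T residues are converted
#' @return normalized sequence string
#' @export
normalizeSequence <- function(seq, notify = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  s <- toupper(gsub("[[:space:]]", "", seq))
  if (grepl("T", s, fixed = TRUE)) {
    if (notify) message("normalizeSequence: converting T to U")
    s <- gsub("T", "U", s, fixed = TRUE)
  }
  bad <- regmatches(s, regexpr("[^ACGU]", s))
  if (length(bad) && nzchar(bad))
    stop("invalid character in sequence: '", bad, "'")
  s
}

## 0-based integer encoding A=0 C=1 G=2 U=3 for the compiled engine
.encodeSeq <- function(seq) {
  match(strsplit(seq, "")[[1]], .BASES) - 1L
}

#' Pair type of two sequence positions
#'
#' @param seq RNA sequence string
#' @param i,j 1-based positions, i < j
#' @return the pair-type code (one of \code{pairTypes()}), or \code{NA} if
#'   (i, j) is not a canonical pair
#' @examples
#' pairTypeOf("GAAAC", 1, 5)
#' @export
pairTypeOf <- function(seq, i, j) {
  s <- strsplit(normalizeSequence(seq), "")[[1]]
  pairTypes()[.pairTypeCode(s[i], s[j])]
}

#' Construct a secondary structure
#'
#' @param seq RNA sequence (T is normalized to U)
#' @param pairs two-column matrix of 1-based pairs, or NULL for the empty
#'   structure
#' @param dotbracket alternatively, a Vienna dot-bracket string
#' @param theta minimum hairpin size to enforce (every pair must satisfy
#'   j - i > theta)
#' @return A \linkS4class{SecondaryStructure}.
#' @examples
#' secondaryStructure("GGGAAACCC", dotbracket = "(((...)))")
#' @export
secondaryStructure <- function(seq, pairs = NULL, dotbracket = NULL, theta = 3L) {
  seq <- normalizeSequence(seq)
  if (!is.null(dotbracket)) {
    if (!is.null(pairs)) stop("give either pairs or dotbracket, not both")
    pairs <- parseDotBracket(dotbracket)
  }
  if (is.null(pairs) || NROW(pairs) == 0L) {
    pairs <- matrix(integer(), 0L, 2L)
  } else {
    pairs <- matrix(as.integer(pairs), ncol = 2L,
                    dimnames = NULL)
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  }
  colnames(pairs) <- c("i", "j")
  if (nrow(pairs) && any(pairs[, 2] - pairs[, 1] <= theta))
    stop("hairpin constraint violated: a pair (i, j) has j - i <= theta")
  new("SecondaryStructure", seq = seq, pairs = pairs)
}

#' Parse a dot-bracket string into a pair matrix
#'
#' @param db string over '(', ')' and '.'
#' @return integer matrix with columns i, j
#' @export
parseDotBracket <- function(db) {
  ch <- strsplit(db, "")[[1]]
  if (any(!ch %in% c("(", ")", ".")))
    stop("dot-bracket may contain only '(', ')' and '.'")
  open <- integer(0)
  out <- matrix(integer(), 0L, 2L)
  for (k in seq_along(ch)) {
    if (ch[k] == "(") open <- c(open, k)
    else if (ch[k] == ")") {
      if (!length(open)) stop("unbalanced ')' at position ", k)
      out <- rbind(out, c(open[length(open)], k))
      open <- open[-length(open)]
    }
  }
  if (length(open)) stop("unbalanced '(' at position ", open[1])
  out[order(out[, 1]), , drop = FALSE]
}

#' @describeIn basePairs pairs of a structure
#' @export
setMethod("basePairs", "SecondaryStructure", function(x) x@pairs)

#' @describeIn basePairs pairs of the MFE structure in a fold result
#' @export
setMethod("basePairs", "FoldResult", function(x) {
  if (!is(x@structure, "SecondaryStructure"))
    stop("this FoldResult carries no structure")
  x@structure@pairs
})

#' @describeIn dotBracket render a structure
#' @export
setMethod("dotBracket", "SecondaryStructure", function(x) {
  n <- nchar(x@seq)
  ch <- rep(".", n)
  if (nrow(x@pairs)) {
    ch[x@pairs[, 1]] <- "("
    ch[x@pairs[, 2]] <- ")"
  }
  paste(ch, collapse = "")
})

#' @describeIn dotBracket render the MFE structure of a fold result
#' @export
setMethod("dotBracket", "FoldResult", function(x) dotBracket(x@structure))

#' @describeIn foldEnergy energy stored in a fold result
#' @export
setMethod("foldEnergy", "FoldResult", function(x) x@energy)

## children of each pair: direct structural tree used by the evaluator and io.
## Returns a list: $top integer vector of indices of top-level pairs, and
## $kids list over pair rows of integer vectors (indices into pairs rows).
.structureTree <- function(pairs) {
  np <- nrow(pairs)
  kids <- vector("list", np)
  top <- integer(0)
  if (np == 0L) return(list(top = top, kids = kids))
  o <- order(pairs[, 1])
  stack <- integer(0)
  for (r in o) {
    while (length(stack) && pairs[stack[length(stack)], 2] < pairs[r, 1])
      stack <- stack[-length(stack)]
    if (!length(stack)) top <- c(top, r)
    else {
      par <- stack[length(stack)]
      kids[[par]] <- c(kids[[par]], r)
    }
    stack <- c(stack, r)
  }
  list(top = top, kids = kids)
}
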