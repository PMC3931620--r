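## File formats (FASTA, CT, dot-bracket, TSV) and fixture generation.

#' Read RNA sequences from a FASTA file
#'
#' @param path FASTA file
#' @return named list of normalized sequence strings (T converted to U).
#' @export
readFasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  out <- lapply(unname(seqs), normalizeSequence)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Locate a shipped example sequence
#'
#' The package ships, as plain FASTA, the three sequences used in the
#' worked examples: the 148-nt XPT guanine riboswitch from
#' \emph{Bacillus subtilis} and two ~70-nt snoRNAs (platypus and galago).
#'
#' @param name one of \code{"xpt"}, \code{"snorna_platypus"},
#'   \code{"snorna_galago"}
#' @return the sequence string.
#' @examples
#' nchar(exampleSequence("xpt"))
#' @export
exampleSequence <- function(name = c("xpt", "snorna_platypus", "snorna_galago")) {
  name <- match.arg(name)
  file <- switch(name, xpt = "xpt_riboswitch.fasta",
                 snorna_platypus = "snorna_platypus.fasta",
                 snorna_galago = "snorna_galago.fasta")
  readFasta(system.file("extdata", file, package = "TripletFold",
                        mustWork = TRUE))[[1]]
}

#' Write a dot-bracket record
#'
#' @param structure a \linkS4class{SecondaryStructure}
#' @param energy optional energy annotated on the structure line
#' @param id FASTA-style identifier
#' @param path output file, or NULL to return the text
#' @return the record text, invisibly when written to a file.
#' @export
writeDotBracket <- function(structure, energy = NULL, id = "seq", path = NULL) {
  stopifnot(is(structure, "SecondaryStructure"))
  line3 <- dotBracket(structure)
  if (!is.null(energy)) line3 <- sprintf("%s (%.2f)", line3, energy)
  txt <- paste0(">", id, "\n", structure@seq, "\n", line3, "\n")
  if (is.null(path)) return(txt)
  cat(txt, file = path)
  invisible(txt)
}

#' Read a secondary structure from a CT file
#'
#' Standard 6-column connectivity table: index, base, previous, next,
#' pairing partner (0 = unpaired), index.  Reciprocal consistency of the
#' pairing column is enforced.
#'
#' @param path CT file
#' @return A \linkS4class{SecondaryStructure}; crossing pairs (pseudoknots)
#'   are dropped with a warning.
#' @export
readCT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty CT file: ", path)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- suppressWarnings(as.integer(header[1]))
  if (is.na(n)) stop("CT header must start with the sequence length (line 1)")
  if (length(lines) < n + 1L) stop("CT file truncated: expected ", n, " rows")
  rows <- strsplit(trimws(lines[2:(n + 1L)]), "\\s+")
  bases <- character(n)
  pairCol <- integer(n)
  for (r in seq_len(n)) {
    f <- rows[[r]]
    if (length(f) < 6L) stop("CT row malformed at line ", r + 1L)
    idx <- as.integer(f[1])
    if (is.na(idx) || idx != r) stop("CT index mismatch at line ", r + 1L)
    bases[r] <- f[2]
    pairCol[r] <- as.integer(f[5])
  }
  for (r in seq_len(n)) {
    p <- pairCol[r]
    if (p < 0L || p > n) stop("CT pairing partner out of range at line ", r + 1L)
    if (p > 0L && pairCol[p] != r)
      stop("CT pairing column inconsistent: row ", r, " pairs ", p,
           " but row ", p, " pairs ", pairCol[p])
  }
  seq <- normalizeSequence(paste(bases, collapse = ""))
  prs <- which(pairCol > seq_len(n))
  pairs <- cbind(prs, pairCol[prs])
  ## drop crossing pairs greedily (references may contain pseudoknots)
  if (nrow(pairs) > 1L) {
    keep <- rep(TRUE, nrow(pairs))
    for (a in seq_len(nrow(pairs) - 1L)) {
      if (!keep[a]) next
      for (b in (a + 1L):nrow(pairs)) {
        if (!keep[b]) next
        i <- pairs[a, 1]; j <- pairs[a, 2]; k <- pairs[b, 1]; l <- pairs[b, 2]
        if (i < k && k < j && j < l) keep[b] <- FALSE
      }
    }
    if (any(!keep)) {
      warning("dropped ", sum(!keep), " crossing (pseudoknotted) pair(s) from ",
              basename(path))
      pairs <- pairs[keep, , drop = FALSE]
    }
  }
  ## drop non-canonical reference pairs as well: the model cannot form them
  s <- strsplit(seq, "")[[1]]
  if (nrow(pairs)) {
    canon <- !is.na(.pairTypeCode(s[pairs[, 1]], s[pairs[, 2]]))
    if (any(!canon)) {
      warning("dropped ", sum(!canon), " non-canonical pair(s) from ",
              basename(path))
      pairs <- pairs[canon, , drop = FALSE]
    }
  }
  secondaryStructure(seq, pairs = pairs, theta = 0L)
}

#' Write a secondary structure as a CT file
#'
#' @param structure a \linkS4class{SecondaryStructure}
#' @param path output file
#' @param id header comment
#' @return \code{path}, invisibly.
#' @export
writeCT <- function(structure, path, id = "seq") {
  stopifnot(is(structure, "SecondaryStructure"))
  s <- strsplit(structure@seq, "")[[1]]
  n <- length(s)
  partner <- integer(n)
  p <- structure@pairs
  if (nrow(p)) {
    partner[p[, 1]] <- p[, 2]
    partner[p[, 2]] <- p[, 1]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %s", n, id), con)
  for (r in seq_len(n))
    writeLines(sprintf("%d %s %d %d %d %d", r, s[r], r - 1L,
                       if (r < n) r + 1L else 0L, partner[r], r), con)
  invisible(path)
}

#' Write a melting curve as TSV
#'
#' @param curve data.frame from \code{\link{meltingCurve}}
#' @param path output file
#' @return \code{path}, invisibly.
#' @export
writeMeltingTSV <- function(curve, path) {
  stopifnot(all(c("temperature_C", "expected_bp", "expected_bp_per_nt")
                %in% names(curve)))
  utils::write.table(curve, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a test-fixture sequence
#'
#' Random mode draws i.i.d. nucleotides at a given GC content.  Scaffold
#' mode (\code{stem}, \code{loop} given) emits a designed stem-loop: a
#' GC-only helix of \code{stem} pairs around an A-loop of \code{loop}
#' bases, whose unique minimum-energy structure is the designed helix.
#'
#' @param n sequence length (scaffold mode requires n = 2 stem + loop)
#' @param gcContent GC fraction for random mode
#' @param stem,loop scaffold dimensions (NULL for random mode)
#' @param seed integer seed
#' @return list(seq, structure) where structure is the designed reference
#'   (scaffold mode) or NULL.
#' @examples
#' generateFixture(14, stem = 5, loop = 4)$structure
#' @export
generateFixture <- function(n, gcContent = 0.5, stem = NULL, loop = NULL,
                            seed = NA_integer_) {
  if (!is.na(seed)) set.seed(as.integer(seed))
  if (!is.null(stem) || !is.null(loop)) {
    stopifnot(!is.null(stem), !is.null(loop))
    if (2 * stem + loop != n)
      stop("scaffold requires n = 2 * stem + loop")
    if (stem > n / 2) stop("stem longer than half the sequence")
    if (loop < 3) stop("scaffold loop must satisfy the hairpin constraint")
    left <- rep(c("G", "C"), length.out = stem)
    seq <- paste(c(left, rep("A", loop),
                   rev(vapply(left, function(b) switch(b, G = "C", C = "G"),
                              character(1)))), collapse = "")
    pairs <- cbind(seq_len(stem), n + 1L - seq_len(stem))
    return(list(seq = seq,
                structure = secondaryStructure(seq, pairs = pairs)))
  }
  stopifnot(gcContent >= 0, gcContent <= 1, n >= 1)
  probs <- c(A = (1 - gcContent) / 2, C = gcContent / 2,
             G = gcContent / 2, U = (1 - gcContent) / 2)
  seq <- paste(sample(names(probs), n, replace = TRUE, prob = probs),
               collapse = "")
  list(seq = seq, structure = NULL)
}
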