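## Structure-prediction accuracy metrics: sensitivity and positive
## predictive value under exact base-pair identity, plus a batch harness
## over CT reference files.

#' Compare a predicted structure against a reference
#'
#' Sensitivity is the number of correctly predicted base pairs divided by
#' the number of pairs in the reference structure; positive predictive
#' value divides by the number of predicted pairs.  A pair is correct only
#' under exact (i, j) identity.  Empty reference (or prediction) gives
#' sensitivity (or PPV) of 1 by convention.
#'
#' @param pred,ref \linkS4class{SecondaryStructure} objects on sequences of
#'   the same length
#' @return list(tp, sensitivity, ppv).
#' @examples
#' a <- secondaryStructure("GGGGAAAACCCC", dotbracket = "((((....))))")
#' b <- secondaryStructure("GGGGAAAACCCC", dotbracket = ".(((....))).")
#' compareStructures(b, a)
#' @export
compareStructures <- function(pred, ref) {
  stopifnot(is(pred, "SecondaryStructure"), is(ref, "SecondaryStructure"))
  if (nchar(pred@seq) != nchar(ref@seq))
    stop("prediction and reference are on sequences of different length")
  key <- function(p) if (nrow(p)) paste(p[, 1], p[, 2]) else character(0)
  tp <- length(intersect(key(pred@pairs), key(ref@pairs)))
  nref <- nrow(ref@pairs); npred <- nrow(pred@pairs)
  list(tp = tp,
       sensitivity = if (nref == 0L) 1 else tp / nref,
       ppv = if (npred == 0L) 1 else tp / npred)
}

#' Fold and score a batch of reference structures
#'
#' Reads each CT file, drops crossing (pseudoknotted) pairs from the
#' reference with a warning, folds the CT's sequence under the configured
#' model and tabulates per-item and average sensitivity/PPV.
#'
#' @param ctFiles character vector of CT file paths (the CT records carry
#'   the sequences); names are used as item ids
#' @param params an \linkS4class{EnergyParams} or set name
#' @param config a \linkS4class{ModelConfig}
#' @return list with \code{per_item} (data.frame: id, n_ref_pairs,
#'   n_pred_pairs, true_positives, sensitivity, ppv), \code{averages}
#'   (unweighted means), and \code{errors} (named character vector of
#'   per-item failures, zero-length when all items folded).
#' @export
runBenchmark <- function(ctFiles, params = "turner99", config = modelConfig()) {
  if (length(ctFiles) == 0L) stop("runBenchmark: empty item list")
  ids <- names(ctFiles)
  if (is.null(ids)) ids <- basename(ctFiles)
  rows <- list()
  errors <- character(0)
  for (idx in seq_along(ctFiles)) {
    res <- tryCatch({
      ref <- readCT(ctFiles[[idx]])
      fr <- mfeFold(ref@seq, params, config)
      cmp <- compareStructures(fr@structure, ref)
      data.frame(id = ids[idx], n_ref_pairs = nrow(ref@pairs),
                 n_pred_pairs = nrow(fr@structure@pairs),
                 true_positives = cmp$tp, sensitivity = cmp$sensitivity,
                 ppv = cmp$ppv)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[ids[idx]] <- conditionMessage(res)
      warning("benchmark item '", ids[idx], "' skipped: ",
              conditionMessage(res))
    } else rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows)) stop("runBenchmark: every item failed")
  per <- do.call(rbind, rows)
  list(per_item = per,
       averages = c(sensitivity = mean(per$sensitivity), ppv = mean(per$ppv)),
       errors = errors)
}
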