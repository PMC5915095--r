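# Scoring of bioactivity fingerprints against the experimental target
# profile: the additive fit score.

#' FitResults: per-compound fit of a fingerprint to the target profile
#'
#' For each compound and each scored (non-excluded) panel target, +1 marks a
#' match of activity between the database compound and the test substance
#' (active-active or inactive-inactive), -1 a mismatch, and 0 the absence of
#' data; interference-excluded targets always contribute 0. The fit score is
#' the arithmetic sum over targets; compounds with fit score >= the
#' well-fitted threshold (default 1) are flagged well-fitted. An ideally
#' fitted compound tested and matching at every scored target scores T, the
#' number of scored targets.
#'
#' @slot per_target integer matrix (compounds x panel targets) of +1/-1/0.
#' @slot fit_score named integer vector of row sums.
#' @slot well_fitted named logical vector.
#' @slot threshold numeric well-fitted threshold.
#' @aliases FitResults-class
#' @exportClass FitResults
setClass("FitResults",
         representation(per_target = "matrix", fit_score = "integer",
                        well_fitted = "logical", threshold = "numeric"))

setValidity("FitResults", function(object) {
  m <- object@per_target
  if (!all(m %in% c(-1L, 0L, 1L))) return("per-target values must be -1, 0, +1")
  if (length(object@fit_score) != nrow(m) ||
      length(object@well_fitted) != nrow(m))
    return("fit_score/well_fitted length must match compound count")
  if (!identical(unname(object@fit_score), unname(as.integer(rowSums(m)))))
    return("fit_score must equal the per-target row sums")
  TRUE
})

#' @exportMethod show
setMethod("show", "FitResults", function(object) {
  cat("FitResults:", nrow(object@per_target), "compounds x",
      ncol(object@per_target), "panel targets\n")
  if (nrow(object@per_target)) {
    cat(sprintf("  fit_score range: [%d, %d]; well-fitted (>= %g): %d\n",
                min(object@fit_score), max(object@fit_score),
                object@threshold, sum(object@well_fitted)))
  }
})

#' @describeIn FitResults-class number of scored compounds.
#' @param x,object a `FitResults`.
#' @export
setMethod("length", "FitResults", function(x) nrow(x@per_target))

#' Accessors for FitResults
#' @param results a [FitResults-class] object.
#' @return `fitScores`: named integer vector; `wellFitted`: named logical
#'   vector; `fitMatrix`: the +1/-1/0 compounds x targets matrix.
#' @export
fitScores <- function(results) results@fit_score

#' @rdname fitScores
#' @export
wellFitted <- function(results) results@well_fitted

#' @rdname fitScores
#' @export
fitMatrix <- function(results) results@per_target

#' Per-target match/mismatch vectors for a fingerprint set
#'
#' @param fingerprints an [ActivityFingerprints-class] object.
#' @param profile a [TargetProfile-class] object sharing the panel target
#'   universe with the fingerprints.
#' @return integer matrix (compounds x targets) with values +1/-1/0.
#' @export
fitVectors <- function(fingerprints, profile) {
  fp <- fingerprintMatrix(fingerprints)
  states <- profileStates(profile)
  if (!setequal(colnames(fp), names(states)))
    stop("fingerprints and profile cover different panel target universes")
  states <- states[colnames(fp)]
  ref <- ifelse(states == "active", 1L,
                ifelse(states == "inactive", 0L, NA_integer_))  # NA = excluded
  refm <- matrix(ref, nrow = nrow(fp), ncol = ncol(fp), byrow = TRUE)
  m <- matrix(0L, nrow = nrow(fp), ncol = ncol(fp), dimnames = dimnames(fp))
  defined <- !is.na(fp) & !is.na(refm)
  m[defined & fp == refm] <- 1L
  m[defined & fp != refm] <- -1L
  m
}

#' Score fingerprints against the experimental profile
#'
#' @inheritParams fitVectors
#' @param well_fitted_threshold minimum fit score for the well-fitted flag
#'   (default 1).
#' @return a [FitResults-class] object.
#' @export
scoreFingerprints <- function(fingerprints, profile,
                              well_fitted_threshold = 1) {
  m <- fitVectors(fingerprints, profile)
  score <- as.integer(rowSums(m))
  names(score) <- rownames(m)
  methods::new("FitResults", per_target = m, fit_score = score,
               well_fitted = stats::setNames(score >= well_fitted_threshold,
                                             rownames(m)),
               threshold = well_fitted_threshold)
}

#' Select well-fitted compounds
#'
#' @param results a [FitResults-class] object.
#' @param threshold minimum fit score (default 1).
#' @return a [FitResults-class] subset, sorted by descending fit score with
#'   ties broken by compound id for reproducible reports.
#' @export
selectWellFitted <- function(results, threshold = 1) {
  keep <- which(results@fit_score >= threshold)
  ord <- keep[order(-results@fit_score[keep],
                    rownames(results@per_target)[keep])]
  methods::new("FitResults",
               per_target = results@per_target[ord, , drop = FALSE],
               fit_score = results@fit_score[ord],
               well_fitted = results@well_fitted[ord],
               threshold = threshold)
}

#' Per-target tally of matching activity
#'
#' Mirrors the "n records of matching activity among m tested compounds"
#' phrasing: for each panel target, how many compounds have a defined entry
#' there (tested) and how many of those match the experimental profile (+1),
#' reported for all compounds and for the well-fitted subset.
#'
#' @param results a [FitResults-class] object.
#' @return data.frame with columns `target`, `n_matching`, `n_tested`,
#'   `n_matching_well_fitted`, `n_tested_well_fitted`.
#' @export
perTargetTally <- function(results) {
  m <- results@per_target
  wf <- m[results@well_fitted, , drop = FALSE]
  data.frame(target = colnames(m),
             n_matching = as.integer(colSums(m == 1L)),
             n_tested = as.integer(colSums(m != 0L)),
             n_matching_well_fitted = as.integer(colSums(wf == 1L)),
             n_tested_well_fitted = as.integer(colSums(wf != 0L)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Total matching and mismatching activity records
#'
#' @param results a [FitResults-class] object.
#' @return named integer vector `c(total_matching =, total_mismatching =)`:
#'   grand sums of +1 and -1 entries over all compounds and targets.
#' @export
matchMismatchTotals <- function(results) {
  m <- results@per_target
  c(total_matching = sum(m == 1L), total_mismatching = sum(m == -1L))
}

#' Write fit results to CSV
#'
#' One row per compound: id, fit score, well-fitted flag, and one +1/-1/0
#' column per panel target.
#'
#' @param results a [FitResults-class] object.
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
writeFitResults <- function(results, file) {
  d <- data.frame(compound_id = rownames(results@per_target),
                  fit_score = results@fit_score,
                  well_fitted = results@well_fitted,
                  results@per_target, check.names = FALSE,
                  row.names = NULL, stringsAsFactors = FALSE)
  utils::write.csv(d, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
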