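#' MethCohort: a cohort of averaged methylation profiles with ages
#'
#' A \code{MethCohort} extends
#' \linkS4class{SummarizedExperiment}: the \code{"methylation"}
#' assay holds one row per locus (canonical order, see
#' \code{\link{locusOrder}}) and one column per sample, with methylation
#' levels as fractions in [0, 1] (\code{NA} where a locus could not be
#' measured); \code{colData} carries \code{age_years} and optionally
#' \code{sex}. Validity enforces unique sample identifiers, strictly
#' positive ages and levels inside the unit interval.
#'
#' @slot .. inherits all slots from \code{SummarizedExperiment}.
#' @seealso \code{\link{MethCohort}} (constructor),
#'   \code{\link{methLevels}}, \code{\link{ages}}
#' @export
setClass("MethCohort", contains = "SummarizedExperiment")

setValidity("MethCohort", function(object) {
  msg <- character()
  if (!"methylation" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'methylation' is required")
  } else {
    m <- SummarizedExperiment::assay(object, "methylation")
    bad <- !is.na(m) & (m < 0 | m > 1)
    if (any(bad)) {
      msg <- c(msg, "methylation levels must lie in [0, 1]")
    }
  }
  if (is.null(colnames(object)) || anyDuplicated(colnames(object))) {
    msg <- c(msg, "sample identifiers (colnames) must be present and unique")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!"age_years" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain 'age_years'")
  } else if (any(!is.na(cd$age_years) & cd$age_years <= 0)) {
    msg <- c(msg, "all ages must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' AgeModel: a linear epigenetic age model over the five loci
#'
#' Stores an intercept (years) and one coefficient per locus (years per
#' unit methylation level) in a fixed locus order, plus a free-text
#' provenance tag (e.g. \code{"published:buccal-5-locus"} or
#' \code{"fitted:n=30"}). Coefficients must cover exactly the loci named
#' in \code{locusOrder}, with no extras.
#'
#' @slot intercept Numeric scalar, years.
#' @slot coefficients Named numeric vector, years per unit methylation.
#' @slot locusOrder Character vector giving the canonical locus order.
#' @slot provenance Character scalar describing where the model came from.
#' @seealso \code{\link{publishedModel}}, \code{\link{fitAgeModel}},
#'   \code{\link{predictAge}}, \code{\link{writeAgeModel}}
#' @export
setClass("AgeModel",
  representation(
    intercept = "numeric",
    coefficients = "numeric",
    locusOrder = "character",
    provenance = "character"
  )
)

setValidity("AgeModel", function(object) {
  msg <- character()
  if (length(object@intercept) != 1L || !is.finite(object@intercept)) {
    msg <- c(msg, "intercept must be a single finite number")
  }
  if (length(object@locusOrder) < 1L || anyDuplicated(object@locusOrder)) {
    msg <- c(msg, "locusOrder must be a non-empty set of unique locus names")
  }
  if (!identical(names(object@coefficients), object@locusOrder)) {
    msg <- c(msg,
      "coefficients must be named exactly by locusOrder, in order")
  }
  if (any(!is.finite(object@coefficients))) {
    msg <- c(msg, "all coefficients must be finite")
  }
  if (length(object@provenance) != 1L) {
    msg <- c(msg, "provenance must be a single string")
  }
  if (length(msg)) msg else TRUE
})

#' EvaluationReport: accuracy metrics for age predictions
#'
#' Holds the number of evaluated samples, the overall mean absolute
#' deviation (MAD, years), MAD per age bin with per-bin sample counts,
#' per-locus Pearson correlation of methylation with age, and the squared
#' Pearson correlation (R-squared) of predicted versus chronological age.
#'
#' @slot n Integer, number of prediction/age pairs evaluated.
#' @slot madOverall Numeric, years.
#' @slot madByBin A \code{data.frame} with columns \code{bin},
#'   \code{lower}, \code{upper}, \code{n}, \code{mad}.
#' @slot pearsonByLocus Named numeric vector of correlations (may contain
#'   \code{NA} where a locus had zero variance or was not evaluated).
#' @slot rSquared Numeric in [0, 1], or \code{NA}.
#' @seealso \code{\link{evaluatePredictions}}
#' @export
setClass("EvaluationReport",
  representation(
    n = "integer",
    madOverall = "numeric",
    madByBin = "data.frame",
    pearsonByLocus = "numeric",
    rSquared = "numeric"
  )
)

setValidity("EvaluationReport", function(object) {
  msg <- character()
  if (!is.na(object@madOverall) && object@madOverall < 0) {
    msg <- c(msg, "madOverall must be >= 0")
  }
  if (!is.na(object@rSquared) &&
      (object@rSquared < 0 || object@rSquared > 1)) {
    msg <- c(msg, "rSquared must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})
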