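#' @rdname methLevels
#' @export
setGeneric("methLevels", function(x, ...) standardGeneric("methLevels"))

#' @rdname ages
#' @export
setGeneric("ages", function(x, ...) standardGeneric("ages"))

#' @rdname predictAge
#' @export
setGeneric("predictAge", function(model, profile, ...)
  standardGeneric("predictAge"))

#' @rdname fitAgeModel
#' @export
setGeneric("fitAgeModel", function(training, ...)
  standardGeneric("fitAgeModel"))

#' @rdname splitCohort
#' @export
setGeneric("splitCohort", function(cohort, trainFraction = 0.5, seed, ...)
  standardGeneric("splitCohort"))
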