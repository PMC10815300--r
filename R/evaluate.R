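#' Age-bin scheme for stratified error reporting
#'
#' Bins are inclusive integer intervals over years; the default is the
#' five strata 23-30, 31-40, 41-50, 51-60, 61-70. Ages outside every bin
#' are collected separately under \code{"other"} by the evaluation
#' functions.
#'
#' @param lower,upper Integer vectors of bin endpoints (both inclusive);
#'   bins must be ascending and non-overlapping.
#' @return A \code{data.frame} with columns \code{bin} (label),
#'   \code{lower}, \code{upper}.
#' @examples
#' ageBins()
#' ageBins(lower = c(20, 40), upper = c(39, 70))
#' @export
ageBins <- function(lower = c(23, 31, 41, 51, 61),
                    upper = c(30, 40, 50, 60, 70)) {
  stopifnot(length(lower) == length(upper), all(lower <= upper))
  if (length(lower) > 1L &&
      any(lower[-1L] <= upper[-length(upper)])) {
    stop("age bins must be ascending and non-overlapping")
  }
  data.frame(bin = sprintf("%d-%d", lower, upper),
             lower = lower, upper = upper, stringsAsFactors = FALSE)
}

# bin label per age; "other" when an age falls in no bin
.assignBins <- function(age, bins) {
  out <- rep("other", length(age))
  for (i in seq_len(nrow(bins))) {
    inBin <- age >= bins$lower[i] & age <= bins$upper[i]
    out[inBin] <- bins$bin[i]
  }
  out
}

#' Mean absolute deviation between predicted and chronological age
#'
#' The headline accuracy metric of an epigenetic clock: the mean of
#' \eqn{|predicted_i - chronological_i|} over paired samples, in years.
#'
#' @param predicted,chronological Paired numeric vectors of ages in
#'   years, equal nonzero length.
#' @return Numeric scalar, years.
#' @examples
#' madError(c(20, 30), c(22, 26))  # 3
#' @export
madError <- function(predicted, chronological) {
  if (length(predicted) != length(chronological)) {
    stop("predicted and chronological ages must be paired ",
         "(lengths ", length(predicted), " vs ", length(chronological), ")")
  }
  if (length(predicted) == 0L) {
    stop("MAD is undefined for empty input")
  }
  mean(abs(predicted - chronological))
}

#' Mean absolute deviation stratified by age group
#'
#' Pairs are assigned to bins by their chronological age (inclusive
#' integer endpoints); the MAD is computed within each bin. Empty bins
#' are reported with \code{n = 0} and \code{NA} MAD; ages outside all
#' bins contribute to an extra \code{"other"} row (only present when
#' non-empty). The n-weighted mean of per-bin MADs recomposes the
#' overall MAD exactly when every age falls in some bin.
#'
#' @inheritParams madError
#' @param bins An age-bin scheme from \code{\link{ageBins}}.
#' @return A \code{data.frame} with columns \code{bin}, \code{lower},
#'   \code{upper}, \code{n}, \code{mad}.
#' @examples
#' madByAgeGroup(c(27, 29), c(25, 27), ageBins())
#' @export
madByAgeGroup <- function(predicted, chronological, bins = ageBins()) {
  if (length(predicted) != length(chronological)) {
    stop("predicted and chronological ages must be paired")
  }
  if (length(predicted) == 0L) {
    stop("MAD is undefined for empty input")
  }
  lab <- .assignBins(chronological, bins)
  rows <- bins
  rows$n <- vapply(bins$bin, function(b) sum(lab == b), integer(1))
  rows$mad <- vapply(bins$bin, function(b) {
    if (!any(lab == b)) return(NA_real_)
    madError(predicted[lab == b], chronological[lab == b])
  }, numeric(1))
  if (any(lab == "other")) {
    rows <- rbind(rows, data.frame(
      bin = "other", lower = NA_real_, upper = NA_real_,
      n = sum(lab == "other"),
      mad = madError(predicted[lab == "other"],
                     chronological[lab == "other"])))
  }
  rownames(rows) <- NULL
  rows
}

#' Pearson correlation of methylation level with age, per locus
#'
#' For each locus, the sample Pearson correlation between the averaged
#' methylation level and chronological age across the cohort, using
#' pairwise-complete samples. A locus with fewer than 3 complete pairs
#' or zero variance in either variable is undefined (\code{NA}, with a
#' warning naming the locus).
#'
#' @param cohort A \linkS4class{MethCohort}.
#' @return Named numeric vector of correlations, one per locus.
#' @examples
#' cohort <- generateCohort(syntheticConfig(nSamples = 20, seed = 5))
#' pearsonPerLocus(cohort)
#' @export
pearsonPerLocus <- function(cohort) {
  stopifnot(is(cohort, "MethCohort"))
  m <- methLevels(cohort)
  a <- unname(ages(cohort))
  out <- setNames(rep(NA_real_, nrow(m)), rownames(m))
  undef <- character()
  for (l in rownames(m)) {
    ok <- !is.na(m[l, ]) & !is.na(a)
    x <- m[l, ok]
    y <- a[ok]
    if (sum(ok) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
      undef <- c(undef, l)
      next
    }
    out[l] <- stats::cor(x, y)
  }
  if (length(undef) > 0L) {
    warning("correlation undefined (zero variance or n < 3) for: ",
            paste(undef, collapse = ", "))
  }
  out
}

#' Squared Pearson correlation of predicted vs chronological age
#'
#' R-squared here is the square of the Pearson correlation between
#' predictions and chronological ages — the R-squared of the fitted
#' regression line through the prediction scatter, not goodness of fit
#' relative to the identity line. A test set can therefore score a
#' higher R-squared than the training set while still being biased.
#'
#' @inheritParams madError
#' @return Numeric scalar in [0, 1], or \code{NA} with a warning when
#'   either vector has zero variance or fewer than 3 pairs.
#' @examples
#' rSquaredAge(c(1, 2, 3), c(2, 4, 6))  # 1
#' @export
rSquaredAge <- function(predicted, chronological) {
  if (length(predicted) != length(chronological)) {
    stop("predicted and chronological ages must be paired")
  }
  if (length(predicted) < 3L || stats::sd(predicted) == 0 ||
      stats::sd(chronological) == 0) {
    warning("R-squared undefined: need >= 3 pairs with nonzero variance")
    return(NA_real_)
  }
  stats::cor(predicted, chronological)^2
}

#' Evaluate age predictions against a cohort
#'
#' Computes the full accuracy report: overall MAD, MAD per age bin,
#' per-locus Pearson correlation of level with age, and the squared
#' Pearson correlation of predicted vs chronological age.
#'
#' @param cohort A \linkS4class{MethCohort} with chronological ages.
#' @param predicted Numeric vector of predicted ages; either named by
#'   sample or in cohort column order. Defaults to applying
#'   \code{model} to the cohort.
#' @param model An \linkS4class{AgeModel} used when \code{predicted} is
#'   not supplied.
#' @param bins Age-bin scheme, default \code{\link{ageBins}()}.
#' @return An \linkS4class{EvaluationReport}.
#' @examples
#' cohort <- generateCohort(syntheticConfig(nSamples = 20, seed = 5))
#' evaluatePredictions(cohort, model = publishedModel())
#' @export
evaluatePredictions <- function(cohort, predicted = NULL, model = NULL,
                                bins = ageBins()) {
  stopifnot(is(cohort, "MethCohort"))
  if (is.null(predicted)) {
    if (is.null(model)) stop("supply either predictions or a model")
    cohort <- completeProfiles(cohort)
    predicted <- predictAge(model, cohort)
  }
  if (!is.null(names(predicted))) {
    if (!all(names(predicted) %in% colnames(cohort))) {
      stop("predictions carry sample names not present in the cohort")
    }
    cohort <- cohort[, names(predicted)]
  }
  chron <- unname(ages(cohort))
  predicted <- unname(predicted)
  new("EvaluationReport",
      n = length(predicted),
      madOverall = madError(predicted, chron),
      madByBin = madByAgeGroup(predicted, chron, bins),
      pearsonByLocus = pearsonPerLocus(cohort),
      rSquared = suppressWarnings(rSquaredAge(predicted, chron)))
}

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport on", object@n, "samples\n")
  cat(sprintf("  MAD overall: %.2f years\n", object@madOverall))
  for (i in seq_len(nrow(object@madByBin))) {
    r <- object@madByBin[i, ]
    if (r$n > 0) {
      cat(sprintf("  MAD %-7s: %.2f years (n = %d)\n", r$bin, r$mad, r$n))
    }
  }
  if (!is.na(object@rSquared)) {
    cat(sprintf("  R-squared (pred vs chron): %.3f\n", object@rSquared))
  }
  pr <- object@pearsonByLocus
  cat("  Pearson r (level vs age):",
      paste(sprintf("%s %.3f", names(pr), pr), collapse = ", "), "\n")
  invisible(NULL)
})

#' Export an EvaluationReport as a plain list (for JSON)
#'
#' @param report An \linkS4class{EvaluationReport}.
#' @return A list mirroring the report slots, suitable for
#'   \code{jsonlite::write_json}.
#' @export
reportAsList <- function(report) {
  stopifnot(is(report, "EvaluationReport"))
  list(n = report@n,
       mad_overall = report@madOverall,
       mad_by_bin = report@madByBin,
       pearson_by_locus = as.list(report@pearsonByLocus),
       r_squared = report@rSquared)
}
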