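#' Construct an AgeModel
#'
#' @param intercept Intercept in years.
#' @param coefficients Named numeric vector of per-locus coefficients
#'   (years per unit methylation); names must be exactly \code{loci}.
#' @param loci Canonical locus order, default \code{\link{locusOrder}()}.
#' @param provenance Free-text origin tag.
#' @return An \linkS4class{AgeModel}.
#' @examples
#' AgeModel(10, setNames(c(50, -11, 74, -49, 84), locusOrder()),
#'          provenance = "example")
#' @export
AgeModel <- function(intercept, coefficients, loci = locusOrder(),
                     provenance = "user") {
  if (is.null(names(coefficients))) {
    stop("coefficients must be named by locus")
  }
  if (!setequal(names(coefficients), loci) ||
      length(coefficients) != length(loci)) {
    stop("coefficients must cover exactly the loci: ",
         paste(loci, collapse = ", "))
  }
  new("AgeModel", intercept = as.numeric(intercept),
      coefficients = coefficients[loci], locusOrder = loci,
      provenance = provenance)
}

#' The published five-locus buccal-swab age model
#'
#' Returns the multivariate linear model reported for buccal-swab samples
#' from a 60-volunteer cohort (ages 23-70), with the six constants exactly
#' as printed:
#' \deqn{age = 50.04231273\,ELOVL2 - 11.16979445\,FHL2 +
#'   73.87032325\,KLF14 - 49.27304295\,C1orf132 + 84.17900486\,TRIM59 +
#'   13.96381427}
#' where each predictor is a methylation fraction in [0, 1].
#'
#' @return An \linkS4class{AgeModel} with provenance
#'   \code{"published:buccal-5-locus"}.
#' @examples
#' m <- publishedModel()
#' coef(m)
#' predictAge(m, setNames(rep(0.5, 5), locusOrder()))
#' @export
publishedModel <- function() {
  AgeModel(
    intercept = 13.96381427,
    coefficients = c(
      ELOVL2 = 50.04231273,
      FHL2 = -11.16979445,
      KLF14 = 73.87032325,
      C1orf132 = -49.27304295,
      TRIM59 = 84.17900486
    ),
    provenance = "published:buccal-5-locus"
  )
}

#' @describeIn AgeModel coefficients (without the intercept), named by
#'   locus in canonical order.
#' @param object An \linkS4class{AgeModel}.
#' @export
setMethod("coef", "AgeModel", function(object) object@coefficients)

#' Intercept of an AgeModel, in years
#'
#' @param model An \linkS4class{AgeModel}.
#' @return Numeric scalar.
#' @export
modelIntercept <- function(model) {
  stopifnot(is(model, "AgeModel"))
  model@intercept
}

#' Provenance tag of an AgeModel
#'
#' @param model An \linkS4class{AgeModel}.
#' @return Character scalar.
#' @export
modelProvenance <- function(model) {
  stopifnot(is(model, "AgeModel"))
  model@provenance
}

setMethod("show", "AgeModel", function(object) {
  cat("AgeModel (", object@provenance, ")\n", sep = "")
  cat("  predicted age [years] =\n")
  for (l in object@locusOrder) {
    cat(sprintf("    %+14.8f x %s\n", object@coefficients[[l]], l))
  }
  cat(sprintf("    %+14.8f\n", object@intercept))
  invisible(NULL)
})

#' Predict age from methylation profiles
#'
#' Applies the affine model \eqn{intercept + \sum_l \beta_l \cdot
#' level_l}. Predictions are returned as-is — no rounding and no clamping
#' to a plausible age range; values outside 0-100 years are reported with
#' a message, since an implausible output is itself diagnostic (e.g. a
#' model transferred from another tissue). A profile missing any model
#' locus is an error naming the locus.
#'
#' @param model An \linkS4class{AgeModel}.
#' @param profile A named numeric vector (locus -> level), a numeric
#'   matrix with loci as rows (samples as columns), or a
#'   \linkS4class{MethCohort}.
#' @param ... Unused.
#' @return Numeric vector of predicted ages in years (named by sample
#'   where sample names exist).
#' @examples
#' predictAge(publishedModel(), setNames(rep(0, 5), locusOrder()))
#' @export
setMethod("predictAge", signature("AgeModel", "numeric"),
  function(model, profile, ...) {
    missing <- model@locusOrder[!model@locusOrder %in% names(profile) |
                                is.na(profile[model@locusOrder])]
    if (length(missing) > 0L) {
      stop("profile is missing predictor locus: ",
           paste(missing, collapse = ", "))
    }
    pred <- model@intercept +
      sum(model@coefficients * profile[model@locusOrder])
    if (is.finite(pred) && (pred < 0 || pred > 100)) {
      message(sprintf("prediction outside 0-100 years: %.2f", pred))
    }
    unname(pred)
  })

#' @rdname predictAge
#' @export
setMethod("predictAge", signature("AgeModel", "matrix"),
  function(model, profile, ...) {
    missing <- setdiff(model@locusOrder, rownames(profile))
    if (length(missing) > 0L) {
      stop("profile matrix is missing predictor locus: ",
           paste(missing, collapse = ", "))
    }
    m <- profile[model@locusOrder, , drop = FALSE]
    if (anyNA(m)) {
      bad <- colnames(m)[colSums(is.na(m)) > 0]
      stop("samples with missing predictor levels: ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
    pred <- drop(crossprod(m, model@coefficients)) + model@intercept
    nOut <- sum(pred < 0 | pred > 100)
    if (nOut > 0) {
      message(nOut, " prediction(s) outside 0-100 years")
    }
    setNames(as.numeric(pred), colnames(m))
  })

#' @rdname predictAge
#' @export
setMethod("predictAge", signature("AgeModel", "MethCohort"),
  function(model, profile, ...) {
    predictAge(model, methLevels(profile), ...)
  })

#' Fit a multivariate linear age model by ordinary least squares
#'
#' Regresses chronological age on the five methylation levels with an
#' intercept, solving the least-squares problem by QR decomposition.
#' Samples with any missing locus level are excluded (with a message
#' giving the count). Requires more complete samples than parameters
#' (n >= p + 2 = 7) and a full-rank design.
#'
#' @param training A \linkS4class{MethCohort}.
#' @param ... Unused.
#' @return An \linkS4class{AgeModel} with provenance
#'   \code{"fitted:n=<training size>"}.
#' @examples
#' cohort <- generateCohort(syntheticConfig(nSamples = 30, seed = 7))
#' fitAgeModel(cohort)
#' @export
setMethod("fitAgeModel", "MethCohort", function(training, ...) {
  complete <- completeProfiles(training)
  nDropped <- ncol(training) - ncol(complete)
  if (nDropped > 0L) {
    message("excluded ", nDropped, " sample(s) with incomplete profiles")
  }
  loci <- rownames(complete)
  n <- ncol(complete)
  p <- length(loci)
  if (n < p + 2L) {
    stop("insufficient data: need at least ", p + 2L,
         " complete samples, got ", n)
  }
  X <- cbind(`(Intercept)` = 1, t(methLevels(complete)))
  y <- unname(ages(complete))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("singular fit: design matrix is rank-deficient (rank ",
         qrX$rank, " < ", ncol(X), ")")
  }
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  AgeModel(intercept = beta[["(Intercept)"]],
           coefficients = beta[loci], loci = loci,
           provenance = sprintf("fitted:n=%d", n))
})

#' Randomly split a cohort into training and test sets
#'
#' Draws a simple random partition: \code{ceiling(n * trainFraction)}
#' samples go to training, the rest to test. The split is reproducible
#' under the same seed and leaves the global random-number state
#' untouched. No age stratification is applied by default (set
#' \code{stratifyBins} to balance age bins across the halves).
#'
#' @param cohort A \linkS4class{MethCohort}.
#' @param trainFraction Fraction of samples for training (0 < f < 1),
#'   default 0.5.
#' @param seed Integer seed controlling the partition.
#' @param stratifyBins Optional age-bin \code{data.frame} (see
#'   \code{\link{ageBins}}); when given, sampling is performed within
#'   bins.
#' @param ... Unused.
#' @return A list with elements \code{training} and \code{test}, both
#'   \linkS4class{MethCohort}s, disjoint and jointly exhaustive.
#' @examples
#' cohort <- generateCohort(syntheticConfig(nSamples = 10, seed = 3))
#' parts <- splitCohort(cohort, 0.5, seed = 42)
#' ncol(parts$training); ncol(parts$test)
#' @export
setMethod("splitCohort", "MethCohort",
  function(cohort, trainFraction = 0.5, seed, stratifyBins = NULL, ...) {
    stopifnot(trainFraction > 0, trainFraction < 1)
    n <- ncol(cohort)
    nTrain <- ceiling(n * trainFraction)
    idx <- withSeed(seed, {
      if (is.null(stratifyBins)) {
        sample.int(n, nTrain)
      } else {
        a <- unname(ages(cohort))
        binOf <- .assignBins(a, stratifyBins)
        picked <- integer()
        for (b in unique(binOf)) {
          members <- which(binOf == b)
          k <- round(length(members) * trainFraction)
          picked <- c(picked, members[sample.int(length(members), k)])
        }
        # adjust to the exact global training size
        if (length(picked) > nTrain) {
          picked <- picked[seq_len(nTrain)]
        } else if (length(picked) < nTrain) {
          pool <- setdiff(seq_len(n), picked)
          picked <- c(picked,
                      pool[sample.int(length(pool), nTrain - length(picked))])
        }
        picked
      }
    })
    list(training = cohort[, sort(idx)],
         test = cohort[, sort(setdiff(seq_len(n), idx))])
  })

#' Write an AgeModel to JSON
#'
#' Serialises intercept, per-locus coefficients, locus order and
#' provenance. Numeric values are written as decimal strings chosen as
#' the shortest representation that parses back to the identical double,
#' so printed constants (e.g. \code{50.04231273}) survive a round trip
#' character-for-character and bit-for-bit.
#'
#' @param model An \linkS4class{AgeModel}.
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readAgeModel}}
#' @export
writeAgeModel <- function(model, path) {
  stopifnot(is(model, "AgeModel"))
  obj <- list(
    intercept = .decimalString(model@intercept),
    coefficients = as.list(vapply(model@coefficients, .decimalString,
                                  character(1))),
    locus_order = as.list(model@locusOrder),
    provenance = model@provenance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read an AgeModel from JSON
#'
#' Accepts the format written by \code{\link{writeAgeModel}} (values as
#' decimal strings) and also plain JSON numbers, so externally published
#' linear models can be loaded from hand-written files.
#'
#' @param path JSON file path.
#' @return An \linkS4class{AgeModel}.
#' @export
readAgeModel <- function(path) {
  obj <- jsonlite::read_json(path)
  loci <- unlist(obj$locus_order, use.names = FALSE)
  coefs <- setNames(vapply(loci, function(l) {
    v <- obj$coefficients[[l]]
    if (is.null(v)) stop("model file lacks coefficient for ", l)
    as.numeric(v)
  }, numeric(1)), loci)
  AgeModel(intercept = as.numeric(obj$intercept), coefficients = coefs,
           loci = loci,
           provenance = if (is.null(obj$provenance)) "loaded"
                        else obj$provenance)
}

# shortest decimal string that round-trips to the identical double
.decimalString <- function(x) {
  for (d in 1:17) {
    s <- formatC(x, digits = d, format = "g", flag = "")
    if (as.numeric(s) == x) return(s)
  }
  sprintf("%.17g", x)
}

# evaluate expr under a temporary RNG state seeded with `seed`
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
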