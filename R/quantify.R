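#' Methylation level from a methylated/unmethylated peak pair
#'
#' The methylation level of a CpG is estimated as the intensity ratio
#' \eqn{I_{meth} / (I_{meth} + I_{unmeth})}: for top-strand assays
#' (ELOVL2, FHL2) this is \eqn{I_C / (I_C + I_T)}, for bottom-strand
#' assays (KLF14, C1orf132, TRIM59) \eqn{I_G / (I_G + I_A)}. The ratio is
#' dimensionless, lies in [0, 1], and is invariant to rescaling both
#' intensities. When both intensities are 0 (or missing) the measurement
#' is undefined and \code{NA} is returned — never 0/0 arithmetic.
#'
#' @param meth,unmeth Nonnegative peak intensities (RFU); vectors are
#'   processed elementwise.
#' @return Numeric vector of methylation fractions in [0, 1], \code{NA}
#'   where undefined.
#' @examples
#' methylationLevel(500, 500)   # 0.5
#' methylationLevel(812, 0)     # 1
#' methylationLevel(300, 100)   # 0.75
#' @export
methylationLevel <- function(meth, unmeth) {
  stopifnot(length(meth) == length(unmeth))
  if (any(meth < 0, na.rm = TRUE) || any(unmeth < 0, na.rm = TRUE)) {
    stop("peak intensities must be nonnegative")
  }
  total <- meth + unmeth
  out <- ifelse(is.na(total) | total == 0, NA_real_, meth / total)
  as.numeric(out)
}

#' Quantify a peak table into per-replicate methylation levels
#'
#' Groups peaks by sample x conversion x amplification x locus, selects
#' the methylated/unmethylated channel pair for each group
#' (\code{\link{selectLocusPair}}) and computes the intensity-ratio
#' methylation level. Peaks below \code{minHeight} are discarded before
#' pairing (default 0: no analytical threshold).
#'
#' @param peaks Canonical peak \code{data.frame} from
#'   \code{\link{readPeakTable}}.
#' @param intensity \code{"height"} (default) or \code{"area"}.
#' @param minHeight Minimum peak height (RFU) for a peak to be used.
#' @return Tidy \code{data.frame} with columns \code{sample_id},
#'   \code{conversion}, \code{amplification}, \code{locus}, \code{level};
#'   \code{level} is \code{NA} where both channels were absent.
#' @seealso \code{\link{averageReplicates}}, \code{\link{cohortHomogeneity}}
#' @export
quantifyPeakTable <- function(peaks, intensity = c("height", "area"),
                              minHeight = 0) {
  intensity <- match.arg(intensity)
  if (minHeight > 0) {
    peaks <- peaks[peaks$height >= minHeight, , drop = FALSE]
  }
  if (nrow(peaks) == 0L) {
    return(data.frame(sample_id = character(), conversion = integer(),
                      amplification = integer(), locus = character(),
                      level = numeric(), stringsAsFactors = FALSE))
  }
  defs <- snapshotLoci()
  key <- interaction(peaks$sample_id, peaks$conversion,
                     peaks$amplification, peaks$locus, drop = TRUE)
  groups <- split(seq_len(nrow(peaks)), key)
  rows <- lapply(groups, function(idx) {
    g <- peaks[idx, , drop = FALSE]
    def <- defs[defs$locus == g$locus[1L], , drop = FALSE]
    pair <- selectLocusPair(g, def, intensity)
    data.frame(sample_id = g$sample_id[1L], conversion = g$conversion[1L],
               amplification = g$amplification[1L], locus = g$locus[1L],
               level = methylationLevel(pair[["meth"]], pair[["unmeth"]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id, out$conversion, out$amplification,
                   match(out$locus, defs$locus)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pooled-variance t-test of homogeneity between two conversion batches
#'
#' Compares methylation levels measured under two independent bisulfite
#' conversions with a two-tailed two-sample t-test assuming equal
#' variances (pooled variance, df = n1 + n2 - 2). Passing means no
#' significant heterogeneity was detected (p >= alpha), in which case
#' replicates from both conversions are normally averaged together.
#' Degenerate inputs are resolved by contract rather than arithmetic:
#' zero pooled variance with equal means gives t = 0, p = 1; zero pooled
#' variance with unequal means gives p = 0 and a degenerate flag.
#'
#' @param levelsConv1,levelsConv2 Numeric vectors of methylation levels
#'   from conversion 1 and conversion 2; each needs at least 2 values.
#' @param alpha Significance level for the pass/fail call (default 0.05).
#' @return A one-row \code{data.frame} with columns \code{t_statistic},
#'   \code{p_value}, \code{df}, \code{passed}, \code{degenerate}.
#' @examples
#' conversionHomogeneityTest(c(0.4, 0.5), c(0.4, 0.5))
#' conversionHomogeneityTest(c(0.2, 0.4), c(0.6, 0.8))
#' @export
conversionHomogeneityTest <- function(levelsConv1, levelsConv2,
                                      alpha = 0.05) {
  x <- levelsConv1[!is.na(levelsConv1)]
  y <- levelsConv2[!is.na(levelsConv2)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("insufficient replicates: each conversion needs >= 2 values")
  }
  df <- length(x) + length(y) - 2L
  pooledVar <- ((length(x) - 1) * stats::var(x) +
                (length(y) - 1) * stats::var(y)) / df
  if (pooledVar == 0) {
    if (mean(x) == mean(y)) {
      return(data.frame(t_statistic = 0, p_value = 1, df = df,
                        passed = TRUE, degenerate = FALSE))
    }
    return(data.frame(t_statistic = sign(mean(x) - mean(y)) * Inf,
                      p_value = 0, df = df, passed = FALSE,
                      degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  data.frame(t_statistic = unname(tt$statistic),
             p_value = tt$p.value, df = df,
             passed = tt$p.value >= alpha, degenerate = FALSE)
}

#' Cohort-level conversion-homogeneity QC per locus
#'
#' Applies \code{\link{conversionHomogeneityTest}} to each locus across
#' the whole cohort, pooling the two amplifications within each
#' conversion so that every sample contributes two values per conversion
#' batch. A per-sample variant (one test per sample x locus) is available
#' but off by default, since with 2 values per group it has almost no
#' power.
#'
#' @param replicateLevels Tidy per-replicate level table from
#'   \code{\link{quantifyPeakTable}}.
#' @param alpha Significance level (default 0.05).
#' @param perSample Logical; run one test per sample x locus instead of
#'   per locus across the cohort.
#' @return A \code{data.frame} with one row per test: \code{locus}
#'   (and \code{sample_id} when \code{perSample}), \code{t_statistic},
#'   \code{p_value}, \code{df}, \code{passed}, \code{degenerate}.
#' @export
cohortHomogeneity <- function(replicateLevels, alpha = 0.05,
                              perSample = FALSE) {
  stopifnot(all(c("sample_id", "conversion", "locus", "level") %in%
                names(replicateLevels)))
  runTest <- function(d, locus, sample_id = NULL) {
    res <- conversionHomogeneityTest(d$level[d$conversion == 1L],
                                     d$level[d$conversion == 2L],
                                     alpha = alpha)
    if (!is.null(sample_id)) res <- cbind(sample_id = sample_id, res)
    cbind(locus = locus, res)
  }
  if (perSample) {
    keys <- unique(replicateLevels[, c("sample_id", "locus")])
    rows <- Map(function(s, l) {
      d <- replicateLevels[replicateLevels$sample_id == s &
                           replicateLevels$locus == l, ]
      runTest(d, l, s)
    }, keys$sample_id, keys$locus)
  } else {
    rows <- lapply(unique(replicateLevels$locus), function(l) {
      runTest(replicateLevels[replicateLevels$locus == l, ], l)
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Average replicate methylation levels into one profile per sample
#'
#' Collapses the per-replicate levels (typically 2 conversions x 2
#' amplifications = 4 per sample and locus) to their arithmetic mean,
#' ignoring replicates where a locus is absent; a locus absent in every
#' replicate stays absent (\code{NA}).
#'
#' @param replicateLevels Tidy per-replicate level table from
#'   \code{\link{quantifyPeakTable}} (columns \code{sample_id},
#'   \code{locus}, \code{level}).
#' @param loci Locus columns of the output, default
#'   \code{\link{locusOrder}()}.
#' @return Wide \code{data.frame}: one row per sample, columns
#'   \code{sample_id} then one per locus with the averaged level.
#' @examples
#' reps <- data.frame(sample_id = "s1", conversion = c(1, 1, 2, 2),
#'                    amplification = c(1, 2, 1, 2), locus = "FHL2",
#'                    level = c(0.2, 0.4, 0.6, 0.8))
#' averageReplicates(reps)  # FHL2 = 0.5
#' @export
averageReplicates <- function(replicateLevels, loci = locusOrder()) {
  stopifnot(all(c("sample_id", "locus", "level") %in%
                names(replicateLevels)))
  samples <- unique(replicateLevels$sample_id)
  out <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  for (l in loci) {
    d <- replicateLevels[replicateLevels$locus == l, , drop = FALSE]
    means <- vapply(samples, function(s) {
      v <- d$level[d$sample_id == s]
      v <- v[!is.na(v)]
      if (length(v) == 0L) NA_real_ else mean(v)
    }, numeric(1))
    out[[l]] <- unname(means)
  }
  out
}

#' Check bisulfite-conversion control samples
#'
#' A fully methylated and a fully unmethylated control DNA are processed
#' alongside the samples; correct bisulfite conversion shows as the
#' methylated control scoring near 1 and the unmethylated control near 0
#' at every locus. The methylated control passes a locus when its level
#' is at least \code{highBound}; the unmethylated control passes when its
#' level is at most \code{lowBound}. A locus absent in a control is
#' unevaluable and raises a warning; the batch flag fails if any
#' evaluable locus fails in either control.
#'
#' @param methControl,unmethControl Named numeric vectors (locus ->
#'   averaged level) for the two controls.
#' @param lowBound,highBound Pass bounds as fractions (defaults 0.1 and
#'   0.9).
#' @return A list with \code{checks} (a \code{data.frame}: \code{locus},
#'   \code{control_type}, \code{level}, \code{passed}) and
#'   \code{batchPassed} (logical over evaluable loci).
#' @examples
#' m <- setNames(rep(0.97, 5), locusOrder())
#' u <- setNames(rep(0.03, 5), locusOrder())
#' checkControls(m, u)$batchPassed
#' @export
checkControls <- function(methControl, unmethControl, lowBound = 0.1,
                          highBound = 0.9) {
  stopifnot(lowBound >= 0, highBound <= 1, lowBound < highBound)
  loci <- locusOrder()
  one <- function(levels, type, passFun) {
    lv <- levels[loci]
    data.frame(locus = loci, control_type = type, level = unname(lv),
               passed = unname(passFun(lv)), stringsAsFactors = FALSE)
  }
  checks <- rbind(
    one(methControl, "methylated", function(lv) lv >= highBound),
    one(unmethControl, "unmethylated", function(lv) lv <= lowBound)
  )
  if (anyNA(checks$level)) {
    warning("control levels absent for: ",
            paste(unique(checks$locus[is.na(checks$level)]),
                  collapse = ", "),
            " - marked unevaluable")
  }
  list(checks = checks,
       batchPassed = all(checks$passed, na.rm = TRUE))
}
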