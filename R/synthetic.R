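#' Configuration for synthetic cohort and peak-table generation
#'
#' Defaults are loaded from the packaged configuration file
#' (\code{system.file("extdata", "default-sim-config.yaml", package =
#' "snapAge")}), which emulates a 60-volunteer buccal-swab study: ages
#' uniform over 23-70 years, five loci whose true methylation fraction
#' is linear in age with per-locus baseline \code{b0}, slope \code{b1}
#' (fraction per year) and biological spread \code{sigma}, a 2x2
#' conversion-by-amplification replicate design, and peak intensities
#' whose ratio encodes the replicate-level methylation. Any argument
#' overrides the file value.
#'
#' @param nSamples Number of cohort samples.
#' @param ageRange Length-2 integer vector, inclusive age range in years.
#' @param loci \code{data.frame} with columns \code{locus}, \code{b0},
#'   \code{b1}, \code{sigma}.
#' @param nConversions,nAmplifications Replicate structure.
#' @param replicateNoiseSD Technical SD (fraction) added per replicate.
#' @param conversionShift Batch effect (fraction): conversion 1 is
#'   shifted by \code{-conversionShift} and conversion 2 by
#'   \code{+conversionShift}.
#' @param totalIntensityMean,totalIntensitySD Log-normal mean/SD (RFU) of
#'   the summed two-channel intensity per locus measurement.
#' @param intensityNoiseCV Multiplicative noise CV applied per channel.
#' @param saturationRFU Instrument ceiling on peak height.
#' @param controlMethLevel,controlUnmethLevel True levels of the fully
#'   methylated / unmethylated control DNAs.
#' @param seed Integer seed; all generation is reproducible given the
#'   config.
#' @param file Alternative YAML configuration file to read defaults from.
#' @return A list of class \code{"syntheticConfig"}.
#' @examples
#' cfg <- syntheticConfig(nSamples = 10, seed = 1)
#' cfg$loci
#' @export
syntheticConfig <- function(nSamples = NULL, ageRange = NULL, loci = NULL,
                            nConversions = NULL, nAmplifications = NULL,
                            replicateNoiseSD = NULL, conversionShift = NULL,
                            totalIntensityMean = NULL,
                            totalIntensitySD = NULL,
                            intensityNoiseCV = NULL, saturationRFU = NULL,
                            controlMethLevel = NULL,
                            controlUnmethLevel = NULL, seed = 1L,
                            file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "default-sim-config.yaml",
                        package = "snapAge")
  }
  def <- yaml::read_yaml(file)
  lociDef <- do.call(rbind, lapply(names(def$loci), function(l) {
    data.frame(locus = l, b0 = def$loci[[l]]$b0, b1 = def$loci[[l]]$b1,
               sigma = def$loci[[l]]$sigma, stringsAsFactors = FALSE)
  }))
  cfg <- list(
    nSamples = if (is.null(nSamples)) def$n_samples else nSamples,
    ageRange = if (is.null(ageRange)) c(def$age_min, def$age_max)
               else ageRange,
    loci = if (is.null(loci)) lociDef else loci,
    nConversions = if (is.null(nConversions)) def$n_conversions
                   else nConversions,
    nAmplifications = if (is.null(nAmplifications)) def$n_amplifications
                      else nAmplifications,
    replicateNoiseSD = if (is.null(replicateNoiseSD))
                         def$replicate_noise_sd else replicateNoiseSD,
    conversionShift = if (is.null(conversionShift)) def$conversion_shift
                      else conversionShift,
    totalIntensityMean = if (is.null(totalIntensityMean))
                           def$total_intensity_mean else totalIntensityMean,
    totalIntensitySD = if (is.null(totalIntensitySD))
                         def$total_intensity_sd else totalIntensitySD,
    intensityNoiseCV = if (is.null(intensityNoiseCV))
                         def$intensity_noise_cv else intensityNoiseCV,
    saturationRFU = if (is.null(saturationRFU)) def$saturation_rfu
                    else saturationRFU,
    controlMethLevel = if (is.null(controlMethLevel))
                         def$control_meth_level else controlMethLevel,
    controlUnmethLevel = if (is.null(controlUnmethLevel))
                           def$control_unmeth_level else controlUnmethLevel,
    seed = as.integer(seed)
  )
  stopifnot(cfg$nSamples >= 1,
            cfg$ageRange[1] < cfg$ageRange[2],
            cfg$replicateNoiseSD >= 0, cfg$totalIntensitySD >= 0,
            cfg$intensityNoiseCV >= 0, cfg$saturationRFU > 0,
            all(cfg$loci$sigma >= 0),
            all(c("locus", "b0", "b1", "sigma") %in% names(cfg$loci)))
  structure(cfg, class = "syntheticConfig")
}

#' @export
print.syntheticConfig <- function(x, ...) {
  cat("syntheticConfig:", x$nSamples, "samples, ages",
      x$ageRange[1], "-", x$ageRange[2], "years,",
      x$nConversions, "x", x$nAmplifications, "replicates, seed",
      x$seed, "\n")
  print(x$loci, row.names = FALSE)
  invisible(x)
}

.clamp01 <- function(x) pmin(1, pmax(0, x))

#' Generate a synthetic cohort with true methylation levels
#'
#' Draws integer ages uniformly over the configured range, 50/50 sex,
#' and true per-locus methylation fractions \code{clamp01(b0 + b1*age +
#' Normal(0, sigma^2))}. The returned cohort's assay holds the true
#' (pre-measurement) levels; pass it to \code{\link{generatePeakTable}}
#' to add replicate and intensity noise. Generation is deterministic
#' given the config (including its seed) and leaves the global RNG state
#' untouched. A warning is raised if clamping at 0 or 1 affects more
#' than half the samples at any locus.
#'
#' @param config A \code{\link{syntheticConfig}}.
#' @return A \linkS4class{MethCohort}; \code{colData} carries
#'   \code{age_years} and \code{sex}.
#' @examples
#' generateCohort(syntheticConfig(nSamples = 6, seed = 11))
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "syntheticConfig"))
  n <- config$nSamples
  withSeed(config$seed, {
    age <- sample(seq(config$ageRange[1], config$ageRange[2]), n,
                  replace = TRUE)
    sex <- sample(rep_len(c("F", "M"), n))
    m <- matrix(NA_real_, nrow = nrow(config$loci), ncol = n,
                dimnames = list(config$loci$locus,
                                sprintf("S%03d", seq_len(n))))
    for (i in seq_len(nrow(config$loci))) {
      p <- config$loci[i, ]
      raw <- p$b0 + p$b1 * age + stats::rnorm(n, 0, p$sigma)
      clamped <- raw < 0 | raw > 1
      if (mean(clamped) > 0.5) {
        warning("locus ", p$locus, ": >50% of samples clamped to [0,1]; ",
                "check b0/b1/sigma")
      }
      m[i, ] <- .clamp01(raw)
    }
    MethCohort(m, age = age, sex = sex, loci = config$loci$locus)
  })
}

#' Generate a SNaPshot peak table for a cohort
#'
#' Emulates the measurement chain downstream of the true methylation
#' level. For every sample x conversion x amplification x locus, the
#' replicate-level methylation is the true level plus an optional
#' between-conversion shift and technical noise, clamped to [0, 1]; a
#' total two-channel intensity is drawn log-normally; each channel's
#' height is \code{round(min(saturation, share * T * (1 + eta)))} with
#' multiplicative noise \code{eta}. Heights land in the correct base
#' channels per locus chemistry (C/T or G/A); zero-height channels emit
#' no peak row, as in real electropherograms. Fully methylated and
#' unmethylated control samples (\code{CTRL_METH}, \code{CTRL_UNMETH})
#' are included by default. Deterministic given config (seeded
#' independently of \code{\link{generateCohort}}).
#'
#' @param cohort A \linkS4class{MethCohort} holding true levels.
#' @param config A \code{\link{syntheticConfig}}.
#' @param path Optional file path; when given the table is also written
#'   in the canonical dialect via \code{\link{writePeakTable}}.
#' @param includeControls Logical, include the two control samples.
#' @return A canonical peak \code{data.frame} (invisibly also written to
#'   \code{path} when given).
#' @examples
#' cfg <- syntheticConfig(nSamples = 3, seed = 2)
#' pk <- generatePeakTable(generateCohort(cfg), cfg)
#' head(pk)
#' @export
generatePeakTable <- function(cohort, config, path = NULL,
                              includeControls = TRUE) {
  stopifnot(is(cohort, "MethCohort"), inherits(config, "syntheticConfig"))
  defs <- snapshotLoci(rownames(cohort))
  truth <- methLevels(cohort)
  if (includeControls) {
    ctrl <- cbind(CTRL_METH = rep(config$controlMethLevel, nrow(truth)),
                  CTRL_UNMETH = rep(config$controlUnmethLevel, nrow(truth)))
    rownames(ctrl) <- rownames(truth)
    truth <- cbind(truth, ctrl)
  }
  grid <- expand.grid(
    locus = rownames(truth),
    amplification = seq_len(config$nAmplifications),
    conversion = seq_len(config$nConversions),
    sample_id = colnames(truth),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid <- grid[, c("sample_id", "conversion", "amplification", "locus")]
  nG <- nrow(grid)
  withSeed(config$seed + 1L, {
    trueLevel <- truth[cbind(grid$locus, grid$sample_id)]
    shift <- config$conversionShift * (grid$conversion - 1.5) * 2
    repLevel <- .clamp01(trueLevel + shift +
                           stats::rnorm(nG, 0, config$replicateNoiseSD))
    if (config$totalIntensitySD == 0) {
      total <- rep(config$totalIntensityMean, nG)
    } else {
      cv <- config$totalIntensitySD / config$totalIntensityMean
      sdlog <- sqrt(log(1 + cv^2))
      meanlog <- log(config$totalIntensityMean) - sdlog^2 / 2
      total <- stats::rlnorm(nG, meanlog, sdlog)
    }
    etaM <- stats::rnorm(nG, 0, config$intensityNoiseCV)
    etaU <- stats::rnorm(nG, 0, config$intensityNoiseCV)
    hMeth <- round(pmin(config$saturationRFU,
                        pmax(0, repLevel * total * (1 + etaM))))
    hUnmeth <- round(pmin(config$saturationRFU,
                          pmax(0, (1 - repLevel) * total * (1 + etaU))))
    di <- match(grid$locus, defs$locus)
    sizeMid <- round((defs$size_min[di] + defs$size_max[di]) / 2)
    mk <- function(base, h) {
      data.frame(sample_id = grid$sample_id, conversion = grid$conversion,
                 amplification = grid$amplification, locus = grid$locus,
                 base = base, height = h, area = round(h * 1.8),
                 size_nt = sizeMid, stringsAsFactors = FALSE)
    }
    peaks <- rbind(mk(defs$methylated_base[di], hMeth),
                   mk(defs$unmethylated_base[di], hUnmeth))
    peaks <- peaks[peaks$height > 0, , drop = FALSE]
    ord <- order(match(peaks$sample_id, colnames(truth)), peaks$conversion,
                 peaks$amplification, match(peaks$locus, defs$locus),
                 peaks$base)
    peaks <- peaks[ord, , drop = FALSE]
    rownames(peaks) <- NULL
    if (!is.null(path)) writePeakTable(peaks, path)
    peaks
  })
}

#' Simulate a full study to disk
#'
#' Generates a cohort and its peak table and writes four plain-text
#' artifacts into \code{dir}: \code{cohort_metadata.csv} (sample id,
#' age, sex), \code{truth_levels.csv} (true per-sample methylation
#' levels), \code{peak_table.csv} (canonical dialect, including
#' controls) and \code{sim_config.yaml} (the configuration used).
#'
#' @param dir Output directory, created if needed.
#' @param config A \code{\link{syntheticConfig}}.
#' @return Named list of the four file paths, invisibly; the generated
#'   \linkS4class{MethCohort} is attached as attribute \code{"cohort"}.
#' @export
simulateStudy <- function(dir, config = syntheticConfig()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generateCohort(config)
  paths <- list(
    metadata = file.path(dir, "cohort_metadata.csv"),
    truth = file.path(dir, "truth_levels.csv"),
    peaks = file.path(dir, "peak_table.csv"),
    config = file.path(dir, "sim_config.yaml")
  )
  meta <- data.frame(sample_id = colnames(cohort),
                     age_years = unname(ages(cohort)),
                     sex = SummarizedExperiment::colData(cohort)$sex,
                     stringsAsFactors = FALSE)
  utils::write.csv(meta, paths$metadata, row.names = FALSE, quote = FALSE)
  truthWide <- cbind(data.frame(sample_id = colnames(cohort),
                                stringsAsFactors = FALSE),
                     as.data.frame(t(methLevels(cohort))))
  utils::write.csv(truthWide, paths$truth, row.names = FALSE, quote = FALSE)
  generatePeakTable(cohort, config, path = paths$peaks)
  cfgOut <- unclass(config)
  cfgOut$loci <- split(cfgOut$loci[, c("b0", "b1", "sigma")],
                       cfgOut$loci$locus)
  cfgOut$loci <- lapply(cfgOut$loci, as.list)
  yaml::write_yaml(cfgOut, paths$config)
  out <- paths
  attr(out, "cohort") <- cohort
  invisible(out)
}

#' Write a QC report (homogeneity tests + control checks) as JSON
#'
#' @param homogeneity Output of \code{\link{cohortHomogeneity}}.
#' @param controls Output of \code{\link{checkControls}}.
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeQCReport <- function(homogeneity, controls, path) {
  obj <- list(
    conversion_homogeneity = homogeneity,
    control_checks = controls$checks,
    batch_passed = controls$batchPassed,
    flagged_loci = homogeneity$locus[!homogeneity$passed]
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}
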