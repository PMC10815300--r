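test_that("the built-in buccal model carries its six constants exactly", {
  m <- publishedModel()
  expect_identical(modelIntercept(m), 13.96381427)
  expect_identical(unname(coef(m)["ELOVL2"]), 50.04231273)
  expect_identical(unname(coef(m)["FHL2"]), -11.16979445)
  expect_identical(unname(coef(m)["KLF14"]), 73.87032325)
  expect_identical(unname(coef(m)["C1orf132"]), -49.27304295)
  expect_identical(unname(coef(m)["TRIM59"]), 84.17900486)
  expect_identical(names(coef(m)), locusOrder())
  expect_match(modelProvenance(m), "published")
})

test_that("prediction is the affine combination of levels", {
  m <- publishedModel()
  expect_identical(predictAge(m, profileOf(rep(0, 5))), 13.96381427)
  expect_equal(suppressMessages(predictAge(m, profileOf(rep(1, 5)))),
               161.61261771, tolerance = 1e-10)
  expect_equal(predictAge(m, profileOf(c(1, 0, 0, 0, 0))),
               64.00612700, tolerance = 1e-10)

  # profile order must not matter: levels are matched by locus name
  shuffled <- profileOf(c(0.5, 0.3, 0.2, 0.6, 0.4))[c(3, 1, 5, 2, 4)]
  expect_equal(predictAge(m, shuffled),
               predictAge(m, profileOf(c(0.5, 0.3, 0.2, 0.6, 0.4))))
})

test_that("prediction is affine in the profile", {
  m <- publishedModel()
  set.seed(3)
  for (i in 1:20) {
    p <- profileOf(runif(5)); q <- profileOf(runif(5))
    lam <- runif(1)
    expect_equal(predictAge(m, lam * p + (1 - lam) * q),
                 lam * predictAge(m, p) + (1 - lam) * predictAge(m, q))
  }
})

test_that("a missing predictor is an error naming the locus", {
  m <- publishedModel()
  p <- profileOf(rep(0.5, 5))
  expect_error(predictAge(m, p[-3]), "KLF14")
  p["FHL2"] <- NA
  expect_error(predictAge(m, p), "FHL2")
})

test_that("vector, matrix and cohort prediction agree", {
  m <- publishedModel()
  co <- linearCohort(n = 8)
  single <- vapply(seq_len(ncol(co)),
                   function(j) predictAge(m, methLevels(co)[, j]),
                   numeric(1))
  expect_equal(unname(predictAge(m, methLevels(co))), single)
  expect_equal(predictAge(m, co), predictAge(m, methLevels(co)))
})

test_that("implausible predictions are returned unclamped but messaged", {
  m <- publishedModel()
  p <- profileOf(c(0, 1, 0, 1, 0))  # -46.48 years
  expect_message(v <- predictAge(m, p), "outside 0-100")
  expect_lt(v, 0)
})

test_that("OLS fitting matches the normal-equations oracle", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    X <- matrix(runif(5 * n), nrow = 5,
                dimnames = list(locusOrder(), sprintf("s%02d", 1:n)))
    y <- runif(n, 20, 80)
    fit <- fitAgeModel(MethCohort(X, age = y))
    beta <- normalEquationsOracle(t(X), y)
    expect_true(agreesTo(modelIntercept(fit), beta[1], 8))
    expect_true(agreesTo(unname(coef(fit)), unname(beta[-1]), 8))
  }
})

test_that("fitting noiseless model-generated ages recovers the generator", {
  set.seed(23)
  n <- 10
  X <- matrix(runif(5 * n, 0.2, 0.8), nrow = 5,
              dimnames = list(locusOrder(), sprintf("s%02d", 1:n)))
  truth <- publishedModel()
  y <- unname(predictAge(truth, X))
  fit <- fitAgeModel(MethCohort(X, age = y))
  expect_lt(abs(modelIntercept(fit) - modelIntercept(truth)), 1e-8)
  expect_lt(max(abs(coef(fit) - coef(truth))), 1e-8)
})

test_that("training-set residuals of a fitted model sum to zero", {
  co <- generateCohort(syntheticConfig(nSamples = 30, seed = 31))
  fit <- fitAgeModel(co)
  r <- predictAge(fit, co) - ages(co)
  expect_lt(abs(sum(r)), 1e-8 * ncol(co))
})

test_that("degenerate designs are refused with informative errors", {
  X <- matrix(runif(30), nrow = 5, dimnames = list(locusOrder(), NULL))
  expect_error(fitAgeModel(MethCohort(X, age = runif(6, 20, 70))),
               "insufficient data")

  # one locus duplicated across two rows for every sample: rank-deficient
  n <- 12
  X <- matrix(runif(5 * n), nrow = 5, dimnames = list(locusOrder(), NULL))
  X["FHL2", ] <- X["ELOVL2", ]
  expect_error(fitAgeModel(MethCohort(X, age = runif(n, 20, 70))),
               "singular fit")
})

test_that("samples with incomplete profiles are excluded with a message", {
  n <- 12
  X <- matrix(runif(5 * n, 0.2, 0.8), nrow = 5,
              dimnames = list(locusOrder(), sprintf("s%02d", 1:n)))
  X["KLF14", 1:2] <- NA
  co <- MethCohort(X, age = runif(n, 20, 70))
  expect_message(fit <- fitAgeModel(co), "excluded 2")
  expect_match(modelProvenance(fit), "n=10")
})

test_that("splitCohort gives a seeded, disjoint, exhaustive partition", {
  co <- generateCohort(syntheticConfig(nSamples = 60, seed = 5))
  parts <- splitCohort(co, 0.5, seed = 42)
  expect_equal(ncol(parts$training), 30)
  expect_equal(ncol(parts$test), 30)
  expect_length(intersect(colnames(parts$training),
                          colnames(parts$test)), 0)
  expect_setequal(c(colnames(parts$training), colnames(parts$test)),
                  colnames(co))

  again <- splitCohort(co, 0.5, seed = 42)
  expect_identical(colnames(again$training), colnames(parts$training))
  other <- splitCohort(co, 0.5, seed = 43)
  expect_false(identical(colnames(other$training),
                         colnames(parts$training)))

  small <- splitCohort(co[, 1:5], 0.5, seed = 1)
  expect_equal(ncol(small$training), 3)
  expect_equal(ncol(small$test), 2)
})

test_that("splitting does not disturb the global RNG stream", {
  co <- generateCohort(syntheticConfig(nSamples = 10, seed = 5))
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(splitCohort(co, 0.5, seed = 7))
  expect_identical(runif(1), before)
})

test_that("model JSON round-trips bit-exactly with printed decimals", {
  path <- withr::local_tempfile(fileext = ".json")
  writeAgeModel(publishedModel(), path)
  txt <- paste(readLines(path), collapse = "\n")
  # the printed constants appear verbatim, not as noisy 17-digit floats
  expect_match(txt, "50.04231273", fixed = TRUE)
  expect_match(txt, "-11.16979445", fixed = TRUE)
  expect_match(txt, "13.96381427", fixed = TRUE)

  back <- readAgeModel(path)
  expect_identical(modelIntercept(back), modelIntercept(publishedModel()))
  expect_identical(coef(back), coef(publishedModel()))

  # fitted (non-terminating decimal) coefficients also round-trip exactly
  fit <- fitAgeModel(generateCohort(syntheticConfig(nSamples = 20,
                                                    seed = 3)))
  writeAgeModel(fit, path)
  back <- readAgeModel(path)
  expect_identical(coef(back), coef(fit))
  expect_identical(modelIntercept(back), modelIntercept(fit))
})

test_that("AgeModel construction enforces the locus contract", {
  expect_error(AgeModel(1, c(A = 1, B = 2)), "cover exactly")
  expect_error(AgeModel(1, rep(1, 5)), "named")
  cfs <- stats::setNames(1:5 * 1.0, locusOrder())
  m <- AgeModel(0, cfs[c(5, 3, 1, 2, 4)])  # order normalised on input
  expect_identical(names(coef(m)), locusOrder())
})
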