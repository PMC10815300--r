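# shared fixtures and independent oracles

# a named five-locus profile
profileOf <- function(values) {
  stats::setNames(values, locusOrder())
}

# canonical peak rows for one locus measurement
peakRows <- function(locus, bases, heights, sample_id = "s1",
                     conversion = 1L, amplification = 1L, size_nt = NA_real_,
                     area = NA_real_) {
  data.frame(sample_id = sample_id, conversion = conversion,
             amplification = amplification, locus = locus, base = bases,
             height = heights, area = area, size_nt = size_nt,
             stringsAsFactors = FALSE)
}

# textbook pooled-variance two-sample two-tailed t-test (oracle)
pooledTOracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / df
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

# direct-formula Pearson correlation (oracle)
pearsonOracle <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# brute-force normal-equations OLS with intercept (oracle)
normalEquationsOracle <- function(X, y) {
  Xi <- cbind(1, X)
  drop(solve(crossprod(Xi), crossprod(Xi, y)))
}

# agreement to at least `digits` significant digits
agreesTo <- function(a, b, digits) {
  all(abs(a - b) <= 10^(-digits) * pmax(abs(b), 1e-12))
}

# a small cohort with exactly linear (noise-free) level-age structure
linearCohort <- function(n = 12, seed = 99) {
  set.seed(seed)
  age <- seq(25, 68, length.out = n)
  m <- matrix(NA_real_, 5, n, dimnames = list(locusOrder(), NULL))
  slopes <- c(0.004, 0.002, 0.004, -0.004, 0.004)
  b0 <- c(0.35, 0.25, 0.10, 0.80, 0.20)
  for (i in 1:5) m[i, ] <- b0[i] + slopes[i] * age
  colnames(m) <- sprintf("L%02d", seq_len(n))
  MethCohort(m, age = age)
}
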