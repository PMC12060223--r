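# small synthetic feature tables with a known generative model
makeFeatureData <- function(n = 12, k = 5, beta = c(x1 = 2), sigma = 0.05,
                            seed = 1, intercept = 40) {
  set.seed(seed)
  X <- matrix(rnorm(n * k), n, k)
  colnames(X) <- paste0("x", seq_len(k))
  y <- intercept + as.numeric(X[, names(beta), drop = FALSE] %*% beta) +
    rnorm(n, 0, sigma)
  data.frame(subject = sprintf("S%02d", seq_len(n)), X, ulFMA = y,
             check.names = FALSE)
}

test_that("the feature table has one row per subject and ordered columns", {
  chans <- c("C3", "C4", "CP4")
  mkNodes <- function(seed) {
    set.seed(seed)
    data.frame(node = chans, degree = sample(3:9, 3), nodal_efficiency = 0.5,
               local_efficiency = runif(3, 0.3, 0.9),
               clustering = runif(3, 0.2, 0.8))
  }
  subjects <- sprintf("S%02d", 1:11)
  gn <- setNames(lapply(seq_along(subjects), function(i)
    list(pre = mkNodes(i), post = mkNodes(i + 100))), subjects)
  em <- setNames(lapply(seq_along(subjects), function(i) {
    set.seed(i + 200)
    data.frame(channel = chans, pre = 1, post = 1, erd = rnorm(3, -20, 5))
  }), subjects)
  outcomes <- setNames(runif(11, 20, 60), subjects)
  ft <- buildFeatures(gn, em, outcomes, channels = chans)
  expect_equal(dim(ft), c(11, 1 + 4 * 3 + 1))
  expect_equal(names(ft)[2:13],
               c(sprintf("DC(%s)", chans), sprintf("LE(%s)", chans),
                 sprintf("CC(%s)", chans), sprintf("ERD(%s)", chans)))
  ## identical call gives identical column ordering and values
  expect_identical(ft, buildFeatures(gn, em, outcomes, channels = chans))
  ## a zero pre-task metric is a hard error naming subject and channel
  gn2 <- gn
  gn2[["S03"]]$pre$clustering[2] <- 0
  expect_error(buildFeatures(gn2, em, outcomes, channels = chans),
               "S03.*C4")
  ## a missing channel is a hard error listing the gap
  em2 <- em
  em2[["S05"]] <- em2[["S05"]][-2, ]
  expect_error(buildFeatures(gn, em2, outcomes, channels = chans), "C4")
})

test_that("stepwise selection recovers a planted linear effect", {
  d <- makeFeatureData(n = 14, k = 5, beta = c(x1 = 2), sigma = 0.05,
                       seed = 2)
  fit <- stepwiseSelect(d)
  expect_true("x1" %in% fit$terms)
  co <- fit$coefficients
  i <- match("x1", co$term)
  ci <- co$beta[i] + c(-2, 2) * co$se[i]
  expect_gt(2, ci[1])
  expect_lt(2, ci[2] + 1e-12)
  ## standardized coefficient identity: b_std = b * sd(x) / sd(y)
  expect_equal(co$std_beta[i], co$beta[i] * sd(d$x1) / sd(d$ulFMA),
               tolerance = 1e-12)
})

test_that("stepwise selection is calibrated under the null", {
  ## with k independent null candidates the chance of any entry is bounded
  ## by the family-wise rate 1 - (1 - alpha)^k; with a single candidate it
  ## is the per-test alpha
  hits4 <- 0L; hits1 <- 0L
  for (s in 1:200) {
    d <- makeFeatureData(n = 12, k = 4, beta = c(x1 = 0), sigma = 1,
                         seed = 1000 + s)
    if (length(stepwiseSelect(d, scope = "linear")$terms) > 0)
      hits4 <- hits4 + 1L
    d1 <- d[, c("subject", "x1", "ulFMA")]
    if (length(stepwiseSelect(d1, scope = "linear")$terms) > 0)
      hits1 <- hits1 + 1L
  }
  ## binomial bounds: 200 * (1 - 0.95^4) + 3 SE, and 200 * 0.05 + 3 SE
  expect_lte(hits4, ceiling(200 * (1 - 0.95^4) + 3 * sqrt(200 * 0.185 * 0.815)))
  expect_lte(hits1, ceiling(200 * 0.05 + 3 * sqrt(200 * 0.05 * 0.95)))
})

test_that("quadratic scope can discover squared and product terms", {
  set.seed(3)
  n <- 20
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  y <- 10 + 3 * x1^2 + rnorm(n, 0, 0.05)
  d <- data.frame(subject = as.character(1:n), x1, x2, x3, ulFMA = y)
  fit <- stepwiseSelect(d)
  expect_true("x1^2" %in% fit$terms)
  y2 <- 5 + 4 * x1 * x2 + rnorm(n, 0, 0.05)
  d2 <- data.frame(subject = as.character(1:n), x1, x2, x3, ulFMA = y2)
  fit2 <- stepwiseSelect(d2)
  expect_true("x1*x2" %in% fit2$terms)
})

test_that("zero-variance candidates are excluded with a warning", {
  d <- makeFeatureData(n = 12, k = 3, beta = c(x1 = 2), sigma = 0.05,
                       seed = 4)
  d$flat <- 7
  expect_warning(fit <- stepwiseSelect(d), "zero-variance")
  expect_true("x1" %in% fit$terms)
  expect_false(any(grepl("flat", fit$terms)))
})

test_that("LOO prediction is exact on noiseless linear data", {
  d <- makeFeatureData(n = 10, k = 3, beta = c(x1 = 2, x2 = -1), sigma = 0,
                       seed = 5)
  pr <- looPredict(d, c("x1", "x2"))
  m <- predictionSummary(pr)
  expect_lt(m[["rmse_n"]], 1e-8)
  expect_equal(m[["correlation"]], 1, tolerance = 1e-8)
  expect_equal(m[["r2"]], 1, tolerance = 1e-8)
  expect_equal(nrow(predictionTable(pr)), 10)
  expect_match(pr@formula, "x1")
})

test_that("LOO prediction error shrinks as outcome noise vanishes", {
  rmses <- vapply(c(2, 0.5, 0.05), function(sig) {
    d <- makeFeatureData(n = 12, k = 3, beta = c(x1 = 2), sigma = sig,
                         seed = 6)
    predictionSummary(looPredict(d, "x1"))[["rmse_n"]]
  }, numeric(1))
  expect_true(all(diff(rmses) < 0))
  expect_lt(rmses[3], 0.1)
})

test_that("prediction metrics match their definitions", {
  a <- c(31, 56, 44, 52, 32)
  p <- c(30, 54, 45, 51, 33)
  m <- predictionMetrics(a, p, nPredictors = 1)
  e <- a - p
  expect_equal(m[["rmse_n"]], sqrt(mean(e^2)))
  expect_equal(m[["rmse_n1"]], sqrt(sum(e^2) / 4))
  expect_equal(m[["r2"]], 1 - sum(e^2) / sum((a - mean(a))^2))
  expect_equal(m[["adj_r2"]], 1 - (1 - m[["r2"]]) * 4 / 3)
  expect_equal(m[["correlation"]], cor(a, p))
  expect_equal(unname(predictionMetrics(a, a)[c(1, 3, 5)]), c(0, 1, 1))
  expect_error(predictionMetrics(a, rep(40, 5)), "constant")
  expect_error(predictionMetrics(a, p[1:4]), "mismatch")
})

test_that("bootstrap stability flags a strong planted feature", {
  d <- makeFeatureData(n = 11, k = 4, beta = c(x1 = 2), sigma = 0.1,
                       seed = 7)
  bs <- bootstrapStability(d, runs = 200, seed = 8, scope = "linear")
  f1 <- bs$frequency[bs$term == "x1"]
  expect_gt(f1, 0.8)
  ## the planted feature tops the stability ranking
  expect_equal(bs$term[1], "x1")
  ## deterministic for a fixed seed
  bs2 <- bootstrapStability(d, runs = 200, seed = 8, scope = "linear")
  expect_identical(bs, bs2)
  ## pure-noise features never reach planted-level stability (resampling
  ## with replacement at small n makes entry anti-conservative, so null
  ## frequencies sit well above the nominal alpha but far below a real
  ## effect)
  dn <- makeFeatureData(n = 11, k = 4, beta = c(x1 = 0), sigma = 1, seed = 9)
  bsn <- bootstrapStability(dn, runs = 200, seed = 10, scope = "linear")
  if (nrow(bsn) > 0) expect_lt(max(bsn$frequency), 0.6)
})

test_that("model formulas are rendered in the plain-text grammar", {
  expect_equal(modelFormula(character(0)), "y ~ 1")
  expect_equal(modelFormula(c("DC(C4)", "CC(C4)^2", "ERD(C2)*ERD(C4)"),
                            "ulFMA"),
               "ulFMA ~ 1 + DC(C4) + CC(C4)^2 + ERD(C2)*ERD(C4)")
})
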