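test_that("task-related activity is the percent pre-to-post change", {
  expect_equal(taskRelatedActivity(10, 15), 50)
  expect_equal(taskRelatedActivity(7, 7), 0)
  expect_equal(taskRelatedActivity(0.08, 0.02), -75)
  ## scale invariance
  set.seed(30)
  pre <- runif(20, 0.1, 2); post <- runif(20, 0.1, 2)
  for (c0 in c(-3, 0.01, 1e4))
    expect_equal(taskRelatedActivity(c0 * pre, c0 * post),
                 taskRelatedActivity(pre, post), tolerance = 1e-12)
  expect_error(taskRelatedActivity(0, 5), "undefined contrast")
  expect_error(taskRelatedActivity(1:3, 1:2), "length")
})

test_that("ERD reflects amplitude halving of band power", {
  ## post amplitude = pre / sqrt(2) -> power halves -> ERD = -50%
  fs <- 256; ns <- 640; nt <- 30
  set.seed(31)
  arr <- array(rnorm(nt * 2 * ns, 0, 0.02), dim = c(nt, 2, ns))
  tt <- ((1:ns) - 257) / fs
  postMask <- tt >= 0.25 & tt < 1.25
  for (tr in seq_len(nt)) {
    f <- runif(1, 14, 29); th <- runif(1, 0, 2 * pi)
    amp <- ifelse(postMask, 1 / sqrt(2), 1)
    arr[tr, 1, ] <- arr[tr, 1, ] + amp * cos(2 * pi * f * tt + th)
    arr[tr, 2, ] <- arr[tr, 2, ] + cos(2 * pi * f * tt + th)
  }
  em <- erd(makeEpochs(arr, fs), c(13, 30))
  expect_lt(abs(em$erd[1] - (-50)), 4)
  ## stationary signal -> ERD ~ 0
  expect_lt(abs(em$erd[2]), 4)
})

test_that("ERD is band-selective: out-of-band noise does not shift it", {
  fs <- 256; ns <- 640; nt <- 30
  set.seed(32)
  tt <- ((1:ns) - 257) / fs
  postMask <- tt >= 0.25 & tt < 1.25
  base <- array(0, dim = c(nt, 1, ns))
  noisy <- base
  for (tr in seq_len(nt)) {
    f <- runif(1, 14, 29); th <- runif(1, 0, 2 * pi)
    sig <- cos(2 * pi * f * tt + th)
    base[tr, 1, ] <- sig + 0.02 * rnorm(ns)
    ## strong 45 Hz tone added only in the post window, outside beta
    noisy[tr, 1, ] <- base[tr, 1, ] +
      2 * postMask * cos(2 * pi * 45 * tt + th)
  }
  e1 <- erd(makeEpochs(base, fs), c(13, 30))$erd
  e2 <- erd(makeEpochs(noisy, fs), c(13, 30))$erd
  expect_lt(abs(e2 - e1), 5)
})

test_that("rank-sum matches the exactly enumerated worked case", {
  rs <- rankSum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$p.value, 0.1)           # 2/20 arrangements as extreme
  expect_equal(rankSum(c(1, 2, 3), c(1, 2, 3), mode = "approx")$p.value, 1,
               tolerance = 1e-9)
  ## label swap leaves p unchanged
  set.seed(33)
  x <- rnorm(8); y <- rnorm(8) + 1
  expect_equal(rankSum(x, y)$p.value, rankSum(y, x)$p.value)
  expect_warning(p1 <- rankSum(rep(2, 5), rep(2, 4))$p.value, "identical")
  expect_equal(p1, 1)
  expect_error(rankSum(numeric(0), 1:3), "nonempty")
})

test_that("exact and approximate rank-sum p-values agree closely at n = 10", {
  set.seed(34)
  for (rep in 1:20) {
    x <- rnorm(10); y <- rnorm(10, 0.5)
    pe <- rankSum(x, y, mode = "exact")$p.value
    pa <- rankSum(x, y, mode = "approx")$p.value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("Spearman correlation handles the worked case and degenerate input", {
  expect_equal(spearmanCorr(1:5, c(1, 3, 2, 5, 4))$rho, 0.8)
  expect_equal(spearmanCorr(1:6, (1:6)^3)$rho, 1)     # monotone increasing
  expect_equal(spearmanCorr(1:6, -(1:6)^3)$rho, -1)   # monotone decreasing
  expect_error(spearmanCorr(rep(1, 5), 1:5), "constant")
  expect_error(spearmanCorr(1:2, 1:2), "at least 3")
})

test_that("ANCOVA removes group differences carried by the covariate", {
  ## post = pre + noise, groups differ only through pre; the noise is
  ## orthogonalized against the group so nothing is left for the group
  ## factor after covariate adjustment
  set.seed(36)
  g <- rep(c("a", "b"), each = 10)
  pre <- c(rnorm(10, 0), rnorm(10, 3))
  M <- cbind(1, as.numeric(g == "b"), pre)
  eps <- rnorm(20, 0, 0.3)
  eps <- eps - M %*% solve(crossprod(M), crossprod(M, eps))
  post <- pre + as.numeric(eps)
  res <- ancovaGroupEffect(post, g, pre)
  expect_lt(res$F, 1e-18)
  expect_gt(res$p.value, 0.999)
})

test_that("with an orthogonal covariate the group sum of squares matches one-way ANOVA", {
  ## covariate constructed orthogonal to intercept, group and response:
  ## the Type II group SS then equals the one-way between-group SS
  set.seed(35)
  n <- 12
  g <- rep(c("a", "b"), each = n / 2)
  y <- rnorm(n) + 2 * (g == "b")
  ## build x orthogonal to 1, the group indicator and y
  M <- cbind(1, as.numeric(g == "b"), y)
  x <- rnorm(n)
  x <- x - M %*% solve(crossprod(M), crossprod(M, x))
  res <- ancovaGroupEffect(y, g, as.numeric(x))
  a1 <- anova(lm(y ~ factor(g)))
  ssGroup <- a1$`Sum Sq`[1]
  rssFull <- sum(residuals(lm(y ~ factor(g) + as.numeric(x)))^2)
  expect_equal(res$F, (ssGroup / 1) / (rssFull / (n - 3)), tolerance = 1e-9)
  ## and the F only differs from one-way by the residual-df bookkeeping
  expect_equal(res$F * (rssFull / (n - 3)), a1$`F value`[1] *
                 (a1$`Sum Sq`[2] / a1$Df[2]), tolerance = 1e-9)
})

test_that("ANCOVA rejects degenerate designs", {
  y <- rnorm(10)
  g <- rep(c("a", "b"), each = 5)
  expect_error(ancovaGroupEffect(y, rep("a", 10), rnorm(10)), "2 groups")
  expect_error(ancovaGroupEffect(y, g, c(rep(0, 5), rep(1, 5))),
               "degenerate|aliased|collinear")
})

test_that("threshold scan recovers a planted group difference in network structure", {
  ## stroke subjects get a post-window hub: reliable lagged couplings from C4
  ## to every other channel. Proportional thresholding fixes the edge count,
  ## so the group difference appears as topology: the stroke post-task graphs
  ## are star-connected (high global efficiency) at moderate thresholds while
  ## control graphs of equal density are random and often fragmented.
  chans <- c("C1", "C2", "C3", "C4", "CP3", "CP4", "FC3", "FC4")
  hub <- setdiff(chans, "C4")
  spec <- cohortSpec(nSubjectsPerGroup = 5,
                     channels = chans,
                     nTrials = 24, epochWindow = c(-1, 1.5), seed = 51,
                     plantedEdges = plantedEdge(rep("C4", 7), hub, "beta",
                                                pi / 2, 0.9, "post",
                                                "stroke"),
                     subjectSD = 0.05)
  co <- generateCohort(spec)
  icoh <- lapply(co, function(s) icohMatrices(subjectEpochs(s)))
  scanIn <- lapply(icoh, function(x) list(pre = x$pre$beta,
                                          post = x$post$beta))
  groups <- vapply(co, subjectGroup, "")
  res <- thresholdScan(scanIn, groups, fractions = seq(0.05, 0.9, 0.05))
  expect_false(is.na(res$selected))
  expect_lt(res$selectedP, 0.05)
  ## stroke task-related global efficiency exceeds control at the selection
  k <- which.min(abs(res$table$fraction - res$selected))
  expect_gt(res$table$mean_stroke[k], res$table$mean_control[k])
})

test_that("the tidy stats table assembles rows faithfully", {
  tab <- statsTable("rank_sum", "beta", "C4", 12, 0.03, 10)
  expect_equal(names(tab),
               c("analysis", "band", "channel", "statistic", "p",
                 "n_per_group"))
  expect_equal(nrow(tab), 1)
})
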