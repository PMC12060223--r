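#' @include AllClasses.R
NULL

#' Task-related activity
#'
#' Percent change of a metric from the pre-task to the post-task window:
#' (post - pre) / pre * 100. Scale-invariant; undefined when the pre value is
#' zero, which raises an error (the caller excludes that contrast).
#'
#' @param pre,post numeric values (vectorized).
#' @return percent change, same length as the inputs.
#' @export
#' @examples
#' taskRelatedActivity(10, 15)   # +50
taskRelatedActivity <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre and post lengths differ")
  if (any(pre == 0))
    stop("undefined contrast: pre-task value is zero at position(s) ",
         paste(which(pre == 0), collapse = ", "))
  (post - pre) / pre * 100
}

## mean short-time band power of one signal: Hann frames, 50% overlap
.stftBandPower <- function(x, fs, band, winSec = 0.5, overlap = 0.5) {
  nwin <- as.integer(round(winSec * fs))
  hop <- max(1L, as.integer(round(nwin * (1 - overlap))))
  n <- length(x)
  if (n < nwin) stop("window shorter than the STFT frame")
  starts <- seq(1L, n - nwin + 1L, by = hop)
  w <- .hann(nwin)
  freqs <- (seq_len(nwin %/% 2L + 1L) - 1) * fs / nwin
  bins <- which(freqs >= band[1] & freqs <= band[2])
  if (length(bins) == 0L) stop("no STFT bins inside the band")
  pw <- vapply(starts, function(s0) {
    X <- stats::fft(x[s0:(s0 + nwin - 1L)] * w)
    sum(Mod(X[bins])^2)
  }, numeric(1))
  mean(pw)
}

#' Event-related desynchronization/synchronization map
#'
#' Trial-averaged band power from Hann-windowed short-time spectra (0.5 s
#' frames, 50% overlap) in the post-task window, expressed as percent change
#' relative to the pre-task baseline window (-1 to 0 s by default): negative
#' values are ERD (power suppression), positive ERS.
#'
#' @param e an [EpochSet-class].
#' @param band numeric `c(low, high)` in Hz.
#' @param winSec STFT frame length in seconds.
#' @param overlap frame overlap fraction.
#' @return data.frame (channel, pre, post, erd) with one row per channel.
#' @export
erd <- function(e, band, winSec = 0.5, overlap = 0.5) {
  stopifnot(is(e, "EpochSet"))
  wins <- extractWindows(e)
  fs <- samplingRate(e)
  nch <- dim(wins$pre)[2]
  pre <- post <- numeric(nch)
  for (ch in seq_len(nch)) {
    pre[ch] <- mean(apply(wins$pre[, ch, , drop = FALSE], 1, .stftBandPower,
                          fs = fs, band = band, winSec = winSec,
                          overlap = overlap))
    post[ch] <- mean(apply(wins$post[, ch, , drop = FALSE], 1, .stftBandPower,
                           fs = fs, band = band, winSec = winSec,
                           overlap = overlap))
  }
  if (any(pre == 0))
    stop("undefined contrast: zero baseline band power on channel(s) ",
         paste(channelNames(e)[pre == 0], collapse = ", "))
  data.frame(channel = channelNames(e), pre = pre, post = post,
             erd = (post - pre) / pre * 100, stringsAsFactors = FALSE)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null enumeration when both samples have at most 10 observations and
#' no ties; normal approximation with tie and continuity correction
#' otherwise. When every value in both samples is identical the test carries
#' no information and p = 1 is returned with a warning.
#'
#' @param x,y nonempty numeric samples.
#' @param mode "auto" (default), "exact" or "approx".
#' @return list(statistic, p.value); the statistic is the Mann-Whitney U of
#'   `x`.
#' @export
#' @examples
#' rankSum(c(1, 2, 3), c(4, 5, 6))$p.value   # exact 0.1
rankSum <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be nonempty")
  if (length(unique(c(x, y))) == 1L) {
    warning("all values identical across both samples; p = 1")
    return(list(statistic = length(x) * length(y) / 2, p.value = 1))
  }
  hasTies <- anyDuplicated(c(x, y)) > 0L
  exact <- switch(mode,
                  auto = length(x) <= 10L && length(y) <= 10L && !hasTies,
                  exact = TRUE, approx = FALSE)
  if (exact && hasTies) {
    warning("ties present; falling back to the normal approximation")
    exact <- FALSE
  }
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Spearman rank correlation
#'
#' Rank correlation with tie handling; the p-value is exact for n <= 9
#' without ties and a t-approximation otherwise.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list(rho, p.value).
#' @export
#' @examples
#' spearmanCorr(1:5, c(1, 3, 2, 5, 4))$rho   # 0.8
spearmanCorr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rho undefined for constant input")
  hasTies <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = length(x) <= 9L && !hasTies))
  list(rho = unname(ht$estimate), p.value = ht$p.value)
}

#' ANCOVA group effect with a pre-task covariate
#'
#' F-test of the group factor in post ~ group + pre, Type II sums of squares:
#' the group effect is assessed after statistically controlling for the
#' pre-task covariate.
#'
#' @param post numeric response (post-task values).
#' @param group group labels (two or more levels).
#' @param pre numeric covariate (pre-task values).
#' @return list(F, p.value, df).
#' @export
ancovaGroupEffect <- function(post, group, pre) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (length(post) != length(group) || length(post) != length(pre))
    stop("input lengths differ")
  df <- data.frame(y = post, g = group, x = pre)
  fit <- stats::lm(y ~ g + x, data = df)
  if (any(is.na(stats::coef(fit))))
    stop("degenerate design: collinear covariate or aliased group effect")
  if (fit$df.residual < 1L) stop("no residual degrees of freedom")
  aov2 <- car::Anova(fit, type = 2)
  i <- match("g", rownames(aov2))
  list(F = aov2$`F value`[i], p.value = aov2$`Pr(>F)`[i],
       df = c(aov2$Df[i], fit$df.residual))
}

#' Group threshold scan over proportional network densities
#'
#' For every threshold fraction, computes each subject's task-related global
#' efficiency (percent change of post-window vs pre-window global efficiency
#' of the graph retaining that fraction of top-|iCOH| edges) and the
#' two-sided rank-sum p-value between groups. The selected threshold is the
#' significant (p < 0.05) fraction with the smallest p; if none is
#' significant the selection is empty. Subjects with zero pre-window global
#' efficiency at a fraction are excluded from that fraction's contrast.
#'
#' @param subjects list of `list(pre = matrix, post = matrix)` iCOH matrices,
#'   one entry per subject.
#' @param groups character vector of group labels ("stroke"/"control"),
#'   parallel to `subjects`; at least 2 subjects per group.
#' @param fractions thresholds to scan; default 1% to 90% in 1% steps.
#' @param alpha significance level for selection.
#' @return list with `table` (fraction, p, mean per group), `selected`
#'   (fraction or NA), `selectedP`, and `activity` (subjects x fractions
#'   matrix of task-related global efficiency).
#' @export
thresholdScan <- function(subjects, groups,
                          fractions = seq(0.01, 0.90, by = 0.01),
                          alpha = 0.05) {
  groups <- as.character(groups)
  if (length(subjects) != length(groups))
    stop("subjects and groups lengths differ")
  if (any(table(groups) < 2L)) stop("need at least 2 subjects per group")
  ns <- length(subjects)
  act <- matrix(NA_real_, ns, length(fractions))
  for (s in seq_len(ns)) {
    for (k in seq_along(fractions)) {
      gPre <- globalEfficiency(
        thresholdTopFraction(subjects[[s]]$pre, fractions[k]))$global
      gPost <- globalEfficiency(
        thresholdTopFraction(subjects[[s]]$post, fractions[k]))$global
      if (gPre > 0) act[s, k] <- (gPost - gPre) / gPre * 100
    }
  }
  grpLevels <- unique(groups)
  tab <- data.frame(fraction = fractions, p = NA_real_,
                    mean_g1 = NA_real_, mean_g2 = NA_real_)
  names(tab)[3:4] <- paste0("mean_", grpLevels[1:2])
  for (k in seq_along(fractions)) {
    a1 <- act[groups == grpLevels[1], k]
    a2 <- act[groups == grpLevels[2], k]
    a1 <- a1[!is.na(a1)]; a2 <- a2[!is.na(a2)]
    if (length(a1) >= 2L && length(a2) >= 2L) {
      ## degenerate fractions (e.g. identical complete graphs pre and post)
      ## legitimately yield all-equal activities; rankSum's p = 1 is wanted
      ## without per-fraction warnings
      tab$p[k] <- suppressWarnings(rankSum(a1, a2)$p.value)
      tab[k, 3] <- mean(a1)
      tab[k, 4] <- mean(a2)
    }
  }
  sig <- which(!is.na(tab$p) & tab$p < alpha)
  sel <- if (length(sig)) sig[which.min(tab$p[sig])] else NA_integer_
  list(table = tab,
       selected = if (is.na(sel)) NA_real_ else fractions[sel],
       selectedP = if (is.na(sel)) NA_real_ else tab$p[sel],
       activity = act)
}

#' Tidy statistical-output table
#'
#' Assembles (analysis, band, channel, statistic, p, n_per_group) rows, the
#' package's export format for test results.
#'
#' @param analysis,band,channel,statistic,p,nPerGroup vectors of equal
#'   length.
#' @return data.frame.
#' @export
statsTable <- function(analysis, band, channel, statistic, p, nPerGroup) {
  data.frame(analysis = analysis, band = band, channel = channel,
             statistic = statistic, p = p, n_per_group = nPerGroup,
             stringsAsFactors = FALSE)
}
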