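#' @include AllClasses.R
NULL

#' Standard 64-channel montage labels
#'
#' The 10-10 labels of the 64-channel active-electrode layout used for the
#' grasp-task recordings (A1-B32 geometry). Left-hemisphere labels carry odd
#' digits, right-hemisphere labels even digits, midline labels end in "z".
#'
#' @return character vector of 64 unique channel labels.
#' @export
#' @examples
#' head(montage64())
montage64 <- function() {
  c("Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3", "FC1",
    "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1", "P3", "P5",
    "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz", "Pz", "CPz", "Fpz",
    "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4", "F6", "F8", "FT8", "FC6",
    "FC4", "FC2", "FCz", "Cz", "C2", "C4", "C6", "T8", "TP8", "CP6", "CP4",
    "CP2", "P2", "P4", "P6", "P8", "P10", "PO8", "PO4", "O2")
}

#' Default sensorimotor frequency bands
#'
#' Alpha 8-13 Hz and beta 13-30 Hz, the standard sensorimotor conventions.
#'
#' @return data.frame with columns name, low, high.
#' @export
defaultBands <- function() {
  data.frame(name = c("alpha", "beta"), low = c(8, 13), high = c(13, 30),
             stringsAsFactors = FALSE)
}

#' Planted-feature labels
#'
#' Labels identifying planted generative features: a phase-lagged coupling is
#' `icoh:<chi>-<chj>:<band>`, an ERD effect is `erd:<channel>:<band>`. The
#' outcome model's coefficient names use these labels.
#'
#' @param chi,chj,channel channel labels.
#' @param band band name.
#' @return character label.
#' @export
edgeFeatureLabel <- function(chi, chj, band) sprintf("icoh:%s-%s:%s", chi, chj, band)

#' @rdname edgeFeatureLabel
#' @export
erdFeatureLabel <- function(channel, band) sprintf("erd:%s:%s", channel, band)

#' Build a planted-edge table
#'
#' @param chi,chj channel labels of the coupled pair.
#' @param band band name the coupling lives in.
#' @param phase phase lag in radians (0 = instantaneous mixing, which iCOH
#'   must not detect).
#' @param strength coupling strength in [0, 1] (amplitude of the delayed copy).
#' @param window "pre", "post" or "both".
#' @param group "both", "stroke" or "control" (plants group differences in
#'   network structure).
#' @return data.frame suitable for the `plantedEdges` slot.
#' @export
plantedEdge <- function(chi, chj, band, phase, strength, window = "both",
                        group = "both") {
  k <- length(chi)
  data.frame(chi = chi, chj = chj, band = band, phase = phase,
             strength = strength, window = rep_len(window, k),
             group = rep_len(group, k), stringsAsFactors = FALSE)
}

#' Build an ERD-effect table
#'
#' @param channel channel carrying the effect.
#' @param band band name.
#' @param ratio post/pre band-power ratio (> 0; < 1 is desynchronization).
#' @param group "both", "stroke" or "control".
#' @return data.frame suitable for the `erdEffects` slot.
#' @export
erdEffect <- function(channel, band, ratio, group = "both") {
  data.frame(channel = channel, band = band, ratio = ratio,
             group = rep_len(group, length(channel)),
             stringsAsFactors = FALSE)
}

#' Construct a synthetic-cohort specification
#'
#' Defaults follow the grasp-task protocol: 64 channels at 256 Hz, 42 trials
#' per subject, epochs spanning -2 to +5 s around the cue, and 12 subjects
#' per group. All parameters are overridable.
#'
#' @param nSubjectsPerGroup subjects per group.
#' @param channels montage labels.
#' @param fs sampling rate (Hz).
#' @param nTrials trials per subject.
#' @param epochWindow epoch span (s) around the cue.
#' @param seed integer seed.
#' @param bands data.frame name/low/high.
#' @param plantedEdges data.frame from [plantedEdge()] rows (rbind to combine).
#' @param erdEffects data.frame from [erdEffect()] rows.
#' @param outcomeIntercept,outcomeCoefficients,outcomeNoiseSD outcome model:
#'   UL-FMA = intercept + sum(coef * realized feature value) + N(0, noiseSD),
#'   clipped to [0, 66]. Coefficient names are planted-feature labels.
#' @param subjectSD lognormal SD of per-subject effect-magnitude scaling.
#' @param commonSourceStrength zero-lag common source amplitude (0 disables).
#' @param backgroundSD white background-noise SD per channel.
#' @param sourceAmplitude amplitude of planted oscillators.
#' @return a validated [CohortSpec-class].
#' @export
#' @examples
#' spec <- cohortSpec(nSubjectsPerGroup = 2, channels = c("C3", "C4", "CP4"),
#'                    nTrials = 8, epochWindow = c(-1, 1.5), seed = 7)
#' spec
cohortSpec <- function(nSubjectsPerGroup = 12L,
                       channels = montage64(),
                       fs = 256,
                       nTrials = 42L,
                       epochWindow = c(-2, 5),
                       seed = 1L,
                       bands = defaultBands(),
                       plantedEdges = plantedEdge(character(), character(),
                                                 character(), numeric(),
                                                 numeric()),
                       erdEffects = erdEffect(character(), character(),
                                              numeric()),
                       outcomeIntercept = 45,
                       outcomeCoefficients = stats::setNames(numeric(0),
                                                            character(0)),
                       outcomeNoiseSD = 5,
                       subjectSD = 0.15,
                       commonSourceStrength = 0.5,
                       backgroundSD = 1,
                       sourceAmplitude = 1) {
  spec <- new("CohortSpec",
              nSubjectsPerGroup = as.integer(nSubjectsPerGroup),
              channels = channels, fs = fs, nTrials = as.integer(nTrials),
              epochWindow = as.numeric(epochWindow), seed = as.integer(seed),
              bands = bands, plantedEdges = plantedEdges,
              erdEffects = erdEffects,
              outcomeModel = list(intercept = outcomeIntercept,
                                  coefficients = outcomeCoefficients,
                                  noiseSD = outcomeNoiseSD),
              subjectSD = subjectSD,
              commonSourceStrength = commonSourceStrength,
              backgroundSD = backgroundSD, sourceAmplitude = sourceAmplitude)
  methods::validObject(spec)
  spec
}

## Subject-level ground truth, drawn from a fixed-order RNG block so that
## plantedTruth() and generateCohort() see identical values for the same
## seed. Signal-level draws in generateCohort() follow after this block.
.drawCohortTruth <- function(spec) {
  set.seed(spec@seed)
  n <- spec@nSubjectsPerGroup
  groups <- rep(c("stroke", "control"), each = n)
  ids <- c(sprintf("S%02d", seq_len(n)), sprintf("C%02d", seq_len(n)))
  pe <- spec@plantedEdges
  ee <- spec@erdEffects
  om <- spec@outcomeModel
  subjects <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    grp <- groups[k]
    ## performing hand: affected hand for stroke (either side); controls use
    ## the non-dominant (left) hand, as in the protocol
    handDraw <- stats::runif(1)
    hand <- if (grp == "stroke") c("left", "right")[1L + (handDraw > 0.5)]
            else "left"
    edges <- NULL
    if (nrow(pe) > 0) {
      realized <- pmin(1, pe$strength * exp(stats::rnorm(nrow(pe), 0,
                                                         spec@subjectSD)))
      active <- pe$group == "both" | pe$group == grp
      edges <- cbind(pe, realized = ifelse(active, realized, 0))
    }
    erds <- NULL
    if (nrow(ee) > 0) {
      realized <- ee$ratio * exp(stats::rnorm(nrow(ee), 0, spec@subjectSD))
      active <- ee$group == "both" | ee$group == grp
      erds <- cbind(ee, realized = ifelse(active, realized, 1))
    }
    feats <- c(
      if (!is.null(edges))
        stats::setNames(edges$realized,
                        edgeFeatureLabel(edges$chi, edges$chj, edges$band)),
      if (!is.null(erds))
        stats::setNames(erds$realized,
                        erdFeatureLabel(erds$channel, erds$band)))
    yTrue <- om$intercept
    if (length(om$coefficients)) {
      miss <- setdiff(names(om$coefficients), names(feats))
      if (length(miss))
        stop("outcome coefficients name unplanted features: ",
             paste(miss, collapse = ", "))
      yTrue <- yTrue + sum(om$coefficients * feats[names(om$coefficients)])
    }
    noise <- stats::rnorm(1, 0, om$noiseSD)
    subjects[[k]] <- list(id = ids[k], group = grp, hand = hand,
                          edges = edges, erds = erds, features = feats,
                          yTrue = yTrue,
                          ulFMA = min(66, max(0, yTrue + noise)))
  }
  subjects
}

#' Noise-free planted feature values and outcome coefficients
#'
#' Returns, for each subject, the realized (per-subject) magnitude of every
#' planted feature and the noise-free outcome, for parameter-recovery tests.
#' Uses the same seeded draws as [generateCohort()], so the values are exactly
#' those embedded in the generated signals.
#'
#' @param spec a [CohortSpec-class].
#' @return data.frame (subject, group, feature, value), one row per subject
#'   per planted feature (empty when nothing is planted). Attributes:
#'   "coefficients" and "intercept" of the outcome model, and "outcome", a
#'   data.frame (subject, ulFMA_noiseless, ulFMA) with the noise-free and
#'   realized (noisy, clipped) outcomes.
#' @export
plantedTruth <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  methods::validObject(spec)
  subjects <- .drawCohortTruth(spec)
  rows <- lapply(subjects, function(s) {
    if (length(s$features) == 0L) return(NULL)
    data.frame(subject = s$id, group = s$group, feature = names(s$features),
               value = unname(s$features), stringsAsFactors = FALSE)
  })
  truth <- do.call(rbind, rows)
  if (is.null(truth))
    truth <- data.frame(subject = character(), group = character(),
                        feature = character(), value = numeric(),
                        stringsAsFactors = FALSE)
  attr(truth, "coefficients") <- spec@outcomeModel$coefficients
  attr(truth, "intercept") <- spec@outcomeModel$intercept
  attr(truth, "outcome") <- data.frame(
    subject = vapply(subjects, `[[`, "", "id"),
    ulFMA_noiseless = vapply(subjects, `[[`, 0, "yTrue"),
    ulFMA = vapply(subjects, `[[`, 0, "ulFMA"),
    stringsAsFactors = FALSE)
  truth
}

## half-open [start, end) window in seconds -> sample index vector
.windowIndices <- function(t0, fs, window, nsamp) {
  i0 <- t0 + as.integer(round(window[1] * fs))
  i1 <- t0 + as.integer(round(window[2] * fs)) - 1L
  if (i0 < 1L || i1 > nsamp) stop("window outside epoch span")
  i0:i1
}

#' Generate a synthetic EEG cohort
#'
#' Realizes the generative model of a [CohortSpec-class]: per-channel white
#' background noise, an optional zero-lag common source in every channel
#' (volume-conduction surrogate), band-limited oscillators implementing each
#' planted coupling (projected to channel i directly and to channel j with a
#' phase delay), ERD effects as post-window amplitude scaling of a baseline
#' oscillation, and UL-FMA scores from the outcome model. Identical spec and
#' seed give a bit-identical cohort.
#'
#' @param spec a [CohortSpec-class].
#' @return list of [SubjectRecord-class], stroke subjects first.
#' @export
#' @examples
#' spec <- cohortSpec(nSubjectsPerGroup = 1, channels = c("C3", "C4"),
#'                    nTrials = 4, epochWindow = c(-1, 1.5), seed = 1)
#' cohort <- generateCohort(spec)
#' cohort[[1]]
generateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  methods::validObject(spec)
  subjects <- .drawCohortTruth(spec)
  fs <- spec@fs
  nch <- length(spec@channels)
  nsamp <- as.integer(round(diff(spec@epochWindow) * fs))
  t0 <- as.integer(round(-spec@epochWindow[1] * fs)) + 1L
  tt <- (seq_len(nsamp) - t0) / fs
  preW <- c(-1, 0)
  postW <- c(0.25, 1.25)
  ## analysis windows must fit the epoch; for very short test epochs shrink
  ## them proportionally is NOT done -- the caller controls the span
  bandIdx <- function(name) which(spec@bands$name == name)

  out <- vector("list", length(subjects))
  for (k in seq_along(subjects)) {
    s <- subjects[[k]]
    arr <- array(stats::rnorm(spec@nTrials * nch * nsamp, 0,
                              spec@backgroundSD),
                 dim = c(spec@nTrials, nch, nsamp))
    preIdx <- .windowIndices(t0, fs, preW, nsamp)
    postIdx <- .windowIndices(t0, fs, postW, nsamp)
    for (tr in seq_len(spec@nTrials)) {
      sig <- matrix(0, nch, nsamp)
      if (spec@commonSourceStrength > 0) {
        cs <- stats::rnorm(nsamp) * spec@commonSourceStrength
        sig <- sig + matrix(cs, nch, nsamp, byrow = TRUE)
      }
      if (!is.null(s$edges) && nrow(s$edges)) {
        for (e in seq_len(nrow(s$edges))) {
          ed <- s$edges[e, ]
          if (ed$realized == 0) next
          b <- spec@bands[bandIdx(ed$band), ]
          f <- stats::runif(1, b$low, b$high)
          th <- stats::runif(1, 0, 2 * pi)
          idx <- switch(ed$window,
                        pre = preIdx, post = postIdx, both = seq_len(nsamp))
          ci <- match(ed$chi, spec@channels)
          cj <- match(ed$chj, spec@channels)
          ph <- 2 * pi * f * tt[idx] + th
          sig[ci, idx] <- sig[ci, idx] + spec@sourceAmplitude * cos(ph)
          sig[cj, idx] <- sig[cj, idx] +
            spec@sourceAmplitude * ed$realized * cos(ph - ed$phase)
        }
      }
      if (!is.null(s$erds) && nrow(s$erds)) {
        for (e in seq_len(nrow(s$erds))) {
          ef <- s$erds[e, ]
          b <- spec@bands[bandIdx(ef$band), ]
          f <- stats::runif(1, b$low, b$high)
          th <- stats::runif(1, 0, 2 * pi)
          amp <- rep(spec@sourceAmplitude, nsamp)
          amp[postIdx] <- spec@sourceAmplitude * sqrt(ef$realized)
          cc <- match(ef$channel, spec@channels)
          sig[cc, ] <- sig[cc, ] + amp * cos(2 * pi * f * tt + th)
        }
      }
      arr[tr, , ] <- arr[tr, , ] + sig
    }
    epochs <- new("EpochSet", data = arr, fs = fs, channels = spec@channels,
                  t0 = t0, preWindow = preW, postWindow = postW)
    out[[k]] <- new("SubjectRecord", id = s$id, group = s$group,
                    hand = s$hand, ulFMA = s$ulFMA, epochs = epochs)
  }
  out
}

#' Write / read a cohort as delimited text
#'
#' One tab-delimited epoch file per subject (columns: trial, sample, one
#' column per channel) plus a subject manifest (id, group, hand, ul_fma,
#' fs, t0, file). A plain-text round-trip format for tests and export; not a
#' clinical EEG format.
#'
#' @param cohort list of [SubjectRecord-class].
#' @param dir output directory (created if needed).
#' @return `writeCohort()` returns the manifest path invisibly; `readCohort()`
#'   the reconstructed list of subjects.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- data.frame(id = character(), group = character(),
                         hand = character(), ul_fma = numeric(),
                         fs = numeric(), t0 = integer(),
                         file = character(), stringsAsFactors = FALSE)
  for (s in cohort) {
    e <- subjectEpochs(s)
    d <- epochData(e)
    nt <- dim(d)[1]; ns <- dim(d)[3]
    flat <- matrix(aperm(d, c(3, 1, 2)), nrow = nt * ns)
    df <- data.frame(trial = rep(seq_len(nt), each = ns),
                     sample = rep(seq_len(ns), times = nt), flat)
    names(df) <- c("trial", "sample", channelNames(e))
    fn <- paste0(subjectId(s), "_epochs.tsv")
    utils::write.table(df, file.path(dir, fn), sep = "\t", row.names = FALSE,
                       quote = FALSE)
    manifest <- rbind(manifest,
                      data.frame(id = subjectId(s), group = subjectGroup(s),
                                 hand = performingHand(s), ul_fma = ulFMA(s),
                                 fs = samplingRate(e), t0 = cueIndex(e),
                                 file = fn, stringsAsFactors = FALSE))
  }
  mf <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mf, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(mf)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  mf <- file.path(dir, "manifest.tsv")
  if (!file.exists(mf)) stop("no manifest.tsv in ", dir)
  manifest <- utils::read.delim(mf, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    df <- utils::read.delim(file.path(dir, m$file), check.names = FALSE)
    chans <- setdiff(names(df), c("trial", "sample"))
    nt <- max(df$trial); ns <- max(df$sample)
    arr <- aperm(array(as.matrix(df[order(df$trial, df$sample), chans]),
                       dim = c(ns, nt, length(chans))), c(2, 3, 1))
    epochs <- new("EpochSet", data = arr, fs = m$fs, channels = chans,
                  t0 = as.integer(m$t0), preWindow = c(-1, 0),
                  postWindow = c(0.25, 1.25))
    new("SubjectRecord", id = m$id, group = m$group, hand = m$hand,
        ulFMA = m$ul_fma, epochs = epochs)
  })
}
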