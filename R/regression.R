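#' @include AllClasses.R
NULL

#' Motor-area channel set
#'
#' The bilateral motor-area channels used as feature sources: premotor (FC*),
#' primary motor (C*) and sensorimotor integration (CP*) rows of both
#' hemispheres.
#'
#' @return character vector of 18 channel labels.
#' @export
motorAreaChannels <- function() {
  c("FC1", "FC3", "FC5", "C1", "C3", "C5", "CP1", "CP3", "CP5",
    "FC2", "FC4", "FC6", "C2", "C4", "C6", "CP2", "CP4", "CP6")
}

#' Build the subjects x features table
#'
#' One row per subject; columns are task-related activity (percent pre-to-post
#' change) of each graph metric per channel — degree centrality `DC(ch)`,
#' local efficiency `LE(ch)`, clustering `CC(ch)` — plus the ERD percent per
#' channel `ERD(ch)`, and the UL-FMA outcome. A zero pre-task metric value
#' makes the contrast undefined and raises an error naming the subject and
#' channel (no silent drops). Column order is deterministic: metrics in the
#' order given, channels in the order given.
#'
#' @param graphNodes named list (by subject) of `list(pre, post)` node-metric
#'   data.frames as produced by [graphMetrics()]`$nodes`.
#' @param erdMaps named list (by subject) of [erd()] data.frames; NULL to
#'   omit ERD features.
#' @param outcomes named numeric vector of UL-FMA scores by subject.
#' @param channels channels to use; default [motorAreaChannels()].
#' @param metrics graph metrics to include, subset of c("DC", "LE", "CC").
#' @return data.frame with columns subject, one per feature, and ulFMA.
#' @export
buildFeatures <- function(graphNodes, erdMaps, outcomes,
                          channels = motorAreaChannels(),
                          metrics = c("DC", "LE", "CC")) {
  subjects <- names(outcomes)
  if (is.null(subjects)) stop("outcomes must be named by subject")
  metricCol <- c(DC = "degree", LE = "local_efficiency", CC = "clustering")
  useGraph <- length(metrics) > 0L && !is.null(graphNodes)
  if (useGraph) metrics <- match.arg(metrics, several.ok = TRUE)
  rows <- lapply(subjects, function(s) {
    vals <- numeric(0)
    if (useGraph) {
      gn <- graphNodes[[s]]
      if (is.null(gn)) stop("missing graph metrics for subject ", s)
      for (m in metrics) {
        col <- metricCol[[m]]
        pre <- gn$pre[[col]][match(channels, gn$pre$node)]
        post <- gn$post[[col]][match(channels, gn$post$node)]
        if (anyNA(pre) || anyNA(post))
          stop("subject ", s, ": missing ", m, " for channel(s) ",
               paste(channels[is.na(pre) | is.na(post)], collapse = ", "))
        if (any(pre == 0))
          stop("subject ", s, ": undefined task contrast (pre-task ", m,
               " is zero) at channel(s) ",
               paste(channels[pre == 0], collapse = ", "))
        v <- (post - pre) / pre * 100
        names(v) <- sprintf("%s(%s)", m, channels)
        vals <- c(vals, v)
      }
    }
    if (!is.null(erdMaps)) {
      em <- erdMaps[[s]]
      if (is.null(em)) stop("missing ERD map for subject ", s)
      ev <- em$erd[match(channels, em$channel)]
      if (anyNA(ev))
        stop("subject ", s, ": missing ERD for channel(s) ",
             paste(channels[is.na(ev)], collapse = ", "))
      names(ev) <- sprintf("ERD(%s)", channels)
      vals <- c(vals, ev)
    }
    vals
  })
  feat <- do.call(rbind, rows)
  if (any(!is.finite(feat))) stop("non-finite feature values")
  out <- data.frame(subject = subjects, feat, ulFMA = unname(outcomes),
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

## ---------------------------------------------------------------------------
## Quadratic-scope term bookkeeping
## ---------------------------------------------------------------------------

## term definitions over candidate columns: linear, squared, pairwise product
.makeTermDefs <- function(candidates, scope = c("quadratic", "linear")) {
  scope <- match.arg(scope)
  defs <- data.frame(id = candidates, type = "linear", v1 = candidates,
                     v2 = NA_character_, stringsAsFactors = FALSE)
  if (scope == "quadratic") {
    sq <- data.frame(id = paste0(candidates, "^2"), type = "squared",
                     v1 = candidates, v2 = NA_character_,
                     stringsAsFactors = FALSE)
    pr <- NULL
    if (length(candidates) > 1L) {
      cmb <- utils::combn(candidates, 2)
      pr <- data.frame(id = paste0(cmb[1, ], "*", cmb[2, ]),
                       type = "product", v1 = cmb[1, ], v2 = cmb[2, ],
                       stringsAsFactors = FALSE)
    }
    defs <- rbind(defs, sq, pr)
  }
  defs
}

## realize term columns from a feature table
.termColumns <- function(data, defs) {
  cols <- vapply(seq_len(nrow(defs)), function(i) {
    d <- defs[i, ]
    switch(d$type,
           linear = data[[d$v1]],
           squared = data[[d$v1]]^2,
           product = data[[d$v1]] * data[[d$v2]])
  }, numeric(nrow(data)))
  cols <- matrix(cols, nrow = nrow(data))
  colnames(cols) <- defs$id
  cols
}

#' Stepwise regression with partial-F entry and removal
#'
#' Selects terms for a linear model of the outcome by iterative addition and
#' removal, using the partial F-test on the change in the sum of squared
#' errors at significance `alphaEnter` / `alphaRemove`. The candidate scope
#' is quadratic: intercept plus linear, squared, and all pairwise-product
#' terms of the candidate features; the start model is the intercept only and
#' addition is tried first. Hierarchy is not enforced (a squared term may
#' enter without its linear parent). Zero-variance candidates are excluded
#' with a warning; a repeated model state stops the loop with a warning.
#'
#' @param data feature table from [buildFeatures()] (or any data.frame).
#' @param outcome name of the outcome column (default "ulFMA").
#' @param candidates candidate feature columns; default all columns except
#'   the outcome and "subject".
#' @param scope "quadratic" (default) or "linear".
#' @param alphaEnter,alphaRemove entry and removal significance levels.
#' @param maxTerms maximum model size; default keeps at least one residual
#'   degree of freedom.
#' @return object of class "stepwiseFit": list with `terms` (selected term
#'   ids), `termDefs`, `coefficients` (term, beta, se, std_beta, t, p),
#'   `r2`, `adj_r2`, `fstat`, `model_p`, `formula`, `outcome`, `n`.
#' @export
stepwiseSelect <- function(data, outcome = "ulFMA", candidates = NULL,
                           scope = c("quadratic", "linear"),
                           alphaEnter = 0.05, alphaRemove = 0.05,
                           maxTerms = NULL) {
  scope <- match.arg(scope)
  y <- data[[outcome]]
  if (is.null(y)) stop("no outcome column '", outcome, "'")
  n <- length(y)
  if (n < 3L) stop("need at least 3 subjects")
  if (is.null(candidates))
    candidates <- setdiff(names(data), c(outcome, "subject"))
  sds <- vapply(candidates, function(v) stats::sd(data[[v]]), numeric(1))
  if (any(sds == 0)) {
    warning("zero-variance candidate(s) excluded: ",
            paste(candidates[sds == 0], collapse = ", "))
    candidates <- candidates[sds > 0]
  }
  if (length(candidates) == 0L) stop("no usable candidate features")
  defs <- .makeTermDefs(candidates, scope)
  TT <- .termColumns(data, defs)
  termSd <- apply(TT, 2, stats::sd)
  usable <- which(termSd > 0)
  if (is.null(maxTerms)) maxTerms <- n - 2L

  model <- integer(0)
  visited <- character(0)
  repeat {
    sig <- paste(sort(model), collapse = ",")
    if (sig %in% visited) {
      warning("stepwise add/remove cycle detected; returning current model")
      break
    }
    visited <- c(visited, sig)
    changed <- FALSE
    ## forward: partial F of each single-term addition via residualization
    if (length(model) < maxTerms) {
      Xcur <- cbind(1, TT[, model, drop = FALSE])
      qrX <- qr(Xcur)
      p0 <- qrX$rank
      dfRes <- n - p0 - 1L               # residual df after adding one term
      if (dfRes >= 1L) {
        r <- qr.resid(qrX, y)
        rss0 <- sum(r^2)
        cand <- setdiff(usable, model)
        if (length(cand)) {
          Tres <- qr.resid(qrX, TT[, cand, drop = FALSE])
          ss <- colSums(Tres^2)
          num <- as.numeric(crossprod(Tres, r))
          delta <- ifelse(ss > 1e-10 * rss0 + 1e-300, num^2 / ss, 0)
          rss1 <- pmax(rss0 - delta, 0)
          Fv <- ifelse(ss > 1e-10, delta / (rss1 / dfRes), 0)
          pv <- stats::pf(Fv, 1, dfRes, lower.tail = FALSE)
          pv[ss <= 1e-10] <- 1
          best <- which.min(pv)
          if (length(best) && is.finite(pv[best]) && pv[best] < alphaEnter) {
            model <- c(model, cand[best])
            changed <- TRUE
          }
        }
      }
    }
    ## backward: partial F of each single-term removal (t^2 of the term)
    if (length(model) > 0L) {
      X <- cbind(`(Intercept)` = 1, TT[, model, drop = FALSE])
      fit <- stats::lm.fit(X, y)
      dfRes <- n - fit$rank
      if (dfRes >= 1L && fit$rank == ncol(X)) {
        rss <- sum(fit$residuals^2)
        XtXinv <- chol2inv(chol(crossprod(X)))
        se <- sqrt(diag(XtXinv) * rss / dfRes)
        tv <- fit$coefficients / se
        pv <- 2 * stats::pt(abs(tv), dfRes, lower.tail = FALSE)
        pv <- pv[-1]                     # never drop the intercept
        worst <- which.max(pv)
        if (length(worst) && pv[worst] > alphaRemove) {
          model <- model[-worst]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }

  .stepwiseFitObject(y, TT, defs, model, outcome, n)
}

## assemble the fit summary for a chosen term set
.stepwiseFitObject <- function(y, TT, defs, model, outcome, n) {
  X <- cbind(`(Intercept)` = 1, TT[, model, drop = FALSE])
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) stop("selected design matrix is rank deficient")
  dfRes <- n - fit$rank
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  k <- length(model)
  adj <- if (dfRes > 0) 1 - (1 - r2) * (n - 1) / dfRes else NA_real_
  coefTab <- NULL
  if (dfRes > 0) {
    XtXinv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(diag(XtXinv) * rss / dfRes)
    tv <- fit$coefficients / se
    pv <- 2 * stats::pt(abs(tv), dfRes, lower.tail = FALSE)
    sdy <- stats::sd(y)
    stdb <- c(NA, fit$coefficients[-1] *
                apply(TT[, model, drop = FALSE], 2, stats::sd) / sdy)
    coefTab <- data.frame(term = c("(Intercept)", defs$id[model]),
                          beta = unname(fit$coefficients),
                          se = unname(se), std_beta = unname(stdb),
                          t = unname(tv), p = unname(pv),
                          stringsAsFactors = FALSE)
  }
  Fv <- if (k > 0 && dfRes > 0 && rss > 0)
    ((tss - rss) / k) / (rss / dfRes) else NA_real_
  modelP <- if (!is.na(Fv)) stats::pf(Fv, k, dfRes, lower.tail = FALSE)
            else NA_real_
  structure(list(terms = defs$id[model],
                 termDefs = defs[model, , drop = FALSE],
                 coefficients = coefTab, r2 = r2, adj_r2 = adj, fstat = Fv,
                 model_p = modelP,
                 formula = modelFormula(defs$id[model], outcome),
                 outcome = outcome, n = n),
            class = "stepwiseFit")
}

#' Plain-text model formula
#'
#' @param terms character term ids (possibly empty).
#' @param outcome outcome name.
#' @return e.g. `"y ~ 1 + DC(C4) + CC(C4)^2 + ERD(C2)*ERD(C4)"`.
#' @export
modelFormula <- function(terms, outcome = "y") {
  paste(outcome, "~", paste(c("1", terms), collapse = " + "))
}

#' @export
print.stepwiseFit <- function(x, ...) {
  cat("Stepwise fit:", x$formula, "\n")
  cat(sprintf("  n = %d, R2 = %.4f, adj R2 = %.4f, F = %.3g (p = %.3g)\n",
              x$n, x$r2, x$adj_r2, x$fstat, x$model_p))
  if (!is.null(x$coefficients)) print(x$coefficients, digits = 4)
  invisible(x)
}

## resolve a term-id vector against a feature table
.defsForTerms <- function(data, terms) {
  candidates <- setdiff(names(data), "subject")
  defs <- .makeTermDefs(candidates, "quadratic")
  idx <- match(terms, defs$id)
  ## products may be written in either order
  if (anyNA(idx)) {
    flip <- function(id) {
      parts <- strsplit(id, "*", fixed = TRUE)[[1]]
      if (length(parts) == 2) paste0(parts[2], "*", parts[1]) else id
    }
    idx[is.na(idx)] <- match(vapply(terms[is.na(idx)], flip, ""), defs$id)
  }
  if (anyNA(idx))
    stop("unknown term(s): ", paste(terms[is.na(idx)], collapse = ", "))
  defs[idx, , drop = FALSE]
}

#' Leave-one-out prediction with a fixed term set
#'
#' For each subject, refits the model coefficients on the other n-1 subjects
#' and predicts the held-out one. The term set is fixed before the loop
#' (normally from [stepwiseSelect()] on the full sample); set
#' `nested = TRUE` to instead rerun selection inside every fold, which
#' removes selection optimism at the cost of a possibly different term set
#' per fold.
#'
#' @param data feature table from [buildFeatures()].
#' @param terms character term ids, or a "stepwiseFit" object.
#' @param outcome outcome column name.
#' @param nested logical; rerun stepwise selection within each fold.
#' @param ... passed to [stepwiseSelect()] when `nested = TRUE`.
#' @return a [PredictionResult-class].
#' @export
looPredict <- function(data, terms, outcome = "ulFMA", nested = FALSE, ...) {
  if (inherits(terms, "stepwiseFit")) terms <- terms$terms
  n <- nrow(data)
  y <- data[[outcome]]
  subj <- if ("subject" %in% names(data)) data$subject
          else as.character(seq_len(n))
  defs <- .defsForTerms(data[, setdiff(names(data), outcome), drop = FALSE],
                        terms)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    train <- data[-i, , drop = FALSE]
    useTerms <- terms
    useDefs <- defs
    if (nested) {
      f <- stepwiseSelect(train, outcome = outcome, ...)
      useTerms <- f$terms
      useDefs <- f$termDefs
    }
    Xtr <- cbind(1, .termColumns(train, useDefs))
    fit <- stats::lm.fit(Xtr, y[-i])
    if (fit$rank < ncol(Xtr) || anyNA(fit$coefficients))
      stop("singular refit on fold ", i, " (subject ", subj[i], ")")
    Xte <- cbind(1, .termColumns(data[i, , drop = FALSE], useDefs))
    pred[i] <- drop(Xte %*% fit$coefficients)
  }
  m <- predictionMetrics(y, pred, nPredictors = length(terms))
  new("PredictionResult",
      table = data.frame(subject = subj, actual = y, predicted = pred,
                         stringsAsFactors = FALSE),
      metrics = m, formula = modelFormula(terms, outcome))
}

#' Prediction quality metrics
#'
#' RMSE under both denominator conventions (sqrt(SSE/n) and sqrt(SSE/(n-1))),
#' R-squared = 1 - SSE/SStot, adjusted R-squared with the stated predictor
#' count, and the Pearson correlation between actual and predicted.
#'
#' @param actual,predicted numeric vectors of equal length >= 3.
#' @param nPredictors predictor count used for the adjusted R-squared.
#' @return named numeric: rmse_n, rmse_n1, r2, adj_r2, correlation.
#' @export
predictionMetrics <- function(actual, predicted, nPredictors = 1) {
  if (length(actual) != length(predicted)) stop("length mismatch")
  n <- length(actual)
  if (n < 3L) stop("need at least 3 observations")
  if (stats::sd(predicted) == 0)
    stop("correlation undefined: predictions are constant")
  sse <- sum((actual - predicted)^2)
  sstot <- sum((actual - mean(actual))^2)
  r2 <- 1 - sse / sstot
  adj <- if (n - nPredictors - 1 > 0)
    1 - (1 - r2) * (n - 1) / (n - nPredictors - 1) else NA_real_
  c(rmse_n = sqrt(sse / n), rmse_n1 = sqrt(sse / (n - 1)), r2 = r2,
    adj_r2 = adj, correlation = stats::cor(actual, predicted))
}

#' Bootstrap stability of stepwise feature selection
#'
#' Leave-one-out bootstrapping: run k holds out subject ((k-1) mod n) + 1,
#' resamples the remaining n-1 subjects with replacement, runs stepwise
#' selection on the resample, and records the selected terms. Resamples with
#' a constant outcome are skipped and counted. Deterministic for a fixed
#' seed.
#'
#' @param data feature table.
#' @param runs number of bootstrap runs (default 1000).
#' @param seed integer seed.
#' @param outcome outcome column name.
#' @param ... passed to [stepwiseSelect()].
#' @return data.frame (term, count, frequency) sorted by frequency, with
#'   attributes "runs" (effective) and "skipped".
#' @export
bootstrapStability <- function(data, runs = 1000, seed = 1,
                               outcome = "ulFMA", ...) {
  n <- nrow(data)
  if (n < 5L) stop("need at least 5 subjects")
  set.seed(seed)
  counts <- new.env(parent = emptyenv())
  skipped <- 0L
  for (k in seq_len(runs)) {
    hold <- ((k - 1L) %% n) + 1L
    pool <- setdiff(seq_len(n), hold)
    idx <- sample(pool, n - 1L, replace = TRUE)
    boot <- data[idx, , drop = FALSE]
    if (stats::sd(boot[[outcome]]) == 0) {
      skipped <- skipped + 1L
      next
    }
    fit <- suppressWarnings(stepwiseSelect(boot, outcome = outcome, ...))
    for (tm in fit$terms)
      assign(tm, (if (exists(tm, counts)) get(tm, counts) else 0L) + 1L,
             counts)
  }
  eff <- runs - skipped
  terms <- ls(counts)
  out <- data.frame(term = terms,
                    count = vapply(terms, function(tm) get(tm, envir = counts),
                                   0L),
                    stringsAsFactors = FALSE)
  out$frequency <- out$count / max(eff, 1L)
  out <- out[order(-out$frequency, out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "runs") <- eff
  attr(out, "skipped") <- skipped
  out
}
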