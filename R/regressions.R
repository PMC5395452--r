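#' Simple linear regression with r-squared and slope p-value
#'
#' Ordinary least squares of `y` on `x`: slope, intercept, squared Pearson
#' correlation, and a two-sided t-test on the slope with `n - 2` degrees of
#' freedom. A zero-variance response is not an error — it returns slope 0,
#' intercept `mean(y)`, r2 0, p 1, flagged `degenerate` — while a
#' zero-variance predictor is (the slope is undefined).
#'
#' @param x,y equal-length finite numeric vectors, length >= 3.
#' @return an [OLSFit].
#' @examples
#' olsFit(1:10, 2 * (1:10) + 1)
#' @export
olsFit <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("need at least 3 points")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("'x' and 'y' must be finite")
  }
  if (var(x) == 0) stop("zero-variance x: slope undefined")
  n <- length(x)
  if (var(y) == 0) {
    return(new("OLSFit", slope = 0, intercept = mean(y), r2 = 0, p = 1,
               n = as.integer(n), degenerate = TRUE))
  }
  fit <- lm(y ~ x)
  # summary() warns on exact fits; a perfect linear relation is valid input
  sm <- suppressWarnings(summary(fit))
  new("OLSFit",
      slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
      r2 = sm$r.squared, p = unname(sm$coefficients[2L, 4L]),
      n = as.integer(n), degenerate = FALSE)
}

#' Family-level relationships of consumer diversity
#'
#' The two cross-family regressions: the utilizer ratio against
#' log10(apparency) (diversity increases with island "area") and against
#' PD_min (diversity decays with phylogenetic distance to the mainland).
#'
#' @param summaries data.frame with columns `UR`, `apparency`, `PD_min`
#'   (one row per family), e.g. the per-family table from [runPipeline()].
#' @return named list of two [OLSFit]: `urApparency`, `urPdMin`.
#' @examples
#' d <- data.frame(apparency = 10^runif(50, 0, 4), PD_min = runif(50, 0, 300))
#' d$UR <- 0.1 * log10(d$apparency) + 0.01
#' familyRelationships(d)$urApparency
#' @export
familyRelationships <- function(summaries) {
  need <- c("UR", "apparency", "PD_min")
  miss <- setdiff(need, names(summaries))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(summaries$apparency <= 0)) {
    stop("apparency must be positive for the log10 transform")
  }
  list(urApparency = olsFit(log10(summaries$apparency), summaries$UR),
       urPdMin = olsFit(summaries$PD_min, summaries$UR))
}

#' Cross-group relationships of host breadth
#'
#' The five regressions relating per-group results to host breadth HF:
#' `log10(PA_05) ~ HF`, `log10(PA_095) ~ HF`, `UP_0 ~ HF`,
#' `D ~ log10(HF)`, and `UP_0 ~ log10(D)`. Groups with invalid fits
#' (non-converged, separated, or slope `a <= 0`) are excluded from all
#' five; groups with nonpositive thresholds or nonpositive D are
#' additionally excluded from the regressions that take their logarithm.
#' Every exclusion is logged with its reason.
#'
#' @param summaries data.frame with one row per group and columns `group`,
#'   `HF`, `a`, `converged`, `separated`, `PA_05`, `PA_095`, `UP_0`, `D`.
#' @return list with `fits` (named [OLSFit] list) and `exclusions`
#'   (data.frame of group, regression, reason).
#' @examples
#' study <- simulateStudy(nFamilies = 120, nGroups = 8, seed = 5)
#' res <- runPipeline(study = study, outDir = tempfile(),
#'                    nPerm = 100, seed = 5)
#' groupRelationships(res$groups)$fits$up0Hf
#' @export
groupRelationships <- function(summaries) {
  need <- c("group", "HF", "a", "converged", "separated",
            "PA_05", "PA_095", "UP_0", "D")
  miss <- setdiff(need, names(summaries))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  s <- summaries
  excl <- data.frame(group = character(), regression = character(),
                     reason = character(), stringsAsFactors = FALSE)
  note <- function(g, reg, why) {
    rbind(excl, data.frame(group = g, regression = reg, reason = why,
                           stringsAsFactors = FALSE))
  }
  bad <- !s$converged | s$separated | !(s$a > 0) | is.na(s$a)
  for (g in s$group[bad]) excl <- note(g, "all", "invalid fit (non-converged, separated, or a <= 0)")
  s <- s[!bad, , drop = FALSE]
  if (nrow(s) < 3L) stop("fewer than 3 groups with valid fits")

  run <- function(x, y, keep, reg, why) {
    dropped <- s$group[!keep]
    for (g in dropped) excl <<- note(g, reg, why)
    if (sum(keep) < 3L) return(NULL)
    olsFit(x[keep], y[keep])
  }
  okD <- !is.na(s$D)
  fits <- list(
    logPa05Hf = run(s$HF, suppressWarnings(log10(s$PA_05)),
                    s$PA_05 > 0, "logPa05Hf", "nonpositive PA_05"),
    logPa095Hf = run(s$HF, suppressWarnings(log10(s$PA_095)),
                     s$PA_095 > 0, "logPa095Hf", "nonpositive PA_095"),
    up0Hf = olsFit(s$HF, s$UP_0),
    dLogHf = run(suppressWarnings(log10(s$HF)), s$D, okD,
                 "dLogHf", "missing D"),
    up0LogD = run(suppressWarnings(log10(s$D)), s$UP_0, okD & s$D > 0,
                  "up0LogD", "nonpositive or missing D"))
  list(fits = fits, exclusions = excl)
}

#' Randomized binomial baseline for the logit fits
#'
#' The null comparison for the per-group fits: for each success probability
#' in `probs`, draw `nReps` presence vectors i.i.d. Bernoulli(p) —
#' independent of apparency by construction — refit the logit model
#' against the supplied apparency vector, and record coefficients and
#' derived quantities. Because presence is independent of apparency, the
#' fitted slope centers on 0 and the fitted baseline probability `UP_0`
#' centers on p; real consumer groups fall below this baseline at small
#' apparency.
#'
#' @param pa apparency vector (one value per family).
#' @param probs Bernoulli success probabilities.
#' @param nReps replicates per probability.
#' @param seed integer seed.
#' @return data.frame with one row per (p, rep): coefficients, variances,
#'   `PA_05`, `PA_095`, `UP_0`, and `converged`/`separated`/`degenerate`
#'   flags (degenerate and separated draws carry NA derived quantities and
#'   are meant to be excluded from summaries).
#' @examples
#' set.seed(1)
#' pa <- rlnorm(100, 4, 1.5)
#' base <- randomizedBaseline(pa, probs = 0.5, nReps = 50, seed = 2)
#' mean(base$UP_0, na.rm = TRUE)
#' @export
randomizedBaseline <- function(pa, probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                               nReps = 1000L, seed = 1L) {
  if (sd(pa) == 0) stop("'pa' must not be constant")
  if (any(probs <= 0 | probs >= 1)) stop("'probs' must lie in (0, 1)")
  n <- length(pa)
  grid <- expand.grid(rep = seq_len(nReps), p = probs)
  withSeed(seed, {
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      p <- grid$p[i]
      y <- rbinom(n, 1L, p)
      if (all(y == 0) || all(y == 1)) {
        return(data.frame(p = p, rep = grid$rep[i], a = NA_real_,
                          b = NA_real_, var_a = NA_real_, var_b = NA_real_,
                          PA_05 = NA_real_, PA_095 = NA_real_,
                          UP_0 = NA_real_, converged = FALSE,
                          separated = FALSE, degenerate = TRUE))
      }
      fit <- fitBinomialLogit(pa, y)
      ok <- fit@converged && !fit@separated && fit@slope != 0
      dq <- if (ok) derivedQuantities(fit) else
        list(PA_05 = NA_real_, PA_095 = NA_real_, UP_0 = NA_real_)
      data.frame(p = p, rep = grid$rep[i], a = fit@slope, b = fit@intercept,
                 var_a = fit@varSlope, var_b = fit@varIntercept,
                 PA_05 = dq$PA_05, PA_095 = dq$PA_095, UP_0 = dq$UP_0,
                 converged = fit@converged, separated = fit@separated,
                 degenerate = FALSE)
    })
    do.call(rbind, rows)
  })
}
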