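#' Fit the binomial logit model of utilization on apparency
#'
#' Maximum-likelihood fit of `logit(UP) = a * PA + b` by iteratively
#' reweighted least squares: starting from `a = 0`,
#' `b = logit(mean(y))` (mean clipped to `[1e-6, 1 - 1e-6]`), Newton steps
#' are taken until the deviance changes by less than 1e-8. Coefficient
#' variances come from the inverse observed information (for the logit link
#' observed and expected information coincide). Quasi-complete separation —
#' a standardized slope `|a| * sd(PA) > 50`, or a deviance collapsing to 0
#' with a non-degenerate response — is flagged rather than reported as a
#' finite estimate, and downstream quantities refuse to compute from a
#' separated fit.
#'
#' @param pa numeric vector of plant apparency (finite, non-constant).
#' @param y binary 0/1 response: presence of the utilization group on each
#'   family. Must contain both classes.
#' @param maxIterations IRLS iteration cap.
#' @return an [ApparencyFit].
#' @examples
#' set.seed(1)
#' pa <- rlnorm(200, 4, 1.5)
#' y <- rbinom(200, 1, plogis(0.02 * pa - 2))
#' fitBinomialLogit(pa, y)
#' @export
fitBinomialLogit <- function(pa, y, maxIterations = 100L) {
  if (length(pa) != length(y)) stop("'pa' and 'y' must have equal length")
  if (length(y) < 2L) stop("need at least 2 observations")
  if (!all(is.finite(pa))) stop("'pa' must be finite")
  if (!all(y %in% c(0, 1))) stop("'y' must be 0/1")
  if (all(y == 0) || all(y == 1)) {
    stop("degenerate response: y is constant (all ",
         y[1L], "); the logit model is undefined", call. = FALSE)
  }
  sdpa <- sd(pa)
  if (sdpa == 0) stop("'pa' is constant; slope is undefined")

  n <- length(y)
  mu0 <- min(max(mean(y), 1e-6), 1 - 1e-6)
  beta <- c(qlogis(mu0), 0)           # (intercept b, slope a)
  X <- cbind(1, pa)
  dev <- devianceBinomial(y, plogis(X %*% beta))
  trace <- dev
  converged <- FALSE
  iter <- 0L
  XtWX <- NULL
  while (iter < maxIterations) {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtWX <- crossprod(X, X * w)
    beta <- tryCatch(unname(drop(solve(XtWX, crossprod(X, w * z)))),
                     error = function(e) stop(
                       "IRLS failed: singular weighted design", call. = FALSE))
    newDev <- devianceBinomial(y, plogis(drop(X %*% beta)))
    trace <- c(trace, newDev)
    if (abs(dev - newDev) < 1e-8) {
      dev <- newDev
      converged <- TRUE
      break
    }
    dev <- newDev
  }
  # information at the final estimate
  mu <- plogis(drop(X %*% beta))
  w <- pmax(mu * (1 - mu), 1e-12)
  XtWX <- crossprod(X, X * w)
  V <- tryCatch(solve(XtWX), error = function(e) matrix(Inf, 2, 2))
  separated <- abs(beta[2L]) * sdpa > 50 || dev < 1e-6
  fit <- new("ApparencyFit",
             slope = beta[2L], intercept = beta[1L],
             varSlope = max(V[2L, 2L], 0), varIntercept = max(V[1L, 1L], 0),
             n = as.integer(n), deviance = dev, iterations = iter,
             converged = converged, separated = separated)
  attr(fit, "devianceTrace") <- trace
  fit
}

devianceBinomial <- function(y, mu) {
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
}

#' Wald G test of the apparency slope
#'
#' `G = a^2 / VAR(a)`, compared with the upper tail of a chi-square
#' distribution with one degree of freedom, tests whether the slope of the
#' logit model differs from zero.
#'
#' @param fit an [ApparencyFit]; must not be separated and must have a
#'   positive slope variance.
#' @return list with elements `G` and `p`.
#' @examples
#' set.seed(1)
#' pa <- rlnorm(300, 4, 1.5)
#' fit <- fitBinomialLogit(pa, rbinom(300, 1, plogis(0.01 * pa - 2)))
#' gStatistic(fit)
#' @export
gStatistic <- function(fit) {
  stopifnot(is(fit, "ApparencyFit"))
  if (fit@separated) {
    stop("fit is separated; exclude this group from the G test", call. = FALSE)
  }
  if (!(fit@varSlope > 0)) stop("slope variance must be positive")
  G <- fit@slope^2 / fit@varSlope
  list(G = G, p = pchisq(G, df = 1, lower.tail = FALSE))
}

#' Apparency thresholds and baseline utilization probability
#'
#' From a converged fit of `logit(UP) = a * PA + b` with `a != 0`:
#' * `PA_05 = -b / a`, the apparency at which utilization probability
#'   reaches 0.5;
#' * `PA_095 = (ln 19 - b) / a`, where it reaches 0.95;
#' * `UP_0 = exp(b) / (1 + exp(b))`, the utilization probability of the
#'   most unapparent families (PA -> 0).
#'
#' @param fit an [ApparencyFit].
#' @return list with `PA_05`, `PA_095`, `UP_0`.
#' @examples
#' set.seed(1)
#' pa <- rlnorm(300, 4, 1.5)
#' fit <- fitBinomialLogit(pa, rbinom(300, 1, plogis(0.02 * pa - 2)))
#' derivedQuantities(fit)
#' @export
derivedQuantities <- function(fit) {
  stopifnot(is(fit, "ApparencyFit"))
  if (fit@separated) stop("fit is separated; thresholds are undefined",
                          call. = FALSE)
  if (!fit@converged) stop("fit did not converge")
  a <- fit@slope; b <- fit@intercept
  if (a == 0) stop("slope is exactly 0; apparency thresholds are undefined")
  list(PA_05 = -b / a, PA_095 = (log(19) - b) / a, UP_0 = plogis(b))
}

#' Predicted utilization probability
#'
#' Evaluates the fitted logistic curve `UP = logistic(a * PA + b)` at new
#' apparency values; strictly inside (0, 1) and monotone increasing in PA
#' exactly when the slope is positive.
#'
#' @param fit an [ApparencyFit].
#' @param pa numeric apparency value(s).
#' @return numeric vector of probabilities.
#' @examples
#' set.seed(1)
#' pav <- rlnorm(300, 4, 1.5)
#' fit <- fitBinomialLogit(pav, rbinom(300, 1, plogis(0.02 * pav - 2)))
#' predictUp(fit, c(0, 100, 1000))
#' @export
predictUp <- function(fit, pa) {
  stopifnot(is(fit, "ApparencyFit"))
  if (!fit@converged) stop("fit did not converge")
  plogis(fit@slope * pa + fit@intercept)
}
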