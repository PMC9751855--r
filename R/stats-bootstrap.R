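#' @include AllClasses.R
NULL

#' Bias-corrected and accelerated (BCa) bootstrap interval
#'
#' Computes the BCa interval from a set of bootstrap resample statistics
#' and jackknife (leave-one-out) statistics.  The bias correction is
#' \eqn{z_0 = \Phi^{-1}(\#\{\hat\theta^* < \hat\theta\}/B)}; the
#' acceleration is the jackknife skewness
#' \eqn{a = \sum(\bar\theta_{(\cdot)} - \theta_{(i)})^3 /
#' \{6[\sum(\bar\theta_{(\cdot)} - \theta_{(i)})^2]^{3/2}\}}.  The interval
#' endpoints are the empirical quantiles of the resample statistics at
#' \eqn{\alpha_{1,2} = \Phi(z_0 + (z_0 \pm z_{\alpha})/(1 - a(z_0 \pm
#' z_{\alpha})))}.  With \eqn{z_0 = 0} and \eqn{a = 0} this reduces to the
#' percentile interval.
#'
#' Degenerate cases: identical resample statistics give the point interval
#' (estimate, estimate) with a warning; resamples all on one side of the
#' estimate give an infinite \eqn{z_0}, which is clamped (via a
#' \eqn{1/(2B)} fraction) with a warning.
#'
#' @param estimate statistic on the original data.
#' @param resampleStats numeric, \eqn{B \ge 100} bootstrap statistics.
#' @param jackknifeStats numeric, leave-one-out statistics over the
#'   original observations.
#' @param level confidence level.
#' @return Numeric \code{c(low, high)} with attributes \code{z0}, \code{a},
#'   \code{alpha}.
#' @examples
#' set.seed(1)
#' x <- rnorm(50)
#' rs <- replicate(999, mean(sample(x, replace = TRUE)))
#' jk <- vapply(seq_along(x), function(i) mean(x[-i]), numeric(1))
#' bcaInterval(mean(x), rs, jk)
#' @export
bcaInterval <- function(estimate, resampleStats, jackknifeStats,
                        level = 0.95) {
  B <- length(resampleStats)
  if (B < 100L) stop("at least 100 resample statistics are required")
  if (diff(range(resampleStats)) < .Machine$double.eps * 100) {
    warning("all resample statistics identical; degenerate interval")
    out <- base::c(estimate, estimate)
    attributes(out) <- list(z0 = 0, a = 0, alpha = base::c(NA, NA))
    return(out)
  }
  frac <- mean(resampleStats < estimate)
  if (frac == 0 || frac == 1) {
    warning("all resample statistics on one side of the estimate; z0 clamped")
    frac <- min(max(frac, 1 / (2 * B)), 1 - 1 / (2 * B))
  }
  z0 <- stats::qnorm(frac)
  # delete-one refits can be undefined (e.g. a covariate that loses its
  # only contrast); the acceleration uses the finite ones
  jackknifeStats <- jackknifeStats[is.finite(jackknifeStats)]
  if (length(jackknifeStats) < 3L) {
    warning("fewer than 3 finite jackknife statistics; acceleration set to 0")
    jackknifeStats <- base::c(0, 0, 0)
  }
  jm <- mean(jackknifeStats)
  dev <- jm - jackknifeStats
  den <- 6 * sum(dev^2)^1.5
  a <- if (den == 0) 0 else sum(dev^3) / den
  zal <- stats::qnorm((1 - level) / 2)   # negative
  adj <- function(z) stats::pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  alpha <- base::c(adj(zal), adj(-zal))
  out <- unname(stats::quantile(resampleStats, probs = alpha, type = 6,
                                names = FALSE))
  attributes(out) <- list(z0 = z0, a = a, alpha = alpha)
  out
}

#' Bootstrapped t-test for a two-group mean difference
#'
#' Validates a group comparison against skewness and heteroscedasticity:
#' the mean difference is re-estimated over \code{B} resamples (each group
#' resampled with replacement) and interval-estimated with [bcaInterval()]
#' (jackknife over all original observations).  The two-sided p-value comes
#' from the studentized null distribution: both groups are shifted to the
#' common grand mean, resampled \code{B} times, and the Welch t statistic
#' compared with its observed value
#' (\eqn{p = (1 + \#\{|t^*| \ge |t|\})/(B + 1)}).
#'
#' @param x,y numeric samples of size \eqn{\ge 2} (NAs dropped).
#' @param B number of resamples (1000 by default).
#' @param seed integer RNG seed (optional).
#' @param level confidence level.
#' @return A [BootstrapResult-class].
#' @export
bootstrapT <- function(x, y, B = 1000L, seed = NULL, level = 0.95) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L)
    stop("each sample must have at least 2 observations")
  if (!is.null(seed)) set.seed(seed)
  est <- mean(x) - mean(y)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    warning("zero variance in both groups; degenerate bootstrap")
    return(new("BootstrapResult", estimate = est,
               statistic = "mean difference", B = as.integer(B),
               resampleStats = rep(est, B), ciLow = est, ciHigh = est,
               level = level, pValue = NA_real_,
               seed = if (is.null(seed)) NA_integer_ else as.integer(seed)))
  }
  ix <- matrix(sample.int(n1, n1 * B, replace = TRUE), n1)
  iy <- matrix(sample.int(n2, n2 * B, replace = TRUE), n2)
  rs <- colMeans(matrix(x[ix], n1)) - colMeans(matrix(y[iy], n2))

  # jackknife over the combined observations
  jx <- (sum(x) - x) / (n1 - 1) - mean(y)
  jy <- mean(x) - (sum(y) - y) / (n2 - 1)
  ci <- bcaInterval(est, rs, base::c(jx, jy), level = level)

  welch <- function(a, b) {
    va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
    (mean(a) - mean(b)) / sqrt(va + vb)
  }
  tobs <- welch(x, y)
  grand <- mean(base::c(x, y))
  xs <- x - mean(x) + grand; ys <- y - mean(y) + grand
  ix <- matrix(sample.int(n1, n1 * B, replace = TRUE), n1)
  iy <- matrix(sample.int(n2, n2 * B, replace = TRUE), n2)
  xm <- matrix(xs[ix], n1); ym <- matrix(ys[iy], n2)
  tstar <- (colMeans(xm) - colMeans(ym)) /
    sqrt(apply(xm, 2, stats::var) / n1 + apply(ym, 2, stats::var) / n2)
  tstar <- tstar[is.finite(tstar)]
  p <- (1 + sum(abs(tstar) >= abs(tobs))) / (length(tstar) + 1)

  new("BootstrapResult", estimate = est, statistic = "mean difference",
      B = as.integer(B), resampleStats = as.numeric(rs),
      ciLow = ci[1], ciHigh = ci[2], level = level, pValue = p,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

# wild-bootstrap coefficient resamples: y* = fitted + resid * W column-wise
.wildCoefs <- function(pinv, fitted, resid, W) {
  pinv %*% (fitted + resid * W)
}

.wildWeights <- function(n, B, law) {
  if (law == "rademacher") {
    matrix(sample(base::c(-1, 1), n * B, replace = TRUE), n)
  } else {  # Mammen two-point law: mean 0, variance 1, third moment 1
    phi <- (1 + sqrt(5)) / 2
    p <- (sqrt(5) + 1) / (2 * sqrt(5))
    matrix(ifelse(stats::runif(n * B) < p, 1 - phi, phi), n)
  }
}

#' Wild-bootstrap multiple linear regression with BCa intervals
#'
#' Fits OLS and quantifies coefficient uncertainty with the wild bootstrap,
#' which preserves heteroscedasticity: each resample is
#' \eqn{y^* = \hat y + w \hat e} with independent weights \eqn{w} per
#' observation (Rademacher \eqn{\pm 1} by default, Mammen two-point law
#' optional), and the model is refitted per resample.  Each coefficient
#' gets a BCa interval (delete-one jackknife refits for the acceleration)
#' and a two-sided bootstrap p-value from the null-centred resample
#' distribution.  With all weights equal to +1 every resample reproduces
#' the original fit exactly.
#'
#' @param formula,data model formula and data.frame (rows with NAs
#'   dropped), or pass a design matrix \code{X} and response \code{y}
#'   directly.
#' @param X design matrix (including the intercept column).
#' @param y numeric response.
#' @param B number of wild resamples (2000 by default).
#' @param seed integer RNG seed (optional).
#' @param weights weight law, \code{"rademacher"} or \code{"mammen"}.
#' @param level confidence level.
#' @return A [RegressionResult-class].
#' @examples
#' d <- data.frame(g = rep(0:1, each = 20), y = rnorm(40))
#' fit <- wildBootstrapRegression(y ~ g, d, B = 200, seed = 1)
#' fit
#' @export
wildBootstrapRegression <- function(formula = NULL, data = NULL, X = NULL,
                                    y = NULL, B = 2000L, seed = NULL,
                                    weights = base::c("rademacher", "mammen"),
                                    level = 0.95) {
  weights <- match.arg(weights)
  if (!is.null(formula)) {
    mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
    X <- stats::model.matrix(attr(mf, "terms"), mf)
    y <- stats::model.response(mf)
  }
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (n <= p) stop("need more observations than predictors")
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  coef <- qr.coef(qx, y)
  fitted <- drop(X %*% coef)
  resid <- y - fitted
  rss <- sum(resid^2)
  hasInt <- "(Intercept)" %in% colnames(X) ||
    all(abs(X[, 1] - 1) < .Machine$double.eps)
  tss <- if (hasInt) sum((y - mean(y))^2) else sum(y^2)
  r2 <- if (tss == 0) NA_real_ else 1 - rss / tss
  adjR2 <- if (is.na(r2)) NA_real_ else
    1 - (1 - r2) * (n - if (hasInt) 1 else 0) / (n - p)

  pinv <- chol2inv(chol(crossprod(X))) %*% t(X)
  W <- .wildWeights(n, B, weights)
  cstar <- .wildCoefs(pinv, fitted, resid, W)   # p x B
  rownames(cstar) <- colnames(X)

  # delete-one jackknife refits
  jack <- matrix(NA_real_, p, n, dimnames = list(colnames(X), NULL))
  for (i in seq_len(n))
    jack[, i] <- stats::lm.fit(X[-i, , drop = FALSE], y[-i])$coefficients

  ci <- matrix(NA_real_, p, 2,
               dimnames = list(colnames(X), base::c("low", "high")))
  pv <- stats::setNames(numeric(p), colnames(X))
  degenerate <- max(abs(resid)) <
    .Machine$double.eps^0.5 * max(1, max(abs(y)))
  for (j in seq_len(p)) {
    if (degenerate) {
      # noiseless response: every resample reproduces the fit exactly
      ci[j, ] <- base::c(coef[j], coef[j])
      pv[j] <- if (abs(coef[j]) > 0) 0 else 1
      next
    }
    ci[j, ] <- suppressWarnings(
      bcaInterval(coef[j], cstar[j, ], jack[j, ], level = level))
    centred <- cstar[j, ] - coef[j]
    pv[j] <- (1 + sum(abs(centred) >= abs(coef[j]))) / (B + 1)
  }

  new("RegressionResult", coefficients = coef, ci = ci, pValues = pv,
      r2 = r2, adjR2 = adjR2, B = as.integer(B), weightLaw = weights,
      resampleCoefs = cstar, residuals = as.numeric(resid),
      fitted = fitted,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}
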