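#' @include AllClasses.R
NULL

#' Odds ratio of a 2x2 contingency table with Woolf interval
#'
#' Cross-product odds ratio \eqn{OR = ad/bc} with the Woolf log-scale
#' interval \eqn{\exp(\ln OR \pm z_{\alpha/2}\sqrt{1/a+1/b+1/c+1/d})}.  For
#' a 2x2 table the binomial-logistic MLE of the group effect equals the
#' cross-product ratio, so this is the exact unadjusted logistic odds
#' ratio.  Any zero cell leaves the OR undefined and it is reported as NA,
#' unless the Haldane--Anscombe +0.5 correction is explicitly enabled.
#'
#' @param a,b,c,d cell counts: a = exposed-impaired, b = exposed-unimpaired,
#'   c = unexposed-impaired, d = unexposed-unimpaired.  \code{a} may also be
#'   a 2x2 matrix (rows = exposure, columns = impaired/unimpaired).
#' @param haldane add 0.5 to every cell when any cell is zero.
#' @param conf.level confidence level of the Woolf interval.
#' @return list with \code{estimate}, \code{ciLow}, \code{ciHigh},
#'   \code{table}.
#' @examples
#' oddsRatio2x2(36, 20, 10, 26)$estimate  # 4.68
#' @export
oddsRatio2x2 <- function(a, b = NULL, c = NULL, d = NULL, haldane = FALSE,
                         conf.level = 0.95) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2L))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- base::c(a = a, b = b, c = c, d = d)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  if (any(cells == 0)) {
    if (!haldane)
      return(list(estimate = NA_real_, ciLow = NA_real_, ciHigh = NA_real_,
                  table = cells))
    cells <- cells + 0.5
  }
  or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  list(estimate = unname(or), ciLow = unname(exp(log(or) - z * se)),
       ciHigh = unname(exp(log(or) + z * se)), table = cells)
}

#' Cumulative-logit (proportional-odds) odds ratio for an ordinal outcome
#'
#' Fits the proportional-odds model \eqn{\mathrm{logit}\,P(Y \le j \mid x) =
#' \theta_j - \beta x} for an ordinal outcome and a binary group indicator
#' by Newton iteration (analytic score, numerically differentiated Hessian,
#' step-halving).  \eqn{e^\beta} is the common odds ratio of a worse
#' outcome category for the exposed group; with a 2-level outcome the model
#' reduces exactly to binary logistic regression and the estimate equals
#' the 2x2 cross-product ratio.  Complete separation is reported as
#' non-convergence, not as a finite estimate.
#'
#' @param outcome ordered factor (or integer codes) with \eqn{\ge 2}
#'   observed levels; worse outcomes are higher levels.
#' @param group binary indicator (logical, 0/1, or 2-level factor;
#'   the second level / TRUE / 1 is the exposed group).
#' @param conf.level confidence level of the Wald interval.
#' @param maxit,tol Newton iteration controls.
#' @return list with \code{or}, \code{beta}, \code{se}, \code{ciLow},
#'   \code{ciHigh}, \code{thetas}, \code{logLik}, \code{converged},
#'   \code{iterations}.
#' @export
cumulativeLogitOR <- function(outcome, group, conf.level = 0.95,
                              maxit = 100L, tol = 1e-10) {
  keep <- !(is.na(outcome) | is.na(group))
  outcome <- outcome[keep]; group <- group[keep]
  if (is.factor(group)) group <- as.integer(group) - 1L
  group <- as.numeric(group)
  if (!all(group %in% c(0, 1))) stop("group must be binary")
  if (length(unique(group)) < 2L)
    stop("at least one observation per group is required")
  y <- if (is.factor(outcome)) as.integer(droplevels(outcome))
       else as.integer(factor(outcome))
  K <- max(y)
  if (K < 2L) stop("outcome must have at least 2 observed levels")

  # sufficient statistics: counts per (group, level)
  cnt <- table(factor(group, levels = c(0, 1)), factor(y, levels = 1:K))
  xs <- c(0, 1)

  nll <- function(par) {
    theta <- par[1:(K - 1)]; beta <- par[K]
    if (K > 2 && any(diff(theta) <= 0)) return(Inf)
    ll <- 0
    for (gi in 1:2) {
      eta <- theta - beta * xs[gi]
      cum <- c(0, stats::plogis(eta), 1)
      p <- pmax(diff(cum), 1e-300)
      ll <- ll + sum(cnt[gi, ] * log(p))
    }
    -ll
  }
  grad <- function(par) {
    theta <- par[1:(K - 1)]; beta <- par[K]
    g <- numeric(K)
    for (gi in 1:2) {
      eta <- theta - beta * xs[gi]
      Fj <- c(0, stats::plogis(eta), 1)
      fj <- c(0, stats::dlogis(eta), 0)
      p <- pmax(diff(Fj), 1e-300)
      w <- cnt[gi, ] / p
      # d p_j / d theta_m: +f_m for j = m, -f_m for j = m + 1
      for (m in 1:(K - 1))
        g[m] <- g[m] - (w[m] * fj[m + 1] - w[m + 1] * fj[m + 1])
      g[K] <- g[K] + xs[gi] * sum(w * diff(fj))
    }
    g
  }
  # initial values from marginal cumulative proportions
  pmarg <- cumsum(colSums(cnt)) / sum(cnt)
  par <- unname(base::c(
    stats::qlogis(pmin(pmax(pmarg[1:(K - 1)], 1e-4), 1 - 1e-4)), 0))

  converged <- FALSE; it <- 0L
  f0 <- nll(par)
  numHess <- function(par) {
    h <- 1e-5
    H <- matrix(0, K, K)
    for (j in 1:K) {
      e <- numeric(K); e[j] <- h
      H[, j] <- (grad(par + e) - grad(par - e)) / (2 * h)
    }
    (H + t(H)) / 2
  }
  while (it < maxit) {
    it <- it + 1L
    g <- grad(par)
    H <- numHess(par)
    step <- tryCatch(solve(H, g), error = function(e) g * 0.01)
    sz <- 1
    repeat {
      cand <- par - sz * step
      fc <- nll(cand)
      if (is.finite(fc) && fc <= f0 + 1e-12) break
      sz <- sz / 2
      if (sz < 1e-12) { cand <- par; fc <- f0; break }
    }
    moved <- f0 - fc
    par <- cand; f0 <- fc
    if (max(abs(g)) < tol || moved < tol) { converged <- TRUE; break }
  }
  beta <- par[K]
  if (abs(beta) > 15 || !converged) {
    warning("cumulative-logit fit did not converge (possible separation)")
    return(list(or = NA_real_, beta = beta, se = NA_real_, ciLow = NA_real_,
                ciHigh = NA_real_, thetas = par[1:(K - 1)], logLik = -f0,
                converged = FALSE, iterations = it))
  }
  H <- numHess(par)
  se <- sqrt(diag(solve(H)))[K]
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  list(or = exp(beta), beta = beta, se = se,
       ciLow = exp(beta - z * se), ciHigh = exp(beta + z * se),
       thetas = par[1:(K - 1)], logLik = -f0, converged = TRUE,
       iterations = it)
}

.dropDegenerate <- function(tab) {
  tab <- as.matrix(tab)
  zr <- rowSums(tab) == 0; zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    warning("dropping all-zero row(s)/column(s); df adjusted")
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  tab
}

#' Likelihood-ratio (G) test of independence for an r x c table
#'
#' \eqn{G = 2\sum O \ln(O/E)} with expectations from the margins; cells
#' with zero observed count contribute 0.  All-zero rows or columns are
#' dropped with a warning and the degrees of freedom
#' \eqn{(r-1)(c-1)} adjusted accordingly.
#'
#' @param tab matrix (or table) of non-negative counts.
#' @return list with \code{statistic}, \code{df}, \code{p_value}.
#' @examples
#' likelihoodRatioTest(matrix(c(10, 10, 10, 10), 2))$statistic  # 0
#' @export
likelihoodRatioTest <- function(tab) {
  tab <- .dropDegenerate(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  n <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / n
  terms <- tab * log(tab / E)
  terms[tab == 0] <- 0
  G <- 2 * sum(terms)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = G, df = df,
       p_value = stats::pchisq(G, df, lower.tail = FALSE))
}

#' Pearson chi-square test of independence
#'
#' Classical (uncorrected) chi-square on an r x c count table; all-zero
#' margins are dropped with a warning.
#'
#' @param tab matrix of non-negative counts.
#' @return list with \code{statistic}, \code{df}, \code{p_value}.
#' @export
chiSquareTest <- function(tab) {
  tab <- .dropDegenerate(tab)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact two-sided hypergeometric p-value (probability-mass ordering).
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return list with \code{p_value} and the conditional odds-ratio MLE.
#' @export
fisherExactTest <- function(tab) {
  stopifnot(all(dim(as.matrix(tab)) == 2L))
  ft <- stats::fisher.test(as.matrix(tab))
  list(p_value = ft$p.value, estimate = unname(ft$estimate))
}

#' Mann--Whitney U test
#'
#' Two-sample rank test with midranks for ties and the continuity-corrected
#' normal approximation.  When every value in both samples is identical the
#' test is degenerate and returns p = 1 with a warning.
#'
#' @param x,y numeric samples (NAs dropped).
#' @return list with \code{U} (number of (x, y) pairs with x > y, ties
#'   counted 1/2), \code{p_value}.
#' @export
mannWhitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(unique(c(x, y))) == 1L) {
    warning("all values tied; Mann-Whitney test is degenerate, p = 1")
    return(list(U = length(x) * length(y) / 2, p_value = 1))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Welch two-sample t-test
#'
#' @param x,y numeric samples of size \eqn{\ge 2} (NAs dropped).
#' @return list with \code{statistic}, \code{df} (Satterthwaite),
#'   \code{p_value}, \code{meanDiff}.
#' @export
welchT <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample must have at least 2 observations")
  tt <- stats::t.test(x, y)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, meanDiff = unname(diff(rev(tt$estimate))))
}

#' Cohen's d standardized mean difference
#'
#' \eqn{d = (\bar x - \bar y)/s_p} with the pooled standard deviation;
#' 0.2 / 0.5 / 0.8 are the conventional small / medium / large benchmarks.
#'
#' @param x,y numeric samples of size \eqn{\ge 2} (NAs dropped).
#' @return Numeric d.
#' @export
cohenD <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L)
    stop("each sample must have at least 2 observations")
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  if (sp == 0) return(0)
  (mean(x) - mean(y)) / sp
}

#' Benjamini--Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: on sorted p-values,
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, order restored.  Rejecting
#' all hypotheses with \eqn{q \le \alpha} is the classical BH procedure at
#' level \eqn{\alpha}.
#'
#' @param p numeric vector of p-values in \eqn{[0, 1]} (NAs carried
#'   through).
#' @return Vector of q-values, same order as \code{p}.
#' @examples
#' bhFDR(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bhFDR <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
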