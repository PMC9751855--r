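#' @include registry.R
NULL

#' Closed-form impairment probability under the latent-liability model
#'
#' The generator draws, for each child, a latent liability
#' \eqn{L \sim N(\mu_g, 1)} (\eqn{\mu_{EPT} = -\code{latent\_shift}},
#' \eqn{\mu_{TERM} = 0}) and, for each continuous domain \eqn{d}, a z-scale
#' score \eqn{z_d = \delta_d + \lambda_d L + \sqrt{1-\lambda_d^2}\,\epsilon}
#' with \eqn{\epsilon \sim N(0,1)}.  The marginal impairment probability is
#' therefore \eqn{\Phi(c_d - \delta_d - \lambda_d \mu_g)} for cutoff
#' \eqn{c_d}: the difficulty offset \eqn{\delta_d} sets the term-group rate
#' and the loading \eqn{\lambda_d} (together with the shift) the EPT excess.
#'
#' @param loading \eqn{\lambda_d \in [0, 1]}.
#' @param offset difficulty offset \eqn{\delta_d} (z units).
#' @param cutoff_z impairment cutoff on the z scale (see
#'   [registryEntries()]\code{$cutoff_z}).
#' @param groupMean latent liability mean \eqn{\mu_g} (0 for term,
#'   \eqn{-}shift for EPT).
#' @return Impairment probability.
#' @export
impairmentProbability <- function(loading, offset, cutoff_z, groupMean) {
  stats::pnorm(cutoff_z - offset - loading * groupMean)
}

#' Closed-form MND rate under the latent-liability model
#'
#' Each of the \code{nDomains} Touwen functional domains is dysfunctional
#' when \eqn{\lambda L + \sqrt{1-\lambda^2}\epsilon_j < \tau}, with
#' \eqn{\tau} set so that the per-domain dysfunction probability at
#' liability 0 equals \code{baseRate}.  MND (simple or complex) means at
#' least one dysfunctional domain; its marginal rate is obtained by
#' integrating over \eqn{L \sim N(\mu_g, 1)}.
#'
#' @param baseRate per-domain dysfunction probability at liability 0.
#' @param loading Touwen loading \eqn{\lambda \in [0, 1)}.
#' @param groupMean latent liability mean.
#' @param nDomains number of Touwen functional domains (8).
#' @return MND probability (dysfunction in at least one domain).
#' @export
mndRate <- function(baseRate, loading, groupMean, nDomains = 8L) {
  s <- sqrt(1 - loading^2)
  tau <- stats::qnorm(baseRate) * s
  grid <- seq(groupMean - 8, groupMean + 8, length.out = 801L)
  w <- stats::dnorm(grid, mean = groupMean)
  w <- w / sum(w)
  p <- stats::pnorm((tau - loading * grid) / s)
  sum(w * (1 - (1 - p)^nDomains))
}

.floorRate <- function(rate, N) {
  floored <- rate <= 0 | rate >= 1
  rate[rate <= 0] <- 1 / (2 * N[rate <= 0])
  rate[rate >= 1] <- 1 - 1 / (2 * N[rate >= 1])
  list(rate = rate, floored = floored)
}

#' Calibrate generator loadings to target impairment rates
#'
#' Solves, per domain, for the loading and difficulty offset of the
#' latent-liability model so that the model-implied impairment probabilities
#' match target (EPT, term) rates.  For continuous domains the solution is
#' closed-form: \eqn{\delta_d = c_d - \Phi^{-1}(\mathrm{term}_d)} and
#' \eqn{\lambda_d = (\Phi^{-1}(\mathrm{ept}_d) -
#' \Phi^{-1}(\mathrm{term}_d))/\mathrm{shift}}.  For MND the pair
#' (\code{touwen_base_rate}, Touwen loading) is found by numerical
#' root-finding on the [mndRate()] integral.
#'
#' When \code{latentShift} is NULL it is set to the largest probit gap
#' \eqn{\Phi^{-1}(\mathrm{ept}) - \Phi^{-1}(\mathrm{term})} across
#' continuous domains, which puts every loading in \eqn{[0, 1]}.  Target
#' rates of exactly 0 (or 1) are unreachable on the probit scale; they are
#' floored at \eqn{1/(2N)} and flagged in the feasibility table.  Pairs
#' that remain infeasible (term rate above EPT rate, or a required loading
#' above 1 for a user-fixed shift) are reported per domain, never clamped.
#'
#' @param targets data.frame with columns \code{domain}, \code{ept_rate},
#'   \code{term_rate} (and optionally \code{ept_N}, \code{term_N}, used for
#'   the zero-rate floor).  Defaults to [referenceImpairmentRates()].
#' @param latentShift fixed latent shift, or NULL to choose it from the data.
#' @param registry a [DomainRegistry-class].
#' @param nDomains number of Touwen functional domains.
#' @return list with elements \code{latent_shift}, \code{loadings} (named,
#'   all 20 domains), \code{offsets} (named, 19 continuous domains),
#'   \code{touwen_base_rate}, and \code{feasibility} (data.frame with one
#'   row per domain: \code{feasible}, \code{floored}, \code{note}).
#' @examples
#' cal <- calibrateLoadings()
#' cal$latent_shift
#' round(cal$loadings, 2)
#' @export
calibrateLoadings <- function(targets = referenceImpairmentRates(),
                              latentShift = NULL,
                              registry = domainRegistry(),
                              nDomains = 8L) {
  e <- registryEntries(registry)
  if (!all(c("domain", "ept_rate", "term_rate") %in% names(targets)))
    stop("targets must have columns domain, ept_rate, term_rate")
  miss <- setdiff(e$abbreviation, targets$domain)
  if (length(miss))
    stop("targets missing domain(s): ", paste(miss, collapse = ", "))
  t <- targets[match(e$abbreviation, targets$domain), ]
  eN <- if ("ept_N" %in% names(t)) t$ept_N else rep(100, nrow(t))
  tN <- if ("term_N" %in% names(t)) t$term_N else rep(100, nrow(t))
  fe <- .floorRate(t$ept_rate, eN)
  ft <- .floorRate(t$term_rate, tN)
  ept <- fe$rate; term <- ft$rate
  if (any(ept <= 0 | ept >= 1 | term <= 0 | term >= 1))
    stop("target rates must lie in (0, 1) after flooring")
  floored <- fe$floored | ft$floored

  cont <- e$instrument != "TOUWEN"
  gap <- stats::qnorm(ept) - stats::qnorm(term)
  feasible <- rep(TRUE, nrow(e))
  note <- ifelse(floored, "zero/unit rate floored at 1/(2N)", "")

  if (is.null(latentShift)) {
    pos <- cont & gap > 0
    latentShift <- if (any(pos)) max(gap[pos]) else 0
  }
  loadings <- stats::setNames(rep(NA_real_, nrow(e)), e$abbreviation)
  offsets <- stats::setNames(rep(NA_real_, sum(cont)), e$abbreviation[cont])

  for (i in which(cont)) {
    d <- e$abbreviation[i]
    offsets[d] <- e$cutoff_z[i] - stats::qnorm(term[i])
    if (gap[i] < 0) {
      feasible[i] <- FALSE
      note[i] <- paste(note[i],
        "term rate exceeds EPT rate: no non-negative loading exists")
      next
    }
    if (latentShift == 0) {
      # tie-break: with no group shift any loading matches equal rates;
      # return the smallest (0)
      if (gap[i] == 0) loadings[d] <- 0
      else { feasible[i] <- FALSE; note[i] <- "nonzero gap with zero shift" }
      next
    }
    lam <- gap[i] / latentShift
    if (lam > 1 + 1e-9) {
      feasible[i] <- FALSE
      note[i] <- sprintf("requires loading %.3f > 1 at shift %.3f",
                         lam, latentShift)
    } else loadings[d] <- min(lam, 1)
  }

  # MND: 2-parameter numerical solve on the closed-form integral
  iM <- which(e$abbreviation == "MND")
  targ <- c(ept[iM], term[iM])
  obj <- function(par) {
    base <- stats::plogis(par[1])
    lam <- 0.995 * stats::plogis(par[2])
    r <- c(mndRate(base, lam, -latentShift, nDomains),
           mndRate(base, lam, 0, nDomains))
    sum((r - targ)^2)
  }
  best <- NULL
  for (start in list(c(stats::qlogis(0.05), 0), c(stats::qlogis(0.02), 1),
                     c(stats::qlogis(0.1), -1))) {
    fit <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  touwen_base_rate <- stats::plogis(best$par[1])
  loadings["MND"] <- 0.995 * stats::plogis(best$par[2])
  if (best$value > 1e-6) {
    feasible[iM] <- FALSE
    note[iM] <- sprintf("MND targets not reached (residual %.2g)", best$value)
  }

  list(latent_shift = latentShift,
       loadings = loadings,
       offsets = offsets,
       touwen_base_rate = touwen_base_rate,
       feasibility = data.frame(domain = e$abbreviation, feasible = feasible,
                                floored = floored, note = trimws(note),
                                row.names = e$abbreviation,
                                stringsAsFactors = FALSE))
}

.checkProb <- function(x, field, open1 = FALSE) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1) ||
      (open1 && any(x >= 1)))
    stop("invalid SyntheticConfig: ", field, " must be ",
         if (open1) "in [0, 1)" else "in [0, 1]", call. = FALSE)
}

#' Configuration of the synthetic-cohort generator
#'
#' Assembles and validates the parameters of the latent-liability generator.
#' Defaults emulate the reference extremely-preterm cohort: group sizes
#' 56/37, loadings, offsets and Touwen base rate calibrated to
#' [referenceImpairmentRates()], covariate marginals from the published
#' cohort characteristics, and 8\% missing cells (missing completely at
#' random, matching the non-systematic missingness of the reference data).
#'
#' @param n_ept,n_term group sizes (each at least 2).
#' @param latent_shift group difference in latent liability, SD units
#'   (EPT mean is \code{-latent_shift}).
#' @param loadings named numeric, loading per domain in \eqn{[0, 1]}
#'   (all 20 domains, MND included).
#' @param offsets named numeric, per-domain difficulty offset for the 19
#'   continuous domains (z units).
#' @param touwen_base_rate per-domain Touwen dysfunction probability at
#'   liability 0.
#' @param missing_rate probability that any score (or the Touwen block) is
#'   missing, in \eqn{[0, 1)}.
#' @param seed integer RNG seed; mandatory, generation is fully reproducible.
#' @param sex_p named numeric, probability of male sex per group.
#' @param mother_education_p 3 x 2 matrix of level probabilities
#'   (rows: high-school-or-lower, bachelor, master-or-higher; columns EPT,
#'   TERM; each column sums to 1).
#' @param brain_injury_p named numeric, probability of severe neonatal brain
#'   injury (IVH grade III-IV) per group.
#' @param morbidity_p named numeric, probability of the combined neonatal
#'   morbidity flag (sepsis and/or BPD and/or NEC) per group.
#' @param registry a [DomainRegistry-class].
#' @return A validated list of class \code{SyntheticConfig}.
#' @seealso [generateCohort()], [calibrateLoadings()]
#' @export
syntheticConfig <- function(n_ept = 56L, n_term = 37L,
                            latent_shift = NULL, loadings = NULL,
                            offsets = NULL, touwen_base_rate = NULL,
                            missing_rate = 0.08, seed,
                            sex_p = c(EPT = 35 / 56, TERM = 19 / 37),
                            mother_education_p =
                              cbind(EPT = c(0.46, 0.32, 0.22),
                                    TERM = c(0.19, 0.30, 0.51)),
                            brain_injury_p = c(EPT = 6 / 56, TERM = 0),
                            morbidity_p = c(EPT = 0.6, TERM = 0),
                            registry = domainRegistry()) {
  if (missing(seed) || is.null(seed))
    stop("invalid SyntheticConfig: seed is mandatory", call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed))
    stop("invalid SyntheticConfig: seed must be an integer", call. = FALSE)
  if (is.null(latent_shift) || is.null(loadings) || is.null(offsets) ||
      is.null(touwen_base_rate)) {
    cal <- calibrateLoadings(registry = registry)
    if (is.null(latent_shift)) latent_shift <- cal$latent_shift
    if (is.null(loadings)) loadings <- cal$loadings
    if (is.null(offsets)) offsets <- cal$offsets
    if (is.null(touwen_base_rate)) touwen_base_rate <- cal$touwen_base_rate
  }
  for (nm in c("n_ept", "n_term")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 2 ||
        v != round(v))
      stop("invalid SyntheticConfig: ", nm, " must be an integer >= 2",
           call. = FALSE)
  }
  if (!is.numeric(latent_shift) || length(latent_shift) != 1L ||
      is.na(latent_shift))
    stop("invalid SyntheticConfig: latent_shift must be a number",
         call. = FALSE)
  abbr <- layoutOrder(registry)
  if (!all(abbr %in% names(loadings)))
    stop("invalid SyntheticConfig: loadings must be named for all 20 domains",
         call. = FALSE)
  .checkProb(loadings[abbr], "loadings")
  sc <- scoreDomains(registry)
  if (!all(sc %in% names(offsets)))
    stop("invalid SyntheticConfig: offsets must be named for the 19 score domains",
         call. = FALSE)
  if (anyNA(offsets[sc]))
    stop("invalid SyntheticConfig: offsets must be finite", call. = FALSE)
  .checkProb(touwen_base_rate, "touwen_base_rate")
  .checkProb(missing_rate, "missing_rate", open1 = TRUE)
  .checkProb(sex_p, "sex_p"); .checkProb(brain_injury_p, "brain_injury_p")
  .checkProb(morbidity_p, "morbidity_p")
  if (!is.matrix(mother_education_p) || nrow(mother_education_p) != 3L ||
      ncol(mother_education_p) != 2L ||
      any(abs(colSums(mother_education_p) - 1) > 1e-6))
    stop("invalid SyntheticConfig: mother_education_p must be a 3 x 2 matrix of probabilities with unit column sums",
         call. = FALSE)
  structure(list(n_ept = as.integer(n_ept), n_term = as.integer(n_term),
                 latent_shift = latent_shift,
                 loadings = loadings[abbr], offsets = offsets[sc],
                 touwen_base_rate = touwen_base_rate,
                 missing_rate = missing_rate, seed = seed,
                 sex_p = sex_p, mother_education_p = mother_education_p,
                 brain_injury_p = brain_injury_p, morbidity_p = morbidity_p,
                 registry = registry),
            class = "SyntheticConfig")
}

#' Generate a synthetic cohort
#'
#' Draws a two-group cohort from the group-shifted latent-liability model.
#' For each child a latent liability \eqn{L \sim N(\mu_g, 1)}
#' (\eqn{\mu_{EPT} = -}shift, \eqn{\mu_{TERM} = 0}) induces correlated
#' impairments across instruments: continuous domains follow
#' \eqn{\mathrm{mean} + \mathrm{SD}(\delta_d + \lambda_d L +
#' \sqrt{1-\lambda_d^2}\epsilon)} on their native scales (MABC-2 and
#' NEPSY-II rounded to integer scores 1--19, SIPT clipped to \eqn{[-3, 3]}),
#' and each of the 8 Touwen domains is dysfunctional when its own
#' liability-linked latent draw falls below the probit threshold implied by
#' \code{touwen_base_rate}.  Covariates are drawn from the configured
#' marginals, independent of liability.  Each score (and the Touwen block
#' as a whole) is missing completely at random at \code{missing_rate}.
#' The result is fully reproducible from \code{config$seed}.
#'
#' @param config a \code{SyntheticConfig} from [syntheticConfig()].
#' @return A [Cohort-class].
#' @examples
#' coh <- generateCohort(syntheticConfig(n_ept = 20, n_term = 15, seed = 1))
#' coh
#' @export
generateCohort <- function(config) {
  if (!inherits(config, "SyntheticConfig"))
    stop("config must be created by syntheticConfig()")
  reg <- config$registry
  e <- registryEntries(reg)
  set.seed(config$seed)
  n <- config$n_ept + config$n_term
  group <- c(rep("EPT", config$n_ept), rep("TERM", config$n_term))
  mu <- ifelse(group == "EPT", -config$latent_shift, 0)
  L <- stats::rnorm(n, mean = mu)

  sex <- ifelse(stats::runif(n) < config$sex_p[group], "M", "F")
  medu <- integer(n)
  for (g in c("EPT", "TERM")) {
    idx <- which(group == g)
    medu[idx] <- sample.int(3L, length(idx), replace = TRUE,
                            prob = config$mother_education_p[, g]) - 1L
  }
  brain_injury <- stats::runif(n) < config$brain_injury_p[group]
  morbidity <- stats::runif(n) < config$morbidity_p[group]

  lamT <- config$loadings[["MND"]]
  sT <- sqrt(1 - lamT^2)
  tau <- stats::qnorm(config$touwen_base_rate) * sT
  touwen <- matrix(NA, nrow = n, ncol = 8L,
                   dimnames = list(NULL, paste0("touwen_", 1:8)))
  for (j in 1:8)
    touwen[, j] <- lamT * L + sT * stats::rnorm(n) < tau

  sc <- scoreDomains(reg)
  scores <- matrix(NA_real_, nrow = n, ncol = length(sc),
                   dimnames = list(NULL, sc))
  for (d in sc) {
    lam <- config$loadings[[d]]
    z <- config$offsets[[d]] + lam * L + sqrt(1 - lam^2) * stats::rnorm(n)
    i <- match(d, e$abbreviation)
    if (e$instrument[i] == "SIPT") {
      scores[, d] <- pmin(3, pmax(-3, z))
    } else {
      scores[, d] <- pmin(19, pmax(1, round(e$native_mean[i] +
                                              e$native_sd[i] * z)))
    }
  }

  if (config$missing_rate > 0) {
    blk <- stats::runif(n) < config$missing_rate
    touwen[blk, ] <- NA
    for (d in sc)
      scores[stats::runif(n) < config$missing_rate, d] <- NA_real_
  }

  children <- data.frame(
    child_id = sprintf("%s%03d", ifelse(group == "EPT", "E", "T"),
                       c(seq_len(config$n_ept), seq_len(config$n_term))),
    group = group, sex = sex, mother_education = medu,
    brain_injury = brain_injury, morbidity = morbidity,
    touwen, scores, stringsAsFactors = FALSE, check.names = FALSE)
  new("Cohort", children = children, registry = reg)
}
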