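#' @include registry.R AllClasses.R
NULL

#' Classify minor neurological dysfunction from Touwen domain flags
#'
#' The Touwen examination covers eight functional domains.  Dysfunction in
#' one or two domains is simple MND, in more than two complex MND, and in
#' none a normal neurological condition.  A missing flag makes the whole
#' classification indeterminate (propagated as missing) rather than being
#' scored on a partial count.
#'
#' @param flags logical vector of length 8 (TRUE = dysfunctional domain),
#'   NAs allowed.
#' @return list with \code{status} (\code{"NORMAL"}, \code{"SIMPLE"},
#'   \code{"COMPLEX"}, or NA if any flag is missing) and
#'   \code{n_dysfunctional} (0--8, NA if indeterminate).
#' @examples
#' classifyMND(rep(FALSE, 8))$status              # NORMAL
#' classifyMND(c(TRUE, TRUE, rep(FALSE, 6)))$status  # SIMPLE
#' @export
classifyMND <- function(flags) {
  if (length(flags) != 8L)
    stop("exactly 8 Touwen domain flags are required, got ", length(flags))
  flags <- as.logical(flags)
  if (anyNA(flags))
    return(list(status = NA_character_, n_dysfunctional = NA_integer_))
  k <- sum(flags)
  status <- if (k == 0L) "NORMAL" else if (k <= 2L) "SIMPLE" else "COMPLEX"
  list(status = status, n_dysfunctional = as.integer(k))
}

# vectorised MND status over a children x 8 flag matrix
.mndStatusMatrix <- function(touwen) {
  k <- rowSums(touwen)
  status <- rep(NA_character_, length(k))
  ok <- !is.na(k)
  status[ok & k == 0L] <- "NORMAL"
  status[ok & k >= 1L & k <= 2L] <- "SIMPLE"
  status[ok & k > 2L] <- "COMPLEX"
  list(status = status, n = as.integer(k))
}

#' Per-instrument impairment call for a raw score
#'
#' Impairment is performance more than 1 SD below test norms on the
#' instrument's native scale: MABC-2 and NEPSY-II standard/scaled score
#' \eqn{\le 7} (scores are integers 1--19); SIPT z-score below \eqn{-1.0}.
#' The SIPT boundary is strict by default (a score of exactly \eqn{-1.0} is
#' not impaired, honouring the "below 1 SD" cutoff); set
#' \code{siptStrict = FALSE} to include the boundary in the impaired band.
#' Missing scores yield no call (NA).
#'
#' @param score numeric vector on the instrument's native scale.
#' @param instrument one of \code{"MABC2"}, \code{"SIPT"}, \code{"NEPSY2"}.
#' @param siptStrict logical; see above.
#' @return logical vector (TRUE = impaired, NA = no call).
#' @examples
#' isImpaired(c(7, 8), "NEPSY2")      # TRUE FALSE
#' isImpaired(c(-1.2, -1, 0), "SIPT") # TRUE FALSE FALSE
#' @export
isImpaired <- function(score, instrument = c("MABC2", "SIPT", "NEPSY2"),
                       siptStrict = TRUE) {
  instrument <- match.arg(instrument)
  ok <- !is.na(score)
  if (instrument == "SIPT") {
    if (any(ok & (score < -3 - 1e-9 | score > 3 + 1e-9)))
      stop("SIPT z-scores must lie in [-3, 3]")
    if (siptStrict) score < -1 else score <= -1
  } else {
    if (any(ok & (score < 1 | score > 19)))
      stop(instrument, " scores must lie in [1, 19]")
    score <= 7
  }
}

#' Impute missing scores with the group median
#'
#' Replaces missing values of one score domain, within one group, by the
#' median of the observed values in that group (the imputation used for
#' sparse non-systematic missingness in skewed score distributions).  The
#' imputed cells are recorded in the \code{imputations} attribute of the
#' returned cohort's child table.
#'
#' @param cohort a [Cohort-class].
#' @param domain a score-domain abbreviation.
#' @param group \code{"EPT"} or \code{"TERM"}.
#' @return The cohort with imputed values; idempotent when nothing is
#'   missing.
#' @export
imputeGroupMedian <- function(cohort, domain, group) {
  stopifnot(is(cohort, "Cohort"))
  ch <- childData(cohort)
  if (!domain %in% scoreDomains(registryOf(cohort)))
    stop("unknown score domain: ", domain)
  if (!domain %in% names(ch)) stop("cohort has no column ", domain)
  sel <- ch$group == group
  obs <- ch[[domain]][sel]
  if (all(is.na(obs)))
    stop("no observed ", domain, " value in group ", group,
         "; cannot impute")
  med <- stats::median(obs, na.rm = TRUE)
  fill <- sel & is.na(ch[[domain]])
  if (any(fill)) {
    ch[[domain]][fill] <- med
    log <- rbind(attr(ch, "imputations"),
                 data.frame(child_id = ch$child_id[fill], domain = domain,
                            method = "group_median", value = med,
                            stringsAsFactors = FALSE))
    attr(ch, "imputations") <- log
  }
  methods::initialize(cohort, children = ch)
}

#' Impute a composite member from the mean of its observed siblings
#'
#' Fills a missing target column for individual children with the mean of
#' the observed members of its composite (the rule used for missing IQ
#' subtest scores, where a missing subtest is replaced by the mean of the
#' available Performance or Verbal subtests).  Children whose target is
#' already observed are untouched; a child with no observed member raises
#' an error.
#'
#' @param cohort a [Cohort-class] (any data.frame columns accepted; the
#'   composite need not be registry domains).
#' @param members character, columns forming the composite.
#' @param target column to fill.
#' @return The cohort with imputed values and an \code{imputations} log
#'   attribute; idempotent.
#' @export
imputeSubtestMean <- function(cohort, members, target) {
  stopifnot(is(cohort, "Cohort"))
  ch <- childData(cohort)
  missing_cols <- setdiff(c(members, target), names(ch))
  if (length(missing_cols))
    stop("cohort has no column(s): ", paste(missing_cols, collapse = ", "))
  fill <- which(is.na(ch[[target]]))
  for (i in fill) {
    vals <- unlist(ch[i, members, drop = TRUE])
    if (all(is.na(vals)))
      stop("child ", ch$child_id[i],
           ": all composite members missing, cannot impute ", target)
    ch[[target]][i] <- mean(vals, na.rm = TRUE)
  }
  if (length(fill)) {
    log <- rbind(attr(ch, "imputations"),
                 data.frame(child_id = ch$child_id[fill], domain = target,
                            method = "subtest_mean",
                            value = ch[[target]][fill],
                            stringsAsFactors = FALSE))
    attr(ch, "imputations") <- log
  }
  methods::initialize(cohort, children = ch)
}

#' Build the 20-domain impairment matrix
#'
#' Converts raw multi-instrument scores into binary impairment calls: the
#' MND column pools simple and complex MND from the eight Touwen flags
#' ([classifyMND()]); the 19 score columns apply the per-instrument cutoffs
#' ([isImpaired()]).  Missing scores (and Touwen sets with any missing flag)
#' propagate to the observed mask: an unobserved cell is never counted as
#' impaired, and downstream denominators follow the observed data.
#'
#' @param cohort a [Cohort-class].
#' @param siptStrict passed to [isImpaired()].
#' @return An [ImpairmentMatrix-class] (domains x children), rows in
#'   registry layout order.
#' @examples
#' coh <- generateCohort(syntheticConfig(n_ept = 10, n_term = 10, seed = 1))
#' im <- buildImpairmentMatrix(coh)
#' colSums(impairmentCalls(im))   # per-child impairment burden
#' @export
buildImpairmentMatrix <- function(cohort, siptStrict = TRUE) {
  stopifnot(is(cohort, "Cohort"))
  reg <- registryOf(cohort)
  e <- registryEntries(reg)
  ch <- childData(cohort)
  n <- nrow(ch)
  abbr <- e$abbreviation
  calls <- matrix(FALSE, nrow = length(abbr), ncol = n,
                  dimnames = list(abbr, ch$child_id))
  observed <- matrix(FALSE, nrow = length(abbr), ncol = n,
                     dimnames = list(abbr, ch$child_id))

  tw_cols <- paste0("touwen_", 1:8)
  if (all(tw_cols %in% names(ch))) {
    tw <- as.matrix(ch[tw_cols])
    mnd <- .mndStatusMatrix(tw)
    observed["MND", ] <- !is.na(mnd$status)
    calls["MND", ] <- !is.na(mnd$status) & mnd$status != "NORMAL"
  }

  for (d in intersect(scoreDomains(reg), names(ch))) {
    ins <- e$instrument[match(d, abbr)]
    call_d <- isImpaired(ch[[d]], ins, siptStrict = siptStrict)
    observed[d, ] <- !is.na(call_d)
    calls[d, ] <- !is.na(call_d) & call_d
  }

  cd <- ch[intersect(c("child_id", "group", "sex", "mother_education",
                       "brain_injury", "morbidity"), names(ch))]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(calls = calls, observed = observed),
    rowData = S4Vectors::DataFrame(e, row.names = abbr),
    colData = S4Vectors::DataFrame(cd, row.names = ch$child_id))
  out <- new("ImpairmentMatrix", se)
  S4Vectors::metadata(out)$siptStrict <- siptStrict
  out
}

#' Write an impairment matrix as TSV
#'
#' One row per child, one 0/1/NA column per domain (NA = unobserved),
#' columns in registry layout order, preceded by \code{child_id} and
#' \code{group}.
#'
#' @param im an [ImpairmentMatrix-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeImpairmentMatrix <- function(im, path) {
  calls <- t(impairmentCalls(im)) * 1L
  calls[!t(observedMask(im))] <- NA_integer_
  df <- data.frame(child_id = colnames(im), group = childGroup(im),
                   calls, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}
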