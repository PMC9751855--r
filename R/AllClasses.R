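#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
NULL

#' DomainRegistry: the catalogue of neurodevelopmental test domains
#'
#' Holds the fixed set of 20 test domains used throughout the package: the
#' minor-neurological-dysfunction (MND) summary of the Touwen examination,
#' three MABC-2 motor subtests, six SIPT sensory-integration tests, and ten
#' NEPSY-II neuropsychological subtests.  Row order is the canonical
#' relationship-map layout order (upper semicircle MND..BMC, lower semicircle
#' AuAttn..GeoP).
#'
#' @slot entries data.frame with one row per domain and columns
#'   \code{abbreviation}, \code{label}, \code{instrument} (one of
#'   \code{TOUWEN}, \code{MABC2}, \code{SIPT}, \code{NEPSY2}), \code{scale},
#'   \code{native_mean}, \code{native_sd}, \code{cutoff_z} (impairment cutoff
#'   expressed in native-SD units of the continuous generating scale; NA for
#'   the derived MND column).
#'
#' @seealso [domainRegistry()]
#' @export
setClass("DomainRegistry", representation(entries = "data.frame"))

setValidity("DomainRegistry", function(object) {
  e <- object@entries
  msgs <- character()
  need <- c("abbreviation", "label", "instrument", "scale",
            "native_mean", "native_sd", "cutoff_z")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  if (nrow(e) != 20L)
    msgs <- c(msgs, "registry must contain exactly 20 domains")
  if (anyDuplicated(e$abbreviation))
    msgs <- c(msgs, "domain abbreviations must be unique")
  comp <- table(factor(e$instrument,
                       levels = c("TOUWEN", "MABC2", "SIPT", "NEPSY2")))
  if (!all(comp == c(TOUWEN = 1L, MABC2 = 3L, SIPT = 6L, NEPSY2 = 10L)))
    msgs <- c(msgs,
              "composition must be 1 Touwen + 3 MABC-2 + 6 SIPT + 10 NEPSY-II")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Cohort: child-level records plus their domain registry
#'
#' A thin container pairing a child-level table (group label, covariates,
#' eight Touwen domain-dysfunction flags, and raw scores on the 19
#' continuous-score domains, all with missing values allowed) with the
#' [DomainRegistry-class] that interprets the score columns.
#'
#' @slot children data.frame, one row per child; see [cohortColumns()] for the
#'   required layout.
#' @slot registry a [DomainRegistry-class].
#'
#' @seealso [generateCohort()], [readCohort()], [buildImpairmentMatrix()]
#' @export
setClass("Cohort",
         representation(children = "data.frame", registry = "DomainRegistry"))

setValidity("Cohort", function(object) {
  ch <- object@children
  msgs <- character()
  base <- c("child_id", "group")
  if (!all(base %in% names(ch)))
    return("children must have at least child_id and group columns")
  if (anyDuplicated(ch$child_id))
    msgs <- c(msgs, "child_id values must be unique")
  if (any(is.na(ch$group)))
    msgs <- c(msgs, "group must be present for every child")
  bad <- setdiff(unique(as.character(ch$group)), c("EPT", "TERM"))
  if (length(bad))
    msgs <- c(msgs, paste0("unknown group label(s): ",
                           paste(bad, collapse = ", ")))
  sc <- intersect(names(ch), scoreDomains(object@registry))
  if ("MND" %in% names(ch))
    msgs <- c(msgs, "MND is derived from the Touwen flags, never stored raw")
  for (d in sc) if (!is.numeric(ch[[d]]))
    msgs <- c(msgs, paste0("score column ", d, " must be numeric"))
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' ImpairmentMatrix: binary impairment calls for a cohort
#'
#' Extends \linkS4class{SummarizedExperiment}; rows are the 20 registry
#' domains (in layout order), columns are children.  Two logical assays:
#' \code{calls} (TRUE = impaired) and \code{observed} (FALSE where the
#' underlying score was missing and unimputed).  A call is never TRUE where
#' it is unobserved, so missing data can never count as impairment.
#' Child covariates (group, sex, ...) live in \code{colData}, domain
#' metadata in \code{rowData}.
#'
#' @seealso [buildImpairmentMatrix()], [impairmentCalls()], [observedMask()]
#' @export
setClass("ImpairmentMatrix", contains = "SummarizedExperiment")

setValidity("ImpairmentMatrix", function(object) {
  msgs <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("calls", "observed") %in% an))
    return("assays 'calls' and 'observed' are required")
  calls <- SummarizedExperiment::assay(object, "calls")
  obs <- SummarizedExperiment::assay(object, "observed")
  if (!is.logical(calls) || !is.logical(obs))
    msgs <- c(msgs, "calls and observed must be logical matrices")
  else {
    if (any(calls & !obs))
      msgs <- c(msgs, "a call must be FALSE wherever it is unobserved")
    if (anyNA(calls) || anyNA(obs))
      msgs <- c(msgs, "calls/observed must be NA-free (missingness is encoded in 'observed')")
  }
  if (!"group" %in% names(SummarizedExperiment::colData(object)))
    msgs <- c(msgs, "colData must carry a 'group' column")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' BurdenProfile: per-child impairment burden
#'
#' @slot burden data.frame with columns \code{child_id}, \code{group},
#'   \code{burden} (number of impaired domains, 0--20) and \code{n_observed}
#'   (number of domains with an observed call for that child).
#'
#' @seealso [burdenProfile()], [burdenHistogram()], [exceedsReferenceMax()]
#' @export
setClass("BurdenProfile", representation(burden = "data.frame"))

setValidity("BurdenProfile", function(object) {
  b <- object@burden
  need <- c("child_id", "group", "burden", "n_observed")
  if (!all(need %in% names(b)))
    return(paste("burden must have columns:", paste(need, collapse = ", ")))
  if (any(b$burden > b$n_observed))
    return("burden cannot exceed the number of observed domains")
  if (any(b$burden < 0L))
    return("burden must be non-negative")
  TRUE
})

#' CooccurrenceGraph: thresholded co-occurrence relationship map
#'
#' Nodes are the 20 test domains, annotated with the number of impaired
#' children; the symmetric pair-count matrix holds, for every unordered pair
#' of domains, the number of children impaired in both.  A child with a
#' missing (unobserved) call in either domain of a pair contributes nothing
#' to that pair.
#'
#' @slot nodeCounts named integer vector (one entry per domain, layout order).
#' @slot pairCounts symmetric integer matrix, diagonal set to NA (a domain is
#'   never paired with itself).
#' @slot group character, which group the map describes.
#' @slot nChildren integer, number of children in that group.
#' @slot thresholds integer vector of edge-display cutoffs.
#'
#' @seealso [pairCounts()], [edgesAtThreshold()], [totalImpairedPairs()],
#'   [renderRelationshipMap()]
#' @export
setClass("CooccurrenceGraph",
         representation(nodeCounts = "integer", pairCounts = "matrix",
                        group = "character", nChildren = "integer",
                        thresholds = "integer"))

setValidity("CooccurrenceGraph", function(object) {
  pc <- object@pairCounts
  nc <- object@nodeCounts
  msgs <- character()
  if (nrow(pc) != length(nc) || ncol(pc) != length(nc))
    return("pairCounts must be square with one row per node")
  off <- !diag(TRUE, nrow(pc))
  if (!isTRUE(all.equal(pc[off], t(pc)[off])))
    msgs <- c(msgs, "pairCounts must be symmetric")
  lim <- outer(nc, nc, pmin)
  if (any(pc[off] > lim[off]))
    msgs <- c(msgs, "a pair count can never exceed either node count")
  if (any(object@thresholds < 1L))
    msgs <- c(msgs, "thresholds must be >= 1")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' BootstrapResult: a bootstrapped statistic with its BCa interval
#'
#' @slot estimate numeric, the statistic on the original data.
#' @slot statistic character, what was bootstrapped.
#' @slot B integer, number of resamples.
#' @slot resampleStats numeric of length B.
#' @slot ciLow,ciHigh numeric, 95\% BCa bounds (level recorded in
#'   \code{level}).
#' @slot level numeric, confidence level.
#' @slot pValue numeric, two-sided bootstrap p-value where defined (NA
#'   otherwise).
#' @slot seed integer, RNG seed used (NA if none supplied).
#'
#' @seealso [bootstrapT()], [bcaInterval()]
#' @export
setClass("BootstrapResult",
         representation(estimate = "numeric", statistic = "character",
                        B = "integer", resampleStats = "numeric",
                        ciLow = "numeric", ciHigh = "numeric",
                        level = "numeric", pValue = "numeric",
                        seed = "integer"))

setValidity("BootstrapResult", function(object) {
  if (length(object@resampleStats) != object@B)
    return("resampleStats must have length B")
  if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
      object@ciLow > object@ciHigh)
    return("interval bounds must be ordered")
  TRUE
})

#' RegressionResult: wild-bootstrap multiple regression fit
#'
#' @slot coefficients named numeric, OLS coefficients on the original data.
#' @slot ci matrix (p x 2) of per-coefficient BCa bounds.
#' @slot pValues named numeric, two-sided bootstrap p-values per coefficient
#'   (null-centred resample distribution).
#' @slot r2,adjR2 numeric, coefficient of determination of the original fit.
#' @slot B integer, number of wild resamples.
#' @slot weightLaw character, "rademacher" or "mammen".
#' @slot resampleCoefs matrix (p x B) of resampled coefficients.
#' @slot residuals,fitted numeric, from the original fit.
#' @slot seed integer.
#'
#' @seealso [wildBootstrapRegression()]
#' @export
setClass("RegressionResult",
         representation(coefficients = "numeric", ci = "matrix",
                        pValues = "numeric", r2 = "numeric", adjR2 = "numeric",
                        B = "integer", weightLaw = "character",
                        resampleCoefs = "matrix", residuals = "numeric",
                        fitted = "numeric", seed = "integer"))

setValidity("RegressionResult", function(object) {
  p <- length(object@coefficients)
  if (nrow(object@ci) != p || ncol(object@ci) != 2L)
    return("ci must be a p x 2 matrix")
  ok <- stats::complete.cases(object@ci)
  if (any(object@ci[ok, 1] > object@ci[ok, 2]))
    return("interval bounds must be ordered")
  if (!is.na(object@adjR2) && !is.na(object@r2) &&
      object@adjR2 > object@r2 + 1e-12)
    return("adjusted r-squared cannot exceed r-squared")
  TRUE
})
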