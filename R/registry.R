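#' @include AllClasses.R
NULL

# Continuous-scale impairment cutoffs in native-SD (z) units of the
# generating scale.  MABC-2 / NEPSY-II scores are integers obtained by
# rounding 10 + 3z, so "standard score <= 7" is the event z < (7.5 - 10)/3.
# SIPT is impaired below -1 z (strict by default, see isImpaired()).
.CUT_INT <- (7.5 - 10) / 3
.CUT_SIPT <- -1

#' The canonical 20-domain test registry
#'
#' Returns the fixed catalogue of 20 neurodevelopmental test domains used for
#' impairment classification and relationship maps, in relationship-map
#' layout order: upper semicircle MND (Touwen), MD, AC, BAL (MABC-2), MFP,
#' FI, DC, MAc, PPr, BMC (SIPT); lower semicircle AuAttn, VisAttn, MemoD,
#' MemoF, MemoN, ImHP, Arrows, BloC, DeCo, GeoP (NEPSY-II).
#'
#' Impairment means performance more than 1 SD below test norms on each
#' instrument's native scale: MABC-2 and NEPSY-II standard/scaled score
#' \eqn{\le 7} (mean 10, SD 3; \eqn{\le 7} is below the 16th percentile),
#' SIPT z-score below \eqn{-1.0}, and for the Touwen examination minor
#' neurological dysfunction (MND: dysfunction in at least one of the eight
#' functional domains, pooling simple and complex MND).
#'
#' @return A [DomainRegistry-class] object.
#' @examples
#' reg <- domainRegistry()
#' registryEntries(reg)[, c("abbreviation", "instrument")]
#' @export
domainRegistry <- function() {
  e <- data.frame(
    abbreviation = c("MND", "MD", "AC", "BAL", "MFP", "FI", "DC", "MAc",
                     "PPr", "BMC", "AuAttn", "VisAttn", "MemoD", "MemoF",
                     "MemoN", "ImHP", "Arrows", "BloC", "DeCo", "GeoP"),
    label = c("minor neurological dysfunction", "manual dexterity",
              "aiming and catching", "balance", "manual form perception",
              "finger identification", "design copying", "motor accuracy",
              "postural praxis", "bilateral motor coordination",
              "auditory attention", "visual attention", "memory for designs",
              "memory for faces", "narrative memory",
              "imitating hand positions", "arrows", "block construction",
              "design copying", "geometric puzzles"),
    instrument = c("TOUWEN", rep("MABC2", 3), rep("SIPT", 6),
                   rep("NEPSY2", 10)),
    scale = c("binary-dysfunction-count", rep("standard-score", 3),
              rep("z-score", 6), rep("scaled-score", 10)),
    native_mean = c(NA, rep(10, 3), rep(0, 6), rep(10, 10)),
    native_sd = c(NA, rep(3, 3), rep(1, 6), rep(3, 10)),
    cutoff_z = c(NA, rep(.CUT_INT, 3), rep(.CUT_SIPT, 6), rep(.CUT_INT, 10)),
    stringsAsFactors = FALSE)
  rownames(e) <- e$abbreviation
  new("DomainRegistry", entries = e)
}

#' Score-bearing domains of a registry
#'
#' The 19 domains carrying a raw numeric score (all registry domains except
#' MND, which is derived from the eight Touwen dysfunction flags and never
#' stored raw).
#'
#' @param registry a [DomainRegistry-class].
#' @return Character vector of 19 abbreviations, layout order.
#' @export
scoreDomains <- function(registry = domainRegistry()) {
  e <- registryEntries(registry)
  e$abbreviation[e$instrument != "TOUWEN"]
}

#' Column layout of a cohort file
#'
#' @param registry a [DomainRegistry-class].
#' @return Character vector: \code{child_id}, \code{group}, \code{sex},
#'   \code{mother_education}, \code{brain_injury}, \code{morbidity},
#'   \code{touwen_1..touwen_8}, then the 19 score columns in registry order.
#' @export
cohortColumns <- function(registry = domainRegistry()) {
  c("child_id", "group", "sex", "mother_education", "brain_injury",
    "morbidity", paste0("touwen_", 1:8), scoreDomains(registry))
}

#' Reference impairment prevalences for an extremely-preterm cohort
#'
#' Published impairment counts per registry domain for a cohort of 56
#' extremely-preterm (EPT, born before 28 gestational weeks) and 37
#' term-born children assessed at about 6 years of age.  Denominators vary
#' by domain because of non-systematic missing assessments.  These rates are
#' the default calibration targets of the synthetic-cohort generator, so
#' simulated cohorts carry realistic marginal impairment prevalences.
#'
#' @return data.frame with columns \code{domain}, \code{ept_n}, \code{ept_N},
#'   \code{term_n}, \code{term_N}, \code{ept_rate}, \code{term_rate}.
#' @seealso [calibrateLoadings()], [syntheticConfig()]
#' @examples
#' head(referenceImpairmentRates())
#' @export
referenceImpairmentRates <- function() {
  r <- data.frame(
    domain = c("MND", "MD", "AC", "BAL", "MFP", "FI", "DC", "MAc", "PPr",
               "BMC", "AuAttn", "VisAttn", "MemoD", "MemoF", "MemoN",
               "ImHP", "Arrows", "BloC", "DeCo", "GeoP"),
    ept_n  = c(36, 13,  3,  6, 10, 24, 14, 15, 16, 19, 12,  6, 16,  9, 12,
               19,  8,  9, 33, 10),
    ept_N  = c(56, 50, 50, 50, 49, 49, 49, 49, 49, 49, 46, 45, 45, 44, 48,
               44, 47, 46, 49, 45),
    term_n = c(10,  1,  1,  0,  0, 10,  1,  1,  4,  3,  1,  1,  7,  5,  2,
                7,  1,  1, 12,  2),
    term_N = c(36, 36, 36, 36, 33, 33, 33, 33, 33, 33, 33, 34, 34, 34, 34,
               34, 34, 34, 34, 34),
    stringsAsFactors = FALSE)
  r$ept_rate <- r$ept_n / r$ept_N
  r$term_rate <- r$term_n / r$term_N
  rownames(r) <- r$domain
  r
}
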