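#' @include AllClasses.R
NULL

#' Accessors for morbimap classes
#'
#' Small accessor generics: \code{registryEntries} and \code{layoutOrder}
#' for [DomainRegistry-class]; \code{childData} and \code{registryOf} for
#' [Cohort-class]; \code{impairmentCalls}, \code{observedMask} and
#' \code{childGroup} for [ImpairmentMatrix-class]; \code{nodeCounts},
#' \code{pairCountMatrix} and \code{mapGroup} for [CooccurrenceGraph-class];
#' \code{burdenTable} for [BurdenProfile-class].
#'
#' @param x an object of the documented class.
#' @return The underlying component: a data.frame, character vector, logical
#'   matrix, integer vector or matrix as appropriate.
#' @name accessors
#' @aliases registryEntries layoutOrder childData registryOf impairmentCalls
#'   observedMask childGroup nodeCounts pairCountMatrix mapGroup burdenTable
#' @examples
#' reg <- domainRegistry()
#' layoutOrder(reg)
NULL

#' @rdname accessors
#' @export
setGeneric("registryEntries", function(x) standardGeneric("registryEntries"))
#' @rdname accessors
#' @export
setGeneric("layoutOrder", function(x) standardGeneric("layoutOrder"))
#' @rdname accessors
#' @export
setGeneric("childData", function(x) standardGeneric("childData"))
#' @rdname accessors
#' @export
setGeneric("registryOf", function(x) standardGeneric("registryOf"))
#' @rdname accessors
#' @export
setGeneric("impairmentCalls", function(x) standardGeneric("impairmentCalls"))
#' @rdname accessors
#' @export
setGeneric("observedMask", function(x) standardGeneric("observedMask"))
#' @rdname accessors
#' @export
setGeneric("childGroup", function(x) standardGeneric("childGroup"))
#' @rdname accessors
#' @export
setGeneric("nodeCounts", function(x) standardGeneric("nodeCounts"))
#' @rdname accessors
#' @export
setGeneric("pairCountMatrix", function(x) standardGeneric("pairCountMatrix"))
#' @rdname accessors
#' @export
setGeneric("mapGroup", function(x) standardGeneric("mapGroup"))
#' @rdname accessors
#' @export
setGeneric("burdenTable", function(x) standardGeneric("burdenTable"))

#' @rdname accessors
setMethod("registryEntries", "DomainRegistry", function(x) x@entries)
#' @rdname accessors
setMethod("layoutOrder", "DomainRegistry", function(x) x@entries$abbreviation)
#' @rdname accessors
setMethod("childData", "Cohort", function(x) x@children)
#' @rdname accessors
setMethod("registryOf", "Cohort", function(x) x@registry)
#' @rdname accessors
setMethod("impairmentCalls", "ImpairmentMatrix",
          function(x) SummarizedExperiment::assay(x, "calls"))
#' @rdname accessors
setMethod("observedMask", "ImpairmentMatrix",
          function(x) SummarizedExperiment::assay(x, "observed"))
#' @rdname accessors
setMethod("childGroup", "ImpairmentMatrix",
          function(x) as.character(SummarizedExperiment::colData(x)$group))
#' @rdname accessors
setMethod("nodeCounts", "CooccurrenceGraph", function(x) x@nodeCounts)
#' @rdname accessors
setMethod("pairCountMatrix", "CooccurrenceGraph", function(x) x@pairCounts)
#' @rdname accessors
setMethod("mapGroup", "CooccurrenceGraph", function(x) x@group)
#' @rdname accessors
setMethod("burdenTable", "BurdenProfile", function(x) x@burden)

setMethod("show", "DomainRegistry", function(object) {
  e <- object@entries
  cat("DomainRegistry with", nrow(e), "test domains\n")
  for (ins in unique(e$instrument))
    cat(sprintf("  %-7s %s\n", ins,
                paste(e$abbreviation[e$instrument == ins], collapse = ", ")))
  invisible(NULL)
})

setMethod("show", "Cohort", function(object) {
  ch <- object@children
  tab <- table(factor(ch$group, levels = c("EPT", "TERM")))
  cat("Cohort of", nrow(ch), "children (EPT:", tab[["EPT"]],
      " TERM:", tab[["TERM"]], ")\n")
  sc <- intersect(names(ch), scoreDomains(object@registry))
  miss <- if (length(sc)) mean(is.na(as.matrix(ch[sc]))) else NA_real_
  cat(sprintf("  %d score columns, %.1f%% missing cells\n",
              length(sc), 100 * miss))
  invisible(NULL)
})

setMethod("show", "CooccurrenceGraph", function(object) {
  cat(sprintf("CooccurrenceGraph (%s group, n = %d children)\n",
              object@group, object@nChildren))
  cat("  impaired-domain (node) counts:",
      paste0(names(object@nodeCounts), "=", object@nodeCounts)[
        object@nodeCounts > 0][seq_len(min(6, sum(object@nodeCounts > 0)))],
      "...\n")
  for (k in object@thresholds)
    cat(sprintf("  pairs with >= %2d co-occurring children: %d\n",
                k, totalImpairedPairs(object, k)))
  invisible(NULL)
})

setMethod("show", "BurdenProfile", function(object) {
  b <- object@burden
  cat("BurdenProfile for", nrow(b), "children\n")
  for (g in unique(b$group)) {
    v <- b$burden[b$group == g]
    cat(sprintf("  %-4s mean burden %.1f, max %d\n", g, mean(v), max(v)))
  }
  invisible(NULL)
})

setMethod("show", "BootstrapResult", function(object) {
  cat(sprintf("BootstrapResult: %s = %.4g, %g%% BCa [%.4g, %.4g] (B = %d)\n",
              object@statistic, object@estimate, 100 * object@level,
              object@ciLow, object@ciHigh, object@B))
  if (!is.na(object@pValue))
    cat(sprintf("  two-sided bootstrap p = %.4g\n", object@pValue))
  invisible(NULL)
})

setMethod("show", "RegressionResult", function(object) {
  cat(sprintf("RegressionResult (wild bootstrap, %s weights, B = %d)\n",
              object@weightLaw, object@B))
  tab <- data.frame(B = round(object@coefficients, 4),
                    ci_low = round(object@ci[, 1], 4),
                    ci_high = round(object@ci[, 2], 4),
                    p = signif(object@pValues, 3))
  print(tab)
  cat(sprintf("  r2 = %.3f, adjusted r2 = %.3f\n", object@r2, object@adjR2))
  invisible(NULL)
})
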