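#' @include comorbidity.R stats-tests.R stats-bootstrap.R plot.R
NULL

#' Impairment-rate table with unadjusted odds ratios
#'
#' One row per registry domain: impaired / observed counts and rates per
#' group, the unadjusted 2x2 cross-product odds ratio with Woolf interval
#' (NA on zero cells unless \code{haldane}), the likelihood-ratio G test
#' p-value of the 2x2 table, and Benjamini--Hochberg q-values across the
#' family of domains with a computable test.  Denominators follow the
#' observed data: missing, unimputed calls are excluded, never counted as
#' unimpaired.
#'
#' @param im an [ImpairmentMatrix-class].
#' @param haldane passed to [oddsRatio2x2()].
#' @return data.frame with columns \code{domain}, \code{ept_n},
#'   \code{ept_N}, \code{ept_rate}, \code{term_n}, \code{term_N},
#'   \code{term_rate}, \code{or}, \code{or_low}, \code{or_high}, \code{p},
#'   \code{q}, \code{excluded}.
#' @export
impairmentRateTable <- function(im, haldane = FALSE) {
  stopifnot(is(im, "ImpairmentMatrix"))
  grp <- childGroup(im)
  calls <- impairmentCalls(im); obs <- observedMask(im)
  e <- grp == "EPT"; t <- grp == "TERM"
  out <- data.frame(
    domain = rownames(im),
    ept_n = rowSums(calls[, e, drop = FALSE]),
    ept_N = rowSums(obs[, e, drop = FALSE]),
    term_n = rowSums(calls[, t, drop = FALSE]),
    term_N = rowSums(obs[, t, drop = FALSE]),
    stringsAsFactors = FALSE)
  out$ept_rate <- ifelse(out$ept_N > 0, out$ept_n / out$ept_N, NA)
  out$term_rate <- ifelse(out$term_N > 0, out$term_n / out$term_N, NA)
  out$or <- out$or_low <- out$or_high <- out$p <- NA_real_
  out$excluded <- FALSE
  for (i in seq_len(nrow(out))) {
    a <- out$ept_n[i]; b <- out$ept_N[i] - a
    cc <- out$term_n[i]; d <- out$term_N[i] - cc
    if (out$ept_N[i] == 0 || out$term_N[i] == 0) {
      out$excluded[i] <- TRUE  # no observed data in a group: no test
      next
    }
    orr <- oddsRatio2x2(a, b, cc, d, haldane = haldane)
    out$or[i] <- orr$estimate
    out$or_low[i] <- orr$ciLow; out$or_high[i] <- orr$ciHigh
    tab <- matrix(base::c(a, b, cc, d), 2, byrow = TRUE)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
      out$p[i] <- likelihoodRatioTest(tab)$p_value
    else out$excluded[i] <- TRUE
  }
  out$q <- NA_real_
  fam <- !out$excluded & !is.na(out$p)
  out$q[fam] <- bhFDR(out$p[fam])
  rownames(out) <- out$domain
  out[, base::c("domain", "ept_n", "ept_N", "ept_rate", "term_n", "term_N",
                "term_rate", "or", "or_low", "or_high", "p", "q",
                "excluded")]
}

#' Burden histogram with likelihood-ratio comparison
#'
#' Builds the group x burden-value contingency table over the burden values
#' observed in the pooled sample and tests it with the likelihood-ratio G
#' test; with two groups and k observed burden values the test has k - 1
#' degrees of freedom.  If a single burden value is observed the test is
#' skipped with a note.
#'
#' @param profile a [BurdenProfile-class].
#' @return list with \code{histogram} (data.frame), \code{summary}
#'   (per-group mean/median/max), \code{test} (statistic, df, p, or NULL),
#'   \code{note}.
#' @export
burdenComparison <- function(profile) {
  h <- burdenHistogram(profile)
  s <- burdenSummary(profile)
  vals <- sort(unique(h$burden))
  if (length(vals) < 2L)
    return(list(histogram = h, summary = s, test = NULL,
                note = "single burden value observed; test skipped"))
  b <- burdenTable(profile)
  tab <- table(b$group, factor(b$burden, levels = vals))
  list(histogram = h, summary = s, test = likelihoodRatioTest(tab),
       note = "")
}

.mndOrdinal <- function(cohort) {
  ch <- childData(cohort)
  tw <- as.matrix(ch[paste0("touwen_", 1:8)])
  st <- .mndStatusMatrix(tw)
  factor(st$status, levels = base::c("NORMAL", "SIMPLE", "COMPLEX"),
         ordered = TRUE)
}

#' Group comparisons with wild-bootstrap regression
#'
#' For each of the 19 continuous score domains, regresses the native-scale
#' score on group (EPT = 1, so a negative coefficient means worse EPT
#' performance), unadjusted and -- when covariates are available --
#' adjusted for sex, mother's education (0--2), neonatal brain injury and
#' neonatal morbidity.  Coefficient intervals and p-values come from
#' [wildBootstrapRegression()]; q-values are Benjamini--Hochberg across
#' the 19 domains within each model family.  Cohen's d is oriented so that
#' positive d means worse EPT performance.  The MND row is an ordinal
#' (cumulative-logit) odds ratio for group, unadjusted.
#'
#' @param cohort a [Cohort-class].
#' @param B number of wild resamples per model.
#' @param seed integer; per-domain seeds are derived deterministically.
#' @param adjusted fit the covariate-adjusted model as well.
#' @param weights wild-bootstrap weight law.
#' @return list with \code{table} (one row per score domain) and
#'   \code{mnd} (the cumulative-logit result).
#' @export
groupComparisonTable <- function(cohort, B = 2000L, seed = NULL,
                                 adjusted = TRUE,
                                 weights = "rademacher") {
  stopifnot(is(cohort, "Cohort"))
  ch <- childData(cohort)
  sc <- intersect(scoreDomains(registryOf(cohort)), names(ch))
  covs <- base::c("sex", "mother_education", "brain_injury", "morbidity")
  haveCovs <- adjusted && all(covs %in% names(ch))
  rows <- vector("list", length(sc))
  for (i in seq_along(sc)) {
    d <- sc[i]
    base_df <- data.frame(y = ch[[d]], group = as.integer(ch$group == "EPT"))
    adjTerms <- character()
    if (haveCovs) {
      base_df$sex <- as.integer(ch$sex == "M")
      base_df$mother_education <- as.numeric(ch$mother_education)
      base_df$brain_injury <- as.integer(ch$brain_injury)
      base_df$morbidity <- as.integer(ch$morbidity)
      cc <- stats::complete.cases(base_df)
      # a covariate without contrast in the analysed rows cannot enter
      adjTerms <- covs[vapply(covs, function(v)
        length(unique(base_df[[v]][cc])) > 1L, logical(1))]
    }
    dseed <- if (is.null(seed)) NULL else seed + 101L * i
    un <- wildBootstrapRegression(y ~ group, base_df, B = B, seed = dseed,
                                  weights = weights)
    x_ept <- ch[[d]][ch$group == "EPT"]; x_term <- ch[[d]][ch$group == "TERM"]
    row <- data.frame(
      domain = d,
      d = cohenD(x_term, x_ept),
      n = sum(stats::complete.cases(base_df[base::c("y", "group")])),
      B_unadj = un@coefficients[["group"]],
      unadj_low = un@ci["group", 1], unadj_high = un@ci["group", 2],
      p_unadj = un@pValues[["group"]],
      stringsAsFactors = FALSE)
    if (haveCovs) {
      fml <- stats::reformulate(base::c("group", adjTerms), response = "y")
      ad <- wildBootstrapRegression(
        fml, base_df, B = B,
        seed = if (is.null(dseed)) NULL else dseed + 1L, weights = weights)
      row$B_adj <- ad@coefficients[["group"]]
      row$adj_low <- ad@ci["group", 1]; row$adj_high <- ad@ci["group", 2]
      row$p_adj <- ad@pValues[["group"]]
      row$adj_r2 <- ad@adjR2
    }
    rows[[i]] <- row
  }
  tab <- do.call(rbind, rows)
  tab$q_unadj <- bhFDR(tab$p_unadj)
  if (haveCovs) tab$q_adj <- bhFDR(tab$p_adj)
  rownames(tab) <- tab$domain

  mnd <- NULL
  if (all(paste0("touwen_", 1:8) %in% names(ch))) {
    y <- .mndOrdinal(cohort)
    mnd <- tryCatch(
      cumulativeLogitOR(y, as.integer(ch$group == "EPT")),
      error = function(e) NULL, warning = function(w) NULL)
  }
  list(table = tab, mnd = mnd)
}

#' Pipeline run configuration
#'
#' @param input path to a cohort CSV/TSV, or NULL to generate a synthetic
#'   cohort.
#' @param synthetic a \code{SyntheticConfig} (required when \code{input} is
#'   NULL).
#' @param siptStrict SIPT boundary flag, see [isImpaired()].
#' @param thresholds relationship-map edge cutoffs, strictly increasing
#'   positive integers.
#' @param bootstrapB bootstrap-t resamples.
#' @param regressionB wild-bootstrap resamples.
#' @param fdrLevel FDR level in (0, 1).
#' @param seed integer seed for all stochastic stages.
#' @param outDir output directory (created if needed).
#' @return A validated list of class \code{RunConfig}.
#' @export
runConfig <- function(input = NULL, synthetic = NULL, siptStrict = TRUE,
                      thresholds = base::c(1L, 5L, 10L), bootstrapB = 1000L,
                      regressionB = 2000L, fdrLevel = 0.05, seed = 1L,
                      outDir = tempfile("morbimap_run")) {
  if (is.null(input) && is.null(synthetic))
    stop("either an input cohort path or a synthetic config is required")
  if (!is.null(input) && !file.exists(input))
    stop("input file not found: ", input)
  thresholds <- as.integer(thresholds)
  if (anyNA(thresholds) || any(thresholds < 1L) ||
      any(diff(thresholds) <= 0L))
    stop("thresholds must be strictly increasing positive integers")
  if (!(fdrLevel > 0 && fdrLevel < 1)) stop("fdrLevel must be in (0, 1)")
  if (bootstrapB < 100L || regressionB < 100L)
    stop("bootstrap resample counts must be at least 100")
  structure(list(input = input, synthetic = synthetic,
                 siptStrict = isTRUE(siptStrict), thresholds = thresholds,
                 bootstrapB = as.integer(bootstrapB),
                 regressionB = as.integer(regressionB),
                 fdrLevel = fdrLevel, seed = as.integer(seed),
                 outDir = outDir),
            class = "RunConfig")
}

.configHash <- function(config) {
  x <- config[setdiff(names(config), "outDir")]
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x, control = "all"), f)
  unname(tools::md5sum(f))
}

#' Run the full multimorbidity pipeline
#'
#' Executes generate/read, classification, burden profiling, relationship
#' maps at every configured threshold, the impairment-rate table with
#' unadjusted odds ratios and FDR, the wild-bootstrap group comparisons,
#' and the headline joint-impairment triples; writes TSV tables, figures
#' (PDF, plus PNG when the device is available) and a machine-readable
#' JSON report into \code{config$outDir}.  A run is fully determined by
#' its configuration: identical config and seed give an identical report.
#' The config hash is stamped into every output; an existing report from a
#' different configuration is never silently overwritten.
#'
#' @param config a [runConfig()] object.
#' @return Invisibly, the report list (also written as
#'   \code{report.json}).
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "RunConfig"))
    stop("config must be created by runConfig()")
  hash <- .configHash(config)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  reportPath <- file.path(config$outDir, "report.json")
  if (file.exists(reportPath)) {
    old <- tryCatch(jsonlite::read_json(reportPath), error = function(e) NULL)
    if (!is.null(old$metadata$config_hash) &&
        !identical(old$metadata$config_hash, hash))
      stop("output directory holds a report from a different configuration; ",
           "refusing to overwrite")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cohort <- stage("input", {
    if (!is.null(config$input)) readCohort(config$input)
    else generateCohort(config$synthetic)
  })
  im <- stage("classify", buildImpairmentMatrix(cohort, config$siptStrict))
  writeImpairmentMatrix(im, file.path(config$outDir, "impairment_matrix.tsv"))
  profile <- stage("profile", burdenProfile(im))
  burden <- stage("burden", burdenComparison(profile))
  exceed <- stage("burden", exceedsReferenceMax(profile, "TERM"))
  rates <- stage("stats", impairmentRateTable(im))
  groups <- intersect(base::c("EPT", "TERM"), unique(childGroup(im)))
  maps <- list()
  for (g in groups) {
    gr <- stage("maps", pairCounts(im, g, thresholds = config$thresholds))
    writeEdgeList(gr, file.path(config$outDir,
                                paste0("edges_", tolower(g), ".tsv")),
                  header = paste0("config=", hash, " seed=", config$seed))
    maps[[g]] <- list(
      node_counts = as.list(nodeCounts(gr)),
      total_pairs = stats::setNames(
        lapply(config$thresholds, totalImpairedPairs, graph = gr),
        paste0("k", config$thresholds)),
      incidence_sum = incidenceSum(gr))
    for (k in config$thresholds)
      stage("render", renderRelationshipMap(
        gr, k, file.path(config$outDir,
                         sprintf("map_%s_k%d.pdf", tolower(g), k))))
    if (capabilities("png"))
      stage("render", renderRelationshipMap(
        gr, config$thresholds[1],
        file.path(config$outDir,
                  sprintf("map_%s_k%d.png", tolower(g),
                          config$thresholds[1]))))
  }
  comp <- stage("stats", groupComparisonTable(
    cohort, B = config$regressionB, seed = config$seed))
  triples <- list()
  if (all(base::c("MND", "DeCo", "FI", "ImHP") %in% rownames(im))) {
    for (tr in list(base::c("MND", "DeCo", "FI"),
                    base::c("MND", "DeCo", "ImHP"))) {
      ji <- stage("stats", jointImpairment(im, tr))
      or <- oddsRatio2x2(ji$table[["a"]], ji$table[["b"]],
                         ji$table[["c"]], ji$table[["d"]])
      triples[[paste(tr, collapse = "+")]] <- list(
        counts = as.list(ji$counts),
        conditional = as.list(ji$conditional),
        or = or$estimate, or_low = or$ciLow, or_high = or$ciHigh)
    }
  }
  stage("render", plotBurdenHistogram(
    profile, file.path(config$outDir, "burden_histogram.pdf")))
  hdr <- paste0("# config=", hash, " seed=", config$seed)
  .writeTsv <- function(df, name) {
    p <- file.path(config$outDir, name)
    con <- file(p, "w"); on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  .writeTsv(rates, "impairment_rates.tsv")
  .writeTsv(comp$table, "group_comparisons.tsv")
  .writeTsv(burden$histogram, "burden_histogram.tsv")

  report <- list(
    metadata = list(package = "morbimap",
                    version = as.character(utils::packageVersion("morbimap")),
                    seed = config$seed, config_hash = hash,
                    sipt_strict = config$siptStrict,
                    fdr_level = config$fdrLevel),
    cohort = list(n_ept = sum(childGroup(im) == "EPT"),
                  n_term = sum(childGroup(im) == "TERM")),
    impairment_rates = rates,
    burden = list(histogram = burden$histogram, summary = burden$summary,
                  test = burden$test, note = burden$note,
                  exceeding_reference = list(
                    reference_max = exceed$reference_max,
                    count = exceed$count,
                    proportion = exceed$proportion)),
    relationship_maps = maps,
    triples = triples,
    group_comparisons = comp$table,
    mnd_ordinal = if (!is.null(comp$mnd))
      comp$mnd[base::c("or", "ciLow", "ciHigh", "converged")])
  jsonlite::write_json(report, reportPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(report)
}
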