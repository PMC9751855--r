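#' @include classify.R
NULL

#' Per-child impairment burden
#'
#' Counts, for each child, the number of test domains with an impaired call
#' (0--20).  Unobserved domains never contribute, so a child's burden is
#' bounded by the number of domains observed for that child.
#'
#' @param im an [ImpairmentMatrix-class].
#' @return A [BurdenProfile-class].
#' @examples
#' coh <- generateCohort(syntheticConfig(n_ept = 20, n_term = 15, seed = 2))
#' bp <- burdenProfile(buildImpairmentMatrix(coh))
#' burdenSummary(bp)
#' @export
burdenProfile <- function(im) {
  stopifnot(is(im, "ImpairmentMatrix"))
  if (ncol(im) == 0L) stop("empty impairment matrix")
  b <- data.frame(child_id = colnames(im), group = childGroup(im),
                  burden = as.integer(colSums(impairmentCalls(im))),
                  n_observed = as.integer(colSums(observedMask(im))),
                  stringsAsFactors = FALSE)
  new("BurdenProfile", burden = b)
}

#' Burden histogram per group
#'
#' @param profile a [BurdenProfile-class].
#' @return data.frame with one row per (group, burden value) over the pooled
#'   range of observed burdens, column \code{n} the number of children.
#' @export
burdenHistogram <- function(profile) {
  b <- burdenTable(profile)
  vals <- sort(unique(b$burden))
  out <- expand.grid(group = unique(b$group), burden = vals,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n <- mapply(function(g, v) sum(b$group == g & b$burden == v),
                  out$group, out$burden)
  out[order(out$group, out$burden), ]
}

#' Per-group burden summary
#'
#' @param profile a [BurdenProfile-class].
#' @return data.frame with per-group n, mean, median and max burden.
#' @export
burdenSummary <- function(profile) {
  b <- burdenTable(profile)
  do.call(rbind, lapply(split(b$burden, b$group), function(v)
    data.frame(n = length(v), mean = mean(v), median = stats::median(v),
               max = max(v))))
}

#' Children whose burden exceeds the reference group's maximum
#'
#' Flags children outside the reference group whose impairment burden
#' strictly exceeds the largest burden observed in the reference group
#' (e.g. EPT children with more impaired domains than any term-born child).
#'
#' @param profile a [BurdenProfile-class].
#' @param referenceGroup the comparison group (default \code{"TERM"}).
#' @return list with \code{reference_max}, \code{flagged} (named logical per
#'   non-reference child), \code{count} and \code{proportion}.
#' @export
exceedsReferenceMax <- function(profile, referenceGroup = "TERM") {
  b <- burdenTable(profile)
  ref <- b$burden[b$group == referenceGroup]
  if (!length(ref)) stop("reference group ", referenceGroup, " is absent")
  others <- b[b$group != referenceGroup, ]
  flagged <- stats::setNames(others$burden > max(ref), others$child_id)
  list(reference_max = max(ref), flagged = flagged,
       count = sum(flagged), proportion = mean(flagged))
}

#' Pairwise co-occurrence counts for one group
#'
#' Builds the relationship-map substrate for a group: for every unordered
#' pair of domains, the number of children impaired in both, plus the
#' per-domain impaired-child (node) counts.  A child with an unobserved
#' call in either domain of a pair contributes nothing to that pair (an
#' unobserved call is never impaired).
#'
#' @param im an [ImpairmentMatrix-class].
#' @param group which group to map.
#' @param thresholds edge-display cutoffs stored with the graph.
#' @return A [CooccurrenceGraph-class].
#' @examples
#' coh <- generateCohort(syntheticConfig(n_ept = 30, n_term = 20, seed = 3))
#' g <- pairCounts(buildImpairmentMatrix(coh), "EPT")
#' totalImpairedPairs(g)
#' @export
pairCounts <- function(im, group, thresholds = c(1L, 5L, 10L)) {
  stopifnot(is(im, "ImpairmentMatrix"))
  sel <- childGroup(im) == group
  if (!any(sel)) stop("group ", group, " not present in the matrix")
  calls <- impairmentCalls(im)[, sel, drop = FALSE] * 1L
  pc <- tcrossprod(calls)
  nc <- as.integer(diag(pc))
  names(nc) <- rownames(calls)
  diag(pc) <- NA_integer_
  storage.mode(pc) <- "integer"
  new("CooccurrenceGraph", nodeCounts = nc, pairCounts = pc,
      group = group, nChildren = sum(sel),
      thresholds = as.integer(sort(thresholds)))
}

#' Edges of a relationship map at a minimum co-occurrence threshold
#'
#' @param graph a [CooccurrenceGraph-class].
#' @param k minimum number of co-occurring children (\eqn{\ge 1}).
#' @return data.frame with columns \code{domain_a}, \code{domain_b} (a
#'   before b in layout order), \code{n_cooccurring}, \code{group},
#'   \code{threshold}; rows in deterministic layout order.
#' @export
edgesAtThreshold <- function(graph, k) {
  stopifnot(is(graph, "CooccurrenceGraph"), k >= 1)
  pc <- pairCountMatrix(graph)
  nd <- names(nodeCounts(graph))
  idx <- which(upper.tri(pc) & !is.na(pc) & pc >= k, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(domain_a = nd[idx[, 1]], domain_b = nd[idx[, 2]],
             n_cooccurring = pc[idx], group = rep(graph@group, nrow(idx)),
             threshold = rep(as.integer(k), nrow(idx)),
             stringsAsFactors = FALSE)
}

#' Number of impaired test pairs
#'
#' The number of distinct domain pairs in which at least \code{k} children
#' are simultaneously impaired (the count printed bottom-left of each
#' relationship map).  The alternative reading -- summing co-occurrence
#' incidences over pairs -- is available as \code{incidenceSum}.
#'
#' @param graph a [CooccurrenceGraph-class].
#' @param k minimum number of co-occurring children.
#' @return Integer count of distinct pairs (at most \eqn{\binom{20}{2} =
#'   190}).
#' @export
totalImpairedPairs <- function(graph, k = 1L) {
  pc <- pairCountMatrix(graph)
  sum(pc[upper.tri(pc)] >= k, na.rm = TRUE)
}

#' @rdname totalImpairedPairs
#' @export
incidenceSum <- function(graph, k = 1L) {
  pc <- pairCountMatrix(graph)
  v <- pc[upper.tri(pc)]
  sum(v[!is.na(v) & v >= k])
}

#' Joint impairment over a set of domains
#'
#' Evaluates, per child, whether the child is impaired in every listed
#' domain (the conjunction behind "triple relationships" such as MND +
#' design copying + finger identification).  A child needs an observed,
#' impaired call in all listed domains to evaluate TRUE.  The 2x2 group
#' table returned (\code{a} = EPT jointly impaired, \code{b} = EPT not,
#' \code{c}/\code{d} term) feeds [oddsRatio2x2()].
#'
#' @param im an [ImpairmentMatrix-class].
#' @param domains character vector of registry abbreviations.
#' @return list with \code{perChild} (named logical), \code{counts}
#'   (per-group jointly-impaired counts), \code{table} (a, b, c, d), and
#'   \code{conditional} (per-group proportion jointly impaired among
#'   children impaired in \code{domains[1]}).
#' @export
jointImpairment <- function(im, domains) {
  stopifnot(is(im, "ImpairmentMatrix"))
  unknown <- setdiff(domains, rownames(im))
  if (length(unknown))
    stop("unknown domain(s): ", paste(unknown, collapse = ", "))
  calls <- impairmentCalls(im)[domains, , drop = FALSE]
  joint <- apply(calls, 2, all)
  grp <- childGroup(im)
  counts <- vapply(c(EPT = "EPT", TERM = "TERM"),
                   function(g) sum(joint[grp == g]), integer(1))
  first <- impairmentCalls(im)[domains[1], ]
  conditional <- vapply(c(EPT = "EPT", TERM = "TERM"), function(g) {
    den <- sum(first[grp == g])
    if (den == 0) NA_real_ else sum(joint[grp == g]) / den
  }, numeric(1))
  list(perChild = joint, counts = counts,
       table = c(a = counts[["EPT"]], b = sum(grp == "EPT") - counts[["EPT"]],
                 c = counts[["TERM"]],
                 d = sum(grp == "TERM") - counts[["TERM"]]),
       conditional = conditional)
}

#' Write relationship-map edge lists as TSV
#'
#' @param graph a [CooccurrenceGraph-class].
#' @param path output file.
#' @param thresholds thresholds to include (default: those stored in the
#'   graph); one block of rows per threshold.
#' @param header optional comment line (e.g. a config hash) written before
#'   the table.
#' @return \code{path}, invisibly.
#' @export
writeEdgeList <- function(graph, path, thresholds = graph@thresholds,
                          header = NULL) {
  rows <- do.call(rbind, lapply(thresholds, edgesAtThreshold, graph = graph))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(rows, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
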