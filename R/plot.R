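#' @include comorbidity.R
NULL

# circular layout: upper semicircle clockwise (first 10 domains),
# lower semicircle anti-clockwise (last 10), matching the registry order
.mapLayout <- function(domains) {
  stopifnot(length(domains) == 20L)
  i <- seq_len(10)
  upper <- pi * (1 - (i - 0.5) / 10)       # 171..9 degrees
  lower <- pi * (1 + (i - 0.5) / 10)       # 189..351 degrees
  data.frame(domain = domains, angle = base::c(upper, lower),
             x = cos(base::c(upper, lower)), y = sin(base::c(upper, lower)),
             stringsAsFactors = FALSE)
}

.openDevice <- function(path, width = 8, height = 8) {
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2) != 0)
    stop("cannot write figure: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         pdf = grDevices::pdf(path, width = width, height = height),
         svg = grDevices::svg(path, width = width, height = height),
         png = grDevices::png(path, width = width * 100,
                              height = height * 100, res = 100),
         stop("unsupported figure format: .", ext))
}

#' Render a relationship map
#'
#' Draws the thresholded co-occurrence map: the 20 domains on a circle
#' (upper semicircle clockwise MND..BMC, lower anti-clockwise
#' AuAttn..GeoP), each node annotated with its impaired-child count (red),
#' an edge for every domain pair with at least \code{threshold}
#' co-occurring children, edge thickness linear in the count (minimum
#' visible width 0.5), and the total number of impaired test pairs printed
#' bottom left.  Output is deterministic for a fixed graph.
#'
#' @param graph a [CooccurrenceGraph-class].
#' @param threshold minimum co-occurrence count for a displayed edge.
#' @param path optional output file (\code{.pdf}, \code{.svg} or
#'   \code{.png} by extension); when NULL, draws on the current device.
#' @param edgeLabels print co-occurrence counts above edges (default: only
#'   when at most 30 edges are shown).
#' @param main plot title.
#' @return Invisibly, a list with the node \code{layout} (data.frame),
#'   the displayed \code{edges}, and \code{totalPairs}.
#' @export
renderRelationshipMap <- function(graph, threshold = 1L, path = NULL,
                                  edgeLabels = NULL,
                                  main = NULL) {
  stopifnot(is(graph, "CooccurrenceGraph"))
  lay <- .mapLayout(names(nodeCounts(graph)))
  edges <- edgesAtThreshold(graph, threshold)
  total <- totalImpairedPairs(graph, threshold)
  if (is.null(edgeLabels)) edgeLabels <- nrow(edges) <= 30
  if (is.null(main))
    main <- sprintf("%s group (n = %d), co-occurrence >= %d child%s",
                    mapGroup(graph), graph@nChildren, threshold,
                    if (threshold > 1) "ren" else "")
  if (!is.null(path)) {
    .openDevice(path)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mar = base::c(2, 2, 3, 2))
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  graphics::plot(NA, xlim = base::c(-1.45, 1.45), ylim = base::c(-1.45, 1.45),
                 asp = 1, axes = FALSE, xlab = "", ylab = "", main = main)
  if (nrow(edges)) {
    maxc <- max(edges$n_cooccurring)
    for (k in seq_len(nrow(edges))) {
      i <- match(edges$domain_a[k], lay$domain)
      j <- match(edges$domain_b[k], lay$domain)
      lwd <- max(0.5, 6 * edges$n_cooccurring[k] / maxc)
      graphics::segments(lay$x[i], lay$y[i], lay$x[j], lay$y[j],
                         lwd = lwd, col = grDevices::grey(0.35))
      if (edgeLabels)
        graphics::text((lay$x[i] + lay$x[j]) / 2,
                       (lay$y[i] + lay$y[j]) / 2 + 0.035,
                       edges$n_cooccurring[k], cex = 0.6)
    }
  }
  graphics::points(lay$x, lay$y, pch = 21, bg = "white", cex = 2.2)
  graphics::text(1.08 * lay$x, 1.08 * lay$y, nodeCounts(graph),
                 col = "red3", cex = 0.7)
  graphics::text(1.3 * lay$x, 1.3 * lay$y, lay$domain, cex = 0.75)
  graphics::text(-1.4, -1.4, sprintf("impaired test pairs: %d", total),
                 adj = 0, cex = 0.9)
  invisible(list(layout = lay, edges = edges, totalPairs = total))
}

#' Plot the impairment-burden histogram
#'
#' Grouped bar chart of the number of children against the number of
#' impaired test domains, one bar colour per group.
#'
#' @param profile a [BurdenProfile-class].
#' @param path optional output file (by extension, as in
#'   [renderRelationshipMap()]).
#' @return Invisibly, the histogram data.frame.
#' @export
plotBurdenHistogram <- function(profile, path = NULL) {
  h <- burdenHistogram(profile)
  groups <- sort(unique(h$group))
  vals <- sort(unique(h$burden))
  m <- matrix(0, nrow = length(vals), ncol = length(groups),
              dimnames = list(vals, groups))
  for (g in groups) {
    hg <- h[h$group == g, ]
    m[match(hg$burden, vals), g] <- hg$n
  }
  if (!is.null(path)) {
    .openDevice(path, width = 9, height = 5)
    on.exit(grDevices::dev.off())
  }
  graphics::barplot(t(m), beside = TRUE, names.arg = vals,
                    legend.text = groups,
                    col = base::c("firebrick", "steelblue")[seq_along(groups)],
                    xlab = "impaired test domains",
                    ylab = "number of children")
  invisible(h)
}
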