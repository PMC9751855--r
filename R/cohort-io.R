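#' @include registry.R
NULL

.sepFor <- function(path) {
  if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Construct a Cohort from a child-level table
#'
#' @param children data.frame with columns as in [cohortColumns()]; only
#'   \code{child_id} and \code{group} are mandatory.
#' @param registry a [DomainRegistry-class].
#' @return A [Cohort-class].
#' @export
Cohort <- function(children, registry = domainRegistry()) {
  new("Cohort", children = as.data.frame(children), registry = registry)
}

#' Read / write a cohort file
#'
#' Cohort files are CSV or TSV (decided by extension: \code{.tsv}/\code{.tab}/
#' \code{.txt} are tab-separated) with a header row and one row per child:
#' \code{child_id}, \code{group} (EPT/TERM), \code{sex} (M/F),
#' \code{mother_education} (0 = high school or lower, 1 = bachelor,
#' 2 = master or higher), \code{brain_injury}, \code{morbidity} (logical),
#' \code{touwen_1..touwen_8} (logical dysfunction flags), then one column per
#' score domain named by its registry abbreviation.  An empty cell is a
#' missing value, never a zero.
#'
#' @param path file path.
#' @param registry a [DomainRegistry-class].
#' @param cohort a [Cohort-class].
#' @return \code{readCohort} returns a [Cohort-class]; \code{writeCohort}
#'   returns \code{path} invisibly.  Writing then reading a cohort restores
#'   values and missingness exactly.
#' @examples
#' coh <- generateCohort(syntheticConfig(n_ept = 3, n_term = 3, seed = 1))
#' f <- tempfile(fileext = ".csv")
#' writeCohort(coh, f)
#' identical(childData(readCohort(f))$FI, childData(coh)$FI)
#' @export
readCohort <- function(path, registry = domainRegistry()) {
  sep <- .sepFor(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           na.strings = c("", "NA"), check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  valid <- cohortColumns(registry)
  unknown <- setdiff(names(raw), valid)
  if (length(unknown))
    stop("unknown column(s) ", paste(unknown, collapse = ", "),
         "; valid score columns are: ",
         paste(scoreDomains(registry), collapse = ", "))
  needed <- c("child_id", "group")
  if (!all(needed %in% names(raw)))
    stop("cohort file must have child_id and group columns")
  out <- data.frame(child_id = raw$child_id, group = toupper(raw$group),
                    stringsAsFactors = FALSE)
  if ("sex" %in% names(raw)) out$sex <- raw$sex
  if ("mother_education" %in% names(raw))
    out$mother_education <- .numCol(raw, "mother_education")
  for (cl in c("brain_injury", "morbidity", paste0("touwen_", 1:8)))
    if (cl %in% names(raw)) out[[cl]] <- .boolCol(raw, cl)
  for (d in intersect(scoreDomains(registry), names(raw)))
    out[[d]] <- .numCol(raw, d)
  new("Cohort", children = out, registry = registry)
}

.numCol <- function(raw, col) {
  x <- raw[[col]]
  v <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(v))
  if (length(bad))
    stop(sprintf("non-numeric value '%s' in row %d, column %s",
                 x[bad[1]], bad[1], col))
  v
}

.boolCol <- function(raw, col) {
  x <- toupper(raw[[col]])
  v <- rep(NA, length(x))
  v[x %in% c("TRUE", "T", "1")] <- TRUE
  v[x %in% c("FALSE", "F", "0")] <- FALSE
  bad <- which(!is.na(x) & is.na(v))
  if (length(bad))
    stop(sprintf("non-logical value '%s' in row %d, column %s",
                 raw[[col]][bad[1]], bad[1], col))
  v
}

#' @rdname readCohort
#' @export
writeCohort <- function(cohort, path) {
  stopifnot(is(cohort, "Cohort"))
  ch <- childData(cohort)
  num <- vapply(ch, is.double, logical(1))
  for (cl in names(ch)[num])  # full precision so the round trip is exact
    ch[[cl]] <- ifelse(is.na(ch[[cl]]), NA,
                       formatC(ch[[cl]], digits = 17, format = "g"))
  utils::write.table(ch, path, sep = .sepFor(path), row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}
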