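# CSV dialect is fixed: comma separator, UTF-8, "." decimal, header required.

#' Read a patch annotation table with row-level validation
#'
#' Expected columns: `patch_id`, `site`, `survey_year`, `taxon`, `area_cm2`,
#' `extent_pct`, `severity`, `x_m`, `y_m` (centroids optional, may be empty).
#' A missing required column is a hard error. Rows violating the patch
#' invariants (non-positive area, extent outside \[0, 100\], severity outside
#' 0..3, duplicate (site, year, patch) key) are excluded and reported with
#' their row numbers.
#'
#' @param path CSV file path.
#' @return list with `patches` (clean data.frame) and `report` (data.frame
#'   of `row`, `patch_id`, `problem`; zero rows when clean).
#' @export
readPatchTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("patch_id", "site", "survey_year", "taxon",
                "area_cm2", "extent_pct", "severity")
  miss <- setdiff(required, names(raw))
  if (length(miss) > 0)
    stop("patch table missing required column(s): ",
         paste(miss, collapse = ", "))
  if (!"x_m" %in% names(raw)) raw$x_m <- NA_real_
  if (!"y_m" %in% names(raw)) raw$y_m <- NA_real_
  bad <- character(nrow(raw))
  bad[!is.finite(raw$area_cm2) | raw$area_cm2 <= 0] <- "area_cm2 must be > 0"
  ext <- !is.finite(raw$extent_pct) | raw$extent_pct < 0 | raw$extent_pct > 100
  bad[ext & bad == ""] <- "extent_pct must lie in [0, 100]"
  sev <- !(raw$severity %in% 0:3)
  bad[sev & bad == ""] <- "severity must be in {0, 1, 2, 3}"
  key <- patchKey(raw$site, raw$survey_year, raw$patch_id)
  dup <- duplicated(key)
  bad[dup & bad == ""] <- "duplicate (site, year, patch_id)"
  report <- data.frame(row = which(bad != ""),
                       patch_id = raw$patch_id[bad != ""],
                       problem = bad[bad != ""], stringsAsFactors = FALSE)
  list(patches = raw[bad == "", PATCH_COLUMNS], report = report)
}

#' @rdname readPatchTable
#' @details `readLinkTable()` expects columns `site`, `from_year`,
#'   `from_patch`, `to_year`, `to_patch`. Link-endpoint existence and the
#'   consecutive-survey rule are checked when the tables are combined into a
#'   [CoralSurvey].
#' @export
readLinkTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(LINK_COLUMNS, names(raw))
  if (length(miss) > 0)
    stop("link table missing required column(s): ",
         paste(miss, collapse = ", "))
  raw[, LINK_COLUMNS]
}

#' @rdname readPatchTable
#' @details `readRubric()` reads a 5-row threshold table with columns
#'   `category`, `index_min`, `index_max` (the strings `Inf`/`-Inf` are
#'   honoured) and validates it with the same monotonicity checks as the
#'   default rubric.
#' @export
readRubric <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  r <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  r$index_min <- as.numeric(r$index_min)
  r$index_max <- as.numeric(r$index_max)
  checkRubric(r)
}

#' @rdname readPatchTable
#' @param x data.frame to write.
#' @param path output path.
#' @export
writeTable <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
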