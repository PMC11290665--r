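#' @include coralfate-package.R
NULL

PATCH_COLUMNS <- c("patch_id", "site", "survey_year", "taxon",
                   "area_cm2", "extent_pct", "severity", "x_m", "y_m")
LINK_COLUMNS <- c("site", "from_year", "from_patch", "to_year", "to_patch")

#' CoralSurvey: validated patch and temporal-link tables
#'
#' A `CoralSurvey` holds the raw fate-tracking data: one row per contiguous
#' live-tissue patch per survey year, plus patch-to-patch links between
#' consecutive surveys that encode fission (one-to-many) and fusion
#' (many-to-one). Validity enforces the patch invariants (positive planar
#' area, bleaching extent in \[0, 100\], severity in \{0, 1, 2, 3\}, unique
#' (site, year, patch) keys), that every link endpoint exists in the patch
#' table, and that links only join consecutive surveys.
#'
#' @slot patches data.frame with columns `patch_id`, `site`, `survey_year`,
#'   `taxon`, `area_cm2`, `extent_pct`, `severity`, `x_m`, `y_m` (centroid in
#'   metres, site-local frame; may be `NA`).
#' @slot links data.frame with columns `site`, `from_year`, `from_patch`,
#'   `to_year`, `to_patch`.
#' @slot surveys sorted integer vector of survey years.
#'
#' @aliases CoralSurvey
#' @export
setClass("CoralSurvey",
         slots = c(patches = "data.frame",
                   links = "data.frame",
                   surveys = "integer"))

patchKey <- function(site, year, patch) paste(site, year, patch, sep = "\r")

validCoralSurvey <- function(object) {
  p <- object@patches
  l <- object@links
  errs <- character()
  miss <- setdiff(PATCH_COLUMNS, names(p))
  if (length(miss) > 0)
    return(sprintf("patch table missing column(s): %s",
                   paste(miss, collapse = ", ")))
  miss <- setdiff(LINK_COLUMNS, names(l))
  if (length(miss) > 0)
    return(sprintf("link table missing column(s): %s",
                   paste(miss, collapse = ", ")))
  if (length(object@surveys) < 1 || is.unsorted(object@surveys, strictly = TRUE))
    errs <- c(errs, "surveys must be strictly increasing survey years")
  if (!all(p$survey_year %in% object@surveys))
    errs <- c(errs, "patch survey_year outside the configured survey list")
  if (any(!is.finite(p$area_cm2)) || any(p$area_cm2 <= 0))
    errs <- c(errs, "planar area must be finite and > 0 for every patch")
  if (any(!is.finite(p$extent_pct)) || any(p$extent_pct < 0 | p$extent_pct > 100))
    errs <- c(errs, "bleaching extent must lie in [0, 100]")
  if (any(!(p$severity %in% 0:3)))
    errs <- c(errs, "bleaching severity must be an integer in {0, 1, 2, 3}")
  key <- patchKey(p$site, p$survey_year, p$patch_id)
  if (anyDuplicated(key) > 0)
    errs <- c(errs, sprintf("duplicated (site, year, patch_id) key(s): %s",
                            paste(unique(p$patch_id[duplicated(key)]), collapse = ", ")))
  if (nrow(l) > 0) {
    step <- match(l$to_year, object@surveys) - match(l$from_year, object@surveys)
    # forward-in-time only; the consecutive-survey rule itself is enforced in
    # assembleGenets(), where strict mode can be opted out of
    if (any(is.na(step)) || any(step < 1L))
      errs <- c(errs, "links must run forward between years in the survey list")
    fromk <- patchKey(l$site, l$from_year, l$from_patch)
    tok <- patchKey(l$site, l$to_year, l$to_patch)
    dangling <- c(l$from_patch[!(fromk %in% key)], l$to_patch[!(tok %in% key)])
    if (length(dangling) > 0)
      errs <- c(errs, sprintf("link endpoint(s) missing from the patch table: %s",
                              paste(unique(dangling), collapse = ", ")))
  }
  if (length(errs) == 0) TRUE else errs
}
setValidity("CoralSurvey", validCoralSurvey)

#' GenetSet: genets assembled from a patch/link network
#'
#' Genets are connected components of the temporal link graph: networks of
#' tissue patches interconnected through time by fission and fusion. A
#' `GenetSet` records the membership of every patch, per-genet metadata
#' (site, modal taxon, first and last year observed), and carries the member
#' patch rows so that areas and bleaching scores can be computed without
#' the original survey object.
#'
#' @slot members data.frame with columns `genet_id`, `site`, `survey_year`,
#'   `patch_id`; one row per member patch.
#' @slot info data.frame with one row per genet: `genet_id`, `site`, `taxon`,
#'   `first_year`, `last_year`.
#' @slot patches data.frame of the member patch rows (patch-table schema plus
#'   `genet_id`).
#' @slot surveys sorted integer vector of survey years.
#'
#' @aliases GenetSet
#' @export
setClass("GenetSet",
         slots = c(members = "data.frame",
                   info = "data.frame",
                   patches = "data.frame",
                   surveys = "integer"))

setValidity("GenetSet", function(object) {
  errs <- character()
  if (!identical(sort(unique(object@members$genet_id)),
                 sort(object@info$genet_id)))
    errs <- c(errs, "genet ids in members and info disagree")
  if (nrow(object@members) != nrow(object@patches))
    errs <- c(errs, "members and patches must have one row per member patch")
  if (anyDuplicated(object@info$genet_id) > 0)
    errs <- c(errs, "duplicated genet_id in info")
  if (length(errs) == 0) TRUE else errs
})

#' @describeIn CoralSurvey-class construct a validated survey object.
#' @param patches,links data.frames as described for the slots.
#' @param surveys integer vector of survey years; defaults to the years seen
#'   in the patch table.
#' @return `CoralSurvey()` returns a `CoralSurvey` object.
#' @export
CoralSurvey <- function(patches, links = emptyLinkTable(),
                        surveys = sort(unique(patches$survey_year))) {
  patches <- as.data.frame(patches)
  links <- as.data.frame(links)
  if (!"x_m" %in% names(patches)) patches$x_m <- NA_real_
  if (!"y_m" %in% names(patches)) patches$y_m <- NA_real_
  patches$survey_year <- as.integer(patches$survey_year)
  patches$severity <- as.integer(patches$severity)
  patches$patch_id <- as.character(patches$patch_id)
  patches$site <- as.character(patches$site)
  if (nrow(links) > 0) {
    links$from_year <- as.integer(links$from_year)
    links$to_year <- as.integer(links$to_year)
    links$site <- as.character(links$site)
    links$from_patch <- as.character(links$from_patch)
    links$to_patch <- as.character(links$to_patch)
  }
  new("CoralSurvey", patches = patches[, PATCH_COLUMNS],
      links = links[, LINK_COLUMNS, drop = FALSE],
      surveys = as.integer(surveys))
}

#' @rdname CoralSurvey-class
#' @return `emptyLinkTable()` returns a zero-row link table with the
#'   canonical columns.
#' @export
emptyLinkTable <- function() {
  data.frame(site = character(), from_year = integer(),
             from_patch = character(), to_year = integer(),
             to_patch = character(), stringsAsFactors = FALSE)
}

#' @rdname CoralSurvey-class
#' @param x,object a `CoralSurvey`.
#' @export
patchTable <- function(x) x@patches

#' @rdname CoralSurvey-class
#' @export
linkTable <- function(x) x@links

#' @rdname CoralSurvey-class
#' @export
surveyYears <- function(x) x@surveys

setMethod("show", "CoralSurvey", function(object) {
  cat(sprintf("CoralSurvey: %d patches, %d links\n",
              nrow(object@patches), nrow(object@links)))
  cat("  surveys:", paste(object@surveys, collapse = ", "), "\n")
  cat("  sites:  ", paste(sort(unique(object@patches$site)), collapse = ", "), "\n")
  cat("  taxa:   ", paste(sort(unique(object@patches$taxon)), collapse = ", "), "\n")
})

setMethod("show", "GenetSet", function(object) {
  cat(sprintf("GenetSet: %d genets over %d member patches\n",
              nrow(object@info), nrow(object@members)))
  cat("  surveys:", paste(object@surveys, collapse = ", "), "\n")
  tt <- table(object@info$taxon)
  cat("  genets by taxon:",
      paste(sprintf("%s=%d", names(tt), as.integer(tt)), collapse = ", "), "\n")
})

#' @rdname GenetSet-class
#' @param x a `GenetSet`.
#' @return `genetInfo()` returns the per-genet metadata data.frame.
#' @export
genetInfo <- function(x) x@info

#' @rdname GenetSet-class
#' @return `genetMembers()` returns the membership data.frame.
#' @export
genetMembers <- function(x) x@members

#' @rdname GenetSet-class
#' @export
nGenets <- function(x) nrow(x@info)
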