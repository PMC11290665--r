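#' Assemble genets as connected components of the temporal link graph
#'
#' Every patch is a vertex; every temporal link (fission or fusion edge) joins
#' patches in consecutive surveys. Connected components define genets; patches
#' with no links become singleton genets. Genet ids are assigned
#' deterministically: components are ordered by site, then by the first survey
#' year in which the genet appears, then by the lexicographically smallest
#' patch id at that year, and numbered 1..K. The genet taxon is the modal
#' member taxon (ties broken alphabetically); mixed-taxon components trigger a
#' warning since they usually indicate an annotation error.
#'
#' In strict mode (default) links are required to join consecutive surveys,
#' so a genet absent at an interior survey but present before and after it is
#' rejected as a data error (tissue missed by the annotator, or a wrong
#' link). Set `strict = FALSE` to accept gap-skipping links and keep such
#' genets, with a warning.
#'
#' @param survey a [CoralSurvey].
#' @param strict logical; reject genets with interior gaps (default `TRUE`).
#' @return a [GenetSet].
#' @export
assembleGenets <- function(survey, strict = TRUE) {
  stopifnot(is(survey, "CoralSurvey"))
  p <- survey@patches
  l <- survey@links
  key <- patchKey(p$site, p$survey_year, p$patch_id)
  g <- igraph::make_empty_graph(n = nrow(p), directed = FALSE)
  igraph::V(g)$name <- key
  if (nrow(l) > 0) {
    from <- match(patchKey(l$site, l$from_year, l$from_patch), key)
    to <- match(patchKey(l$site, l$to_year, l$to_patch), key)
    g <- igraph::add_edges(g, rbind(from, to))
  }
  comp <- igraph::components(g)$membership

  # deterministic genet ids: site, then first year, then min patch id there
  ord <- order(p$survey_year, p$patch_id)
  first_row <- ord[!duplicated(comp[ord])]   # first member in (year, id) order
  comp_first <- comp[first_row]
  rank <- order(p$site[first_row], p$survey_year[first_row], p$patch_id[first_row])
  genet_of_comp <- integer(length(comp_first))
  genet_of_comp[comp_first[rank]] <- seq_along(rank)
  genet_id <- genet_of_comp[comp]

  sites <- vapply(split(p$site, genet_id), function(s) s[1], character(1))
  multi_site <- vapply(split(p$site, genet_id),
                       function(s) length(unique(s)) > 1, logical(1))
  if (any(multi_site))
    stop("genet(s) spanning multiple sites: ",
         paste(which(multi_site), collapse = ", "))
  taxa <- vapply(split(p$taxon, genet_id), function(tx) {
    tt <- sort(table(tx), decreasing = TRUE)
    if (length(tt) > 1)
      warning("mixed-taxon genet collapsed to modal taxon: ",
              paste(names(tt), collapse = "/"), call. = FALSE)
    names(tt)[1]
  }, character(1))
  yr <- split(p$survey_year, genet_id)
  first_year <- vapply(yr, min, integer(1))
  last_year <- vapply(yr, max, integer(1))

  # interior-gap check (a gap can only arise from a gap-skipping link)
  gap <- vapply(yr, function(y) {
    span <- survey@surveys[survey@surveys >= min(y) & survey@surveys <= max(y)]
    !all(span %in% y)
  }, logical(1))
  if (any(gap)) {
    msg <- sprintf("genet(s) with an interior survey gap: %s",
                   paste(names(yr)[gap], collapse = ", "))
    if (strict) stop(msg, " (set strict = FALSE to keep them)") else warning(msg)
  }

  ids <- sort(unique(genet_id))
  info <- data.frame(genet_id = ids, site = sites[as.character(ids)],
                     taxon = taxa[as.character(ids)],
                     first_year = first_year[as.character(ids)],
                     last_year = last_year[as.character(ids)],
                     row.names = NULL, stringsAsFactors = FALSE)
  members <- data.frame(genet_id = genet_id, site = p$site,
                        survey_year = p$survey_year, patch_id = p$patch_id,
                        stringsAsFactors = FALSE)
  patches <- cbind(genet_id = genet_id, p)
  o <- order(members$genet_id, members$survey_year, members$patch_id)
  new("GenetSet", members = members[o, ], info = info,
      patches = patches[o, ], surveys = survey@surveys)
}

#' Genet planar-area trajectories
#'
#' Total planar area of each genet at each survey, obtained by summing the
#' planar area of member patches; 0 at surveys where the genet has no live
#' tissue.
#'
#' @param genets a [GenetSet].
#' @return numeric matrix, genets x surveys (cm^2); rownames are genet ids,
#'   colnames are survey years.
#' @export
genetAreas <- function(genets) {
  stopifnot(is(genets, "GenetSet"))
  p <- genets@patches
  m <- matrix(0, nrow = nrow(genets@info), ncol = length(genets@surveys),
              dimnames = list(genets@info$genet_id, genets@surveys))
  i <- match(p$genet_id, genets@info$genet_id)
  j <- match(p$survey_year, genets@surveys)
  for (k in seq_len(nrow(p))) m[i[k], j[k]] <- m[i[k], j[k]] + p$area_cm2[k]
  m
}

#' Genet survivorship over the timeseries
#'
#' A genet survived the full timeseries if at least one of its patches existed
#' at both the first and the last survey year considered.
#'
#' @param genets a [GenetSet].
#' @param tFirst,tLast survey years; default to the first and last configured
#'   survey.
#' @return named logical vector (names = genet ids).
#' @export
survivedGenets <- function(genets, tFirst = genets@surveys[1],
                           tLast = genets@surveys[length(genets@surveys)]) {
  stopifnot(is(genets, "GenetSet"))
  if (!(tFirst %in% genets@surveys) || !(tLast %in% genets@surveys))
    stop("unknown survey year: ",
         paste(setdiff(c(tFirst, tLast), genets@surveys), collapse = ", "))
  if (!(tFirst < tLast)) stop("tFirst must precede tLast")
  m <- genets@members
  atFirst <- unique(m$genet_id[m$survey_year == tFirst])
  atLast <- unique(m$genet_id[m$survey_year == tLast])
  setNames(genets@info$genet_id %in% atFirst & genets@info$genet_id %in% atLast,
           genets@info$genet_id)
}

#' Restrict to the cohort alive at the start of the timeseries
#'
#' Retains only genets with at least one patch at `tFirst`; genets that
#' recruited later are excluded, since fate-tracking analyses focus on the
#' cohort alive at the start of the timeseries.
#'
#' @param genets a [GenetSet].
#' @param tFirst survey year defining the cohort (default: first survey).
#' @return a [GenetSet] containing the retained genets.
#' @export
cohortFilter <- function(genets, tFirst = genets@surveys[1]) {
  stopifnot(is(genets, "GenetSet"))
  if (!(tFirst %in% genets@surveys)) stop("unknown survey year: ", tFirst)
  keep <- unique(genets@members$genet_id[genets@members$survey_year == tFirst])
  subsetGenets(genets, keep)
}

#' @rdname GenetSet-class
#' @param ids genet ids to retain.
#' @return `subsetGenets()` returns a `GenetSet` restricted to `ids`.
#' @export
subsetGenets <- function(x, ids) {
  keepM <- x@members$genet_id %in% ids
  new("GenetSet", members = x@members[keepM, ],
      info = x@info[x@info$genet_id %in% ids, ],
      patches = x@patches[keepM, ], surveys = x@surveys)
}

#' Genet x survey area matrix as a SummarizedExperiment
#'
#' Wraps [genetAreas()] in a [SummarizedExperiment::SummarizedExperiment]
#' with per-genet metadata (site, taxon, first/last year, survivorship over
#' the full timeseries) as rowData and the survey years as colData, so the
#' assembled genets interoperate with the wider Bioconductor ecosystem.
#'
#' @param genets a [GenetSet].
#' @return a `SummarizedExperiment` with one assay, `"area"` (cm^2).
#' @export
genetExperiment <- function(genets) {
  stopifnot(is(genets, "GenetSet"))
  area <- genetAreas(genets)
  info <- genets@info
  info$survived <- as.logical(survivedGenets(genets))
  SummarizedExperiment(
    assays = list(area = area),
    rowData = DataFrame(info, row.names = rownames(area)),
    colData = DataFrame(survey_year = genets@surveys,
                        row.names = colnames(area)))
}
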