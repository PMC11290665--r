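#' Bleaching categories and the default scoring rubric
#'
#' Bleaching is assessed visually per patch as two numbers: extent, the
#' percent of the patch's area (0-100) showing some degree of paling, and
#' severity, an ordinal 0-3 score of pigmentation loss on the bleached tissue
#' only (0 practically no loss, 1 slight paling, 2 significant loss, 3 almost
#' or completely stark white). The two are combined into one of five ordered
#' bleaching categories: 1 no bleaching or very minor paling, 2 minor,
#' 3 moderate, 4 severe, 5 extreme.
#'
#' The default rubric maps the pair through a bleaching index
#' `I = extent * severity` (0-300): category 1 when `I == 0` or extent < 5;
#' 2 when `0 < I <= 25`; 3 when `25 < I <= 100`; 4 when `100 < I <= 200`;
#' 5 when `I > 200`. The index is monotone in both inputs and anchors the
#' two labelled corners (no paling -> 1; fully stark white -> 5). The rubric
#' is a plain threshold table (`category`, `index_min`, `index_max`), so a
#' different calibration can be dropped in from a CSV via [readRubric()].
#'
#' @return `defaultRubric()` returns the 5-row threshold data.frame.
#' @export
defaultRubric <- function() {
  data.frame(category = 1:5,
             index_min = c(-Inf, 0, 25, 100, 200),
             index_max = c(0, 25, 100, 200, Inf))
}

#' @rdname defaultRubric
#' @export
bleachingLabels <- function() {
  c("no bleaching or very minor paling", "minor bleaching",
    "moderate bleaching", "severe bleaching", "extreme bleaching")
}

checkRubric <- function(rubric) {
  stopifnot(is.data.frame(rubric),
            all(c("category", "index_min", "index_max") %in% names(rubric)))
  if (!identical(sort(rubric$category), 1:5) && !identical(sort(rubric$category), as.numeric(1:5)))
    stop("rubric must define exactly the five categories 1..5")
  r <- rubric[order(rubric$category), ]
  if (any(r$index_max[-5] != r$index_min[-1]))
    stop("rubric intervals must tile (index_max of one row = index_min of the next)")
  invisible(r)
}

#' Score a patch's bleaching category from extent and severity
#'
#' Computes the bleaching index `extent * severity` and looks it up in the
#' rubric threshold table; extent below 5% always maps to category 1
#' (very minor paling). Vectorised over `extent` and `severity`.
#'
#' @param extent percent of patch area paled, in \[0, 100\].
#' @param severity ordinal severity in \{0, 1, 2, 3\}.
#' @param rubric threshold table, see [defaultRubric()].
#' @return integer vector of categories in 1..5.
#' @export
scorePatch <- function(extent, severity, rubric = defaultRubric()) {
  if (any(!is.finite(extent)) || any(extent < 0 | extent > 100))
    stop("extent must lie in [0, 100]")
  if (any(!(severity %in% 0:3)))
    stop("severity must be an integer in {0, 1, 2, 3}")
  r <- checkRubric(rubric)
  idx <- extent * severity
  # intervals are (index_min, index_max], category 1 additionally catches I = 0
  cat <- vapply(seq_along(idx), function(i) {
    hit <- which(idx[i] > r$index_min & idx[i] <= r$index_max)
    if (length(hit) == 0) hit <- which(r$index_min == -Inf)
    r$category[hit[1]]
  }, numeric(1))
  cat[extent < 5] <- 1
  as.integer(cat)
}

#' Area-weighted genet-level bleaching extent
#'
#' Genet extent is the mean of member-patch extents weighted by patch planar
#' area.
#'
#' @param area,extent,severity parallel vectors over a genet's member patches
#'   at one survey.
#' @return percent in \[0, 100\].
#' @export
genetWeightedExtent <- function(area, extent) {
  if (length(area) == 0) stop("genet has no member patches at this survey")
  sum(area * extent) / sum(area)
}

#' @rdname genetWeightedExtent
#' @details Severity is defined on the bleached tissue only, so the
#'   genet-level severity weights each patch by its bleached area
#'   (`area * extent / 100`); if no tissue is bleached the severity is 0.
#' @return `genetWeightedSeverity()` returns a real in \[0, 3\].
#' @export
genetWeightedSeverity <- function(area, extent, severity) {
  if (length(area) == 0) stop("genet has no member patches at this survey")
  b <- area * extent / 100
  if (sum(b) == 0) return(0)
  sum(b * severity) / sum(b)
}

#' Genet-level bleaching category at one survey
#'
#' Two methods are exposed because the scoring can be read two ways, and they
#' genuinely differ on heterogeneous genets:
#' \describe{
#'   \item{`modal` (default)}{each member patch is scored individually and the
#'     genet takes the category with the largest summed patch area (the most
#'     common score across patches, weighted by patch area); ties break toward
#'     the higher (worse) category, which is conservative when testing for
#'     acclimatization.}
#'   \item{`aggregate`}{the rubric is applied to the genet's area-weighted
#'     extent and its bleached-area-weighted severity rounded to the nearest
#'     integer.}
#' }
#'
#' @param genets a [GenetSet].
#' @param year survey year to score.
#' @param method `"modal"` or `"aggregate"`.
#' @param rubric threshold table, see [defaultRubric()].
#' @param ids optional genet ids to score (default: all with tissue at `year`).
#' @return data.frame with columns `genet_id`, `year`, `weighted_extent`,
#'   `weighted_severity`, `category`, `method`.
#' @export
scoreGenets <- function(genets, year, method = c("modal", "aggregate"),
                        rubric = defaultRubric(), ids = NULL) {
  stopifnot(is(genets, "GenetSet"))
  method <- match.arg(method)
  if (!(year %in% genets@surveys)) stop("unknown survey year: ", year)
  p <- genets@patches[genets@patches$survey_year == year, ]
  if (!is.null(ids)) {
    missing <- setdiff(ids, p$genet_id)
    if (length(missing) > 0)
      stop("genet(s) with no member patches at ", year, ": ",
           paste(missing, collapse = ", "))
    p <- p[p$genet_id %in% ids, ]
  }
  if (nrow(p) == 0) stop("no genet has member patches at ", year)
  res <- lapply(split(p, p$genet_id), function(pp) {
    we <- genetWeightedExtent(pp$area_cm2, pp$extent_pct)
    ws <- genetWeightedSeverity(pp$area_cm2, pp$extent_pct, pp$severity)
    cat <- if (method == "modal") {
      pc <- scorePatch(pp$extent_pct, pp$severity, rubric)
      byCat <- tapply(pp$area_cm2, pc, sum)
      cand <- as.integer(names(byCat)[byCat == max(byCat)])
      max(cand)                                  # tie -> worse category
    } else {
      scorePatch(we, as.integer(round(ws)), rubric)
    }
    data.frame(genet_id = pp$genet_id[1], year = year,
               weighted_extent = we, weighted_severity = ws,
               category = as.integer(cat), method = method)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$genet_id), ]
}

#' Change in bleaching category between the two bleaching events
#'
#' The per-genet change statistic is the second-event category minus the
#' first-event category: an integer in -4..4 where 0 means no change, -4
#' means extreme bleaching in the first event and none in the second, and +4
#' the reverse.
#'
#' @param cEvent1,cEvent2 categories in 1..5 (vectorised).
#' @return integer vector in -4..4.
#' @export
changeStatistic <- function(cEvent1, cEvent2) {
  checkCategory(cEvent1); checkCategory(cEvent2)
  as.integer(cEvent2) - as.integer(cEvent1)
}

checkCategory <- function(x) {
  if (any(!(x %in% 1:5))) stop("bleaching category must be in 1..5")
  invisible(x)
}

#' Four-way bleaching response classification
#'
#' A genet that changed by more than one category between the two events has
#' a `decreased` (delta <= -2) or `increased` (delta >= +2) bleaching
#' response. Genets that changed one step or less are stable: stable genets
#' that exhibited moderate bleaching or higher in at least one event are
#' `high_susceptibility`, all others `thermally_tolerant`.
#'
#' @param cEvent1,cEvent2 categories in 1..5 (vectorised).
#' @return factor with levels `thermally_tolerant`, `decreased`, `increased`,
#'   `high_susceptibility`.
#' @export
classifyResponse <- function(cEvent1, cEvent2) {
  delta <- changeStatistic(cEvent1, cEvent2)
  out <- ifelse(delta <= -2, "decreased",
                ifelse(delta >= 2, "increased",
                       ifelse(pmax(cEvent1, cEvent2) >= 3,
                              "high_susceptibility", "thermally_tolerant")))
  factor(out, levels = responseLevels())
}

#' @rdname classifyResponse
#' @export
responseLevels <- function() {
  c("thermally_tolerant", "decreased", "increased", "high_susceptibility")
}

#' Binary bleaching indicator
#'
#' 1 for genets with moderate, severe or extreme bleaching (category >= 3),
#' 0 for minor or no bleaching — the response variable of the size-dependent
#' bleaching logistic model.
#'
#' @param category categories in 1..5 (vectorised).
#' @return integer vector of 0/1.
#' @export
binarizeBleaching <- function(category) {
  checkCategory(category)
  as.integer(category >= 3)
}

#' Classify every genet's response across the two bleaching events
#'
#' Scores each genet at both event years, keeps genets present in both events
#' (the change statistic is only defined for survivors of both), and returns
#' the per-genet change statistic and four-way response class.
#'
#' @param genets a [GenetSet].
#' @param eventYears length-2 integer vector of bleaching-event survey years.
#' @param method,rubric passed to [scoreGenets()].
#' @return data.frame with columns `genet_id`, `site`, `taxon`, `c_event1`,
#'   `c_event2`, `delta`, `response`.
#' @export
classifyGenets <- function(genets, eventYears, method = "modal",
                           rubric = defaultRubric()) {
  stopifnot(length(eventYears) == 2, all(eventYears %in% genets@surveys))
  s1 <- scoreGenets(genets, eventYears[1], method = method, rubric = rubric)
  s2 <- scoreGenets(genets, eventYears[2], method = method, rubric = rubric)
  both <- intersect(s1$genet_id, s2$genet_id)
  c1 <- s1$category[match(both, s1$genet_id)]
  c2 <- s2$category[match(both, s2$genet_id)]
  info <- genets@info[match(both, genets@info$genet_id), ]
  data.frame(genet_id = both, site = info$site, taxon = info$taxon,
             c_event1 = c1, c_event2 = c2,
             delta = changeStatistic(c1, c2),
             response = classifyResponse(c1, c2),
             stringsAsFactors = FALSE)
}
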