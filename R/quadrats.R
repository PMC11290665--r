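#' Quadrat sampling of genets
#'
#' Genets are brought into the traced sample through randomly placed,
#' non-overlapping square quadrats (default 0.5 m^2). A genet qualifies if, at
#' the first survey, it has at least one patch larger than the minimum
#' diameter whose centroid falls inside a used quadrat; quadrats are consumed
#' in order until the target number of genets is reached or the maximum
#' number of quadrats is used. Patches below the diameter threshold or
#' outside every quadrat still belong to the sample when they are temporally
#' linked to a selected genet, because selection operates on whole genets.
#' If more genets of one taxon are selected than the per-taxon cap, the
#' sample is thinned to the cap uniformly at random with the configured seed.
#'
#' Patch diameter is the equivalent-circle diameter `2 * sqrt(area / pi)`
#' computed from planar area, since the tables carry no polygon geometry.
#'
#' @param sideLength quadrat side in metres; the default gives a 0.5 m^2
#'   quadrat.
#' @param minDiameter minimum patch diameter in cm for the centroid rule.
#' @param targetGenets stop adding quadrats once this many genets qualify.
#' @param maxQuadrats maximum number of quadrats to use.
#' @param genetCap per-taxon cap on selected genets; excess genets are
#'   subsampled uniformly.
#' @param seed integer seed for quadrat placement / cap subsampling.
#' @return `samplingConfig()` returns a list of the sampling parameters.
#' @export
samplingConfig <- function(minDiameter = 5, targetGenets = 40,
                           maxQuadrats = 25, genetCap = 100, seed = 1L) {
  stopifnot(minDiameter >= 0, targetGenets >= 1, maxQuadrats >= 1, genetCap >= 1)
  list(min_diameter_cm = minDiameter, target_genets = targetGenets,
       max_quadrats = maxQuadrats, genet_cap = genetCap, seed = as.integer(seed))
}

#' @rdname samplingConfig
#' @param n number of quadrats to place.
#' @param frame numeric length-2 vector, the site frame extent in metres
#'   (default a 12 x 12 m orthoprojection).
#' @return `placeQuadrats()` returns a data.frame of non-overlapping quadrats
#'   with columns `x0`, `y0` (lower-left corner, m) and `side` (m).
#' @export
placeQuadrats <- function(n, frame = c(12, 12), sideLength = sqrt(0.5),
                          seed = 1L) {
  withLocalSeed(seed, {
    out <- data.frame(x0 = numeric(0), y0 = numeric(0), side = numeric(0))
    tries <- 0
    while (nrow(out) < n && tries < 10000 * n) {
      tries <- tries + 1
      x0 <- runif(1, 0, frame[1] - sideLength)
      y0 <- runif(1, 0, frame[2] - sideLength)
      overlaps <- nrow(out) > 0 &&
        any(abs(out$x0 - x0) < sideLength & abs(out$y0 - y0) < sideLength)
      if (!overlaps)
        out <- rbind(out, data.frame(x0 = x0, y0 = y0, side = sideLength))
    }
    if (nrow(out) < n)
      stop("could not place ", n, " non-overlapping quadrats in the frame")
    out
  })
}

#' @rdname samplingConfig
#' @param genets a [GenetSet].
#' @param quadrats data.frame from [placeQuadrats()]; used in row order.
#' @param config list from [samplingConfig()].
#' @return `selectQuadratGenets()` returns a list with `genet_ids` (sorted
#'   integer vector of selected genets) and `quadrats_used` (count).
#' @export
selectQuadratGenets <- function(genets, quadrats, config = samplingConfig()) {
  stopifnot(is(genets, "GenetSet"))
  tFirst <- genets@surveys[1]
  p <- genets@patches[genets@patches$survey_year == tFirst, ]
  if (nrow(p) == 0) return(list(genet_ids = integer(0), quadrats_used = 0L))
  noCentroid <- !is.finite(p$x_m) | !is.finite(p$y_m)
  if (any(noCentroid))
    stop("patch(es) without a centroid: ",
         paste(p$patch_id[noCentroid], collapse = ", "))
  diam <- 2 * sqrt(p$area_cm2 / pi)            # equivalent-circle diameter, cm
  eligible <- diam > config$min_diameter_cm

  nq <- min(nrow(quadrats), config$max_quadrats)
  selected <- integer(0)
  used <- 0L
  for (q in seq_len(nq)) {
    used <- q
    inside <- p$x_m >= quadrats$x0[q] & p$x_m <= quadrats$x0[q] + quadrats$side[q] &
      p$y_m >= quadrats$y0[q] & p$y_m <= quadrats$y0[q] + quadrats$side[q]
    selected <- union(selected, unique(p$genet_id[inside & eligible]))
    if (length(selected) >= config$target_genets) break
  }

  info <- genets@info[genets@info$genet_id %in% selected, ]
  out <- integer(0)
  for (tx in sort(unique(info$taxon))) {
    ids <- sort(info$genet_id[info$taxon == tx])
    if (length(ids) > config$genet_cap)
      ids <- withLocalSeed(config$seed,
                           sort(sample(ids, config$genet_cap)))
    out <- c(out, ids)
  }
  list(genet_ids = sort(out), quadrats_used = used)
}
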