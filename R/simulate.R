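#' Per-taxon simulation parameters
#'
#' Bundles the demographic and bleaching-response parameters of one simulated
#' taxon. The bleaching phenotype mix gives the a-priori probabilities of the
#' four response phenotypes (thermally tolerant, decreased response,
#' increased response, high susceptibility) that drive each genet's category
#' draws at the two bleaching events. Survival acts per inter-survey interval
#' through a logistic model `logit(p) = survA + survB * ln(area)`; `survB`
#' may be negative (larger colonies die more), as observed in a
#' Pocillopora-like taxon. Growth is a lognormal multiplicative change per
#' interval (shrinkage allowed); fission splits a genet's tissue into two
#' patches with a uniform \[0.2, 0.8\] fraction, and fragmented genets re-fuse
#' with the fusion probability.
#'
#' @param name taxon label.
#' @param nGenets genets per site.
#' @param mix length-4 numeric, probabilities of (tolerant, decreased,
#'   increased, susceptible); must sum to 1.
#' @param sizeMeanlog,sizeSdlog lognormal initial planar area (cm^2).
#' @param survA,survB per-interval survival logit intercept / ln-area slope.
#' @param growthMeanlog,growthSdlog lognormal per-interval area multiplier.
#' @param fissionProb,fusionProb per-interval fission / fusion probabilities.
#' @return a list of class `"taxonConfig"`.
#' @export
taxonConfig <- function(name, nGenets, mix, sizeMeanlog = log(100),
                        sizeSdlog = 1.2, survA = 0, survB = 0.5,
                        growthMeanlog = 0.1, growthSdlog = 0.3,
                        fissionProb = 0.15, fusionProb = 0.3) {
  stopifnot(length(mix) == 4, all(mix >= 0), abs(sum(mix) - 1) < 1e-9,
            nGenets >= 1, fissionProb >= 0, fissionProb <= 1,
            fusionProb >= 0, fusionProb <= 1)
  structure(list(name = name, n_genets = as.integer(nGenets), mix = mix,
                 size_meanlog = sizeMeanlog, size_sdlog = sizeSdlog,
                 surv_a = survA, surv_b = survB,
                 growth_meanlog = growthMeanlog, growth_sdlog = growthSdlog,
                 fission_prob = fissionProb, fusion_prob = fusionProb),
            class = "taxonConfig")
}

#' Simulation configuration for a synthetic reef community
#'
#' The defaults emulate the study conditions of a leeward-Maui style
#' timeseries: five surveys (2014, 2015, 2017, 2019, 2021) with bleaching
#' events in 2015 and 2019, six sites, and four taxa whose genet counts,
#' phenotype mixes and size-dependent survival are chosen so that end-to-end
#' survivorship at the median colony size matches the reported per-taxon
#' rates (about 54\%, 51\%, 16\% and 63\% for the Montipora capitata-,
#' Montipora patula-, Pocillopora- and Porites lobata-like taxa) and the
#' Pocillopora-like taxon has a negative size-survival slope.
#'
#' @param surveys ordered integer survey years.
#' @param eventYears the two bleaching-event years (must be surveys).
#' @param sites character vector of site labels.
#' @param taxa list of [taxonConfig()] objects.
#' @param palingNoiseProb probability that a surviving genet shows very minor
#'   paling (extent < 5\%, category 1) in a non-event year.
#' @param seed master integer seed; all randomness derives from it through
#'   per-genet substreams.
#' @param nullSymmetric if `TRUE`, event-year categories are drawn i.i.d.
#'   uniform on 1..5 for every genet regardless of phenotype, which makes the
#'   distribution of the change statistic exactly symmetric about 0 (used for
#'   type-I calibration of the acclimatization test).
#' @return list of class `"simConfig"`.
#' @export
simConfig <- function(surveys = c(2014L, 2015L, 2017L, 2019L, 2021L),
                      eventYears = c(2015L, 2019L),
                      sites = c("Kahekili", "Wahikuli", "Olowalu",
                                "Ukumehame", "Keawakapu", "Molokini"),
                      taxa = defaultTaxa(),
                      palingNoiseProb = 0.05,
                      seed = 1L,
                      nullSymmetric = FALSE) {
  surveys <- as.integer(surveys)
  stopifnot(!is.unsorted(surveys, strictly = TRUE),
            length(eventYears) == 2, all(eventYears %in% surveys),
            palingNoiseProb >= 0, palingNoiseProb <= 1)
  structure(list(surveys = surveys, event_years = as.integer(eventYears),
                 sites = sites, taxa = taxa,
                 paling_noise_prob = palingNoiseProb,
                 seed = as.integer(seed),
                 null_symmetric = isTRUE(nullSymmetric)),
            class = "simConfig")
}

#' @rdname simConfig
#' @export
defaultTaxa <- function() {
  list(
    taxonConfig("Montipora capitata", 80, c(0.25, 0.10, 0.10, 0.55),
                survA = -0.50, survB = 0.5),
    taxonConfig("Montipora patula", 80, c(0.78, 0.05, 0.07, 0.10),
                survA = -0.60, survB = 0.5),
    taxonConfig("Pocillopora", 60, c(0.10, 0.25, 0.10, 0.55),
                survA = 2.37, survB = -0.4,
                fissionProb = 0.05, fusionProb = 0.2),
    taxonConfig("Porites lobata", 85, c(0.40, 0.30, 0.05, 0.25),
                survA = -0.19, survB = 0.5))
}

#' @rdname simConfig
#' @param config a `"simConfig"`.
#' @return `nullScenario()` returns a copy of `config` whose event-category
#'   draws are symmetric about zero change; applying it twice is the same as
#'   applying it once.
#' @export
nullScenario <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  config$null_symmetric <- TRUE
  config
}

# valid (c1, c2) category pairs for each phenotype
phenotypePairs <- function(phenotype) {
  switch(phenotype,
         tolerant = cbind(c1 = c(1, 1, 2, 2), c2 = c(1, 2, 1, 2)),
         decreased = cbind(c1 = c(3, 4, 4, 5, 5, 5), c2 = c(1, 1, 2, 1, 2, 3)),
         increased = cbind(c1 = c(1, 1, 2, 1, 2, 3), c2 = c(3, 4, 4, 5, 5, 5)),
         susceptible = cbind(c1 = c(3, 3, 4, 4, 4, 5, 5),
                             c2 = c(3, 4, 3, 4, 5, 4, 5)),
         stop("unknown phenotype: ", phenotype))
}

# extent/severity pair whose rubric category equals `cat` (default rubric);
# jitter stays inside the category's index band; returns c(extent, severity)
drawExtentSeverity <- function(cat) {
  if (cat == 1) c(0, 0)
  else if (cat == 2) c(runif(1, 6, 25), 1)       # I in (6, 25]
  else if (cat == 3) c(runif(1, 14, 50), 2)      # I in (28, 100]
  else if (cat == 4) c(runif(1, 51, 100), 2)     # I in (102, 200]
  else c(runif(1, 68, 100), 3)                   # I in (204, 300]
}

#' Simulate a synthetic reef community with ground truth
#'
#' Generates patch and temporal-link tables with the statistical structure the
#' analysis pipeline assumes, plus a per-genet truth table. Every genet is
#' assigned a bleaching phenotype and an initial size; in each inter-survey
#' interval it survives a size-dependent Bernoulli trial, grows by a lognormal
#' multiplier, may undergo fission into two patches (uniform \[0.2, 0.8\]
#' split) and, when fragmented, may re-fuse. At event years extent and
#' severity are drawn so that the genet's (modal-method) bleaching category
#' equals the phenotype-conditional category draw; in non-event years genets
#' show either no paling or, with the configured noise probability, very
#' minor paling that stays in category 1. All randomness derives from the
#' master seed via per-genet substreams, so the output is reproducible and
#' independent of iteration order.
#'
#' @param config a [simConfig()].
#' @return list with `patches`, `links` (canonical table schemas; see
#'   [CoralSurvey()]) and `truth` (one row per genet: `genet_label`, `site`,
#'   `taxon`, `phenotype`, `survived`, `c_event1`, `c_event2`,
#'   `area_<year>` columns).
#' @export
simulateCommunity <- function(config = simConfig()) {
  stopifnot(inherits(config, "simConfig"))
  surveys <- config$surveys
  nS <- length(surveys)
  ev <- match(config$event_years, surveys)
  nTotal <- length(config$sites) * sum(vapply(config$taxa, `[[`, 1L, "n_genets"))
  maxRows <- nTotal * nS * 2L

  P <- list(patch_id = character(maxRows), site = character(maxRows),
            survey_year = integer(maxRows), taxon = character(maxRows),
            area_cm2 = numeric(maxRows), extent_pct = numeric(maxRows),
            severity = integer(maxRows), x_m = numeric(maxRows),
            y_m = numeric(maxRows))
  L <- list(site = character(maxRows), from_year = integer(maxRows),
            from_patch = character(maxRows), to_year = integer(maxRows),
            to_patch = character(maxRows))
  np <- 0L; nl <- 0L
  Tr <- list(genet_label = character(nTotal), site = character(nTotal),
             taxon = character(nTotal), phenotype = character(nTotal),
             survived = logical(nTotal), c_event1 = integer(nTotal),
             c_event2 = integer(nTotal))
  truthAreas <- matrix(0, nTotal, nS)
  phenoNames <- c("tolerant", "decreased", "increased", "susceptible")
  isEvent <- seq_len(nS) %in% ev
  evIndex <- match(seq_len(nS), ev)
  tr <- 0L

  withLocalSeed(config$seed, for (site in config$sites) {
    gidx <- 0L
    for (tx in config$taxa) {
      mixCum <- cumsum(tx$mix)
      pairsByPheno <- lapply(phenoNames, phenotypePairs)
      for (i in seq_len(tx$n_genets)) {
        gidx <- gidx + 1L
        set.seed(substreamSeed(config$seed, site, tx$name, i))
        label <- sprintf("g%04d", gidx)

        ph <- min(findInterval(runif(1), mixCum, left.open = TRUE) + 1L, 4L)
        phenotype <- phenoNames[ph]
        if (config$null_symmetric) {
          cats <- sample.int(5, 2, replace = TRUE)
        } else {
          pp <- pairsByPheno[[ph]]
          cats <- pp[sample.int(nrow(pp), 1), ]
        }
        cx <- runif(1, 0.5, 11.5); cy <- runif(1, 0.5, 11.5)
        area <- rlnorm(1, tx$size_meanlog, tx$size_sdlog)
        frac <- 1                       # fraction in fragment 1
        nFrag <- 1L
        alive <- TRUE
        areas <- numeric(nS)
        lastIds <- character(0)

        for (s in seq_len(nS)) {
          if (s > 1) {
            # survival, growth, fission/fusion over the preceding interval
            pSurv <- plogis(tx$surv_a + tx$surv_b * log(area))
            if (runif(1) > pSurv) { alive <- FALSE; break }
            area <- area * rlnorm(1, tx$growth_meanlog, tx$growth_sdlog)
            if (nFrag == 1L && runif(1) < tx$fission_prob) {
              nFrag <- 2L
              frac <- runif(1, 0.2, 0.8)
            } else if (nFrag == 2L && runif(1) < tx$fusion_prob) {
              nFrag <- 1L
              frac <- 1
            }
          }
          areas[s] <- area
          if (isEvent[s]) {
            es <- drawExtentSeverity(cats[evIndex[s]])
          } else if (runif(1) < config$paling_noise_prob) {
            es <- c(runif(1, 1, 4.9), 1)
          } else es <- c(0, 0)

          fr <- if (nFrag == 2L) c(frac, 1 - frac) else 1
          ids <- paste0(label, "_", surveys[s], "_", seq_len(nFrag))
          for (k in seq_len(nFrag)) {
            np <- np + 1L
            P$patch_id[np] <- ids[k]
            P$site[np] <- site
            P$survey_year[np] <- surveys[s]
            P$taxon[np] <- tx$name
            P$area_cm2[np] <- area * fr[k]
            P$extent_pct[np] <- es[1]
            P$severity[np] <- as.integer(es[2])
            P$x_m[np] <- min(11.99, max(0.01, cx + (k - 1.5) * 0.2))
            P$y_m[np] <- min(11.99, max(0.01, cy))
          }
          if (s > 1 && length(lastIds) > 0) {
            # connect every consecutive-patch pair along the fragment lineage
            if (length(lastIds) == length(ids)) {
              pairsFrom <- lastIds; pairsTo <- ids
            } else if (length(lastIds) == 1L) {        # fission
              pairsFrom <- rep(lastIds, length(ids)); pairsTo <- ids
            } else {                                   # fusion
              pairsFrom <- lastIds; pairsTo <- rep(ids, length(lastIds))
            }
            for (k in seq_along(pairsFrom)) {
              nl <- nl + 1L
              L$site[nl] <- site
              L$from_year[nl] <- surveys[s - 1L]
              L$from_patch[nl] <- pairsFrom[k]
              L$to_year[nl] <- surveys[s]
              L$to_patch[nl] <- pairsTo[k]
            }
          }
          lastIds <- ids
        }

        tr <- tr + 1L
        Tr$genet_label[tr] <- label
        Tr$site[tr] <- site
        Tr$taxon[tr] <- tx$name
        Tr$phenotype[tr] <- if (config$null_symmetric) "null" else phenotype
        Tr$survived[tr] <- alive
        Tr$c_event1[tr] <- if (areas[ev[1]] == 0) NA_integer_ else as.integer(cats[1])
        Tr$c_event2[tr] <- if (areas[ev[2]] == 0) NA_integer_ else as.integer(cats[2])
        truthAreas[tr, ] <- areas
      }
    }
  })
  patches <- data.frame(lapply(P, function(v) v[seq_len(np)]),
                        stringsAsFactors = FALSE)
  links <- if (nl > 0)
    data.frame(lapply(L, function(v) v[seq_len(nl)]), stringsAsFactors = FALSE)
  else emptyLinkTable()
  truth <- data.frame(Tr, stringsAsFactors = FALSE)
  colnames(truthAreas) <- paste0("area_", surveys)
  truth <- cbind(truth, as.data.frame(truthAreas))
  list(patches = patches, links = links, truth = truth)
}

#' @rdname simulateCommunity
#' @param sim output of `simulateCommunity()`.
#' @return `simulationSurvey()` wraps the simulated tables in a
#'   [CoralSurvey].
#' @export
simulationSurvey <- function(sim, config = simConfig()) {
  CoralSurvey(sim$patches, sim$links, surveys = config$surveys)
}
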