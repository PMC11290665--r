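#' Configuration of a full pipeline run
#'
#' Houses the analysis constants: the survey list, the two bleaching-event
#' years, the survivorship endpoints, the significance level (0.05), the
#' bootstrap resample count (100,000), the minimum surviving genets for an
#' acclimatization test (10), the genet scoring method and rubric, and the
#' master seed.
#'
#' @param patchesPath,linksPath input CSV paths (ignored when `runPipeline()`
#'   is given a `CoralSurvey` directly).
#' @param surveys ordered integer survey years.
#' @param eventYears the two bleaching-event years.
#' @param tFirst,tLast survivorship endpoints (default first/last survey).
#' @param alpha significance level in (0, 1).
#' @param nResamples bootstrap resamples for the acclimatization test.
#' @param minSurvivors eligibility threshold for the acclimatization test.
#' @param rubric threshold table (default [defaultRubric()]), or a path
#'   accepted by [readRubric()].
#' @param method genet scoring method, `"modal"` or `"aggregate"`.
#' @param seed master integer seed.
#' @param outDir output directory (created if needed).
#' @param strict reject genets with interior survey gaps.
#' @return list of class `"runConfig"`.
#' @export
runConfig <- function(patchesPath = NULL, linksPath = NULL,
                      surveys = c(2014L, 2015L, 2017L, 2019L, 2021L),
                      eventYears = c(2015L, 2019L),
                      tFirst = min(surveys), tLast = max(surveys),
                      alpha = 0.05, nResamples = 1e5, minSurvivors = 10,
                      rubric = defaultRubric(), method = "modal",
                      seed = 1L, outDir = "coralfate_out", strict = TRUE) {
  surveys <- as.integer(surveys)
  stopifnot(alpha > 0, alpha < 1, all(eventYears %in% surveys),
            tFirst < tLast, tFirst %in% surveys, tLast %in% surveys)
  if (is.character(rubric)) rubric <- readRubric(rubric)
  structure(list(patches_path = patchesPath, links_path = linksPath,
                 surveys = surveys, event_years = as.integer(eventYears),
                 t_first = as.integer(tFirst), t_last = as.integer(tLast),
                 alpha = alpha, n_resamples = nResamples,
                 min_survivors = minSurvivors, rubric = rubric,
                 method = method, seed = as.integer(seed),
                 out_dir = outDir, strict = isTRUE(strict)),
            class = "runConfig")
}

stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

# popstats for one taxon; degenerate model fits are recorded, not fatal
taxonPopstats <- function(responsesTaxon, survInfo, areas, config) {
  out <- list()
  softly <- function(expr) tryCatch(expr, error = function(e)
    list(error = conditionMessage(e)), warning = function(w)
      tryCatch(suppressWarnings(expr), error = function(e)
        list(error = conditionMessage(e))))

  # site-wise bleaching-response comparison among full-timeseries survivors
  survResponses <- responsesTaxon[responsesTaxon$survived_full, ]
  out$pairwise_fisher <- softly({
    tab <- suppressWarnings(buildResponseTable(survResponses, "site"))
    pw <- pairwiseFisher(tab, alpha = config$alpha, seed = config$seed)
    out_letters <- compactLetters(rownames(tab), pw)
    list(table = as.data.frame(tab), pairs = pw,
         letters = as.list(out_letters))
  })
  out$letters <- if (!is.null(out$pairwise_fisher$letters))
    out$pairwise_fisher$letters else list()

  # bleaching probability vs size at each event, pooled across sites
  out$logistic_bleaching <- lapply(seq_along(config$event_years), function(j) {
    yr <- config$event_years[j]
    sub <- responsesTaxon[!is.na(responsesTaxon[[paste0("area_", yr)]]) &
                            responsesTaxon[[paste0("area_", yr)]] > 0, ]
    softly({
      cat <- sub[[paste0("c_event", j)]]
      fit <- bleachingSizeModel(binarizeBleaching(cat),
                                sub[[paste0("area_", yr)]])
      list(year = yr, n = fit$n, coefficients = as.list(fit$coefficients),
           se = as.list(fit$se), p = as.list(fit$p),
           converged = fit$converged, separation = fit$separation)
    })
  })

  # survivorship vs size x site, all traced genets of the taxon
  out$logistic_survivorship <- softly({
    fit <- survivorshipModel(survInfo$survived, survInfo$area0, survInfo$site)
    contrasts <- pairwiseSiteContrasts(fit, alpha = config$alpha)
    list(n = fit$n, coefficients = as.list(fit$coefficients),
         se = as.list(fit$se), p = as.list(fit$p),
         converged = fit$converged, separation = fit$separation,
         pairwise_contrasts = contrasts)
  })

  # growth ANCOVA on full-timeseries survivors, bleaching response as factor
  out$ancova <- softly({
    g <- survResponses[survResponses$area_first > 0 &
                         survResponses$area_last > 0, ]
    a <- growthAncova(g$area_last, g$area_first, g$response)
    diag <- growthDiagnostics(a$residuals, a$groups)
    list(n = length(a$residuals), slope = a$slope, terms = a$terms,
         dropped_levels = a$dropped_levels,
         diagnostics = list(shapiro_p = diag$shapiro_p,
                            cochran_C = if (is.null(diag$cochran)) NA
                                        else diag$cochran$C,
                            cochran_p = if (is.null(diag$cochran)) NA
                                        else diag$cochran$p))
  })
  out$diagnostics <- if (!is.null(out$ancova$diagnostics))
    out$ancova$diagnostics else list()
  out
}

#' Run the full fate-tracking analysis pipeline
#'
#' Chains the stages: genet assembly from patch/link tables, cohort
#' restriction to genets alive at `tFirst`, bleaching scoring at every
#' survey, two-event response classification, per-population bootstrap
#' acclimatization tests, and the population statistics (pairwise Fisher
#' tests with letters, size-dependent logistic models of bleaching and
#' survivorship, growth ANCOVA with diagnostics). Writes `genets.csv`,
#' `bleaching_scores.csv`, `responses.csv`, `acclim_results.csv`,
#' `popstats.json`, `letters.csv` and `run_log.txt` to the output directory.
#' The result is a pure function of the inputs and the configuration,
#' including the seed.
#'
#' @param config a [runConfig()].
#' @param survey optional [CoralSurvey]; when `NULL` the tables are read from
#'   the configured paths.
#' @return (invisibly) a list with the in-memory results: `genets`,
#'   `genet_table`, `scores`, `responses`, `acclim`, `popstats`.
#' @export
runPipeline <- function(config, survey = NULL) {
  stopifnot(inherits(config, "runConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(config$out_dir, "run_log.txt")
  logLine <- function(...) cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ",
                               sprintf(...), "\n", sep = "", file = logPath,
                               append = TRUE)
  cat("", file = logPath)
  logLine("coralfate %s; seed=%d; method=%s; alpha=%g; resamples=%d",
          as.character(utils::packageVersion("coralfate")), config$seed,
          config$method, config$alpha, as.integer(config$n_resamples))
  logLine("surveys=%s; events=%s; endpoints=%d..%d",
          paste(config$surveys, collapse = ","),
          paste(config$event_years, collapse = ","),
          config$t_first, config$t_last)

  if (is.null(survey)) {
    survey <- stageTry("read", {
      pr <- readPatchTable(config$patches_path)
      if (nrow(pr$report) > 0) {
        logLine("excluded %d invalid patch row(s)", nrow(pr$report))
        warning(sprintf("excluded %d invalid patch row(s)", nrow(pr$report)))
      }
      links <- if (!is.null(config$links_path)) readLinkTable(config$links_path)
               else emptyLinkTable()
      CoralSurvey(pr$patches, links, surveys = config$surveys)
    })
  }

  genets <- stageTry("assemble",
                     cohortFilter(assembleGenets(survey, strict = config$strict),
                                  config$t_first))
  areas <- genetAreas(genets)
  surv <- survivedGenets(genets, config$t_first, config$t_last)
  info <- genetInfo(genets)
  genetTable <- cbind(info[, c("genet_id", "site", "taxon",
                               "first_year", "last_year")],
                      survived = as.logical(surv),
                      as.data.frame(`colnames<-`(areas,
                                                 paste0("area_", colnames(areas)))))
  writeTable(genetTable, file.path(config$out_dir, "genets.csv"))
  logLine("assembled %d genets in the %d cohort", nrow(info), config$t_first)

  scores <- stageTry("score", {
    do.call(rbind, lapply(config$surveys, function(yr) {
      if (!any(genets@patches$survey_year == yr)) return(NULL)
      scoreGenets(genets, yr, method = config$method, rubric = config$rubric)
    }))
  })
  writeTable(scores, file.path(config$out_dir, "bleaching_scores.csv"))

  responses <- stageTry("classify", {
    r <- classifyGenets(genets, config$event_years, method = config$method,
                        rubric = config$rubric)
    r$survived_full <- as.logical(surv[as.character(r$genet_id)])
    r$area_first <- areas[as.character(r$genet_id),
                          as.character(config$t_first)]
    r$area_last <- areas[as.character(r$genet_id), as.character(config$t_last)]
    for (yr in config$event_years)
      r[[paste0("area_", yr)]] <- areas[as.character(r$genet_id),
                                        as.character(yr)]
    r
  })
  writeTable(responses, file.path(config$out_dir, "responses.csv"))
  logLine("classified %d genets present at both events", nrow(responses))

  acclim <- stageTry("test-acclim",
                     acclimTestAll(responses, nResamples = config$n_resamples,
                                   seed = config$seed,
                                   minSurvivors = config$min_survivors,
                                   alpha = config$alpha))
  writeTable(acclim, file.path(config$out_dir, "acclim_results.csv"))
  logLine("acclimatization tests: %d populations, %d eligible",
          nrow(acclim), sum(acclim$eligible))

  popstats <- stageTry("popstats", {
    res <- list()
    for (tx in sort(unique(info$taxon))) {
      rt <- responses[responses$taxon == tx, ]
      ids <- info$genet_id[info$taxon == tx]
      survInfo <- data.frame(
        genet_id = ids,
        site = info$site[info$taxon == tx],
        survived = as.integer(surv[as.character(ids)]),
        area0 = areas[as.character(ids), as.character(config$t_first)])
      survInfo <- survInfo[survInfo$area0 > 0, ]
      res[[tx]] <- taxonPopstats(rt, survInfo, areas, config)
    }
    res
  })
  jsonlite::write_json(popstats, file.path(config$out_dir, "popstats.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE, na = "null")

  letters <- do.call(rbind, lapply(names(popstats), function(tx) {
    l <- popstats[[tx]]$letters
    if (length(l) == 0) return(NULL)
    data.frame(taxon = tx, site = names(l),
               letters = unlist(l), stringsAsFactors = FALSE)
  }))
  if (is.null(letters))
    letters <- data.frame(taxon = character(0), site = character(0),
                          letters = character(0))
  writeTable(letters, file.path(config$out_dir, "letters.csv"))
  logLine("pipeline complete")

  invisible(list(genets = genets, genet_table = genetTable, scores = scores,
                 responses = responses, acclim = acclim, popstats = popstats))
}
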