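# Shared fixtures: hand-built surveys and independent graph oracles.

makePatches <- function(patch_id, site = "A", survey_year, taxon = "T",
                        area_cm2 = 10, extent_pct = 0, severity = 0,
                        x_m = NA_real_, y_m = NA_real_) {
  data.frame(patch_id = patch_id, site = site, survey_year = survey_year,
             taxon = taxon, area_cm2 = area_cm2, extent_pct = extent_pct,
             severity = severity, x_m = x_m, y_m = y_m,
             stringsAsFactors = FALSE)
}

makeLinks <- function(from_year, from_patch, to_year, to_patch, site = "A") {
  data.frame(site = site, from_year = from_year, from_patch = from_patch,
             to_year = to_year, to_patch = to_patch, stringsAsFactors = FALSE)
}

# A hand-drawn survey covering the canonical fate patterns:
#   genet of a1->a2->a3   : simple chain, survives the timeseries
#   genet of b1           : complete mortality after year 1
#   genet of c1->{c2a,c2b}->c3 : fission at year 2, fusion at year 3
#   genet of d2->d3       : recruit (absent at year 1)
tinySurvey <- function() {
  p <- rbind(
    makePatches("a1", survey_year = 1, area_cm2 = 10),
    makePatches("a2", survey_year = 2, area_cm2 = 12),
    makePatches("a3", survey_year = 3, area_cm2 = 14),
    makePatches("b1", survey_year = 1, area_cm2 = 5),
    makePatches("c1", survey_year = 1, area_cm2 = 20),
    makePatches("c2a", survey_year = 2, area_cm2 = 8),
    makePatches("c2b", survey_year = 2, area_cm2 = 9),
    makePatches("c3", survey_year = 3, area_cm2 = 18),
    makePatches("d2", survey_year = 2, area_cm2 = 4),
    makePatches("d3", survey_year = 3, area_cm2 = 6))
  l <- rbind(
    makeLinks(1, "a1", 2, "a2"),
    makeLinks(2, "a2", 3, "a3"),
    makeLinks(1, "c1", 2, "c2a"),
    makeLinks(1, "c1", 2, "c2b"),
    makeLinks(2, "c2a", 3, "c3"),
    makeLinks(2, "c2b", 3, "c3"),
    makeLinks(2, "d2", 3, "d3"))
  CoralSurvey(p, l, surveys = 1:3)
}

# Independent connected-components oracle: breadth-first search over an
# adjacency list keyed by (site, year, patch) strings; no igraph.
bfsComponents <- function(patches, links) {
  key <- paste(patches$site, patches$survey_year, patches$patch_id, sep = "|")
  adj <- setNames(vector("list", length(key)), key)
  if (nrow(links) > 0) {
    a <- paste(links$site, links$from_year, links$from_patch, sep = "|")
    b <- paste(links$site, links$to_year, links$to_patch, sep = "|")
    for (i in seq_along(a)) {
      adj[[a[i]]] <- c(adj[[a[i]]], b[i])
      adj[[b[i]]] <- c(adj[[b[i]]], a[i])
    }
  }
  comp <- setNames(rep(NA_integer_, length(key)), key)
  cid <- 0L
  for (k in key) {
    if (!is.na(comp[k])) next
    cid <- cid + 1L
    queue <- k
    while (length(queue) > 0) {
      cur <- queue[1]
      queue <- queue[-1]
      if (!is.na(comp[cur])) next
      comp[cur] <- cid
      queue <- c(queue, setdiff(adj[[cur]], names(comp)[!is.na(comp)]))
    }
  }
  unname(comp)
}

# Random patch/link tables: n patches spread over 3 surveys in one site,
# random links between consecutive surveys only.
randomSurveyTables <- function(n, seed, linkRate = 1.2) {
  set.seed(seed)
  yrs <- sort(sample(1:3, n, replace = TRUE))
  p <- makePatches(paste0("p", seq_len(n)), survey_year = yrs,
                   area_cm2 = runif(n, 1, 50))
  l <- emptyLinkTable()
  for (t in 1:2) {
    from <- which(yrs == t); to <- which(yrs == t + 1)
    if (length(from) == 0 || length(to) == 0) next
    m <- rbinom(1, round(linkRate * min(length(from), length(to))), 0.8)
    if (m == 0) next
    fromIdx <- from[sample.int(length(from), m, replace = TRUE)]
    toIdx <- to[sample.int(length(to), m, replace = TRUE)]
    l <- rbind(l, makeLinks(t, p$patch_id[fromIdx], t + 1, p$patch_id[toIdx]))
  }
  l <- unique(l)
  list(patches = p, links = l)
}

# partitions as canonical labels for comparison
canonicalPartition <- function(membership) {
  match(membership, unique(membership))
}
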