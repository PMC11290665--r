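#' Bootstrap test for population-scale acclimatization
#'
#' For each coral population (one taxon at one site), the per-genet change in
#' bleaching category between the two bleaching events (an integer in -4..4,
#' survivors of both events only) is resampled with replacement to build a
#' null distribution of the population's median change. The one-sided p value
#' is the proportion of resamples whose median is greater than or equal to 0
#' (inclusive); small p indicates the population's bleaching decreased, i.e.
#' acclimatization. Populations with fewer surviving genets than
#' `minSurvivors` are ineligible and return no p value.
#'
#' The median of an even-length resample is the mean of the two middle order
#' statistics. Internally each resample is drawn as a multinomial count
#' vector over the distinct observed delta values — distributionally
#' identical to drawing `n` values with replacement — and the median is read
#' off the cumulative counts, which keeps 100,000 resamples cheap.
#'
#' @param deltas integer vector of per-genet changes in -4..4.
#' @param nResamples number of bootstrap resamples (default 100,000).
#' @param seed integer seed for the resampling RNG stream.
#' @param minSurvivors minimum surviving genets for eligibility (default 10).
#' @param alpha significance threshold recorded in the result (default 0.05).
#' @return a list of class `"acclimTest"`: `n`, `n_resamples`, `seed`,
#'   `observed_median`, `p` (`NA` when ineligible), `eligible`, `alpha`.
#' @export
acclimTest <- function(deltas, nResamples = 1e5, seed = 1L,
                       minSurvivors = 10, alpha = 0.05) {
  if (length(deltas) > 0 && any(!(deltas %in% -4:4)))
    stop("deltas must be integers in -4..4")
  n <- length(deltas)
  out <- list(n = n, n_resamples = as.integer(nResamples),
              seed = as.integer(seed),
              observed_median = if (n > 0) median(deltas) else NA_real_,
              p = NA_real_, eligible = acclimEligible(n, minSurvivors),
              alpha = alpha)
  class(out) <- "acclimTest"
  if (!out$eligible) return(out)
  vals <- sort(unique(deltas))
  probs <- as.numeric(table(factor(deltas, levels = vals))) / n
  med <- withLocalSeed(seed, resampleMedians(vals, probs, n, nResamples))
  out$p <- mean(med >= 0)
  out
}

# medians of `nResamples` multinomial resamples of size n over `vals`
resampleMedians <- function(vals, probs, n, nResamples) {
  counts <- rmultinom(nResamples, n, probs)       # k x nResamples
  k <- length(vals)
  cum <- counts
  if (k > 1) for (i in 2:k) cum[i, ] <- cum[i, ] + cum[i - 1L, ]
  lo <- (n + 1L) %/% 2L                            # lower middle order stat
  hi <- n %/% 2L + 1L                              # upper middle order stat
  i1 <- k + 1L - .colSums(cum >= lo, k, nResamples)
  i2 <- k + 1L - .colSums(cum >= hi, k, nResamples)
  (vals[i1] + vals[i2]) / 2
}

#' @export
print.acclimTest <- function(x, ...) {
  cat("Bootstrap acclimatization test\n")
  cat(sprintf("  n = %d surviving genets; eligible: %s\n", x$n, x$eligible))
  if (x$eligible)
    cat(sprintf("  observed median delta = %g; p = %.5g (%d resamples, seed %d)\n",
                x$observed_median, x$p, x$n_resamples, x$seed))
  invisible(x)
}

#' Exact resampling p value by enumeration
#'
#' Independent oracle for [acclimTest()]: the exact probability, over all
#' n^n equally likely with-replacement resamples, that the resample median is
#' >= 0. Enumerates count compositions over the distinct values with
#' multinomial weights, so it refuses n > 8.
#'
#' @param deltas integer vector, length <= 8.
#' @return exact probability in \[0, 1\].
#' @export
enumerateExactP <- function(deltas) {
  n <- length(deltas)
  if (n == 0) stop("empty delta vector")
  if (n > 8) stop("exact enumeration limited to n <= 8")
  vals <- sort(unique(deltas))
  probs <- as.numeric(table(factor(deltas, levels = vals))) / n
  k <- length(vals)
  lo <- (n + 1L) %/% 2L
  hi <- n %/% 2L + 1L
  total <- 0
  recurse <- function(i, left, counts) {
    if (i == k) {
      counts[k] <- left
      cum <- cumsum(counts)
      m <- (vals[which(cum >= lo)[1]] + vals[which(cum >= hi)[1]]) / 2
      if (m >= 0) {
        lp <- lgamma(n + 1) - sum(lgamma(counts + 1)) +
          sum(counts[probs > 0] * log(probs[probs > 0]))
        if (any(counts > 0 & probs == 0)) lp <- -Inf
        total <<- total + exp(lp)
      }
      return(invisible())
    }
    for (c_i in 0:left) {
      counts[i] <- c_i
      recurse(i + 1L, left - c_i, counts)
    }
  }
  recurse(1L, n, integer(k))
  min(1, total)
}

#' @rdname acclimTest
#' @param n number of surviving genets.
#' @return `acclimEligible()` returns `TRUE` when `n >= minSurvivors`.
#' @export
acclimEligible <- function(n, minSurvivors = 10) {
  stopifnot(n >= 0)
  n >= minSurvivors
}

#' Per-population acclimatization tests
#'
#' Runs [acclimTest()] for every (site, taxon) population in a classified
#' genet table. Each population gets its own RNG substream derived from the
#' master seed and a stable hash of (site, taxon), so results do not depend
#' on execution order.
#'
#' @param responses data.frame with columns `site`, `taxon`, `delta`
#'   (survivors of both events only, e.g. from [classifyGenets()]).
#' @param nResamples,minSurvivors,alpha see [acclimTest()].
#' @param seed master integer seed.
#' @return data.frame with one row per population: `site`, `taxon`, `n`,
#'   `eligible`, `observed_median`, `p`, `n_resamples`, `seed`.
#' @export
acclimTestAll <- function(responses, nResamples = 1e5, seed = 1L,
                          minSurvivors = 10, alpha = 0.05) {
  stopifnot(all(c("site", "taxon", "delta") %in% names(responses)))
  bySiteTaxon <- split(responses$delta,
                       list(site = responses$site, taxon = responses$taxon),
                       drop = TRUE, sep = "\r")
  keys <- do.call(rbind, strsplit(names(bySiteTaxon), "\r", fixed = TRUE))
  ord <- order(keys[, 1], keys[, 2])
  rows <- lapply(ord, function(i) {
    r <- acclimTest(bySiteTaxon[[i]], nResamples = nResamples,
                    seed = substreamSeed(seed, keys[i, 1], keys[i, 2]),
                    minSurvivors = minSurvivors, alpha = alpha)
    data.frame(site = keys[i, 1], taxon = keys[i, 2], n = r$n,
               eligible = r$eligible, observed_median = r$observed_median,
               p = r$p, n_resamples = r$n_resamples, seed = r$seed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
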