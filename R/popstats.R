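#' Contingency table of bleaching responses by group
#'
#' Cross-tabulates surviving, classified genets by a grouping variable (site
#' or taxon) against the four bleaching response classes. Groups without any
#' surviving genet are dropped with a warning.
#'
#' @param responses data.frame from [classifyGenets()] (survivors only).
#' @param groupBy name of the grouping column, `"site"` or `"taxon"`.
#' @return integer matrix, groups x response classes (column order:
#'   thermally_tolerant, decreased, increased, high_susceptibility).
#' @export
buildResponseTable <- function(responses, groupBy = c("site", "taxon")) {
  groupBy <- match.arg(groupBy)
  if (nrow(responses) == 0) stop("no classified genets to tabulate")
  tab <- table(responses[[groupBy]],
               factor(responses$response, levels = responseLevels()))
  empty <- rowSums(tab) == 0
  if (any(empty)) {
    warning("dropping group(s) with zero survivors: ",
            paste(rownames(tab)[empty], collapse = ", "))
    tab <- tab[!empty, , drop = FALSE]
  }
  m <- matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  m
}

#' Fisher's exact test with an explicit exact / Monte Carlo switch
#'
#' For 2 x 2 tables the two-sided p value is the exact sum of hypergeometric
#' probabilities of all tables (at the observed margins) no more probable
#' than the observed one. For larger tables an exact network computation is
#' used when the space of tables with the observed margins is small (an upper
#' bound of 1e6 candidate tables, estimated from column-margin compositions);
#' otherwise the p value is estimated by seeded Monte Carlo with `B` draws
#' and flagged.
#'
#' @param tab non-negative integer matrix.
#' @param B Monte Carlo draws when the exact computation is infeasible.
#' @param seed integer seed for the Monte Carlo path.
#' @param maxTables threshold on the estimated table-space size.
#' @return list with `p`, `monte_carlo` (logical), `B` (NA unless Monte
#'   Carlo).
#' @export
fisherExact <- function(tab, B = 1e5, seed = 1L, maxTables = 1e6) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  # degenerate shapes: a single row or column admits no association
  if (nrow(tab) < 2 || ncol(tab) < 2)
    return(list(p = 1, monte_carlo = FALSE, B = NA_integer_))
  # drop all-zero rows/columns, which carry no information
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    return(list(p = 1, monte_carlo = FALSE, B = NA_integer_))
  r <- nrow(tab)
  # upper bound on the number of tables with these margins: compositions of
  # each column total into r cells
  logTables <- sum(lchoose(colSums(tab) + r - 1, r - 1))
  if (logTables <= log(maxTables)) {
    p <- fisher.test(tab)$p.value
    list(p = min(1, p), monte_carlo = FALSE, B = NA_integer_)
  } else {
    p <- withLocalSeed(seed,
                       fisher.test(tab, simulate.p.value = TRUE, B = B)$p.value)
    list(p = min(1, p), monte_carlo = TRUE, B = as.integer(B))
  }
}

#' Bonferroni adjustment with an explicit family size
#'
#' @param p raw p values.
#' @param m family size (default: number of p values supplied).
#' @return adjusted p values, `pmin(1, m * p)`.
#' @export
bonferroniAdjust <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1), m >= 1)
  pmin(1, m * p)
}

#' Pairwise Fisher's exact tests across groups with Bonferroni correction
#'
#' Compares every pair of rows of a response contingency table by Fisher's
#' exact test; the Bonferroni family is all `choose(k, 2)` pairs.
#'
#' @param tab groups x classes count matrix, e.g. [buildResponseTable()].
#' @param alpha significance level for the `significant` flag.
#' @param ... passed to [fisherExact()].
#' @return data.frame with `group1`, `group2`, `p_raw`, `p_adj`,
#'   `significant`, `monte_carlo`.
#' @export
pairwiseFisher <- function(tab, alpha = 0.05, ...) {
  groups <- rownames(tab)
  if (length(groups) < 2) stop("need at least two groups")
  pairs <- combn(groups, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(i) {
    f <- fisherExact(tab[pairs[, i], , drop = FALSE], ...)
    data.frame(group1 = pairs[1, i], group2 = pairs[2, i], p_raw = f$p,
               monte_carlo = f$monte_carlo, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bonferroniAdjust(out$p_raw, m)
  out$significant <- out$p_adj < alpha
  out[, c("group1", "group2", "p_raw", "p_adj", "significant", "monte_carlo")]
}

#' Compact letter display from pairwise significance
#'
#' Assigns each group a non-empty string of letters so that two groups share
#' at least one letter if and only if their pairwise comparison is
#' non-significant (the defining invariant of a compact letter display).
#' Implemented by insert-and-absorb: letters start as one column containing
#' all groups; each significant pair found sharing a letter splits that
#' column in two (one without each member), then redundant columns absorbed
#' into supersets are removed. Minimal letter count is not guaranteed.
#'
#' @param groups character vector of group names.
#' @param significant either a data.frame with columns `group1`, `group2`,
#'   `significant` (e.g. [pairwiseFisher()] output) or a logical symmetric
#'   matrix with group dimnames.
#' @return named character vector, group -> letters.
#' @export
compactLetters <- function(groups, significant) {
  k <- length(groups)
  sig <- matrix(FALSE, k, k, dimnames = list(groups, groups))
  if (is.data.frame(significant)) {
    for (i in seq_len(nrow(significant))) {
      g1 <- significant$group1[i]; g2 <- significant$group2[i]
      sig[g1, g2] <- sig[g2, g1] <- isTRUE(significant$significant[i])
    }
  } else {
    sig[rownames(significant), colnames(significant)] <-
      as.logical(significant)
  }
  # columns of a logical membership matrix; start with one all-TRUE column
  cols <- list(setNames(rep(TRUE, k), groups))
  if (k > 1) for (i in 1:(k - 1)) for (j in (i + 1):k) {
    if (!sig[i, j]) next
    shared <- which(vapply(cols, function(cl) cl[i] && cl[j], logical(1)))
    for (s in shared) {
      a <- cols[[s]]; a[i] <- FALSE
      b <- cols[[s]]; b[j] <- FALSE
      cols[[s]] <- a
      cols[[length(cols) + 1]] <- b
    }
    # absorb: drop any column whose members are a subset of another's
    drop <- rep(FALSE, length(cols))
    for (s in seq_along(cols)) for (t in seq_along(cols)) {
      if (s != t && !drop[t] && all(cols[[s]] <= cols[[t]]) &&
          !identical(cols[[s]], cols[[t]])) drop[s] <- TRUE
    }
    # identical duplicates: keep the first
    keys <- vapply(cols, function(cl) paste(as.integer(cl), collapse = ""),
                   character(1))
    drop <- drop | duplicated(keys)
    cols <- cols[!drop]
  }
  letters_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- vapply(seq_len(k), function(i) {
    paste(letters_pool[which(vapply(cols, function(cl) cl[i], logical(1)))],
          collapse = "")
  }, character(1))
  setNames(out, groups)
}
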