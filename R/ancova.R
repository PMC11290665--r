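#' ANCOVA of genet growth on a fixed factor
#'
#' Ordinary least squares of natural-log final planar area on natural-log
#' initial planar area (the covariate) and a fixed factor (bleaching response
#' class or site), optionally with a covariate x factor interaction. Factor
#' levels with fewer than `minGroup` observations are dropped before fitting.
#' Per-term F statistics and p values come from sequential (Type I) sums of
#' squares with the covariate entered first, so the factor is tested after
#' adjusting for initial size.
#'
#' @param finalArea,initialArea planar areas (cm^2), strictly positive; they
#'   are natural-log transformed internally.
#' @param group factor (bleaching response or site).
#' @param includeInteraction add the covariate x factor interaction term.
#' @param minGroup minimum group size retained (default 10).
#' @return list of class `"growthAncova"`: `fit` (the `lm`), `anova` (Type I
#'   table), `terms` data.frame (`term`, `df`, `F`, `p`), `slope` (common
#'   covariate slope), `residuals`, `groups` (retained labels per
#'   observation), `dropped_levels`.
#' @export
growthAncova <- function(finalArea, initialArea, group,
                         includeInteraction = FALSE, minGroup = 10) {
  stopifnot(all(finalArea > 0), all(initialArea > 0),
            length(finalArea) == length(initialArea),
            length(group) == length(finalArea))
  group <- factor(group)
  sizes <- table(group)
  keepLevels <- names(sizes)[sizes >= minGroup]
  dropped <- setdiff(levels(group), keepLevels)
  keep <- group %in% keepLevels
  if (sum(keep) == 0 || length(keepLevels) < 1)
    stop("no factor level reaches the minimum group size")
  d <- data.frame(y = log(finalArea[keep]), x = log(initialArea[keep]),
                  g = droplevels(group[keep]))
  if (any(table(d$g) < 2))
    stop("retained factor level with fewer than 2 observations")
  form <- if (includeInteraction && nlevels(d$g) > 1) y ~ x * g
          else if (nlevels(d$g) > 1) y ~ x + g else y ~ x
  fit <- lm(form, data = d)
  an <- anova(fit)                    # sequential (Type I), covariate first
  termNames <- rownames(an)
  terms <- data.frame(term = termNames, df = an$Df, F = an$`F value`,
                      p = an$`Pr(>F)`, stringsAsFactors = FALSE)
  terms <- terms[terms$term != "Residuals", ]
  structure(list(fit = fit, anova = an, terms = terms,
                 slope = unname(coef(fit)["x"]),
                 residuals = unname(fit$residuals), groups = d$g,
                 dropped_levels = dropped),
            class = "growthAncova")
}

#' @export
print.growthAncova <- function(x, ...) {
  cat("Growth ANCOVA (ln final area ~ ln initial area + factor)\n")
  cat(sprintf("  common slope = %.4f; n = %d\n", x$slope, length(x$residuals)))
  print(x$terms, row.names = FALSE)
  if (length(x$dropped_levels) > 0)
    cat("  dropped levels (< min group size):",
        paste(x$dropped_levels, collapse = ", "), "\n")
  invisible(x)
}

#' Cochran's C statistic for homogeneity of variance
#'
#' `C = max(s_i^2) / sum(s_i^2)` over groups. Under equal variances and equal
#' group sizes, `P(C > c)` is approximated by the classical Bonferroni bound
#' `min(1, k * P(F > (k - 1) c / (1 - c)))` with `F` on `(nu, (k - 1) nu)`
#' degrees of freedom; for unbalanced groups `nu` is the average group
#' degrees of freedom.
#'
#' @param x numeric vector of observations (e.g. model residuals).
#' @param groups group labels, at least two groups.
#' @return list with `C`, `k`, `nu`, `p`.
#' @export
cochranC <- function(x, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  k <- nlevels(groups)
  if (k < 2) stop("Cochran's C requires at least two groups")
  v <- tapply(x, groups, var)
  if (any(is.na(v))) stop("every group needs at least two observations")
  nu <- mean(tapply(x, groups, length)) - 1
  if (sum(v) == 0)   # every group constant: the statistic is undefined
    return(list(C = NA_real_, k = k, nu = unname(nu), p = NA_real_))
  C <- max(v) / sum(v)
  fstat <- (k - 1) * C / (1 - C)
  p <- if (C >= 1) 0 else min(1, k * pf(fstat, nu, (k - 1) * nu, lower.tail = FALSE))
  list(C = unname(C), k = k, nu = unname(nu), p = unname(p))
}

#' Residual diagnostics: Shapiro-Wilk normality and Cochran variance test
#'
#' @param residuals model residuals (>= 3 values for the normality test).
#' @param groups group labels for the variance-homogeneity test; `NULL` skips
#'   it.
#' @return list with `shapiro_p` (`NA`, flagged, when residuals are
#'   constant), `constant_residuals`, and `cochran` (list from [cochranC()]
#'   or `NULL`).
#' @export
growthDiagnostics <- function(residuals, groups = NULL) {
  if (length(residuals) < 3) stop("need at least 3 residuals")
  constant <- sd(residuals) == 0
  shapiro_p <- if (constant) NA_real_ else
    shapiro.test(residuals[seq_len(min(length(residuals), 5000))])$p.value
  cochran <- if (!is.null(groups) && nlevels(droplevels(factor(groups))) >= 2)
    cochranC(residuals, groups) else NULL
  list(shapiro_p = shapiro_p, constant_residuals = constant, cochran = cochran)
}
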