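#' Logistic regression by iteratively reweighted least squares
#'
#' Fits a binomial GLM with logit link by IRLS. Convergence is declared when
#' the largest absolute coefficient change falls below `tol` (default 1e-8),
#' with a cap of `maxIter` iterations. Quasi-complete separation is flagged
#' when any coefficient exceeds 15 in absolute value while the likelihood is
#' still improving; Wald p values are suppressed in that case because the
#' estimates diverge.
#'
#' @param y binary response (0/1).
#' @param X design matrix including an intercept column.
#' @param tol convergence tolerance on the max absolute coefficient change.
#' @param maxIter iteration cap.
#' @return list of class `"logisticFit"`: `coefficients`, `se`, `z`, `p`
#'   (Wald, `NA` under separation), `vcov`, `logLik`, `deviance`,
#'   `deviance_trace` (per-iteration, monotone non-increasing), `converged`,
#'   `separation`, `iterations`, `n`.
#' @export
logisticFit <- function(y, X, tol = 1e-8, maxIter = 100) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dependent <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dependent, collapse = ", "))
  }
  beta <- rep(0, ncol(X))
  devianceOf <- function(eta) {
    mu <- plogis(pmin(pmax(eta, -30), 30))   # clamp so log() stays finite
    -2 * sum(y * log(mu) + (1 - y) * log1p(-mu))
  }
  eta <- drop(X %*% beta)
  devTrace <- devianceOf(eta)
  converged <- FALSE
  iter <- 0
  while (iter < maxIter) {
    iter <- iter + 1
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    fit <- lm.wfit(X, z, w)
    newBeta <- fit$coefficients
    step <- max(abs(newBeta - beta))
    # step-halve if the deviance would increase (guards the IRLS invariant)
    newEta <- drop(X %*% newBeta)
    newDev <- devianceOf(newEta)
    halvings <- 0
    while (newDev > devTrace[length(devTrace)] + 1e-10 && halvings < 20) {
      newBeta <- (newBeta + beta) / 2
      newEta <- drop(X %*% newBeta)
      newDev <- devianceOf(newEta)
      halvings <- halvings + 1
    }
    beta <- newBeta
    eta <- newEta
    devTrace <- c(devTrace, newDev)
    if (step < tol) { converged <- TRUE; break }
  }
  nd <- length(devTrace)
  improving <- nd >= 2 && (devTrace[nd - 1] - devTrace[nd]) > 1e-10
  separation <- any(abs(beta) > 15) && (improving || !converged)
  mu <- plogis(eta)
  w <- mu * (1 - mu)
  XtWX <- crossprod(X * sqrt(w))
  V <- tryCatch(solve(XtWX), error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  se <- sqrt(diag(V))
  zstat <- beta / se
  pv <- 2 * pnorm(-abs(zstat))
  if (separation) { zstat[] <- NA_real_; pv[] <- NA_real_ }
  nm <- colnames(X)
  structure(list(coefficients = setNames(beta, nm), se = setNames(se, nm),
                 z = setNames(zstat, nm), p = setNames(pv, nm),
                 vcov = V, logLik = -devTrace[nd] / 2,
                 deviance = devTrace[nd], deviance_trace = devTrace,
                 converged = converged, separation = separation,
                 iterations = iter, n = length(y)),
            class = "logisticFit")
}

#' @export
print.logisticFit <- function(x, ...) {
  cat(sprintf("Logistic fit (IRLS): n = %d, deviance = %.4f, %s%s\n",
              x$n, x$deviance,
              if (x$converged) "converged" else "NOT converged",
              if (x$separation) ", SEPARATION detected" else ""))
  print(data.frame(estimate = x$coefficients, se = x$se, z = x$z, p = x$p))
  invisible(x)
}

#' Size-dependent bleaching model
#'
#' Logistic regression of the binary bleaching indicator (category >= 3)
#' against colony size at one bleaching event, observations pooled across
#' sites. Size enters as the natural log of planar area by default.
#'
#' @param bleached 0/1 vector from [binarizeBleaching()].
#' @param area planar area (cm^2) at the event year.
#' @param logArea if `TRUE` (default) the covariate is `log(area)`.
#' @return a `"logisticFit"`.
#' @export
bleachingSizeModel <- function(bleached, area, logArea = TRUE) {
  stopifnot(all(area > 0))
  x <- if (logArea) log(area) else area
  X <- cbind(`(Intercept)` = 1, size = x)
  logisticFit(bleached, X)
}

#' Size- and site-dependent survivorship model
#'
#' Logistic regression of survivorship (survived from the first to the last
#' survey) on log initial planar area, site main effects, and site x size
#' interactions, fitted to all traced genets of one taxon.
#'
#' @param survived 0/1 vector.
#' @param area initial planar area (cm^2).
#' @param site factor or character vector of site labels.
#' @param interaction include site x log(area) interactions (default `TRUE`).
#' @param logArea if `TRUE` (default) the covariate is `log(area)`.
#' @return a `"logisticFit"` carrying attributes `sites` (levels) and term
#'   index vectors used by [pairwiseSiteContrasts()].
#' @export
survivorshipModel <- function(survived, area, site, interaction = TRUE,
                              logArea = TRUE) {
  stopifnot(all(area > 0))
  site <- factor(site)
  x <- if (logArea) log(area) else area
  df <- data.frame(x = x, site = site)
  form <- if (interaction && nlevels(site) > 1) ~ x * site
          else if (nlevels(site) > 1) ~ x + site else ~ x
  X <- model.matrix(form, df)
  fit <- logisticFit(survived, X)
  attr(fit, "sites") <- levels(site)
  attr(fit, "main_terms") <- grep("^site", colnames(X)[!grepl(":", colnames(X))],
                                  value = TRUE)
  attr(fit, "interaction_terms") <- grep(":", colnames(X), value = TRUE)
  fit
}

#' Pairwise site contrasts from a survivorship model
#'
#' Sites whose size x site interaction term is significant at `alpha` are
#' excluded (their survivorship-size slopes differ, so a single main-effect
#' contrast is not interpretable); remaining site pairs are compared by Wald
#' tests on the difference of their main-effect coefficients, with Bonferroni
#' adjustment over the pairs actually tested.
#'
#' @param fit a `"logisticFit"` from [survivorshipModel()] with interactions.
#' @param alpha significance level for both the interaction screen and the
#'   `significant` flag.
#' @return data.frame with `group1`, `group2`, `estimate`, `se`, `p_raw`,
#'   `p_adj`, `significant`; zero rows (with a warning) when fewer than two
#'   sites are eligible.
#' @export
pairwiseSiteContrasts <- function(fit, alpha = 0.05) {
  sites <- attr(fit, "sites")
  if (is.null(sites)) stop("fit does not carry site information")
  inter <- attr(fit, "interaction_terms")
  excluded <- character(0)
  for (term in inter) {
    if (!is.na(fit$p[term]) && fit$p[term] < alpha)
      excluded <- c(excluded, sub("^x:site", "", term))
  }
  eligible <- setdiff(sites, unique(excluded))
  if (length(eligible) < 2) {
    warning("fewer than two sites without significant size interactions")
    return(data.frame(group1 = character(0), group2 = character(0),
                      estimate = numeric(0), se = numeric(0),
                      p_raw = numeric(0), p_adj = numeric(0),
                      significant = logical(0)))
  }
  coefName <- function(s) paste0("site", s)
  beta <- fit$coefficients
  V <- fit$vcov
  getCoef <- function(s) if (s == sites[1]) 0 else beta[coefName(s)]
  getVar <- function(s1, s2) {
    # reference level has coefficient fixed at 0 with no uncertainty terms
    n1 <- coefName(s1); n2 <- coefName(s2)
    v <- 0
    if (s1 != sites[1]) v <- v + V[n1, n1]
    if (s2 != sites[1]) v <- v + V[n2, n2]
    if (s1 != sites[1] && s2 != sites[1]) v <- v - 2 * V[n1, n2]
    v
  }
  pairs <- combn(eligible, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    s1 <- pairs[1, i]; s2 <- pairs[2, i]
    est <- getCoef(s2) - getCoef(s1)
    se <- sqrt(getVar(s1, s2))
    p <- 2 * pnorm(-abs(est / se))
    data.frame(group1 = s1, group2 = s2, estimate = unname(est),
               se = se, p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bonferroniAdjust(out$p_raw, nrow(out))
  out$significant <- out$p_adj < alpha
  out
}
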