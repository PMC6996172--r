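# Linear generalized estimating equations (identity link, exchangeable
# working correlation, cluster-robust sandwich covariance), for
# fellow-eye data clustered within subject. With one observation per
# cluster (or rho = 0) the estimator reduces to ordinary least squares.

#' Fit a linear GEE with exchangeable working correlation
#'
#' Marginal linear model estimated by generalized estimating equations:
#' identity link, exchangeable working correlation across observations
#' sharing a cluster id, and robust (sandwich) standard errors. The
#' working correlation and dispersion are estimated by moments from the
#' Pearson residuals and the mean model re-solved until convergence.
#'
#' @param data A data frame.
#' @param formula Model formula for the marginal mean.
#' @param id Name of the cluster (subject) column.
#' @param corstr Working correlation: `"exchangeable"` (default) or
#'   `"independence"` (rho fixed at 0; point estimates equal OLS).
#' @param maxit,tol Iteration control.
#' @return An object of class `gee_lm` with elements `coefficients`,
#'   `vcov_robust`, `vcov_naive`, `rho`, `phi`, `n`, `n_clusters`,
#'   `converged`. Supports [tidy()] and [glance()].
#' @export
#' @examples
#' coh <- generate_cohort(100, seed = 2)
#' fit <- gee_lm(coh, fd ~ age_y + dr_severity, id = "subject_id")
#' tidy(fit)
gee_lm <- function(data, formula, id = "subject_id",
                   corstr = c("exchangeable", "independence"),
                   maxit = 50, tol = 1e-10) {
  corstr <- match.arg(corstr)
  stopifnot(is.data.frame(data))
  if (!id %in% names(data)) abort(paste0("cluster column `", id, "` not found"))
  vars <- all.vars(formula)
  keep <- complete.cases(data[, c(vars, id)])
  d <- data[keep, , drop = FALSE]
  mf <- stats::model.frame(formula, data = d)
  y <- stats::model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    abort(paste0("collinear design; aliased terms: ",
                 paste(aliased, collapse = ", ")),
          class = "deepangio_collinear")
  }
  cl <- factor(d[[id]])
  if (nlevels(cl) < 2) abort("need at least 2 clusters")
  N <- length(y)
  m <- as.vector(table(cl))[as.integer(cl)]   # own-cluster size per row

  beta <- qr.coef(qrX, y)
  rho <- 0
  phi <- 1
  converged <- FALSE
  for (it in seq_len(maxit)) {
    e <- as.vector(y - X %*% beta)
    phi <- sum(e^2) / (N - p)
    esum <- rowsum(e, cl)
    e2sum <- rowsum(e^2, cl)
    sizes <- as.vector(table(cl))
    npairs <- sum(sizes * (sizes - 1) / 2)
    rho <- if (corstr == "exchangeable" && npairs > 0) {
      clamp(sum((esum^2 - e2sum) / 2) / (phi * npairs), -0.9, 0.95)
    } else 0
    g_cl <- rho / (1 + (sizes - 1) * rho)    # per cluster
    S <- rowsum(X, cl)
    scale <- phi * (1 - rho)
    XtWX <- (crossprod(X) - crossprod(S, g_cl * S)) / scale
    XtWy <- (crossprod(X, y) - crossprod(S, g_cl * esum) -
               crossprod(S, g_cl * (S %*% beta))) / scale
    # note: rowsum(y) = S beta + esum, so X'W y uses S %*% beta + esum
    beta_new <- solve(XtWX, XtWy)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  e <- as.vector(y - X %*% beta)
  esum <- rowsum(e, cl)
  sizes <- as.vector(table(cl))
  g_cl <- rho / (1 + (sizes - 1) * rho)
  S <- rowsum(X, cl)
  scale <- phi * (1 - rho)
  A <- (crossprod(X) - crossprod(S, g_cl * S)) / scale
  U <- (rowsum(X * e, cl) - as.vector(g_cl * esum) * S) / scale
  Ainv <- solve(A)
  vr <- Ainv %*% crossprod(U) %*% Ainv
  structure(
    list(
      coefficients = setNames(as.vector(beta), colnames(X)),
      vcov_robust = vr, vcov_naive = Ainv,
      rho = rho, phi = phi, n = N, n_clusters = nlevels(cl),
      corstr = corstr, converged = converged, formula = formula
    ),
    class = "gee_lm"
  )
}

#' @export
print.gee_lm <- function(x, ...) {
  cat("<gee_lm> linear GEE, exchangeable working correlation\n")
  cat(sprintf("  n = %d observations in %d clusters; rho = %.3f, phi = %.3f\n",
              x$n, x$n_clusters, x$rho, x$phi))
  print(x$coefficients)
  invisible(x)
}

#' @rdname gee_lm
#' @param x A `gee_lm` object.
#' @param conf.level Confidence level for Wald intervals.
#' @param robust Use sandwich (default) or model-based standard errors.
#' @param ... Unused.
#' @export
tidy.gee_lm <- function(x, conf.level = 0.95, robust = TRUE, ...) {
  V <- if (robust) x$vcov_robust else x$vcov_naive
  se <- sqrt(diag(V))
  est <- x$coefficients
  z <- est / se
  q <- qnorm(1 - (1 - conf.level) / 2)
  tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    statistic = unname(z), p.value = unname(2 * pnorm(-abs(z))),
    conf.low = unname(est - q * se), conf.high = unname(est + q * se)
  )
}

#' @rdname gee_lm
#' @export
glance.gee_lm <- function(x, ...) {
  tibble(
    n = x$n, n_clusters = x$n_clusters, rho = x$rho, phi = x$phi,
    converged = x$converged
  )
}

pretty_term <- function(term) {
  term <- sub("^dr_severity", "dr_", term)
  term <- sub("^dmeTRUE$", "dme", term)
  term <- sub("^dme$", "dme", term)
  term
}

#' Fit one outcome model on a cohort
#'
#' Convenience wrapper around [gee_lm()] for cohort tables: DR severity
#' enters as three dummies versus the "none" reference, DME as a 0/1
#' indicator, and every other predictor as given (standardize
#' continuous predictors first with [standardize_cohort()]). Returns a
#' per-predictor association table.
#'
#' @param cohort A cohort tibble ([generate_cohort()] schema).
#' @param outcome Outcome column name (`"faz_area_mm2"`, `"vd_pct"`,
#'   `"fd"`).
#' @param predictors Character vector of predictor columns;
#'   `"dr_severity"` expands to its dummies.
#' @param id Cluster column (default `"subject_id"`).
#' @param conf_level Wald confidence level.
#' @return A tibble with columns `outcome`, `predictor`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `p` (intercept omitted).
#' @export
fit_gee <- function(cohort, outcome, predictors, id = "subject_id",
                    conf_level = 0.95) {
  stopifnot(is.data.frame(cohort), length(predictors) >= 1)
  f <- as.formula(paste(outcome, "~", paste(predictors, collapse = " + ")))
  fit <- gee_lm(cohort, f, id = id)
  td <- tidy(fit, conf.level = conf_level)
  td <- td[td$term != "(Intercept)", , drop = FALSE]
  tibble(
    outcome = outcome,
    predictor = pretty_term(td$term),
    beta = td$estimate, se = td$std.error,
    ci_low = td$conf.low, ci_high = td$conf.high, p = td$p.value
  )
}
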