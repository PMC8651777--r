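#' Design matrix for the effect-heterogeneity regression
#'
#' Builds the main-effects + all-two-factor-interactions design from the
#' state covariate table: emissions-source proportions (fire, stationary,
#' mobile), log population density and Census region (dummy-coded, first
#' level as reference). Continuous predictors are centered before the
#' interactions are formed, which decorrelates main effects from
#' interactions. A single-level region factor is dropped (with a warning)
#' together with its interactions; rank-deficient columns are dropped with a
#' reported list.
#'
#' @param covariates Data frame with `state`, `prop_fire`,
#'   `prop_stationary`, `prop_mobile`, `population_density`, `region`.
#' @param log_density Log-transform population density (right-skewed across
#'   states).
#' @param center Center the continuous predictors.
#' @param interactions Include the two-factor interactions (`FALSE` gives
#'   the main-effects-only sensitivity design).
#' @return List with `X` (model matrix, full column rank), `formula`,
#'   `data` (transformed predictor frame), `dropped` (character vector of
#'   removed columns).
#' @export
build_design <- function(covariates, log_density = TRUE, center = TRUE,
                         interactions = TRUE) {
  need <- c("state", "prop_fire", "prop_stationary", "prop_mobile",
            "population_density", "region")
  if (!all(need %in% names(covariates)))
    stop("covariate table is missing columns: ",
         paste(setdiff(need, names(covariates)), collapse = ", "))
  props <- as.matrix(covariates[, c("prop_fire", "prop_stationary", "prop_mobile")])
  if (any(props < 0 | props > 1)) stop("source proportions must lie in [0, 1]")
  if (any(rowSums(props) > 1 + 1e-8))
    stop("fire + stationary + mobile proportions exceed 1")
  d <- data.frame(prop_fire = covariates$prop_fire,
                  prop_stationary = covariates$prop_stationary,
                  prop_mobile = covariates$prop_mobile,
                  log_density = if (log_density)
                    log(covariates$population_density)
                  else covariates$population_density,
                  region = factor(covariates$region))
  cont <- c("prop_fire", "prop_stationary", "prop_mobile", "log_density")
  if (center) for (v in cont) d[[v]] <- d[[v]] - mean(d[[v]])

  use_region <- nlevels(d$region) >= 2
  if (!use_region)
    warning("region has a single level; dropping region and its interactions")
  base_terms <- if (use_region)
    "(prop_fire + prop_stationary + prop_mobile + log_density + region)"
  else "(prop_fire + prop_stationary + prop_mobile + log_density)"
  terms_str <- if (interactions) paste0(base_terms, "^2") else base_terms
  f <- as.formula(paste("~", terms_str))
  X <- model.matrix(f, data = d)
  if (nrow(X) <= ncol(X))
    stop(sprintf(paste("more parameters (%d) than states (%d):",
                       "prune interaction terms"), ncol(X), nrow(X)))
  qrX <- qr(X)
  dropped <- character(0)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[-keep]
    message("dropping rank-deficient design columns: ",
            paste(dropped, collapse = ", "))
    X <- X[, sort(keep), drop = FALSE]
  }
  list(X = X, formula = f, data = d, dropped = dropped)
}

#' Weighted multivariable linear regression of intervention effects
#'
#' Weighted least-squares fit of per-state effects on the
#' [build_design()] matrix. The motivating weights are the inverse
#' bootstrap variances of the per-state effect estimates (heteroscedastic
#' outcomes); equal weights reproduce ordinary least squares and serve as
#' the sensitivity run. Estimates are invariant to rescaling all weights by
#' a positive constant.
#'
#' @param covariates State covariate table (see [build_design()]), or a
#'   prebuilt design list from [build_design()].
#' @param delta Per-state effect estimates (outcome).
#' @param weights Positive weights, one per state; `NULL` for equal weights.
#' @param ... Passed to [build_design()] when `covariates` is a table.
#' @return `wmlr_fit`: list with `coefficients` (data frame term, estimate,
#'   se, t, p), `r2`, `adj_r2`, `n`, `rank`, `weights`, `residuals`,
#'   `dropped`.
#' @export
fit_wmlr <- function(covariates, delta, weights = NULL, ...) {
  design <- if (is.list(covariates) && !is.null(covariates$X)) covariates
  else build_design(covariates, ...)
  X <- design$X
  n <- nrow(X)
  if (length(delta) != n) stop("outcome length does not match design rows")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be positive and one per state")
  if (n <= ncol(X)) stop("need more states than parameters")

  fit <- stats::lm.wfit(X, delta, w = weights)
  p <- fit$rank
  df <- n - p
  rss <- sum(weights * fit$residuals^2)
  sigma2 <- rss / df
  XtWX_inv <- chol2inv(chol(crossprod(X * sqrt(weights))))
  se <- sqrt(diag(XtWX_inv) * sigma2)
  est <- fit$coefficients
  tval <- est / se
  pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  # weighted R^2 about the weighted mean (summary.lm convention)
  ybar <- sum(weights * delta) / sum(weights)
  tss <- sum(weights * (delta - ybar)^2)
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / df
  structure(list(coefficients = data.frame(term = colnames(X), estimate = est,
                                           se = se, t = tval, p = pval,
                                           row.names = NULL),
                 r2 = r2, adj_r2 = adj_r2, n = n, rank = p,
                 weights = weights, residuals = fit$residuals,
                 dropped = design$dropped),
            class = "wmlr_fit")
}

#' @export
print.wmlr_fit <- function(x, ...) {
  cat(sprintf("<wmlr_fit> n = %d states, %d terms, R2 = %.3f (adj %.3f)\n",
              x$n, x$rank, x$r2, x$adj_r2))
  sig <- x$coefficients[x$coefficients$p < 0.05, ]
  if (nrow(sig)) {
    cat("terms with p < 0.05:\n")
    print(sig, digits = 3)
  }
  invisible(x)
}
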