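#' Random-intercept linear mixed model by REML
#'
#' Fits \deqn{y_{ij} = x_{ij}'\beta + u_j + e_{ij}, \quad
#'   u_j \sim N(0, \sigma_u^2), \; e_{ij} \sim N(0, \sigma_e^2)}
#' with one random intercept per group (here: per iTRAQ experiment), by
#' restricted maximum likelihood. The REML criterion is profiled over the
#' variance ratio \eqn{\lambda = \sigma_u^2/\sigma_e^2}: for fixed
#' \eqn{\lambda} the generalized-least-squares fixed effects, the profiled
#' residual variance and the restricted log-likelihood are available in
#' closed form through per-group sums, and a bounded one-dimensional
#' optimizer maximizes over \eqn{\log\lambda}. \eqn{\sigma_u^2} is
#' constrained non-negative; a boundary estimate of 0 (and the single-group
#' case) reduces the fit exactly to ordinary least squares.
#'
#' Inference on fixed effects uses Wald z statistics with a standard-normal
#' reference; fitted values include the BLUP random intercepts.
#'
#' @param formula model formula for the fixed effects, e.g. `y ~ x`.
#' @param data data.frame in which `formula` and `group` are evaluated.
#' @param group grouping factor: a one-sided formula (e.g. `~ experiment`),
#'   a column name, or a vector of length `nrow(data)`.
#' @param tol convergence tolerance on the profiled criterion optimizer.
#' @return An object of class `lmm_ri` with components `coefficients`, `se`,
#'   `vcov`, `sigma2_u`, `sigma2_e`, `lambda`, `loglik_reml`, `ranef`,
#'   `fitted_values` (including BLUPs), `fitted_fixed`, `residuals`,
#'   `n_obs`, `n_groups`, `converged`.
#' @examples
#' d <- data.frame(y = c(1, 2, 3, 3, 4, 5), x = c(0, 1, 2, 0, 1, 2),
#'                 exp = rep(c("a", "b"), each = 3))
#' fit <- lmm_ri(y ~ x, d, group = ~exp)
#' summary(fit)
#' @export
lmm_ri <- function(formula, data, group, tol = 1e-8) {
  mf <- model.frame(formula, data, na.action = na.omit)
  y <- model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  if (inherits(group, "formula")) {
    g <- eval(group[[2L]], data, environment(group))
  } else if (is.character(group) && length(group) == 1L &&
             group %in% names(data)) {
    g <- data[[group]]
  } else {
    g <- group
  }
  dropped <- attr(mf, "na.action")
  if (!is.null(dropped)) g <- g[-as.integer(dropped)]
  if (length(g) != length(y))
    stop("group length does not match the model frame", call. = FALSE)
  fit <- .fit_ri(y, X, g, tol = tol)
  fit$call <- match.call()
  fit$formula <- formula
  fit
}

# Core fitter on a prepared response/design/grouping. Used directly by the
# per-protein analysis loops to avoid model.frame overhead.
.fit_ri <- function(y, X, group, tol = 1e-8) {
  if (is.null(dim(X))) X <- cbind(`(Intercept)` = 1, x = X)
  n <- length(y)
  p <- ncol(X)
  if (n < 3L) stop("at least 3 observations are required", call. = FALSE)
  if (qr(X)$rank < p)
    stop("degenerate design: constant or collinear predictor", call. = FALSE)
  g <- factor(group)
  gi <- as.integer(g)
  G <- nlevels(g)
  nj <- tabulate(gi, G)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y * y)
  SX <- rowsum(X, gi, reorder = TRUE)
  Sy <- rowsum(y, gi, reorder = TRUE)[, 1L]

  eval_lambda <- function(lambda) {
    w <- lambda / (1 + lambda * nj)
    A <- XtX - crossprod(SX, SX * w)
    cc <- Xty - crossprod(SX, Sy * w)
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) return(list(crit = Inf))
    beta <- backsolve(ch, forwardsolve(t(ch), cc))
    yVy <- yty - sum(w * Sy^2)
    rss <- max(yVy - sum(cc * beta), 0)
    sig2 <- rss / (n - p)
    crit <- (n - p) * log(sig2) + sum(log1p(lambda * nj)) +
      2 * sum(log(diag(ch)))
    list(crit = crit, beta = drop(beta), sig2 = sig2, ch = ch, w = w)
  }

  if (G == 1L) {
    lambda_hat <- 0
    converged <- TRUE
  } else {
    obj <- function(t) {
      cr <- eval_lambda(exp(t))$crit
      if (!is.finite(cr) && cr < 0) -.Machine$double.xmax else cr
    }
    opt <- optimize(obj, interval = c(-14, 14), tol = tol)
    cand <- c(0, exp(opt$minimum), exp(-14), exp(14))
    crits <- vapply(cand, function(l) eval_lambda(l)$crit, numeric(1))
    lambda_hat <- cand[which.min(crits)]
    converged <- is.finite(min(crits)) || min(crits) == -Inf
  }
  sol <- eval_lambda(lambda_hat)
  beta <- sol$beta
  names(beta) <- colnames(X)
  Ainv <- chol2inv(sol$ch)
  vc <- sol$sig2 * Ainv
  dimnames(vc) <- list(colnames(X), colnames(X))
  se <- sqrt(pmax(diag(vc), 0))
  r <- y - drop(X %*% beta)
  Sr <- rowsum(r, gi, reorder = TRUE)[, 1L]
  u <- lambda_hat * Sr / (1 + lambda_hat * nj)
  names(u) <- levels(g)
  fitted_fixed <- drop(X %*% beta)
  fitted_all <- fitted_fixed + u[gi]
  loglik <- -0.5 * ((n - p) * (1 + log(2 * pi)) + sol$crit)
  structure(list(
    coefficients = beta,
    se = se,
    vcov = vc,
    sigma2_u = lambda_hat * sol$sig2,
    sigma2_e = sol$sig2,
    lambda = lambda_hat,
    loglik_reml = loglik,
    ranef = u,
    fitted_values = unname(fitted_all),
    fitted_fixed = unname(fitted_fixed),
    residuals = unname(y - fitted_all),
    y = y,
    X = X,
    group = g,
    n_obs = n,
    n_groups = G,
    converged = converged
  ), class = "lmm_ri")
}

#' @export
print.lmm_ri <- function(x, digits = 4, ...) {
  cat("Random-intercept linear mixed model (REML)\n")
  cat("  n =", x$n_obs, " groups =", x$n_groups, "\n")
  cat("Fixed effects:\n")
  print(round(x$coefficients, digits))
  cat("Variance components: sigma2_u =", signif(x$sigma2_u, digits),
      " sigma2_e =", signif(x$sigma2_e, digits), "\n")
  invisible(x)
}

#' @export
summary.lmm_ri <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = object$se,
               `z value` = z,
               `Pr(>|z|)` = 2 * pnorm(-abs(z)))
  structure(list(coefficients = tab, sigma2_u = object$sigma2_u,
                 sigma2_e = object$sigma2_e, loglik_reml = object$loglik_reml,
                 n_obs = object$n_obs, n_groups = object$n_groups),
            class = "summary.lmm_ri")
}

#' @export
print.summary.lmm_ri <- function(x, ...) {
  cat("Random-intercept linear mixed model (REML)\n")
  cat("  n =", x$n_obs, " groups =", x$n_groups,
      " REML logLik =", signif(x$loglik_reml, 6), "\n\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat("\nVariance components:\n")
  cat("  experiment (intercept):", signif(x$sigma2_u, 5), "\n")
  cat("  residual:              ", signif(x$sigma2_e, 5), "\n")
  invisible(x)
}

#' @export
coef.lmm_ri <- function(object, ...) object$coefficients

#' @export
vcov.lmm_ri <- function(object, ...) object$vcov

#' @export
fitted.lmm_ri <- function(object, include_ranef = TRUE, ...) {
  if (include_ranef) object$fitted_values else object$fitted_fixed
}

#' @export
residuals.lmm_ri <- function(object, ...) object$residuals

#' Extract estimated random intercepts (BLUPs)
#'
#' @param object an `lmm_ri` fit.
#' @param ... unused.
#' @return named vector of per-group best linear unbiased predictors.
#' @export
ranef <- function(object, ...) UseMethod("ranef")

#' @rdname ranef
#' @export
ranef.lmm_ri <- function(object, ...) object$ranef

#' @export
logLik.lmm_ri <- function(object, ...) {
  structure(object$loglik_reml, df = length(object$coefficients) + 2,
            class = "logLik")
}

#' @export
nobs.lmm_ri <- function(object, ...) object$n_obs

#' @export
confint.lmm_ri <- function(object, parm, level = 0.95, ...) {
  cf <- object$coefficients
  if (missing(parm)) parm <- names(cf)
  z <- qnorm(1 - (1 - level) / 2)
  out <- cbind(cf[parm] - z * object$se[parm], cf[parm] + z * object$se[parm])
  colnames(out) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  out
}

#' @export
predict.lmm_ri <- function(object, newdata = NULL, include_ranef = TRUE, ...) {
  if (is.null(newdata))
    return(fitted(object, include_ranef = include_ranef))
  X <- model.matrix(stats::delete.response(stats::terms(object$formula)),
                    newdata)
  eta <- drop(X %*% object$coefficients)
  if (include_ranef && "group" %in% names(newdata)) {
    u <- object$ranef[as.character(newdata$group)]
    u[is.na(u)] <- 0
    eta <- eta + u
  }
  eta
}

#' @export
simulate.lmm_ri <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n_obs
  gi <- as.integer(object$group)
  G <- object$n_groups
  out <- replicate(nsim, {
    u <- rnorm(G, 0, sqrt(object$sigma2_u))
    object$fitted_fixed + u[gi] + rnorm(n, 0, sqrt(object$sigma2_e))
  })
  as.data.frame(out)
}

#' Wald test of the slope
#'
#' Two-sided p-value for the null hypothesis that a fixed-effect coefficient
#' is zero, from `z = beta / se` against the standard normal. This is the
#' inference convention used throughout: with up to 72 experiments and
#' several hundred children per fit, the normal reference is adequate.
#'
#' @param fit an `lmm_ri` fit.
#' @param coef_name coefficient to test (default: the first non-intercept
#'   coefficient).
#' @return the two-sided p-value.
#' @export
wald_test <- function(fit, coef_name = NULL) {
  stopifnot(inherits(fit, "lmm_ri"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  cf <- fit$coefficients
  if (is.null(coef_name)) {
    idx <- which(names(cf) != "(Intercept)")
    if (!length(idx)) stop("no slope coefficient to test", call. = FALSE)
    coef_name <- names(cf)[idx[1L]]
  }
  se <- fit$se[coef_name]
  if (!is.finite(se) || se <= 0)
    stop("standard error is zero; Wald test undefined", call. = FALSE)
  unname(2 * pnorm(-abs(cf[coef_name] / se)))
}

#' Proportion of outcome variance explained by fitted values
#'
#' \eqn{R^2 = Var(\hat y)/Var(y)}, clipped to \[0, 1\]. By default the
#' fitted values include the BLUP random intercepts; a fixed-effects-only
#' mode is available for sensitivity analysis.
#'
#' @param fit an `lmm_ri` fit.
#' @param include_ranef include BLUPs in the fitted values (default `TRUE`).
#' @return R-squared in \[0, 1\].
#' @export
fitted_r2 <- function(fit, include_ranef = TRUE) {
  stopifnot(inherits(fit, "lmm_ri"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  vy <- var(fit$y)
  if (!is.finite(vy) || vy == 0)
    stop("constant outcome: R2 undefined", call. = FALSE)
  min(max(var(fitted(fit, include_ranef = include_ranef)) / vy, 0), 1)
}
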