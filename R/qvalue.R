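#' Storey q-values
#'
#' False discovery rate adjusted significance per Storey: the q-value of the
#' i-th smallest p is \eqn{q_{(i)} = \min_{t \ge p_{(i)}}
#' \hat\pi_0 m t / \#\{p \le t\}}, computed as a cumulative minimum over the
#' sorted p-values. The null proportion \eqn{\pi_0} defaults to the smoother
#' estimate: \eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\}/(m(1-\lambda))}
#' over a grid of \eqn{\lambda}, smoothed with a cubic spline and evaluated
#' at the grid maximum. With `pi0_method = "unit"` (\eqn{\pi_0 = 1}) the
#' procedure reduces exactly to Benjamini-Hochberg adjusted p-values.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param lambda_grid grid of tuning values for the smoother (default
#'   0.05, 0.10, ..., 0.95).
#' @param pi0_method `"smoother"` (default), `"fixed"` (single
#'   `lambda_fixed`), or `"unit"` (\eqn{\pi_0 = 1}, i.e. BH).
#' @param lambda_fixed tuning value for `pi0_method = "fixed"`.
#' @return list of class `storey_q`: `q_values` (aligned with `p`),
#'   `pi0_hat`, `lambda_grid`, `pi0_method`.
#' @export
storey_qvalues <- function(p, lambda_grid = seq(0.05, 0.95, by = 0.05),
                           pi0_method = c("smoother", "fixed", "unit"),
                           lambda_fixed = 0.5) {
  pi0_method <- match.arg(pi0_method)
  if (length(p) < 1L) stop("at least one p-value is required", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  pi0 <- switch(pi0_method,
    unit = 1,
    fixed = mean(p > lambda_fixed) / (1 - lambda_fixed),
    smoother = {
      pi0_l <- vapply(lambda_grid, function(l) mean(p > l) / (1 - l),
                      numeric(1))
      if (length(lambda_grid) >= 4L) {
        sp <- smooth.spline(lambda_grid, pi0_l, df = 3)
        predict(sp, x = max(lambda_grid))$y
      } else {
        pi0_l[length(pi0_l)]
      }
    })
  pi0 <- min(pi0, 1)
  if (pi0 <= 0) {
    warning("estimated pi0 <= 0; flooring at 1/m. ",
            "The p-value distribution is extremely non-null.")
    pi0 <- 1 / m
  }
  o <- order(p, decreasing = TRUE)
  q <- numeric(m)
  q[o] <- pmin(1, cummin(pi0 * m * p[o] / (m:1)))
  structure(list(q_values = q, pi0_hat = pi0, lambda_grid = lambda_grid,
                 pi0_method = pi0_method),
            class = "storey_q")
}

#' @export
print.storey_q <- function(x, ...) {
  cat("Storey q-values: m =", length(x$q_values),
      " pi0_hat =", signif(x$pi0_hat, 4),
      " (", x$pi0_method, ")\n", sep = "")
  invisible(x)
}

#' Count discoveries at FDR thresholds
#'
#' Counts q-values strictly below each threshold (the study's primary
#' threshold is q < 0.10, the relaxed network threshold q < 0.20) and
#' returns the identifiers of the discoveries.
#'
#' @param q numeric q-values or a `storey_q` object.
#' @param thresholds FDR thresholds (strict `<`).
#' @param ids optional identifiers aligned with `q`.
#' @return named list per threshold with elements `count` and `ids`.
#' @export
threshold_report <- function(q, thresholds = c(0.10, 0.20), ids = NULL) {
  if (inherits(q, "storey_q")) q <- q$q_values
  if (is.null(ids)) ids <- as.character(seq_along(q))
  out <- lapply(thresholds, function(th) {
    hit <- which(q < th)
    list(count = length(hit), ids = ids[hit[order(q[hit])]])
  })
  names(out) <- paste0("q<", format(thresholds))
  out
}
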