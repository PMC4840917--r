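# Independent brute-force REML oracle: dense-matrix evaluation of the
# restricted log-likelihood at a given variance ratio, maximized over a grid.
# Deliberately shares no code with the package's profiled fitter.
reml_loglik_dense <- function(lambda, y, X, g) {
  g <- factor(g)
  Z <- outer(g, levels(g), `==`) * 1
  n <- length(y)
  p <- ncol(X)
  H <- diag(n) + lambda * tcrossprod(Z)
  Hi <- solve(H)
  A <- t(X) %*% Hi %*% X
  beta <- solve(A, t(X) %*% Hi %*% y)
  r <- y - X %*% beta
  sig2 <- drop(t(r) %*% Hi %*% r) / (n - p)
  ldH <- as.numeric(determinant(H, logarithm = TRUE)$modulus)
  ldA <- as.numeric(determinant(A, logarithm = TRUE)$modulus)
  -0.5 * ((n - p) * (1 + log(2 * pi)) + (n - p) * log(sig2) + ldH + ldA)
}

reml_grid_max <- function(y, X, g,
                          grid = c(0, exp(seq(-14, 14, length.out = 401)))) {
  max(vapply(grid, function(l) reml_loglik_dense(l, y, X, g), numeric(1)))
}

# Random small mixed-model instance generator for oracle comparisons.
random_instance <- function(max_n = 40, max_groups = 6) {
  G <- sample(2:max_groups, 1)
  nj <- sample(2:floor(max_n / G), G, replace = TRUE)
  g <- rep(seq_len(G), nj)
  n <- length(g)
  x <- rnorm(n)
  u <- rnorm(G, 0, runif(1, 0, 1.5))
  y <- runif(1, -1, 1) + runif(1, -1, 1) * x + u[g] + rnorm(n, 0, runif(1, 0.3, 1.5))
  list(y = y, X = cbind(`(Intercept)` = 1, x = x), g = g)
}

# Small two-experiment cohort with hand-set raw intensities, used across
# the I/O and preprocessing tests.
tiny_cohort <- function() {
  subjects <- data.frame(
    child_id = c("c1", "c2", "c3", "c4"),
    experiment_id = c("e1", "e1", "e2", "e2"),
    channel = c(1L, 2L, 1L, 2L),
    pivka2_ugL = c(1.31, 2.5, 0.0005, 1.0),
    stringsAsFactors = FALSE)
  observations <- data.frame(
    gene_symbol = c("F2", "F2", "F2", "GSN", "GSN", "GSN"),
    gi_accession = c("4503635", "4503635", "4503635",
                     "4504165", "4504165", "4504165"),
    child_id = c("c1", "c2", "c3", "c1", "c2", "c4"),
    experiment_id = c("e1", "e1", "e2", "e1", "e1", "e2"),
    value = c(2, 4, 8, 1, 16, 4),
    stringsAsFactors = FALSE)
  cohort_dataset(subjects, observations)
}
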