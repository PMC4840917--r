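test_that("single-group fits reduce exactly to ordinary least squares", {
  # perfect line: slope 1, no residual, no batch variance
  f <- lmm_ri(y ~ x, data.frame(y = c(1, 2, 3), x = c(0, 1, 2)),
              group = rep("g1", 3))
  expect_equal(unname(coef(f)), c(1, 1), tolerance = 1e-12)
  expect_equal(f$sigma2_u, 0)
  expect_equal(f$sigma2_e, 0)
  expect_equal(f$residuals, rep(0, 3), tolerance = 1e-12)

  set.seed(41)
  d <- data.frame(x = rnorm(25))
  d$y <- 2 - 0.7 * d$x + rnorm(25, 0, 0.8)
  f <- lmm_ri(y ~ x, d, group = rep(1, 25))
  ols <- summary(lm(y ~ x, d))
  expect_equal(unname(coef(f)), unname(coef(ols)[, 1]), tolerance = 1e-12)
  expect_equal(unname(f$se), unname(coef(ols)[, 2]), tolerance = 1e-12)
  z <- coef(f)["x"] / f$se["x"]
  expect_equal(wald_test(f), unname(2 * pnorm(-abs(z))))
})

test_that("balanced intercept-only REML matches the closed-form ANOVA estimators", {
  # groups {(1,2), (3,4)}: MSW = 0.5, MSB = 4, n per group = 2
  d <- data.frame(y = c(1, 2, 3, 4), g = c("a", "a", "b", "b"))
  f <- lmm_ri(y ~ 1, d, group = ~g)
  expect_equal(f$sigma2_e, 0.5, tolerance = 1e-7)
  expect_equal(f$sigma2_u, (4 - 0.5) / 2, tolerance = 1e-6)
  # general balanced case against freshly computed ANOVA moments
  set.seed(7)
  for (rep in 1:5) {
    G <- sample(4:8, 1); m <- sample(3:6, 1)
    g <- rep(seq_len(G), each = m)
    y <- rnorm(G, 0, 1.2)[g] + rnorm(G * m)
    msw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / (G * (m - 1))
    msb <- m * sum((tapply(y, g, mean) - mean(y))^2) / (G - 1)
    f <- lmm_ri(y ~ 1, data.frame(y = y), group = g)
    if (msb > msw) {
      expect_equal(f$sigma2_e, msw, tolerance = 1e-5)
      expect_equal(f$sigma2_u, (msb - msw) / m, tolerance = 1e-4)
    } else {
      expect_equal(f$sigma2_u, 0)
    }
  }
})

test_that("profiled REML optimum matches the brute-force dense-matrix oracle", {
  set.seed(11)
  for (i in 1:15) {
    inst <- random_instance()
    f <- lmm_ri(y ~ x, data.frame(y = inst$y, x = inst$X[, "x"]),
                group = inst$g)
    expect_gte(f$loglik_reml, reml_grid_max(inst$y, inst$X, inst$g) - 1e-6)
  }
})

test_that("estimates agree with lme4 on a moderate instance", {
  skip_if_not_installed("lme4")
  set.seed(19)
  d <- data.frame(x = rnorm(160), g = rep(1:20, each = 8))
  d$y <- 0.3 + 0.8 * d$x + rnorm(20, 0, 0.6)[d$g] + rnorm(160, 0, 0.9)
  f <- lmm_ri(y ~ x, d, ~g)
  lf <- lme4::lmer(y ~ x + (1 | g), d, REML = TRUE)
  expect_equal(unname(coef(f)), unname(lme4::fixef(lf)), tolerance = 1e-6)
  vc <- as.data.frame(lme4::VarCorr(lf))$vcov
  expect_equal(c(f$sigma2_u, f$sigma2_e), vc, tolerance = 1e-5)
  expect_equal(f$loglik_reml, as.numeric(logLik(lf)), tolerance = 1e-7)
  expect_equal(unname(f$se), unname(coef(summary(lf))[, "Std. Error"]),
               tolerance = 1e-5)
  expect_equal(unname(ranef(f)), unname(lme4::ranef(lf)$g[, 1]),
               tolerance = 1e-5)
})

test_that("Wald test follows the standard normal reference", {
  set.seed(5)
  d <- data.frame(x = rnorm(30), g = rep(1:3, each = 10))
  d$y <- rnorm(30)
  f <- lmm_ri(y ~ x, d, ~g)
  # beta = 0 => p = 1 (force the coefficient)
  f0 <- f; f0$coefficients["x"] <- 0
  expect_equal(wald_test(f0), 1)
  # z = 1.959964 => p ~= 0.05
  f0$coefficients["x"] <- 1.959964 * f0$se["x"]
  expect_equal(wald_test(f0), 0.05, tolerance = 1e-6)
  # symmetric in the sign of beta
  fneg <- f; fneg$coefficients["x"] <- -f$coefficients["x"]
  expect_equal(wald_test(fneg), wald_test(f))
  # se = 0 is an error
  f0$se["x"] <- 0
  expect_error(wald_test(f0), "zero")
})

test_that("equivariance: outcome shifts move only the intercept; predictor scaling inverts the slope", {
  set.seed(23)
  d <- data.frame(x = rnorm(60), g = rep(1:6, each = 10))
  d$y <- 1 + 0.5 * d$x + rnorm(6, 0, 0.7)[d$g] + rnorm(60, 0, 0.5)
  f1 <- lmm_ri(y ~ x, d, ~g)
  d2 <- transform(d, y = y + 10)
  f2 <- lmm_ri(y ~ x, d2, ~g)
  expect_equal(coef(f2)[["(Intercept)"]], coef(f1)[["(Intercept)"]] + 10,
               tolerance = 1e-6)
  expect_equal(coef(f2)[["x"]], coef(f1)[["x"]], tolerance = 1e-7)
  d3 <- transform(d, x = 4 * x)
  f3 <- lmm_ri(y ~ x, d3, ~g)
  expect_equal(coef(f3)[["x"]], coef(f1)[["x"]] / 4, tolerance = 1e-7)
  expect_equal(f3$sigma2_e, f1$sigma2_e, tolerance = 1e-6)
})

test_that("fitted-value R2 spans its degenerate and calibrated cases", {
  # perfect fit
  f <- lmm_ri(y ~ x, data.frame(y = c(1, 2, 3), x = c(0, 1, 2)),
              group = rep(1, 3))
  expect_equal(fitted_r2(f), 1)
  # constant fitted values (null slope, single group, centered outcome)
  set.seed(2)
  y <- rnorm(40); y <- y - mean(y)
  fc <- lmm_ri(y ~ 1, data.frame(y = y), group = rep(1, 40))
  expect_equal(fitted_r2(fc), 0, tolerance = 1e-20)
  # known signal fraction 0.3 at the study's continuous-subset size
  set.seed(31)
  r2s <- replicate(8, {
    n <- 474
    x <- rnorm(n)
    yy <- sqrt(0.3) * x + rnorm(n, 0, sqrt(0.7))
    fit <- lmm_ri(y ~ x, data.frame(y = yy, x = x),
                  group = rep(1:68, length.out = n))
    fitted_r2(fit)
  })
  expect_equal(mean(r2s), 0.3, tolerance = 0.05)
  # constant outcome errors
  fc$y <- rep(1, 40)
  expect_error(fitted_r2(fc), "constant outcome")
})

test_that("degenerate designs are rejected and model methods are coherent", {
  d <- data.frame(y = rnorm(10), x = rep(1, 10), g = rep(1:2, 5))
  expect_error(lmm_ri(y ~ x, d, ~g), "degenerate design")
  set.seed(13)
  d <- data.frame(x = rnorm(40), g = rep(1:4, each = 10))
  d$y <- 0.5 * d$x + rnorm(4, 0, 1)[d$g] + rnorm(40, 0, 0.4)
  f <- lmm_ri(y ~ x, d, ~g)
  expect_equal(fitted(f) + residuals(f), d$y, tolerance = 1e-12)
  expect_equal(fitted(f, include_ranef = FALSE),
               unname(drop(f$X %*% coef(f))), tolerance = 1e-12)
  ci <- confint(f, "x", level = 0.95)
  expect_lt(ci[1], coef(f)[["x"]]); expect_gt(ci[2], coef(f)[["x"]])
  expect_equal(length(ranef(f)), 4)
  sims <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(40L, 3L))
  expect_output(print(summary(f)), "Variance components")
})
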