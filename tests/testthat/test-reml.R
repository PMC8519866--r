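test_that("REML matches the balanced one-way ANOVA closed form", {
  set.seed(2)
  g <- gl(10, 10)
  y <- rnorm(100) + rep(rnorm(10, 0, 2), each = 10)
  Z <- stats::model.matrix(~ 0 + g)
  fit <- fit_mpp_model(y, "IBD.SQM_U", qtl = Z)
  ms <- anova(lm(y ~ g))[["Mean Sq"]]
  expect_equal(unname(fit$theta[["qtl"]]), (ms[1] - ms[2]) / 10,
               tolerance = 1e-6)
  expect_equal(unname(fit$theta[["resid"]]), ms[2], tolerance = 1e-6)
})

test_that("constant phenotypes push every variance to the zero boundary", {
  y <- rep(2, 40)
  Z <- random_predictors(40, 4)
  fit <- fit_mpp_model(y, "IBD.SQM_U", qtl = Z)
  expect_true(all(fit$theta <= 1e-10))
})

test_that("the optimizer agrees with a likelihood-grid oracle on a toy", {
  set.seed(14)
  n <- 12
  M <- random_predictors(n, 2)
  y <- drop(M %*% c(0.5, -0.5)) + rnorm(n, 0, 0.7)
  fit <- fit_mpp_model(y, "IBD.SQM_U", qtl = M)
  comps <- list(ibdqtl:::vc_lowrank("qtl", M),
                ibdqtl:::vc_diag("resid", rep(1, n)))
  X <- matrix(1, n, 1)
  ll <- function(th) {
    ev <- ibdqtl:::reml_eval(th, y, X, comps, want_derivs = FALSE)
    if (is.null(ev)) -Inf else ev$ll
  }
  # 200 x 200 grid, twice refined around the running optimum
  lo <- c(0, 1e-4); hi <- c(4, 4) * var(y)
  for (pass in 1:3) {
    g1 <- seq(lo[1], hi[1], length.out = 200)
    g2 <- seq(lo[2], hi[2], length.out = 200)
    vals <- outer(g1, g2, Vectorize(function(a, b) ll(c(a, b))))
    ij <- arrayInd(which.max(vals), dim(vals))
    best <- c(g1[ij[1]], g2[ij[2]])
    span <- c(diff(g1[1:2]), diff(g2[1:2])) * 3
    lo <- pmax(best - span, c(0, 1e-6)); hi <- best + span
  }
  expect_lt(max(abs(unname(fit$theta) - best)), 1e-3)
  expect_lt(abs(fit$loglik - ll(best)), 1e-4)
})

test_that("REML is invariant to phenotype location shifts", {
  set.seed(21)
  n <- 80
  M <- random_predictors(n, 4)
  fam <- gl(2, 40)
  y <- drop(M %*% rnorm(4, 0, 0.5)) + rnorm(n)
  f1 <- fit_mpp_model(y, "IBD.SQM_F", family = fam, qtl = M)
  f2 <- fit_mpp_model(y + 100, "IBD.SQM_F", family = fam, qtl = M)
  expect_equal(f1$theta, f2$theta, tolerance = 1e-8)
})

test_that("single-family _F models coincide with the uniform model", {
  set.seed(31)
  n <- 60
  M <- random_predictors(n, 4)
  y <- drop(M %*% rnorm(4, 0, 0.4)) + rnorm(n)
  fU <- fit_mpp_model(y, "IBD.SQM_U", qtl = M)
  fF <- fit_mpp_model(y, "IBD.SQM_F", qtl = M)   # one family: equivalent
  expect_equal(fU$theta, fF$theta, tolerance = 1e-8)
  expect_equal(fU$loglik, fF$loglik, tolerance = 1e-8)
})

test_that("the LRT uses the boundary chi-square mixture", {
  set.seed(41)
  n <- 50
  M <- random_predictors(n, 4)
  y <- rnorm(n)
  nul <- fit_mpp_model(y, "IBD.SQM_U")
  alt <- fit_mpp_model(y, "IBD.SQM_U", qtl = M)
  tst <- lrt_variance_component(nul, alt)
  expect_gte(tst$stat, 0)
  expect_gte(alt$loglik, nul$loglik - 1e-9)  # likelihood monotonicity
  # quantile checks of the mixture p-value
  expect_equal(0.5 * pchisq(2.705543, 1, lower.tail = FALSE), 0.05,
               tolerance = 1e-6)
  fake0 <- nul; fake0$loglik <- alt$loglik   # force LRT = 0
  expect_equal(lrt_variance_component(fake0, alt)$p, 1)
  expect_error(lrt_variance_component(nul, fit_mpp_model(rnorm(n), "IBD.SQM_U",
                                                         qtl = M)),
               "different data")
})

test_that("the Wald test reduces to OLS t-squared when V is isotropic", {
  set.seed(51)
  n <- 60
  xq <- sample(0:2, n, replace = TRUE)
  y <- 0.3 * xq + rnorm(n)
  fit <- fit_mpp_model(y, "IBS.Kin", marker = xq, kinship = diag(n))
  tst <- wald_test_fixed(fit)
  tt <- summary(lm(y ~ xq))$coefficients["xq", "t value"]
  expect_equal(tst$stat, tt^2, tolerance = 1e-6)
  expect_error(fit_mpp_model(y, "IBS.Kin", marker = rep(2, n),
                             kinship = diag(n)), "monomorphic")
})

test_that("the BIC formula evaluates exactly", {
  expect_equal(bic_mixed(-500, df_fixed = 3, df_var = 2, n = 300, r = 3),
               5 * log(300) + 1000, tolerance = 1e-9)
  # one extra variance parameter at equal likelihood costs ln(n - r + DF_fixed)
  b1 <- bic_mixed(-100, 3, 2, 200, 3)
  b2 <- bic_mixed(-100, 3, 3, 200, 3)
  expect_equal(b2 - b1, log(200), tolerance = 1e-12)
  # no variance parameters, intercept only: (1) * ln(n) - 2 lnL
  expect_equal(bic_mixed(-50, 1, 0, 100, 1), log(100) + 100, tolerance = 1e-12)
  expect_error(bic_mixed(-1, 1, 1, 10, 12))
})

test_that("QTL variance is recovered across replicates", {
  set.seed(61)
  n <- 400; reps <- 50
  est <- numeric(reps)
  for (r in seq_len(reps)) {
    M <- random_predictors(n, 4)
    a <- rnorm(4, 0, sqrt(0.16))
    y <- drop(M %*% a) + rnorm(n)
    est[r] <- fit_mpp_model(y, "IBD.SQM_U", qtl = M)$theta[["qtl"]]
  }
  expect_lt(abs(mean(est) - 0.16) / 0.16, 0.15)
})

test_that("parental-effect BLUPs recover signs and shrink", {
  set.seed(71)
  n <- 200; hits <- 0L; reps <- 30L
  for (r in seq_len(reps)) {
    M <- random_predictors(n, 4)
    y <- drop(M %*% c(0.5, 0.5, -0.5, -0.5)) + rnorm(n)
    fit <- fit_mpp_model(y, "IBD.SQM_U", qtl = M)
    u <- ranef(fit)$qtl
    if (all(u[1:2] > 0) && all(u[3:4] < 0)) hits <- hits + 1L
    # shrinkage: BLUPs no larger than the centered least-squares contrasts
    ols <- coef(lm(y ~ 0 + M))
    expect_lte(max(abs(u)), max(abs(ols - mean(ols))) + 1e-8)
  }
  expect_gte(hits, ceiling(0.9 * reps))
  # a zero variance component gives exactly zero BLUPs
  y0 <- rep(1, 40)
  f0 <- fit_mpp_model(y0, "IBD.SQM_U", qtl = random_predictors(40, 4))
  expect_true(all(ranef(f0)$qtl == 0))
})

test_that("fit objects expose the standard accessors", {
  set.seed(81)
  n <- 60
  fam <- gl(3, 20)
  M <- random_predictors(n, 4)
  y <- rnorm(n) + rep(c(0, 1, 2), each = 20)
  fit <- fit_mpp_model(y, "IBD.SQM_F", family = fam, qtl = M)
  expect_named(coef(fit), levels(fam))
  expect_equal(length(residuals(fit)), n)
  expect_equal(unname(fitted(fit) + residuals(fit)), y, tolerance = 1e-12)
  expect_s3_class(logLik(fit), "logLik")
  expect_equal(dim(vcov(fit)), c(3L, 3L))
  expect_output(print(fit), "IBD.SQM_F")
  expect_output(summary(fit), "Variance components")
  # refitting from the solution does not move the optimum
  fit2 <- fit_mpp_model(y, "IBD.SQM_F", family = fam, qtl = M,
                        init = fit$theta, starts = 1L)
  expect_lt(abs(fit2$loglik - fit$loglik), 1e-6)
})
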