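test_that("ols_fit: exact line, normal-equations oracle, collinearity", {
  x <- 1:10
  f <- ols_fit(2 + 3 * x, x)
  expect_equal(unname(f$coefficients), c(2, 3), tolerance = 1e-10)
  expect_equal(f$r_squared, 1)

  set.seed(5)
  X <- cbind(a = rnorm(20), b = rnorm(20))
  y <- rnorm(20)
  f2 <- ols_fit(y, X)
  Xd <- cbind(1, X)
  beta_oracle <- solve(t(Xd) %*% Xd) %*% t(Xd) %*% y
  expect_equal(unname(f2$coefficients), unname(drop(beta_oracle)),
               tolerance = 1e-8)
  expect_equal(f2$aic, 2 * f2$k - 2 * f2$loglik)
  expect_equal(sum(f2$residuals), 0, tolerance = 1e-10)

  # orthogonal response: slope ~ 0, R2 ~ 0
  x0 <- c(-2, -1, 0, 1, 2)
  y0 <- c(1, -1, 0, -1, 1)
  f3 <- ols_fit(y0, x0)
  expect_equal(unname(f3$coefficients[2]), 0, tolerance = 1e-12)
  expect_equal(f3$r_squared, 0, tolerance = 1e-12)

  expect_error(ols_fit(y, cbind(X, a2 = X[, 1])),
               class = "collinearity_error")
})

test_that("rma_fit: slope formula and algebraic identity with OLS", {
  set.seed(9)
  x <- rnorm(25); y <- 0.4 * x + rnorm(25, 0, 0.6)
  f <- rma_fit(y, x)
  expect_equal(unname(f$coefficients[2]), sign(cor(x, y)) * sd(y) / sd(x),
               tolerance = 1e-12)
  f_ols <- ols_fit(y, x)
  expect_equal(abs(f$coefficients[[2]]),
               abs(f_ols$coefficients[[2]]) / abs(cor(x, y)),
               tolerance = 1e-10)

  yn <- -y
  expect_lt(rma_fit(yn, x)$coefficients[[2]], 0)
  expect_error(rma_fit(rep(1, 5), 1:5), class = "invalid_input")
})

test_that("pgls_fit: OLS limit at lambda 0, explicit GLS oracle", {
  tr <- simulate_tree(10, "pure-birth", seed = 12)  # ultrametric
  tab <- simulate_allometric_table(tr, slope = 0.3, intercept = 0.8,
                                   resid_sd = 0.08, seed = 2)
  y <- log10(tab$trait); x <- log10(tab$body_mass_kg)
  names(y) <- tab$species
  f0 <- pgls_fit(y, cbind(mass = x), tr, lam_mode = 0)
  fo <- ols_fit(y, cbind(mass = x))
  expect_equal(unname(f0$coefficients), unname(fo$coefficients),
               tolerance = 1e-8)

  f1 <- pgls_fit(y, cbind(mass = x), tr, lam_mode = 1)
  V <- unclass(vcv_from_tree(tr))
  Xd <- cbind(1, x)
  beta_oracle <- solve(t(Xd) %*% solve(V) %*% Xd) %*%
    (t(Xd) %*% solve(V, as.numeric(y)))
  expect_equal(unname(f1$coefficients), unname(drop(beta_oracle)),
               tolerance = 1e-8)

  fml <- pgls_fit(y, cbind(mass = x), tr, lam_mode = "ML")
  for (lam in c(0, 0.3, 0.7, 1))
    expect_gte(fml$loglik,
               pgls_fit(y, cbind(mass = x), tr, lam_mode = lam)$loglik - 1e-6)
  expect_true(fml$r_squared >= 0 && fml$r_squared <= 1)
})

test_that("pgls slope recovery on allometric simulations (reduced reps)", {
  tr <- simulate_tree(22, "pure-birth", seed = 30)
  slopes <- vapply(1:60, function(i) {
    tab <- simulate_allometric_table(tr, slope = 0.2, intercept = 1,
                                     resid_sd = 0.05, resid_lam = 1,
                                     seed = 3000 + 7 * i)
    y <- setNames(log10(tab$trait), tab$species)
    pgls_fit(y, cbind(mass = log10(tab$body_mass_kg)), tr,
             lam_mode = 1)$coefficients[[2]]
  }, 0)
  expect_lt(abs(mean(slopes) - 0.2), 0.02)
})

test_that("model_select_aic ranks by AIC and rejects invalid comparisons", {
  set.seed(3)
  x <- rnorm(15); y <- 1 + 0.5 * x + rnorm(15, 0, 0.1)
  f1 <- ols_fit(y, cbind(x = x))
  f2 <- ols_fit(y, cbind(x = x, junk = rnorm(15)))
  ranked <- model_select_aic(list(f2, f1))
  expect_equal(attr(ranked, "ranking")$aic,
               sort(attr(ranked, "ranking")$aic))
  # equal loglik => smaller k wins
  fa <- f1; fa$loglik <- 0; fa$k <- 2L; fa$aic <- 2 * 2 - 0
  fb <- f1; fb$loglik <- 0; fb$k <- 3L; fb$aic <- 2 * 3 - 0
  r2 <- model_select_aic(list(fb, fa))
  expect_equal(r2[[1]]$k, 2L)

  fo <- ols_fit(y, x)
  fr <- rma_fit(y, x)
  expect_error(model_select_aic(list(fo, fr)),
               class = "invalid_comparison")
  f_other <- ols_fit(rnorm(15), x, response = "other")
  expect_error(model_select_aic(list(f1, f_other)),
               class = "invalid_comparison")
})

test_that("nested model selection behaves under strong vs null slopes", {
  set.seed(17)
  wins <- c(strong = 0L, null = 0L)
  for (i in 1:60) {
    x1 <- rnorm(20); x2 <- rnorm(20)
    y_strong <- 1 + x1 + 2 * x2 + rnorm(20, 0, 0.3)
    y_null <- 1 + x1 + rnorm(20, 0, 0.3)
    r_s <- model_select_aic(list(ols_fit(y_strong, cbind(x1)),
                                 ols_fit(y_strong, cbind(x1, x2))))
    r_n <- model_select_aic(list(ols_fit(y_null, cbind(x1)),
                                 ols_fit(y_null, cbind(x1, x2))))
    if (length(r_s[[1]]$predictors) == 2) wins["strong"] <- wins["strong"] + 1L
    if (length(r_n[[1]]$predictors) == 1) wins["null"] <- wins["null"] + 1L
  }
  expect_gt(wins[["strong"]], 30)
  expect_gt(wins[["null"]], 30)
})

test_that("standardized_residuals: normalisation and outlier flagging", {
  x <- 1:12
  perfect <- ols_fit(2 + x, x)
  expect_true(all(standardized_residuals(perfect)$std_residual == 0))

  set.seed(21)
  y <- 1 + 0.2 * x + rnorm(12, 0, 0.05)
  f <- ols_fit(y, x)
  expect_equal(sd(standardized_residuals(f)$std_residual), 1,
               tolerance = 1e-6)

  tr <- simulate_tree(20, "pure-birth", seed = 8)
  tab <- simulate_allometric_table(tr, slope = 0.2, resid_sd = 0.05,
                                   seed = 4, outlier_species = "t7",
                                   outlier_shift = 5)
  y2 <- setNames(log10(tab$trait), tab$species)
  fp <- pgls_fit(y2, cbind(mass = log10(tab$body_mass_kg)), tr,
                 lam_mode = 1)
  sr <- standardized_residuals(fp)
  expect_true(sr$flagged[sr$species == "t7"])
})

test_that("predict_expected back-transforms the allometric line", {
  x <- seq(0, 3, length.out = 8)
  f <- ols_fit(1 + 0.5 * x, x, log_base = 10)
  # 10^(1 + 0.5 * log10(100)) = 10^2
  expect_equal(predict_expected(f, 100), 100, tolerance = 1e-8)
  expect_error(predict_expected(f, -1), class = "invalid_input")

  flat <- ols_fit(rep(2, 8) + 1e-12 * x, x, log_base = 10)
  expect_equal(predict_expected(flat, 1), predict_expected(flat, 500),
               tolerance = 1e-6)
  # monotone in body mass for positive slope
  masses <- c(1, 5, 20, 80)
  expect_true(all(diff(predict_expected(f, masses)) > 0))
})

test_that("regression_diagnostics emits reproducible plot tables", {
  set.seed(2)
  x <- rnorm(30); y <- 1 + x + rnorm(30, 0, 0.2)
  d <- regression_diagnostics(ols_fit(y, x), bins = 8)
  expect_equal(sum(d$histogram$count), 30)
  expect_equal(nrow(d$residual_vs_fitted), 30)
  expect_true(all(diff(d$pp$theoretical) >= 0))
})
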