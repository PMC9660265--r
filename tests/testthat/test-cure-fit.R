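test_that("the time grid takes interior quantiles of observed event times", {
  s <- survival_sample(1:11, rep(1, 11))
  g <- make_grid(s, H = 10)
  expect_equal(g$times,
               unname(stats::quantile(1:11, (1:10) / 11, type = 7)))
  expect_equal(make_grid(s, H = 1)$times,
               unname(stats::median(1:11)))
  # fewer distinct event times than requested: use all, with a warning
  s2 <- survival_sample(c(1, 1, 2, 3, 9), c(1, 1, 1, 1, 0))
  expect_warning(g2 <- make_grid(s2, H = 10), "distinct")
  expect_equal(g2$times, c(1, 2, 3))
})

test_that("component fitters produce the advertised coefficient layout", {
  sc <- phmc_scenario(cens_upper = 16)
  s <- gen_phmc(250, sc, seed = 1)
  fit <- fit_phmc(s, flavor = "km", H = 5)
  expect_named(coef(fit$incidence), c("alpha0", "alpha_X1"))
  expect_named(coef(fit$latency),
               c(paste0("xi_", 1:5), "beta_Z1", "beta_Z2"))
  expect_equal(fit$latency$H, 5)
  expect_true(fit$incidence$converged && fit$latency$converged)

  sp <- phph_scenario(cens_upper = 3)
  s2 <- gen_phph(250, sp, seed = 2)
  pfit <- fit_phph(s2, flavor = "km", H = 4)
  expect_named(coef(pfit$long_term), c("gamma0", "gamma_X1"))
  expect_named(coef(pfit$short_term),
               c(paste0("sigma_", 1:4), "phi_X1", "phi_X2"))
})

test_that("estimates are invariant to subject order", {
  sc <- phmc_scenario(cens_upper = 16)
  s <- gen_phmc(80, sc, seed = 5)
  perm <- sample(80)
  sp <- survival_sample(s$time[perm], s$status[perm],
                        X = s$X[perm, , drop = FALSE],
                        Z = s$Z[perm, , drop = FALSE])
  expect_equal(coef(fit_phmc_incidence(s, "np")),
               coef(fit_phmc_incidence(sp, "np")), tolerance = 1e-9)
  g <- make_grid(s, 4)
  expect_equal(coef(fit_phmc_latency(s, g)),
               coef(fit_phmc_latency(sp, g)), tolerance = 1e-9)
})

test_that("constant latency covariates are rejected as rank deficient", {
  sc <- phmc_scenario(cens_upper = 16)
  s <- gen_phmc(60, sc, seed = 3)
  s$Z <- cbind(s$Z, const = 1)   # collides with the time-dummy block
  expect_error(fit_phmc_latency(s, make_grid(s, 3)), "rank deficient")
})

test_that("pseudo-residuals vanish for a perfect fit and center at zero otherwise", {
  # responses equal to the inverse-link means -> zero residuals
  y <- matrix(plogis(0.3 + c(-1, 0, 1, 2)))
  f <- solve_gee(y, cbind(x = c(-1, 0, 1, 2)), "logit")
  expect_equal(max(abs(f$residuals)), 0, tolerance = 1e-7)

  sc <- phmc_scenario(cens_upper = 16)
  s <- gen_phmc(300, sc, seed = 8)
  fit <- fit_phmc_incidence(s, "km")
  res <- pseudo_residuals(fit, s)
  expect_true(all(c("component", "subject", "residual", "X1") %in% names(res)))
  # estimating-equation identity at the solution (weights are near-constant,
  # so the plain mean is near zero)
  expect_lt(abs(mean(res$residual)), 0.02)
})

test_that("misspecified covariate structure leaves a residual trend", {
  set.seed(21)
  n <- 400
  z <- runif(n, -2, 2)
  lat <- -log(runif(n)) / (0.4 * exp(0.8 * z^2))  # quadratic truth
  cens <- runif(n, 0, 6)
  s <- survival_sample(pmin(lat, cens), as.numeric(lat <= cens),
                       Z = cbind(z = z))
  fit <- fit_phmc_latency(s, make_grid(s, 5))     # linear working model
  res <- pseudo_residuals(fit)
  res$z <- z[res$subject]
  rho <- suppressWarnings(
    stats::cor(abs(res$z), res$residual, method = "spearman"))
  expect_gt(abs(rho), 0.05)
})

test_that("cure-rate tables report both model-based and KM benchmarks", {
  sc <- phmc_scenario(cens_upper = 16)
  s <- gen_phmc(400, sc, seed = 13)
  phmc <- fit_phmc(s, H = 5)
  phph <- fit_phph(s, H = 5)
  tab <- cure_rate_table(phmc, phph, profiles = rbind(0, 1))
  a <- coef(phmc$incidence)
  g <- coef(phph$long_term)
  expect_equal(tab$cure_phmc[1], 1 - plogis(a[["alpha0"]]))
  expect_equal(tab$cure_phph[1], exp(-exp(g[["gamma0"]])))
  expect_equal(tab$cure_km, rep(phmc$km$s_tmax, 2))
  # the logistic closed form at the reference design's stated coefficients
  expect_equal(1 - plogis(2.8 + (-1) * 1), 1 / (1 + exp(1.8)),
               tolerance = 1e-12)
})

test_that("model-based and model-free cure rates agree at moderate n", {
  sc <- phmc_scenario(cens_upper = 16)
  s <- gen_phmc(1200, sc, seed = 17)
  phmc <- fit_phmc(s, H = 5)
  phph <- fit_phph(s, H = 5)
  a <- coef(phmc$incidence)
  g <- coef(phph$long_term)
  mean_phmc <- mean(1 - plogis(a[1] + s$X %*% a[-1]))
  mean_phph <- mean(exp(-exp(g[1] + s$X %*% g[-1])))
  km_cure <- phmc$km$s_tmax
  expect_lt(abs(mean_phmc - km_cure), 0.05)
  expect_lt(abs(mean_phph - km_cure), 0.05)
})
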