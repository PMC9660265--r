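test_that("cure fractions match their closed forms", {
  # logistic incidence: 1 - (expit(a0) + expit(a0 - 1)) / 2
  sc <- phmc_scenario(alpha0 = 2.8, alpha = -1, cens_upper = 10)
  s <- gen_phmc(1e5, sc, seed = 101)
  closed <- 1 - (plogis(2.8) + plogis(1.8)) / 2   # 0.0996
  expect_equal(closed, 0.0996, tolerance = 1e-3)
  expect_lt(abs(mean(attr(s, "cure_status")) - closed), 0.005)

  # promotion time: (exp(-e^{0.5}) + exp(-e^{0.4})) / 2
  sp <- phph_scenario(cens_upper = 3)
  s2 <- gen_phph(1e5, sp, seed = 102)
  closed2 <- (exp(-exp(0.5)) + exp(-exp(0.4))) / 2  # about 0.208
  expect_lt(abs(mean(attr(s2, "cure_status")) - closed2), 0.005)
})

test_that("cured subjects are never events", {
  sc <- phmc_scenario(cens_upper = 16)
  s <- gen_phmc(5000, sc, seed = 103)
  cured <- attr(s, "cure_status") == 1
  expect_true(all(s$status[cured] == 0))
  sp <- phph_scenario(cens_upper = 3)
  s2 <- gen_phph(5000, sp, seed = 104)
  expect_true(all(s2$status[attr(s2, "cure_status") == 1] == 0))
})

test_that("null latency effects give exponential susceptible times", {
  sc <- phmc_scenario(alpha0 = 20, beta = c(0, 0), cens_upper = 1e6)
  s <- gen_phmc(2e4, sc, seed = 105)   # essentially everyone susceptible
  ks <- suppressWarnings(stats::ks.test(s$time[s$status == 1],
                                        stats::pexp, rate = 1 / 3))
  expect_gt(ks$p.value, 0.01)
})

test_that("censoring calibration is reproducible and hits its target", {
  sc <- phmc_scenario()
  c1 <- calibrate_censoring(sc, seed = 42)
  c2 <- calibrate_censoring(sc, seed = 42)
  expect_identical(c1, c2)
  # achieved fraction of susceptible subjects censored is near 10%
  sc$cens_upper <- c1
  s <- gen_phmc(2e5, sc, seed = 106)
  susc <- attr(s, "cure_status") == 0
  expect_lt(abs(mean(s$status[susc] == 0) - 0.10), 0.01)
  # the alternative measure is exposed and smaller here
  c_alt <- calibrate_censoring(sc, target = 0.10,
                               measure = "susceptible_among_censored",
                               seed = 42)
  expect_true(c_alt > c1)
  expect_error(calibrate_censoring(sc, target = 0.9,
                                   measure = "susceptible_among_censored",
                                   seed = 1),
               "unattainable")
})

test_that("the promotion-time generator reproduces its improper survival law", {
  # fixed covariate profile: S(t) = exp(-theta (1 - exp(-2t)^eta))
  sp <- phph_scenario(rXZ = function(n)
    list(X = cbind(X1 = rep(1, n)), Z = cbind(X1 = rep(1, n), X2 = 0.5)),
    cens_upper = 1e6)
  s <- gen_phph(1e5, sp, seed = 107)
  theta <- exp(0.5 - 0.1)
  eta <- exp(0.4 - 0.3 * 0.5)
  tg <- seq(0.1, 3, by = 0.1)
  emp <- vapply(tg, function(t) mean(s$time > t | s$status == 0 &
                                       attr(s, "cure_status") == 1),
                numeric(1))
  # survival of the latent T (cured subjects never fail)
  lat <- ifelse(attr(s, "cure_status") == 1, Inf, s$time)
  emp <- vapply(tg, function(t) mean(lat > t), numeric(1))
  truth <- exp(-theta * (1 - exp(-2 * tg)^eta))
  expect_lt(max(abs(emp - truth)), 0.01)
})

test_that("Monte Carlo studies are deterministic and well-formed", {
  sc <- phmc_scenario(cens_upper = 16)
  r1 <- run_mc_study(sc, n = 120, replicates = 3,
                     estimators = "incidence_km", H = 4, seed = 9)
  r2 <- run_mc_study(sc, n = 120, replicates = 3,
                     estimators = "incidence_km", H = 4, seed = 9)
  expect_identical(r1$table, r2$table)
  expect_named(r1$table,
               c("estimator", "coef", "truth", "bias", "ese", "see", "cr"))
  expect_true(all(r1$table$ese >= 0))
  expect_true(all(r1$table$cr >= 0 & r1$table$cr <= 1))
})

test_that("selection scenarios carry the sparse truth and oracle behaves", {
  sc <- phmc_selection_scenario()
  expect_equal(which(sc$alpha != 0), c(2, 3, 6, 7))
  expect_equal(which(sc$beta != 0), c(1, 3, 5, 6))
  sc$cens_upper <- 42
  r <- suppressWarnings(
    run_selection_study(sc, n = 250, replicates = 2,
                        component = "incidence", flavor = "km",
                        methods = c("full", "oracle"), seed = 4))
  tab <- r$table
  expect_equal(tab$tp[tab$method == "oracle"], 4)
  expect_equal(tab$fp[tab$method == "oracle"], 0)
  expect_gte(tab$mse[tab$method == "full"],
             tab$mse[tab$method == "oracle"])
})
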