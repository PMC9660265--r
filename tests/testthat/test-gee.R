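test_that("links and their inverses are mutually consistent", {
  grid <- seq(0.01, 0.99, by = 0.07)
  for (nm in c("logit", "cloglog")) {
    ln <- link_function(nm)
    expect_equal(ln$g(ln$ginv(ln$g(grid))), ln$g(grid), tolerance = 1e-10)
  }
  ln <- link_function("log")
  expect_equal(ln$ginv(ln$g(grid)), grid, tolerance = 1e-12)
  # cloglog is the survival-type complementary log-log
  expect_equal(link_function("cloglog")$ginv(0), exp(-1))
})

test_that("logit GEE on grouped 0/1 data equals closed-form log odds", {
  y <- c(1, 1, 1, 0, 1, 0, 0, 0)
  x <- rep(c(1, 0), each = 4)
  f <- solve_gee(matrix(y), design = cbind(x = x), link = "logit")
  expect_equal(unname(coef(f)),
               c(stats::qlogis(0.25), 2 * log(3)), tolerance = 1e-8)
  expect_true(f$converged)

  # symmetric groups: exact zero coefficients
  f0 <- solve_gee(matrix(c(1, 0, 1, 0)), design = cbind(x = c(1, 1, 0, 0)),
                  link = "logit")
  expect_equal(unname(coef(f0)), c(0, 0), tolerance = 1e-8)
})

test_that("intercept-only log-link fit returns the log mean", {
  f <- solve_gee(matrix(rep(2.5, 20)), link = "log")
  expect_equal(unname(coef(f)), log(2.5), tolerance = 1e-10)
  # zero residuals -> zero sandwich and jackknife variance
  expect_equal(max(abs(f$vcov_sandwich)), 0, tolerance = 1e-18)
  expect_equal(max(abs(f$vcov_jackknife)), 0, tolerance = 1e-18)
})

test_that("identity-link sandwich equals heteroskedasticity-robust OLS", {
  set.seed(42)
  n <- 40
  x <- rnorm(n)
  y <- 1 + 2 * x + rnorm(n) * (1 + abs(x))
  f <- solve_gee(matrix(y), cbind(x = x), link = "identity")
  lmfit <- stats::lm(y ~ x)
  expect_equal(unname(coef(f)), unname(stats::coef(lmfit)), tolerance = 1e-8)
  X <- cbind(1, x)
  r <- stats::resid(lmfit)
  hc0 <- solve(crossprod(X)) %*% crossprod(X * r) %*% solve(crossprod(X))
  expect_equal(unname(f$vcov_sandwich), unname(hc0), tolerance = 1e-6)
})

test_that("covariances are symmetric PSD and solutions ignore duplication", {
  set.seed(7)
  for (rep in 1:3) {
    n <- 30
    x <- matrix(rnorm(2 * n), n, 2)
    y <- matrix(plogis(x[, 1]) + rnorm(n, 0, 0.2))
    f <- solve_gee(y, x, "logit")
    for (V in list(f$vcov_sandwich, f$vcov_jackknife)) {
      expect_equal(V, t(V))
      expect_true(all(eigen(V, symmetric = TRUE)$values > -1e-12))
    }
    # duplicating every subject leaves the estimating equation's root alone
    f2 <- solve_gee(rbind(y, y), rbind(x, x), "logit")
    expect_equal(coef(f2), coef(f), tolerance = 1e-7)
  }
})

test_that("exchangeable and AR1 collapse to independence when H = 1", {
  set.seed(3)
  y <- matrix(rnorm(25, 0.5, 0.2))
  x <- matrix(rnorm(25))
  fi <- solve_gee(y, x, "logit", corr = "independence")
  fe <- solve_gee(y, x, "logit", corr = "exchangeable")
  fa <- solve_gee(y, x, "logit", corr = "ar1")
  expect_equal(coef(fe), coef(fi), tolerance = 1e-10)
  expect_equal(coef(fa), coef(fi), tolerance = 1e-10)
})

test_that("moment estimators recover dispersion and exchangeable correlation", {
  # two-cluster hand fixture, identity link, intercept-only:
  # residuals are known once the mean is fitted
  y <- rbind(c(1, 3), c(3, 5))     # mean 3, residuals (-2,0) and (0,2)
  f <- solve_gee(y, link = "identity", corr = "exchangeable")
  expect_equal(unname(coef(f)), 3, tolerance = 1e-9)
  # dispersion: sum r^2 / (N - k) = 8/3
  expect_equal(f$dispersion, 8 / 3, tolerance = 1e-8)
  # exchangeable rho: sum_i r_i1 r_i2 / phi / (n*H(H-1)/2 - k)
  expect_equal(f$rho, 0 / (8 / 3), tolerance = 1e-8)
})

test_that("one-step jackknife tracks the fully iterated jackknife", {
  # linear estimating equations: the one-step deletion is exact, so the
  # approximate jackknife must coincide with full leave-one-out refitting
  set.seed(9)
  n <- 50
  x <- matrix(rnorm(n))
  y <- matrix(1 + 2 * x + rnorm(n, 0, 0.5))
  f <- solve_gee(y, x, "identity")
  k <- f$k
  psis <- t(vapply(seq_len(n), function(i)
    coef(solve_gee(y[-i, , drop = FALSE], x[-i, , drop = FALSE], "identity")),
    numeric(k)))
  dc <- sweep(psis, 2, colMeans(psis))
  vfull <- ((n - k) / n) * crossprod(dc)
  rel <- norm(f$vcov_jackknife - vfull, "F") / norm(vfull, "F")
  expect_lt(rel, 1e-3)

  # deleting a zero-residual cluster moves nothing
  y0 <- matrix(plogis(0.3 + c(-1, 0, 1, 2)))
  f0 <- solve_gee(y0, cbind(x = c(-1, 0, 1, 2)), "logit")
  expect_equal(max(abs(f0$vcov_jackknife)), 0, tolerance = 1e-12)

  # nonlinear link at larger n: jackknife and sandwich agree to ~10%
  set.seed(10)
  n <- 500
  x <- matrix(rnorm(n))
  y <- matrix(plogis(0.5 + x) + rnorm(n, 0, 0.25))
  fl <- solve_gee(y, x, "logit")
  expect_equal(fl$vcov_jackknife, fl$vcov_sandwich, tolerance = 0.1)
})

test_that("rank-deficient designs are rejected", {
  y <- matrix(rnorm(10))
  x <- cbind(1, rnorm(10))     # duplicates the intercept
  expect_error(solve_gee(y, cbind(x, x[, 1]), "identity"), "rank deficient")
})
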