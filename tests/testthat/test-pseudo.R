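test_that("pseudo-observations of linear statistics reproduce the data", {
  s <- survival_sample(c(1, 2, 3), c(1, 0, 1))
  expect_equal(as.vector(jackknife_pseudo(function(x) mean(x$time), s)$values),
               c(1, 2, 3))
  expect_equal(as.vector(jackknife_pseudo(function(x) 5, s)$values),
               rep(5, 3))
})

test_that("uncured-rate pseudo-observations match hand leave-one-out values", {
  s <- survival_sample(c(1, 2, 3), c(1, 0, 1))
  po <- pseudo_pi_km(s)
  expect_equal(as.vector(po$values), c(1, 1, 2))  # outside [0,1] is expected
  expect_equal(po$full_estimate, 1)

  # no censoring: every leave-one-out plateau is zero
  s2 <- survival_sample(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(as.vector(pseudo_pi_km(s2)$values), rep(1, 4))
})

test_that("degenerate subsamples error with the subject index, or drop on request", {
  s <- survival_sample(c(1, 2), c(1, 0))
  expect_error(pseudo_pi_km(s), "subject 1")
  expect_warning(po <- pseudo_pi_km(s, on_degenerate = "drop"), "dropped")
  expect_equal(po$dropped, 1L)
  expect_true(is.na(po$values[1, ]))
  expect_false(is.na(po$values[2, ]))
})

test_that("all constructors agree with a brute-force survfit-based oracle", {
  for (seed in c(2, 5, 8)) {
    s <- rand_sample(8, seed)
    grid <- sort(s$time[s$status == 1])[1:2] + 1e-9

    expect_equal(pseudo_pi_km(s)$values,
                 brute_force_pseudo(oracle_pi_km, s), tolerance = 1e-10)
    expect_equal(pseudo_su(s, grid)$values,
                 brute_force_pseudo(function(x) oracle_su(x, grid), s),
                 tolerance = 1e-10)
    expect_equal(pseudo_theta_km(s)$values,
                 brute_force_pseudo(oracle_theta_km, s), tolerance = 1e-10)
    expect_equal(pseudo_F_km(s, grid)$values,
                 brute_force_pseudo(function(x) oracle_F_km(x, grid), s),
                 tolerance = 1e-10)
    # NP-flavored constructors against a literal refit of theta_np itself
    expect_equal(pseudo_theta_np(s)$values,
                 brute_force_pseudo(function(x) theta_np(x)$theta, s),
                 tolerance = 1e-10)
    expect_equal(pseudo_pi_np(s)$values,
                 brute_force_pseudo(function(x) 1 - exp(-theta_np(x)$theta), s),
                 tolerance = 1e-10)
    expect_equal(pseudo_F_np(s, grid)$values,
                 brute_force_pseudo(function(x) F_np(theta_np(x), grid), s),
                 tolerance = 1e-10)
  }
})

test_that("column means obey the jackknife bias-correction identity", {
  s <- rand_sample(10, 3)
  grid <- stats::median(s$time[s$status == 1])
  po <- pseudo_su(s, grid)
  loo <- vapply(seq_len(s$n), function(i)
    su_km(fit_km(survival_sample(s$time[-i], s$status[-i])), grid),
    numeric(1))
  expect_equal(mean(po$values),
               s$n * po$full_estimate - (s$n - 1) * mean(loo))
})

test_that("the jackknife does not commute with nonlinear maps", {
  # extra trailing censoring so every leave-one-out plateau stays positive
  s <- survival_sample(c(1, 2, 3, 4, 4.5), c(1, 0, 1, 0, 0))
  pi_po <- pseudo_pi_km(s)$values
  th_po <- pseudo_theta_km(s)$values
  expect_false(isTRUE(all.equal(pi_po, 1 - exp(-th_po))))
})

test_that("pseudo-observation construction is deterministic", {
  s <- rand_sample(9, 11)
  expect_identical(pseudo_pi_np(s), pseudo_pi_np(s))
})

test_that("fixed-tmax evaluation differs only in where the plateau is read", {
  s <- rand_sample(10, 4)
  a <- pseudo_pi_km(s, tmax_rule = "subsample")
  b <- pseudo_pi_km(s, tmax_rule = "full")
  expect_equal(dim(a$values), dim(b$values))
  # subjects whose removal does not change tmax get identical rows
  tmax <- fit_km(s)$tmax
  unaffected <- which(s$time < tmax)
  expect_equal(a$values[unaffected, ], b$values[unaffected, ])
})

test_that("pseudo matrices export tidily", {
  s <- rand_sample(6, 6)
  grid <- sort(unique(s$time[s$status == 1]))[1:2]
  df <- as.data.frame(pseudo_su(s, grid))
  expect_equal(nrow(df), 6 * 2)
  expect_named(df, c("subject", "time", "value", "target"))
  expect_equal(unique(df$target), "su_km")
})
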