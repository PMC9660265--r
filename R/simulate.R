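#' Mixture-cure (PHMC) simulation scenario
#'
#' Describes a data-generating mechanism with logistic incidence and a
#' constant-baseline Cox latency: cure status
#' \eqn{Y \sim \mathrm{Bern}\{\mathrm{expit}(\alpha_0 + \alpha^\top X)\}},
#' susceptible event times with hazard
#' \eqn{\lambda_0 \exp(\beta^\top Z)}, cured subjects never failing, and
#' censoring \eqn{C \sim \mathrm{Unif}(0, c)}.
#'
#' The default covariate laws are one Bernoulli(0.5) incidence covariate
#' and latency covariates (Bernoulli(0.5), Uniform(0,1)); the default
#' coefficients \eqn{\alpha_0 = 2}, \eqn{\alpha = -1} give an average cure
#' rate of 20%.
#'
#' @param alpha0,alpha Incidence intercept and slopes.
#' @param beta Latency slopes.
#' @param lambda0 Constant baseline hazard, default 1/3.
#' @param rX,rZ Covariate samplers, `function(n)` returning a matrix.
#'   `rZ = NULL` means the latency block reuses `X`.
#' @param cens_upper Upper bound \eqn{c} of the uniform censoring law;
#'   leave `NULL` to have it calibrated by [calibrate_censoring()].
#' @param target Calibration target passed to [calibrate_censoring()]
#'   (default 0.10).
#' @param label Free-text scenario label.
#' @return An object of class `"phmc_scenario"`.
#' @export
phmc_scenario <- function(alpha0 = 2, alpha = -1, beta = c(1, 0.5),
                          lambda0 = 1 / 3,
                          rX = function(n) cbind(X1 = stats::rbinom(n, 1, 0.5)),
                          rZ = function(n) cbind(Z1 = stats::rbinom(n, 1, 0.5),
                                                 Z2 = stats::runif(n)),
                          cens_upper = NULL, target = 0.10,
                          label = "phmc") {
  structure(list(alpha0 = alpha0, alpha = alpha, beta = beta,
                 lambda0 = lambda0, rX = rX, rZ = rZ,
                 cens_upper = cens_upper, target = target, label = label),
            class = "phmc_scenario")
}

#' Promotion-time (PHPH) simulation scenario
#'
#' Describes the bounded-cumulative-hazard generator
#' \eqn{S(t \mid X, Z) = \exp[-\theta(X)\{1 - \bar F(t)^{\eta(Z)}\}]} with
#' \eqn{\theta(X) = \exp(\gamma_0 + \gamma^\top X)},
#' \eqn{\eta(Z) = \exp(\phi^\top Z)} and exponential baseline
#' \eqn{\bar F(x) = \exp(-\kappa x)}.  Cure probability is
#' \eqn{\exp\{-\theta(X)\}}.
#'
#' The defaults (\eqn{\gamma_0 = 0.5}, \eqn{\gamma_1 = -0.1},
#' \eqn{\phi = (0.4, -0.3)}, \eqn{\kappa = 2}, covariates Bernoulli(0.5)
#' and standard normal with the Bernoulli shared between blocks) give an
#' average cure rate near 20%.
#'
#' @param gamma0,gamma Long-term intercept and slopes.
#' @param phi Short-term slopes (no intercept).
#' @param kappa Baseline rate of \eqn{\bar F(x) = e^{-\kappa x}},
#'   default 2.
#' @param rXZ Sampler `function(n)` returning a list with matrices `X`
#'   (long-term block) and `Z` (short-term block).
#' @inheritParams phmc_scenario
#' @return An object of class `"phph_scenario"`.
#' @export
phph_scenario <- function(gamma0 = 0.5, gamma = -0.1, phi = c(0.4, -0.3),
                          kappa = 2,
                          rXZ = function(n) {
                            x1 <- stats::rbinom(n, 1, 0.5)
                            x2 <- stats::rnorm(n)
                            list(X = cbind(X1 = x1),
                                 Z = cbind(X1 = x1, X2 = x2))
                          },
                          cens_upper = NULL, target = 0.10,
                          label = "phph") {
  structure(list(gamma0 = gamma0, gamma = gamma, phi = phi, kappa = kappa,
                 rXZ = rXZ, cens_upper = cens_upper, target = target,
                 label = label),
            class = "phph_scenario")
}

# Latent draws shared by the generator and the censoring calibration:
# cure status, susceptible failure time, and the uniform used for C.
phmc_latent <- function(n, sc) {
  X <- sc$rX(n)
  Z <- if (is.null(sc$rZ)) X else sc$rZ(n)
  pY <- stats::plogis(sc$alpha0 + as.vector(X %*% sc$alpha))
  Y <- stats::rbinom(n, 1, pY)
  tstar <- -log(stats::runif(n)) / (sc$lambda0 * exp(as.vector(Z %*% sc$beta)))
  list(X = X, Z = Z, Y = Y, tstar = tstar, u_cens = stats::runif(n))
}

phph_latent <- function(n, sc) {
  cov <- sc$rXZ(n)
  theta <- exp(sc$gamma0 + as.vector(cov$X %*% sc$gamma))
  eta <- exp(as.vector(cov$Z %*% sc$phi))
  Y <- stats::rbinom(n, 1, 1 - exp(-theta))
  u <- stats::runif(n)
  inner <- 1 + log(1 - u * (1 - exp(-theta))) / theta
  stopifnot(all(inner > 0))   # holds analytically since u < 1
  tstar <- -log(inner) / (sc$kappa * eta)
  list(X = cov$X, Z = cov$Z, Y = Y, tstar = tstar, u_cens = stats::runif(n))
}

scenario_latent <- function(scenario, n) {
  if (inherits(scenario, "phmc_scenario")) phmc_latent(n, scenario)
  else if (inherits(scenario, "phph_scenario")) phph_latent(n, scenario)
  else stop("unknown scenario class")
}

latent_to_sample <- function(lat, cens_upper) {
  t_true <- ifelse(lat$Y == 1, lat$tstar, Inf)  # cured never fail
  C <- cens_upper * lat$u_cens
  time <- pmin(t_true, C)
  status <- as.numeric(t_true <= C)
  s <- survival_sample(time, status, X = lat$X, Z = lat$Z)
  attr(s, "cure_status") <- 1 - lat$Y
  s
}

#' Generate a mixture-cure sample
#'
#' Draws `n` subjects from a [phmc_scenario()].  Cured subjects have
#' infinite latent failure time and are always censored.
#'
#' @param n Sample size.
#' @param scenario A [phmc_scenario()] with `cens_upper` set (run
#'   [calibrate_censoring()] first if needed).
#' @param seed Optional integer seed (applied via [set.seed()]).
#' @return A [survival_sample()] with the true cure status attached as
#'   attribute `"cure_status"`.
#' @export
gen_phmc <- function(n, scenario = phmc_scenario(), seed = NULL) {
  stopifnot(inherits(scenario, "phmc_scenario"))
  if (is.null(scenario$cens_upper) || scenario$cens_upper <= 0)
    stop("scenario$cens_upper must be positive; calibrate it first")
  if (!is.null(seed)) set.seed(seed)
  latent_to_sample(phmc_latent(n, scenario), scenario$cens_upper)
}

#' Generate a promotion-time sample
#'
#' Draws `n` subjects from a [phph_scenario()] using the mixture
#' representation of the bounded-cumulative-hazard model: cure with
#' probability \eqn{\exp\{-\theta(X)\}}, and susceptible times by
#' inverting the conditional distribution
#' \eqn{F_u(t) = [1 - \exp\{-\theta(1 - \bar F(t)^\eta)\}] /
#' (1 - e^{-\theta})}, which has the closed-form inverse
#' \eqn{t = -\log[1 + \log\{1 - U(1 - e^{-\theta})\}/\theta] / (\kappa\eta)}.
#'
#' @inheritParams gen_phmc
#' @param scenario A [phph_scenario()] with `cens_upper` set.
#' @export
gen_phph <- function(n, scenario = phph_scenario(), seed = NULL) {
  stopifnot(inherits(scenario, "phph_scenario"))
  if (is.null(scenario$cens_upper) || scenario$cens_upper <= 0)
    stop("scenario$cens_upper must be positive; calibrate it first")
  if (!is.null(seed)) set.seed(seed)
  latent_to_sample(phph_latent(n, scenario), scenario$cens_upper)
}

#' Calibrate the uniform censoring bound
#'
#' Chooses the upper bound \eqn{c} of the \eqn{\mathrm{Unif}(0, c)}
#' censoring law by bisection over a fixed Monte Carlo draw of latent
#' outcomes, so the result is deterministic given the seed.  The target is
#' expressed, by default, as the fraction of *susceptible* subjects that
#' end up censored (10% reproduces the reference scenarios' overall
#' censoring labels: about 30% under 20% cure, about 50% under 40% cure).
#' The alternative measure -- the fraction of *censored* subjects that are
#' susceptible -- is available for sensitivity analyses.
#'
#' @param scenario A [phmc_scenario()] or [phph_scenario()].
#' @param target Target fraction; default `scenario$target`.
#' @param measure Which conditional fraction to match (see above).
#' @param n Monte Carlo size, default 2e5.
#' @param seed Seed for the latent draw, default 1.
#' @param tol Tolerance on the achieved fraction, default 0.002.
#' @return The calibrated bound `c` (a scalar).
#' @export
calibrate_censoring <- function(scenario, target = scenario$target,
                                measure = c("censored_among_susceptible",
                                            "susceptible_among_censored"),
                                n = 2e5, seed = 1, tol = 0.002) {
  measure <- match.arg(measure)
  stopifnot(target > 0, target < 1)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
  set.seed(seed)
  lat <- scenario_latent(scenario, n)
  susc <- lat$Y == 1
  frac <- function(cc) {
    cens_susc <- susc & (cc * lat$u_cens < lat$tstar)
    if (measure == "censored_among_susceptible") {
      mean(cens_susc[susc])
    } else {
      n_cens <- sum(!susc) + sum(cens_susc)
      sum(cens_susc) / n_cens
    }
  }
  # frac is nonincreasing in c (per-subject censoring indicators only
  # switch off as c grows); bracket then bisect
  lo <- 1e-6
  hi <- 1
  f_lo <- frac(lo)
  if (f_lo < target - tol)
    stop(sprintf("target %.3f unattainable: fraction at c ~ 0 is %.3f",
                 target, f_lo))
  while (frac(hi) > target && hi < 1e6) hi <- hi * 2
  if (hi >= 1e6)
    stop(sprintf("target %.3f unattainable: fraction at c = %g is %.3f",
                 target, hi, frac(hi)))
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    fm <- frac(mid)
    if (abs(fm - target) < tol) return(mid)
    if (fm > target) lo <- mid else hi <- mid
    if (hi - lo < 1e-9 * max(1, hi)) break
  }
  (lo + hi) / 2
}

# Resolve the censoring bound, calibrating on demand.
ensure_calibrated <- function(scenario, seed) {
  if (is.null(scenario$cens_upper))
    scenario$cens_upper <- calibrate_censoring(scenario, seed = seed)
  scenario
}

# Truth lookup per estimator label.
estimator_truth <- function(scenario, estimator) {
  if (inherits(scenario, "phmc_scenario")) {
    switch(estimator,
      incidence_km = , incidence_np = c(alpha0 = scenario$alpha0,
                                        alpha = scenario$alpha),
      latency = c(beta = scenario$beta),
      stop("unknown estimator for a PHMC scenario: ", estimator))
  } else {
    switch(estimator,
      long_km = , long_np = c(gamma0 = scenario$gamma0,
                              gamma = scenario$gamma),
      short_km = , short_np = c(phi = scenario$phi),
      stop("unknown estimator for a PHPH scenario: ", estimator))
  }
}

fit_estimator <- function(sample, estimator, H, corr) {
  switch(estimator,
    incidence_km = fit_phmc_incidence(sample, "km", corr),
    incidence_np = fit_phmc_incidence(sample, "np", corr),
    latency = fit_phmc_latency(sample, make_grid(sample, H), corr),
    long_km = fit_phph_long(sample, "km", corr),
    long_np = fit_phph_long(sample, "np", corr),
    short_km = fit_phph_short(sample, make_grid(sample, H), "km", corr),
    short_np = fit_phph_short(sample, make_grid(sample, H), "np", corr))
}

# Slopes of interest (drop time-dummy blocks; keep global intercepts for
# the scalar components, which are part of the reported truth).
report_coefs <- function(fit) {
  co <- coef(fit)
  se <- sqrt(pmax(diag(fit$vcov_jackknife), 0))
  if (fit$intercept == "time") {
    idx <- seq_len(fit$n_intercept)
    co <- co[-idx]; se <- se[-idx]
  }
  list(est = co, se = se)
}

#' Monte Carlo study of the pseudo-observation estimators
#'
#' Replicates a scenario, fits the requested cure-model components per
#' replicate, and aggregates the usual frequentist summaries per
#' coefficient: average bias (Bias), empirical standard error (ESE),
#' average of the jackknife standard error estimator (SEE), and empirical
#' coverage (CR) of the Wald interval at level `conf`.
#'
#' @param scenario A [phmc_scenario()] or [phph_scenario()]; an
#'   uncalibrated `cens_upper` is calibrated first.
#' @param n Sample size per replicate.
#' @param replicates Number of replicates.
#' @param estimators Character vector of component fitters: for PHMC
#'   scenarios any of `"incidence_km"`, `"incidence_np"`, `"latency"`;
#'   for PHPH scenarios `"long_km"`, `"long_np"`, `"short_km"`,
#'   `"short_np"`.
#' @param H Grid size for the time-indexed components, default 10.
#' @param corr Working correlation.
#' @param seed Root seed; each replicate gets its own derived seed.
#' @param conf Wald confidence level, default 0.95.
#' @return An object of class `"sim_report"`: list with `table` (one row
#'   per estimator x coefficient: truth, bias, ese, see, cr), `estimates`
#'   (per-replicate estimates, a matrix per estimator), `n_fail`,
#'   `replicates`, `n`, `seed`, `scenario_label`, `cens_upper`.
#' @export
run_mc_study <- function(scenario, n, replicates = 500,
                         estimators = c("incidence_np", "latency"),
                         H = 10, corr = "independence", seed = 1,
                         conf = 0.95) {
  scenario <- ensure_calibrated(scenario, seed)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, replicates)
  zc <- stats::qnorm(1 - (1 - conf) / 2)
  est_list <- se_list <- stats::setNames(
    vector("list", length(estimators)), estimators)
  n_fail <- 0L
  for (r in seq_len(replicates)) {
    smp <- tryCatch({
      if (inherits(scenario, "phmc_scenario"))
        gen_phmc(n, scenario, seed = rep_seeds[r])
      else gen_phph(n, scenario, seed = rep_seeds[r])
    }, error = identity)
    fits <- tryCatch(
      withCallingHandlers(
        lapply(estimators, function(e)
          report_coefs(fit_estimator(smp, e, H, corr))),
        warning = function(w) invokeRestart("muffleWarning")),
      error = identity)
    if (inherits(smp, "error") || inherits(fits, "error")) {
      n_fail <- n_fail + 1L
      next
    }
    for (j in seq_along(estimators)) {
      est_list[[j]] <- rbind(est_list[[j]], fits[[j]]$est)
      se_list[[j]] <- rbind(se_list[[j]], fits[[j]]$se)
    }
  }
  if (n_fail > 0)
    message(sprintf("%d of %d replicates failed and were excluded",
                    n_fail, replicates))
  rows <- list()
  for (e in estimators) {
    truth <- estimator_truth(scenario, e)
    est <- est_list[[e]]
    se <- se_list[[e]]
    if (is.null(est)) next
    for (j in seq_along(truth)) {
      cover <- mean(abs(est[, j] - truth[j]) <= zc * se[, j])
      rows[[length(rows) + 1L]] <- data.frame(
        estimator = e, coef = colnames(est)[j] %||% names(truth)[j],
        truth = truth[j], bias = mean(est[, j]) - truth[j],
        ese = stats::sd(est[, j]), see = mean(se[, j]), cr = cover)
    }
  }
  structure(list(table = do.call(rbind, rows), estimates = est_list,
                 ses = se_list, n_fail = n_fail,
                 replicates = replicates, n = n, seed = seed,
                 scenario_label = scenario$label,
                 cens_upper = scenario$cens_upper),
            class = "sim_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sim_report <- function(x, ...) {
  cat(sprintf("Monte Carlo study '%s': n = %d, %d replicates (%d failed)\n",
              x$scenario_label, x$n, x$replicates, x$n_fail))
  df <- x$table
  df[, c("truth", "bias", "ese", "see", "cr")] <-
    round(df[, c("truth", "bias", "ese", "see", "cr")], 3)
  print(df, row.names = FALSE)
  invisible(x)
}

# AR(rho^|i-j|) multivariate normal sampler.
rmvnorm_ar <- function(n, d, rho = 0.5) {
  S <- rho^abs(outer(seq_len(d), seq_len(d), "-"))
  matrix(stats::rnorm(n * d), n, d) %*% chol(S)
}

selection_covariates <- function(n) {
  M <- cbind(stats::runif(n), stats::runif(n),
             stats::rbinom(n, 1, 0.5), stats::rbinom(n, 1, 0.5),
             rmvnorm_ar(n, 16, 0.5))
  colnames(M) <- paste0("X", 1:20)
  M
}

#' Sparse 20-covariate selection scenarios
#'
#' The variable-selection study designs: 20 covariates (two Uniform(0,1),
#' two Bernoulli(0.5), and a 16-dimensional normal block with
#' autoregressive correlation \eqn{0.5^{|i-j|}}) shared by both model
#' components, with sparse truth vectors (four nonzero coefficients per
#' component) and about 30% cure.
#'
#' @param target Calibration target for [calibrate_censoring()]
#'   (0.10 or 0.30 give roughly 40% and 60% overall censoring).
#' @return A [phmc_scenario()] (resp. [phph_scenario()]) with the sparse
#'   coefficient vectors.
#' @export
phmc_selection_scenario <- function(target = 0.10) {
  phmc_scenario(
    alpha0 = 1.1,
    alpha = c(0, 1, -1.2, 0, 0, -0.9, 0.8, rep(0, 13)),
    beta = c(-0.7, 0, 1, 0, -0.5, 0.8, rep(0, 14)),
    lambda0 = 1 / 3,
    rX = selection_covariates, rZ = NULL,   # latency reuses X
    target = target, label = "phmc_selection")
}

#' @rdname phmc_selection_scenario
#' @export
phph_selection_scenario <- function(target = 0.10) {
  phph_scenario(
    gamma0 = 0.85,
    gamma = c(0, 0, -0.9, 0, 0, -0.7, 0, 1, rep(0, 12)),
    phi = c(-0.5, 0, 0.8, 0, -0.7, rep(0, 15)),
    kappa = 2,
    rXZ = function(n) {
      M <- selection_covariates(n)
      list(X = M, Z = M)
    },
    target = target, label = "phph_selection")
}

#' Monte Carlo study of SCAD variable selection
#'
#' Replicates a sparse selection scenario and, per replicate, fits the
#' full unpenalized GEE, the oracle GEE (true support only), and the
#' SCAD-penalized GEE with cross-validated tuning, then aggregates MSE /
#' TP / FP per method via [selection_metrics()].
#'
#' @param scenario A [phmc_selection_scenario()] /
#'   [phph_selection_scenario()] (any scenario with sparse truth works).
#' @param n Sample size per replicate.
#' @param replicates Number of replicates.
#' @param component Which component to select on: `"incidence"`,
#'   `"latency"`, `"long_term"`, or `"short_term"`.
#' @param methods Subset of `c("full", "oracle", "scad")`.
#' @param flavor Pseudo-observation flavor where applicable.
#' @param H Grid size for time-indexed components.
#' @param corr Working correlation.
#' @param seed Root seed.
#' @param nlambda,K,lambda_min_ratio Passed to [cv_select()].
#' @return An object of class `"selection_report"`: list with `table`
#'   (method x (mse, tp, fp)), `estimates`, `n_fail`, metadata.
#' @export
run_selection_study <- function(scenario, n, replicates = 20,
                                component = "incidence",
                                methods = c("full", "oracle", "scad"),
                                flavor = "np", H = 10,
                                corr = "independence", seed = 1,
                                nlambda = 30, K = 5,
                                lambda_min_ratio = 0.01) {
  scenario <- ensure_calibrated(scenario, seed)
  truth <- switch(component,
    incidence = scenario$alpha, latency = scenario$beta,
    long_term = scenario$gamma, short_term = scenario$phi)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, replicates)
  link <- switch(component, incidence = "logit", latency = "cloglog",
                 long_term = "log", short_term = "cloglog")
  intercept <- if (component %in% c("latency", "short_term")) "time"
               else "global"
  est <- lapply(stats::setNames(methods, methods), function(m) NULL)
  n_fail <- 0L
  for (r in seq_len(replicates)) {
    out <- tryCatch({
      smp <- if (inherits(scenario, "phmc_scenario"))
        gen_phmc(n, scenario, seed = rep_seeds[r])
      else gen_phph(n, scenario, seed = rep_seeds[r])
      grid <- if (intercept == "time") make_grid(smp, H)
      po <- switch(component,
        incidence = if (flavor == "km") pseudo_pi_km(smp)
                    else pseudo_pi_np(smp),
        latency = pseudo_su(smp, grid$times),
        long_term = if (flavor == "km") pseudo_theta_km(smp)
                    else pseudo_theta_np(smp),
        short_term = {
          p <- if (flavor == "km") pseudo_F_km(smp, grid$times)
               else pseudo_F_np(smp, grid$times)
          p$values <- 1 - p$values
          p
        })
      design <- if (component %in% c("incidence", "long_term")) smp$X
                else smp$Z
      one <- list()
      if ("full" %in% methods) {
        f <- solve_gee(po, design, link, corr, intercept = intercept)
        one$full <- slopes_only(coef(f), intercept, ncol(po$values))
      }
      if ("oracle" %in% methods) {
        supp <- which(truth != 0)
        f <- solve_gee(po, design[, supp, drop = FALSE], link, corr,
                       intercept = intercept)
        v <- numeric(length(truth))
        v[supp] <- slopes_only(coef(f), intercept, ncol(po$values))
        one$oracle <- v
      }
      if ("scad" %in% methods) {
        f <- cv_select(po, design, link, corr, intercept = intercept,
                       nlambda = nlambda, K = K,
                       lambda_min_ratio = lambda_min_ratio)
        one$scad <- slopes_only(coef(f), intercept, ncol(po$values))
      }
      one
    }, error = identity)
    if (inherits(out, "error")) { n_fail <- n_fail + 1L; next }
    for (m in names(out)) est[[m]] <- rbind(est[[m]], out[[m]])
  }
  if (n_fail > 0)
    message(sprintf("%d of %d replicates failed and were excluded",
                    n_fail, replicates))
  rows <- lapply(methods, function(m) {
    if (is.null(est[[m]])) return(NULL)
    sm <- selection_metrics(est[[m]], truth)
    data.frame(method = m, mse = sm$mse,
               tp = if (m == "full") NA_real_ else sm$tp,
               fp = if (m == "full") NA_real_ else sm$fp,
               n_rep = sm$n_rep)
  })
  structure(list(table = do.call(rbind, rows), estimates = est,
                 truth = truth, component = component, n = n,
                 replicates = replicates, n_fail = n_fail, seed = seed,
                 scenario_label = scenario$label,
                 cens_upper = scenario$cens_upper),
            class = "selection_report")
}

slopes_only <- function(co, intercept, H) {
  n_int <- if (intercept == "time") H else if (intercept == "global") 1L else 0L
  unname(co[setdiff(seq_along(co), seq_len(n_int))])
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("Selection study '%s' (%s): n = %d, %d replicates (%d failed)\n",
              x$scenario_label, x$component, x$n, x$replicates, x$n_fail))
  df <- x$table
  df[, c("mse", "tp", "fp")] <- round(df[, c("mse", "tp", "fp")], 2)
  print(df, row.names = FALSE)
  invisible(x)
}
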