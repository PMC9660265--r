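#' Evaluation time grid from event-time quantiles
#'
#' The latency and short-term components evaluate pseudo-observations at
#' `H` time points taken as interior quantiles of the observed event
#' times: levels \eqn{h/(H+1)}, \eqn{h = 1, \dots, H} (type-7
#' interpolation).  Interior levels avoid the degenerate endpoints 0 and
#' \eqn{t_{max}}.  If fewer than `H` distinct event times exist, all of
#' them are used with a warning.
#'
#' @param sample A [survival_sample()] with at least one event.
#' @param H Number of grid points (default 10).
#' @param levels Optional quantile levels overriding the default
#'   \eqn{h/(H+1)} rule.
#' @return An object of class `"time_grid"`: list with `times` and `H`.
#' @export
make_grid <- function(sample, H = 10, levels = NULL) {
  stopifnot(inherits(sample, "survival_sample"), H >= 1)
  et <- sample$time[sample$status == 1]
  if (!length(et)) stop("no events: cannot build a time grid")
  if (length(unique(et)) < H) {
    warning(sprintf("only %d distinct event times; using all of them",
                    length(unique(et))))
    times <- sort(unique(et))
  } else {
    if (is.null(levels)) levels <- seq_len(H) / (H + 1)
    times <- unique(unname(stats::quantile(et, levels, type = 7)))
  }
  structure(list(times = times, H = length(times)), class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("time grid, H = %d: %s\n", x$H,
              paste(signif(x$times, 4), collapse = ", ")))
  invisible(x)
}

as_grid_times <- function(grid) {
  if (inherits(grid, "time_grid")) grid$times else as.numeric(grid)
}

rename_coefs <- function(fit, int_names, slope_names) {
  nm <- c(int_names, slope_names)
  names(fit$coefficients) <- nm
  dimnames(fit$vcov) <- dimnames(fit$vcov_sandwich) <-
    dimnames(fit$vcov_jackknife) <- list(nm, nm)
  fit
}

#' Incidence component of the mixture cure model
#'
#' Fits the logistic incidence model
#' \eqn{\mathrm{logit}\, P(\mathrm{uncured} \mid X) = \alpha_0 + \alpha^\top X}
#' by a GEE on uncured-rate pseudo-observations ([pseudo_pi_km()] or
#' [pseudo_pi_np()]).
#'
#' @param sample A [survival_sample()] with incidence covariates in `X`.
#' @param flavor `"km"` (Kaplan-Meier plateau, default) or `"np"`
#'   (promotion-time estimator) pseudo-observations.
#' @param corr Working correlation (irrelevant at H = 1, kept for a
#'   uniform signature).
#' @param ... Passed to [solve_gee()].
#' @return A `"gee_fit"` with coefficients `alpha0`, `alpha_*`.
#' @export
fit_phmc_incidence <- function(sample, flavor = c("km", "np"),
                               corr = "independence", ...) {
  flavor <- match.arg(flavor)
  po <- if (flavor == "km") pseudo_pi_km(sample) else pseudo_pi_np(sample)
  fit <- solve_gee(po, design = sample$X, link = "logit", corr = corr,
                   intercept = "global", ...)
  fit <- rename_coefs(fit, "alpha0",
                      if (ncol(sample$X)) paste0("alpha_", colnames(sample$X)))
  fit$component <- "incidence"; fit$flavor <- flavor
  fit
}

#' Latency component of the mixture cure model
#'
#' Fits the conditional (susceptible) survival model
#' \eqn{\log\{-\log S_u(t_h \mid Z)\} = \xi_{t_h} + \beta^\top Z}
#' -- the Cox proportional hazards latency model with
#' \eqn{\xi_{t_h} = \log \Lambda_0(t_h)} -- by a GEE with cloglog link on
#' [pseudo_su()] responses over the time grid.  The design has one
#' intercept per grid time and latency covariates shared across times.
#'
#' @param sample A [survival_sample()] with latency covariates in `Z`.
#' @param grid A [make_grid()] object or numeric vector of times.
#' @param corr Working correlation across grid times.
#' @param ... Passed to [solve_gee()].
#' @return A `"gee_fit"` with coefficients `xi_1..xi_H`, `beta_*`.
#' @export
fit_phmc_latency <- function(sample, grid = make_grid(sample),
                             corr = "independence", ...) {
  times <- as_grid_times(grid)
  po <- pseudo_su(sample, times)
  fit <- solve_gee(po, design = sample$Z, link = "cloglog", corr = corr,
                   intercept = "time", ...)
  fit <- rename_coefs(fit, paste0("xi_", seq_along(times)),
                      if (ncol(sample$Z)) paste0("beta_", colnames(sample$Z)))
  fit$component <- "latency"; fit$grid <- times
  fit
}

#' Long-term component of the promotion-time (PHPH) model
#'
#' Fits \eqn{\log \theta(X) = \gamma_0 + \gamma^\top X} by a GEE with log
#' link on theta pseudo-observations ([pseudo_theta_km()] or
#' [pseudo_theta_np()]).  The implied cure rate is
#' \eqn{\exp\{-\theta(X)\}}.
#'
#' @inheritParams fit_phmc_incidence
#' @return A `"gee_fit"` with coefficients `gamma0`, `gamma_*`.
#' @export
fit_phph_long <- function(sample, flavor = c("km", "np"),
                          corr = "independence", ...) {
  flavor <- match.arg(flavor)
  po <- if (flavor == "km") pseudo_theta_km(sample) else pseudo_theta_np(sample)
  fit <- solve_gee(po, design = sample$X, link = "log", corr = corr,
                   intercept = "global", ...)
  fit <- rename_coefs(fit, "gamma0",
                      if (ncol(sample$X)) paste0("gamma_", colnames(sample$X)))
  fit$component <- "long_term"; fit$flavor <- flavor
  fit
}

#' Short-term component of the promotion-time (PHPH) model
#'
#' Under \eqn{F_i(t) = 1 - \bar F(t)^{\eta(Z_i)}} with
#' \eqn{\eta(Z) = \exp(\phi^\top Z)},
#' \eqn{\log[-\log\{1 - F_i(t)\}] = \varsigma_t + \phi^\top Z_i} with
#' \eqn{\varsigma_t = \log\{-\log \bar F(t)\}}.  Fitted by a GEE with
#' cloglog link on the survival-type responses
#' \eqn{1 - \hat F_i(t_h)} built from [pseudo_F_km()] or [pseudo_F_np()];
#' `phi` carries no intercept beyond the per-time block.
#'
#' @inheritParams fit_phmc_latency
#' @param flavor `"km"` or `"np"` pseudo-observations for \eqn{F(t)}.
#' @return A `"gee_fit"` with coefficients `sigma_1..sigma_H`, `phi_*`.
#' @export
fit_phph_short <- function(sample, grid = make_grid(sample),
                           flavor = c("km", "np"),
                           corr = "independence", ...) {
  flavor <- match.arg(flavor)
  times <- as_grid_times(grid)
  po <- if (flavor == "km") pseudo_F_km(sample, times)
        else pseudo_F_np(sample, times)
  po$values <- 1 - po$values
  po$full_estimate <- 1 - po$full_estimate
  po$target <- paste0("one_minus_", po$target)
  fit <- solve_gee(po, design = sample$Z, link = "cloglog", corr = corr,
                   intercept = "time", ...)
  fit <- rename_coefs(fit, paste0("sigma_", seq_along(times)),
                      if (ncol(sample$Z)) paste0("phi_", colnames(sample$Z)))
  fit$component <- "short_term"; fit$grid <- times; fit$flavor <- flavor
  fit
}

#' Fit the full mixture cure (PHMC) model
#'
#' Convenience wrapper fitting the incidence ([fit_phmc_incidence()]) and
#' latency ([fit_phmc_latency()]) components on the same sample.
#'
#' @inheritParams fit_phmc_incidence
#' @param grid A [make_grid()] object or numeric times for the latency
#'   component; built from the sample by default.
#' @param H Grid size when `grid` is not supplied.
#' @return An object of class `"phmc_fit"` with elements `incidence`,
#'   `latency`, `grid`, `flavor`, `km` (the full-sample Kaplan-Meier
#'   curve).
#' @export
fit_phmc <- function(sample, flavor = c("km", "np"), grid = NULL, H = 10,
                     corr = "independence", ...) {
  flavor <- match.arg(flavor)
  if (is.null(grid)) grid <- make_grid(sample, H)
  structure(list(incidence = fit_phmc_incidence(sample, flavor, corr, ...),
                 latency = fit_phmc_latency(sample, grid, corr, ...),
                 grid = as_grid_times(grid), flavor = flavor,
                 km = fit_km(sample)),
            class = "phmc_fit")
}

#' Fit the full promotion-time (PHPH) model
#'
#' Convenience wrapper fitting the long-term ([fit_phph_long()]) and
#' short-term ([fit_phph_short()]) components on the same sample.
#'
#' @inheritParams fit_phmc
#' @return An object of class `"phph_fit"` with elements `long_term`,
#'   `short_term`, `grid`, `flavor`, `km`.
#' @export
fit_phph <- function(sample, flavor = c("km", "np"), grid = NULL, H = 10,
                     corr = "independence", ...) {
  flavor <- match.arg(flavor)
  if (is.null(grid)) grid <- make_grid(sample, H)
  structure(list(long_term = fit_phph_long(sample, flavor, corr, ...),
                 short_term = fit_phph_short(sample, grid, flavor, corr, ...),
                 grid = as_grid_times(grid), flavor = flavor,
                 km = fit_km(sample)),
            class = "phph_fit")
}

#' @export
print.phmc_fit <- function(x, ...) {
  cat(sprintf("PHMC pseudo-observation fit (%s flavor, H = %d)\n",
              x$flavor, length(x$grid)))
  cat("\nIncidence (logit link):\n"); print(summary(x$incidence)$coefficients)
  cat("\nLatency (cloglog link):\n"); print(summary(x$latency)$coefficients)
  invisible(x)
}

#' @export
print.phph_fit <- function(x, ...) {
  cat(sprintf("PHPH pseudo-observation fit (%s flavor, H = %d)\n",
              x$flavor, length(x$grid)))
  cat("\nLong-term (log link):\n"); print(summary(x$long_term)$coefficients)
  cat("\nShort-term (cloglog link):\n"); print(summary(x$short_term)$coefficients)
  invisible(x)
}

#' Pseudo-residual diagnostics
#'
#' Returns the per-subject (and per-grid-time, where applicable)
#' pseudo-residuals \eqn{y_{ih} - g^{-1}(\hat\eta_{ih})} of a fitted
#' component or of both components of a [fit_phmc()] / [fit_phph()]
#' object.  Plotting these against a covariate should show no trend if the
#' component is well specified.
#'
#' @param fit A `"gee_fit"`, `"phmc_fit"`, or `"phph_fit"`.
#' @param sample Optional [survival_sample()]; when given, covariate
#'   columns are attached for plotting.
#' @return A data frame with columns `component`, `subject`, `time`,
#'   `residual`, plus any covariates.
#' @export
pseudo_residuals <- function(fit, sample = NULL) {
  one <- function(g, component) {
    H <- g$H
    times <- if (!is.null(g$grid)) g$grid else rep(NA_real_, H)
    data.frame(component = component,
               subject = rep(seq_len(nrow(g$residuals)), each = H),
               time = rep(times, nrow(g$residuals)),
               residual = as.vector(t(g$residuals)))
  }
  out <- if (inherits(fit, "gee_fit")) {
    one(fit, if (is.null(fit$component)) "gee" else fit$component)
  } else if (inherits(fit, "phmc_fit")) {
    rbind(one(fit$incidence, "incidence"), one(fit$latency, "latency"))
  } else if (inherits(fit, "phph_fit")) {
    rbind(one(fit$long_term, "long_term"), one(fit$short_term, "short_term"))
  } else stop("unsupported fit object")
  if (!is.null(sample)) {
    covs <- cbind(as.data.frame(sample$X),
                  as.data.frame(sample$Z))
    covs <- covs[, !duplicated(names(covs)), drop = FALSE]
    out <- cbind(out, covs[out$subject, , drop = FALSE])
    rownames(out) <- NULL
  }
  out
}

#' Estimated cure rates for covariate profiles
#'
#' For each covariate profile, reports the mixture-cure estimate
#' \eqn{1 - \mathrm{expit}(\hat\alpha_0 + \hat\alpha^\top x)}, the
#' promotion-time estimate
#' \eqn{\exp\{-\exp(\hat\gamma_0 + \hat\gamma^\top x)\}}, and the
#' model-free Kaplan-Meier benchmark \eqn{\hat S_{KM}(t_{max})}.
#'
#' @param phmc A [fit_phmc()] object or `NULL`.
#' @param phph A [fit_phph()] object or `NULL`.
#' @param profiles Numeric matrix or data frame, one row per profile, with
#'   the incidence covariates in model-column order.
#' @return A data frame with one row per profile.
#' @export
cure_rate_table <- function(phmc = NULL, phph = NULL, profiles) {
  profiles <- as.matrix(profiles)
  out <- as.data.frame(profiles)
  lincomb <- function(co, x) co[1] + as.vector(x %*% co[-1])
  if (!is.null(phmc)) {
    a <- coef(phmc$incidence)
    out$cure_phmc <- 1 - stats::plogis(lincomb(a, profiles))
    out$cure_km <- phmc$km$s_tmax
  }
  if (!is.null(phph)) {
    g <- coef(phph$long_term)
    out$cure_phph <- exp(-exp(lincomb(g, profiles)))
    if (is.null(out$cure_km)) out$cure_km <- phph$km$s_tmax
  }
  out
}
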