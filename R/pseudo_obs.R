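#' Leave-one-out jackknife pseudo-observations
#'
#' Generic pseudo-observation engine.  For a statistic
#' \eqn{\hat\varrho} computed on the full sample and
#' \eqn{\hat\varrho^{-i}} on the sample without subject \eqn{i}, the
#' pseudo-observation of subject \eqn{i} is
#' \deqn{\hat\varrho_i = n\,\hat\varrho - (n-1)\,\hat\varrho^{-i}.}
#' The statistic may be vector-valued (one value per time point of an
#' evaluation grid).  The statistic is literally refitted on each of the
#' \eqn{n} subsamples; no incremental update is attempted.
#'
#' Pseudo-observations of survival-type functionals routinely fall outside
#' \eqn{[0,1]}; no clipping is applied.
#'
#' @param statistic Function taking a [survival_sample()] and returning a
#'   numeric vector of fixed length `H`.
#' @param sample A [survival_sample()].
#' @param grid Optional numeric vector of the `H` evaluation times (kept as
#'   metadata; `NULL` for scalar targets).
#' @param target Label describing the statistic.
#' @param on_degenerate What to do when the statistic fails on a
#'   leave-one-out subsample (e.g. removing the only event):
#'   `"error"` (default) signals an error naming the subject,
#'   `"drop"` sets that subject's row to `NA` with a warning.
#' @return An object of class `"pseudo_matrix"`: list with `values`
#'   (n x H matrix), `grid`, `target`, `full_estimate`, `n`, and
#'   `dropped` (indices of subjects dropped under `on_degenerate = "drop"`).
#' @examples
#' s <- survival_sample(c(1, 2, 3), c(1, 0, 1))
#' jackknife_pseudo(function(x) mean(x$time), s)$values  # a mean's pseudo
#' @export
jackknife_pseudo <- function(statistic, sample, grid = NULL,
                             target = "custom",
                             on_degenerate = c("error", "drop")) {
  stopifnot(inherits(sample, "survival_sample"))
  on_degenerate <- match.arg(on_degenerate)
  n <- sample$n
  full <- statistic(sample)
  H <- length(full)
  values <- matrix(NA_real_, n, H)
  dropped <- integer(0)
  for (i in seq_len(n)) {
    loo <- tryCatch(statistic(sample_subset(sample, -i)), error = identity)
    if (inherits(loo, "error")) {
      if (on_degenerate == "error")
        stop(sprintf("statistic undefined when leaving out subject %d: %s",
                     i, conditionMessage(loo)))
      dropped <- c(dropped, i)
    } else {
      values[i, ] <- n * full - (n - 1) * loo
    }
  }
  if (length(dropped))
    warning(sprintf("dropped %d subject(s) with degenerate leave-one-out fits",
                    length(dropped)))
  structure(list(values = values, grid = grid, target = target,
                 full_estimate = full, n = n, dropped = dropped),
            class = "pseudo_matrix")
}

#' @export
print.pseudo_matrix <- function(x, ...) {
  cat(sprintf("pseudo_matrix '%s': %d subjects x %d time point(s)\n",
              x$target, x$n, ncol(x$values)))
  cat(sprintf("  value range [%.3f, %.3f]; full estimate %s\n",
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE),
              paste(signif(x$full_estimate, 4), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.pseudo_matrix <- function(x, ...) {
  H <- ncol(x$values)
  grid <- if (is.null(x$grid)) rep(NA_real_, H) else x$grid
  data.frame(subject = rep(seq_len(x$n), each = H),
             time = rep(grid, x$n),
             value = as.vector(t(x$values)),
             target = x$target)
}

# Shared plumbing for the concrete constructors: `tmax_rule` resolves the
# ambiguity of where the leave-one-out plateau is read off -- at the
# subsample's own largest event time (default) or at the full sample's.
km_stat_factory <- function(kind, grid, tmax_rule) {
  force(grid)
  if (tmax_rule == "subsample") {
    switch(kind,
      pi_km = function(s) uncured_km(fit_km(s)),
      su = function(s) su_km(fit_km(s), grid),
      theta_km = function(s) {
        cv <- fit_km(s)
        if (cv$s_tmax <= 0)
          stop("S(tmax) = 0: theta_km is infinite (no plateau)")
        -log(cv$s_tmax)
      },
      F_km = function(s) F_km(fit_km(s), grid))
  } else {
    # evaluate every leave-one-out curve at a fixed time point, injected
    # later via the "tmax" attribute
    switch(kind,
      pi_km = function(s, at) 1 - km_surv_at(fit_km(s), at),
      su = function(s, at) {
        cv <- fit_km(s)
        s_at <- km_surv_at(cv, at)
        if (s_at >= 1) stop("S(tmax) = 1: susceptible survival undefined")
        (km_surv_at(cv, grid) - s_at) / (1 - s_at)
      },
      theta_km = function(s, at) {
        s_at <- km_surv_at(fit_km(s), at)
        if (s_at <= 0) stop("S(tmax) = 0: theta_km is infinite (no plateau)")
        -log(s_at)
      },
      F_km = function(s, at) {
        cv <- fit_km(s)
        s_at <- km_surv_at(cv, at)
        if (s_at <= 0 || s_at >= 1) stop("F_km requires 0 < S(tmax) < 1")
        pmin(log(km_surv_at(cv, grid)) / log(s_at), 1)
      })
  }
}

pseudo_km_generic <- function(sample, kind, grid = NULL, target = kind,
                              tmax_rule = c("subsample", "full"),
                              on_degenerate = "error") {
  tmax_rule <- match.arg(tmax_rule)
  stat <- km_stat_factory(kind, grid, tmax_rule)
  if (tmax_rule == "full") {
    at <- fit_km(sample)$tmax
    stat_fixed <- function(s) stat(s, at)
    jackknife_pseudo(stat_fixed, sample, grid, target, on_degenerate)
  } else {
    jackknife_pseudo(stat, sample, grid, target, on_degenerate)
  }
}

#' Pseudo-observations for the uncured rate (Kaplan-Meier plateau)
#'
#' Jackknifes \eqn{\hat\pi_{KM} = 1 - \hat S_{KM}(t_{max})}.
#'
#' @inheritParams jackknife_pseudo
#' @param tmax_rule Where each leave-one-out plateau is evaluated:
#'   at the subsample's own largest event time (`"subsample"`, default) or
#'   at the full sample's (`"full"`, for sensitivity checks).
#' @return A [jackknife_pseudo()] matrix with one column.
#' @examples
#' s <- survival_sample(c(1, 2, 3), c(1, 0, 1))
#' pseudo_pi_km(s)$values  # (1, 1, 2): values above 1 are expected
#' @export
pseudo_pi_km <- function(sample, tmax_rule = c("subsample", "full"),
                         on_degenerate = "error") {
  pseudo_km_generic(sample, "pi_km", target = "pi_km",
                    tmax_rule = match.arg(tmax_rule),
                    on_degenerate = on_degenerate)
}

#' Pseudo-observations for the uncured rate (promotion-time estimator)
#'
#' Jackknifes \eqn{\hat\pi_{NP} = 1 - \exp(-\hat\theta_{NP})} with
#' \eqn{\hat\theta_{NP}} from [theta_np()].
#'
#' @inheritParams jackknife_pseudo
#' @return A [jackknife_pseudo()] matrix with one column.
#' @export
pseudo_pi_np <- function(sample, on_degenerate = "error") {
  jackknife_pseudo(function(s) 1 - exp(-theta_np(s)$theta), sample,
                   grid = NULL, target = "pi_np",
                   on_degenerate = on_degenerate)
}

#' Pseudo-observations for the susceptible survival function
#'
#' Jackknifes \eqn{\hat S_u(t)} of [su_km()] on a time grid; the result has
#' one column per grid time and feeds the latency (Cox) component of the
#' mixture cure model.
#'
#' @inheritParams pseudo_pi_km
#' @param grid Numeric vector of evaluation times.
#' @export
pseudo_su <- function(sample, grid, tmax_rule = c("subsample", "full"),
                      on_degenerate = "error") {
  pseudo_km_generic(sample, "su", grid = grid, target = "su_km",
                    tmax_rule = match.arg(tmax_rule),
                    on_degenerate = on_degenerate)
}

#' Pseudo-observations for theta (Kaplan-Meier plateau)
#'
#' Jackknifes \eqn{\hat\theta_{KM} = -\log \hat S_{KM}(t_{max})}.
#'
#' @inheritParams pseudo_pi_km
#' @export
pseudo_theta_km <- function(sample, tmax_rule = c("subsample", "full"),
                            on_degenerate = "error") {
  pseudo_km_generic(sample, "theta_km", target = "theta_km",
                    tmax_rule = match.arg(tmax_rule),
                    on_degenerate = on_degenerate)
}

#' Pseudo-observations for theta (promotion-time estimator)
#'
#' Jackknifes \eqn{\hat\theta_{NP}} from [theta_np()].
#'
#' @inheritParams jackknife_pseudo
#' @export
pseudo_theta_np <- function(sample, on_degenerate = "error") {
  jackknife_pseudo(function(s) theta_np(s)$theta, sample, grid = NULL,
                   target = "theta_np", on_degenerate = on_degenerate)
}

#' Pseudo-observations for the promotion-time distribution F (KM plug-in)
#'
#' Jackknifes [F_km()] on a time grid; feeds the short-term component of
#' the PHPH model.
#'
#' @inheritParams pseudo_su
#' @export
pseudo_F_km <- function(sample, grid, tmax_rule = c("subsample", "full"),
                        on_degenerate = "error") {
  pseudo_km_generic(sample, "F_km", grid = grid, target = "F_km",
                    tmax_rule = match.arg(tmax_rule),
                    on_degenerate = on_degenerate)
}

#' Pseudo-observations for the promotion-time distribution F (jump form)
#'
#' Jackknifes [F_np()] on a time grid.
#'
#' @inheritParams pseudo_su
#' @export
pseudo_F_np <- function(sample, grid, on_degenerate = "error") {
  jackknife_pseudo(function(s) F_np(theta_np(s), grid), sample, grid = grid,
                   target = "F_np", on_degenerate = on_degenerate)
}
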