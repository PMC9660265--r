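#' Kaplan-Meier curve for cure-rate estimation
#'
#' Product-limit estimator of the survival function with the conventions
#' needed by the nonparametric cure-rate estimators: at tied times events
#' are processed before censorings (subjects censored at an event time are
#' still counted at risk), and `tmax` is the largest *event* time even when
#' censored follow-up extends beyond it.  The height of the curve at
#' `tmax` is the Kaplan-Meier plateau, whose complement estimates the
#' uncured rate.
#'
#' @param sample A [survival_sample()] with at least one event.
#' @return An object of class `"km_curve"`: list with `event_times`
#'   (unique, increasing), `surv` (the estimate just after each event
#'   time), `tmax`, `s_tmax`, `n`.
#' @examples
#' s <- survival_sample(c(1, 2, 3, 4), c(1, 0, 1, 0))
#' fit_km(s)$s_tmax  # (3/4) * (1/2)
#' @seealso [uncured_km()], [su_km()], [theta_np()]
#' @export
fit_km <- function(sample) {
  stopifnot(inherits(sample, "survival_sample"))
  time <- sample$time
  status <- sample$status
  if (!any(status == 1))
    stop("no events: cure-rate estimators are undefined")
  n <- length(time)
  et <- time[status == 1]
  ut <- sort(unique(et))
  d <- tabulate(match(et, ut), length(ut))
  st <- sort(time)
  r <- n - findInterval(ut, st, left.open = TRUE)  # at risk: time >= ut
  surv <- cumprod(1 - d / r)
  structure(list(event_times = ut, surv = surv, n_event = d, n_risk = r,
                 tmax = ut[length(ut)], s_tmax = surv[length(surv)], n = n),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d distinct event times\n",
              x$n, length(x$event_times)))
  cat(sprintf("  plateau S(tmax = %g) = %.4f  (uncured rate %.4f)\n",
              x$tmax, x$s_tmax, 1 - x$s_tmax))
  invisible(x)
}

# Right-continuous evaluation of the step function; S = 1 before the first
# event time.
km_surv_at <- function(curve, t) {
  idx <- findInterval(t, curve$event_times)
  c(1, curve$surv)[idx + 1L]
}

#' Kaplan-Meier estimate of the uncured rate
#'
#' The plateau-based estimate \eqn{\hat\pi = 1 - \hat S_{KM}(t_{max})},
#' where \eqn{t_{max}} is the largest observed event time.
#'
#' @param curve A [fit_km()] curve.
#' @return A scalar in \[0, 1\].
#' @export
uncured_km <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  1 - curve$s_tmax
}

#' Conditional survival of the susceptible subpopulation
#'
#' Kaplan-Meier plug-in estimate of \eqn{S_u(t)}, the survival function of
#' the event time given that the subject is susceptible:
#' \deqn{\hat S_u(t) = \{\hat S_{KM}(t) - \hat S_{KM}(t_{max})\} /
#'       \{1 - \hat S_{KM}(t_{max})\}.}
#'
#' @param curve A [fit_km()] curve with `s_tmax < 1`.
#' @param t Numeric vector of evaluation times.
#' @return Values in \[0, 1\]; 1 at `t = 0`, 0 at `t >= tmax`.
#' @export
su_km <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  if (curve$s_tmax >= 1)
    stop("S(tmax) = 1: susceptible survival is undefined")
  (km_surv_at(curve, t) - curve$s_tmax) / (1 - curve$s_tmax)
}

#' Nonparametric promotion-time estimates: theta and its jumps
#'
#' Estimates the bounded cumulative hazard \eqn{\theta = \Lambda(\infty)}
#' of the promotion-time (BCH) model \eqn{S(t) = \exp\{-\theta F(t)\}} by
#' the Tsodikov-type closed form.  With unique event times
#' \eqn{t_{(1)} < \dots < t_{(D)}}, \eqn{M_j} events at \eqn{t_{(j)}} and
#' \eqn{N_j} censorings in \eqn{[t_{(j)}, t_{(j+1)})} (censorings before
#' the first event are excluded from these counts, \eqn{t_{(D+1)}=\infty}),
#' \deqn{\hat\theta_k = -\log\frac{\sum_{\ell>k} M_\ell + \sum_{\ell\ge k} N_\ell}
#'                                {\sum_{\ell\ge k} M_\ell + \sum_{\ell\ge k} N_\ell},
#'       \qquad \hat\theta = \sum_k \hat\theta_k,}
#' and the jump of the estimated proper distribution \eqn{\hat F(t)} at
#' \eqn{t_{(j)}} is \eqn{\hat J_j = \hat\theta_j / \hat\theta}.
#'
#' When no censored follow-up remains at or after the last event time
#' (\eqn{N_D = 0}) the last component is infinite: the sample carries no
#' evidence of a cured fraction and an error of class
#' `"pocure_no_plateau"` is signalled.
#'
#' @param sample A [survival_sample()] with at least one event.
#' @return An object of class `"np_cure"`: list with `event_times`,
#'   `theta_k`, `theta`, `jumps`, `M`, `N`, `D`.
#' @examples
#' s <- survival_sample(c(1, 1.5, 2, 2.5), c(1, 0, 1, 0))
#' theta_np(s)$theta  # log(8/3)
#' @export
theta_np <- function(sample) {
  stopifnot(inherits(sample, "survival_sample"))
  time <- sample$time
  status <- sample$status
  if (!any(status == 1))
    stop("no events: theta estimator is undefined")
  et <- time[status == 1]
  ut <- sort(unique(et))
  D <- length(ut)
  M <- tabulate(match(et, ut), D)
  cens <- time[status == 0]
  idx <- findInterval(cens, ut)          # 0: censored before t_(1), excluded
  N <- tabulate(idx[idx > 0L], D)
  if (N[D] == 0L)
    stop(structure(class = c("pocure_no_plateau", "error", "condition"),
                   list(message = paste("no censored follow-up at or beyond the last",
                                        "event time: theta estimate is infinite",
                                        "(no evidence of a cured fraction)"),
                        call = sys.call(-1))))
  Mrev <- rev(cumsum(rev(M)))
  Nrev <- rev(cumsum(rev(N)))
  theta_k <- -log((c(Mrev[-1L], 0) + Nrev) / (Mrev + Nrev))
  theta <- sum(theta_k)
  structure(list(event_times = ut, theta_k = theta_k, theta = theta,
                 jumps = theta_k / theta, M = M, N = N, D = D),
            class = "np_cure")
}

#' @export
print.np_cure <- function(x, ...) {
  cat(sprintf("Nonparametric BCH estimate: theta = %.4f over %d event times\n",
              x$theta, x$D))
  cat(sprintf("  implied cure rate exp(-theta) = %.4f\n", exp(-x$theta)))
  invisible(x)
}

#' Nonparametric distribution function of the promotion-time model
#'
#' Evaluates \eqn{\hat F(t) = \sum_{j: t_{(j)} \le t} \hat J_j}, the
#' right-continuous step distribution with the jump sizes from
#' [theta_np()].
#'
#' @param est An [theta_np()] estimate.
#' @param t Numeric vector of evaluation times.
#' @return Values in \[0, 1\]; 0 before the first event time, 1 at and
#'   after the last.
#' @export
F_np <- function(est, t) {
  stopifnot(inherits(est, "np_cure"))
  idx <- findInterval(t, est$event_times)
  c(0, cumsum(est$jumps))[idx + 1L]
}

#' Kaplan-Meier plug-in distribution function of the promotion-time model
#'
#' Under \eqn{S(t) = \exp\{-\theta F(t)\}} the proper distribution is
#' identified by \eqn{F(t) = \log S(t) / \log S(t_{max})}, estimated by the
#' Kaplan-Meier plug-in.  Requires \eqn{0 < \hat S_{KM}(t_{max}) < 1}.
#'
#' @param curve A [fit_km()] curve.
#' @param t Numeric vector of evaluation times.
#' @return Values in \[0, 1\], nondecreasing in `t`, 1 at `t >= tmax`.
#' @export
F_km <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  if (curve$s_tmax <= 0 || curve$s_tmax >= 1)
    stop("F_km requires 0 < S(tmax) < 1")
  pmin(log(km_surv_at(curve, t)) / log(curve$s_tmax), 1)
}
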