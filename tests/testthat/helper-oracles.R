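# Independent oracles and small fixtures shared across the suite.

# Kaplan-Meier via survival::survfit, evaluated just after time t
# (right-continuous).  Independent of the package's own product-limit code.
survfit_surv_at <- function(time, status, t) {
  sf <- survival::survfit(survival::Surv(time, status) ~ 1)
  vapply(t, function(tt) {
    idx <- which(sf$time <= tt)
    if (!length(idx)) 1 else sf$surv[max(idx)]
  }, numeric(1))
}

# survfit-based versions of the cure statistics (tmax = largest event time)
oracle_pi_km <- function(s) {
  tmax <- max(s$time[s$status == 1])
  1 - survfit_surv_at(s$time, s$status, tmax)
}
oracle_su <- function(s, grid) {
  tmax <- max(s$time[s$status == 1])
  sm <- survfit_surv_at(s$time, s$status, tmax)
  (survfit_surv_at(s$time, s$status, grid) - sm) / (1 - sm)
}
oracle_theta_km <- function(s) {
  tmax <- max(s$time[s$status == 1])
  -log(survfit_surv_at(s$time, s$status, tmax))
}
oracle_F_km <- function(s, grid) {
  tmax <- max(s$time[s$status == 1])
  sm <- survfit_surv_at(s$time, s$status, tmax)
  log(survfit_surv_at(s$time, s$status, grid)) / log(sm)
}

# Literal leave-one-out pseudo-observations around any statistic.
brute_force_pseudo <- function(statistic, s) {
  n <- s$n
  full <- statistic(s)
  out <- vapply(seq_len(n), function(i) {
    sub <- survival_sample(s$time[-i], s$status[-i],
                           X = s$X[-i, , drop = FALSE],
                           Z = s$Z[-i, , drop = FALSE])
    n * full - (n - 1) * statistic(sub)
  }, numeric(length(full)))
  if (length(full) == 1L) matrix(out, ncol = 1) else t(out)
}

# Small random censored sample guaranteed to satisfy the estimators'
# regularity needs: >= 2 events and, so that every leave-one-out subsample
# keeps a plateau, >= 2 censored subjects at or after the last event.
rand_sample <- function(n, seed, p = 0, q = 0) {
  set.seed(seed)
  repeat {
    time <- round(rexp(n), 3)
    status <- rbinom(n, 1, 0.6)
    ev <- which(status == 1)
    if (length(ev) >= 2 &&
        sum(status == 0 & time >= max(time[ev])) >= 2) break
  }
  survival_sample(time, status,
                  X = if (p) matrix(rnorm(n * p), n, p),
                  Z = if (q) matrix(rnorm(n * q), n, q))
}

# The worked 4-subject sample used throughout: one censored subject inside
# the event range and one beyond it.
four_subject <- function() survival_sample(c(1, 2, 3, 4), c(1, 0, 1, 0))
two_event <- function() survival_sample(c(1, 1.5, 2, 2.5), c(1, 0, 1, 0))
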