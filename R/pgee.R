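#' SCAD penalty derivative
#'
#' First derivative of the smoothly clipped absolute deviation penalty,
#' \deqn{q_\lambda(u) = \lambda\, 1\{u \le \lambda\} +
#'   \frac{(a\lambda - u)_+}{a - 1}\, 1\{u > \lambda\}, \qquad u \ge 0,}
#' which is flat at \eqn{\lambda} for small arguments, decays linearly,
#' and vanishes for \eqn{u \ge a\lambda} (near-unbiasedness for large
#' coefficients).
#'
#' @param u Nonnegative numeric vector (coefficient magnitudes).
#' @param lambda Tuning parameter, \eqn{\lambda \ge 0}.
#' @param a Shape constant, default 3.7 (the usual SCAD convention).
#' @return Penalty derivative values, same length as `u`.
#' @examples
#' scad_deriv(c(0.5, 2, 4), lambda = 1)  # 1, 1.7/2.7, 0
#' @export
scad_deriv <- function(u, lambda, a = 3.7) {
  stopifnot(all(u >= 0), lambda >= 0, a > 2)
  ifelse(u <= lambda, lambda, pmax(a * lambda - u, 0) / (a - 1))
}

# A, U (dispersion-free) and residuals at the given coefficients, with the
# working correlation re-estimated from the current residuals.
gee_parts <- function(prep, link, corr, psi) {
  eta <- as.vector(prep$Xs %*% psi)
  mu <- link$ginv(eta)
  dmu <- link$dginv(eta)
  r <- prep$yv - mu
  phi <- sum(r^2) / max(length(r) - prep$k, 1)
  rho <- estimate_corr(r, phi, corr, prep$n, prep$H, prep$k)
  Q <- solve(corr_matrix(corr, rho, prep$H))
  M <- dmu * prep$Xs
  QM <- if (corr == "independence" || prep$H == 1) M
        else block_mult(Q, M, prep$H)
  list(A = crossprod(M, QM), U = as.vector(crossprod(QM, r)),
       r = r, phi = phi, rho = rho)
}

#' SCAD-penalized GEE for one cure-model component
#'
#' Solves the penalized estimating equation
#' \eqn{S(\psi) = U(\psi) - n\, q_\lambda(|\psi_P|) \circ \mathrm{sign}(\psi_P)}
#' (penalty applied to the penalized block only; intercepts and time
#' dummies are never penalized) by a local quadratic approximation:
#' \deqn{\psi \leftarrow \psi + (A + nE)^{-1}\{U(\psi) - nE\psi\}, \qquad
#'   E = \mathrm{diag}\{m_j\, q_\lambda(|\psi_j|) / (\epsilon + |\psi_j|)\}.}
#' Coefficients whose magnitude falls below `zero_tol` at convergence are
#' set to exactly zero and the equation is re-solved on the surviving
#' active set, so a saturating \eqn{\lambda} leaves the unpenalized block
#' fitted alone.
#'
#' @inheritParams solve_gee
#' @param lambda SCAD tuning parameter (0 recovers the unpenalized GEE).
#' @param a SCAD shape constant, default 3.7.
#' @param penalized Logical mask over coefficient positions (intercept
#'   block first, then design columns); default penalizes exactly the
#'   design columns.
#' @param init Initial coefficients; default is the unpenalized
#'   [solve_gee()] fit, as the estimating equations are nonconvex.
#' @param eps LQA denominator guard, default 1e-6.
#' @param tol Convergence tolerance on the coefficient change, default 1e-4.
#' @param zero_tol Magnitude below which a penalized coefficient is
#'   truncated to exact zero, default 1e-3.
#' @return An object of class `"pgee_fit"`: list with `coefficients`
#'   (exact zeros included), `selected` (logical over penalized
#'   coefficients), `lambda`, `converged`, `n_iter`, `penalized`.
#' @export
solve_pgee <- function(responses, design = NULL, link = "logit",
                       corr = c("independence", "exchangeable", "ar1"),
                       lambda, a = 3.7, intercept = "global",
                       penalized = NULL, init = NULL, eps = 1e-6,
                       tol = 1e-4, maxit = 200, zero_tol = 1e-3) {
  corr <- match.arg(corr)
  if (is.character(link)) link <- link_function(link)
  prep <- gee_prepare(responses, design, intercept)
  k <- prep$k
  if (is.null(penalized))
    penalized <- seq_len(k) > prep$n_intercept
  stopifnot(length(penalized) == k)
  if (is.null(init)) {
    init <- coef(solve_gee(responses, design, link, corr,
                           intercept = intercept))
  }
  psi <- as.numeric(init)
  names(psi) <- colnames(prep$Xs)
  n <- prep$n

  lqa <- function(psi, active) {
    # `active` indexes columns of the full design kept in the iteration
    if (!length(active))
      return(list(psi = numeric(0), converged = TRUE, n_iter = 0L))
    sub <- prep
    sub$Xs <- prep$Xs[, active, drop = FALSE]
    sub$k <- length(active)
    pen <- penalized[active]
    ps <- psi[active]
    converged <- FALSE
    iter <- 0
    while (iter < maxit) {
      iter <- iter + 1
      parts <- gee_parts(sub, link, corr, ps)
      Ediag <- numeric(length(ps))
      if (lambda > 0 && any(pen)) {
        ab <- abs(ps[pen])
        Ediag[pen] <- scad_deriv(ab, lambda, a) / (eps + ab)
      }
      step <- tryCatch(
        solve(parts$A + n * diag(Ediag, length(ps)),
              parts$U - n * Ediag * ps),
        error = function(e) stop("penalized Hessian is singular"))
      ps <- ps + as.vector(step)
      if (max(abs(step)) < tol) { converged <- TRUE; break }
    }
    list(psi = ps, converged = converged, n_iter = iter)
  }

  res <- lqa(psi, seq_len(k))
  psi_full <- numeric(k); names(psi_full) <- colnames(prep$Xs)
  psi_full[seq_len(k)] <- res$psi
  drop_idx <- which(penalized & abs(psi_full) < zero_tol)
  psi_full[drop_idx] <- 0
  if (length(drop_idx)) {
    active <- setdiff(seq_len(k), drop_idx)
    res2 <- lqa(psi_full, active)
    psi_full[active] <- res2$psi
    # re-truncate anything the restricted solve pushed below the threshold
    again <- which(penalized & abs(psi_full) < zero_tol)
    psi_full[again] <- 0
    res$converged <- res$converged && res2$converged
    res$n_iter <- res$n_iter + res2$n_iter
  }
  if (!res$converged)
    warning("penalized GEE did not converge")
  structure(list(coefficients = psi_full,
                 selected = penalized & psi_full != 0,
                 lambda = lambda, a = a, penalized = penalized,
                 converged = res$converged, n_iter = res$n_iter,
                 link = link$name, corr = corr, intercept = intercept,
                 n = n, H = prep$H),
            class = "pgee_fit")
}

#' @export
coef.pgee_fit <- function(object, ...) object$coefficients

#' @export
print.pgee_fit <- function(x, ...) {
  cat(sprintf("Penalized GEE (SCAD, lambda = %.4g): %d of %d penalized coefficients selected\n",
              x$lambda, sum(x$selected), sum(x$penalized)))
  print(x$coefficients)
  invisible(x)
}

# Smallest lambda (by doubling search) that zeroes every penalized
# coefficient.
find_lambda_max <- function(responses, design, link, corr, intercept,
                            init, a, ...) {
  lam <- 0.01
  for (it in 1:40) {
    fit <- solve_pgee(responses, design, link, corr, lambda = lam, a = a,
                      intercept = intercept, init = init, ...)
    if (!any(fit$selected)) return(lam)
    lam <- lam * 2
  }
  warning("lambda_max search did not saturate; using last value")
  lam
}

#' Cross-validated SCAD tuning for penalized GEEs
#'
#' Selects the SCAD tuning parameter by K-fold cross-validation at the
#' subject level (all of a subject's pseudo-observations stay in one
#' fold).  For each fold and candidate \eqn{\lambda} the penalized GEE is
#' fitted on the complement and scored on the held-out subjects by the
#' mean squared pseudo-residual
#' \deqn{CV(\lambda) = |N_{(k)}|^{-1} \sum_{j \in N_{(k)}} m_j^{-1}
#'   \sum_{\ell=1}^{m_j} \{y_{j\ell} - g^{-1}(\hat\vartheta_{(-k)}^\top
#'   W_{j\ell})\}^2,}
#' averaged over folds; the minimizing \eqn{\lambda} is refitted on the
#' full data.
#'
#' @inheritParams solve_pgee
#' @param lambda Optional vector of candidate values; by default a
#'   log-spaced grid of `nlambda` points from the saturating
#'   \eqn{\lambda_{max}} down to `lambda_min_ratio` times it.
#' @param nlambda Grid size, default 30.
#' @param lambda_min_ratio Lower end of the grid relative to
#'   \eqn{\lambda_{max}}, default 0.01.
#' @param K Number of folds, default 5.
#' @param seed Optional integer seed for the fold assignment (applied
#'   locally; the global RNG state is restored).
#' @param one_se If `TRUE`, pick the largest \eqn{\lambda} whose CV error
#'   is within one standard error (across folds) of the minimum instead of
#'   the plain minimizer.
#' @return A `"pgee_fit"` (the full-data refit at the chosen
#'   \eqn{\lambda}) with extra fields `cv` (data frame of `lambda`,
#'   `cv_error`), `lambda_grid`, `folds`.
#' @export
cv_select <- function(responses, design = NULL, link = "logit",
                      corr = c("independence", "exchangeable", "ar1"),
                      intercept = "global", lambda = NULL, nlambda = 30,
                      lambda_min_ratio = 0.01, K = 5, a = 3.7,
                      seed = NULL, one_se = FALSE, ...) {
  corr <- match.arg(corr)
  if (is.character(link)) link <- link_function(link)
  ymat <- if (inherits(responses, "pseudo_matrix")) responses$values
          else as.matrix(responses)
  n <- nrow(ymat)
  if (!is.null(design)) design <- as.matrix(design)

  init_full <- coef(solve_gee(ymat, design, link, corr, intercept = intercept))
  if (is.null(lambda)) {
    lmax <- find_lambda_max(ymat, design, link, corr, intercept,
                            init_full, a, ...)
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                      length.out = nlambda))
  }
  lambda <- sort(lambda, decreasing = TRUE)

  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
    set.seed(seed)
  }
  folds <- sample(rep_len(seq_len(K), n))

  cv_mat <- matrix(NA_real_, length(lambda), K)
  for (kf in seq_len(K)) {
    tr <- folds != kf
    te <- which(!tr)
    ok <- tryCatch({
      y_tr <- ymat[tr, , drop = FALSE]
      d_tr <- if (is.null(design)) NULL else design[tr, , drop = FALSE]
      init_tr <- coef(solve_gee(y_tr, d_tr, link, corr, intercept = intercept))
      TRUE
    }, error = function(e) {
      warning(sprintf("fold %d skipped: %s", kf, conditionMessage(e)))
      FALSE
    })
    if (!ok) next
    for (li in seq_along(lambda)) {
      fit <- tryCatch(
        solve_pgee(y_tr, d_tr, link, corr, lambda = lambda[li], a = a,
                   intercept = intercept, init = init_tr, ...),
        error = identity)
      if (inherits(fit, "error")) next
      cv_mat[li, kf] <- cv_score(fit, ymat, design, link, te)
    }
  }
  cv_error <- rowMeans(cv_mat, na.rm = TRUE)
  if (all(is.na(cv_error))) stop("cross-validation failed in every fold")
  best <- which.min(cv_error)
  if (one_se) {
    se_min <- stats::sd(cv_mat[best, ], na.rm = TRUE) /
      sqrt(sum(!is.na(cv_mat[best, ])))
    best <- min(which(cv_error <= cv_error[best] + se_min))
  }
  final <- solve_pgee(ymat, design, link, corr, lambda = lambda[best],
                      a = a, intercept = intercept, init = init_full, ...)
  final$cv <- data.frame(lambda = lambda, cv_error = cv_error)
  final$lambda_grid <- lambda
  final$folds <- folds
  final
}

# Mean squared pseudo-residual of held-out subjects under a fitted
# coefficient vector.
cv_score <- function(fit, ymat, design, link, test_idx) {
  H <- ncol(ymat)
  n_int <- if (fit$intercept == "time") H else
           if (fit$intercept == "global") 1L else 0L
  co <- fit$coefficients
  int <- if (fit$intercept == "time") co[seq_len(H)] else
         if (fit$intercept == "global") rep(co[1], H) else rep(0, H)
  slopes <- co[setdiff(seq_along(co), seq_len(n_int))]
  lin <- if (length(slopes))
    as.vector(design[test_idx, , drop = FALSE] %*% slopes) else
    numeric(length(test_idx))
  per_subject <- vapply(seq_along(test_idx), function(j) {
    eta <- int + lin[j]
    pr <- ymat[test_idx[j], ] - link$ginv(eta)
    mean(pr^2, na.rm = TRUE)
  }, numeric(1))
  mean(per_subject, na.rm = TRUE)
}

#' Variable selection for a cure-model component
#'
#' Builds the pseudo-observation responses and design for one of the four
#' cure-model components and runs [cv_select()] on it.
#'
#' @param sample A [survival_sample()].
#' @param component `"incidence"`, `"latency"`, `"long_term"`, or
#'   `"short_term"`.
#' @param flavor Pseudo-observation flavor for the scalar components and
#'   the short-term component, `"km"` or `"np"`.
#' @param grid [make_grid()] object or times for the time-indexed
#'   components.
#' @param H Grid size when `grid` is not supplied.
#' @param corr Working correlation.
#' @param ... Passed to [cv_select()].
#' @return A `"pgee_fit"` from [cv_select()].
#' @export
cure_select <- function(sample, component = c("incidence", "latency",
                                              "long_term", "short_term"),
                        flavor = c("km", "np"), grid = NULL, H = 10,
                        corr = "independence", ...) {
  component <- match.arg(component)
  flavor <- match.arg(flavor)
  if (component %in% c("latency", "short_term") && is.null(grid))
    grid <- make_grid(sample, H)
  times <- if (!is.null(grid)) as_grid_times(grid)
  switch(component,
    incidence = {
      po <- if (flavor == "km") pseudo_pi_km(sample) else pseudo_pi_np(sample)
      cv_select(po, sample$X, link = "logit", corr = corr,
                intercept = "global", ...)
    },
    latency = {
      po <- pseudo_su(sample, times)
      cv_select(po, sample$Z, link = "cloglog", corr = corr,
                intercept = "time", ...)
    },
    long_term = {
      po <- if (flavor == "km") pseudo_theta_km(sample)
            else pseudo_theta_np(sample)
      cv_select(po, sample$X, link = "log", corr = corr,
                intercept = "global", ...)
    },
    short_term = {
      po <- if (flavor == "km") pseudo_F_km(sample, times)
            else pseudo_F_np(sample, times)
      cv_select(1 - po$values, sample$Z, link = "cloglog", corr = corr,
                intercept = "time", ...)
    })
}

#' Selection metrics over Monte Carlo replicates
#'
#' Aggregates replicated coefficient estimates against the truth:
#' \itemize{
#'   \item MSE: mean over replicates of the squared Euclidean error
#'     \eqn{\|\hat\beta_j - \beta\|^2};
#'   \item TP: average number of selected (nonzero) coefficients whose
#'     true value is nonzero;
#'   \item FP: average number of selected coefficients whose true value is
#'     zero.
#' }
#'
#' @param estimates Numeric matrix, one row per replicate, columns
#'   matching `truth` (intercepts excluded).
#' @param truth True coefficient vector.
#' @return A list with `mse`, `tp`, `fp`, `n_rep`.
#' @export
selection_metrics <- function(estimates, truth) {
  estimates <- as.matrix(estimates)
  stopifnot(ncol(estimates) == length(truth))
  err <- sweep(estimates, 2, truth)
  list(mse = mean(rowSums(err^2)),
       tp = mean(rowSums(estimates[, truth != 0, drop = FALSE] != 0)),
       fp = mean(rowSums(estimates[, truth == 0, drop = FALSE] != 0)),
       n_rep = nrow(estimates))
}
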