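#' Link functions for pseudo-observation GEEs
#'
#' Returns the forward map, inverse and mean derivative for the three links
#' used by the cure-model components: `logit` (incidence), `log`
#' (long-term/theta), and `cloglog`, the survival-type complementary
#' log-log \eqn{g(x) = \log\{-\log(x)\}} with inverse
#' \eqn{g^{-1}(\eta) = \exp(-e^\eta)} (latency and short-term components).
#'
#' @param name One of `"logit"`, `"log"`, `"cloglog"`, `"identity"`.
#' @return A list with elements `name`, `g`, `ginv`, `dginv`
#'   (\eqn{d\mu/d\eta}).
#' @export
link_function <- function(name = c("logit", "log", "cloglog", "identity")) {
  name <- match.arg(name)
  switch(name,
    identity = list(name = "identity", g = identity, ginv = identity,
                    dginv = function(eta) rep(1, length(eta))),
    logit = list(name = "logit", g = stats::qlogis, ginv = stats::plogis,
                 dginv = function(eta) {
                   p <- stats::plogis(eta)
                   p * (1 - p)
                 }),
    log = list(name = "log", g = log, ginv = exp, dginv = exp),
    cloglog = list(name = "cloglog",
                   g = function(x) log(-log(x)),
                   ginv = function(eta) exp(-exp(eta)),
                   dginv = function(eta) -exp(eta - exp(eta))))
}

# Clamp means into the link's domain before applying g (initialization only).
link_init <- function(link, m) {
  if (link$name == "identity") m
  else if (link$name == "log") link$g(pmax(m, 1e-6))
  else link$g(pmin(pmax(m, 1e-6), 1 - 1e-6))
}

# Stack responses and design cluster-major (subject i, time h fastest).
# intercept: "global" (one column of 1s), "time" (H indicator columns),
# or "none".  Subjects with any NA response (dropped pseudo-observations)
# are excluded as whole clusters.
gee_prepare <- function(responses, design = NULL,
                        intercept = c("global", "time", "none")) {
  intercept <- match.arg(intercept)
  if (inherits(responses, "pseudo_matrix")) responses <- responses$values
  y <- as.matrix(responses)
  n <- nrow(y)
  H <- ncol(y)
  if (!is.null(design)) {
    design <- as.matrix(design)
    storage.mode(design) <- "double"
    if (nrow(design) != n) stop("design and responses row counts differ")
    if (is.null(colnames(design)))
      colnames(design) <- paste0("x", seq_len(ncol(design)))
  } else {
    design <- matrix(numeric(0), n, 0)
  }
  keep <- which(stats::complete.cases(y) & stats::complete.cases(design))
  y <- y[keep, , drop = FALSE]
  design <- design[keep, , drop = FALSE]
  m <- length(keep)
  icol <- switch(intercept,
    global = matrix(1, m * H, 1, dimnames = list(NULL, "(Intercept)")),
    time = {
      I <- diag(H)[rep(seq_len(H), m), , drop = FALSE]
      colnames(I) <- paste0("t", seq_len(H))
      I
    },
    none = matrix(numeric(0), m * H, 0))
  Xs <- cbind(icol, design[rep(seq_len(m), each = H), , drop = FALSE])
  k <- ncol(Xs)
  if (k == 0) stop("empty design")
  if (qr(Xs)$rank < k) stop("design is rank deficient")
  list(yv = as.vector(t(y)), Xs = Xs, n = m, H = H, k = k,
       keep = keep, n_all = n, intercept = intercept,
       n_intercept = ncol(icol))
}

# Apply an H x H matrix blockwise to a stacked vector or matrix.
block_mult <- function(Q, M, H) {
  if (is.null(dim(M))) return(as.vector(Q %*% matrix(M, nrow = H)))
  out <- vapply(seq_len(ncol(M)),
                function(j) as.vector(Q %*% matrix(M[, j], nrow = H)),
                numeric(nrow(M)))
  matrix(out, nrow = nrow(M))
}

# Moment estimators of dispersion and the working correlation parameter.
estimate_corr <- function(r, phi, structure, n, H, k) {
  if (structure == "independence" || H == 1) return(0)
  rm <- matrix(r, nrow = H)  # H x n
  z <- rm / sqrt(phi)
  if (structure == "exchangeable") {
    num <- (colSums(z)^2 - colSums(z^2)) / 2
    denom <- n * H * (H - 1) / 2 - k
    rho <- sum(num) / max(denom, 1)
    eps <- 1e-6
    min(max(rho, -1 / (H - 1) + eps), 1 - eps)
  } else {  # ar1
    num <- colSums(z[-H, , drop = FALSE] * z[-1, , drop = FALSE])
    denom <- n * (H - 1) - k
    rho <- sum(num) / max(denom, 1)
    min(max(rho, -1 + 1e-6), 1 - 1e-6)
  }
}

corr_matrix <- function(structure, rho, H) {
  if (structure == "independence" || H == 1) return(diag(H))
  if (structure == "exchangeable") {
    R <- matrix(rho, H, H); diag(R) <- 1; R
  } else {
    rho^abs(outer(seq_len(H), seq_len(H), "-"))
  }
}

#' Fit a generalized estimating equation to pseudo-observation responses
#'
#' Solves \eqn{U(\psi) = \sum_i D_i^\top V_i^{-1} (y_i - \mu_i) = 0} by
#' Fisher scoring, where \eqn{\mu_{ih} = g^{-1}(x_{ih}^\top \psi)} and
#' \eqn{V_i = \phi R(\rho)} uses an identity variance function with a
#' moment-estimated dispersion \eqn{\phi} and working correlation
#' \eqn{R(\rho)}.  The identity (Gaussian-type) working variance is what
#' makes logit/cloglog fits well defined on pseudo-observations, which can
#' fall outside \eqn{[0,1]}.
#'
#' Both a sandwich covariance \eqn{A^{-1} B A^{-1}} and the approximate
#' (one-step) jackknife covariance are computed; the jackknife is the
#' default reported in summaries.
#'
#' @param responses A [jackknife_pseudo()] matrix, or an n x H numeric
#'   matrix (H = 1 for scalar targets).
#' @param design Numeric covariate matrix with one row per subject,
#'   repeated across the H time points; may be `NULL` for an
#'   intercept-only model.
#' @param link Link name or [link_function()] object.
#' @param corr Working correlation structure: `"independence"` (default),
#'   `"exchangeable"`, or `"ar1"`.
#' @param intercept `"global"` for a single intercept, `"time"` for one
#'   intercept per response column, `"none"`.
#' @param tol Convergence tolerance on the maximum absolute coefficient
#'   change (default 1e-8).
#' @param maxit Maximum Fisher-scoring iterations (default 100).
#' @return An object of class `"gee_fit"` with elements `coefficients`,
#'   `vcov` (jackknife), `vcov_sandwich`, `vcov_jackknife`, `residuals`
#'   (n x H, `NA` rows for excluded subjects), `fitted`, `dispersion`,
#'   `rho`, `converged`, `n_iter`, and bookkeeping fields.
#' @examples
#' y <- c(1, 1, 1, 0, 1, 0, 0, 0)
#' x <- rep(c(1, 0), each = 4)
#' f <- solve_gee(matrix(y), design = cbind(x = x), link = "logit")
#' coef(f)  # slope = logit(3/4) - logit(1/4) = 2 log 3
#' @export
solve_gee <- function(responses, design = NULL, link = "logit",
                      corr = c("independence", "exchangeable", "ar1"),
                      intercept = "global", tol = 1e-8, maxit = 100) {
  corr <- match.arg(corr)
  if (is.character(link)) link <- link_function(link)
  prep <- gee_prepare(responses, design, intercept)
  yv <- prep$yv; Xs <- prep$Xs
  n <- prep$n; H <- prep$H; k <- prep$k
  if (length(prep$keep) < prep$n_all && prep$n_all - length(prep$keep) > 0)
    message(sprintf("excluding %d subject(s) with missing responses",
                    prep$n_all - length(prep$keep)))

  # initial values: intercept block from link of column means, slopes 0
  psi <- numeric(k)
  names(psi) <- colnames(Xs)
  ymat <- matrix(yv, nrow = H)
  if (prep$n_intercept > 0) {
    cm <- rowMeans(ymat)
    psi[seq_len(prep$n_intercept)] <-
      if (prep$intercept == "global") link_init(link, mean(yv))
      else link_init(link, cm)
  }

  rho <- 0
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    eta <- as.vector(Xs %*% psi)
    mu <- link$ginv(eta)
    dmu <- link$dginv(eta)
    r <- yv - mu
    phi <- sum(r^2) / max(length(r) - k, 1)
    rho <- estimate_corr(r, phi, corr, n, H, k)
    Q <- solve(corr_matrix(corr, rho, H))
    M <- dmu * Xs
    QM <- if (corr == "independence" || H == 1) M else block_mult(Q, M, H)
    A <- crossprod(M, QM)
    U <- crossprod(QM, r)
    step <- tryCatch(solve(A, U), error = function(e)
      stop("estimating-equation Hessian is singular"))
    psi <- psi + as.vector(step)
    if (max(abs(step)) < tol) { converged <- TRUE; break }
    if (iter >= maxit) break
  }
  if (!converged)
    warning(sprintf("GEE did not converge in %d iterations", maxit))

  # pieces at the solution
  eta <- as.vector(Xs %*% psi)
  mu <- link$ginv(eta)
  dmu <- link$dginv(eta)
  r <- yv - mu
  phi <- sum(r^2) / max(length(r) - k, 1)
  Q <- solve(corr_matrix(corr, rho, H))
  M <- dmu * Xs
  QM <- if (corr == "independence" || H == 1) M else block_mult(Q, M, H)
  A <- crossprod(M, QM)
  Qr <- if (corr == "independence" || H == 1) r else block_mult(Q, r, H)
  cluster <- rep(seq_len(n), each = H)
  scores <- rowsum(M * Qr, cluster)           # n x k cluster scores
  Ainv <- solve(A)
  vcov_sand <- Ainv %*% crossprod(scores) %*% Ainv
  vcov_sand <- (vcov_sand + t(vcov_sand)) / 2

  # one-step leave-one-cluster-out jackknife
  deltas <- matrix(0, n, k)
  for (i in seq_len(n)) {
    rows <- ((i - 1) * H + 1):(i * H)
    Ai <- crossprod(M[rows, , drop = FALSE], QM[rows, , drop = FALSE])
    deltas[i, ] <- solve(A - Ai, scores[i, ])
  }
  dc <- sweep(deltas, 2, colMeans(deltas))
  vcov_jack <- ((n - k) / n) * crossprod(dc)
  vcov_jack <- (vcov_jack + t(vcov_jack)) / 2
  dimnames(vcov_sand) <- dimnames(vcov_jack) <- list(names(psi), names(psi))

  res_full <- matrix(NA_real_, prep$n_all, H)
  res_full[prep$keep, ] <- matrix(r, ncol = H, byrow = TRUE)
  fit_full <- matrix(NA_real_, prep$n_all, H)
  fit_full[prep$keep, ] <- matrix(mu, ncol = H, byrow = TRUE)

  structure(list(coefficients = psi, vcov = vcov_jack,
                 vcov_sandwich = vcov_sand, vcov_jackknife = vcov_jack,
                 residuals = res_full, fitted = fit_full,
                 dispersion = phi, rho = rho, corr = corr,
                 link = link$name, intercept = prep$intercept,
                 n_intercept = prep$n_intercept,
                 n = n, H = H, k = k, keep = prep$keep,
                 n_iter = iter, converged = converged),
            class = "gee_fit")
}

#' @export
coef.gee_fit <- function(object, ...) object$coefficients

#' @export
vcov.gee_fit <- function(object, type = c("jackknife", "sandwich"), ...) {
  switch(match.arg(type), jackknife = object$vcov_jackknife,
         sandwich = object$vcov_sandwich)
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("GEE fit (%s link, %s working correlation, H = %d)\n",
              x$link, x$corr, x$H))
  print(summary(x)$coefficients)
  if (!x$converged) cat("** did not converge **\n")
  invisible(x)
}

#' @export
summary.gee_fit <- function(object, se = c("jackknife", "sandwich"), ...) {
  se <- match.arg(se)
  V <- if (se == "jackknife") object$vcov_jackknife else object$vcov_sandwich
  est <- object$coefficients
  s <- sqrt(pmax(diag(V), 0))
  z <- est / s
  tab <- cbind(Estimate = est, `Std. Error` = s, `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, se_type = se,
                 dispersion = object$dispersion, rho = object$rho,
                 converged = object$converged, n = object$n, H = object$H),
            class = "summary.gee_fit")
}

#' @export
print.summary.gee_fit <- function(x, ...) {
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("dispersion %.4f, rho %.3f, n = %d, H = %d (%s SEs)\n",
              x$dispersion, x$rho, x$n, x$H, x$se_type))
  invisible(x)
}
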