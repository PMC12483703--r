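#' Per-response maximum-likelihood threshold estimation
#'
#' Re-estimates the thresholds of one response with the structural values
#' entering as a fixed offset (a predictor with coefficient 1 and no other
#' covariates), exactly as in the proportional-odds regression model.  The
#' optimization runs in the unconstrained parametrization
#' \eqn{(\tau_1, \log(\tau_2-\tau_1), \dots)} so the order constraint holds
#' throughout, using Newton steps (analytic gradient and tridiagonal
#' Hessian) with step halving on the negative log-likelihood until the
#' gradient norm drops below `tol`.
#'
#' Empty categories would push their thresholds to infinity; thresholds are
#' capped at `cap` on the latent scale with a warning instead.
#'
#' @param y_r integer vector of categories 1..C.
#' @param theta_r numeric vector of structural offsets, same length.
#' @param C number of categories (defaults to `max(y_r)`).
#' @param start optional starting thresholds (used to warm-start the outer
#'   EMM loop).
#' @param tol gradient-norm convergence tolerance.
#' @param maxit maximum Newton iterations.
#' @param cap absolute bound on fitted thresholds.
#' @return numeric vector of strictly increasing thresholds (length C - 1).
#' @export
fit_thresholds <- function(y_r, theta_r, C = max(y_r), start = NULL,
                           tol = 1e-8, maxit = 200L, cap = 30) {
  y_r <- as.integer(y_r)
  n <- length(y_r)
  if (length(theta_r) != n) stop("'y_r' and 'theta_r' lengths differ")
  if (any(y_r < 1L | y_r > C)) stop("categories outside 1..C")
  K <- C - 1L
  counts <- tabulate(y_r, nbins = C)
  empty <- counts == 0L
  if (any(empty))
    warning("empty response categories; affected thresholds capped at +/-",
            cap)

  nll <- function(tau) {
    te <- c(-Inf, tau, Inf)
    p <- stats::plogis(te[y_r + 1L] - theta_r) -
      stats::plogis(te[y_r] - theta_r)
    -sum(log(pmax(p, 1e-12)))
  }

  ## analytic gradient and tridiagonal Hessian of the negative
  ## log-likelihood with respect to tau.  For a cell in category y with
  ## boundary arguments a = tau_y - theta (upper) and b = tau_{y-1} - theta
  ## (lower): d(-log p)/dtau_y = -f(a)/p, d(-log p)/dtau_{y-1} = f(b)/p,
  ## with second derivatives -f'(a)/p + (f(a)/p)^2, f'(b)/p + (f(b)/p)^2
  ## and cross term -f(a) f(b)/p^2, where f'(u) = f(u) (1 - 2 F(u)).
  grad_hess_tau <- function(tau) {
    te <- c(-Inf, tau, Inf)
    a <- te[y_r + 1L] - theta_r
    b <- te[y_r] - theta_r
    Fa <- stats::plogis(a); Fb <- stats::plogis(b)
    fa <- stats::dlogis(a); fb <- stats::dlogis(b)
    p <- Fa - Fb
    ## cells at the probability floor contribute a constant to the floored
    ## objective; drop them so gradient and objective stay consistent
    keep <- p > 1e-12
    fa <- fa * keep; fb <- fb * keep
    p <- pmax(p, 1e-12)
    cell <- cbind(gu = -fa / p,
                  gl = fb / p,
                  Huu = -fa * (1 - 2 * Fa) / p + (fa / p)^2,
                  Hll = fb * (1 - 2 * Fb) / p + (fb / p)^2,
                  Hul = -fa * fb / p^2)
    agg <- matrix(0, C, 5L)
    sums <- rowsum(cell, y_r)
    agg[as.integer(rownames(sums)), ] <- sums
    gt <- agg[seq_len(K), 1L] + agg[1L + seq_len(K), 2L]
    H <- diag(agg[seq_len(K), 3L] + agg[1L + seq_len(K), 4L], K)
    if (K > 1L)
      for (k in seq_len(K - 1L))
        H[k, k + 1L] <- H[k + 1L, k] <- agg[k + 1L, 5L]
    list(gt = gt, H = H)
  }

  ## unconstrained parametrization: tau_c = eta_1 + sum_{j<=c} exp(eta_j)
  to_tau <- function(eta) eta[1L] + c(0, cumsum(exp(eta[-1L])))
  to_eta <- function(tau) {
    if (C == 2L) tau else c(tau[1L], log(pmax(diff(tau), 1e-8)))
  }
  jac <- function(eta) {
    J <- matrix(0, K, K)
    J[, 1L] <- 1
    if (K > 1L)
      for (j in 2L:K) J[j:K, j] <- exp(eta[j])
    J
  }
  ## clamp in tau space so every iterate stays in the reportable box and
  ## the final cap is a no-op (keeps the offset likelihood monotone under
  ## warm starts)
  clamp_eta <- function(eta) {
    tau <- pmin(pmax(to_tau(eta), -cap), cap)
    if (C > 2L)
      for (cc in 2L:(C - 1L))
        tau[cc] <- max(tau[cc], tau[cc - 1L] + 1e-8)
    to_eta(tau)
  }

  if (is.null(start)) {
    cp <- cumsum(counts)[seq_len(K)] / n
    cp <- pmin(pmax(cp, 1 / (2 * n)), 1 - 1 / (2 * n))
    start <- stats::qlogis(cp) + mean(theta_r)
    start <- start + cumsum(c(0, diff(start) <= 0) * 1e-6)  # repair ties
  }
  eta <- clamp_eta(to_eta(start))
  f <- nll(to_tau(eta))

  converged <- FALSE
  for (it in seq_len(maxit)) {
    gh <- grad_hess_tau(to_tau(eta))
    J <- jac(eta)
    ge <- drop(crossprod(J, gh$gt))
    if (sqrt(sum(ge^2)) < tol) { converged <- TRUE; break }
    ## chain rule curvature term: tau is linear in eta_1 and exponential in
    ## the gap parameters, adding exp(eta_j) sum_{c>=j} gt_c on the diagonal
    H <- crossprod(J, gh$H %*% J)
    if (K > 1L) {
      extra <- c(0, ge[-1L])
      diag(H) <- diag(H) + extra
    }
    step <- tryCatch(solve(H + diag(1e-10, K), ge), error = function(e) ge)
    if (!all(is.finite(step)) || sum(step * ge) <= 0) step <- ge
    ## step halving: never increase the negative log-likelihood
    alpha <- 1
    repeat {
      cand <- clamp_eta(eta - alpha * step)
      fc <- nll(to_tau(cand))
      if (fc <= f + 1e-12 || alpha < 1e-12) break
      alpha <- alpha / 2
    }
    if (fc > f + 1e-12) break   # no descent direction left
    moved <- max(abs(cand - eta))
    eta <- cand; f <- fc
    if (moved < 1e-12) break    # pinned at the parameter clamp
  }

  tau <- to_tau(eta)
  ## cap runaway thresholds (empty or separated categories)
  capped <- pmin(pmax(tau, -cap), cap)
  if (C > 2L)
    for (cc in 2L:(C - 1L))
      capped[cc] <- max(capped[cc], capped[cc - 1L] + 1e-8)
  if (!converged && !any(empty)) {
    gn <- sqrt(sum(drop(crossprod(jac(eta), grad_hess_tau(tau)$gt))^2))
    if (gn > 1e-3) {
      cond <- simpleError(sprintf(
        "threshold estimation did not converge (gradient norm %.2e)", gn))
      cond$tau <- capped
      stop(cond)
    }
    warning("threshold estimation stopped with gradient norm above 'tol'")
  }
  capped
}
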