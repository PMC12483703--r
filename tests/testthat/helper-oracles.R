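# Independent oracles and fixture builders used across the suite.

# Expected gradient of the complete-data negative log density by adaptive
# quadrature: E[1 - 2F(z - theta)] for a logistic latent variable truncated
# to the observed category's threshold interval.
quad_estep <- function(theta, tau, cat) {
  te <- c(-Inf, tau, Inf)
  lo <- te[cat]; hi <- te[cat + 1L]
  dens <- function(z) stats::dlogis(z - theta)
  p <- stats::integrate(dens, lo, hi, rel.tol = 1e-12)$value
  num <- stats::integrate(function(z) (1 - 2 * stats::plogis(z - theta)) *
                            dens(z), lo, hi, rel.tol = 1e-12)$value
  num / p
}

# Expected complete-data negative log density (up to the truncation
# constant) at trial value 'theta', expectation taken at 'theta0':
# integral of -log f(z - theta) times the truncated density at theta0.
quad_expected_nll <- function(theta, theta0, tau, cat) {
  te <- c(-Inf, tau, Inf)
  lo <- te[cat]; hi <- te[cat + 1L]
  dens0 <- function(z) stats::dlogis(z - theta0)
  p0 <- stats::integrate(dens0, lo, hi, rel.tol = 1e-10)$value
  stats::integrate(function(z) {
    e <- z - theta
    (abs(e) + 2 * log1p(exp(-abs(e)))) * dens0(z) / p0
  }, lo, hi, rel.tol = 1e-10)$value
}

# Random ordinal fixture drawn from a low-rank dominance truth.
rand_ordinal <- function(N, R, C = 3L, ndim = 2L, seed = 1,
                         representation = "dominance", scale = 1) {
  set.seed(seed)
  U <- matrix(rnorm(N * ndim), N, ndim) * scale
  V <- matrix(rnorm(R * ndim), R, ndim)
  theta <- if (representation == "dominance") tcrossprod(U, V)
           else -as.matrix(stats::dist(rbind(U, V)))[seq_len(N),
                                                     N + seq_len(R)]
  tau <- lapply(seq_len(R), function(r) {
    ctr <- stats::median(theta[, r])
    ctr + sort(stats::runif(C - 1L, -1.5, 1.5))
  })
  y <- matrix(0L, N, R)
  probs <- cl_probabilities(theta, tau)
  for (r in seq_len(R)) {
    cum <- t(apply(probs[[r]], 1L, cumsum))
    u <- runif(N)
    y[, r] <- 1L + rowSums(u > cum[, -ncol(cum), drop = FALSE])
  }
  ## guarantee every category is observed so threshold ML is well posed
  for (r in seq_len(R)) {
    missing <- setdiff(seq_len(C), unique(y[, r]))
    for (m in missing) y[sample(N, 1L), r] <- m
  }
  list(y = y, U = U, V = V, theta = theta, tau = tau)
}

# Joint maximum-likelihood graded-response machinery in one dimension
# (person scores u, item slopes v, item thresholds with log-gap coding),
# coded independently of the EMM path: analytic-gradient BFGS on the
# observed-data deviance.  Returns the deviance function, its gradient and
# a multistart fitter.
grm_machine <- function(y, C) {
  N <- nrow(y); R <- ncol(y); K <- C - 1L
  unpack <- function(par) {
    u <- par[1:N]; v <- par[N + 1:R]
    eta <- matrix(par[N + R + seq_len(R * K)], K, R)
    tau <- matrix(apply(eta, 2, function(e)
      e[1] + c(0, cumsum(exp(e[-1])))[1:K]), K, R)
    list(u = u, v = v, eta = eta, tau = tau)
  }
  dev <- function(par) {
    p <- unpack(par)
    d <- 0
    for (r in 1:R) {
      te <- c(-Inf, p$tau[, r], Inf)
      th <- p$u * p$v[r]
      pr <- plogis(te[y[, r] + 1] - th) - plogis(te[y[, r]] - th)
      d <- d - 2 * sum(log(pmax(pr, 1e-12)))
    }
    d
  }
  grad <- function(par) {
    p <- unpack(par)
    gu <- numeric(N); gv <- numeric(R); geta <- matrix(0, K, R)
    for (r in 1:R) {
      te <- c(-Inf, p$tau[, r], Inf)
      th <- p$u * p$v[r]
      a <- te[y[, r] + 1] - th; b <- te[y[, r]] - th
      fa <- dlogis(a); fb <- dlogis(b)
      pr <- pmax(plogis(a) - plogis(b), 1e-12)
      gth <- 2 * (fa - fb) / pr
      gu <- gu + gth * p$v[r]
      gv[r] <- sum(gth * p$u)
      gtau <- numeric(K)
      for (k in 1:K) {
        up <- y[, r] == k; dn <- y[, r] == k + 1
        gtau[k] <- -2 * sum(fa[up] / pr[up]) + 2 * sum(fb[dn] / pr[dn])
      }
      ge <- numeric(K); ge[1] <- sum(gtau)
      if (K > 1) for (j in 2:K) ge[j] <- exp(p$eta[j, r]) * sum(gtau[j:K])
      geta[, r] <- ge
    }
    c(gu, gv, as.vector(geta))
  }
  fit <- function(n_restarts = 2, seed = 42) {
    best <- NULL
    for (k in seq_len(n_restarts)) {
      set.seed(seed + k)
      init <- c(rnorm(N, 0, 0.5), rnorm(R, 0, 0.5) + 0.5,
                unlist(lapply(1:R, function(r) {
                  cp <- pmin(pmax(cumsum(tabulate(y[, r], C))[1:K] / N,
                                  0.02), 0.98)
                  t0 <- qlogis(cp)
                  c(t0[1], if (K > 1) log(pmax(diff(t0), 0.05)))
                })))
      op <- optim(init, dev, grad, method = "BFGS",
                  control = list(maxit = 5000, reltol = 1e-15))
      op <- optim(op$par, dev, grad, method = "BFGS",
                  control = list(maxit = 5000, reltol = 1e-15))
      if (is.null(best) || op$value < best$value) best <- op
    }
    best
  }
  list(dev = dev, grad = grad, fit = fit, unpack = unpack)
}

# A 50 x 4 fixture for the one-dimensional equivalence check: a perfectly
# scalable (Guttman-type) pattern with four latent levels and a common cut
# structure, so the shared likelihood supremum (deviance 0) is approached
# by both implementations and the comparison of fitted deviances is well
# posed.
grm_fixture <- function() {
  s <- rep(c(-1.5, -0.5, 0.5, 1.5), times = c(13, 12, 12, 13))
  sapply(1:4, function(r) 1L + findInterval(s, c(-1, 0)))
}
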