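#' Cumulative logistic multidimensional data analysis
#'
#' Fits a low-dimensional cumulative logistic (proportional-odds) model to a
#' matrix of ordinal responses by maximum likelihood.  The structural part
#' \eqn{\theta_{ir}} of the latent scale is either an inner product
#' \eqn{u_i'v_r} (dominance representation; CLPCA, or CLRRR when predictors
#' restrict \eqn{U = XB}) or a negated Euclidean distance
#' \eqn{-\|u_i - v_r\|} (proximity representation; CLMDU / CLRMDU).
#'
#' Estimation alternates (a) an E-step producing working responses from the
#' closed-form truncated-logistic expectations, (b) a least-squares update of
#' the structural part (truncated SVD, generalized SVD, or a SMACOF
#' unfolding sweep with the negative-dissimilarity device), and (c)
#' per-response maximum-likelihood threshold re-estimation with the
#' structural values as offset.  The observed-data deviance is non-increasing
#' across iterations.  For the dominance models the likelihood has a single
#' optimum; for the proximity models local optima occur and several starting
#' configurations are tried (a correspondence-analysis-flavored deterministic
#' start plus random starts), the best fit being returned.
#'
#' @param y integer matrix or data frame (N x R) of ordinal responses coded
#'   1..\eqn{C_r}; categories may differ per response.
#' @param x optional N x P numeric predictor matrix (or data frame passed
#'   through [build_predictors()]); when supplied the row scores are
#'   restricted to \eqn{U = XB}.
#' @param representation `"dominance"` (inner products) or `"proximity"`
#'   (distances).
#' @param ndim dimensionality S of the structural part.
#' @param categories optional integer vector of category counts per response
#'   (defaults to the observed maxima).
#' @param control list from [clmda_control()].
#' @param start optional list with components `U`, `V` (and `B` for
#'   restricted models) used as the single starting configuration.
#' @return An object of class `"clmda"`; see Details.
#' @details The returned object has components `U`, `V`, `B` (restricted
#'   models), `tau`, `theta`, `deviance`, `null_deviance`, `trace` (deviance
#'   per outer iteration of the best start), `n_parameters`, `AIC`, `BIC`,
#'   `converged`, `start_best`, plus bookkeeping fields.  Methods:
#'   [print.clmda()], [summary.clmda()], [coef.clmda()], [predict.clmda()],
#'   [plot.clmda()], [simulate.clmda()], [logLik.clmda()],
#'   [residuals.clmda()], [fitted.clmda()].
#' @examples
#' dat <- generate_dataset(simulation_design(N = 150, seed = 7))
#' fit <- clmda(dat$y, dat$x, representation = "dominance", ndim = 2,
#'              control = clmda_control(maxit = 200))
#' fit
#' @export
clmda <- function(y, x = NULL,
                  representation = c("dominance", "proximity"),
                  ndim = 2L, categories = NULL,
                  control = clmda_control(), start = NULL) {
  representation <- match.arg(representation)
  y <- as.matrix(y)
  storage.mode(y) <- "integer"
  N <- nrow(y); R <- ncol(y)
  if (is.null(categories)) categories <- apply(y, 2L, max)
  categories <- as.integer(categories)
  .check_y(y, categories)
  if (any(categories < 2L)) stop("each response needs at least 2 categories")

  pred_info <- NULL
  if (!is.null(x)) {
    if (is.data.frame(x)) {
      bp <- build_predictors(x)
      pred_info <- bp$info
      x <- bp$X
    }
    x <- as.matrix(x)
    if (nrow(x) != N) stop("'x' and 'y' row counts differ")
  }
  restricted <- !is.null(x)
  model <- paste0("cl", if (restricted) "r" else "",
                  if (representation == "dominance") {
                    if (restricted) "rr" else "pca"
                  } else {
                    if (restricted) "mdu" else "mdu"
                  })
  ndim <- as.integer(ndim)
  maxdim <- if (restricted) min(ncol(x), R) else min(N, R)
  if (ndim < 1L || ndim > maxdim)
    stop("'ndim' must be between 1 and ", maxdim)

  qrX <- if (restricted) qr(x) else NULL
  if (restricted && qrX$rank < ncol(x))
    stop("predictor matrix is rank deficient; drop collinear predictors")

  ## null model: thresholds only (theta = 0)
  tau0 <- lapply(seq_len(R), function(r)
    fit_thresholds(y[, r], rep(0, N), C = categories[r]))
  null_dev <- cl_deviance(y, matrix(0, N, R), tau0)

  nstarts <- if (!is.null(start)) 1L
             else if (representation == "dominance") control$starts_dominance
             else control$starts_proximity

  best <- NULL
  for (k in seq_len(nstarts)) {
    init <- if (!is.null(start)) start
            else .clmda_start(y, x, representation, ndim, categories, k,
                              control$seed, qrX)
    fit <- .clmda_emm(y, x, representation, ndim, categories, init,
                      control, qrX, tau0, null_dev)
    if (is.null(best) || fit$deviance < best$deviance) {
      best <- fit
      best$start_best <- k
    }
  }

  best$model <- model
  best$representation <- representation
  best$restricted <- restricted
  best$ndim <- ndim
  best$categories <- categories
  best$N <- N; best$R <- R; best$P <- if (restricted) ncol(x) else NULL
  best$y <- y
  best$x <- x
  best$pred_info <- pred_info
  best$null_deviance <- null_dev
  best$n_parameters <- count_parameters(model, ndim = ndim, N = N,
                                        P = best$P, R = R,
                                        categories = categories)
  best$AIC <- best$deviance + 2 * best$n_parameters
  best$BIC <- best$deviance + log(N) * best$n_parameters
  best$n_starts <- nstarts
  best$control <- control
  best$call <- match.call()
  class(best) <- "clmda"
  best
}

#' Control settings for [clmda()]
#'
#' @param tol relative deviance-change convergence tolerance of the outer
#'   EMM loop.
#' @param maxit maximum number of outer iterations.
#' @param inner number of structural-update sweeps per outer iteration
#'   (relevant for the distance models).
#' @param starts_dominance,starts_proximity number of starting
#'   configurations.  Dominance fits reach the same optimum from any start,
#'   so one deterministic start suffices; proximity fits default to one
#'   deterministic start plus nine random starts.
#' @param accelerate enable safeguarded step expansion: after each EMM
#'   update the step is extrapolated with a growing multiplier and kept only
#'   when the deviance still decreases (the plain majorization step is the
#'   fallback).  Useful when the likelihood supremum lies on the boundary of
#'   the parameter space, where plain majorization steps shrink; the
#'   deviance trace remains monotone either way.
#' @param eps small positive constant guarding the weight redefinition in
#'   the negative-dissimilarity unfolding system.
#' @param seed integer seed from which random-start seeds are derived
#'   (`NULL` leaves the RNG state alone).
#' @param verbose print the deviance each iteration.
#' @return A list of settings.
#' @export
clmda_control <- function(tol = 1e-6, maxit = 5000L, inner = 1L,
                          starts_dominance = 1L, starts_proximity = 10L,
                          accelerate = FALSE, eps = 1e-8, seed = NULL,
                          verbose = FALSE) {
  list(tol = tol, maxit = as.integer(maxit), inner = as.integer(inner),
       starts_dominance = as.integer(starts_dominance),
       starts_proximity = as.integer(starts_proximity),
       accelerate = isTRUE(accelerate), eps = eps, seed = seed,
       verbose = isTRUE(verbose))
}

## starting configuration; k = 1 is deterministic, k > 1 random
.clmda_start <- function(y, x, representation, ndim, categories, k, seed,
                         qrX) {
  N <- nrow(y); R <- ncol(y)
  restricted <- !is.null(x)
  if (k == 1L) {
    ## correspondence-analysis-flavored start: SVD of the double-centered
    ## integer-coded response matrix
    Z <- scale(y, center = TRUE, scale = FALSE)
    Z <- Z - rowMeans(Z)
    sv <- svd(Z, nu = ndim, nv = ndim)
    d <- sqrt(sv$d[seq_len(ndim)] + 1e-8)
    U <- sv$u %*% diag(d, ndim)
    V <- sv$v %*% diag(d, ndim)
    if (representation == "proximity") V <- 2 * V   # spread items outward
  } else {
    if (!is.null(seed)) set.seed((seed + 104729L * k) %% .Machine$integer.max)
    U <- matrix(stats::rnorm(N * ndim), N, ndim)
    V <- matrix(stats::rnorm(R * ndim), R, ndim)
  }
  if (restricted) {
    B <- qr.coef(qrX, U)
    U <- x %*% B
    list(U = U, V = V, B = B)
  } else list(U = U, V = V)
}

.clmda_theta <- function(representation, U, V) {
  if (representation == "dominance") tcrossprod(U, V) else -.distances(U, V)
}

## one EMM run from a given starting configuration
.clmda_emm <- function(y, x, representation, ndim, categories, init,
                       control, qrX, tau0, null_dev) {
  N <- nrow(y); R <- ncol(y)
  restricted <- !is.null(x)
  U <- as.matrix(init$U); V <- as.matrix(init$V)
  B <- if (restricted) as.matrix(init$B) else NULL
  theta <- .clmda_theta(representation, U, V)
  tau <- lapply(seq_len(R), function(r)
    fit_thresholds(y[, r], theta[, r], C = categories[r], start = tau0[[r]]))

  dev <- Inf
  trace <- numeric(0)
  converged <- FALSE
  accel_m <- 2
  for (it in 0:control$maxit) {
    ## one boundary-probability pass serves both the deviance of the
    ## current state and the next E-step
    lam <- .cell_lambdas(y, theta, tau)
    dev_new <- -2 * sum(log(pmax(lam$hi - lam$lo, 1e-12)))
    if (!is.finite(dev_new))
      stop("non-finite deviance at iteration ", it)
    trace <- c(trace, dev_new)
    if (control$verbose)
      message(sprintf("iter %4d  deviance %.6f", it, dev_new))
    if (it > 0L && abs(dev - dev_new) < control$tol * abs(dev)) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
    if (it == control$maxit) break

    ## E-step and working responses
    g <- 1 - lam$lo - lam$hi
    zt <- theta - 2 * g

    ## M-step: structural update
    Uo <- U; Vo <- V; Bo <- B
    if (representation == "dominance") {
      if (restricted) {
        up <- update_rrr(zt, x, ndim, qrX = qrX)
        B <- up$B; U <- up$U; V <- up$V
      } else {
        up <- update_pca(zt, ndim)
        U <- up$U; V <- up$V
      }
    } else {
      for (sweep in seq_len(control$inner)) {
        sys <- build_smacof_system(zt, U, V, eps = control$eps)
        if (restricted) {
          up <- update_rmdu(sys, x, B, V)
          B <- up$Bx; U <- up$U; V <- up$V
        } else {
          up <- update_mdu(sys, U, V)
          U <- up$U; V <- up$V
        }
      }
    }

    ## optional safeguarded step expansion: extrapolate along the update
    ## direction and keep the longer step only when the deviance still
    ## decreases; the plain majorization step is the guaranteed fallback,
    ## so the deviance trace stays monotone
    accepted <- FALSE
    if (control$accelerate && accel_m > 1) {
      Ue <- Uo + accel_m * (U - Uo)
      Ve <- Vo + accel_m * (V - Vo)
      Be <- if (restricted) Bo + accel_m * (B - Bo) else NULL
      theta_e <- .clmda_theta(representation, Ue, Ve)
      tau_e <- lapply(seq_len(R), function(r)
        tryCatch(fit_thresholds(y[, r], theta_e[, r], C = categories[r],
                                start = tau[[r]], maxit = 50L),
                 error = function(e) if (!is.null(e$tau)) e$tau else stop(e)))
      lam_e <- .cell_lambdas(y, theta_e, tau_e)
      dev_e <- -2 * sum(log(pmax(lam_e$hi - lam_e$lo, 1e-12)))
      if (is.finite(dev_e) && dev_e <= dev) {
        U <- Ue; V <- Ve; B <- Be; theta <- theta_e; tau <- tau_e
        accel_m <- min(accel_m * 2, 2^16)
        accepted <- TRUE
      } else {
        accel_m <- 2
      }
    }

    if (!accepted) {
      theta <- .clmda_theta(representation, U, V)
      ## threshold re-estimation (warm started); a response whose Newton
      ## run stalls (near-boundary configurations) keeps its last iterate
      tau <- lapply(seq_len(R), function(r)
        tryCatch(
          fit_thresholds(y[, r], theta[, r], C = categories[r],
                         start = tau[[r]], maxit = 50L),
          error = function(e) if (!is.null(e$tau)) e$tau else stop(e)))
    }

    ## with acceleration on, also search the global scale direction (the
    ## slow manifold when the likelihood supremum lies at infinity, e.g.
    ## separable data): double the configuration while the deviance
    ## improves, re-estimating thresholds at each trial scale
    if (control$accelerate) {
      lam_c <- .cell_lambdas(y, theta, tau)
      dev_c <- -2 * sum(log(pmax(lam_c$hi - lam_c$lo, 1e-12)))
      repeat {
        if (representation == "dominance") {
          Us <- 2 * U; Vs <- V; Bs <- if (restricted) 2 * B else NULL
        } else {
          Us <- 2 * U; Vs <- 2 * V; Bs <- if (restricted) 2 * B else NULL
        }
        theta_s <- .clmda_theta(representation, Us, Vs)
        tau_s <- lapply(seq_len(R), function(r)
          tryCatch(fit_thresholds(y[, r], theta_s[, r], C = categories[r],
                                  start = tau[[r]], maxit = 50L),
                   error = function(e)
                     if (!is.null(e$tau)) e$tau else stop(e)))
        lam_s <- .cell_lambdas(y, theta_s, tau_s)
        dev_s <- -2 * sum(log(pmax(lam_s$hi - lam_s$lo, 1e-12)))
        if (!is.finite(dev_s) || dev_s >= dev_c) break
        U <- Us; V <- Vs; B <- Bs; theta <- theta_s; tau <- tau_s
        dev_c <- dev_s
      }
    }
  }

  ## reporting identification: center unrestricted proximity solutions
  if (representation == "proximity" && !restricted) {
    ctr <- colMeans(rbind(U, V))
    U <- sweep(U, 2L, ctr); V <- sweep(V, 2L, ctr)
  }

  list(U = U, V = V, B = B, tau = tau, theta = theta,
       deviance = dev, trace = trace, converged = converged,
       iterations = length(trace) - 1L)
}

#' Number of free parameters
#'
#' Thresholds contribute \eqn{\sum_r (C_r - 1)}.  The structural part
#' contributes its parameter count net of indeterminacies: for the
#' inner-product models \eqn{S(N+R) - S^2} (CLPCA) and \eqn{S(P+R) - S^2}
#' (CLRRR), the \eqn{S^2} accounting for the invertible-transformation
#' indeterminacy of \eqn{U V'}; for the distance models rotations (and, when
#' unrestricted, translations) of the joint configuration leave all
#' distances unchanged, giving \eqn{S(N+R) - S(S+1)/2} (CLMDU) and
#' \eqn{S(P+R) - S(S-1)/2} (CLRMDU).  `ndim = 0` gives the thresholds-only
#' null model.
#'
#' @param model one of `"clpca"`, `"clrrr"`, `"clmdu"`, `"clrmdu"`.
#' @param ndim dimensionality S.
#' @param N,P,R numbers of observations, predictors, responses.
#' @param categories integer vector of category counts (length R, or a
#'   single value recycled).
#' @return Integer parameter count.
#' @examples
#' count_parameters("clrrr", ndim = 2, P = 10, R = 10, categories = 3)
#' @export
count_parameters <- function(model = c("clpca", "clrrr", "clmdu", "clrmdu"),
                             ndim, N = NULL, P = NULL, R,
                             categories) {
  model <- match.arg(model)
  S <- as.integer(ndim)
  categories <- rep_len(as.integer(categories), R)
  k_tau <- sum(categories - 1L)
  if (S == 0L) return(k_tau)
  k_str <- switch(model,
    clpca  = S * (N + R) - S^2,
    clrrr  = S * (P + R) - S^2,
    clmdu  = S * (N + R) - S * (S + 1L) / 2L,
    clrmdu = S * (P + R) - S * (S - 1L) / 2L)
  as.integer(k_tau + k_str)
}
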