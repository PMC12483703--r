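#' Population parameter fixture for simulation studies
#'
#' A fixed, documented set of population values with P = 5 predictors and
#' S = 2 dimensions: a coefficient matrix B, item structure V for 4
#' responses (the 8-response version appends a copy of V rotated by 45
#' degrees, so every added item is an isometric image of an original one),
#' thresholds for 3- or 5-category responses, and an AR(1) predictor
#' correlation matrix with lag-one correlation 0.3.  Threshold locations
#' differ by representation because distance-model structural values are
#' necessarily negative.
#'
#' @param R number of responses (4 or 8).
#' @param categories categories per response (3 or 5).
#' @param representation `"dominance"` or `"proximity"`.
#' @return list with components `B` (5 x 2), `V` (R x 2), `tau` (list of
#'   length R), `Sigma` (5 x 5), and `ndim = 2`.
#' @export
clmda_population <- function(R = 4, categories = 3,
                             representation = c("dominance", "proximity")) {
  representation <- match.arg(representation)
  if (!R %in% c(4L, 8L)) stop("'R' must be 4 or 8")
  if (!categories %in% c(3L, 5L)) stop("'categories' must be 3 or 5")
  B <- matrix(c( 0.8, -0.4,
                 0.6,  0.3,
                -0.5,  0.7,
                 0.2, -0.6,
                -0.3,  0.5), 5, 2, byrow = TRUE)
  V4 <- if (representation == "dominance") {
    matrix(c( 1.0,  0.0,
              0.7,  0.7,
              0.0,  1.0,
             -0.7,  0.7), 4, 2, byrow = TRUE)
  } else {
    matrix(c( 1.5,  0.0,
              0.0,  1.5,
             -1.5,  0.0,
              0.0, -1.5), 4, 2, byrow = TRUE)
  }
  V <- if (R == 8L) rbind(V4, V4 %*% .rotation2(pi / 4)) else V4
  tau1 <- if (representation == "dominance") {
    if (categories == 3L) c(-1, 1) else c(-2, -0.7, 0.7, 2)
  } else {
    if (categories == 3L) c(-3, -1) else c(-3.4, -2.6, -1.4, -0.6)
  }
  Sigma <- 0.3^abs(outer(1:5, 1:5, `-`))
  list(B = B, V = V, tau = rep(list(tau1), R), Sigma = Sigma, ndim = 2L,
       representation = representation)
}

.rotation2 <- function(angle)
  matrix(c(cos(angle), -sin(angle), sin(angle), cos(angle)), 2, 2)

#' Simulation design
#'
#' Bundles the factors of the data-generating process: sample size, numbers
#' of responses and categories, the predictor distribution (correlated
#' normal, moment-matched uniform, or a 5-point Likert discretization of
#' the correlated normal), the population parameters, a replication count
#' and a master seed.  Replicate draws are reproducible from (seed,
#' replicate index) alone, so condition order never affects them.
#'
#' @param representation `"dominance"` or `"proximity"`.
#' @param N sample size.
#' @param R number of responses (4 or 8).
#' @param categories categories per response (3 or 5).
#' @param predictors `"normal"`, `"uniform"` or `"likert"`.
#' @param reps number of replications.
#' @param seed master seed (integer).
#' @param population optional population list as from [clmda_population()].
#' @return list of class `"simulation_design"`.
#' @export
simulation_design <- function(representation = c("dominance", "proximity"),
                              N = 250, R = 4, categories = 3,
                              predictors = c("normal", "uniform", "likert"),
                              reps = 1, seed = 1,
                              population = NULL) {
  representation <- match.arg(representation)
  predictors <- match.arg(predictors)
  if (is.null(population))
    population <- clmda_population(R, categories, representation)
  stopifnot(reps >= 1)
  for (tr in population$tau)
    if (length(tr) > 1L && any(diff(tr) <= 0))
      stop("population thresholds must be strictly increasing")
  structure(list(representation = representation, N = as.integer(N),
                 R = as.integer(R), categories = as.integer(categories),
                 predictors = predictors, reps = as.integer(reps),
                 seed = as.integer(seed), population = population),
            class = "simulation_design")
}

## deterministic sub-seed below 2^31 from (master seed, replicate)
.sub_seed <- function(seed, replicate) {
  as.integer((as.double(seed) * 1000003 + as.double(replicate) * 7919) %%
               2147483629 + 1)
}

## variance of the 5-point Likert discretization of a standard normal at
## cuts -1.5, -0.5, 0.5, 1.5
.likert_sd <- local({
  p <- diff(stats::pnorm(c(-Inf, -1.5, -0.5, 0.5, 1.5, Inf)))
  sqrt(sum(p * ((1:5) - sum(p * (1:5)))^2))
})

#' Generate one synthetic dataset
#'
#' Predictors X are drawn per the design's distribution (all three are
#' centered and scaled to unit variance, the uniform and Likert variants
#' obtained by transforming the correlated normal draw so the correlation
#' structure carries over).  Row scores are \eqn{U = XB}; structural values
#' are inner products (dominance) or negated distances (proximity); each
#' response is drawn independently from the multinomial implied by the
#' cumulative logistic probabilities.
#'
#' @param design a [simulation_design()].
#' @param replicate replicate index (determines the sub-seed).
#' @return list with `y` (N x R integer), `x` (N x P), `theta`, `U`, and
#'   the design.
#' @export
generate_dataset <- function(design, replicate = 1) {
  pop <- design$population
  set.seed(.sub_seed(design$seed, replicate))
  P <- nrow(pop$B)
  Z <- matrix(stats::rnorm(design$N * P), design$N, P) %*% chol(pop$Sigma)
  X <- switch(design$predictors,
    normal  = Z,
    uniform = (stats::pnorm(Z) - 0.5) * sqrt(12),
    likert  = {
      L <- matrix(cut(Z, c(-Inf, -1.5, -0.5, 0.5, 1.5, Inf),
                      labels = FALSE), design$N, P)
      (L - 3) / .likert_sd
    })
  U <- X %*% pop$B
  theta <- .clmda_theta(design$representation, U, pop$V)
  probs <- cl_probabilities(theta, pop$tau)
  y <- matrix(0L, design$N, design$R)
  for (r in seq_len(design$R)) y[, r] <- .draw_categories(probs[[r]])
  colnames(y) <- paste0("item", seq_len(design$R))
  colnames(X) <- paste0("x", seq_len(P))
  list(y = y, x = X, theta = theta, U = U, design = design,
       replicate = replicate)
}

#' Recovery statistic Q
#'
#' Normalized root discrepancy between estimated and true structural
#' matrices,
#' \deqn{Q = \sqrt{\sum_{ir} (\hat\theta_{ir} - \theta_{ir})^2 \Big/
#'        \sum_{ir} \theta_{ir}^2},}
#' a Stress-1-type measure.  Because it compares \eqn{\Theta} directly it is
#' invariant to rotation, reflection and the other configuration
#' indeterminacies.
#'
#' @param theta_hat,theta_true matrices of equal dimension.
#' @return A single nonnegative number (0 for perfect recovery; 1 for the
#'   all-zero estimate).
#' @export
recovery_Q <- function(theta_hat, theta_true) {
  theta_hat <- as.matrix(theta_hat); theta_true <- as.matrix(theta_true)
  if (!identical(dim(theta_hat), dim(theta_true)))
    stop("dimension mismatch")
  ss <- sum(theta_true^2)
  if (ss == 0) stop("all-zero true structural matrix; Q undefined")
  sqrt(sum((theta_hat - theta_true)^2) / ss)
}

## fit a restricted model with the population-truth start plus
## extra random starts, returning the best
.study_fit <- function(dat, ndim, control, extra_starts) {
  pop <- dat$design$population
  truth_start <- if (ndim == pop$ndim) {
    list(U = dat$U, V = pop$V, B = pop$B)
  } else NULL
  fits <- list()
  if (!is.null(truth_start))
    fits[[1L]] <- clmda(dat$y, dat$x, dat$design$representation,
                        ndim = ndim, categories = rep(dat$design$categories,
                                                      dat$design$R),
                        control = control, start = truth_start)
  n_rand <- if (dat$design$representation == "proximity") extra_starts
            else if (is.null(truth_start)) 1L else 0L
  if (n_rand > 0L) {
    ctl <- control
    ctl$starts_dominance <- 1L
    ctl$starts_proximity <- max(1L, n_rand)
    ctl$seed <- .sub_seed(dat$design$seed, dat$replicate + 500000L)
    fits[[length(fits) + 1L]] <-
      clmda(dat$y, dat$x, dat$design$representation, ndim = ndim,
            categories = rep(dat$design$categories, dat$design$R),
            control = ctl)
  }
  fits[[which.min(vapply(fits, function(f) f$deviance, 1))]]
}

#' Parameter-recovery study
#'
#' Runs the restricted-model recovery protocol over a factorial grid:
#' generate data at the population values, fit the matching restricted
#' model at the population dimensionality, and record the recovery
#' statistic [recovery_Q()] per replicate.  Proximity fits start from the
#' population-truth configuration, the protocol the studies are designed
#' around; `extra_starts` adds random starts on top.
#'
#' @param representation `"dominance"` (CLRRR) or `"proximity"` (CLRMDU).
#' @param N,R,categories,predictors vectors of factor levels crossed into
#'   the study grid.
#' @param reps replications per condition.
#' @param seed master seed.
#' @param control fitting control; the default caps the outer loop at 300
#'   iterations, ample for the recovery statistic.
#' @param extra_starts random starts added to the population start for
#'   proximity fits.
#' @return data.frame with one row per (condition, replicate) holding `Q`,
#'   the fitted deviance and a convergence flag.
#' @export
run_recovery_study <- function(representation = "dominance",
                               N = c(250, 500, 1000), R = c(4, 8),
                               categories = c(3, 5),
                               predictors = "normal",
                               reps = 20, seed = 1,
                               control = clmda_control(maxit = 300L),
                               extra_starts = 0L) {
  grid <- expand.grid(N = N, R = R, categories = categories,
                      predictors = predictors,
                      stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid) * reps)
  k <- 0L
  for (g in seq_len(nrow(grid))) {
    design <- simulation_design(representation, N = grid$N[g],
                                R = grid$R[g],
                                categories = grid$categories[g],
                                predictors = grid$predictors[g],
                                reps = reps, seed = seed)
    for (rep_i in seq_len(reps)) {
      dat <- generate_dataset(design, rep_i)
      fit <- .study_fit(dat, design$population$ndim, control, extra_starts)
      k <- k + 1L
      out[[k]] <- data.frame(representation = representation,
                             N = grid$N[g], R = grid$R[g],
                             categories = grid$categories[g],
                             predictors = grid$predictors[g],
                             replicate = rep_i,
                             Q = recovery_Q(fit$theta, dat$theta),
                             deviance = fit$deviance,
                             converged = fit$converged)
    }
  }
  do.call(rbind, out)
}

#' Dimension-selection study
#'
#' Generates data at the two-dimensional population values and fits the
#' matching restricted model at each candidate dimensionality, recording
#' which dimensionality each information criterion selects.
#'
#' @inheritParams run_recovery_study
#' @param dims candidate dimensionalities fitted to each replicate.
#' @return list with `fits` (long data.frame: one row per replicate and
#'   dimensionality with deviance, AIC, BIC) and `counts` (selection counts
#'   per condition, criterion and dimensionality; counts sum to `reps`).
#' @export
run_dimension_selection_study <- function(representation = "dominance",
                                          N = 1000, R = 4, categories = 3,
                                          predictors = "normal",
                                          dims = 1:3, reps = 20, seed = 1,
                                          control = clmda_control(maxit = 300L),
                                          extra_starts = 0L) {
  grid <- expand.grid(N = N, R = R, categories = categories,
                      predictors = predictors, stringsAsFactors = FALSE)
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    design <- simulation_design(representation, N = grid$N[g], R = grid$R[g],
                                categories = grid$categories[g],
                                predictors = grid$predictors[g],
                                reps = reps, seed = seed)
    for (rep_i in seq_len(reps)) {
      dat <- generate_dataset(design, rep_i)
      for (S in dims) {
        fit <- .study_fit(dat, S, control, extra_starts)
        rows[[length(rows) + 1L]] <-
          data.frame(N = grid$N[g], R = grid$R[g],
                     categories = grid$categories[g],
                     predictors = grid$predictors[g], replicate = rep_i,
                     ndim = S, deviance = fit$deviance, AIC = fit$AIC,
                     BIC = fit$BIC)
      }
    }
  }
  fits <- do.call(rbind, rows)
  pick <- function(crit) {
    do.call(rbind, lapply(
      split(fits, fits[c("N", "R", "categories", "predictors", "replicate")],
            drop = TRUE),
      function(d) cbind(d[1L, c("N", "R", "categories", "predictors",
                                "replicate")],
                        criterion = crit,
                        chosen = d$ndim[which.min(d[[crit]])])))
  }
  sel <- rbind(pick("AIC"), pick("BIC"))
  rownames(sel) <- NULL
  tab <- stats::aggregate(replicate ~ N + R + categories + predictors +
                            criterion + chosen, data = sel, FUN = length)
  names(tab)[names(tab) == "replicate"] <- "count"
  list(fits = fits, selections = sel, counts = tab)
}
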