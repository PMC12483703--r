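#' Cumulative logistic probability machinery
#'
#' Internal machinery shared by all four model variants.  The model for
#' response variable \eqn{r} with ordered categories \eqn{1, \dots, C_r}
#' places a logistic latent variable at structural value \eqn{\theta_{ir}}
#' and cuts it at strictly increasing thresholds
#' \eqn{\tau_{r1} < \dots < \tau_{r,C_r-1}}:
#' \deqn{P(y_{ir} \le c) = \lambda_{irc} = F(\tau_{rc} - \theta_{ir}),}
#' with \eqn{F} the standard logistic distribution function, so that
#' \eqn{p_{irc} = \lambda_{irc} - \lambda_{ir,c-1}}.
#'
#' @name logistic-core
#' @keywords internal
NULL

## strictly increasing thresholds, length C - 1
.check_tau <- function(tau, C = NULL) {
  if (!is.list(tau)) stop("'tau' must be a list of per-response threshold vectors")
  for (r in seq_along(tau)) {
    tr <- tau[[r]]
    if (anyNA(tr) || any(!is.finite(tr)))
      stop(sprintf("non-finite threshold for response %d", r))
    if (length(tr) > 1L && any(diff(tr) <= 0))
      stop(sprintf("thresholds for response %d are not strictly increasing", r))
    if (!is.null(C) && length(tr) != C[r] - 1L)
      stop(sprintf("response %d: expected %d thresholds, got %d",
                   r, C[r] - 1L, length(tr)))
  }
  invisible(TRUE)
}

.check_y <- function(y, C) {
  if (anyNA(y)) stop("missing responses are not supported")
  for (r in seq_len(ncol(y))) {
    yr <- y[, r]
    if (any(yr < 1L | yr > C[r] | yr != round(yr)))
      stop(sprintf("response %d: categories must be integers in 1..%d", r, C[r]))
  }
  invisible(TRUE)
}

## cumulative probabilities at the two boundaries of each observed category.
## Returns N x R matrices lo = lambda_{i r, y-1} and hi = lambda_{i r, y}.
## plogis is numerically stable for arguments of any magnitude.
.cell_lambdas <- function(y, theta, tau) {
  N <- nrow(theta); R <- ncol(theta)
  lo <- matrix(0, N, R)
  hi <- matrix(1, N, R)
  for (r in seq_len(R)) {
    te <- c(-Inf, tau[[r]], Inf)            # tau_{r0} = -Inf, tau_{rC} = +Inf
    yr <- y[, r]
    lo[, r] <- stats::plogis(te[yr] - theta[, r])
    hi[, r] <- stats::plogis(te[yr + 1L] - theta[, r])
  }
  list(lo = lo, hi = hi)
}

#' Category probabilities under the cumulative logistic model
#'
#' @param theta numeric matrix (N x R) of structural values.
#' @param tau list of length R; element r holds the strictly increasing
#'   thresholds for response r (length \eqn{C_r - 1}).
#' @return A list of length R; element r is an N x \eqn{C_r} matrix of
#'   category probabilities with rows summing to one.
#' @examples
#' p <- cl_probabilities(matrix(0, 1, 1), list(c(-1, 1)))
#' rowSums(p[[1]])
#' @export
cl_probabilities <- function(theta, tau) {
  theta <- as.matrix(theta)
  .check_tau(tau)
  if (length(tau) != ncol(theta))
    stop("length(tau) must equal ncol(theta)")
  lapply(seq_along(tau), function(r) {
    lam <- cbind(0, stats::plogis(outer(-theta[, r], tau[[r]], `+`)), 1)
    lam[, -1L, drop = FALSE] - lam[, -ncol(lam), drop = FALSE]
  })
}

#' Observed-data deviance
#'
#' Twice the observed-data negative log-likelihood,
#' \eqn{-2 \sum_{i,r} \log p_{i r, y_{ir}}}.  Probabilities are floored at
#' 1e-12 inside the logarithm so the deviance stays finite on degenerate
#' cells.
#'
#' @param y integer matrix (N x R) of categories, coded 1..\eqn{C_r}.
#' @inheritParams cl_probabilities
#' @return A single number.
#' @export
cl_deviance <- function(y, theta, tau) {
  y <- as.matrix(y); theta <- as.matrix(theta)
  C <- vapply(tau, length, 1L) + 1L
  .check_tau(tau)
  .check_y(y, C)
  lam <- .cell_lambdas(y, theta, tau)
  p <- pmax(lam$hi - lam$lo, 1e-12)
  -2 * sum(log(p))
}

#' E-step: expected gradient for each cell
#'
#' For cell \eqn{(i, r)} with observed category \eqn{c}, the latent logistic
#' variable \eqn{z} is truncated to \eqn{(\tau_{r,c-1}, \tau_{rc})}.  The
#' conditional expectation of the gradient of the complete-data negative
#' log density, \eqn{E[\partial/\partial\theta \{-\log f(z-\theta)\}]},
#' has the closed form
#' \deqn{g_{ir} = 1 - \lambda_{ir,c-1} - \lambda_{irc},}
#' which follows from \eqn{F(z - \theta)} being uniform on
#' \eqn{(\lambda_{ir,c-1}, \lambda_{irc})} given the observed category.
#'
#' @inheritParams cl_deviance
#' @return N x R numeric matrix of expected gradients, evaluated at the
#'   supplied parameters.
#' @export
cl_estep_gradient <- function(y, theta, tau) {
  y <- as.matrix(y); theta <- as.matrix(theta)
  C <- vapply(tau, length, 1L) + 1L
  .check_tau(tau)
  .check_y(y, C)
  lam <- .cell_lambdas(y, theta, tau)
  1 - lam$lo - lam$hi
}

#' Working responses for the majorization step
#'
#' The second derivative of the complete-data negative log density is
#' \eqn{2 f(z - \theta) \le 1/2} (the logistic density is at most 1/4), so
#' the expected complete-data objective is majorized by a quadratic with
#' curvature 1/2, minimized at the working response
#' \deqn{\tilde z_{ir} = \theta_{ir} - 2 g_{ir}.}
#' The M-step therefore reduces to least squares on \eqn{\tilde Z}.
#'
#' @param theta structural matrix at which `g` was computed.
#' @param g expected-gradient matrix from [cl_estep_gradient()].
#' @return N x R matrix of working responses.
#' @export
cl_working_responses <- function(theta, g) {
  theta <- as.matrix(theta); g <- as.matrix(g)
  stopifnot(identical(dim(theta), dim(g)))
  theta - 2 * g
}
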