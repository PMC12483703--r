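#' Least-squares updates of the structural part
#'
#' Given working responses the M-step minimizes \eqn{\|\tilde Z - \Theta\|^2}
#' over the chosen parametrization of \eqn{\Theta}: truncated SVD for the
#' inner-product (dominance) models, a generalized SVD in the X'X metric for
#' reduced rank regression, and one sweep of a SMACOF unfolding update --
#' extended to negative working dissimilarities -- for the distance
#' (proximity) models.
#'
#' @name structural-updates
#' @keywords internal
NULL

## deterministic sign convention: largest-magnitude element of each column
## of V positive; U flipped along
.sign_fix <- function(U, V) {
  for (s in seq_len(ncol(V))) {
    j <- which.max(abs(V[, s]))
    if (V[j, s] < 0) { V[, s] <- -V[, s]; U[, s] <- -U[, s] }
  }
  list(U = U, V = V)
}

#' Rank-S principal-component update
#'
#' Truncated singular value decomposition \eqn{\tilde Z = P \Phi Q'} with
#' \eqn{U = P_S \Phi_S} and \eqn{V = Q_S}; by Eckart-Young \eqn{U V'} is the
#' best rank-S least-squares approximation of the working responses.
#'
#' @param ztilde N x R working-response matrix.
#' @param ndim dimensionality S.
#' @return list with components `U` (N x S) and `V` (R x S).
#' @export
update_pca <- function(ztilde, ndim) {
  ztilde <- as.matrix(ztilde)
  S <- as.integer(ndim)
  if (S < 1L) stop("'ndim' must be at least 1")
  if (S > min(dim(ztilde)))
    stop("'ndim' exceeds min(N, R)")
  sv <- svd(ztilde, nu = S, nv = S)
  d <- sv$d[seq_len(S)]
  if (any(d < .Machine$double.eps * max(sv$d, 1))) {
    warning("working-response matrix has rank below 'ndim'; ",
            "effective rank reduced")
  }
  .sign_fix(U = sv$u %*% diag(d, S), V = sv$v)
}

#' Reduced-rank regression update
#'
#' Minimizes \eqn{\|\tilde Z - X B V'\|^2} over B (P x S) and V (R x S)
#' through the generalized SVD in the X'X metric: with X = QR the thin QR
#' decomposition and \eqn{Q'\tilde Z = P \Phi Q_2'} the ordinary SVD,
#' \eqn{B = R^{-1} P_S \Phi_S} and \eqn{V = Q_{2,S}}.  With X the identity
#' this reduces exactly to [update_pca()].
#'
#' @inheritParams update_pca
#' @param X N x P predictor matrix of full column rank.
#' @param qrX optional pre-computed `qr(X)` (reused across EMM iterations).
#' @return list with components `B` (P x S), `V` (R x S) and `U = X B`.
#' @export
update_rrr <- function(ztilde, X, ndim, qrX = NULL) {
  ztilde <- as.matrix(ztilde); X <- as.matrix(X)
  S <- as.integer(ndim)
  if (S > min(ncol(X), ncol(ztilde)))
    stop("'ndim' exceeds min(P, R)")
  if (is.null(qrX)) qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("predictor matrix is rank deficient; drop collinear predictors")
  M <- qr.qty(qrX, ztilde)[seq_len(ncol(X)), , drop = FALSE]   # Q'Z, P x R
  sv <- svd(M, nu = S, nv = S)
  d <- sv$d[seq_len(S)]
  Rm <- qr.R(qrX)
  B <- backsolve(Rm, sv$u %*% diag(d, S))
  fix <- .sign_fix(B, sv$v)
  list(B = fix$U, V = fix$V, U = X %*% fix$U)
}

.distances <- function(U, V) {
  ## Euclidean distances between rows of U (N x S) and rows of V (R x S)
  sqU <- rowSums(U^2); sqV <- rowSums(V^2)
  d2 <- outer(sqU, sqV, `+`) - 2 * tcrossprod(U, V)
  sqrt(pmax(d2, 0))
}

#' Adjusted dissimilarities and weights for the unfolding step
#'
#' The distance-model M-step minimizes raw STRESS
#' \eqn{\sum_{ir} (\delta_{ir} - d_{ir})^2} with working dissimilarities
#' \eqn{\delta_{ir} = -\tilde z_{ir}}, which may be negative.  A negative
#' dissimilarity flips the sign of the cross term \eqn{-2\delta d}; bounding
#' \eqn{d \le (d^2 + \tilde d^2) / (2\tilde d)} at the current distance
#' \eqn{\tilde d} absorbs it into the quadratic part.  The resulting
#' majorizer is an ordinary weighted raw STRESS with
#' \deqn{a_{ir} = \max(\delta_{ir}, 0), \qquad
#'       w_{ir} = 1 + |\delta_{ir}| / \max(\tilde d_{ir}, \epsilon)
#'       \text{ if } \delta_{ir} < 0, \text{ else } 1.}
#' When all dissimilarities are nonnegative this is the standard least
#' squares unfolding system.  Both matrices change from iteration to
#' iteration.
#'
#' @inheritParams update_pca
#' @param U,V current configuration (ideal points and item locations).
#' @param eps small positive guard used when a current distance is zero.
#' @return list with components `A`, `W` (N x R matrices) and the current
#'   distance matrix `D`.
#' @export
build_smacof_system <- function(ztilde, U, V, eps = 1e-8) {
  delta <- -as.matrix(ztilde)
  D <- .distances(as.matrix(U), as.matrix(V))
  neg <- delta < 0
  A <- pmax(delta, 0)
  W <- matrix(1, nrow(delta), ncol(delta))
  if (any(neg))
    W[neg] <- 1 + abs(delta[neg]) / pmax(D[neg], eps)
  list(A = A, W = W, D = D)
}

## Guttman-type B matrix for targets A: b_ir = w a / d (0 where d = 0)
.guttman_b <- function(system) {
  B <- system$W * system$A / pmax(system$D, .Machine$double.xmin)
  B[system$D == 0] <- 0
  B
}

#' One alternating unfolding update (ideal points, then item locations)
#'
#' A Guttman-type update of the configuration for the weighted raw STRESS
#' majorizer built by [build_smacof_system()].  With row and column weight
#' totals \eqn{D_r = \mathrm{diag}(W 1)}, \eqn{D_c = \mathrm{diag}(W' 1)} and
#' \eqn{B} the Guttman matrix \eqn{b_{ir} = w_{ir} a_{ir} / d_{ir}},
#' \deqn{U^+ = D_r^{-1} (B_r U + (W - B) V), \qquad
#'       V^+ = D_c^{-1} (B_c V + (W - B)' U^+),}
#' where \eqn{B_r, B_c} are the diagonal row/column totals of \eqn{B}.  The
#' weighted raw STRESS never increases.
#'
#' @param system output of [build_smacof_system()].
#' @param U,V current configuration.
#' @return list with updated `U` and `V`.
#' @export
update_mdu <- function(system, U, V) {
  U <- as.matrix(U); V <- as.matrix(V)
  B <- .guttman_b(system)
  WB <- system$W - B
  dr <- rowSums(system$W); dc <- colSums(system$W)
  if (any(dr <= 0) || any(dc <= 0)) {
    warning("singular weight totals in unfolding update; ridge guard applied")
    dr <- dr + 1e-10; dc <- dc + 1e-10
  }
  Unew <- (rowSums(B) * U + WB %*% V) / dr
  Vnew <- (colSums(B) * V + crossprod(WB, Unew)) / dc
  list(U = Unew, V = Vnew)
}

#' Restricted unfolding update
#'
#' As [update_mdu()] but with ideal points constrained to \eqn{U = X B_x}:
#' the coefficient update solves the same majorizer normal equations in the
#' column space of X,
#' \deqn{B_x^+ = (X' D_r X)^{-1} X' (B_r U + (W - B) V),}
#' after which \eqn{U = X B_x^+} and the item locations are updated as
#' before.  With X the identity this reduces to [update_mdu()].
#'
#' @inheritParams update_mdu
#' @param X N x P predictor matrix of full column rank.
#' @param Bx current P x S coefficient matrix (U must equal `X %*% Bx`).
#' @return list with updated `Bx`, `U = X Bx` and `V`.
#' @export
update_rmdu <- function(system, X, Bx, V) {
  X <- as.matrix(X); V <- as.matrix(V)
  U <- X %*% Bx
  B <- .guttman_b(system)
  WB <- system$W - B
  dr <- rowSums(system$W); dc <- colSums(system$W)
  rhs <- crossprod(X, rowSums(B) * U + WB %*% V)
  XtWX <- crossprod(X, dr * X)
  Bx <- tryCatch(solve(XtWX, rhs), error = function(e) {
    warning("near-singular weighted cross-product; ridge guard applied")
    solve(XtWX + diag(1e-8, ncol(X)), rhs)
  })
  Unew <- X %*% Bx
  Vnew <- (colSums(B) * V + crossprod(WB, Unew)) / dc
  list(Bx = Bx, U = Unew, V = Vnew)
}

#' Weighted raw STRESS
#'
#' \eqn{\sum_{ir} w_{ir} (\delta_{ir} - d_{ir})^2} for a configuration;
#' with unit weights and \eqn{\delta = -\tilde Z} this is the least-squares
#' objective the distance-model M-step decreases.
#'
#' @param delta dissimilarity matrix.
#' @param U,V configuration.
#' @param W optional weight matrix (default all ones).
#' @return A single number.
#' @export
raw_stress <- function(delta, U, V, W = NULL) {
  D <- .distances(as.matrix(U), as.matrix(V))
  if (is.null(W)) W <- 1
  sum(W * (delta - D)^2)
}
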