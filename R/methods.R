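#' @export
print.clmda <- function(x, ...) {
  cat(sprintf("%s: cumulative logistic %s %smodel\n",
              toupper(x$model),
              if (x$representation == "dominance") "dominance (inner-product)"
              else "proximity (distance)",
              if (x$restricted) "restricted " else ""))
  cat(sprintf("  N = %d observations, R = %d responses%s, S = %d dimensions\n",
              x$N, x$R,
              if (x$restricted) sprintf(", P = %d predictors", x$P) else "",
              x$ndim))
  cat(sprintf("  deviance %.2f on %d parameters (null %.2f)\n",
              x$deviance, x$n_parameters, x$null_deviance))
  cat(sprintf("  AIC %.2f   BIC %.2f\n", x$AIC, x$BIC))
  cat(sprintf("  %d outer iterations, %sconverged (best of %d start%s)\n",
              x$iterations, if (x$converged) "" else "NOT ",
              x$n_starts, if (x$n_starts > 1L) "s" else ""))
  invisible(x)
}

#' Summary of a fitted cumulative logistic multidimensional model
#'
#' @param object a fitted [clmda()] model.
#' @param ... unused.
#' @export
summary.clmda <- function(object, ...) {
  out <- list(fit = object,
              tau = object$tau,
              V = object$V,
              B = object$B,
              category_fit = vapply(seq_len(object$R), function(r) {
                p <- cl_probabilities(object$theta[, r, drop = FALSE],
                                      object$tau[r])[[1L]]
                mean(max.col(p) == object$y[, r])
              }, numeric(1)))
  class(out) <- "summary.clmda"
  out
}

#' @export
print.summary.clmda <- function(x, ...) {
  print(x$fit)
  cat("\nItem structure (V):\n")
  V <- x$V
  dimnames(V) <- list(colnames(x$fit$y),
                      paste0("dim", seq_len(ncol(V))))
  print(round(V, 3))
  if (!is.null(x$B)) {
    cat("\nCoefficients (B):\n")
    B <- x$B
    dimnames(B) <- list(colnames(x$fit$x), paste0("dim", seq_len(ncol(B))))
    print(round(B, 3))
  }
  cat("\nThresholds:\n")
  for (r in seq_along(x$tau))
    cat(sprintf("  response %d: %s\n", r,
                paste(sprintf("%.3f", x$tau[[r]]), collapse = " ")))
  invisible(x)
}

#' Extract model coefficients
#'
#' Returns the coefficient matrix B for restricted models and the item
#' structure V otherwise; `what` selects a specific component.
#'
#' @param object a fitted [clmda()] model.
#' @param what `"B"`, `"V"`, `"U"` or `"tau"`.
#' @param ... unused.
#' @export
coef.clmda <- function(object,
                       what = if (object$restricted) "B" else "V", ...) {
  switch(match.arg(what, c("B", "V", "U", "tau")),
         B = object$B, V = object$V, U = object$U, tau = object$tau)
}

#' @export
logLik.clmda <- function(object, ...) {
  structure(-object$deviance / 2,
            df = object$n_parameters, nobs = object$N,
            class = "logLik")
}

#' Fitted structural values or category probabilities
#'
#' @param object a fitted [clmda()] model.
#' @param type `"link"` for the structural matrix \eqn{\Theta},
#'   `"probs"` for per-response category probabilities.
#' @param ... unused.
#' @export
fitted.clmda <- function(object, type = c("link", "probs"), ...) {
  type <- match.arg(type)
  if (type == "link") object$theta
  else cl_probabilities(object$theta, object$tau)
}

#' Predictions from a fitted model
#'
#' For restricted models `newdata` (a predictor matrix or data frame on the
#' original scale) is mapped through the stored preprocessing to new row
#' scores \eqn{U = XB}; unrestricted models predict for the fitted rows.
#' The `"class"` prediction uses the latent-variable rule: category
#' \eqn{c} is predicted when \eqn{\tau_{r,c-1} \le \hat\theta_{ir} <
#' \tau_{rc}}.
#'
#' @param object a fitted [clmda()] model.
#' @param newdata optional new predictors (restricted models only).
#' @param type `"link"`, `"probs"` or `"class"`.
#' @param ... unused.
#' @export
predict.clmda <- function(object, newdata = NULL,
                          type = c("link", "probs", "class"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    theta <- object$theta
  } else {
    if (!object$restricted)
      stop("'newdata' predictions require a restricted model")
    X <- if (is.data.frame(newdata)) {
      apply_predictors(object$pred_info, newdata)
    } else as.matrix(newdata)
    U <- X %*% object$B
    theta <- .clmda_theta(object$representation, U, object$V)
  }
  switch(type,
         link  = theta,
         probs = cl_probabilities(theta, object$tau),
         class = latent_class(theta, object$tau))
}

#' Latent-rule category assignment
#'
#' @param theta structural matrix.
#' @param tau threshold list.
#' @return integer matrix of predicted categories.
#' @export
latent_class <- function(theta, tau) {
  theta <- as.matrix(theta)
  out <- matrix(1L, nrow(theta), ncol(theta))
  for (r in seq_along(tau))
    out[, r] <- 1L + rowSums(outer(theta[, r], tau[[r]], `>=`))
  out
}

#' Simulate ordinal responses from a fitted model
#'
#' @param object a fitted [clmda()] model.
#' @param nsim number of replicate response matrices.
#' @param seed optional seed.
#' @param ... unused.
#' @return A list of `nsim` integer matrices.
#' @export
simulate.clmda <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  probs <- cl_probabilities(object$theta, object$tau)
  replicate(nsim, {
    y <- matrix(0L, object$N, object$R)
    for (r in seq_len(object$R))
      y[, r] <- .draw_categories(probs[[r]])
    y
  }, simplify = FALSE)
}

## one multinomial draw per row of a probability matrix (inverse CDF)
.draw_categories <- function(p) {
  cum <- t(apply(p, 1L, cumsum))
  u <- stats::runif(nrow(p))
  1L + rowSums(u > cum[, -ncol(cum), drop = FALSE])
}

#' Deviance residuals
#'
#' Per-cell deviance residuals \eqn{\mathrm{sign}(y - \hat y)
#' \sqrt{-2 \log p_{ir,y_{ir}}}}, where \eqn{\hat y} is the latent-rule
#' predicted category.
#'
#' @param object a fitted [clmda()] model.
#' @param ... unused.
#' @export
residuals.clmda <- function(object, ...) {
  lam <- .cell_lambdas(object$y, object$theta, object$tau)
  p <- pmax(lam$hi - lam$lo, 1e-12)
  yhat <- latent_class(object$theta, object$tau)
  sign(object$y - yhat) * sqrt(-2 * log(p))
}

#' @export
deviance.clmda <- function(object, ...) object$deviance
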