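#' Stepwise model selection
#'
#' Two-stage selection for the restricted models, keeping the computational
#' load modest.  Stage 1 fits the model with all predictors at each candidate
#' dimensionality and selects S by the chosen information criterion.  Stage 2
#' keeps S fixed and iteratively tries to drop predictor groups (sets of
#' columns of X); the drop that most improves the criterion is accepted and
#' the pass repeats until no drop improves it.
#'
#' @inheritParams clmda
#' @param x predictor matrix (N x P).
#' @param dims candidate dimensionalities.
#' @param groups named list mapping group names to column indices of `x`;
#'   defaults to one group per column.
#' @param criterion `"AIC"` or `"BIC"`.
#' @return An object of class `"clmda_step"` with components `dimension`
#'   (stage-1 table), `drops` (stage-2 table: the full model plus one row
#'   per evaluated candidate drop), `ndim`, `kept`, and `fit` (the final
#'   model).
#' @export
clmda_step <- function(y, x, representation = c("dominance", "proximity"),
                       dims = 1:3, groups = NULL,
                       criterion = c("AIC", "BIC"),
                       categories = NULL, control = clmda_control()) {
  representation <- match.arg(representation)
  criterion <- match.arg(criterion)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (is.null(groups)) {
    groups <- as.list(seq_len(ncol(x)))
    names(groups) <- colnames(x)
  }

  ## stage 1: dimensionality with all predictors
  dim_tab <- do.call(rbind, lapply(dims, function(S) {
    fit <- clmda(y, x, representation, ndim = S, categories = categories,
                 control = control)
    data.frame(ndim = S, deviance = fit$deviance,
               n_parameters = fit$n_parameters, AIC = fit$AIC, BIC = fit$BIC)
  }))
  S <- dim_tab$ndim[which.min(dim_tab[[criterion]])]

  ## stage 2: backward elimination of predictor groups at fixed S
  kept <- names(groups)
  current <- clmda(y, x, representation, ndim = S, categories = categories,
                   control = control)
  drops <- data.frame(pass = 0L, dropped = "(none)",
                      deviance = current$deviance, AIC = current$AIC,
                      BIC = current$BIC, accepted = TRUE)
  pass <- 0L
  repeat {
    if (length(kept) < 2L) break
    pass <- pass + 1L
    cand <- lapply(kept, function(g) {
      cols <- sort(unlist(groups[setdiff(kept, g)]))
      clmda(y, x[, cols, drop = FALSE], representation, ndim = S,
            categories = categories, control = control)
    })
    crit <- vapply(cand, function(f) f[[criterion]], numeric(1))
    drops <- rbind(drops, data.frame(pass = pass, dropped = kept,
                                     deviance = vapply(cand, deviance, 1),
                                     AIC = vapply(cand, function(f) f$AIC, 1),
                                     BIC = vapply(cand, function(f) f$BIC, 1),
                                     accepted = FALSE))
    best <- which.min(crit)
    if (crit[best] < current[[criterion]]) {
      drops$accepted[nrow(drops) - length(kept) + best] <- TRUE
      current <- cand[[best]]
      kept <- setdiff(kept, kept[best])
    } else break
  }

  structure(list(dimension = dim_tab, drops = drops, ndim = S,
                 kept = kept, criterion = criterion, fit = current),
            class = "clmda_step")
}

#' @export
print.clmda_step <- function(x, ...) {
  cat("Stepwise selection (criterion:", x$criterion, ")\n\n")
  cat("Stage 1 - dimensionality:\n")
  print(x$dimension, row.names = FALSE)
  cat(sprintf("\nSelected S = %d\n\nStage 2 - predictor groups:\n", x$ndim))
  print(x$drops, row.names = FALSE)
  cat("\nRetained groups:", paste(x$kept, collapse = ", "), "\n")
  invisible(x)
}
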