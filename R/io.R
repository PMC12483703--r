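#' Predictor preprocessing
#'
#' Numeric columns are standardized (centered, unit variance); factor or
#' character columns are dummy-coded against a reference category.  The
#' returned metadata lets [apply_predictors()] map new data identically and
#' lets the triplot back-transform axis markers to the original scale.
#'
#' @param x data frame of predictors.
#' @param reference named list: reference level per categorical column
#'   (default: first level).
#' @param scale standardize numeric columns.
#' @return list with `X` (numeric matrix) and `info` (metadata).
#' @export
build_predictors <- function(x, reference = list(), scale = TRUE) {
  stopifnot(is.data.frame(x))
  cols <- list(); center <- list(); scl <- list()
  levels_info <- list(); dummy_columns <- character()
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.numeric(v)) {
      ctr <- if (scale) mean(v) else 0
      s <- if (scale) stats::sd(v) else 1
      if (!is.finite(s) || s == 0) stop("constant numeric predictor: ", nm)
      cols[[nm]] <- (v - ctr) / s
      center[[nm]] <- ctr; scl[[nm]] <- s
    } else {
      v <- as.factor(v)
      ref <- if (nm %in% names(reference)) reference[[nm]] else levels(v)[1L]
      if (!ref %in% levels(v)) stop("unknown reference level for ", nm)
      lev <- c(ref, setdiff(levels(v), ref))
      levels_info[[nm]] <- lev
      for (lv in lev[-1L]) {
        cn <- paste(nm, lv, sep = ".")
        cols[[cn]] <- as.numeric(v == lv)
        dummy_columns <- c(dummy_columns, cn)
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, info = list(center = center, scale = scl,
                          levels = levels_info,
                          dummy_columns = dummy_columns,
                          columns = colnames(X)))
}

#' Apply stored predictor preprocessing to new data
#'
#' @param info metadata from [build_predictors()].
#' @param newdata data frame with the original predictor columns.
#' @return numeric matrix with the same columns as the training matrix.
#' @export
apply_predictors <- function(info, newdata) {
  stopifnot(is.data.frame(newdata))
  cols <- list()
  for (nm in names(info$center))
    cols[[nm]] <- (newdata[[nm]] - info$center[[nm]]) / info$scale[[nm]]
  for (nm in names(info$levels)) {
    lev <- info$levels[[nm]]
    v <- as.character(newdata[[nm]])
    if (any(!v %in% lev)) stop("unknown category in predictor ", nm)
    for (lv in lev[-1L])
      cols[[paste(nm, lv, sep = ".")]] <- as.numeric(v == lv)
  }
  X <- do.call(cbind, cols[info$columns])
  colnames(X) <- info$columns
  X
}

#' Read an ordinal dataset from a delimited text file
#'
#' Reads a CSV (UTF-8, header row, comma-delimited) and maps the declared
#' response columns onto consecutive integer categories following the
#' user-supplied category order -- the coding direction matters for the
#' proximity models, so every response column must declare its order
#' explicitly.  Predictor columns are preprocessed via
#' [build_predictors()].
#'
#' @param path CSV file path.
#' @param responses named list: for each response column, the category
#'   labels in increasing order (character, or numeric values in increasing
#'   order).
#' @param predictors optional character vector of predictor column names.
#' @param reference named list of reference levels for categorical
#'   predictors.
#' @return list with `y` (integer matrix), `categories`, `x` (matrix or
#'   `NULL`), `pred_info`, and `data` (the raw data frame).
#' @export
read_ordinal_data <- function(path, responses, predictors = NULL,
                              reference = list()) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(names(responses)) || any(names(responses) == ""))
    stop("'responses' must be a named list of category orderings")
  missing_cols <- setdiff(c(names(responses), predictors), names(dat))
  if (length(missing_cols))
    stop("columns not found: ", paste(missing_cols, collapse = ", "))
  y <- matrix(0L, nrow(dat), length(responses),
              dimnames = list(NULL, names(responses)))
  for (j in seq_along(responses)) {
    nm <- names(responses)[j]
    ord <- as.character(responses[[j]])
    v <- as.character(dat[[nm]])
    idx <- match(v, ord)
    if (anyNA(idx)) {
      bad <- which(is.na(idx))[1L]
      stop(sprintf("undeclared category '%s' in column '%s', row %d",
                   v[bad], nm, bad))
    }
    y[, j] <- idx
  }
  categories <- vapply(responses, length, 1L)
  log <- sprintf("response '%s': %d categories mapped in declared order %s",
                 names(responses), categories,
                 vapply(responses, function(o)
                   paste(o, collapse = " < "), ""))
  x <- NULL; pred_info <- NULL
  if (!is.null(predictors)) {
    bp <- build_predictors(dat[predictors], reference = reference)
    x <- bp$X; pred_info <- bp$info
    log <- c(log,
             sprintf("numeric predictor '%s': centered %.6g, scaled %.6g",
                     names(pred_info$center),
                     unlist(pred_info$center), unlist(pred_info$scale)),
             sprintf("categorical predictor '%s': dummy-coded, reference '%s'",
                     names(pred_info$levels),
                     vapply(pred_info$levels, `[`, "", 1L)))
  }
  list(y = y, categories = categories, x = x, pred_info = pred_info,
       data = dat, log = log)
}

#' Serialize a fitted model to JSON
#'
#' Writes the model specification, estimated parameters, deviance trace and
#' information criteria as a structured-text document; [read_clmda_json()]
#' restores an object suitable for plotting and prediction (the raw data
#' are included so the biplot can show observation points).
#'
#' @param fit a fitted [clmda()] model.
#' @param path output file.
#' @export
write_clmda_json <- function(fit, path) {
  obj <- list(model = fit$model, representation = fit$representation,
              restricted = fit$restricted, ndim = fit$ndim,
              categories = fit$categories,
              N = fit$N, R = fit$R, P = fit$P,
              U = fit$U, V = fit$V, B = fit$B, tau = fit$tau,
              theta = fit$theta, y = fit$y, x = fit$x,
              deviance = fit$deviance, null_deviance = fit$null_deviance,
              trace = fit$trace, n_parameters = fit$n_parameters,
              AIC = fit$AIC, BIC = fit$BIC, converged = fit$converged,
              iterations = fit$iterations, start_best = fit$start_best)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_clmda_json
#' @export
read_clmda_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("U", "V", "B", "theta", "y", "x"))
    if (!is.null(obj[[nm]])) obj[[nm]] <- as.matrix(obj[[nm]])
  tt <- obj$tau   # equal-length threshold vectors simplify to a matrix
  obj$tau <- if (is.matrix(tt)) {
    lapply(seq_len(nrow(tt)), function(i) as.numeric(tt[i, ]))
  } else lapply(tt, as.numeric)
  class(obj) <- "clmda"
  obj
}

#' Export biplot geometry as structured text
#'
#' @param geometry output of [clmda_geometry()].
#' @param path output JSON file.
#' @export
write_geometry_json <- function(geometry, path) {
  jsonlite::write_json(unclass(geometry), path, digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}
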