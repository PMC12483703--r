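#' Biplot and triplot geometry
#'
#' Computes the drawable elements of the model display on a selected pair of
#' dimensions.  Observations are points at the row scores.  For the
#' dominance models each response gets a calibrated variable axis through
#' the origin with direction \eqn{v_r}: the marker for threshold
#' \eqn{\tau_{rc}} sits at \eqn{(\tau_{rc} / v_r'v_r)\, v_r} and is labeled
#' "c|c+1"; every point projecting onto that marker has latent value exactly
#' \eqn{\tau_{rc}}, and the decision line through the marker orthogonal to
#' the axis separates the predicted categories.  For the proximity models
#' each response is a point with threshold circles of radius
#' \eqn{-\tau_{rc}}: inside the circle \eqn{P(y > c) > 0.5}; circles with
#' nonpositive radius are suppressed.  For restricted models predictor
#' geometry is added: numeric predictors get interpolation axes along the
#' rows of B with a solid segment spanning the observed range and value
#' markers back-transformed to the original scale; dummy-coded categories
#' get points at their coefficient rows, the reference sitting at the
#' origin.
#'
#' @param fit a fitted [clmda()] model.
#' @param dims length-2 integer vector selecting the dimension pair.
#' @return A list of class `"clmda_geometry"` with components `points`,
#'   `responses`, and (restricted models) `predictors`.
#' @export
clmda_geometry <- function(fit, dims = c(1, 2)) {
  dims <- as.integer(dims)
  if (length(dims) != 2L || any(dims < 1L) || any(dims > fit$ndim))
    stop("'dims' must select two fitted dimensions")
  U <- fit$U[, dims, drop = FALSE]
  V <- fit$V[, dims, drop = FALSE]
  rnames <- colnames(fit$y)
  if (is.null(rnames)) rnames <- paste0("item", seq_len(fit$R))

  responses <- lapply(seq_len(fit$R), function(r) {
    v <- V[r, ]
    tau <- fit$tau[[r]]
    labels <- paste0(seq_along(tau), "|", seq_along(tau) + 1L)
    if (fit$representation == "dominance") {
      vv <- sum(v^2)
      if (vv < 1e-12) {
        warning("zero loading vector for response ", r, "; axis suppressed")
        return(list(name = rnames[r], type = "axis", suppressed = TRUE))
      }
      mk <- outer(tau / vv, v)       # marker coordinates, one row per cut
      list(name = rnames[r], type = "axis", suppressed = FALSE,
           direction = v,
           markers = data.frame(d1 = mk[, 1L], d2 = mk[, 2L],
                                tau = tau, label = labels),
           ## decision lines: through each marker, orthogonal to v
           lines = data.frame(d1 = mk[, 1L], d2 = mk[, 2L],
                              dir1 = -v[2L], dir2 = v[1L], label = labels))
    } else {
      radius <- -tau
      list(name = rnames[r], type = "point", center = v,
           circles = data.frame(radius = radius, tau = tau, label = labels,
                                drawn = radius > 0))
    }
  })

  out <- list(points = data.frame(d1 = U[, 1L], d2 = U[, 2L]),
              representation = fit$representation,
              dims = dims, responses = responses)

  if (fit$restricted) {
    B <- fit$B[, dims, drop = FALSE]
    info <- fit$pred_info
    pnames <- colnames(fit$x)
    if (is.null(pnames)) pnames <- paste0("x", seq_len(nrow(B)))
    out$predictors <- lapply(seq_len(nrow(B)), function(p) {
      b <- B[p, ]
      xp <- fit$x[, p]
      is_dummy <- all(xp %in% c(0, 1)) &&
        !is.null(info) && pnames[p] %in% info$dummy_columns
      if (is_dummy) {
        list(name = pnames[p], type = "category_point", position = b)
      } else {
        rng <- range(xp)
        ## value markers at pretty raw values, mapped through the stored
        ## standardization when available
        ctr <- 0; scl <- 1
        if (!is.null(info) && pnames[p] %in% names(info$center)) {
          ctr <- info$center[[pnames[p]]]; scl <- info$scale[[pnames[p]]]
        }
        raw <- pretty(rng * scl + ctr, n = 4)
        std <- (raw - ctr) / scl
        keep <- std >= rng[1L] & std <= rng[2L]
        list(name = pnames[p], type = "axis", direction = b,
             segment = rbind(rng[1L] * b, rng[2L] * b),
             markers = data.frame(d1 = std[keep] * b[1L],
                                  d2 = std[keep] * b[2L],
                                  value = raw[keep]))
      }
    })
  }
  class(out) <- "clmda_geometry"
  out
}

#' Interpolate predictor profiles into the display
#'
#' Positions of supplied predictor profiles by vector addition of the
#' per-predictor contributions, i.e. \eqn{x'B} row by row.
#'
#' @param fit a fitted restricted [clmda()] model.
#' @param xnew matrix or data frame of predictor profiles (data frames are
#'   mapped through the stored preprocessing).
#' @return Matrix of positions (rows) in the full S dimensions.
#' @export
interpolate_profile <- function(fit, xnew) {
  if (!fit$restricted) stop("interpolation requires a restricted model")
  X <- if (is.data.frame(xnew)) apply_predictors(fit$pred_info, xnew)
       else matrix(xnew, ncol = nrow(fit$B))
  X %*% fit$B
}

#' Biplot / triplot of a fitted model
#'
#' Renders the geometry of [clmda_geometry()] with base graphics:
#' observation points, calibrated response axes with "c|c+1" threshold
#' markers and dotted decision lines (dominance) or response points with
#' threshold circles (proximity), plus predictor axes (solid over the
#' observed range, dotted to the plot edge) and category points for
#' restricted models.  Variable labels sit at the positive end of each
#' axis.  One-dimensional fits fall back to a stripe plot.
#'
#' @param x a fitted [clmda()] model.
#' @param dims dimension pair to display.
#' @param decision_lines draw the per-response decision boundaries.
#' @param cex.points,col.points styling for observation points.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.clmda <- function(x, dims = c(1, 2), decision_lines = TRUE,
                       cex.points = 0.5, col.points = "grey50", ...) {
  if (x$ndim == 1L) {
    graphics::stripchart(x$U[, 1L], method = "jitter", pch = 16,
                         cex = cex.points, col = col.points,
                         xlab = "dimension 1",
                         main = toupper(x$model))
    for (r in seq_len(x$R))
      graphics::abline(v = if (x$representation == "dominance")
        x$tau[[r]] / x$V[r, 1L] else NA, lty = 3)
    return(invisible(x))
  }
  geom <- clmda_geometry(x, dims)
  pts <- geom$points
  cent <- lapply(geom$responses, function(rs)
    if (rs$type == "point") rs$center else c(0, 0))
  lim <- range(c(pts$d1, pts$d2, unlist(cent), 0))
  lim <- lim + c(-0.1, 0.1) * diff(lim)
  graphics::plot(NA, xlim = lim, ylim = lim, asp = 1,
                 xlab = sprintf("dimension %d", dims[1L]),
                 ylab = sprintf("dimension %d", dims[2L]),
                 main = toupper(x$model), ...)
  graphics::points(pts$d1, pts$d2, pch = 16, cex = cex.points,
                   col = col.points)
  ext <- 2 * max(abs(lim))

  for (rs in geom$responses) {
    if (rs$type == "axis") {
      if (isTRUE(rs$suppressed)) next
      v <- rs$direction / sqrt(sum(rs$direction^2))
      graphics::segments(-ext * v[1L], -ext * v[2L], ext * v[1L],
                         ext * v[2L], col = "darkgreen")
      graphics::points(rs$markers$d1, rs$markers$d2, pch = 3,
                       col = "darkgreen")
      graphics::text(rs$markers$d1, rs$markers$d2, rs$markers$label,
                     pos = 3, cex = 0.7, col = "darkgreen")
      if (decision_lines)
        graphics::segments(rs$lines$d1 - ext * rs$lines$dir1,
                           rs$lines$d2 - ext * rs$lines$dir2,
                           rs$lines$d1 + ext * rs$lines$dir1,
                           rs$lines$d2 + ext * rs$lines$dir2,
                           lty = 3, col = "darkgreen")
      lab_at <- 0.95 * max(abs(lim)) * v
      graphics::text(lab_at[1L], lab_at[2L], rs$name, col = "darkgreen",
                     cex = 0.8, font = 2)
    } else {
      graphics::points(rs$center[1L], rs$center[2L], pch = 17,
                       col = "darkgreen")
      graphics::text(rs$center[1L], rs$center[2L], rs$name, pos = 3,
                     cex = 0.8, font = 2, col = "darkgreen")
      drawn <- rs$circles[rs$circles$drawn, , drop = FALSE]
      if (nrow(drawn) && decision_lines) {
        graphics::symbols(rep(rs$center[1L], nrow(drawn)),
                          rep(rs$center[2L], nrow(drawn)),
                          circles = drawn$radius, inches = FALSE,
                          add = TRUE, fg = "darkgreen", lty = 2)
        graphics::text(rs$center[1L] + drawn$radius, rs$center[2L],
                       drawn$label, cex = 0.6, col = "darkgreen")
      }
    }
  }

  if (!is.null(geom$predictors)) {
    for (pr in geom$predictors) {
      if (pr$type == "category_point") {
        graphics::points(pr$position[1L], pr$position[2L], pch = 15,
                         col = "steelblue")
        graphics::text(pr$position[1L], pr$position[2L], pr$name, pos = 3,
                       cex = 0.8, col = "steelblue")
      } else {
        b <- pr$direction
        if (sum(b^2) < 1e-12) next
        u <- b / sqrt(sum(b^2))
        graphics::segments(-ext * u[1L], -ext * u[2L], ext * u[1L],
                           ext * u[2L], lty = 3, col = "steelblue")
        graphics::segments(pr$segment[1L, 1L], pr$segment[1L, 2L],
                           pr$segment[2L, 1L], pr$segment[2L, 2L],
                           lwd = 2, col = "steelblue")
        if (nrow(pr$markers)) {
          graphics::points(pr$markers$d1, pr$markers$d2, pch = 4,
                           cex = 0.6, col = "steelblue")
          graphics::text(pr$markers$d1, pr$markers$d2, pr$markers$value,
                         pos = 1, cex = 0.6, col = "steelblue")
        }
        lab_at <- 0.9 * max(abs(lim)) * u
        graphics::text(lab_at[1L], lab_at[2L], pr$name, cex = 0.8,
                       col = "steelblue", font = 2)
      }
    }
  }
  invisible(x)
}

#' Export a biplot to an image file
#'
#' The device is chosen from the file extension: `.png`, `.svg` or `.pdf`.
#'
#' @inheritParams plot.clmda
#' @param fit a fitted [clmda()] model.
#' @param file output path.
#' @param width,height device size in inches.
#' @export
clmda_biplot_file <- function(fit, file, dims = c(1, 2), width = 7,
                              height = 7, ...) {
  ext <- tolower(tools::file_ext(file))
  switch(ext,
         png = grDevices::png(file, width = width, height = height,
                              units = "in", res = 150),
         svg = grDevices::svg(file, width = width, height = height),
         pdf = grDevices::pdf(file, width = width, height = height),
         stop("unsupported extension: ", ext))
  on.exit(grDevices::dev.off())
  plot(fit, dims = dims, ...)
  invisible(file)
}
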