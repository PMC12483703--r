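make_dom_fit <- function() {
  fx <- rand_ordinal(40, 3, C = 4, seed = 120)
  clmda(fx$y, representation = "dominance", ndim = 2,
        control = clmda_control(maxit = 100))
}

test_that("variable-axis markers calibrate the latent scale", {
  fit <- make_dom_fit()
  ## impose a known loading/threshold pair and inspect the geometry
  fit$V[1, ] <- c(1, 0)
  fit$tau[[1]] <- c(-2, 0, 2)
  g <- clmda_geometry(fit)
  mk <- g$responses[[1]]$markers
  expect_equal(mk$d1, c(-2, 0, 2), tolerance = 1e-12)
  expect_equal(mk$d2, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(mk$label, c("1|2", "2|3", "3|4"))

  ## diagonal axis: marker at tau/(v'v) v, and points on the orthogonal
  ## line through the marker all have latent value tau
  fit$V[2, ] <- c(1, 1)
  fit$tau[[2]] <- c(0.4, 1, 1.8)
  g <- clmda_geometry(fit)
  mk <- g$responses[[2]]$markers
  expect_equal(unlist(mk[2, c("d1", "d2")]), c(0.5, 0.5),
               tolerance = 1e-12, ignore_attr = TRUE)
  for (t in c(-3, -0.5, 2)) {
    pt <- c(mk$d1[2], mk$d2[2]) + t * c(-1, 1)   # orthogonal direction
    expect_equal(sum(pt * fit$V[2, ]), 1, tolerance = 1e-12)
  }

  ## homogeneity: doubling the loading halves the marker distance
  v <- fit$V[3, ]; tau3 <- fit$tau[[3]]
  g1 <- clmda_geometry(fit)
  fit$V[3, ] <- 2 * v
  g2 <- clmda_geometry(fit)
  expect_equal(g2$responses[[3]]$markers$d1,
               g1$responses[[3]]$markers$d1 / 2, tolerance = 1e-12)

  ## zero loading vector suppresses the axis with a warning
  fit$V[3, ] <- c(0, 0)
  expect_warning(g3 <- clmda_geometry(fit), "suppressed")
  expect_true(g3$responses[[3]]$suppressed)
})

test_that("threshold circles encode the median-probability boundary", {
  fx <- rand_ordinal(30, 3, C = 4, seed = 121,
                     representation = "proximity")
  fit <- clmda(fx$y, representation = "proximity", ndim = 2,
               control = clmda_control(maxit = 80, starts_proximity = 1))
  fit$tau[[1]] <- c(-2, -1, 1)
  g <- clmda_geometry(fit)
  circ <- g$responses[[1]]$circles
  expect_equal(circ$radius, c(2, 1, -1), tolerance = 1e-12)
  expect_identical(circ$drawn, c(TRUE, TRUE, FALSE))

  ## on the circle P(y > c) is exactly one half; just inside it exceeds it
  v <- g$responses[[1]]$center
  for (cc in 1:2) {
    rad <- circ$radius[cc]
    pt_on <- v + c(rad, 0)
    pt_in <- v + c(rad - 1e-3, 0)
    pt_out <- v + c(rad + 1e-3, 0)
    pgt <- function(pt) {
      th <- -sqrt(sum((pt - v)^2))
      1 - plogis(fit$tau[[1]][cc] - th)
    }
    expect_equal(pgt(pt_on), 0.5, tolerance = 1e-10)
    expect_gt(pgt(pt_in), 0.5)
    expect_lte(pgt(pt_out), 0.5)
  }

  ## degenerate circle at the item point
  fit$tau[[1]] <- c(-1, 0, 1)
  g <- clmda_geometry(fit)
  expect_equal(g$responses[[1]]$circles$radius[2], 0)
})

test_that("triplot interpolation is vector addition", {
  d <- simulation_design("dominance", N = 200, R = 4, categories = 3,
                         seed = 140)
  dat <- generate_dataset(d, 1)
  fit <- clmda(dat$y, dat$x, "dominance", ndim = 2,
               control = clmda_control(maxit = 100))

  ## all-reference / all-zero profile sits at the origin
  expect_equal(drop(interpolate_profile(fit, rep(0, 5))), c(0, 0),
               tolerance = 1e-12)

  ## a one-hot profile lands on the corresponding coefficient row
  oh <- c(0, 0, 1, 0, 0)
  expect_equal(drop(interpolate_profile(fit, oh)), fit$B[3, ],
               tolerance = 1e-12)

  ## random profiles equal x'B
  set.seed(9)
  X <- matrix(rnorm(15), 3, 5)
  expect_equal(interpolate_profile(fit, X), X %*% fit$B,
               tolerance = 1e-12)

  g <- clmda_geometry(fit)
  expect_length(g$predictors, 5)
  expect_true(all(vapply(g$predictors, function(p) p$type, "") == "axis"))
})

test_that("grid category assignment from the geometry matches the latent
           rule for both families", {
  ## dominance: projection value against thresholds
  fit <- make_dom_fit()
  grid <- as.matrix(expand.grid(seq(-3, 3, length.out = 60),
                                seq(-3, 3, length.out = 60)))
  for (r in 1:3) {
    v <- fit$V[r, ]; tau <- fit$tau[[r]]
    theta <- drop(grid %*% v)
    from_rule <- 1L + rowSums(outer(theta, tau, `>=`))
    ## geometry: compare projection position along the axis with marker
    ## positions (all scaled by v'v, so comparisons are equivalent)
    g <- clmda_geometry(fit)
    mk <- g$responses[[r]]$markers
    proj <- drop(grid %*% v) / sum(v^2)
    mk_pos <- drop(as.matrix(mk[, c("d1", "d2")]) %*% v) / sum(v^2)
    from_geom <- 1L + rowSums(outer(proj, mk_pos, `>=`))
    expect_identical(from_geom, from_rule)
    ## and both agree with the probability argmax under the latent rule
    probs <- cl_probabilities(matrix(theta, ncol = 1), fit$tau[r])[[1]]
    ## the latent rule picks the category whose interval contains theta;
    ## verify it always has positive probability mass
    expect_true(all(probs[cbind(seq_len(nrow(probs)), from_rule)] > 0))
  }

  ## proximity: distance against circle radii
  fx <- rand_ordinal(30, 3, C = 4, seed = 122,
                     representation = "proximity")
  fitp <- clmda(fx$y, representation = "proximity", ndim = 2,
                control = clmda_control(maxit = 80, starts_proximity = 1))
  gp <- clmda_geometry(fitp)
  for (r in 1:3) {
    v <- gp$responses[[r]]$center
    tau <- fitp$tau[[r]]
    d <- sqrt(rowSums(sweep(grid, 2, v)^2))
    from_rule <- 1L + rowSums(outer(-d, tau, `>=`))
    radii <- gp$responses[[r]]$circles$radius
    from_geom <- 1L + rowSums(outer(d, radii, `<=`))
    expect_identical(from_geom, from_rule)
  }
})

test_that("rendering produces parseable files and honours dimension
           selection", {
  fit3 <- local({
    fx <- rand_ordinal(30, 4, C = 3, seed = 123)
    clmda(fx$y, representation = "dominance", ndim = 3,
          control = clmda_control(maxit = 60))
  })
  ## dimension pair selection recomputes the geometry on those coordinates
  g13 <- clmda_geometry(fit3, dims = c(1, 3))
  expect_equal(g13$points$d2, fit3$U[, 3], tolerance = 1e-12)
  expect_equal(g13$responses[[1]]$direction, fit3$V[1, c(1, 3)],
               tolerance = 1e-12)

  f_png <- tempfile(fileext = ".png")
  clmda_biplot_file(fit3, f_png)
  expect_true(file.exists(f_png) && file.size(f_png) > 0)

  ## vector output is text and carries drawn elements; the marker labels
  ## live in the exported geometry (glyphs are outlined in the svg itself)
  if (capabilities("cairo")) {
    f_svg <- tempfile(fileext = ".svg")
    clmda_biplot_file(fit3, f_svg)
    svg_txt <- paste(readLines(f_svg, warn = FALSE), collapse = "\n")
    expect_true(grepl("<svg", svg_txt, fixed = TRUE))
    expect_true(grepl("use xlink", svg_txt) || grepl("glyph", svg_txt) ||
                  grepl("text", svg_txt))
    unlink(f_svg)
  }
  labs <- unlist(lapply(clmda_geometry(fit3)$responses,
                        function(r) r$markers$label))
  expect_true(all(c("1|2", "2|3") %in% labs))
  unlink(f_png)

  ## geometry export as structured text round-trips
  f_json <- tempfile(fileext = ".json")
  write_geometry_json(clmda_geometry(fit3), f_json)
  back <- jsonlite::read_json(f_json, simplifyVector = TRUE)
  expect_equal(nrow(back$points), 30)
  unlink(f_json)
})
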