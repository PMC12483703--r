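fit_ctl <- clmda_control(maxit = 150)

test_that("EMM deviance trace is monotone and beats the null model", {
  set.seed(41)
  for (rep_i in 1:3) {
    fx <- rand_ordinal(40, 3, C = 3, seed = 100 + rep_i)
    X <- matrix(rnorm(40 * 2), 40, 2)
    fits <- list(
      clmda(fx$y, representation = "dominance", ndim = 1,
            control = fit_ctl),
      clmda(fx$y, X, representation = "dominance", ndim = 1,
            control = fit_ctl),
      clmda(fx$y, representation = "proximity", ndim = 2,
            control = clmda_control(maxit = 150, starts_proximity = 2,
                                    seed = rep_i)),
      clmda(fx$y, X, representation = "proximity", ndim = 2,
            control = clmda_control(maxit = 150, starts_proximity = 2,
                                    seed = rep_i)))
    expect_identical(vapply(fits, function(f) f$model, ""),
                     c("clpca", "clrrr", "clmdu", "clrmdu"))
    for (f in fits) {
      expect_true(all(diff(f$trace) <= 1e-8))
      expect_lt(f$deviance, f$null_deviance)
      expect_equal(f$AIC, f$deviance + 2 * f$n_parameters)
      expect_equal(f$BIC, f$deviance + log(40) * f$n_parameters)
    }
  }
})

test_that("strong low-rank dominance structure is recovered", {
  d <- simulation_design("dominance", N = 4000, R = 8, categories = 5,
                         seed = 99)
  dat <- generate_dataset(d, 1)
  fit <- clmda(dat$y, dat$x, "dominance", ndim = 2,
               control = clmda_control(maxit = 400))
  expect_lt(recovery_Q(fit$theta, dat$theta), 0.05)
})

test_that("dominance fits are start-invariant", {
  ## restricted fixture: interior optimum, so different random starts must
  ## land on the same deviance
  d <- simulation_design("dominance", N = 300, R = 4, categories = 3,
                         seed = 17)
  dat <- generate_dataset(d, 1)
  set.seed(1)
  ctl <- clmda_control(tol = 1e-9, maxit = 3000)
  devs <- vapply(1:2, function(k) {
    B0 <- matrix(rnorm(10), 5, 2)
    s <- list(B = B0, U = dat$x %*% B0, V = matrix(rnorm(8), 4, 2))
    clmda(dat$y, dat$x, representation = "dominance", ndim = 2,
          control = ctl, start = s)$deviance
  }, 1)
  expect_lt(abs(devs[1] - devs[2]), 1e-4)
})

test_that("best-of-starts deviance never worsens with more starts", {
  fx <- rand_ordinal(30, 3, C = 3, seed = 66, representation = "proximity")
  devs <- vapply(c(1, 3, 5), function(ns)
    clmda(fx$y, representation = "proximity", ndim = 2,
          control = clmda_control(maxit = 120, starts_proximity = ns,
                                  seed = 7))$deviance, 1)
  expect_true(all(diff(devs) <= 1e-10))
})

test_that("the 1-D model assigns the same likelihood as a graded-response
           formulation at matched parameters", {
  ## structural equivalence: CLPCA in one dimension and a joint-ML graded
  ## response model share the deviance function cell for cell
  set.seed(77)
  y <- rand_ordinal(20, 3, C = 4, seed = 77)$y
  m <- grm_machine(y, 4)
  for (k in 1:5) {
    u <- rnorm(20); v <- rnorm(3, 1, 0.4)
    eta <- replicate(3, c(rnorm(1), log(runif(2, 0.3, 1.5))))
    par <- c(u, v, as.vector(eta))
    tau <- lapply(1:3, function(r)
      eta[1, r] + c(0, cumsum(exp(eta[-1, r]))))
    expect_equal(cl_deviance(y, outer(u, v), tau), m$dev(par),
                 tolerance = 1e-10)
  }
})

test_that("parameter counts follow the indeterminacy-adjusted formulas", {
  ## rank-2 reduced-rank regression, 10 predictors, 10 responses, C = 3
  expect_identical(count_parameters("clrrr", ndim = 2, P = 10, R = 10,
                                    categories = 3), 56L)
  ## full-rank: equivalent to ten separate proportional-odds fits with 12
  ## parameters each
  expect_identical(count_parameters("clrrr", ndim = 10, P = 10, R = 10,
                                    categories = 3), 120L)
  ## thresholds-only null
  expect_identical(count_parameters("clpca", ndim = 0, N = 50, R = 4,
                                    categories = c(3, 4, 5, 2)), 10L)
  ## distance models: translation free only when unrestricted
  expect_identical(count_parameters("clmdu", ndim = 2, N = 50, R = 4,
                                    categories = 3),
                   as.integer(2 * 54 - 3 + 8))
  expect_identical(count_parameters("clrmdu", ndim = 2, P = 5, R = 4,
                                    categories = 3),
                   as.integer(2 * 9 - 1 + 8))
})

test_that("fitted-model methods are mutually consistent", {
  fx <- rand_ordinal(35, 3, C = 3, seed = 88)
  X <- matrix(rnorm(35 * 2), 35, 2, dimnames = list(NULL, c("a", "b")))
  fit <- clmda(fx$y, X, representation = "dominance", ndim = 2,
               control = fit_ctl)

  expect_s3_class(fit, "clmda")
  expect_output(print(fit), "CLRRR")
  expect_output(print(summary(fit)), "Thresholds")
  expect_equal(unname(AIC(fit)), fit$AIC)
  expect_equal(unname(BIC(fit)), fit$BIC)
  expect_equal(dim(coef(fit)), c(2L, 2L))

  ## predict: link equals U V', probabilities row-normalized, classes from
  ## the latent rule
  expect_equal(predict(fit), fit$theta)
  pr <- predict(fit, type = "probs")
  expect_equal(rowSums(pr[[2]]), rep(1, 35), tolerance = 1e-12)
  cls <- predict(fit, type = "class")
  te <- fit$tau[[1]]
  expect_identical(cls[, 1],
                   1L + rowSums(outer(fit$theta[, 1], te, `>=`)))

  ## newdata round trip through X B
  Xn <- matrix(rnorm(10), 5, 2)
  expect_equal(predict(fit, newdata = Xn),
               tcrossprod(Xn %*% fit$B, fit$V), tolerance = 1e-12)

  ## simulate reproducibly
  s1 <- simulate(fit, nsim = 2, seed = 5)
  s2 <- simulate(fit, nsim = 2, seed = 5)
  expect_identical(s1, s2)
  expect_true(all(s1[[1]] %in% 1:3))

  ## residuals finite, zero only where prediction is "certain"
  res <- residuals(fit)
  expect_true(all(is.finite(res)))

  ## JSON round trip preserves the estimated model
  f <- tempfile(fileext = ".json")
  write_clmda_json(fit, f)
  back <- read_clmda_json(f)
  expect_equal(back$deviance, fit$deviance)
  expect_equal(back$U, fit$U, ignore_attr = TRUE)
  expect_equal(back$tau, fit$tau, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$trace, fit$trace)
  unlink(f)
})

test_that("stepwise selection keeps informative predictors and reports all
           candidates", {
  ## stage bookkeeping: single S, no droppable groups
  fx <- rand_ordinal(40, 3, C = 3, seed = 101)
  X <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
  sel <- clmda_step(fx$y, X, "dominance", dims = 2, groups = list(),
                    control = fit_ctl)
  expect_identical(nrow(sel$dimension), 1L)
  expect_identical(nrow(sel$drops), 1L)
  expect_identical(sel$fit$ndim, 2L)

  ## a predictor with true zero coefficients is dropped without AIC loss
  ok <- 0L
  for (rep_i in 1:6) {
    d <- simulation_design("dominance", N = 800, R = 4, categories = 3,
                           seed = 200 + rep_i)
    dat <- generate_dataset(d, 1)
    Xz <- cbind(dat$x, junk = rnorm(800))
    full <- clmda(dat$y, Xz, "dominance", ndim = 2, control = fit_ctl)
    red <- clmda(dat$y, dat$x, "dominance", ndim = 2, control = fit_ctl)
    if (red$AIC <= full$AIC) ok <- ok + 1L
  }
  expect_gte(ok, 5L)

  ## full stepwise pass: report rows = 1 + number of candidate drops
  d <- simulation_design("dominance", N = 400, R = 4, categories = 3,
                         seed = 300)
  dat <- generate_dataset(d, 1)
  Xz <- cbind(dat$x, junk = rnorm(400))
  sel2 <- clmda_step(dat$y, Xz, "dominance", dims = 2, control = fit_ctl)
  n_cand <- sum(sel2$drops$pass > 0)
  expect_identical(nrow(sel2$drops), 1L + n_cand)
  expect_identical(nrow(sel2$dimension), 1L)
})
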