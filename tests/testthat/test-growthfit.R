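test_that("origin-constrained linear fit has the closed form", {
  # exact line through the origin
  f <- fit_linear_origin(data.frame(t_scaled = 1:5, n_outlier = 3 * (1:5)))
  expect_equal(f$params[["c"]], 3)
  expect_equal(f$rss, 0)
  # x = {1,2}, y = {1,3}: c = 7/5, verified against a brute-force grid
  f2 <- fit_linear_origin(data.frame(t_scaled = c(1, 2),
                                     n_outlier = c(1, 3)))
  expect_equal(f2$params[["c"]], 7 / 5)
  grid <- seq(0.5, 2.5, by = 1e-4)
  rss_grid <- vapply(grid, function(cc) sum((c(1, 3) - cc * c(1, 2))^2),
                     numeric(1))
  expect_equal(f2$params[["c"]], grid[which.min(rss_grid)],
               tolerance = 1e-3)
  # adding (0, 0) leaves the slope unchanged
  f3 <- fit_linear_origin(data.frame(t_scaled = c(0, 1, 2),
                                     n_outlier = c(0, 1, 3)))
  expect_equal(f3$params[["c"]], f2$params[["c"]])
  expect_error(fit_linear_origin(data.frame(t_scaled = c(0, 0),
                                            n_outlier = c(1, 2))),
               "all x are zero")
})

test_that("exponential fit recovers exact parameters from noiseless data", {
  x <- seq(2, 16, 2)
  y <- -5 * (1 - exp(0.4 * x))
  f <- fit_exponential_origin(data.frame(t_scaled = x, n_outlier = y))
  expect_true(f$converged)
  expect_equal(f$params[["a"]], -5, tolerance = 1e-4)
  expect_equal(f$params[["b"]], 0.4, tolerance = 1e-4)
  expect_lt(f$rss, 1e-6)
  # saturating branch is reachable too
  ys <- 30 * (1 - exp(-0.3 * x))
  fs <- fit_exponential_origin(data.frame(t_scaled = x, n_outlier = ys))
  expect_true(fs$converged)
  expect_equal(fs$params[["b"]], -0.3, tolerance = 1e-4)
})

test_that("exponential fit matches a 2-D brute-force grid on noisy data", {
  set.seed(8)
  x <- seq(2, 16, 2)
  y <- 2 * x + rnorm(8, sd = 1.5)  # noisy linear data
  f <- fit_exponential_origin(data.frame(t_scaled = x, n_outlier = y))
  agrid <- seq(-200, 200, length.out = 400)
  bgrid <- seq(-1, 1, length.out = 801)
  best <- Inf
  for (b in bgrid) {
    u <- 1 - exp(b * x)
    for (a in agrid) {
      r <- sum((y - a * u)^2)
      if (r < best) best <- r
    }
  }
  expect_lte(f$rss, best * 1.001)
})

test_that("flat series yield nonconvergence; plateaus hit the saturating branch", {
  # near-constant counts (the high-recent-gene-flow signature): the best
  # least-squares "exponential" degenerates to a constant, b runs to the
  # working bound and the fit is reported as non-converged
  y <- c(20, 19, 21, 20, 20, 21, 19, 20)
  f <- fit_exponential_origin(data.frame(t_scaled = seq(2, 16, 2),
                                         n_outlier = y))
  expect_false(f$converged)
  expect_true(is.na(f$aic))
  # rise-then-plateau data converge on the saturating branch (b < 0)
  plateau <- c(0, 15, 19, 20, 20, 21, 20, 20)
  f2 <- fit_exponential_origin(data.frame(t_scaled = seq(2, 16, 2),
                                          n_outlier = plateau))
  expect_true(f2$converged)
  expect_lt(f2$params[["b"]], 0)
})

test_that("degenerate all-zero series returns the documented a = 0 fit", {
  f <- fit_exponential_origin(data.frame(t_scaled = seq(2, 16, 2),
                                         n_outlier = rep(0, 8)))
  expect_true(f$converged)
  expect_equal(f$params[["a"]], 0)
  expect_equal(f$rss, 0)
  expect_equal(f$aic, -Inf)
})

test_that("AIC bookkeeping follows n log(rss/n) + 2k", {
  x <- seq(2, 16, 2)
  fl <- fit_linear_origin(data.frame(t_scaled = x,
                                     n_outlier = x + c(1, -1)))
  expect_equal(fl$aic, 8 * log(fl$rss / 8) + 4)
  # identical rss: the exponential pays one extra parameter
  fe <- fl; fe$params <- c(a = 1, b = 1); class(fe) <- "growth_fit"
  fe$aic <- 8 * log(fl$rss / 8) + 6
  expect_equal(compare_aic(fl, fe), -2)
  # rss smaller by exactly exp(2/n) offsets the penalty (algebraic check)
  n <- 8
  rss1 <- 4
  rss2 <- rss1 / exp(2 / n)
  expect_equal((n * log(rss1 / n) + 4) - (n * log(rss2 / n) + 6), 0)
  # strongly curved noiseless exponential data
  y <- -2 * (1 - exp(0.45 * x))
  d <- data.frame(t_scaled = x, n_outlier = y)
  expect_gt(compare_aic(fit_linear_origin(d), fit_exponential_origin(d)),
            100)
})

test_that("Delta-AIC is NA with a warning when a fit did not converge", {
  d <- data.frame(t_scaled = seq(2, 16, 2),
                  n_outlier = c(20, 19, 21, 20, 20, 21, 19, 20))
  fe <- fit_exponential_origin(d)
  fl <- fit_linear_origin(d)
  expect_warning(da <- compare_aic(fl, fe), "did not converge")
  expect_true(is.na(da))
})

test_that("b is invariant to rescaling y (absorbed by a)", {
  set.seed(12)
  x <- seq(2, 16, 2)
  y <- abs(-0.5 * (1 - exp(0.35 * x)) + rnorm(8, sd = 2))
  f1 <- fit_exponential_origin(data.frame(t_scaled = x, n_outlier = y))
  f2 <- fit_exponential_origin(data.frame(t_scaled = x, n_outlier = 10 * y))
  expect_equal(f2$params[["b"]], f1$params[["b"]], tolerance = 1e-6)
  expect_equal(f2$params[["a"]], 10 * f1$params[["a"]], tolerance = 1e-6)
})

test_that("exponential fit agrees with nls as an independent route", {
  set.seed(4)
  x <- seq(2, 16, 2)
  y <- -0.4 * (1 - exp(0.38 * x)) * exp(rnorm(8, sd = 0.1))
  f <- fit_exponential_origin(data.frame(t_scaled = x, n_outlier = y))
  nf <- stats::nls(y ~ a * (1 - exp(b * x)),
                   start = list(a = -1, b = 0.3),
                   control = stats::nls.control(maxiter = 1000))
  expect_equal(f$params[["b"]], coef(nf)[["b"]], tolerance = 1e-4)
  expect_equal(f$rss, sum(residuals(nf)^2), tolerance = 1e-6)
})

test_that("tidy and glance summarise growth fits", {
  d <- data.frame(t_scaled = seq(2, 16, 2),
                  n_outlier = -1 * (1 - exp(0.3 * seq(2, 16, 2))))
  f <- fit_exponential_origin(d)
  td <- tidy(f)
  expect_equal(td$term, c("a", "b"))
  g <- glance(f)
  expect_true(g$converged)
  expect_equal(g$model, "exponential_origin")
  row <- fit_growth_models(d)
  expect_gt(row$delta_aic, 0)
})
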