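test_that("one-way ANOVA matches brute-force sums of squares", {
  set.seed(2)
  d <- data.frame(scenario = rep(c("s1", "s2", "s3"), each = 5),
                  b = c(rnorm(5, 0.38), rnorm(5, 0.45), rnorm(5, 0.32)))
  res <- anova_coefficients(d)
  # independent route: explicit sums of squares
  gm <- mean(d$b)
  means <- tapply(d$b, d$scenario, mean)
  ssb <- sum(5 * (means - gm)^2)
  ssw <- sum((d$b - means[d$scenario])^2)
  f_oracle <- (ssb / 2) / (ssw / 12)
  expect_equal(res$f_statistic, f_oracle)
  expect_equal(res$p_value, pf(f_oracle, 2, 12, lower.tail = FALSE))
  # and against R's own aov
  expect_equal(res$f_statistic,
               summary(aov(b ~ scenario, d))[[1]]$`F value`[1])
})

test_that("ANOVA degenerate cases use the documented sentinels", {
  ident <- data.frame(scenario = rep(c("a", "b"), each = 3),
                      b = rep(c(1, 2, 3), 2))
  res <- anova_coefficients(ident)
  expect_equal(res$f_statistic, 0)
  expect_equal(res$p_value, 1)
  sep <- data.frame(scenario = rep(c("a", "b"), each = 3),
                    b = rep(c(0, 1), each = 3))
  res2 <- anova_coefficients(sep)
  expect_equal(res2$f_statistic, Inf)
  expect_equal(res2$p_value, 0)
  expect_error(anova_coefficients(
    data.frame(scenario = c("a", "a", "b"), b = 1:3)), ">= 2")
})

test_that("Tukey HSD q statistics match a brute-force studentized range", {
  set.seed(6)
  d <- data.frame(scenario = rep(c("s1", "s2", "s3"), each = 5),
                  b = c(rnorm(5, 0), rnorm(5, 0.2), rnorm(5, 2)))
  res <- tukey_hsd(d)
  # brute-force: q = |diff| / sqrt(MSE/n), p from ptukey
  means <- tapply(d$b, d$scenario, mean)
  mse <- sum((d$b - means[d$scenario])^2) / 12
  for (i in seq_len(nrow(res))) {
    diffm <- means[res$group1[i]] - means[res$group2[i]]
    q <- abs(diffm) / sqrt(mse / 5)
    expect_equal(res$p_adj[i], unname(ptukey(q, 3, 12, lower.tail = FALSE)),
                 tolerance = 1e-10)
    expect_equal(res$estimate[i], unname(diffm))
  }
  # far-outlying group gets its own letter
  lets <- attr(res, "letters")
  expect_false(lets$letters[lets$group == "s3"] %in%
                 lets$letters[lets$group != "s3"])
})

test_that("identical groups share one letter with all p = 1", {
  d <- data.frame(scenario = rep(c("a", "b", "c"), each = 4),
                  b = rep(c(1, 2, 2, 3), 3))
  res <- tukey_hsd(d)
  expect_true(all(res$p_adj > 0.999))
  lets <- attr(res, "letters")
  expect_equal(unique(lets$letters), "a")
})

test_that("BCa interval matches an independent re-derivation", {
  x <- c(0.31, 0.45, 0.28, 0.52, 0.38, 0.41, 0.35, 0.47, 0.30, 0.44)
  set.seed(99)
  ci <- bca_ci(x, n_boot = 4000)
  # independent route: plain percentile bootstrap + analytic z0/a formulas
  set.seed(99)
  boots <- replicate(4000, mean(sample(x, replace = TRUE)))
  z0 <- qnorm(sum(boots < mean(x)) / 4000)
  jk <- sapply(seq_along(x), function(i) mean(x[-i]))
  a <- sum((mean(jk) - jk)^3) / (6 * sum((mean(jk) - jk)^2)^1.5)
  al <- pnorm(z0 + (z0 + qnorm(c(0.025, 0.975))) /
                (1 - a * (z0 + qnorm(c(0.025, 0.975)))))
  oracle <- quantile(boots, al, names = FALSE)
  expect_equal(ci$lower, oracle[1])
  expect_equal(ci$upper, oracle[2])
  expect_lt(ci$lower, mean(x))
  expect_gt(ci$upper, mean(x))
})

test_that("BCa handles constant and symmetric inputs", {
  cst <- bca_ci(rep(0.4, 10))
  expect_equal(cst$lower, 0.4)
  expect_equal(cst$upper, 0.4)
  set.seed(5)
  sym <- bca_ci(rep(c(-1, 0, 1), 30), n_boot = 8000)
  expect_equal(sym$lower, -sym$upper, tolerance = 0.2)
  expect_error(bca_ci(c(1, 2)), "n >= 3")
})

test_that("BCa agrees with the boot package on the same resamples scale", {
  skip_if_not_installed("boot")
  set.seed(17)
  x <- rnorm(25, mean = 0.4, sd = 0.1)
  set.seed(1)
  mine <- bca_ci(x, n_boot = 20000)
  set.seed(1)
  bt <- boot::boot(x, function(d, i) mean(d[i]), R = 20000)
  bci <- boot::boot.ci(bt, type = "bca")$bca
  expect_equal(mine$lower, bci[4], tolerance = 0.01)
  expect_equal(mine$upper, bci[5], tolerance = 0.01)
})

test_that("scenario_summary drops nonconverged replicates with counts", {
  set.seed(10)
  fits <- tibble::tibble(
    scenario = rep(c("a", "b"), each = 10),
    b = c(rnorm(10, 0.4, 0.05), rnorm(10, 0.3, 0.05)),
    converged = rep(c(TRUE, TRUE, TRUE, TRUE, FALSE), 4))
  s <- scenario_summary(fits, n_boot = 500)
  expect_equal(s$n_total, c(10, 10))
  expect_equal(s$n_converged, c(8, 8))
  expect_equal(s$mean_b[1], mean(fits$b[fits$scenario == "a" &
                                          fits$converged]))
  expect_true(all(s$ci_lower < s$mean_b & s$ci_upper > s$mean_b))
})
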