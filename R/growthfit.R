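# Origin-constrained growth-curve fits of divergent-genome size versus
# divergence time, and their AIC comparison.  The linear model y = c x has
# a closed form; the exponential model y = a (1 - e^(b x)) (through the
# origin for all a, b) is fitted by multi-start damped Newton on b with a
# profiled analytically.  x is divergence time in units of N generations
# (2..16 in the default design); the scale of b depends on this choice.

new_growth_fit <- function(model, params, rss, n, converged, iterations,
                           data) {
  k <- length(params) + 1  # mean parameters + error variance
  aic <- if (!converged) NA_real_
         else if (rss <= 0) -Inf
         else n * log(rss / n) + 2 * k
  structure(list(model = model, params = params, rss = rss, n = n,
                 aic = aic, converged = converged, iterations = iterations,
                 data = data), class = "growth_fit")
}

resolve_xy <- function(data, x, y) {
  if (is.data.frame(data)) {
    xv <- rlang::eval_tidy(rlang::enquo(x), data)
    yv <- rlang::eval_tidy(rlang::enquo(y), data)
  } else {
    xv <- data; yv <- x
  }
  stopifnot(is.numeric(xv), is.numeric(yv), length(xv) == length(yv))
  keep <- !is.na(xv) & !is.na(yv)
  list(x = as.numeric(xv[keep]), y = as.numeric(yv[keep]))
}

#' Linear regression through the origin
#'
#' Least-squares fit of `y = c x` with no intercept; closed form
#' `c = sum(xy) / sum(x^2)`.
#'
#' @param data A data frame (default columns `t_scaled`, `n_outlier`), or
#'   the x vector if `x` is the y vector.
#' @param x,y Columns to use (tidy evaluation) or numeric vectors.
#' @return A `growth_fit` object; see [tidy.growth_fit()].
#' @export
#' @examples
#' fit_linear_origin(data.frame(t_scaled = 1:4, n_outlier = c(2, 4, 6, 8)))
fit_linear_origin <- function(data, x = t_scaled, y = n_outlier) {
  d <- resolve_xy(data, {{ x }}, {{ y }})
  if (length(d$x) < 2) stop("need at least 2 points", call. = FALSE)
  sxx <- sum(d$x^2)
  if (sxx == 0) stop("all x are zero; slope undefined", call. = FALSE)
  cc <- sum(d$x * d$y) / sxx
  rss <- sum((d$y - cc * d$x)^2)
  new_growth_fit("linear_origin", c(c = cc), rss, length(d$x),
                 converged = TRUE, iterations = 0L,
                 data = tibble::tibble(x = d$x, y = d$y))
}

exp_rss <- function(b, x, y) {
  u <- 1 - exp(b * x)
  su2 <- sum(u^2)
  if (su2 == 0) return(list(rss = sum(y^2), a = 0))
  a <- sum(y * u) / su2
  list(rss = sum((y - a * u)^2), a = a)
}

#' Exponential regression through the origin
#'
#' Least-squares fit of `y = a (1 - e^(b x))`, which passes through the
#' origin for every `(a, b)`.  Superlinear growth corresponds to `a < 0,
#' b > 0`; the saturating branch (`a > 0, b < 0`) describes growth to a
#' plateau.  For each start of a sign-spanning grid of `b` values, `a` is
#' profiled analytically (`a = sum(y u) / sum(u^2)`, `u = 1 - e^(bx)`) and
#' `b` updated by damped Newton steps.  A fit converges when the relative
#' gradient norm drops below 1e-8 or the step below 1e-10 within
#' `max_iter` iterations; runs that drift to the working bound on |b| are
#' reported as non-converged (this is the typical outcome for
#' flat-then-plateau data, where the best least-squares "exponential"
#' degenerates to a constant).
#'
#' @inheritParams fit_linear_origin
#' @param max_iter Iteration cap per start (default 1000).
#' @param b_grid Starting values for `b`; the default spans both signs.
#' @return A `growth_fit`; `converged` is `FALSE` when no start met the
#'   tolerance (the best fit found is still reported, with `aic = NA`).
#' @export
#' @examples
#' x <- seq(2, 16, 2)
#' y <- -5 * (1 - exp(0.4 * x))
#' tidy(fit_exponential_origin(data.frame(t_scaled = x, n_outlier = y)))
fit_exponential_origin <- function(data, x = t_scaled, y = n_outlier,
                                   max_iter = 1000,
                                   b_grid = c(0.01, 0.05, 0.1, 0.2, 0.35,
                                              0.6, 1, 1.5)) {
  d <- resolve_xy(data, {{ x }}, {{ y }})
  n <- length(d$x)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  dat <- tibble::tibble(x = d$x, y = d$y)
  if (all(d$y == 0)) {
    return(new_growth_fit("exponential_origin", c(a = 0, b = 0), 0, n,
                          converged = TRUE, iterations = 0L, data = dat))
  }
  b_cap <- 5 * max(1, 16 / max(abs(d$x)))
  starts <- c(b_grid, -b_grid)
  best <- NULL
  for (b0 in starts) {
    b <- b0
    f <- exp_rss(b, d$x, d$y)
    it <- 0L
    conv <- FALSE
    while (it < max_iter) {
      it <- it + 1L
      # analytic gradient of the profiled RSS (envelope theorem)
      u <- 1 - exp(b * d$x)
      a <- f$a
      r <- d$y - a * u
      g <- 2 * a * sum(r * d$x * exp(b * d$x))
      if (abs(g) / max(1, f$rss) < 1e-8) { conv <- TRUE; break }
      h <- 1e-6 * max(1, abs(b))
      g2 <- local({
        fp <- exp_rss(b + h, d$x, d$y)
        up <- 1 - exp((b + h) * d$x)
        2 * fp$a * sum((d$y - fp$a * up) * d$x * exp((b + h) * d$x))
      })
      hess <- (g2 - g) / h
      step <- if (is.finite(hess) && hess > 0) -g / hess else -sign(g) * 0.1
      step <- max(min(step, 0.5), -0.5)
      # backtrack to a descent step
      ok <- FALSE
      for (bt in 0:40) {
        bn <- max(min(b + step, b_cap), -b_cap)
        fn <- exp_rss(bn, d$x, d$y)
        if (fn$rss <= f$rss) { ok <- TRUE; break }
        step <- step / 2
        if (abs(step) < 1e-12) break
      }
      if (!ok) { conv <- TRUE; break }  # no descent possible: at a minimum
      moved <- abs(bn - b)
      b <- bn; f <- fn
      if (moved < 1e-10) { conv <- TRUE; break }
    }
    at_bound <- abs(b) >= b_cap - 1e-8
    cand <- list(b = b, a = f$a, rss = f$rss, it = it,
                 conv = conv && !at_bound)
    if (is.null(best) ||
        (cand$conv && !best$conv) ||
        (cand$conv == best$conv && cand$rss < best$rss - 1e-12))
      best <- cand
  }
  new_growth_fit("exponential_origin", c(a = best$a, b = best$b), best$rss,
                 n, converged = best$conv, iterations = best$it, data = dat)
}

#' AIC difference between the linear and exponential fits
#'
#' `AIC = n log(rss/n) + 2k` with `k` = mean parameters + 1 for the error
#' variance (2 for the linear model, 3 for the exponential), identical
#' constants dropped in both models.  Returns `AIC_linear -
#' AIC_exponential`; positive values favor the exponential model.  A fit
#' with `rss = 0` has `AIC = -Inf` (documented sentinel); if either fit did
#' not converge the comparison is undefined and `NA` is returned with a
#' warning.
#'
#' @param fit_linear,fit_exponential `growth_fit` objects.
#' @return A single numeric Delta-AIC.
#' @export
compare_aic <- function(fit_linear, fit_exponential) {
  stopifnot(inherits(fit_linear, "growth_fit"),
            inherits(fit_exponential, "growth_fit"))
  if (!fit_linear$converged || !fit_exponential$converged) {
    warning("Delta-AIC undefined: a fit did not converge", call. = FALSE)
    return(NA_real_)
  }
  fit_linear$aic - fit_exponential$aic
}

#' Fit both growth models to one replicate's series
#'
#' Convenience wrapper returning a one-row tibble with the linear slope,
#' the exponential parameters, convergence flag and Delta-AIC
#' (linear - exponential).
#'
#' @inheritParams fit_linear_origin
#' @return A one-row tibble with columns `c`, `a`, `b`, `rss_linear`,
#'   `rss_exponential`, `aic_linear`, `aic_exponential`, `delta_aic`,
#'   `converged`, `iterations`.
#' @export
fit_growth_models <- function(data, x = t_scaled, y = n_outlier) {
  fl <- fit_linear_origin(data, {{ x }}, {{ y }})
  fe <- fit_exponential_origin(data, {{ x }}, {{ y }})
  tibble::tibble(
    c = fl$params[["c"]],
    a = fe$params[["a"]], b = fe$params[["b"]],
    rss_linear = fl$rss, rss_exponential = fe$rss,
    aic_linear = fl$aic, aic_exponential = fe$aic,
    delta_aic = if (fe$converged) fl$aic - fe$aic else NA_real_,
    converged = fe$converged, iterations = fe$iterations)
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit> ", x$model, "\n  ", sep = "")
  cat(paste(names(x$params), signif(unlist(x$params), 5), sep = " = ",
            collapse = ", "),
      sprintf("\n  rss = %.4g, n = %d, aic = %.4g, converged = %s\n",
              x$rss, x$n, x$aic, x$converged))
  invisible(x)
}

#' Tidy methods for growth fits
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter; `glance()`: a one-row model
#'   summary.
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(unlist(x$params)))
}

#' @rdname tidy.growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(model = x$model, rss = x$rss, aic = x$aic, n = x$n,
                 converged = x$converged, iterations = x$iterations)
}
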