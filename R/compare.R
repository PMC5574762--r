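# Cross-scenario statistics on the exponential growth coefficients:
# one-way ANOVA, Tukey HSD with significance letters, and BCa bootstrap
# confidence intervals for scenario means.

resolve_groups <- function(data, value, group) {
  if (is.data.frame(data)) {
    v <- rlang::eval_tidy(rlang::enquo(value), data)
    g <- rlang::eval_tidy(rlang::enquo(group), data)
  } else if (is.list(data)) {
    v <- unlist(data, use.names = FALSE)
    g <- rep(names(data) %||% as.character(seq_along(data)),
             lengths(data))
  } else stop("data must be a data frame or a named list", call. = FALSE)
  keep <- !is.na(v)
  list(value = as.numeric(v[keep]), group = factor(g[keep]))
}

#' One-way ANOVA on exponential growth coefficients
#'
#' Fixed-effects one-way ANOVA of the coefficient `b` across gene-flow
#' scenarios.  Scenarios where the exponential fit mostly failed to
#' converge should be excluded before calling (see [scenario_summary()]).
#' Degenerate cases are reported with documented sentinels: zero
#' between-group variation gives `F = 0, p = 1`; zero within-group
#' variation with distinct means gives `F = Inf, p = 0`.
#'
#' @param data A data frame, or a named list of numeric vectors (one per
#'   scenario).
#' @param value,group Columns holding the coefficient and scenario label
#'   (tidy evaluation; defaults `b`, `scenario`).
#' @return A one-row tibble: `f_statistic`, `p_value`, `df_between`,
#'   `df_within`.
#' @export
anova_coefficients <- function(data, value = b, group = scenario) {
  d <- resolve_groups(data, {{ value }}, {{ group }})
  tab <- table(d$group)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  k <- length(tab); n <- length(d$value)
  gm <- mean(d$value)
  means <- tapply(d$value, d$group, mean)
  ss_b <- sum(tab * (means - gm)^2)
  ss_w <- sum((d$value - means[d$group])^2)
  df_b <- k - 1; df_w <- n - k
  if (ss_b <= 1e-300) {
    f <- 0; p <- 1
  } else if (ss_w <= 1e-300) {
    f <- Inf; p <- 0
  } else {
    f <- (ss_b / df_b) / (ss_w / df_w)
    p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  }
  tibble::tibble(f_statistic = f, p_value = p,
                 df_between = df_b, df_within = df_w)
}

#' Tukey honestly-significant-difference comparisons
#'
#' All-pairs studentized-range comparisons of scenario means with
#' family-wise error control (via [stats::TukeyHSD()]), plus significance
#' letters: scenarios that do not share a letter differ significantly.
#'
#' @inheritParams anova_coefficients
#' @param conf_level Family-wise confidence level (default 0.95).
#' @return A tibble of pairwise comparisons (`group1`, `group2`,
#'   `estimate`, `conf_low`, `conf_high`, `p_adj`) with a `letters`
#'   attribute: a tibble mapping each scenario to its letter set.
#' @export
tukey_hsd <- function(data, value = b, group = scenario,
                      conf_level = 0.95) {
  d <- resolve_groups(data, {{ value }}, {{ group }})
  tab <- table(d$group)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  fit <- stats::aov(value ~ group, data = data.frame(value = d$value,
                                                     group = d$group))
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$group
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  out <- tibble::tibble(
    group1 = vapply(nm, `[`, character(1), 1),
    group2 = vapply(nm, `[`, character(1), 2),
    estimate = unname(tk[, "diff"]),
    conf_low = unname(tk[, "lwr"]), conf_high = unname(tk[, "upr"]),
    p_adj = unname(tk[, "p adj"]))
  ord <- names(sort(tapply(d$value, d$group, mean)))
  attr(out, "letters") <- significance_letters(out, ord,
                                               alpha = 1 - conf_level)
  out
}

# compact letter display: groups connected by non-significant pairs share
# a letter (insert-and-absorb over mean-ordered groups)
significance_letters <- function(pairs, groups, alpha = 0.05) {
  k <- length(groups)
  sig <- matrix(FALSE, k, k, dimnames = list(groups, groups))
  for (i in seq_len(nrow(pairs))) {
    if (!is.na(pairs$p_adj[i]) && pairs$p_adj[i] < alpha) {
      sig[pairs$group1[i], pairs$group2[i]] <- TRUE
      sig[pairs$group2[i], pairs$group1[i]] <- TRUE
    }
  }
  # maximal intervals of mutually non-significant groups
  sets <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(sig[i:(j + 1), i:(j + 1)])) j <- j + 1
    sets[[length(sets) + 1]] <- i:j
  }
  # drop nested
  keep <- vapply(seq_along(sets), function(s) {
    !any(vapply(seq_along(sets), function(t)
      t != s && all(sets[[s]] %in% sets[[t]]), logical(1)))
  }, logical(1))
  sets <- unique(sets[keep])
  lets <- vapply(seq_len(k), function(i) {
    paste(letters[which(vapply(sets, function(s) i %in% s, logical(1)))],
          collapse = "")
  }, character(1))
  tibble::tibble(group = groups, letters = lets)
}

#' Bias-corrected and accelerated bootstrap CI of the mean
#'
#' BCa interval (Efron): bootstrap the mean `n_boot` times, estimate the
#' bias-correction `z0` from the fraction of bootstrap means below the
#' observed mean and the acceleration `a` from the jackknife skewness, and
#' read adjusted percentiles off the bootstrap distribution.  With
#' `bc_only = TRUE` the acceleration is set to 0 (bias correction only).
#' A constant input yields the degenerate zero-width interval at the value.
#'
#' @param x Numeric vector (n >= 3).
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param level Confidence level (default 0.95).
#' @param bc_only Drop the acceleration term?
#' @return A one-row tibble `lower`, `upper` (attributes `z0`, `accel`).
#' @export
#' @examples
#' set.seed(1)
#' bca_ci(rnorm(20))
bca_ci <- function(x, n_boot = 10000, level = 0.95, bc_only = FALSE) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (stats::var(x) == 0) {
    out <- tibble::tibble(lower = x[1], upper = x[1])
    attr(out, "z0") <- 0; attr(out, "accel") <- 0
    return(out)
  }
  theta <- mean(x)
  boots <- vapply(seq_len(n_boot),
                  function(i) mean(x[sample.int(n, n, replace = TRUE)]),
                  numeric(1))
  prop <- sum(boots < theta) / n_boot
  prop <- min(max(prop, 1 / (n_boot + 1)), n_boot / (n_boot + 1))
  z0 <- stats::qnorm(prop)
  a <- 0
  if (!bc_only) {
    jk <- vapply(seq_len(n), function(i) mean(x[-i]), numeric(1))
    dj <- mean(jk) - jk
    denom <- sum(dj^2)^1.5
    a <- if (denom > 0) sum(dj^3) / (6 * denom) else 0
  }
  zq <- stats::qnorm(c((1 - level) / 2, (1 + level) / 2))
  adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  ci <- stats::quantile(boots, adj, names = FALSE, type = 7)
  out <- tibble::tibble(lower = ci[1], upper = ci[2])
  attr(out, "z0") <- z0; attr(out, "accel") <- a
  out
}

#' Per-scenario summary of exponential coefficients
#'
#' Mean, SD, convergence counts and BCa bootstrap CI of the mean `b` for
#' each scenario; non-converged replicates are dropped (with counts
#' reported).
#'
#' @param fits A tibble with columns `scenario`, `b`, `converged` (one row
#'   per replicate), e.g. `run_experiment()$fits`.
#' @param n_boot,level Passed to [bca_ci()].
#' @return A tibble with one row per scenario: `scenario`, `n_total`,
#'   `n_converged`, `mean_b`, `sd_b`, `ci_lower`, `ci_upper`.
#' @export
scenario_summary <- function(fits, n_boot = 10000, level = 0.95) {
  stopifnot(all(c("scenario", "b", "converged") %in% names(fits)))
  fits |>
    dplyr::group_by(.data$scenario) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_converged = sum(.data$converged),
      mean_b = mean(.data$b[.data$converged]),
      sd_b = stats::sd(.data$b[.data$converged]),
      ci = if (sum(.data$converged) >= 3)
        bca_ci(.data$b[.data$converged], n_boot = n_boot, level = level)
      else tibble::tibble(lower = NA_real_, upper = NA_real_),
      .groups = "drop") |>
    tidyr::unpack("ci", names_sep = "_")
}
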