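# Pooled-threshold outlier calling across all sister pairs of one
# replicate, including the relaxed 95%+75% bridging rule, and the
# divergent-genome-size series.

OUTLIER_RULES <- c("p80", "p95", "p99", "p95_bridge75")

#' Pooled F_ST percentile thresholds for one replicate
#'
#' Pools the defined per-window F_ST values of all sister pairs of one
#' replicate and returns the 75th/80th/95th/99th empirical percentiles.
#' A single pooled threshold (rather than per-pair thresholds) is what
#' makes outlier counts comparable across divergence times.  Quantiles use
#' linear interpolation of the empirical CDF (R's default type 7);
#' undefined F_ST windows carry no rank information and are excluded.
#'
#' @param windows A window table (rows from [window_table()] for all pairs
#'   of one replicate, stacked).
#' @return A one-row tibble with columns `q75`, `q80`, `q95`, `q99` and
#'   `n_pooled` (number of defined F_ST values).
#' @export
pooled_thresholds <- function(windows) {
  stopifnot(is.data.frame(windows), "fst" %in% names(windows))
  v <- windows$fst[!is.na(windows$fst)]
  if (length(v) == 0)
    stop("no defined F_ST values to pool", call. = FALSE)
  q <- stats::quantile(v, c(0.75, 0.80, 0.95, 0.99), names = FALSE, type = 7)
  tibble::tibble(q75 = q[1], q80 = q[2], q95 = q[3], q99 = q[4],
                 n_pooled = length(v))
}

#' Call outlier windows against pooled thresholds
#'
#' Simple rules (`"p80"`, `"p95"`, `"p99"`) flag windows with F_ST strictly
#' greater than the corresponding pooled percentile.  The relaxed rule
#' `"p95_bridge75"` first flags `fst > q95`, then, within each pair, for
#' every maximal run of non-flagged windows lying between two flagged
#' windows, flags the whole run iff every window in it has defined
#' `fst > q75`.  Bridging never crosses pair boundaries, never extends past
#' the first/last flagged window, and undefined-F_ST windows break bridges.
#' Ties at a threshold are non-outliers.
#'
#' @param windows A window table for one replicate (any number of pairs;
#'   windows are grouped by `pair_age`).
#' @param thresholds A row from [pooled_thresholds()].
#' @param rule One of `"p80"`, `"p95"`, `"p99"`, `"p95_bridge75"`.
#' @return `windows` with a logical `outlier` column appended (attribute
#'   `rule` records the rule used).
#' @export
call_outliers <- function(windows, thresholds,
                          rule = c("p95_bridge75", "p80", "p95", "p99")) {
  rule <- match.arg(rule)
  stopifnot(is.data.frame(windows), "fst" %in% names(windows))
  thr <- switch(rule,
                p80 = thresholds$q80,
                p95 = thresholds$q95,
                p99 = thresholds$q99,
                p95_bridge75 = thresholds$q95)
  out <- windows |>
    dplyr::group_by(.data$pair_age) |>
    dplyr::arrange(.data$window_index, .by_group = TRUE) |>
    dplyr::mutate(outlier = bridge_calls(.data$fst, thr,
                                         if (rule == "p95_bridge75")
                                           thresholds$q75 else NULL)) |>
    dplyr::ungroup()
  attr(out, "rule") <- rule
  out
}

# strict-threshold calls plus optional 75th-percentile bridging of runs
# between consecutive flagged windows
bridge_calls <- function(fst, thr_hi, thr_bridge = NULL) {
  flag <- !is.na(fst) & fst > thr_hi
  if (is.null(thr_bridge) || sum(flag) < 2) return(flag)
  hits <- which(flag)
  ok <- !is.na(fst) & fst > thr_bridge
  for (i in seq_len(length(hits) - 1)) {
    lo <- hits[i]; hi <- hits[i + 1]
    if (hi - lo > 1 && all(ok[(lo + 1):(hi - 1)]))
      flag[(lo + 1):(hi - 1)] <- TRUE
  }
  flag
}

#' Divergent-genome-size series for one replicate
#'
#' Counts outlier windows per sister pair and expresses divergence time in
#' units of N generations: the x axis of the growth-curve fits.
#'
#' @param calls Output of [call_outliers()] covering all pairs of one
#'   replicate.
#' @param N_e Effective population size used to scale the time axis.
#' @return A tibble with one row per pair: `pair_age`, `t_scaled`
#'   (`pair_age / N_e`) and `n_outlier`.
#' @export
divergent_genome_series <- function(calls, N_e) {
  stopifnot(is.data.frame(calls), "outlier" %in% names(calls))
  assert_scalar_num(N_e, "N_e", 0, allow_zero = FALSE)
  calls |>
    dplyr::group_by(.data$pair_age) |>
    dplyr::summarise(n_outlier = sum(.data$outlier), .groups = "drop") |>
    dplyr::mutate(t_scaled = .data$pair_age / N_e) |>
    dplyr::arrange(.data$t_scaled) |>
    dplyr::select("pair_age", "t_scaled", "n_outlier")
}
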