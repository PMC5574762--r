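# Orchestration: simulate -> mutate -> scan -> pooled thresholds ->
# outlier calls -> growth fits -> scenario comparison, with counter-based
# seed derivation so any subset of the experiment reruns identically.

#' Run one replicate of a scenario through the full pipeline
#'
#' Simulates all sister pairs (neutral or selected, depending on the
#' scenario), computes the 500-bp window scan per pair, pools the F_ST
#' values to set thresholds, calls outliers under `rule`, and fits both
#' growth models to the divergent-genome-size series.
#'
#' @param spec A [scenario_spec()].
#' @param replicate Replicate index (used in seed derivation).
#' @param seed Master seed.
#' @param window_bp Scan window size (default 500).
#' @param rule Outlier rule (see [call_outliers()]).
#' @param keep_windows Keep the per-window table in the result?
#' @return A list with elements `series` (tibble), `fits` (one-row tibble
#'   from [fit_growth_models()]), `thresholds`, and optionally `windows`.
#' @export
run_replicate <- function(spec, replicate = 1, seed = 1, window_bp = 500,
                          rule = "p95_bridge75", keep_windows = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"))
  windows <- purrr::imap(spec$pair_ages, function(age, i) {
    s <- derive_seed(seed, spec$label, replicate, "pair", i, "coal")
    aln <- if (is.null(spec$selection))
      simulate_pair_alignment(spec, age, s)
    else simulate_selected_pair_alignment(spec, age, s, window_bp = window_bp)
    window_table(aln, window_bp = window_bp, pair_age = age)
  }) |> purrr::list_rbind()
  thr <- pooled_thresholds(windows)
  calls <- call_outliers(windows, thr, rule = rule)
  series <- divergent_genome_series(calls, spec$N_e)
  fits <- fit_growth_models(series)
  fits$n_undefined_windows <- sum(is.na(windows$fst))
  out <- list(series = series, fits = fits, thresholds = thr,
              n_undefined = sum(is.na(windows$fst)))
  if (keep_windows) out$windows <- calls
  out
}

#' Run all replicates of one scenario
#'
#' @inheritParams run_replicate
#' @param n_replicates Number of replicates (default `spec$n_replicates`).
#' @param progress Print a dot per replicate to stderr?
#' @return A list with `fits` (one row per successful replicate, including
#'   `scenario`, `replicate` and the per-replicate count of
#'   undefined-F_ST windows), `series` and `thresholds` (stacked per
#'   replicate), and `failed_replicates` (indices of replicates that
#'   errored and were skipped, normally empty).
#' @export
run_scenario <- function(spec, seed = 1, n_replicates = spec$n_replicates,
                         window_bp = 500, rule = "p95_bridge75",
                         progress = FALSE) {
  reps <- purrr::map(seq_len(n_replicates), function(r) {
    if (progress) cat(".", file = stderr())
    # partial-failure policy: a failed replicate is recorded and skipped,
    # never silently imputed
    tryCatch(run_replicate(spec, replicate = r, seed = seed,
                           window_bp = window_bp, rule = rule),
             error = function(e) {
               warning("replicate ", r, " of scenario '", spec$label,
                       "' failed and was skipped: ", conditionMessage(e),
                       call. = FALSE)
               NULL
             })
  })
  if (progress) cat("\n", file = stderr())
  failed <- which(vapply(reps, is.null, logical(1)))
  kept <- setdiff(seq_len(n_replicates), failed)
  reps <- reps[kept]
  if (length(reps) == 0) stop("all replicates failed", call. = FALSE)
  stack <- function(field) {
    purrr::map2(reps, kept, function(x, r)
      dplyr::mutate(x[[field]], scenario = spec$label, replicate = r,
                    .before = 1)) |> purrr::list_rbind()
  }
  list(fits = stack("fits"), series = stack("series"),
       thresholds = stack("thresholds"), failed_replicates = failed)
}

#' Configure a multi-scenario experiment
#'
#' @param scenarios A list of [scenario_spec()]s with unique labels.
#' @param window_bp Scan window size.
#' @param rule Outlier rule.
#' @param seed Master seed.
#' @param out_dir Optional directory for TSV outputs.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(scenarios, window_bp = 500,
                              rule = "p95_bridge75", seed = 1,
                              out_dir = NULL) {
  if (inherits(scenarios, "scenario_spec")) scenarios <- list(scenarios)
  stopifnot(all(vapply(scenarios, inherits, logical(1), "scenario_spec")))
  labels <- vapply(scenarios, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("scenario labels must be unique", call. = FALSE)
  rule <- match.arg(rule, OUTLIER_RULES)
  structure(list(scenarios = scenarios, window_bp = window_bp, rule = rule,
                 seed = seed, out_dir = out_dir),
            class = "experiment_config")
}

#' Run a multi-scenario experiment
#'
#' Runs every scenario of the configuration through [run_scenario()] and
#' summarises the exponential coefficients per scenario.  Fully
#' reproducible from `(config, seed)`; when `out_dir` is set, fits, series
#' and the summary are also written as TSV.
#'
#' @param config An [experiment_config()].
#' @param progress Print progress to stderr?
#' @return A `divergome_experiment` list: `fits`, `series`, `thresholds`,
#'   `summary` (from [scenario_summary()]; bootstrap seeded from the
#'   master seed).
#' @export
run_experiment <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  runs <- purrr::map(config$scenarios, function(sp) {
    if (progress) cat(sp$label, ": ", file = stderr())
    run_scenario(sp, seed = config$seed, window_bp = config$window_bp,
                 rule = config$rule, progress = progress)
  })
  fits <- purrr::list_rbind(purrr::map(runs, "fits"))
  series <- purrr::list_rbind(purrr::map(runs, "series"))
  thresholds <- purrr::list_rbind(purrr::map(runs, "thresholds"))
  summary <- with_seed(derive_seed(config$seed, "bca"),
                       scenario_summary(fits))
  out <- structure(list(fits = fits, series = series,
                        thresholds = thresholds, summary = summary,
                        config = config),
                   class = "divergome_experiment")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("fits", "series", "thresholds", "summary")) {
      utils::write.table(out[[nm]],
                         file.path(config$out_dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}

#' @export
print.divergome_experiment <- function(x, ...) {
  cat("<divergome_experiment> ", length(x$config$scenarios),
      " scenario(s), rule = ", x$config$rule, "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
glance.divergome_experiment <- function(x, ...) x$summary
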