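#' Selection parameters for a divergently selected locus
#'
#' Describes a biallelic locus under mirror-image divergent selection
#' between the two sister species: in each species the locally favored
#' homozygote has fitness `1 + s_hom`, the heterozygote `1 + s_het`, and the
#' other homozygote `1 + s_other` (defaults 0.01 / 0.005 / 0).  The locus
#' sits `locus_offset_bp` base pairs to the left of the simulated neutral
#' region (default 1, i.e. immediately adjacent to coordinate 0).
#'
#' @param s_hom Selection coefficient of the locally favored homozygote.
#' @param s_het Selection coefficient of the heterozygote.
#' @param s_other Selection coefficient of the disfavored homozygote.
#' @param locus_offset_bp Distance (bp) from the selected locus to the start
#'   of the neutral region.
#' @return An object of class `selection_spec`.
#' @export
#' @examples
#' selection_spec()
selection_spec <- function(s_hom = 0.01, s_het = 0.005, s_other = 0,
                           locus_offset_bp = 1) {
  assert_scalar_num(s_hom, "s_hom", 0)
  assert_scalar_num(s_het, "s_het", 0)
  assert_scalar_num(s_other, "s_other", 0)
  if (!(s_other <= s_het && s_het <= s_hom))
    stop("selection coefficients must satisfy s_other <= s_het <= s_hom",
         call. = FALSE)
  structure(list(s_hom = s_hom, s_het = s_het, s_other = s_other,
                 locus_offset_bp = locus_offset_bp),
            class = "selection_spec")
}

#' Specify one simulation scenario
#'
#' A scenario fixes the demography and rates for all eight sister pairs:
#' two demes of constant diploid size `N_e` splitting `pair_ages`
#' generations ago from an ancestral deme of the same size, with gene flow
#' at scaled rate `migration_4Nm` restricted to one 2N-generation epoch.
#' `gene_flow_mode = "early"` places the epoch in the first 2N generations
#' after each pair's divergence (speciation with gene flow followed by
#' isolation); `"recent"` places it in the most recent 2N generations
#' (secondary contact); `"none"` disables migration.  "Unidirectional"
#' migration moves lineages (backward in time) from species 2 into species
#' 1, i.e. forward-in-time migrants from species 1 into species 2.
#'
#' @param N_e Diploid effective population size of each deme.
#' @param pair_ages Divergence times in generations, strictly positive and
#'   ascending.  Default `seq(2, 16, by = 2) * N_e` (eight sister pairs).
#' @param samples_per_species Number of haploid sequences sampled per
#'   species (default 10).
#' @param seq_length_bp Length of the simulated sequence (default 100000).
#' @param mu Per-site per-generation mutation rate (default 5e-9).
#' @param rec Per-site per-generation recombination rate (default 1e-8).
#' @param gene_flow_mode One of `"none"`, `"early"`, `"recent"`.
#' @param migration_4Nm Scaled migration parameter 4Nm (0 when mode is
#'   `"none"`).
#' @param direction `"unidirectional"` or `"bidirectional"`.
#' @param selection Optional [selection_spec()].
#' @param selection_N Rescaled diploid size at which the selection engine
#'   runs (composite parameters 2Ns, 4Nm, 4Nmu, 4Nr and T/N are preserved).
#' @param n_replicates Number of replicate simulations (default 30).
#' @param label Scenario label used in summaries and seed derivation.
#' @return An object of class `scenario_spec`.
#' @export
#' @examples
#' spec <- scenario_spec(N_e = 1e4, mu = 5e-7, rec = 1e-6)
#' spec$pair_ages / spec$N_e
scenario_spec <- function(N_e,
                          pair_ages = NULL,
                          samples_per_species = 10,
                          seq_length_bp = 100000,
                          mu = 5e-9,
                          rec = 1e-8,
                          gene_flow_mode = c("none", "early", "recent"),
                          migration_4Nm = 0,
                          direction = c("unidirectional", "bidirectional"),
                          selection = NULL,
                          selection_N = 1000,
                          n_replicates = 30,
                          label = NULL) {
  gene_flow_mode <- match.arg(gene_flow_mode)
  direction <- match.arg(direction)
  assert_scalar_num(N_e, "N_e", 0, allow_zero = FALSE)
  if (is.null(pair_ages)) pair_ages <- seq(2, 16, by = 2) * N_e
  if (any(pair_ages <= 0)) stop("pair_ages must be strictly positive", call. = FALSE)
  if (is.unsorted(pair_ages, strictly = TRUE))
    stop("pair_ages must be sorted ascending without ties", call. = FALSE)
  assert_scalar_num(migration_4Nm, "migration_4Nm", 0)
  if (gene_flow_mode == "none" && migration_4Nm != 0)
    stop("migration_4Nm must be 0 when gene_flow_mode = \"none\"", call. = FALSE)
  assert_scalar_num(mu, "mu", 0)
  assert_scalar_num(rec, "rec", 0)
  assert_scalar_num(seq_length_bp, "seq_length_bp", 0, allow_zero = FALSE)
  if (!is.null(selection) && !inherits(selection, "selection_spec"))
    stop("selection must be NULL or a selection_spec", call. = FALSE)
  if (is.null(label)) {
    label <- paste0(gene_flow_mode,
                    if (gene_flow_mode != "none") paste0("_4Nm", migration_4Nm),
                    if (!is.null(selection)) "_sel")
  }
  structure(list(
    N_e = N_e, pair_ages = as.numeric(pair_ages),
    samples_per_species = as.integer(samples_per_species),
    seq_length_bp = as.numeric(seq_length_bp),
    mu = mu, rec = rec,
    gene_flow_mode = gene_flow_mode,
    migration_4Nm = migration_4Nm,
    direction = direction,
    selection = selection,
    selection_N = selection_N,
    n_replicates = as.integer(n_replicates),
    label = label), class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec> ", x$label, "\n", sep = "")
  cat("  N_e = ", format(x$N_e), ", pair ages (units of N): ",
      paste(x$pair_ages / x$N_e, collapse = ", "), "\n", sep = "")
  cat("  ", x$samples_per_species, " sequences/species, L = ",
      format(x$seq_length_bp), " bp, mu = ", format(x$mu),
      ", rec = ", format(x$rec), "\n", sep = "")
  cat("  gene flow: ", x$gene_flow_mode,
      if (x$gene_flow_mode != "none")
        paste0(" (4Nm = ", x$migration_4Nm, ", ", x$direction, ")"),
      "\n", sep = "")
  if (!is.null(x$selection))
    cat("  selection: s_hom = ", x$selection$s_hom, ", s_het = ",
        x$selection$s_het, "\n", sep = "")
  invisible(x)
}

#' Rescale a scenario for desk-scale simulation
#'
#' Divides `N_e` and all divergence times by `factor` and multiplies the
#' mutation and recombination rates by it, so that the scaled compound
#' parameters (4Nmu, 4Nr, T/N, 4Nm) are unchanged.  All downstream
#' statistics are distributionally invariant to this transformation.
#'
#' @param spec A [scenario_spec()].
#' @param factor Positive rescaling factor c.
#' @return A rescaled `scenario_spec`.
#' @export
scale_scenario <- function(spec, factor) {
  stopifnot(inherits(spec, "scenario_spec"))
  assert_scalar_num(factor, "factor", 0, allow_zero = FALSE)
  spec$N_e <- spec$N_e / factor
  spec$pair_ages <- spec$pair_ages / factor
  spec$mu <- spec$mu * factor
  spec$rec <- spec$rec * factor
  if (!is.null(spec$selection)) {
    # preserve 2Ns as well; Wright-Fisher fitnesses 1 + s stay valid for
    # s > 1 (see the methods vignette on selection rescaling)
    spec$selection$s_hom <- spec$selection$s_hom * factor
    spec$selection$s_het <- spec$selection$s_het * factor
    spec$selection$s_other <- spec$selection$s_other * factor
  }
  spec
}

#' Migration epoch for one sister pair
#'
#' Returns the epoch of active gene flow for a pair of age `pair_age`, in
#' generations before present: `[0, 2N)` for recent gene flow,
#' `[T - 2N, T)` for early gene flow.  For the youngest pair (T = 2N) the
#' two modes coincide.  The per-lineage backward migration rates are
#' `migration_4Nm / (4 N_e)`; under unidirectional gene flow only lineages
#' in species 2 move (into species 1).
#'
#' @param spec A [scenario_spec()].
#' @param pair_age Divergence time in generations.
#' @return A tibble with columns `start_gen`, `end_gen`, `rate_4Nm_12`,
#'   `rate_4Nm_21`.
#' @export
migration_epoch <- function(spec, pair_age) {
  stopifnot(inherits(spec, "scenario_spec"))
  twoN <- 2 * spec$N_e
  if (spec$gene_flow_mode == "none" || spec$migration_4Nm == 0) {
    return(tibble::tibble(start_gen = 0, end_gen = 0,
                          rate_4Nm_12 = 0, rate_4Nm_21 = 0))
  }
  if (spec$gene_flow_mode == "early") {
    lo <- max(0, pair_age - twoN); hi <- pair_age
  } else {
    lo <- 0; hi <- min(twoN, pair_age)
  }
  r21 <- spec$migration_4Nm  # backward: species 2 -> species 1
  r12 <- if (spec$direction == "bidirectional") spec$migration_4Nm else 0
  tibble::tibble(start_gen = lo, end_gen = hi,
                 rate_4Nm_12 = r12, rate_4Nm_21 = r21)
}

# backward per-generation, per-lineage migration rates (deme 0 = species 1)
backward_rates <- function(spec, pair_age) {
  ep <- migration_epoch(spec, pair_age)
  list(start = ep$start_gen, end = ep$end_gen,
       m0 = ep$rate_4Nm_12 / (4 * spec$N_e),
       m1 = ep$rate_4Nm_21 / (4 * spec$N_e))
}

#' Read or write a scenario configuration file
#'
#' Scenario specifications round-trip through a small YAML schema so runs
#' can be configured from plain-text files.
#'
#' @param spec A [scenario_spec()].
#' @param path File path.
#' @return `read_scenario_config()` returns a `scenario_spec`;
#'   `write_scenario_config()` returns `path` invisibly.
#' @export
write_scenario_config <- function(spec, path) {
  stopifnot(inherits(spec, "scenario_spec"))
  x <- unclass(spec)
  if (!is.null(x$selection)) x$selection <- unclass(x$selection)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  x <- yaml::read_yaml(path)
  sel <- if (!is.null(x$selection)) do.call(selection_spec, x$selection)
  scenario_spec(N_e = x$N_e, pair_ages = x$pair_ages,
                samples_per_species = x$samples_per_species,
                seq_length_bp = x$seq_length_bp,
                mu = x$mu, rec = x$rec,
                gene_flow_mode = x$gene_flow_mode,
                migration_4Nm = x$migration_4Nm,
                direction = x$direction,
                selection = sel,
                selection_N = x$selection_N %||% 1000,
                n_replicates = x$n_replicates %||% 30,
                label = x$label)
}

#' Headline study scenarios at a chosen desk scale
#'
#' Convenience constructors for the scenarios analysed in the package
#' vignette: sister pairs of ages 2N..16N with N nominally 1e6,
#' mu = 5e-9 and rec = 1e-8, rescaled by `scale` (default 100, i.e. run at
#' N = 1e4 with rates multiplied by 100).
#'
#' @param gene_flow_mode,migration_4Nm,direction,selection,n_replicates
#'   Passed to [scenario_spec()].
#' @param scale Desk-scale factor c (see [scale_scenario()]).
#' @param label Optional label override.
#' @return A `scenario_spec`.
#' @export
#' @examples
#' study_scenario("recent", 0.1, scale = 100)
study_scenario <- function(gene_flow_mode = "none", migration_4Nm = 0,
                           direction = "unidirectional", selection = NULL,
                           n_replicates = 30, scale = 100, label = NULL) {
  spec <- scenario_spec(N_e = 1e6,
                        gene_flow_mode = gene_flow_mode,
                        migration_4Nm = migration_4Nm,
                        direction = direction,
                        selection = selection,
                        n_replicates = n_replicates,
                        label = label)
  scale_scenario(spec, scale)
}
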