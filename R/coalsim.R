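# Neutral two-population coalescent with recombination (SMC') and
# epoch-limited migration.  The heavy lifting is in C++ (src/coalsim.cpp);
# this file provides the tidy interfaces and the conversion of local
# genealogies to ape "phylo" objects.

# convert one C++ tree snapshot (1-based parent array, node times) to phylo
snapshot_to_phylo <- function(seg, tip_labels) {
  par <- seg$parent; tim <- seg$node_time; n <- seg$n_tips
  M <- length(par)
  root <- which(is.na(par))
  internal <- setdiff(seq_len(M), seq_len(n))
  # ape convention: tips 1..n, root n+1, other internals follow
  imap <- integer(M)
  imap[seq_len(n)] <- seq_len(n)
  ord <- c(root, setdiff(internal, root))
  imap[ord] <- n + seq_along(ord)
  child <- setdiff(seq_len(M), root)
  edge <- cbind(imap[par[child]], imap[child])
  phy <- structure(list(
    edge = edge,
    edge.length = tim[par[child]] - tim[child],
    tip.label = tip_labels,
    Nnode = M - n), class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

pair_tip_labels <- function(spec) {
  k <- spec$samples_per_species
  c(paste0("sp1|", seq_len(k)), paste0("sp2|", seq_len(k)))
}

sim_pair_raw <- function(spec, pair_age, seed, collect_trees, mutate) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!pair_age %in% spec$pair_ages)
    stop("pair_age must be one of spec$pair_ages", call. = FALSE)
  br <- backward_rates(spec, pair_age)
  k <- spec$samples_per_species
  with_seed(seed, sim_pair_cpp(
    n1 = k, n2 = k, N = spec$N_e, Tsplit = pair_age,
    L = spec$seq_length_bp, rec = spec$rec, mu = spec$mu,
    mig_start = br$start, mig_end = br$end, m0 = br$m0, m1 = br$m1,
    collect_trees = collect_trees, mutate = mutate, validate = FALSE))
}

#' Simulate local genealogies for one sister pair
#'
#' Draws the sequence of local genealogies along the chromosome for one
#' sister pair under the two-deme isolation(-with-migration) model: both
#' demes of diploid size `N_e`, splitting `pair_age` generations ago from an
#' ancestral deme of the same size, with migration active only inside the
#' pair's epoch (see [migration_epoch()]).  Recombination along the
#' sequence follows the SMC' approximation, so adjacent segments differ by
#' single subtree-prune-regraft moves and tree changes arise only from
#' recombination events.
#'
#' With the default 100 kbp sequence this returns tens of thousands of
#' segments; for the full simulate-mutate-scan pipeline use
#' [simulate_pair_alignment()], which never materialises the trees in R.
#'
#' @param spec A [scenario_spec()].
#' @param pair_age Divergence time in generations; must be one of
#'   `spec$pair_ages`.
#' @param seed Integer seed (deterministic given `(spec, pair_age, seed)`).
#' @return A tibble with columns `start_bp`, `end_bp` (0-based half-open,
#'   partitioning `[0, seq_length_bp)`) and `tree`, a list column of
#'   `phylo` genealogies with branch lengths in generations and tip labels
#'   `sp1|i` / `sp2|i`.
#' @export
#' @examples
#' spec <- scenario_spec(N_e = 500, pair_ages = c(1000, 2000),
#'                       samples_per_species = 3, seq_length_bp = 2000,
#'                       mu = 1e-6, rec = 1e-7)
#' simulate_pair(spec, 1000, seed = 1)
simulate_pair <- function(spec, pair_age, seed = 1) {
  r <- sim_pair_raw(spec, pair_age, seed, collect_trees = TRUE, mutate = FALSE)
  labs <- pair_tip_labels(spec)
  tibble::tibble(
    start_bp = vapply(r$segments, `[[`, numeric(1), "start_bp"),
    end_bp = vapply(r$segments, `[[`, numeric(1), "end_bp"),
    tree = lapply(r$segments, snapshot_to_phylo, tip_labels = labs))
}

#' Simulate and mutate one sister pair in a single pass
#'
#' Runs the SMC' genealogy simulation and the Jukes-Cantor mutation overlay
#' in one streaming pass, returning only the haplotype alignment.  This is
#' the fast path used by [run_scenario()].
#'
#' @inheritParams simulate_pair
#' @return A [hap_alignment()] with `2 * samples_per_species` rows.
#' @export
simulate_pair_alignment <- function(spec, pair_age, seed = 1) {
  r <- sim_pair_raw(spec, pair_age, seed, collect_trees = FALSE, mutate = TRUE)
  k <- spec$samples_per_species
  hap_alignment(r$aln, rep(c("sp1", "sp2"), each = k))
}

#' Simulate one replicate: all sister pairs of a scenario
#'
#' Calls [simulate_pair_alignment()] (or [simulate_pair()] when
#' `output = "trees"`) independently for each pair age, with per-pair seeds
#' derived from `seed` by a counter-based scheme, so adding pairs never
#' perturbs existing ones.  Pairs are simulated independently: under
#' neutrality with gene flow restricted to sister species, non-sister
#' history does not affect within-pair genealogies.
#'
#' @inheritParams simulate_pair
#' @param output `"alignment"` (default) or `"trees"`.
#' @return A tibble with columns `pair_age` and `sim` (a list column of
#'   alignments or segment tables).  Deterministic given `(spec, seed)`.
#' @export
simulate_replicate <- function(spec, seed = 1,
                               output = c("alignment", "trees")) {
  output <- match.arg(output)
  stopifnot(inherits(spec, "scenario_spec"))
  seeds <- vapply(seq_along(spec$pair_ages), function(i)
    derive_seed(seed, spec$label, "pair", i), integer(1))
  if (anyDuplicated(seeds))
    stop("derived per-pair seeds collide; choose another master seed",
         call. = FALSE)
  sims <- purrr::imap(spec$pair_ages, function(age, i) {
    s <- seeds[i]
    if (output == "alignment") {
      if (is.null(spec$selection)) simulate_pair_alignment(spec, age, s)
      else simulate_selected_pair_alignment(spec, age, s)
    } else {
      if (is.null(spec$selection)) simulate_pair(spec, age, s)
      else simulate_selected_pair(spec, age, s)
    }
  })
  tibble::tibble(pair_age = spec$pair_ages, sim = sims)
}
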