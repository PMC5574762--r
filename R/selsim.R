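# Divergent selection at a linked locus: forward Wright-Fisher allele
# trajectories and genealogies of the adjacent neutral region drawn from
# the trajectory-conditioned structured coalescent.  The engine runs at the
# rescaled population size spec$selection_N with 2Ns, 4Nm, 4Nmu, 4Nr and
# T/N held fixed.

sel_scaled <- function(spec, pair_age) {
  sel <- spec$selection
  if (is.null(sel)) stop("spec has no selection component", call. = FALSE)
  k <- spec$N_e / spec$selection_N
  br <- backward_rates(spec, pair_age)
  list(Np = spec$selection_N,
       Tgen = as.integer(round(pair_age / k)),
       s_hom = sel$s_hom * k, s_het = sel$s_het * k,
       mu = spec$mu * k, rec = spec$rec * k,
       m0 = br$m0 * k, m1 = br$m1 * k,
       epoch_lo = br$start / k, epoch_hi = br$end / k,
       locus_offset = sel$locus_offset_bp)
}

#' Wright-Fisher trajectory of the selected allele in both demes
#'
#' Simulates the forward-in-time frequency path of the focal allele (the
#' one favored in species 1) in the two demes, from divergence to the
#' present, under mirror-image semidominant divergent selection with the
#' scenario's migration epoch.  At divergence the species are fixed for
#' alternative alleles (divergence from a standing difference).  The
#' engine runs at the rescaled size `spec$selection_N`; the returned
#' generations are on that scale.
#'
#' @param spec A [scenario_spec()] with a selection component.
#' @param pair_age Divergence time in generations (nominal scale).
#' @param seed Integer seed.
#' @return A tibble with columns `generation` (before present, 0 =
#'   present), `freq_deme1`, `freq_deme2`: frequencies of the focal allele.
#' @export
simulate_trajectory <- function(spec, pair_age, seed = 1) {
  p <- sel_scaled(spec, pair_age)
  tr <- with_seed(seed, wf_trajectory_cpp(
    p$Np, p$Tgen, p$s_hom, p$s_het, p$m0, p$m1,
    p$epoch_lo, p$epoch_hi, 1, 0))
  tibble::tibble(generation = seq_len(nrow(tr)) - 1,
                 freq_deme1 = tr[, 1], freq_deme2 = tr[, 2])
}

#' Write an allele trajectory as TSV
#'
#' @param traj A tibble from [simulate_trajectory()].
#' @param path Output file.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(traj, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

sim_selected_raw <- function(spec, pair_age, seed, window_bp,
                             collect_trees, mutate) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!pair_age %in% spec$pair_ages)
    stop("pair_age must be one of spec$pair_ages", call. = FALSE)
  p <- sel_scaled(spec, pair_age)
  k <- spec$samples_per_species
  with_seed(seed, {
    traj <- wf_trajectory_cpp(p$Np, p$Tgen, p$s_hom, p$s_het, p$m0, p$m1,
                              p$epoch_lo, p$epoch_hi, 1, 0)
    sim_selected_pair_cpp(
      n1 = k, n2 = k, Np = p$Np, Tgen = p$Tgen, L = spec$seq_length_bp,
      window_bp = window_bp, rec = p$rec, mu = p$mu, traj = traj,
      s_hom = p$s_hom, s_het = p$s_het, m0 = p$m0, m1 = p$m1,
      epoch_lo = p$epoch_lo, epoch_hi = p$epoch_hi,
      locus_offset = p$locus_offset,
      collect_trees = collect_trees, mutate = mutate)
  })
}

#' Simulate genealogies of a neutral region linked to a selected locus
#'
#' Genealogies of the 100 kb region adjacent to the divergently selected
#' locus, drawn from the structured coalescent conditioned on the selected
#' allele's Wright-Fisher trajectory: lineages carry a (deme, background)
#' state, recombination between the locus and a window moves lineages
#' between backgrounds, migration is weighted by background frequencies,
#' and coalescence within a background occurs at rate 1/(2N x).  One
#' genealogy is drawn per `window_bp` tile (the whole region shares a
#' single genealogy when `rec = 0`); the contract is distributional, not
#' mechanistic.
#'
#' @inheritParams simulate_trajectory
#' @param window_bp Tiling used for the per-window genealogies (default
#'   500, matching the scan windows).
#' @return For `simulate_selected_pair()`, a tibble of segments with
#'   `phylo` trees (times on the rescaled-generation scale); for
#'   `simulate_selected_pair_alignment()`, a [hap_alignment()].
#' @export
simulate_selected_pair <- function(spec, pair_age, seed = 1, window_bp = 500) {
  r <- sim_selected_raw(spec, pair_age, seed, window_bp,
                        collect_trees = TRUE, mutate = FALSE)
  labs <- pair_tip_labels(spec)
  tibble::tibble(
    start_bp = vapply(r$segments, `[[`, numeric(1), "start_bp"),
    end_bp = vapply(r$segments, `[[`, numeric(1), "end_bp"),
    tree = lapply(r$segments, snapshot_to_phylo, tip_labels = labs))
}

#' @rdname simulate_selected_pair
#' @export
simulate_selected_pair_alignment <- function(spec, pair_age, seed = 1,
                                             window_bp = 500) {
  r <- sim_selected_raw(spec, pair_age, seed, window_bp,
                        collect_trees = FALSE, mutate = TRUE)
  k <- spec$samples_per_species
  hap_alignment(r$aln, rep(c("sp1", "sp2"), each = k))
}
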