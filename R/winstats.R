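# Per-window and global population-genetic statistics for one sister pair:
# Hudson F_ST (ratio of sums over polymorphic sites), d_xy and fixed
# differences, tiled over non-overlapping windows.

stats_slice <- function(aln, start_bp, end_bp, window_bp) {
  stopifnot(inherits(aln, "hap_aln"))
  L <- ncol(aln$seq)
  if (is.null(end_bp)) end_bp <- L
  if (start_bp < 0 || end_bp > L || start_bp >= end_bp)
    stop("invalid window [", start_bp, ", ", end_bp, ")", call. = FALSE)
  pop <- pop_codes(aln)
  sub <- aln$seq[, (start_bp + 1):end_bp, drop = FALSE]
  window_stats_cpp(sub, pop, as.integer(window_bp))
}

#' Hudson F_ST for a window of an alignment
#'
#' `F_ST = 1 - H_w / H_b`, where `H_w` is the mean per-site pairwise
#' difference within populations (averaged over the two species) and `H_b`
#' the mean between populations, each summed over the polymorphic sites of
#' the window before taking the ratio ("ratio of sums").  Returns `NA`
#' when `H_b = 0` (no polymorphic sites, or no between-population
#' differences), in which case the window carries no rank information for
#' outlier scans.  Negative values are possible and are not clamped.
#'
#' @param aln A [hap_alignment()] with exactly two populations.
#' @param start_bp,end_bp 0-based half-open window bounds (defaults: the
#'   whole alignment).
#' @return A single numeric value, or `NA`.
#' @export
#' @examples
#' a <- hap_alignment(matrix(c("A", "A", "T", "T"), 2), c("x", "y"))
#' hudson_fst(a)  # fixed difference: F_ST = 1
hudson_fst <- function(aln, start_bp = 0, end_bp = NULL) {
  r <- stats_slice(aln, start_bp, end_bp %||% ncol(aln$seq),
                   window_bp = ncol(aln$seq))
  hb <- sum(r$hb_sum)
  if (hb == 0) return(NA_real_)
  1 - sum(r$hw_sum) / hb
}

#' Mean between-population nucleotide divergence (d_xy)
#'
#' Mean over all between-population sequence pairs of the per-site
#' difference proportion in the window (Nei's d_xy); insensitive to
#' within-population diversity.
#'
#' @inheritParams hudson_fst
#' @return Per-site divergence in `[0, 1]`.
#' @export
dxy <- function(aln, start_bp = 0, end_bp = NULL) {
  r <- stats_slice(aln, start_bp, end_bp %||% ncol(aln$seq),
                   window_bp = ncol(aln$seq))
  stats::weighted.mean(r$dxy, r$end_bp - r$start_bp)
}

#' Count fixed differences between the two species
#'
#' Sites at which all samples of species 1 share one base and all samples
#' of species 2 share a different base.  Within-species polymorphism at a
#' site disqualifies it.
#'
#' @inheritParams hudson_fst
#' @return Integer count.
#' @export
fixed_differences <- function(aln, start_bp = 0, end_bp = NULL) {
  r <- stats_slice(aln, start_bp, end_bp %||% ncol(aln$seq),
                   window_bp = ncol(aln$seq))
  sum(r$n_fixed)
}

#' Windowed scan statistics for one sister pair
#'
#' Computes `n_poly`, Hudson `fst`, `dxy` and `n_fixed` for each
#' non-overlapping `window_bp` window tiling the sequence.  The whole
#' sequence (ratio-of-sums) F_ST and the mean of the defined per-window
#' F_ST values are attached as attributes `global_fst` and
#' `mean_window_fst`.
#'
#' @inheritParams hudson_fst
#' @param window_bp Window size in bp (default 500); a warning is issued if
#'   the sequence length is not a multiple of it (the last window is then
#'   short).
#' @param pair_age Optional divergence time recorded in the table.
#' @return A tibble with one row per window: `pair_age`, `window_index`
#'   (1-based), `start_bp`, `end_bp`, `n_poly`, `fst`, `dxy`, `n_fixed`.
#' @export
window_table <- function(aln, window_bp = 500, pair_age = NA_real_) {
  stopifnot(inherits(aln, "hap_aln"))
  assert_scalar_num(window_bp, "window_bp", 0, allow_zero = FALSE)
  L <- ncol(aln$seq)
  if (L %% window_bp != 0)
    warning("sequence length ", L, " is not a multiple of window_bp = ",
            window_bp, "; the last window is short", call. = FALSE)
  r <- stats_slice(aln, 0, L, as.integer(window_bp))
  fst <- ifelse(r$hb_sum == 0, NA_real_, 1 - r$hw_sum / r$hb_sum)
  tbl <- tibble::tibble(
    pair_age = pair_age,
    window_index = seq_along(r$start_bp),
    start_bp = r$start_bp, end_bp = r$end_bp,
    n_poly = r$n_poly, fst = fst, dxy = r$dxy, n_fixed = r$n_fixed)
  hb <- sum(r$hb_sum)
  attr(tbl, "global_fst") <- if (hb == 0) NA_real_ else 1 - sum(r$hw_sum) / hb
  attr(tbl, "mean_window_fst") <- mean(fst, na.rm = TRUE)
  tbl
}

#' Export windows as BED
#'
#' 0-based half-open intervals with the window F_ST (scaled by 1000) in the
#' score column; undefined F_ST is written as score 0 with name `NA`.
#'
#' @param windows A tibble from [window_table()] (or with an `outlier`
#'   column from [call_outliers()], in which case only outlier windows are
#'   written).
#' @param path Output file.
#' @param chrom Chromosome name for column 1.
#' @return `path`, invisibly.
#' @export
write_windows_bed <- function(windows, path, chrom = "sim") {
  w <- windows
  if ("outlier" %in% names(w)) w <- dplyr::filter(w, .data$outlier)
  bed <- data.frame(
    chrom = chrom,
    start = format(w$start_bp, scientific = FALSE, trim = TRUE),
    end = format(w$end_bp, scientific = FALSE, trim = TRUE),
    name = ifelse(is.na(w$fst), "NA", "fst"),
    score = ifelse(is.na(w$fst), 0, round(w$fst * 1000)))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
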