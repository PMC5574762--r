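BASES <- c("A", "C", "G", "T")

#' Haplotype alignment with population labels
#'
#' The substrate of all window statistics: a matrix of nucleotides (rows =
#' sampled haplotypes, columns = sites, 0-based half-open coordinate
#' convention for windows) plus a per-row species assignment.  Internally
#' bases are stored as raw codes 0..3 (A, C, G, T); use [aln_matrix()] for
#' a character matrix view.
#'
#' @param seqs A character matrix of bases (case-insensitive) or a raw
#'   matrix of codes 0..3.
#' @param pop A vector of species labels, one per row (exactly two distinct
#'   labels for two-population statistics).
#' @return An object of class `hap_aln`.
#' @export
#' @examples
#' m <- matrix(c("A", "A", "T", "T"), nrow = 2, byrow = TRUE,
#'             dimnames = NULL)
#' hap_alignment(m, c("sp1", "sp2"))
hap_alignment <- function(seqs, pop) {
  if (is.character(seqs)) {
    up <- toupper(seqs)
    codes <- match(up, BASES) - 1L
    if (anyNA(codes) && length(seqs) > 0)
      stop("alignment contains non-ACGT characters", call. = FALSE)
    raw_mat <- matrix(as.raw(codes), nrow = nrow(seqs))
  } else if (is.raw(seqs)) {
    raw_mat <- seqs
    if (length(raw_mat) && max(as.integer(raw_mat)) > 3)
      stop("raw base codes must be 0..3", call. = FALSE)
  } else {
    stop("seqs must be a character or raw matrix", call. = FALSE)
  }
  if (length(pop) != nrow(raw_mat))
    stop("pop must have one label per alignment row", call. = FALSE)
  structure(list(seq = raw_mat, pop = as.character(pop)),
            class = "hap_aln")
}

#' @export
print.hap_aln <- function(x, ...) {
  tab <- table(x$pop)
  cat("<hap_aln> ", nrow(x$seq), " haplotypes x ", ncol(x$seq), " sites (",
      paste(names(tab), tab, sep = ": ", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @export
dim.hap_aln <- function(x) dim(x$seq)

#' @rdname hap_alignment
#' @param aln A `hap_aln`.
#' @export
aln_matrix <- function(aln) {
  stopifnot(inherits(aln, "hap_aln"))
  m <- matrix(BASES[as.integer(aln$seq) + 1L], nrow = nrow(aln$seq))
  rownames(m) <- aln_names(aln)
  m
}

#' @rdname hap_alignment
#' @export
pop_labels <- function(aln) {
  stopifnot(inherits(aln, "hap_aln"))
  aln$pop
}

# per-row names "species|index"
aln_names <- function(aln) {
  idx <- stats::ave(seq_along(aln$pop), aln$pop, FUN = seq_along)
  paste0(aln$pop, "|", idx)
}

# integer 0/1 vector mapping the two species labels to demes, first label
# (by order of appearance) = 0
pop_codes <- function(aln) {
  lv <- unique(aln$pop)
  if (length(lv) != 2)
    stop("exactly two populations are required (found ",
         length(lv), ")", call. = FALSE)
  if (any(table(aln$pop) == 0))
    stop("one population is empty", call. = FALSE)
  match(aln$pop, lv) - 1L
}
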