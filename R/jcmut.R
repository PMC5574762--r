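# Finite-sites Jukes-Cantor sequence evolution along local genealogies,
# plus the standard-format writers (FASTA, ms-style haplotypes, newick).

#' Evolve sequences along local genealogies under Jukes-Cantor
#'
#' Each site evolves independently down the genealogy of its segment from a
#' uniform-random root base; substitutions occur as a Poisson process at
#' rate `mu` per site per generation, the new base drawn uniformly from the
#' three alternatives (JC69, finite sites: multiple hits per site are
#' allowed).
#'
#' @param segments A tibble of segments as returned by [simulate_pair()]
#'   (columns `start_bp`, `end_bp`, `tree`); segments must partition
#'   `[0, L)`.
#' @param mu Per-site per-generation mutation rate.
#' @param seed Integer seed.
#' @return A [hap_alignment()]; rows follow the tip labels of the trees
#'   (`species|index`).
#' @export
#' @examples
#' spec <- scenario_spec(N_e = 200, pair_ages = 500,
#'                       samples_per_species = 2, seq_length_bp = 1000,
#'                       mu = 1e-5, rec = 0)
#' segs <- simulate_pair(spec, 500, seed = 1)
#' evolve_sequences(segs, mu = 1e-5, seed = 2)
evolve_sequences <- function(segments, mu, seed = 1) {
  stopifnot(is.data.frame(segments),
            all(c("start_bp", "end_bp", "tree") %in% names(segments)))
  assert_scalar_num(mu, "mu", 0)
  segments <- dplyr::arrange(segments, .data$start_bp)
  if (nrow(segments) == 0) stop("no segments supplied", call. = FALSE)
  if (any(segments$start_bp[-1] != segments$end_bp[-nrow(segments)]) ||
      segments$start_bp[1] != 0)
    stop("segments must partition [0, L) without gaps or overlap",
         call. = FALSE)
  L <- segments$end_bp[nrow(segments)]
  tips <- segments$tree[[1]]$tip.label
  n <- length(tips)
  conv <- lapply(segments$tree, phylo_to_parent, tip_labels = tips)
  aln <- with_seed(seed, jc_evolve_cpp(
    parents = lapply(conv, `[[`, "parent"),
    times = lapply(conv, `[[`, "time"),
    starts = segments$start_bp, ends = segments$end_bp,
    n_tips = n, L = L, mu = mu))
  hap_alignment(aln, sub("\\|.*$", "", tips))
}

# phylo -> (parent array, node times) with tips first, in tip_labels order
phylo_to_parent <- function(phy, tip_labels) {
  stopifnot(inherits(phy, "phylo"))
  n <- length(phy$tip.label)
  M <- n + phy$Nnode
  if (any(phy$edge.length < 0))
    stop("negative branch length in genealogy", call. = FALSE)
  perm <- match(phy$tip.label, tip_labels)
  if (anyNA(perm)) stop("tree tip labels do not match", call. = FALSE)
  remap <- c(perm, (n + 1L):M)
  parent <- rep(NA_integer_, M)
  parent[remap[phy$edge[, 2]]] <- remap[phy$edge[, 1]]
  # node depths from root
  depth <- rep(NA_real_, M)
  root <- remap[setdiff(phy$edge[, 1], phy$edge[, 2])[1]]
  elen <- rep(0, M)
  elen[remap[phy$edge[, 2]]] <- phy$edge.length
  depth[root] <- 0
  repeat {
    todo <- which(is.na(depth) & !is.na(parent) & !is.na(depth[parent]))
    if (length(todo) == 0) break
    depth[todo] <- depth[parent[todo]] + elen[todo]
  }
  height <- max(depth[seq_len(n)]) - depth
  list(parent = parent, time = height)
}

#' Read and write haplotype alignments as FASTA
#'
#' Lossless round-trip including population labels, encoded in the headers
#' as `species|sample_index`.  Lowercase bases are normalised to uppercase
#' on read; a ragged alignment is rejected with the offending record.
#'
#' @param aln A [hap_alignment()].
#' @param path File path.
#' @return `read_fasta()` returns a `hap_aln`; `write_fasta()` returns
#'   `path` invisibly.
#' @export
write_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "hap_aln"))
  if (nrow(aln$seq) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  seqs <- apply(aln_matrix(aln), 1, paste, collapse = "")
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- aln_names(aln)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) stop("failed to read FASTA: ",
                                         conditionMessage(e), call. = FALSE))
  if (length(x) == 0) {
    return(hap_alignment(matrix(character(0), nrow = 0, ncol = 0),
                         character(0)))
  }
  w <- Biostrings::width(x)
  if (length(unique(w)) != 1)
    stop("ragged alignment: record ", which(w != w[1])[1],
         " has length ", w[which(w != w[1])[1]], " (expected ", w[1], ")",
         call. = FALSE)
  m <- t(vapply(seq_along(x),
                function(i) strsplit(toupper(as.character(x[[i]])), "")[[1]],
                character(w[1])))
  pop <- sub("\\|.*$", "", names(x))
  hap_alignment(m, pop)
}

#' Write an alignment in ms-style 0/1 haplotype format
#'
#' Writes the classic `//` block with `segsites:` and `positions:` lines
#' and one 0/1 row per haplotype, using the biallelic polymorphic sites of
#' the alignment (0 = the allele carried by the first haplotype).  Sites
#' with more than two alleles cannot be represented and are dropped with a
#' message reporting the count.
#'
#' @param aln A [hap_alignment()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_ms <- function(aln, path) {
  stopifnot(inherits(aln, "hap_aln"))
  m <- aln$seq
  L <- ncol(m)
  nal <- apply(m, 2, function(col) length(unique(col)))
  poly <- which(nal == 2)
  dropped <- sum(nal > 2)
  if (dropped > 0)
    message("write_ms: dropped ", dropped, " site(s) with >2 alleles")
  lines <- c("//", paste("segsites:", length(poly)))
  if (length(poly) > 0) {
    lines <- c(lines, paste("positions:",
                            paste(sprintf("%.6f", (poly - 0.5) / L),
                                  collapse = " ")))
    # 0 = allele of haplotype 1 at each site
    sub <- m[, poly, drop = FALSE]
    ref <- sub[1, ]
    hap <- apply(sub, 1, function(row) paste(as.integer(row != ref),
                                             collapse = ""))
    lines <- c(lines, hap)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write local genealogies as newick
#'
#' One tree per line, branch lengths in generations, preceded by a bracket
#' comment `[&interval=start-end]` recording the bp interval the genealogy
#' spans.
#'
#' @param segments A segment tibble from [simulate_pair()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_segments_newick <- function(segments, path) {
  stopifnot(is.data.frame(segments), "tree" %in% names(segments))
  lines <- purrr::pmap_chr(
    segments[c("start_bp", "end_bp", "tree")],
    function(start_bp, end_bp, tree) {
      paste0("[&interval=", format(start_bp, scientific = FALSE), "-",
             format(end_bp, scientific = FALSE), "]",
             ape::write.tree(tree))
    })
  writeLines(lines, path)
  invisible(path)
}
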