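# Independent brute-force oracles used across the suite.  These are kept
# deliberately naive (all-pairs loops, explicit event simulation) and never
# share code with the implementation they check.

# mean pairwise difference proportion between two sets of rows of a
# character matrix, counting all between-pair site comparisons explicitly
brute_dxy <- function(mat, rows1, rows2) {
  tot <- 0; np <- 0
  for (i in rows1) for (j in rows2) {
    tot <- tot + mean(mat[i, ] != mat[j, ])
    np <- np + 1
  }
  unname(tot / np)
}

# Hudson F_ST by explicit per-site pairwise counting, ratio of sums over
# polymorphic sites
brute_fst <- function(mat, rows1, rows2) {
  L <- ncol(mat)
  hw_sum <- 0; hb_sum <- 0
  for (s in seq_len(L)) {
    col <- mat[, s]
    if (length(unique(col[c(rows1, rows2)])) < 2) next
    pw <- function(rows) {
      if (length(rows) < 2) return(0)
      d <- 0; n <- 0
      for (i in seq_along(rows)) for (j in seq_along(rows)) {
        if (i < j) { d <- d + (col[rows[i]] != col[rows[j]]); n <- n + 1 }
      }
      d / n
    }
    hb <- 0; n <- 0
    for (i in rows1) for (j in rows2) { hb <- hb + (col[i] != col[j]); n <- n + 1 }
    hw_sum <- hw_sum + (pw(rows1) + pw(rows2)) / 2
    hb_sum <- hb_sum + hb / n
  }
  if (hb_sum == 0) return(NA_real_)
  unname(1 - hw_sum / hb_sum)
}

brute_fixed <- function(mat, rows1, rows2) {
  n <- 0
  for (s in seq_len(ncol(mat))) {
    a1 <- unique(mat[rows1, s]); a2 <- unique(mat[rows2, s])
    if (length(a1) == 1 && length(a2) == 1 && a1 != a2) n <- n + 1
  }
  n
}

# single-locus structured coalescent sampler, event by event, independent
# of the C++ implementation: returns the TMRCA of n1+n2 lineages under the
# two-deme isolation model with an optional migration epoch
oracle_tmrca <- function(n1, n2, N, Tsplit, m_epoch = c(0, 0), m1 = 0) {
  deme <- c(rep(0, n1), rep(1, n2))
  t <- 0
  while (length(deme) > 1) {
    k0 <- sum(deme == 0); k1 <- sum(deme == 1)
    merged <- t >= Tsplit
    crate <- if (merged) choose(length(deme), 2) / (2 * N)
             else (choose(k0, 2) + choose(k1, 2)) / (2 * N)
    in_ep <- !merged && t >= m_epoch[1] && t < m_epoch[2]
    mrate <- if (in_ep) k1 * m1 else 0
    tot <- crate + mrate
    bound <- min(c(m_epoch, Tsplit)[c(m_epoch, Tsplit) > t], Inf)
    if (tot == 0) { t <- bound; next }
    dt <- rexp(1, tot)
    if (t + dt >= bound) { t <- bound; next }
    t <- t + dt
    if (runif(1) < crate / tot) {
      if (merged) {
        deme <- deme[-1]
      } else {
        d <- if (runif(1) < choose(k0, 2) / (choose(k0, 2) + choose(k1, 2))) 0 else 1
        idx <- which(deme == d)
        deme <- deme[-idx[1]]
      }
    } else {
      idx <- which(deme == 1)
      deme[idx[sample.int(length(idx), 1)]] <- 0
    }
  }
  t
}

# toy alignment builder
toy_aln <- function(strings, pop) {
  hap_alignment(do.call(rbind, strsplit(strings, "")), pop)
}
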