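win_tbl <- function(fst, pair = 1) {
  tibble::tibble(pair_age = pair, window_index = seq_along(fst),
                 start_bp = (seq_along(fst) - 1) * 500,
                 end_bp = seq_along(fst) * 500,
                 n_poly = 10, fst = fst, dxy = 0.01, n_fixed = 0)
}

test_that("pooled thresholds match the order-statistic oracle", {
  # constant pool: every quantile equals the constant
  cst <- pooled_thresholds(win_tbl(rep(0.3, 40)))
  expect_equal(unlist(cst[c("q75", "q80", "q95", "q99")]),
               c(q75 = 0.3, q80 = 0.3, q95 = 0.3, q99 = 0.3))
  # 1..100: check against explicit type-7 interpolation
  v <- sample(1:100)  # order must not matter
  thr <- pooled_thresholds(win_tbl(v))
  type7 <- function(p, x) {
    x <- sort(x); h <- (length(x) - 1) * p + 1
    x[floor(h)] + (h - floor(h)) * (x[ceiling(h)] - x[floor(h)])
  }
  expect_equal(thr$q95, type7(0.95, v))
  expect_equal(thr$q75, type7(0.75, v))
  expect_true(thr$q75 <= thr$q80 && thr$q80 <= thr$q95 && thr$q95 <= thr$q99)
  # undefined windows are excluded, all-undefined rejected
  expect_equal(pooled_thresholds(win_tbl(c(v, NA, NA)))$n_pooled, 100)
  expect_error(pooled_thresholds(win_tbl(c(NA, NA))), "no defined")
})

test_that("pooling is pair-blind", {
  set.seed(3)
  f1 <- runif(30); f2 <- runif(30)
  a <- dplyr::bind_rows(win_tbl(f1, 1), win_tbl(f2, 2))
  b <- dplyr::bind_rows(win_tbl(f2, 1), win_tbl(f1, 2))
  expect_equal(pooled_thresholds(a), pooled_thresholds(b))
})

test_that("the 95%+75% bridge rule handles the worked cases", {
  thr <- tibble::tibble(q75 = 0.75, q80 = 0.80, q95 = 0.95, q99 = 0.99)
  # [>q95, >q75, >q75, >q95] -> all 4 outliers
  out <- call_outliers(win_tbl(c(0.96, 0.80, 0.80, 0.97)), thr,
                       "p95_bridge75")
  expect_equal(out$outlier, rep(TRUE, 4))
  # [>q95, <q75, >q95] -> only the flanks
  out <- call_outliers(win_tbl(c(0.96, 0.50, 0.97)), thr, "p95_bridge75")
  expect_equal(out$outlier, c(TRUE, FALSE, TRUE))
  # trailing [>q95, >q75] without a closing 95% window -> 1 outlier
  out <- call_outliers(win_tbl(c(0.96, 0.80)), thr, "p95_bridge75")
  expect_equal(out$outlier, c(TRUE, FALSE))
  # undefined F_ST breaks a bridge
  out <- call_outliers(win_tbl(c(0.96, NA, 0.97)), thr, "p95_bridge75")
  expect_equal(out$outlier, c(TRUE, FALSE, TRUE))
  # ties at the threshold are non-outliers
  out <- call_outliers(win_tbl(c(0.95, 0.96)), thr, "p95")
  expect_equal(out$outlier, c(FALSE, TRUE))
})

test_that("bridging never crosses pair boundaries", {
  thr <- tibble::tibble(q75 = 0.75, q80 = 0.80, q95 = 0.95, q99 = 0.99)
  tbl <- dplyr::bind_rows(win_tbl(c(0.80, 0.96), 1),
                          win_tbl(c(0.96, 0.80), 2))
  out <- call_outliers(tbl, thr, "p95_bridge75")
  # the >q75 windows flank a 95% hit only across the pair boundary
  expect_equal(out$outlier[out$pair_age == 1], c(FALSE, TRUE))
  expect_equal(out$outlier[out$pair_age == 2], c(TRUE, FALSE))
})

test_that("bridge rule agrees with a brute-force run scanner", {
  brute_bridge <- function(fst, q95, q75) {
    flag <- !is.na(fst) & fst > q95
    res <- flag
    for (i in seq_along(fst)) {
      if (flag[i]) next
      left <- which(flag & seq_along(fst) < i)
      right <- which(flag & seq_along(fst) > i)
      if (length(left) == 0 || length(right) == 0) next
      lo <- max(left); hi <- min(right)
      if (all(!is.na(fst[(lo + 1):(hi - 1)]) &
              fst[(lo + 1):(hi - 1)] > q75))
        res[i] <- TRUE
    }
    res
  }
  thr <- tibble::tibble(q75 = 0.5, q80 = 0.6, q95 = 0.9, q99 = 0.99)
  set.seed(11)
  for (rep in 1:20) {
    fst <- runif(15)
    fst[sample(15, 2)] <- NA
    out <- call_outliers(win_tbl(fst), thr, "p95_bridge75")
    expect_equal(out$outlier, brute_bridge(fst, 0.9, 0.5))
  }
})

test_that("outlier calls nest across thresholds", {
  set.seed(21)
  fst <- runif(400)
  tbl <- win_tbl(fst)
  thr <- pooled_thresholds(tbl)
  o80 <- call_outliers(tbl, thr, "p80")$outlier
  o95 <- call_outliers(tbl, thr, "p95")$outlier
  o99 <- call_outliers(tbl, thr, "p99")$outlier
  ob <- call_outliers(tbl, thr, "p95_bridge75")$outlier
  expect_true(all(o99 <= o95))
  expect_true(all(o95 <= o80))
  expect_true(all(o95 <= ob))
  # counts close to the nominal tail fractions
  expect_equal(sum(o95), 20, tolerance = 0.25)
})

test_that("divergent-genome series counts outliers per pair", {
  thr <- tibble::tibble(q75 = 0.5, q80 = 0.6, q95 = 0.9, q99 = 0.99)
  tbl <- dplyr::bind_rows(win_tbl(c(0.95, 0.2), 2000),
                          win_tbl(c(0.95, 0.95), 4000))
  calls <- call_outliers(tbl, thr, "p95")
  s <- divergent_genome_series(calls, N_e = 1000)
  expect_equal(s$t_scaled, c(2, 4))
  expect_equal(s$n_outlier, c(1, 2))
  # all-equal F_ST -> nothing exceeds a quantile of a constant
  cst <- win_tbl(rep(0.4, 10), 2000)
  calls <- call_outliers(cst, pooled_thresholds(cst), "p95")
  expect_equal(sum(calls$outlier), 0)
  # processing order of pairs is irrelevant
  s2 <- divergent_genome_series(
    call_outliers(tbl[c(3, 4, 1, 2), ], thr, "p95"), N_e = 1000)
  expect_equal(s2, s)
})
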