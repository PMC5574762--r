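# Internal helpers shared across modules.

# Counter-based seed derivation: folds the master seed and an arbitrary
# token path (scenario label, replicate, pair index, stage name) into a
# 31-bit integer.  Adding new tokens downstream never perturbs seeds
# derived from other paths, so sub-experiments rerun identically.
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1)
  tokens <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                         character(1)), collapse = "/")
  h <- as.double(master) %% 2147483647
  for (b in utf8ToInt(tokens)) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

assert_scalar_num <- function(x, name, lower = -Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x))
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  if (x < lower || (!allow_zero && x == lower))
    stop(sprintf("`%s` must be %s %s", name,
                 if (allow_zero) ">=" else ">", lower), call. = FALSE)
  invisible(x)
}
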