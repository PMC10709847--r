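`%||%` <- function(a, b) if (is.null(a)) b else a

# Seed the RNG for the calling function only: the caller's exit restores the
# global .Random.seed, so seeded package functions do not disturb user code.
local_rng <- function(seed, envir = parent.frame()) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  restore <- if (is.null(old)) {
    quote(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  } else {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  }
  do.call("on.exit", list(restore, add = TRUE), envir = envir)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  invisible(NULL)
}

# Derive a reproducible child seed (kept below 2^31).
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset) %% 2011L
}

# Row variances of a numeric matrix without copies per row.
row_vars <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  (rowSums(x * x) - n * mu * mu) / (n - 1)
}
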