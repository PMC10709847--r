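# Shared fixtures, built in code and cached per test run. Heavy objects are
# constructed lazily so cheap test files stay cheap.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .cache)) assign(key, force(expr), .cache)
  get(key, .cache)
}

# Small cohort: 4 groups (two multi-type, two singleton), fast to generate.
small_spec <- function(seed = 101L, ...) {
  cohort_spec(n_groups = 4L, types_per_group = c(2L, 2L, 1L, 1L),
              subtypes_per_type = 2L, samples_per_subtype = 10L,
              n_background_probes = 400L, n_markers_per_group = 10L,
              n_markers_per_type = 10L, n_sex_probes = 10L,
              seed = seed, ...)
}

small_cohort <- function() cached("small_cohort", simulate_cohort(small_spec()))

# Fitted hierarchical model on the small cohort (Boruta kept on, short).
small_fit <- function() cached("small_fit", {
  co <- small_cohort()
  suppressWarnings(methhier(co$beta, co$manifest, annotation = co$annotation,
                            boruta_max_iter = 40L, boruta_trees = 60L,
                            min_markers = 5L,
                            config = forest_config(n_trees = 100L, seed = 7L)))
})

# Default-scale cohort and fit (the study conditions); used by the
# acceptance-facing tests, built once.
default_cohort <- function() cached("default_cohort",
                                    simulate_cohort(cohort_spec(seed = 1L)))

default_fit <- function() cached("default_fit", {
  co <- default_cohort()
  suppressWarnings(methhier(co$beta, co$manifest, annotation = co$annotation,
                            seed = 42L))
})

# Cleanly separable toy classification problem: `p` informative features
# shifted per class plus noise features.
separable_xy <- function(n_per_class = 30L, classes = c("a", "b", "c"),
                         p_info = 5L, p_noise = 20L, seed = 5L) {
  set.seed(seed)
  y <- rep(classes, each = n_per_class)
  n <- length(y)
  shift <- matrix(stats::rnorm(length(classes) * p_info, sd = 3),
                  length(classes), p_info)
  x <- cbind(shift[match(y, classes), , drop = FALSE] +
               matrix(stats::rnorm(n * p_info, sd = 0.3), n, p_info),
             matrix(stats::rnorm(n * p_noise), n, p_noise))
  colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
  list(x = x, y = y)
}

# Beta matrix + labels with class-separated probes, for cascade tests:
# `delta` mean shift on `n_marker` probes per class (one-vs-all),
# `n_flat` background probes.
separable_beta <- function(classes = c("a", "b", "c"), n_per_class = 20L,
                           n_marker = 10L, n_flat = 50L, delta = 0.3,
                           kappa = 80, seed = 9L) {
  set.seed(seed)
  labels <- rep(classes, each = n_per_class)
  n <- length(labels)
  p <- n_marker * length(classes) + n_flat
  mean_mat <- matrix(0.4, p, n)
  for (ci in seq_along(classes)) {
    rows <- (ci - 1L) * n_marker + seq_len(n_marker)
    mean_mat[rows, labels == classes[ci]] <- 0.4 + delta
  }
  beta <- matrix(stats::rbeta(p * n, mean_mat * kappa, (1 - mean_mat) * kappa),
                 p, n)
  rownames(beta) <- sprintf("cg%07d", seq_len(p))
  colnames(beta) <- sprintf("S%04d", seq_len(n))
  marker_of <- stats::setNames(
    lapply(seq_along(classes), function(ci)
      rownames(beta)[(ci - 1L) * n_marker + seq_len(n_marker)]), classes)
  list(beta = beta, labels = labels, markers = marker_of)
}

make_manifest <- function(types, subtypes = types, n_each = 10L,
                          cohort = "c1") {
  df <- data.frame(
    cancer_type = rep(types, each = n_each),
    subtype = rep(subtypes, each = n_each),
    cohort = cohort, split = "unassigned", stringsAsFactors = FALSE)
  df$sample_id <- sprintf("S%04d", seq_len(nrow(df)))
  df[, c("sample_id", "cancer_type", "subtype", "cohort", "split")]
}

# silhouette oracle: direct transcription of the definition
# direct transcription of the definition, one point at a time
brute_silhouette <- function(d, cl) {
  n <- nrow(d)
  vapply(seq_len(n), function(i) {
    mine <- setdiff(which(cl == cl[i]), i)
    if (!length(mine)) return(0)
    a <- mean(d[i, mine])
    b <- min(vapply(setdiff(unique(cl), cl[i]),
                    function(g) mean(d[i, cl == g]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
}
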