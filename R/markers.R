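# Marker screening: a one-way ANOVA screen per CpG, Tukey-Kramer one-vs-all-
# others selection with an adaptive delta-beta relaxation schedule. Both
# tests are computed vectorised across probes (the per-probe ANOVA F and the
# studentized-range adjusted p reduce to group means, counts and the pooled
# within-class variance).

# Group means (k x P), group sizes, pooled within-class variance per probe.
class_stats <- function(beta, labels) {
  labels <- as.character(labels)
  stopifnot(ncol(beta) == length(labels))
  idx <- split(seq_along(labels), labels)
  k <- length(idx)
  n_g <- lengths(idx)
  if (k < 2L) stop("need at least two classes")
  means <- t(matrix(vapply(idx, function(ix) rowMeans(beta[, ix, drop = FALSE]),
                           numeric(nrow(beta))),
                    nrow(beta), k, dimnames = list(NULL, names(idx))))
  ssw <- rowSums(beta * beta) - colSums(n_g * means * means)
  ssw[ssw < 0] <- 0                       # numerical guard
  N <- length(labels)
  list(means = means, n = n_g, k = k, N = N, ssw = ssw,
       mse = ssw / (N - k), classes = names(idx))
}

#' One-way ANOVA screen across CpG probes
#'
#' Computes, for every probe, the one-way fixed-effects ANOVA F statistic
#' (between-class mean square over within-class mean square) of beta values
#' across the class labels, and retains probes with `p < alpha`. Degenerate
#' probes (zero variance everywhere) get `p = 1` and are excluded; probes
#' with zero within-class variance but distinct means get `p = 0` and are
#' retained.
#'
#' @param beta Beta matrix (probes x samples).
#' @param labels Class label per sample.
#' @param alpha Retention threshold on the p-value (default 0.05).
#' @return data.frame `probe_id`, `F`, `p_value`, `retained`, ordered as the
#'   input probes.
#' @export
anova_screen <- function(beta, labels, alpha = 0.05) {
  st <- class_stats(beta, labels)
  if (any(st$n < 2L)) stop("every class needs at least two samples")
  grand <- colSums(st$n * st$means) / st$N
  ssb <- colSums(st$n * sweep(st$means, 2L, grand)^2)
  df1 <- st$k - 1L
  df2 <- st$N - st$k
  f <- (ssb / df1) / (st$ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  # zero within-class variance: equal means -> no signal (p = 1);
  # distinct means -> infinite F (p = 0)
  p[st$ssw == 0 & ssb <= 1e-12] <- 1
  f[st$ssw == 0 & ssb <= 1e-12] <- 0
  p[st$ssw == 0 & ssb > 1e-12] <- 0
  data.frame(probe_id = rownames(beta), F = unname(f), p_value = unname(p),
             retained = unname(p < alpha), stringsAsFactors = FALSE)
}

# All pairwise Tukey-Kramer comparisons, vectorised over probes.
# Returns list: pairs (2 x n_pairs class indices), diff and adj_p
# (n_pairs x P matrices).
tukey_all <- function(beta, labels) {
  st <- class_stats(beta, labels)
  if (any(st$n < 2L)) stop("every class needs at least two samples")
  pairs <- utils::combn(st$k, 2L)
  df <- st$N - st$k
  diff <- st$means[pairs[1L, ], , drop = FALSE] -
    st$means[pairs[2L, ], , drop = FALSE]
  se2 <- outer(0.5 * (1 / st$n[pairs[1L, ]] + 1 / st$n[pairs[2L, ]]), st$mse)
  q <- abs(diff) / sqrt(se2)
  adj_p <- matrix(stats::ptukey(q, nmeans = st$k, df = df, lower.tail = FALSE),
                  nrow(q), ncol(q))
  adj_p[abs(diff) < 1e-15] <- 1          # identical means (incl. 0/0)
  list(pairs = pairs, classes = st$classes, diff = diff, adj_p = adj_p,
       probe_ids = rownames(beta))
}

#' Tukey-Kramer pairwise comparisons at a single CpG
#'
#' All-pairs post-hoc comparison of class mean beta values using the
#' studentized range distribution, valid for unequal class sizes: for a pair
#' (g, h), `SE = sqrt((MSE/2)(1/n_g + 1/n_h))`, `q = |m_g - m_h| / SE`, and
#' the adjusted p is the upper tail of the studentized range distribution
#' with `k` means and `N - k` degrees of freedom.
#'
#' @param beta Beta matrix (probes x samples).
#' @param labels Class label per sample.
#' @param probe Probe id (or row index) to test.
#' @return data.frame with one row per class pair: `class_g`, `class_h`,
#'   `mean_diff` (`m_g - m_h`), `adj_p`.
#' @export
tukey_kramer <- function(beta, labels, probe) {
  tk <- tukey_all(beta[probe, , drop = FALSE], labels)
  data.frame(probe_id = tk$probe_ids[1L],
             class_g = tk$classes[tk$pairs[1L, ]],
             class_h = tk$classes[tk$pairs[2L, ]],
             mean_diff = tk$diff[, 1L],
             adj_p = tk$adj_p[, 1L],
             stringsAsFactors = FALSE)
}

#' One-vs-all-others marker selection with delta-beta relaxation
#'
#' A probe is a marker for class g at level delta iff, for every other class
#' h, the Tukey-Kramer adjusted p of the (g, h) comparison is below
#' `p_threshold` and the absolute class mean difference exceeds delta. For
#' each class, the first delta in the (strictly decreasing) schedule that
#' yields at least `min_markers` markers is accepted and recorded; a class
#' failing at every level keeps its largest panel (the last schedule entry)
#' and is recorded as a failure.
#'
#' @param beta Beta matrix, typically restricted to ANOVA-retained probes and
#'   training samples.
#' @param labels Class label per sample.
#' @param delta_schedule Strictly decreasing delta-beta levels; default
#'   `c(0.2, 0.15, 0.1)`.
#' @param p_threshold Tukey-adjusted p cut-off (default 0.01).
#' @param min_markers Minimum panel size before relaxing delta (default 20).
#' @return Object of class `marker_panel`: `markers` (named list of probe-id
#'   vectors per class), `accepted_delta`, `p_threshold`, `failed` (classes
#'   under-powered at every level).
#' @export
select_markers <- function(beta, labels, delta_schedule = c(0.2, 0.15, 0.1),
                           p_threshold = 0.01, min_markers = 20L) {
  if (is.unsorted(rev(delta_schedule), strictly = TRUE))
    stop("delta_schedule must be strictly decreasing")
  tk <- tukey_all(beta, labels)
  classes <- tk$classes
  markers <- vector("list", length(classes))
  names(markers) <- classes
  accepted <- stats::setNames(rep(NA_real_, length(classes)), classes)
  failed <- character()
  for (g in classes) {
    gi <- match(g, classes)
    rows <- tk$pairs[1L, ] == gi | tk$pairs[2L, ] == gi
    sig_all <- colSums(tk$adj_p[rows, , drop = FALSE] >= p_threshold) == 0L
    min_diff <- apply(abs(tk$diff[rows, , drop = FALSE]), 2L, min)
    for (delta in delta_schedule) {
      hit <- sig_all & min_diff > delta
      if (sum(hit) >= min_markers || delta == delta_schedule[length(delta_schedule)]) {
        markers[[g]] <- tk$probe_ids[hit]
        accepted[g] <- delta
        if (sum(hit) < min_markers) failed <- c(failed, g)
        break
      }
    }
  }
  structure(list(markers = markers, accepted_delta = accepted,
                 p_threshold = p_threshold, min_markers = min_markers,
                 delta_schedule = delta_schedule, failed = failed),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("Marker panel over", length(x$markers), "classes;",
      length(unique(unlist(x$markers))), "distinct probes\n")
  df <- data.frame(class = names(x$markers), n_markers = lengths(x$markers),
                   accepted_delta = unname(x$accepted_delta))
  print(df, row.names = FALSE)
  if (length(x$failed))
    cat("under-powered at all delta levels:", paste(x$failed, collapse = ", "), "\n")
  invisible(x)
}

#' Write a marker panel as TSV
#' @param panel A `marker_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_panel <- function(panel, path) {
  df <- data.frame(
    class = rep(names(panel$markers), lengths(panel$markers)),
    probe_id = unlist(panel$markers, use.names = FALSE),
    accepted_delta = rep(unname(panel$accepted_delta), lengths(panel$markers)))
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}
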