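# Derivation of the class taxonomy: per-subtype mean methylomes, restricted
# to the most variable CpGs, are clustered by UPGMA under Pearson correlation
# distance, and the dendrogram is cut into groups at the silhouette-optimal
# cluster count (with explicit manual overrides where curation is wanted).

#' Per-subtype mean methylation profiles
#'
#' Collapses the sample-level beta matrix into one mean profile per clinical
#' subtype (arithmetic mean per probe over that subtype's samples).
#'
#' @param beta Beta matrix (probes x samples), missing values already removed.
#' @param manifest Manifest covering the matrix samples.
#' @return List of class `subtype_profiles`: `means` (subtypes x probes
#'   matrix), `subtype_ids`, `type_of_subtype` (named character).
#' @export
subtype_means <- function(beta, manifest) {
  validate_beta_matrix(beta)
  man <- manifest[match(colnames(beta), manifest$sample_id), , drop = FALSE]
  if (anyNA(man$sample_id))
    stop("manifest is missing sample(s) present in the beta matrix")
  idx <- split(seq_len(ncol(beta)), man$subtype)
  if (any(lengths(idx) == 0L)) stop("empty subtype")
  means <- t(matrix(vapply(idx, function(ix) rowMeans(beta[, ix, drop = FALSE]),
                           numeric(nrow(beta))),
                    nrow(beta), length(idx),
                    dimnames = list(rownames(beta), names(idx))))
  type_of <- vapply(idx, function(ix) man$cancer_type[ix[1L]], character(1))
  structure(list(means = means, subtype_ids = rownames(means),
                 type_of_subtype = type_of),
            class = "subtype_profiles")
}

#' Most variable CpG probes
#'
#' Returns the `ceiling(fraction * n_probes)` probes with the largest
#' across-sample variance. Ties are broken by probe id (stable order), and a
#' zero-variance probe is never chosen while a higher-variance one remains.
#'
#' @param beta Beta matrix (probes x samples).
#' @param fraction Fraction of probes to keep, in (0, 1]; default 0.01, the
#'   top 1%.
#' @return Character vector of probe ids.
#' @export
top_variance_probes <- function(beta, fraction = 0.01) {
  stopifnot(fraction > 0, fraction <= 1, ncol(beta) >= 2L)
  v <- row_vars(beta)
  n_keep <- ceiling(fraction * nrow(beta))
  ord <- order(-v, rownames(beta))
  rownames(beta)[ord[seq_len(n_keep)]]
}

#' Pearson correlation distance between subtype profiles
#'
#' `d(i, j) = 1 - r(i, j)` with `r` the Pearson correlation of the two mean
#' profiles across the clustering probe set; symmetric, zero diagonal,
#' values in [0, 2].
#'
#' @param profiles A `subtype_profiles` object, or a plain matrix with one
#'   row per profile.
#' @param probes Optional probe ids to restrict the profiles to.
#' @return Symmetric distance matrix.
#' @export
pearson_distance <- function(profiles, probes = NULL) {
  m <- if (inherits(profiles, "subtype_profiles")) profiles$means else profiles
  if (!is.null(probes)) m <- m[, probes, drop = FALSE]
  if (nrow(m) < 2L) stop("need at least two profiles")
  sds <- apply(m, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant profile(s), correlation undefined: ",
         paste(rownames(m)[sds == 0], collapse = ", "))
  d <- 1 - stats::cor(t(m))
  d[d < 0] <- 0            # clamp numerical noise at r ~ 1
  diag(d) <- 0
  d
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomerative clustering: at each step the two clusters at
#' minimal average distance merge, and the merged cluster's distance to the
#' rest is the size-weighted mean. Node height is merge distance / 2, so the
#' tree is ultrametric and cophenetic distances reproduce an ultrametric
#' input exactly.
#'
#' @param d Symmetric distance matrix (or `dist`) with labels.
#' @return Object of class `taxonomy_tree`: `hclust` (the dendrogram, heights
#'   on the distance scale), `phylo` (the ape tree, heights halved), and
#'   `labels`.
#' @export
upgma_tree <- function(d) {
  if (!inherits(d, "dist")) {
    stopifnot(is.matrix(d), isSymmetric(unname(d)))
    d <- stats::as.dist(d)
  }
  if (anyNA(d)) stop("distance matrix contains NA")
  if (any(d < 0)) stop("distances must be non-negative")
  hc <- stats::hclust(d, method = "average")
  structure(list(hclust = hc, phylo = ape::as.phylo(hc), labels = hc$labels),
            class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("UPGMA taxonomy over", length(x$labels), "leaves;",
      "root height", format(max(x$hclust$height) / 2, digits = 4), "\n")
  invisible(x)
}

#' Write a taxonomy tree as Newick
#' @param tree A `taxonomy_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tree, path) {
  ape::write.tree(tree$phylo, file = path)
  invisible(path)
}

#' Silhouette scores for a clustering
#'
#' For each point, `s = (b - a) / max(a, b)` where `a` is its mean distance
#' to its own cluster's other members and `b` the smallest mean distance to
#' any other cluster. Members of singleton clusters score 0.
#'
#' @param d Symmetric distance matrix.
#' @param assignment Cluster labels, one per row of `d`.
#' @return List: `widths` (per-point scores) and `mean`.
#' @export
silhouette_scores <- function(d, assignment) {
  stopifnot(is.matrix(d), nrow(d) == length(assignment))
  assignment <- as.character(assignment)
  cl <- unique(assignment)
  if (length(cl) < 2L) stop("silhouette needs at least two clusters")
  n <- nrow(d)
  sizes <- table(assignment)
  # mean distance from every point to every cluster
  cl_mean <- vapply(cl, function(g)
    rowSums(d[, assignment == g, drop = FALSE]) / sizes[[g]], numeric(n))
  s <- numeric(n)
  for (i in seq_len(n)) {
    g <- assignment[i]
    if (sizes[[g]] == 1L) { s[i] <- 0; next }
    a <- cl_mean[i, g] * sizes[[g]] / (sizes[[g]] - 1L)  # exclude self
    b <- min(cl_mean[i, setdiff(cl, g)])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  names(s) <- rownames(d)
  list(widths = s, mean = mean(s))
}

#' Cut the taxonomy into groups at the silhouette-optimal cluster count
#'
#' For each k in `k_range` the tree is cut into k clades and the mean
#' silhouette of the induced partition is computed on the clustering
#' distances; the k maximising it wins (ties to the smaller k). Manual
#' overrides are applied last, as an explicit curation step: a named
#' character vector mapping subtype id to a group label replaces that
#' subtype's assignment. A cancer type whose subtypes land in different
#' groups is split into per-subtype class labels (`TYPE.subtype`).
#'
#' @param tree A `taxonomy_tree` over subtypes.
#' @param d The distance matrix the tree was built from.
#' @param type_of_subtype Named character: subtype id -> cancer type.
#' @param k_range Candidate cluster counts; default 2 .. min(20, leaves - 1).
#' @param overrides Optional named character vector (subtype -> group label).
#' @return List of class `group_assignment`: `group_of_subtype`,
#'   `class_of_subtype` (type or split-type label), `group_of_class`,
#'   `n_groups`, `k_silhouette` (the silhouette profile over `k_range`).
#' @export
choose_groups <- function(tree, d, type_of_subtype,
                          k_range = NULL, overrides = NULL) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  labs <- tree$labels
  n <- length(labs)
  if (is.null(k_range)) k_range <- 2:min(20L, n - 1L)
  stopifnot(all(k_range >= 2L), all(k_range <= n))
  d <- as.matrix(d)[labs, labs]
  sil <- vapply(k_range, function(k) {
    if (k == n) return(0)  # all singletons score 0 by convention
    silhouette_scores(d, stats::cutree(tree$hclust, k = k))$mean
  }, numeric(1))
  names(sil) <- k_range
  best_k <- k_range[which.max(sil)]          # which.max takes the first max
  cut <- stats::cutree(tree$hclust, k = best_k)
  group_of_subtype <- sprintf("G%02d", cut[labs])
  names(group_of_subtype) <- labs
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), labs)
    if (length(unknown))
      stop("override references unknown subtype(s): ",
           paste(unknown, collapse = ", "))
    group_of_subtype[names(overrides)] <- overrides
  }
  type_of_subtype <- type_of_subtype[labs]

  # types whose subtypes span several groups become per-subtype classes
  class_of_subtype <- character(n)
  names(class_of_subtype) <- labs
  for (ty in unique(type_of_subtype)) {
    members <- labs[type_of_subtype == ty]
    gs <- unique(group_of_subtype[members])
    class_of_subtype[members] <-
      if (length(gs) == 1L) ty else paste(ty, members, sep = ".")
  }
  group_of_class <- tapply(group_of_subtype, class_of_subtype,
                           function(g) unique(g)[1L])
  group_of_class <- stats::setNames(as.character(group_of_class),
                                    names(group_of_class))
  structure(list(group_of_subtype = group_of_subtype,
                 class_of_subtype = class_of_subtype,
                 group_of_class = group_of_class,
                 n_groups = length(unique(group_of_subtype)),
                 k_silhouette = sil),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("Group assignment:", length(x$group_of_subtype), "subtypes ->",
      x$n_groups, "groups\n")
  print(table(x$group_of_class))
  invisible(x)
}

#' Derive sample-level class labels from a group assignment
#'
#' Maps each manifest sample to its classification label at both layers:
#' the group (first layer) and the class (cancer type, or split-type label,
#' second layer).
#'
#' @param assignment A `group_assignment`.
#' @param manifest Manifest data.frame.
#' @return data.frame: `sample_id`, `class` and `group`.
#' @export
sample_classes <- function(assignment, manifest) {
  cls <- unname(assignment$class_of_subtype[manifest$subtype])
  if (anyNA(cls))
    stop("manifest contains subtype(s) absent from the group assignment")
  data.frame(sample_id = manifest$sample_id, class = cls,
             group = unname(assignment$group_of_class[cls]),
             stringsAsFactors = FALSE)
}

#' Collapse a subtype taxonomy to one leaf per group
#'
#' Keeps one representative subtype per group and returns the induced
#' group-level topology, for comparison with a reference tree (e.g. the
#' planted tree of a synthetic cohort). Requires every group to be a clade.
#'
#' @param tree A `taxonomy_tree` over subtypes.
#' @param group_of_subtype Named character vector, subtype -> group.
#' @return An `ape` phylo with group labels as tips.
#' @export
collapse_to_groups <- function(tree, group_of_subtype) {
  reps <- tapply(names(group_of_subtype), group_of_subtype, `[`, 1L)
  ph <- ape::keep.tip(tree$phylo, unname(reps))
  ph$tip.label <- names(reps)[match(ph$tip.label, reps)]
  ph
}
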