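# The fitted hierarchical classifier. `methhier()` runs the whole training
# procedure: preprocessing filters, the 4:1 stratified split, taxonomy
# derivation (UPGMA over subtype mean profiles), the marker cascade per
# classification problem, and one forest per problem. The result is an S3
# object with predict/print/summary/plot methods.

# ANOVA -> Tukey-Kramer one-vs-all-others -> Boruta, on training data.
marker_cascade <- function(beta, labels, anova_alpha = 0.05,
                           delta_schedule = c(0.2, 0.15, 0.1),
                           p_threshold = 0.01, min_markers = 20L,
                           boruta = TRUE, boruta_max_iter = 100L,
                           boruta_trees = 100L, seed = 1L) {
  screen <- anova_screen(beta, labels, alpha = anova_alpha)
  kept <- screen$probe_id[screen$retained]
  if (!length(kept)) stop("ANOVA screen retained no probes")
  panel_sel <- select_markers(beta[kept, , drop = FALSE], labels,
                              delta_schedule = delta_schedule,
                              p_threshold = p_threshold,
                              min_markers = min_markers)
  candidates <- unique(unlist(panel_sel$markers, use.names = FALSE))
  if (!length(candidates))
    stop("one-vs-all-others selection produced an empty panel")
  bor <- NULL
  panel <- candidates
  if (boruta) {
    bor <- boruta_confirm(t(beta[candidates, , drop = FALSE]), labels,
                          max_iter = boruta_max_iter, n_trees = boruta_trees,
                          seed = seed)
    if (length(bor$confirmed)) panel <- bor$confirmed
    else warning("Boruta confirmed no features; keeping the Tukey panel")
  }
  list(panel = panel, selection = panel_sel, anova = screen, boruta = bor)
}

#' Fit a hierarchical methylation classifier
#'
#' Trains the full two-layer classifier from a beta matrix and a sample
#' manifest: (i) probe and subtype filters, (ii) a stratified 4:1
#' train/test split (unless the manifest already carries one), (iii) taxonomy
#' derivation — per-subtype mean profiles, top-variance probe selection,
#' Pearson-distance UPGMA, silhouette-guided cut into groups, (iv) the
#' ANOVA/Tukey-Kramer/Boruta marker cascade and a random forest for the
#' first-layer group problem and for each multi-type group's second-layer
#' problem. Singleton groups are predicted directly by the first layer.
#'
#' @param beta Beta matrix (probes x samples).
#' @param manifest Sample manifest (`sample_id`, `cancer_type`, `subtype`,
#'   `cohort`, optional `split`).
#' @param annotation Optional probe annotation for the sex-chromosome filter.
#' @param cohort_probe_sets Optional list of per-cohort probe-id sets; probes
#'   outside their intersection are dropped.
#' @param split_ratio Training fraction for the stratified split
#'   (default 0.8).
#' @param top_fraction Fraction of most-variable probes used for clustering
#'   (default 0.01).
#' @param k_range Candidate group counts for the silhouette scan.
#' @param overrides Optional named character vector (subtype -> group label)
#'   applied after the silhouette cut.
#' @param assignment Optional precomputed `group_assignment`, skipping the
#'   taxonomy stage.
#' @param anova_alpha ANOVA screen level (default 0.05).
#' @param delta_schedule Delta-beta relaxation schedule
#'   (default 0.2, 0.15, 0.1).
#' @param p_threshold Tukey-adjusted p cut-off (default 0.01).
#' @param min_markers Minimum markers per class before relaxing delta.
#' @param boruta Run the Boruta confirmation stage (default TRUE).
#' @param boruta_max_iter,boruta_trees Boruta round limit and trees per
#'   round.
#' @param subtype_min_count,subtype_min_fraction,exclude_subtypes Subtype
#'   filter thresholds (see [filter_subtypes()]).
#' @param config A [forest_config()].
#' @param seed Master seed for split, cascade and forests.
#' @param preprocess Apply probe/subtype filters (default TRUE); set FALSE if
#'   the inputs are already filtered.
#' @return Object of class `methhier`.
#' @seealso [predict.methhier()], [train_flat_baseline()]
#' @export
methhier <- function(beta, manifest, annotation = NULL,
                     cohort_probe_sets = NULL, split_ratio = 0.8,
                     top_fraction = 0.01, k_range = NULL, overrides = NULL,
                     assignment = NULL, anova_alpha = 0.05,
                     delta_schedule = c(0.2, 0.15, 0.1), p_threshold = 0.01,
                     min_markers = 20L, boruta = TRUE,
                     boruta_max_iter = 100L, boruta_trees = 100L,
                     subtype_min_count = 5L, subtype_min_fraction = 0.10,
                     exclude_subtypes = character(),
                     config = forest_config(), seed = config$seed,
                     preprocess = TRUE) {
  cl <- match.call()
  validate_beta_matrix(beta)
  if (preprocess) {
    beta <- filter_probes(beta, annotation, cohort_probe_sets)
    manifest <- filter_subtypes(manifest, min_count = subtype_min_count,
                                min_fraction = subtype_min_fraction,
                                exclude = exclude_subtypes)
  }
  manifest <- manifest[manifest$sample_id %in% colnames(beta), , drop = FALSE]
  beta <- beta[, manifest$sample_id, drop = FALSE]
  if (!"split" %in% names(manifest) || all(manifest$split == "unassigned"))
    manifest <- stratified_split(manifest, ratio = split_ratio,
                                 seed = child_seed(seed, 1L))

  # taxonomy over the full cohort's subtype mean profiles
  profiles <- subtype_means(beta, manifest)
  clust_probes <- top_variance_probes(beta, top_fraction)
  d <- pearson_distance(profiles, clust_probes)
  tree <- upgma_tree(d)
  if (is.null(assignment))
    assignment <- choose_groups(tree, d, profiles$type_of_subtype,
                                k_range = k_range, overrides = overrides)
  classes <- sample_classes(assignment, manifest)
  routing <- split(names(assignment$group_of_class),
                   unname(assignment$group_of_class))

  train_idx <- manifest$split == "train"
  beta_tr <- beta[, train_idx, drop = FALSE]
  grp_tr <- classes$group[train_idx]
  cls_tr <- classes$class[train_idx]

  layer_cfg <- function(off) {
    cfg <- config; cfg$seed <- child_seed(seed, off); cfg
  }
  cascade1 <- marker_cascade(beta_tr, grp_tr, anova_alpha, delta_schedule,
                             p_threshold, min_markers, boruta,
                             boruta_max_iter, boruta_trees,
                             seed = child_seed(seed, 2L))
  layer1 <- train_layer(beta_tr, grp_tr, cascade1$panel, layer_cfg(100L))

  multi <- names(routing)[lengths(routing) > 1L]
  layer2 <- list(); cascades2 <- list()
  for (i in seq_along(multi)) {
    g <- multi[i]
    in_g <- grp_tr == g
    cas <- marker_cascade(beta_tr[, in_g, drop = FALSE], cls_tr[in_g],
                          anova_alpha, delta_schedule, p_threshold,
                          min_markers, boruta, boruta_max_iter, boruta_trees,
                          seed = child_seed(seed, 10L + i))
    layer2[[g]] <- train_layer(beta_tr[, in_g, drop = FALSE], cls_tr[in_g],
                               cas$panel, layer_cfg(100L + i))
    cascades2[[g]] <- cas
  }

  structure(list(tree = tree, distances = d, clustering_probes = clust_probes,
                 assignment = assignment, routing = routing,
                 layer1 = layer1, layer2 = layer2,
                 cascades = c(list(layer1 = cascade1), cascades2),
                 manifest = manifest, classes = classes, config = config,
                 params = list(split_ratio = split_ratio,
                               top_fraction = top_fraction,
                               anova_alpha = anova_alpha,
                               delta_schedule = delta_schedule,
                               p_threshold = p_threshold,
                               min_markers = min_markers, boruta = boruta,
                               seed = seed),
                 call = cl),
            class = "methhier")
}

#' @export
print.methhier <- function(x, ...) {
  cat("Hierarchical methylation classifier\n")
  cat("  ", length(unique(x$classes$class)), "classes in",
      length(x$routing), "groups (",
      sum(lengths(x$routing) == 1L), "singleton )\n")
  cat("  first layer:", length(x$layer1$panel), "marker CpGs;",
      "second layer:", length(x$layer2), "group model(s)\n")
  cat("  training samples:", sum(x$manifest$split == "train"),
      "; test samples:", sum(x$manifest$split == "test"), "\n")
  invisible(x)
}

#' @export
summary.methhier <- function(object, ...) {
  cat("Groups and routing:\n")
  for (g in names(object$routing))
    cat(sprintf("  %s: %s\n", g, paste(object$routing[[g]], collapse = ", ")))
  cat("\nPanel sizes (post-Boruta):\n")
  sizes <- c(layer1 = length(object$layer1$panel),
             vapply(object$layer2, function(m) length(m$panel), integer(1)))
  print(sizes)
  cat("\nSilhouette profile over k:\n")
  print(round(object$assignment$k_silhouette, 3))
  invisible(object)
}

#' Plot the class taxonomy dendrogram
#' @param x A `methhier` model.
#' @param ... Passed to [plot.hclust()].
#' @export
plot.methhier <- function(x, ...) {
  plot(x$tree$hclust, hang = -1,
       main = "UPGMA taxonomy of subtype methylomes",
       xlab = "clinical subtype", sub = "", ylab = "Pearson distance", ...)
  invisible(x)
}

#' Flat-classification baseline
#'
#' Trains a single forest over all type-level classes, using the same marker
#' cascade run once with every class against all others — the head-to-head
#' comparator for the hierarchical model.
#'
#' @param beta Beta matrix (probes x samples).
#' @param manifest Manifest with a filled `split` column (only training
#'   samples are used).
#' @param labels Optional class label per manifest row; defaults to
#'   `cancer_type`.
#' @param config A [forest_config()].
#' @param seed Master seed.
#' @inheritParams methhier
#' @return A `layer_model` with the cascade stored in `$cascade`.
#' @export
train_flat_baseline <- function(beta, manifest, labels = NULL,
                                anova_alpha = 0.05,
                                delta_schedule = c(0.2, 0.15, 0.1),
                                p_threshold = 0.01, min_markers = 20L,
                                boruta = TRUE, boruta_max_iter = 100L,
                                boruta_trees = 100L,
                                config = forest_config(),
                                seed = config$seed) {
  labels <- labels %||% manifest$cancer_type
  tr <- manifest$split == "train"
  beta_tr <- beta[, manifest$sample_id[tr], drop = FALSE]
  cas <- marker_cascade(beta_tr, labels[tr], anova_alpha, delta_schedule,
                        p_threshold, min_markers, boruta, boruta_max_iter,
                        boruta_trees, seed = child_seed(seed, 3L))
  cfg <- config; cfg$seed <- child_seed(seed, 200L)
  model <- train_layer(beta_tr, labels[tr], cas$panel, cfg)
  model$cascade <- cas
  model
}

#' Serialize a fitted model to a directory bundle
#'
#' Writes a version-stamped metadata file (JSON: routing, panels, parameters)
#' alongside per-layer fitted-model files, the taxonomy in Newick, and the
#' group assignment as TSV.
#'
#' @param object A `methhier` model.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_model <- function(object, dir) {
  stopifnot(inherits(object, "methhier"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format = "methhier-model", version = 1L,
               params = object$params, routing = object$routing,
               groups = names(object$routing),
               panel_sizes = c(list(layer1 = length(object$layer1$panel)),
                               lapply(object$layer2, function(m) length(m$panel))))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  saveRDS(object$layer1, file.path(dir, "layer1.rds"))
  for (g in names(object$layer2))
    saveRDS(object$layer2[[g]], file.path(dir, sprintf("layer2_%s.rds", g)))
  write_taxonomy(object$tree, file.path(dir, "taxonomy.nwk"))
  saveRDS(object[setdiff(names(object), c("layer1", "layer2"))],
          file.path(dir, "model_state.rds"))
  asn <- object$assignment
  data.table::fwrite(
    data.frame(subtype = names(asn$group_of_subtype),
               class = unname(asn$class_of_subtype[names(asn$group_of_subtype)]),
               group = unname(asn$group_of_subtype)),
    file.path(dir, "group_assignment.tsv"), sep = "\t", quote = FALSE)
  invisible(dir)
}

#' Load a serialized model bundle
#' @param dir Directory written by [write_model()].
#' @return A `methhier` model.
#' @export
read_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  if (!identical(meta$format, "methhier-model"))
    stop("not a methhier model bundle: ", dir)
  state <- readRDS(file.path(dir, "model_state.rds"))
  state$layer1 <- readRDS(file.path(dir, "layer1.rds"))
  l2 <- list()
  for (g in setdiff(unlist(meta$groups), character())) {
    f <- file.path(dir, sprintf("layer2_%s.rds", g))
    if (file.exists(f)) l2[[g]] <- readRDS(f)
  }
  state$layer2 <- l2
  structure(state, class = "methhier")
}
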