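# Synthetic methylation cohorts with a planted class hierarchy.
#
# The generator emulates the data regime of a pan-cancer 450K compendium:
# cancer groups related by a lineage tree, cancer types nested in groups,
# clinical subtypes nested in types, per-class marker CpGs with a fixed
# effect size (delta-beta), beta-distributed measurement noise, per-cohort
# batch shifts, missing cells and sex-chromosome probes. Group signatures
# evolve along a random ultrametric binary tree by cumulative Brownian mean
# drift on a designated fraction of lineage-variable CpGs (real methylomes
# behave the same way: most CpGs are stable across lineages, a minority are
# strongly tissue-variable and dominate the top-variance set). Between-group
# Pearson distance therefore grows with tree distance, and the tree is
# ultrametric, so recovery by UPGMA is a meaningful, well-posed check.

#' Specification for a synthetic methylation cohort
#'
#' Defaults describe a desk-scale analogue of a pan-cancer compendium:
#' 12 groups whose type counts mirror a real taxonomy (three singleton
#' groups), 30 cancer types, 2 clinical subtypes per type, 20 samples per
#' subtype, 5000 background CpGs plus planted markers.
#'
#' @param n_groups Number of top-level groups.
#' @param types_per_group Integer vector (length `n_groups`) of cancer types
#'   per group; singletons allowed.
#' @param subtypes_per_type Subtypes per type (scalar or per-type vector).
#' @param samples_per_subtype Samples drawn per subtype.
#' @param n_background_probes Background (non-marker) CpGs.
#' @param n_markers_per_group Planted one-vs-all marker CpGs per group.
#' @param n_markers_per_type Planted within-group marker CpGs per type in
#'   multi-type groups.
#' @param marker_delta Planted marker effect size: the focal class mean is
#'   shifted by this beta fraction relative to all other classes.
#' @param noise_precision Concentration kappa of the beta noise; per-sample
#'   values are Beta(m*kappa, (1-m)*kappa) around the planted mean m.
#' @param batch_shift Mean beta offset added to the second and later cohorts
#'   (cohort j is shifted by `(j-1) * batch_shift`, clipped at the mean).
#' @param n_cohorts Number of cohorts/batches samples are assigned to.
#' @param missing_rate Per-cell probability of a missing value.
#' @param n_sex_probes CpGs annotated to chrX/chrY (excluded by
#'   preprocessing).
#' @param group_drift_sd Cumulative (root-to-leaf) Brownian drift standard
#'   deviation on lineage-variable background CpGs; the planted tree is
#'   scaled to unit depth, so a leaf's lineage deviation has this sd.
#' @param lineage_fraction Fraction of background CpGs that are
#'   lineage-variable (carry the group drift); the rest are lineage-stable.
#'   The default (1.28%, i.e. 64 CpGs at the default probe count) makes the
#'   lineage panel fill the top-1% variance window used for clustering.
#' @param type_drift_sd,subtype_sd Independent per-probe deviation scales at
#'   the type and subtype level (applied to all background CpGs).
#' @param planted_tree Optional Newick string fixing the group-level topology
#'   (tip labels must be the group labels `G01`, `G02`, ...); otherwise a
#'   random binary tree is drawn.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the spec.
#' @return Object of class `cohort_spec`.
#' @seealso [simulate_cohort()]
#' @export
cohort_spec <- function(n_groups = 12L,
                        types_per_group = c(1L, 2L, 1L, 2L, 4L, 4L, 2L, 2L,
                                            1L, 3L, 4L, 4L),
                        subtypes_per_type = 2L,
                        samples_per_subtype = 20L,
                        n_background_probes = 5000L,
                        n_markers_per_group = 40L,
                        n_markers_per_type = 30L,
                        marker_delta = 0.3,
                        noise_precision = 50,
                        batch_shift = 0,
                        n_cohorts = 2L,
                        missing_rate = 0,
                        n_sex_probes = 100L,
                        group_drift_sd = 0.2,
                        lineage_fraction = 0.0128,
                        type_drift_sd = 0.02,
                        subtype_sd = 0.01,
                        planted_tree = NULL,
                        seed = 1L) {
  spec <- list(n_groups = as.integer(n_groups),
               types_per_group = as.integer(types_per_group),
               subtypes_per_type = subtypes_per_type,
               samples_per_subtype = as.integer(samples_per_subtype),
               n_background_probes = as.integer(n_background_probes),
               n_markers_per_group = as.integer(n_markers_per_group),
               n_markers_per_type = as.integer(n_markers_per_type),
               marker_delta = marker_delta,
               noise_precision = noise_precision,
               batch_shift = batch_shift,
               n_cohorts = as.integer(n_cohorts),
               missing_rate = missing_rate,
               n_sex_probes = as.integer(n_sex_probes),
               group_drift_sd = group_drift_sd,
               lineage_fraction = lineage_fraction,
               type_drift_sd = type_drift_sd,
               subtype_sd = subtype_sd,
               planted_tree = planted_tree,
               seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    stopifnot(n_groups >= 1L, length(types_per_group) == n_groups,
              all(types_per_group >= 1L), samples_per_subtype >= 1L,
              n_background_probes >= 0L, n_markers_per_group >= 0L,
              n_markers_per_type >= 0L,
              marker_delta >= 0, marker_delta < 1,
              noise_precision > 0, batch_shift >= 0, batch_shift < 1,
              missing_rate >= 0, missing_rate <= 1, n_sex_probes >= 0L,
              n_cohorts >= 1L, lineage_fraction >= 0, lineage_fraction <= 1)
    # marker baselines are drawn from [0.1, 0.9 - delta]; an empty range
    # means the shifted mean cannot stay inside (0, 1)
    if (marker_delta > 0 && 0.9 - marker_delta < 0.1)
      stop("infeasible spec: marker mean +/- marker_delta leaves (0, 1)")
  })
  invisible(spec)
}

# Bimodal baseline means typical of CpG methylation: most sites are either
# mostly unmethylated or mostly methylated.
draw_baseline <- function(n) {
  hi <- stats::runif(n) < 0.5
  m <- ifelse(hi, stats::rbeta(n, 8, 2), stats::rbeta(n, 2, 8))
  pmin(pmax(m, 0.02), 0.98)
}

# Random ultrametric binary tree: clusters merge in a uniformly random
# order, merge t of n-1 at height 0.2 + 0.8 (t/(n-1))^1.5 (unit depth:
# every leaf is at distance 1 from the root). The height floor keeps even
# the most recently diverged groups well separated from the within-group
# scale, and the convex profile keeps consecutive merge heights apart by a
# roughly constant relative gap, as lineage trees estimated from real
# methylomes tend to show.
random_ultrametric_tree <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 2L)
  nwk <- labels
  height <- rep(0, n)
  for (t in seq_len(n - 1L)) {
    h <- if (t == n - 1L) 1 else 0.2 + 0.8 * (t / (n - 1L))^1.5
    pair <- sample(length(nwk), 2L)
    merged <- sprintf("(%s:%g,%s:%g)", nwk[pair[1L]], h - height[pair[1L]],
                      nwk[pair[2L]], h - height[pair[2L]])
    nwk <- c(nwk[-pair], merged)
    height <- c(height[-pair], h)
  }
  ape::read.tree(text = paste0(nwk, ";"))
}

# Cumulative lineage drift along a phylo tree, as a variance-exact
# discretization of Brownian motion: each edge adds a fixed-magnitude
# (sd * sqrt(length)) sign pattern across the probes, and the sign patterns
# of distinct edges are mutually orthogonal columns of a Sylvester/Hadamard
# matrix (randomly chosen and randomly flipped). Squared profile distance
# between two tips then equals sd^2 times their path length in the tree,
# exactly when the probe count is a power of two and to within a small
# truncation error otherwise — so recovery of the planted topology measures
# the taxonomy code, not the generator's sampling luck. Returns tips x
# n_probes.
brownian_tips <- function(tree, n_probes, sd) {
  n_tip <- length(tree$tip.label)
  tree <- stats::reorder(tree, "cladewise")   # parents before children
  n_edge <- nrow(tree$edge)
  m <- 2L
  while (m < max(n_edge + 1L, n_probes)) m <- m * 2L
  H <- matrix(1, 1L, 1L)
  while (nrow(H) < m) H <- rbind(cbind(H, H), cbind(H, -H))
  cols <- sample(2:m, n_edge)                 # skip the constant column
  flip <- sample(c(-1, 1), n_edge, replace = TRUE)
  vals <- matrix(0, n_tip + tree$Nnode, n_probes)
  for (i in seq_len(n_edge)) {
    par <- tree$edge[i, 1L]; chd <- tree$edge[i, 2L]
    len <- if (is.null(tree$edge.length)) 1 else tree$edge.length[i]
    vals[chd, ] <- vals[par, ] +
      sd * sqrt(len) * flip[i] * H[seq_len(n_probes), cols[i]]
  }
  out <- vals[seq_len(n_tip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

#' Generate a synthetic methylation cohort
#'
#' Draws a complete cohort from a [cohort_spec()]: a beta matrix
#' (probes x samples), a sample manifest, a probe annotation, and the ground
#' truth (planted group tree, type-to-group map, planted marker sets, and the
#' planted per-subtype mean profiles). Fully reproducible from the spec seed.
#'
#' Marker CpGs carry no lineage drift: a group marker's mean equals a common
#' baseline in every group except its focal group, which is shifted by
#' `marker_delta`; type markers behave the same for one type against all
#' others (type markers are planted only in multi-type groups, where
#' within-group discrimination is needed). Background CpGs carry the
#' Brownian group drift plus smaller independent type- and subtype-level
#' deviations.
#'
#' @param spec A [cohort_spec()] (or arguments passed on to it).
#' @param ... Used to build a spec when `spec` is missing.
#' @return List with elements `beta` (matrix), `manifest` (data.frame),
#'   `annotation` (data.frame) and `truth` (list: `planted_tree` Newick
#'   string, `group_of_type`, `marker_probes`, `subtype_means`,
#'   `group_labels`).
#' @examples
#' co <- simulate_cohort(cohort_spec(n_groups = 3, types_per_group = c(1, 2, 2),
#'                                   n_background_probes = 200,
#'                                   samples_per_subtype = 5, seed = 7))
#' dim(co$beta)
#' @export
simulate_cohort <- function(spec, ...) {
  if (missing(spec)) spec <- cohort_spec(...)
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  local_rng(spec$seed)

  groups <- sprintf("G%02d", seq_len(spec$n_groups))
  n_types <- sum(spec$types_per_group)
  types <- sprintf("T%02d", seq_len(n_types))
  group_of_type <- rep(groups, spec$types_per_group)
  names(group_of_type) <- types
  subs_per_type <- rep_len(as.integer(spec$subtypes_per_type), n_types)
  subtype_type <- rep(types, subs_per_type)
  subtypes <- paste0(subtype_type,
                     unlist(lapply(subs_per_type, function(k) letters[seq_len(k)])))
  n_sub <- length(subtypes)

  # planted group topology
  if (!is.null(spec$planted_tree)) {
    tree <- ape::read.tree(text = spec$planted_tree)
    if (!setequal(tree$tip.label, groups))
      stop("planted_tree tip labels must be ", paste(groups, collapse = ", "))
    if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
  } else if (spec$n_groups >= 2L) {
    tree <- random_ultrametric_tree(groups)
  } else {
    tree <- NULL
  }

  # probe ids by role
  p_bg <- spec$n_background_probes
  bg_ids <- sprintf("cg0%06d", seq_len(p_bg))
  gm_class <- rep(groups, each = spec$n_markers_per_group)
  gm_ids <- sprintf("cg2%06d", seq_along(gm_class))
  multi_types <- types[group_of_type[types] %in%
                         groups[spec$types_per_group > 1L]]
  tm_class <- rep(multi_types, each = spec$n_markers_per_type)
  tm_ids <- sprintf("cg3%06d", seq_along(tm_class))
  sex_ids <- sprintf("cg4%06d", seq_len(spec$n_sex_probes))
  probe_ids <- c(bg_ids, gm_ids, tm_ids, sex_ids)

  # planted per-subtype means, probes x subtypes
  means <- matrix(0, length(probe_ids), n_sub,
                  dimnames = list(probe_ids, subtypes))
  sub_group <- group_of_type[subtype_type]

  n_lin <- round(spec$lineage_fraction * p_bg)
  lineage_probes <- if (n_lin > 0) bg_ids[seq_len(n_lin)] else character()
  if (p_bg > 0) {
    # lineage-variable CpGs: intermediate baselines, Brownian group drift;
    # lineage-stable CpGs: bimodal baselines, no group-level signal
    base_bg <- c(stats::runif(n_lin, 0.4, 0.6),
                 draw_baseline(p_bg - n_lin))
    g_drift <- matrix(0, length(groups), p_bg, dimnames = list(groups, NULL))
    if (!is.null(tree) && spec$n_groups > 1L && n_lin > 0)
      g_drift[, seq_len(n_lin)] <-
        brownian_tips(tree, n_lin, spec$group_drift_sd)[groups, , drop = FALSE]
    t_dev <- matrix(stats::rnorm(n_types * p_bg, 0, spec$type_drift_sd),
                    n_types, p_bg, dimnames = list(types, NULL))
    s_dev <- matrix(stats::rnorm(n_sub * p_bg, 0, spec$subtype_sd),
                    n_sub, p_bg)
    for (j in seq_len(n_sub)) {
      m <- base_bg + g_drift[sub_group[j], ] + t_dev[subtype_type[j], ] + s_dev[j, ]
      means[seq_len(p_bg), j] <- pmin(pmax(m, 0.02), 0.98)
    }
  }

  plant_markers <- function(ids, class_of_probe, class_of_subtype) {
    if (!length(ids)) return(invisible())
    sgn <- sample(c(-1, 1), length(ids), replace = TRUE)
    lo <- ifelse(sgn > 0, 0.1, 0.1 + spec$marker_delta)
    hi <- ifelse(sgn > 0, 0.9 - spec$marker_delta, 0.9)
    base <- stats::runif(length(ids), lo, hi)
    for (i in seq_along(ids)) {
      row <- rep(base[i], n_sub)
      row[class_of_subtype == class_of_probe[i]] <-
        base[i] + sgn[i] * spec$marker_delta
      means[ids[i], ] <<- row
    }
  }
  plant_markers(gm_ids, gm_class, sub_group)
  plant_markers(tm_ids, tm_class, subtype_type)
  if (spec$n_sex_probes > 0)
    means[sex_ids, ] <- matrix(draw_baseline(spec$n_sex_probes),
                               spec$n_sex_probes, n_sub)

  # samples, cohorts and batch shifts
  n_samp <- n_sub * spec$samples_per_subtype
  samp_subtype <- rep(subtypes, each = spec$samples_per_subtype)
  sample_ids <- sprintf("S%05d", seq_len(n_samp))
  cohorts <- paste0("cohort", sample(rep_len(seq_len(spec$n_cohorts), n_samp)))
  offset <- (match(cohorts, paste0("cohort", seq_len(spec$n_cohorts))) - 1L) *
    spec$batch_shift

  mu <- means[, samp_subtype, drop = FALSE]
  mu <- sweep(mu, 2L, offset, `+`)
  mu <- pmin(pmax(mu, 0.02), 0.98)     # clip shifted means, never draws
  kappa <- spec$noise_precision
  beta <- matrix(stats::rbeta(length(mu), mu * kappa, (1 - mu) * kappa),
                 nrow(mu), ncol(mu), dimnames = list(probe_ids, sample_ids))
  if (spec$missing_rate > 0) {
    beta[stats::runif(length(beta)) < spec$missing_rate] <- NA_real_
  }
  # guard against boundary draws: beta values live in [0, 1)
  beta[!is.na(beta) & beta >= 1] <- 1 - 1e-9

  manifest <- data.frame(sample_id = sample_ids,
                         cancer_type = subtype_type[match(samp_subtype, subtypes)],
                         subtype = samp_subtype,
                         cohort = cohorts,
                         split = "unassigned",
                         stringsAsFactors = FALSE)
  annotation <- data.frame(
    probe_id = probe_ids,
    chromosome = c(paste0("chr", sample(1:22, p_bg + length(gm_ids) +
                                          length(tm_ids), replace = TRUE)),
                   sample(c("chrX", "chrY"), spec$n_sex_probes, replace = TRUE)),
    stringsAsFactors = FALSE)

  marker_probes <- c(split(gm_ids, gm_class)[unique(gm_class)],
                     split(tm_ids, tm_class)[unique(tm_class)])
  truth <- list(
    planted_tree = if (!is.null(tree)) ape::write.tree(tree) else NULL,
    group_of_type = group_of_type,
    marker_probes = marker_probes,
    lineage_probes = lineage_probes,
    subtype_means = means,
    group_labels = groups)
  list(beta = beta, manifest = manifest, annotation = annotation,
       truth = truth, spec = spec)
}

#' Realized delta-beta of planted marker CpGs
#'
#' For every planted group marker, computes the minimum over all other groups
#' of the absolute difference between the focal group's realized mean beta
#' and the other group's; analogously for type markers within their group.
#' Used to validate that the generator actually produces the marker effect
#' size it was asked for.
#'
#' @param cohort Output of [simulate_cohort()].
#' @return data.frame with columns `class`, `level` ("group"/"type"),
#'   `probe_id`, `min_delta`.
#' @export
planted_delta_check <- function(cohort) {
  beta <- cohort$beta; truth <- cohort$truth; man <- cohort$manifest
  g_of_t <- truth$group_of_type
  samp_group <- unname(g_of_t[man$cancer_type])
  out <- list()
  for (cls in names(truth$marker_probes)) {
    probes <- truth$marker_probes[[cls]]
    is_group <- cls %in% truth$group_labels
    if (is_group) {
      labels <- samp_group
    } else {
      keep <- samp_group == g_of_t[[cls]]
      labels <- man$cancer_type[keep]
    }
    sub <- beta[probes, if (is_group) TRUE else keep, drop = FALSE]
    gm <- vapply(split(seq_along(labels), labels),
                 function(ix) rowMeans(sub[, ix, drop = FALSE], na.rm = TRUE),
                 numeric(length(probes)))
    if (is.null(dim(gm))) gm <- matrix(gm, nrow = 1,
                                       dimnames = list(probes, names(gm)))
    focal <- gm[, cls]
    others <- gm[, setdiff(colnames(gm), cls), drop = FALSE]
    min_d <- apply(abs(others - focal), 1L, min)
    out[[cls]] <- data.frame(class = cls,
                             level = if (is_group) "group" else "type",
                             probe_id = probes, min_delta = unname(min_d),
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write a synthetic cohort to disk
#'
#' Emits the same TSV formats the readers consume, plus the ground truth as a
#' Newick tree and a marker-map TSV.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_beta_matrix(cohort$beta, file.path(dir, "beta_matrix.tsv"))
  write_manifest(cohort$manifest, file.path(dir, "manifest.tsv"))
  data.table::fwrite(cohort$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE)
  if (!is.null(cohort$truth$planted_tree))
    writeLines(cohort$truth$planted_tree, file.path(dir, "planted_tree.nwk"))
  mk <- cohort$truth$marker_probes
  data.table::fwrite(
    data.frame(class = rep(names(mk), lengths(mk)),
               probe_id = unlist(mk, use.names = FALSE)),
    file.path(dir, "marker_probes.tsv"), sep = "\t", quote = FALSE)
  invisible(dir)
}
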