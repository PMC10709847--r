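# Per-node random forests. Each classification problem in the hierarchy
# (groups at the first layer, types within a multi-type group at the second)
# gets its own probability forest over that problem's marker panel.

#' Random forest configuration
#'
#' @param n_trees Number of trees (default 200).
#' @param class_weight `"balanced"` (weights inversely proportional to class
#'   frequency, the default, to counter unequal class sizes) or `"none"`.
#' @param mtry,min_node_size Passed to [ranger::ranger()]; NULL keeps the
#'   estimator defaults.
#' @param max_missing_features Prediction-time guard: error when more than
#'   this fraction of a panel is absent from the input (default 0.5);
#'   features below the threshold are mean-imputed from the training set.
#' @param seed Integer seed (forests are deterministic given it).
#' @return Object of class `forest_config`.
#' @export
forest_config <- function(n_trees = 200L, class_weight = c("balanced", "none"),
                          mtry = NULL, min_node_size = NULL,
                          max_missing_features = 0.5, seed = 1L) {
  class_weight <- match.arg(class_weight)
  stopifnot(n_trees >= 1L)
  structure(list(n_trees = as.integer(n_trees), class_weight = class_weight,
                 mtry = mtry, min_node_size = min_node_size,
                 max_missing_features = max_missing_features,
                 seed = as.integer(seed)),
            class = "forest_config")
}

#' Train one classification layer
#'
#' Fits a probability forest on the given marker panel. Training-set feature
#' means are stored for prediction-time imputation of missing probes (e.g.
#' validation cohorts from other platforms).
#'
#' @param beta Beta matrix (probes x samples), training samples.
#' @param labels Class label per training sample.
#' @param panel Character vector of marker probe ids (subset of the matrix
#'   probes).
#' @param config A [forest_config()].
#' @return Object of class `layer_model`: `fit`, `classes`, `panel`,
#'   `feature_means`, `config`.
#' @export
train_layer <- function(beta, labels, panel, config = forest_config()) {
  stopifnot(inherits(config, "forest_config"))
  missing_p <- setdiff(panel, rownames(beta))
  if (length(missing_p))
    stop("panel probe(s) absent from matrix: ",
         paste(utils::head(missing_p, 3L), collapse = ", "))
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("need at least two classes")
  if (any(table(y) == 0L)) stop("class with zero training samples")
  x <- t(beta[panel, , drop = FALSE])
  cw <- if (config$class_weight == "balanced") {
    tab <- table(y)
    as.numeric(length(y) / (nlevels(y) * tab))
  } else NULL
  fit <- ranger::ranger(x = x, y = y, num.trees = config$n_trees,
                        probability = TRUE, class.weights = cw,
                        mtry = config$mtry,
                        min.node.size = config$min_node_size,
                        seed = config$seed, num.threads = 1L)
  structure(list(fit = fit, classes = levels(y), panel = panel,
                 feature_means = colMeans(x), config = config),
            class = "layer_model")
}

#' Class probabilities from a layer model
#'
#' Aligns the input matrix to the model's panel, mean-imputing panel probes
#' that are absent (with a warning reporting how many), and returns the
#' forest's class probabilities. Errors when more than
#' `config$max_missing_features` of the panel is absent for the batch.
#'
#' @param model A `layer_model`.
#' @param beta Beta matrix (probes x samples) to predict.
#' @return Matrix samples x classes of probabilities (rows sum to 1),
#'   columns ordered as `model$classes`.
#' @export
predict_layer <- function(model, beta) {
  stopifnot(inherits(model, "layer_model"))
  panel <- model$panel
  absent <- setdiff(panel, rownames(beta))
  frac <- length(absent) / length(panel)
  if (frac > model$config$max_missing_features)
    stop(sprintf("%.0f%% of panel features missing from input (limit %.0f%%)",
                 100 * frac, 100 * model$config$max_missing_features))
  x <- matrix(rep(model$feature_means, each = ncol(beta)),
              ncol(beta), length(panel),
              dimnames = list(colnames(beta), panel))
  present <- intersect(panel, rownames(beta))
  x[, present] <- t(beta[present, , drop = FALSE])
  # per-cell missingness is imputed the same way
  nacells <- which(is.na(x), arr.ind = TRUE)
  if (nrow(nacells)) x[nacells] <- model$feature_means[nacells[, 2L]]
  if (length(absent) || nrow(nacells))
    warning(sprintf("imputed %d absent panel probe(s) and %d missing cell(s) with training means",
                    length(absent), nrow(nacells)))
  pr <- stats::predict(model$fit, data = x, num.threads = 1L)$predictions
  rownames(pr) <- colnames(beta)
  pr[, model$classes, drop = FALSE]
}

#' @export
print.layer_model <- function(x, ...) {
  cat("Layer model:", length(x$classes), "classes,", length(x$panel),
      "features,", x$config$n_trees, "trees\n")
  invisible(x)
}
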