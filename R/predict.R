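# Hierarchical top-k^2 prediction and evaluation. A sample is routed through
# the top-k first-layer groups; each selected singleton group contributes its
# type directly, each multi-type group contributes the top-min(k, group size)
# types of its second-layer forest. With k = 2 the candidate set therefore
# holds 2-4 labels.

# Rank labels by descending probability, ties broken by label (stable).
rank_labels <- function(p) names(p)[order(-p, names(p))]

#' Predict cancer type candidates for new samples
#'
#' Runs the two-layer routing: the `k` highest-probability groups from the
#' first layer are selected; singleton groups add their single type, and
#' multi-type groups are forwarded to their second-layer forest which adds
#' its top-`min(k, group size)` types. The candidate set is the union
#' (duplicates collapse); `top1` follows the highest-probability group's
#' highest-probability type.
#'
#' @param object A fitted `methhier` model.
#' @param newdata Beta matrix (probes x samples) to classify.
#' @param k Branching factor per layer (default 2, the top-2^2 rule).
#' @param ... Unused.
#' @return Object of class `methhier_prediction`: data.frame `results`
#'   (`sample_id`, `top1`, `candidates` comma-joined, `n_candidates`),
#'   `candidate_sets` (named list), `layer1_probs` (samples x groups),
#'   `layer2_probs` (per multi-type group).
#' @export
predict.methhier <- function(object, newdata, k = 2L, ...) {
  stopifnot(k >= 1L)
  l1 <- predict_layer(object$layer1, newdata)
  l2 <- lapply(object$layer2, predict_layer, beta = newdata)
  n <- nrow(l1)
  cand <- vector("list", n)
  top1 <- character(n)
  for (i in seq_len(n)) {
    groups <- rank_labels(l1[i, ])[seq_len(min(k, ncol(l1)))]
    labs <- character()
    for (g in groups) {
      types <- object$routing[[g]]
      if (length(types) == 1L) {
        labs <- c(labs, types)
      } else {
        ranked <- rank_labels(l2[[g]][i, ])
        labs <- c(labs, ranked[seq_len(min(k, length(ranked)))])
      }
    }
    cand[[i]] <- unique(labs)
    g1 <- groups[1L]
    top1[i] <- if (length(object$routing[[g1]]) == 1L) object$routing[[g1]]
    else rank_labels(l2[[g1]][i, ])[1L]
  }
  names(cand) <- rownames(l1)
  res <- data.frame(sample_id = rownames(l1), top1 = top1,
                    candidates = vapply(cand, paste, "", collapse = ","),
                    n_candidates = lengths(cand),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(results = res, candidate_sets = cand, layer1_probs = l1,
                 layer2_probs = l2, k = k),
            class = "methhier_prediction")
}

#' @export
print.methhier_prediction <- function(x, ...) {
  cat("Hierarchical predictions for", nrow(x$results), "sample(s), k =",
      x$k, "\n")
  print(utils::head(x$results, 10L), row.names = FALSE)
  if (nrow(x$results) > 10L) cat("  ...\n")
  invisible(x)
}

#' Top-k^2 candidate-set accuracy
#'
#' Fraction of samples whose true label is contained in the hierarchical
#' candidate set.
#'
#' @param prediction A `methhier_prediction` (or a list of candidate label
#'   vectors).
#' @param truth True class label per sample, aligned with the predictions.
#' @return Accuracy in [0, 1].
#' @export
topk2_accuracy <- function(prediction, truth) {
  sets <- if (inherits(prediction, "methhier_prediction"))
    prediction$candidate_sets else prediction
  if (length(sets) != length(truth))
    stop("predictions and truth have different lengths")
  mean(mapply(`%in%`, truth, sets))
}

#' Top-1 routed accuracy
#' @inheritParams topk2_accuracy
#' @return Accuracy in [0, 1].
#' @export
top1_accuracy <- function(prediction, truth) {
  top1 <- if (inherits(prediction, "methhier_prediction"))
    prediction$results$top1 else prediction
  if (length(top1) != length(truth))
    stop("predictions and truth have different lengths")
  mean(top1 == truth)
}

#' Per-class precision/recall and confusion matrix
#'
#' Metrics are computed on the single routed (top-1) prediction: precision =
#' TP / predicted-positive, recall = TP / actual-positive per class, plus the
#' full confusion matrix (rows = truth) and overall accuracy.
#'
#' @param predicted Predicted label per sample (or a `methhier_prediction`,
#'   whose `top1` is used).
#' @param truth True label per sample.
#' @return Object of class `classification_report`: `confusion`, `per_class`
#'   (data.frame), `accuracy`, `n`.
#' @export
classification_report <- function(predicted, truth) {
  if (inherits(predicted, "methhier_prediction"))
    predicted <- predicted$results$top1
  if (length(predicted) != length(truth))
    stop("predictions and truth have different lengths")
  levs <- sort(unique(c(predicted, truth)))
  confusion <- table(truth = factor(truth, levs),
                     predicted = factor(predicted, levs))
  tp <- diag(confusion)
  precision <- tp / colSums(confusion)
  recall <- tp / rowSums(confusion)
  per_class <- data.frame(class = levs,
                          n_true = as.integer(rowSums(confusion)),
                          precision = as.numeric(precision),
                          recall = as.numeric(recall),
                          stringsAsFactors = FALSE, row.names = NULL)
  structure(list(confusion = confusion, per_class = per_class,
                 accuracy = mean(predicted == truth),
                 n = length(truth)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Accuracy %.4f on %d sample(s)\n", x$accuracy, x$n))
  print(x$per_class, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Stratified k-fold cross-validation of a layer
#'
#' Splits the samples into `k_folds` stratified folds (every sample in
#' exactly one validation fold), trains a forest on the remaining folds and
#' scores top-1 accuracy on the held-out fold. Classes smaller than
#' `k_folds` are spread over as many folds as they have samples, with a
#' warning.
#'
#' @param beta Beta matrix (probes x samples).
#' @param labels Class label per sample.
#' @param panel Marker probe ids to train on.
#' @param config A [forest_config()].
#' @param k_folds Number of folds (default 5).
#' @param seed Fold assignment seed.
#' @return List: `scores` (per fold), `mean`, `folds` (assignment).
#' @export
kfold_cv <- function(beta, labels, panel, config = forest_config(),
                     k_folds = 5L, seed = 1L) {
  stopifnot(k_folds >= 2L)
  labels <- as.character(labels)
  small <- names(which(table(labels) < k_folds))
  if (length(small))
    warning("class(es) smaller than k_folds spread unevenly: ",
            paste(small, collapse = ", "))
  local_rng(seed)
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(k_folds), length(idx))
  }
  scores <- vapply(seq_len(k_folds), function(f) {
    val <- fold == f
    cfg <- config; cfg$seed <- child_seed(seed, f)
    m <- train_layer(beta[, !val, drop = FALSE], labels[!val], panel, cfg)
    pr <- predict_layer(m, beta[, val, drop = FALSE])
    mean(colnames(pr)[max.col(pr, ties.method = "first")] == labels[val])
  }, numeric(1))
  list(scores = scores, mean = mean(scores), folds = fold)
}

#' One-vs-rest AUC from class probabilities
#'
#' Computes, per class, the ROC AUC of that class's predicted probability
#' against the binary truth (class vs rest), and the macro (default) or
#' micro average. Classes absent from the truth are excluded with a warning.
#'
#' @param probs Matrix samples x classes of probabilities (e.g. from
#'   [predict_layer()]).
#' @param truth True class label per sample.
#' @param average `"macro"` (mean of per-class AUCs) or `"micro"` (single
#'   AUC over the pooled sample-class indicators).
#' @return List: `per_class` (named numeric, NA where undefined),
#'   `average`.
#' @export
ovr_auc <- function(probs, truth, average = c("macro", "micro")) {
  average <- match.arg(average)
  stopifnot(nrow(probs) == length(truth))
  classes <- colnames(probs)
  auc1 <- function(pos, score) {
    if (!any(pos) || all(pos)) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(response = pos, predictor = score,
                                   levels = c(FALSE, TRUE), direction = "<",
                                   quiet = TRUE)))
  }
  per_class <- vapply(classes, function(cls)
    auc1(truth == cls, probs[, cls]), numeric(1))
  if (anyNA(per_class))
    warning("class(es) absent from truth excluded from AUC: ",
            paste(classes[is.na(per_class)], collapse = ", "))
  avg <- if (average == "macro") {
    mean(per_class, na.rm = TRUE)
  } else {
    pos <- as.vector(vapply(classes, function(cls) truth == cls,
                            logical(length(truth))))
    auc1(pos, as.vector(probs))
  }
  list(per_class = per_class, average = avg)
}

#' Evaluate a fitted model on its held-out test split
#'
#' Convenience wrapper: predicts the model's test samples and returns the
#' hierarchical top-k^2 accuracy, top-1 accuracy, the per-class report, and
#' the first-layer one-vs-rest AUC.
#'
#' @param object A fitted `methhier` model.
#' @param beta The beta matrix the model was fitted from (test columns are
#'   selected by the stored split).
#' @param k Branching factor (default 2).
#' @return List: `prediction`, `topk2_accuracy`, `top1_accuracy`, `report`,
#'   `layer1_auc`.
#' @export
evaluate_model <- function(object, beta, k = 2L) {
  test <- object$manifest$split == "test"
  ids <- object$manifest$sample_id[test]
  truth <- object$classes$class[match(ids, object$classes$sample_id)]
  pred <- predict(object, beta[, ids, drop = FALSE], k = k)
  grp_truth <- object$classes$group[match(ids, object$classes$sample_id)]
  list(prediction = pred,
       topk2_accuracy = topk2_accuracy(pred, truth),
       top1_accuracy = top1_accuracy(pred, truth),
       report = classification_report(pred, truth),
       layer1_auc = ovr_auc(pred$layer1_probs, grp_truth))
}
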