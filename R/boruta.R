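# Boruta shadow-feature confirmation. Each round appends a permuted
# ("shadow") copy of every feature, fits a random forest, and
# scores a hit for every real feature whose impurity importance exceeds the
# best shadow importance. Hit counts are tested against Binomial(rounds, 1/2)
# two-sided with a Bonferroni correction across the features still undecided
# that round AND across the rounds themselves (the same feature is re-tested
# every round; without the sequential correction a feature whose chance
# correlation with the labels sits in the upper tail of the null maximum
# wins often enough to be confirmed spuriously). Features significantly
# above chance are confirmed, below are rejected.

#' Confirm features by the Boruta shadow-feature procedure
#'
#' @param x Feature matrix, samples x features (e.g. `t(beta[panel, ])`).
#' @param y Class label per sample.
#' @param max_iter Maximum number of shadow rounds (default 100).
#' @param alpha Two-sided test level before the Bonferroni correction over
#'   undecided features and testing rounds (default 0.05).
#' @param n_trees Trees per forest round (default 100; importance estimation
#'   only, the final classifier is trained separately).
#' @param tentative How to treat features still undecided at `max_iter`:
#'   `"drop"` (default) or `"rough_fix"` (confirm a tentative feature whose
#'   median importance over its rounds exceeds the median of the max-shadow
#'   importances).
#' @param seed Integer seed; the whole run is reproducible.
#' @return Object of class `boruta_result`: `confirmed`, `rejected`,
#'   `tentative` (feature names), `hits`, `n_iter`, `decision` (named
#'   factor).
#' @export
boruta_confirm <- function(x, y, max_iter = 100L, alpha = 0.05,
                           n_trees = 100L, tentative = c("drop", "rough_fix"),
                           seed = 1L) {
  tentative <- match.arg(tentative)
  if (max_iter < 1L) stop("max_iter must be >= 1")
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- factor(y)
  if (nlevels(y) < 2L) stop("need at least two classes")
  p <- ncol(x)
  local_rng(seed)
  status <- rep("undecided", p)
  hits <- integer(p)
  imp_hist <- matrix(NA_real_, max_iter, p,
                     dimnames = list(NULL, colnames(x)))
  shadow_max_hist <- rep(NA_real_, max_iter)
  iter <- 0L
  while (iter < max_iter && any(status == "undecided")) {
    iter <- iter + 1L
    und <- which(status == "undecided")
    # shadows are fresh permutations of EVERY original feature, so the
    # max-shadow bar keeps the same null distribution in every round even
    # after most features are decided
    shadow <- apply(x, 2L, sample)
    colnames(shadow) <- paste0(".shadow.", seq_len(p))
    dat <- cbind(x[, und, drop = FALSE], shadow)
    fit <- ranger::ranger(x = dat, y = y, num.trees = n_trees,
                          importance = "impurity",
                          seed = child_seed(seed, iter), num.threads = 1L)
    imp <- fit$variable.importance
    smax <- max(imp[seq_len(p) + length(und)])
    real <- imp[seq_along(und)]
    hits[und] <- hits[und] + (real > smax)
    imp_hist[iter, und] <- real
    shadow_max_hist[iter] <- smax
    m <- length(und)
    p_up <- stats::pbinom(hits[und] - 1L, iter, 0.5, lower.tail = FALSE)
    p_dn <- stats::pbinom(hits[und], iter, 0.5)
    p_two <- pmin(1, 2 * pmin(p_up, p_dn))
    thr <- alpha / (m * iter)            # features x rounds Bonferroni
    status[und[p_two < thr & p_up < p_dn]] <- "confirmed"
    status[und[p_two < thr & p_dn < p_up]] <- "rejected"
  }
  if (tentative == "rough_fix" && any(status == "undecided")) {
    for (j in which(status == "undecided")) {
      used <- !is.na(imp_hist[, j])
      status[j] <- if (stats::median(imp_hist[used, j]) >
                         stats::median(shadow_max_hist[used]))
        "confirmed" else "rejected"
    }
  }
  decision <- factor(ifelse(status == "undecided", "tentative", status),
                     levels = c("confirmed", "tentative", "rejected"))
  names(decision) <- colnames(x)
  structure(list(confirmed = colnames(x)[status == "confirmed"],
                 rejected = colnames(x)[status == "rejected"],
                 tentative = colnames(x)[status == "undecided"],
                 hits = stats::setNames(hits, colnames(x)),
                 n_iter = iter, decision = decision),
            class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  cat("Boruta:", length(x$confirmed), "confirmed,", length(x$rejected),
      "rejected,", length(x$tentative), "tentative after", x$n_iter,
      "round(s)\n")
  invisible(x)
}
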