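test_that("per-probe ANOVA F matches the aov oracle", {
  set.seed(4)
  labels <- rep(c("a", "b", "c"), times = c(4, 6, 5))
  beta <- matrix(runif(8 * length(labels), 0.2, 0.8), 8,
                 dimnames = list(sprintf("cg%02d", 1:8), NULL))
  colnames(beta) <- sprintf("s%02d", seq_along(labels))
  res <- anova_screen(beta, labels, alpha = 0.05)
  for (i in 1:8) {
    ref <- stats::anova(stats::aov(beta[i, ] ~ factor(labels)))
    expect_equal(res$F[i], ref$`F value`[1], tolerance = 1e-10)
    expect_equal(res$p_value[i], ref$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("degenerate ANOVA cases are handled without crashing", {
  labels <- rep(c("a", "b"), each = 3)
  flat <- matrix(0.5, 1, 6, dimnames = list("cgA", paste0("s", 1:6)))
  res <- anova_screen(flat, labels)
  expect_equal(res$p_value, 1)
  expect_false(res$retained)

  sep <- matrix(rep(c(0.2, 0.8), each = 3), 1, byrow = FALSE,
                dimnames = list("cgB", paste0("s", 1:6)))
  res2 <- anova_screen(sep, labels)
  expect_equal(res2$p_value, 0)
  expect_true(res2$retained)

  expect_error(anova_screen(flat, c("a", "a", "a", "a", "a", "b")),
               "at least two samples")
})

test_that("a planted marker with delta 0.3 passes the screen at n = 20", {
  sb <- separable_beta(n_per_class = 20, delta = 0.3, seed = 2)
  res <- anova_screen(sb$beta, sb$labels, alpha = 0.05)
  planted <- unlist(sb$markers)
  expect_true(all(res$retained[match(planted, res$probe_id)]))
})

test_that("Tukey-Kramer adjusted p matches TukeyHSD and the t-test identity", {
  set.seed(6)
  labels <- rep(c("a", "b", "c"), each = 6)         # balanced
  x <- matrix(c(rnorm(6, 0.4, 0.05), rnorm(6, 0.5, 0.05),
                rnorm(6, 0.45, 0.05)), 1,
              dimnames = list("cg1", paste0("s", 1:18)))
  tk <- tukey_kramer(x, labels, "cg1")
  ref <- stats::TukeyHSD(stats::aov(x[1, ] ~ factor(labels)))$`factor(labels)`
  pair_key <- paste(tk$class_h, tk$class_g, sep = "-")   # TukeyHSD is h-g
  expect_equal(tk$adj_p, unname(ref[pair_key, "p adj"]), tolerance = 1e-6)
  expect_equal(-tk$mean_diff, unname(ref[pair_key, "diff"]), tolerance = 1e-12)

  # unbalanced (Kramer) case
  labs2 <- rep(c("a", "b", "c"), times = c(4, 7, 5))
  x2 <- matrix(rnorm(16, rep(c(0.3, 0.5, 0.4), times = c(4, 7, 5)), 0.06), 1,
               dimnames = list("cg1", paste0("s", 1:16)))
  tk2 <- tukey_kramer(x2, labs2, "cg1")
  ref2 <- stats::TukeyHSD(stats::aov(x2[1, ] ~ factor(labs2)))$`factor(labs2)`
  expect_equal(tk2$adj_p,
               unname(ref2[paste(tk2$class_h, tk2$class_g, sep = "-"),
                           "p adj"]),
               tolerance = 1e-6)

  # equal means give adjusted p of 1
  xe <- matrix(rep(c(0.2, 0.8), 9), 1, dimnames = list("cg1", paste0("s", 1:18)))
  tke <- tukey_kramer(xe, labels, "cg1")
  expect_equal(tke$adj_p, rep(1, 3))

  # with k = 2 classes the Tukey decision equals the pooled-variance t test
  labs3 <- rep(c("a", "b"), each = 8)
  x3 <- matrix(rnorm(16, rep(c(0.4, 0.52), each = 8), 0.08), 1,
               dimnames = list("cg1", paste0("s", 1:16)))
  tk3 <- tukey_kramer(x3, labs3, "cg1")
  tt <- stats::t.test(x3[1, labs3 == "a"], x3[1, labs3 == "b"],
                      var.equal = TRUE)
  expect_equal(tk3$adj_p, tt$p.value, tolerance = 1e-6)
})

test_that("adjusted p decreases as the mean difference grows", {
  n <- 10
  base <- rep(c(0, 0, 0), each = n)
  noise <- rep(seq(-0.5, 0.5, length.out = n), 3) * 0.1
  labels <- rep(c("a", "b", "c"), each = n)
  p_at <- vapply(c(0.02, 0.05, 0.1, 0.2), function(delta) {
    x <- matrix(0.4 + base + noise, 1, dimnames = list("cg1", NULL))
    colnames(x) <- paste0("s", seq_along(labels))
    x[1, labels == "b"] <- x[1, labels == "b"] + delta
    tukey_kramer(x, labels, "cg1")$adj_p[1]
  }, numeric(1))
  expect_true(all(diff(p_at) < 0))
})

test_that("one-vs-all-others marker selection enforces the printed rule", {
  sb <- separable_beta(n_per_class = 20, delta = 0.3, seed = 3)
  panel <- select_markers(sb$beta, sb$labels, min_markers = 5)
  expect_equal(unname(panel$accepted_delta), rep(0.2, 3))
  for (cls in names(sb$markers)) {
    hits <- mean(sb$markers[[cls]] %in% panel$markers[[cls]])
    expect_gte(hits, 0.9)
  }

  # brute-force re-check of the rule for every selected marker
  for (cls in names(panel$markers)) {
    for (pb in panel$markers[[cls]]) {
      tk <- tukey_kramer(sb$beta, sb$labels, pb)
      rows <- tk$class_g == cls | tk$class_h == cls
      expect_true(all(tk$adj_p[rows] < 0.01 & abs(tk$mean_diff[rows]) > 0.2))
    }
  }

  # a probe equal-mean to one other class is never selected
  beta2 <- sb$beta
  shared <- "cg9999999"
  row <- matrix(stats::rbeta(ncol(beta2), 0.7 * 80, 0.3 * 80), 1)
  row[sb$labels == "c"] <- stats::rbeta(sum(sb$labels == "c"), 0.3 * 80, 0.7 * 80)
  beta2 <- rbind(beta2, row)
  rownames(beta2)[nrow(beta2)] <- shared      # a == b, both differ from c
  panel2 <- select_markers(beta2, sb$labels, min_markers = 1)
  expect_false(shared %in% panel2$markers[["a"]])
  expect_false(shared %in% panel2$markers[["b"]])
  expect_true(shared %in% panel2$markers[["c"]])
})

test_that("marker sets are nested along the delta schedule", {
  sb <- separable_beta(n_per_class = 15, delta = 0.22, seed = 8)
  at_level <- lapply(c(0.2, 0.15, 0.1), function(d)
    select_markers(sb$beta, sb$labels, delta_schedule = d, min_markers = 0))
  for (cls in c("a", "b", "c")) {
    expect_true(all(at_level[[1]]$markers[[cls]] %in%
                      at_level[[2]]$markers[[cls]]))
    expect_true(all(at_level[[2]]$markers[[cls]] %in%
                      at_level[[3]]$markers[[cls]]))
  }
})

test_that("delta relaxes until the panel is large enough", {
  # markers with a planted effect of 0.17: too weak for 0.2, found at 0.15
  sb <- separable_beta(n_per_class = 40, n_marker = 25, delta = 0.17,
                       kappa = 300, seed = 10)
  panel <- select_markers(sb$beta, sb$labels, min_markers = 20)
  expect_equal(unname(panel$accepted_delta), rep(0.15, 3))
  expect_length(panel$failed, 0)

  # and a class that fails everywhere is recorded, not thrown
  sb0 <- separable_beta(n_per_class = 10, n_marker = 3, delta = 0.05,
                        seed = 11)
  panel0 <- select_markers(sb0$beta, sb0$labels, min_markers = 20)
  expect_gt(length(panel0$failed), 0)

  expect_error(select_markers(sb$beta, sb$labels,
                              delta_schedule = c(0.1, 0.2)),
               "decreasing")
})
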