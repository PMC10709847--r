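test_that("layer training separates well-separated classes deterministically", {
  sxy <- separable_xy()
  beta_like <- t(sxy$x)                       # features x samples layout
  colnames(beta_like) <- sprintf("S%03d", seq_len(ncol(beta_like)))
  cfg <- forest_config(n_trees = 100, seed = 3)
  m <- train_layer(beta_like, sxy$y, rownames(beta_like), cfg)
  pr <- predict_layer(m, beta_like)
  expect_equal(rowSums(pr), rep(1, ncol(beta_like)), tolerance = 1e-9,
               ignore_attr = TRUE)
  acc <- mean(colnames(pr)[max.col(pr, ties.method = "first")] == sxy$y)
  expect_gte(acc, 0.99)

  m2 <- train_layer(beta_like, sxy$y, rownames(beta_like), cfg)
  expect_identical(predict_layer(m2, beta_like), pr)

  expect_error(train_layer(beta_like, sxy$y, c("f001", "nope"), cfg), "nope")
  expect_error(train_layer(beta_like, rep("one", ncol(beta_like)),
                           rownames(beta_like), cfg),
               "two classes")
})

test_that("prediction imputes absent panel probes and guards the limit", {
  sxy <- separable_xy()
  beta_like <- t(sxy$x)
  colnames(beta_like) <- sprintf("S%03d", seq_len(ncol(beta_like)))
  m <- train_layer(beta_like, sxy$y, rownames(beta_like),
                   forest_config(n_trees = 100, seed = 3))
  dropped <- beta_like[-(20:25), , drop = FALSE]        # 6 noise probes absent
  expect_warning(pr <- predict_layer(m, dropped), "imputed")
  acc <- mean(colnames(pr)[max.col(pr, ties.method = "first")] == sxy$y)
  expect_gte(acc, 0.95)

  gutted <- beta_like[-(1:15), , drop = FALSE]          # > 50% absent
  expect_error(predict_layer(m, gutted), "missing")

  holey <- beta_like; holey[2, 5] <- NA                 # cell-level NA
  expect_warning(pr2 <- predict_layer(m, holey), "missing cell")
  expect_equal(rowSums(pr2), rep(1, ncol(beta_like)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("the hierarchical model routes every class and keys layer 2 correctly", {
  fit <- small_fit()
  routed <- unlist(fit$routing, use.names = FALSE)
  expect_setequal(routed, unique(fit$classes$class))
  multi <- names(fit$routing)[lengths(fit$routing) > 1]
  expect_setequal(names(fit$layer2), multi)
  expect_length(fit$layer2, 2L)             # the two planted multi-type groups
  expect_equal(sum(lengths(fit$routing) == 1L), 2L)
})

test_that("a serialized model round-trips with identical predictions", {
  fit <- small_fit()
  co <- small_cohort()
  test_ids <- fit$manifest$sample_id[fit$manifest$split == "test"][1:12]
  batch <- co$beta[, test_ids]
  p0 <- predict(fit, batch)
  dir <- withr::local_tempdir()
  write_model(fit, dir)
  fit2 <- read_model(dir)
  p1 <- predict(fit2, batch)
  expect_identical(p0$results, p1$results)
  expect_equal(p0$layer1_probs, p1$layer1_probs)
})

test_that("all-singleton taxonomies yield a flat first layer", {
  co <- simulate_cohort(cohort_spec(
    n_groups = 3, types_per_group = c(1, 1, 1), subtypes_per_type = 2,
    samples_per_subtype = 10, n_background_probes = 400,
    n_markers_per_group = 10, n_markers_per_type = 0, n_sex_probes = 5,
    seed = 77))
  fit <- suppressWarnings(methhier(co$beta, co$manifest,
                                   annotation = co$annotation,
                                   boruta_max_iter = 30, min_markers = 5,
                                   config = forest_config(n_trees = 80,
                                                          seed = 2)))
  expect_length(fit$layer2, 0)
  expect_true(all(lengths(fit$routing) == 1))
  pred <- predict(fit, co$beta[, 1:6], k = 2)
  expect_true(all(pred$results$n_candidates == 2))
})

test_that("more trees do not cost accuracy on held-out data", {
  co <- small_cohort()
  accs <- sapply(c(50L, 200L), function(nt) {
    mean(sapply(c(31L, 32L), function(sd) {
      fit <- suppressWarnings(methhier(
        co$beta, co$manifest, annotation = co$annotation,
        boruta = FALSE, min_markers = 5,
        config = forest_config(n_trees = nt, seed = sd)))
      suppressWarnings(evaluate_model(fit, co$beta))$top1_accuracy
    }))
  })
  expect_gte(accs[2], accs[1] - 0.02)
})

test_that("the flat baseline trains on the same cascade and separates types", {
  co <- small_cohort()
  man <- stratified_split(co$manifest, seed = 5)
  beta <- filter_probes(co$beta, co$annotation)
  flat <- suppressWarnings(train_flat_baseline(
    beta, man, boruta_max_iter = 30, min_markers = 5,
    config = forest_config(n_trees = 100, seed = 6)))
  expect_setequal(flat$classes, unique(man$cancer_type))
  # the flat panel is drawn from the union of per-type one-vs-all selections
  union_sel <- unique(unlist(flat$cascade$selection$markers))
  expect_true(all(flat$panel %in% union_sel))
  test_ids <- man$sample_id[man$split == "test"]
  pr <- predict_layer(flat, beta[, test_ids])
  truth <- man$cancer_type[match(test_ids, man$sample_id)]
  acc <- mean(colnames(pr)[max.col(pr, ties.method = "first")] == truth)
  expect_gte(acc, 0.95)
})
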