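test_that("subtype mean profiles are arithmetic means per probe", {
  beta <- matrix(c(0.2, 0.4, 0.1, 0.3, 0.8, 0.6), nrow = 1,
                 dimnames = list("cg1", paste0("s", 1:6)))
  man <- data.frame(sample_id = paste0("s", 1:6),
                    cancer_type = c("A", "A", "A", "A", "B", "B"),
                    subtype = c("A1", "A1", "A2", "A2", "B1", "B1"),
                    cohort = "c", split = "unassigned")
  pr <- subtype_means(beta, man)
  expect_equal(pr$means["A1", "cg1"], 0.3)
  expect_equal(pr$means["A2", "cg1"], 0.2)
  expect_equal(unname(pr$type_of_subtype["B1"]), "B")

  # a single-sample subtype reproduces that sample
  man1 <- man; man1$subtype[5] <- "B0"
  pr1 <- subtype_means(beta, man1)
  expect_equal(unname(pr1$means["B0", "cg1"]), 0.8)

  # on a simulated cohort the profiles sit within 3 SE of the planted means
  co <- small_cohort()
  pr2 <- subtype_means(co$beta, co$manifest)
  planted <- t(co$truth$subtype_means)[rownames(pr2$means), colnames(pr2$means)]
  n <- small_spec()$samples_per_subtype
  se <- sqrt(planted * (1 - planted) / (small_spec()$noise_precision + 1) / n)
  frac_in <- mean(abs(pr2$means - planted) <= 3 * pmax(se, 1e-6))
  expect_gt(frac_in, 0.99)
})

test_that("top-variance probe selection honors count, ties and zero variance", {
  set.seed(2)
  x <- matrix(runif(4000), 1000, 4,
              dimnames = list(sprintf("cg%04d", 1:1000), paste0("s", 1:4)))
  expect_length(top_variance_probes(x, 0.01), 10)

  y <- rbind(a = c(0, 0.6, 0, 0.6), b = c(0.1, 0.5, 0.1, 0.5),
             c = c(0.25, 0.45, 0.25, 0.45), d = c(0.4, 0.4, 0.4, 0.4))
  colnames(y) <- paste0("s", 1:4)     # variances 0.12, 0.0533, 0.0133, 0
  expect_identical(top_variance_probes(y, 0.5), c("a", "b"))
  expect_false("d" %in% top_variance_probes(y, 0.75))
})

test_that("Pearson distance matches the correlation formula", {
  p <- rbind(p1 = c(0.1, 0.4, 0.2, 0.6), p2 = c(0.3, 0.5, 0.1, 0.9),
             p3 = c(0.9, 0.2, 0.8, 0.1))
  d <- pearson_distance(p)
  for (i in 1:3) for (j in 1:3)
    expect_equal(d[i, j], 1 - stats::cor(p[i, ], p[j, ]), tolerance = 1e-12)
  expect_equal(unname(diag(d)), rep(0, 3))

  same <- rbind(a = c(0.1, 0.2, 0.3), b = c(0.1, 0.2, 0.3))
  expect_equal(max(pearson_distance(same)), 0)
  anti <- rbind(a = c(0.1, 0.2, 0.3), b = 0.9 - 2 * c(0.1, 0.2, 0.3))
  expect_equal(pearson_distance(anti)["a", "b"], 2)
  flat <- rbind(a = c(0.1, 0.2, 0.3), konst = c(0.4, 0.4, 0.4))
  expect_error(pearson_distance(flat), "konst")
})

test_that("UPGMA reproduces the manual trace and round-trips ultrametric input", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma_tree(d)
  expect_equal(sort(tr$hclust$height), c(2, 4))      # merge distances
  # node heights are distance/2 in the phylo representation
  depths <- ape::node.depth.edgelength(tr$phylo)
  expect_equal(max(depths), 2)                        # root at 4/2
  expect_equal(as.matrix(stats::cophenetic(tr$hclust))[names(d[1, ]),
                                                       names(d[1, ])], d)

  two <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  t2 <- upgma_tree(two)
  expect_equal(t2$hclust$height, 3)
  expect_equal(unname(t2$phylo$edge.length), c(1.5, 1.5))

  # ultrametric input: cophenetic distances reproduce the input exactly
  set.seed(42)
  for (rep in 1:3) {
    ph <- ape::rcoal(8)
    du <- as.matrix(stats::cophenetic(ph))
    tru <- upgma_tree(du)
    expect_lt(max(abs(as.matrix(stats::cophenetic(tru$hclust))[
      rownames(du), colnames(du)] - du)), 1e-10)
  }

  dn <- d; dn[1, 2] <- NA; dn[2, 1] <- NA
  expect_error(upgma_tree(dn), "NA")
})


test_that("silhouette equals the brute-force definition on small instances", {
  set.seed(7)
  for (n in 4:8) {
    pts <- matrix(runif(2 * n), n)
    d <- as.matrix(stats::dist(pts))
    dimnames(d) <- list(paste0("p", 1:n), paste0("p", 1:n))
    for (k in 2:n) {
      for (rep in 1:8) {
        cl <- sample(paste0("g", 1:k), n, replace = TRUE)
        if (length(unique(cl)) < 2) next
        got <- silhouette_scores(d, cl)
        expect_equal(unname(got$widths), brute_silhouette(d, cl),
                     tolerance = 1e-12)
        expect_equal(got$mean, mean(brute_silhouette(d, cl)),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("silhouette behaves at the geometric extremes", {
  # two tight, far-apart clusters
  set.seed(3)
  pts <- rbind(matrix(rnorm(10, 0, 0.01), 5), matrix(rnorm(10, 10, 0.01), 5))
  d <- as.matrix(stats::dist(pts))
  s <- silhouette_scores(d, rep(c("u", "v"), each = 5))
  expect_gt(s$mean, 0.9)

  # equidistant point scores zero
  d3 <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3)
  s3 <- silhouette_scores(d3, c("a", "a", "b"))
  expect_equal(unname(s3$widths[3]), 0)   # singleton convention
  expect_equal(unname(s3$widths[1]), 0)   # a = b = 1

  expect_error(silhouette_scores(d3, c("a", "a", "a")), "two clusters")
})

test_that("silhouette agrees with the cluster package implementation", {
  skip_if_not_installed("cluster")
  set.seed(12)
  pts <- matrix(rnorm(40), 20)
  d <- as.matrix(stats::dist(pts))
  cl <- sample(1:3, 20, replace = TRUE)
  ours <- silhouette_scores(d, cl)
  ref <- cluster::silhouette(cl, stats::as.dist(d))
  expect_equal(unname(ours$widths), unname(ref[, "sil_width"]),
               tolerance = 1e-12)
})

test_that("group choice cuts the tree at the silhouette optimum", {
  co <- small_cohort()
  b <- filter_probes(co$beta, co$annotation)
  pr <- subtype_means(b, co$manifest)
  d <- pearson_distance(pr, top_variance_probes(b, 0.01))
  tr <- upgma_tree(d)
  asn <- choose_groups(tr, d, pr$type_of_subtype)
  truth <- co$truth$group_of_type[pr$type_of_subtype]
  expect_equal(asn$n_groups, 4L)
  tab <- table(asn$group_of_subtype, truth)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))

  # every group is a clade of the tree
  for (g in unique(asn$group_of_subtype)) {
    members <- names(asn$group_of_subtype)[asn$group_of_subtype == g]
    if (length(members) > 1) {
      mrca <- ape::getMRCA(tr$phylo, members)
      clade <- ape::extract.clade(tr$phylo, mrca)$tip.label
      expect_setequal(clade, members)
    }
  }

  # k_range = n leaves: every subtype its own group
  n <- length(tr$labels)
  asn_n <- choose_groups(tr, d, pr$type_of_subtype, k_range = n)
  expect_equal(asn_n$n_groups, n)

  expect_error(choose_groups(tr, d, pr$type_of_subtype,
                             overrides = c(nosuch = "G99")), "nosuch")
})

test_that("a type whose subtypes split across groups gets split class labels", {
  co <- small_cohort()
  man <- co$manifest
  # relabel one type from each of the two multi-type sister groups as a
  # single cancer type with two subtypes
  g_of_t <- co$truth$group_of_type
  tyA <- names(g_of_t)[g_of_t == "G01"][1]
  tyB <- names(g_of_t)[g_of_t == "G02"][1]
  pick <- man$cancer_type %in% c(tyA, tyB)
  man$cancer_type[pick] <- "MIXED"
  b <- filter_probes(co$beta, co$annotation)
  pr <- subtype_means(b, man)
  d <- pearson_distance(pr, top_variance_probes(b, 0.01))
  asn <- choose_groups(upgma_tree(d), d, pr$type_of_subtype)
  mixed_classes <- unique(asn$class_of_subtype[pr$type_of_subtype == "MIXED"])
  expect_gt(length(mixed_classes), 1)
  expect_true(all(grepl("^MIXED\\.", mixed_classes)))
})

test_that("taxonomy recovers the planted hierarchy on the small cohort", {
  skip_if_not_installed("phangorn")
  co <- small_cohort()
  b <- filter_probes(co$beta, co$annotation)
  pr <- subtype_means(b, co$manifest)
  d <- pearson_distance(pr, top_variance_probes(b, 0.01))
  tr <- upgma_tree(d)
  truth <- co$truth$group_of_type[pr$type_of_subtype]
  ph <- collapse_to_groups(tr, stats::setNames(truth, rownames(pr$means)))
  expect_equal(phangorn::RF.dist(ph,
                                 ape::read.tree(text = co$truth$planted_tree)),
               0)
})
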