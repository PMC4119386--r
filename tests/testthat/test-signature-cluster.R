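test_that("the signature requires passing against every other group", {
  genes <- c("g1", "g2", "g3")
  tabs <- list()
  for (f in c("TC5", "TC10")) {
    for (o in c("O1", "O2")) {
      # g1 passes everywhere; g2 fails only against O2; g3 is down
      folds <- c(2, if (o == "O2") 0.5 else 2, -3)
      tabs[[paste(f, o)]] <- fake_fold_table(genes, folds, f, o)
    }
  }
  sig <- specific_signature(tabs, threshold = 1)
  expect_identical(sig$up, "g1")
  expect_identical(sig$down, "g3")
  expect_error(specific_signature(tabs[1:3]), "missing comparison")
})

test_that("timepoint rules both/either behave as stated", {
  data <- generate_dataset(small_config(effect_timepoints = "5"))
  g <- collapse_probes_to_genes(filter_to_annotated(data$matrix,
                                                    data$annotation),
                                data$annotation)
  chr <- restrict_to_chromosome(g, data$annotation, "1")
  gm <- group_means(chr, data$metadata)
  tables <- pairwise_fold_tables(gm, data$truth$focal_groups,
                                 setdiff(colnames(gm),
                                         data$truth$focal_groups))
  both <- specific_signature(tables, 1, "both")
  either <- specific_signature(tables, 1, "either")
  expect_length(both$up, 0L)
  expect_length(both$down, 0L)
  expect_setequal(either$up, data$truth$up_genes)
  expect_setequal(either$down, data$truth$down_genes)
})

test_that("signatures recover planted truth noiselessly and nest across thresholds", {
  data <- generate_dataset(small_config())
  g <- collapse_probes_to_genes(filter_to_annotated(data$matrix,
                                                    data$annotation),
                                data$annotation)
  chr <- restrict_to_chromosome(g, data$annotation, "1")
  gm <- group_means(chr, data$metadata)
  tables <- pairwise_fold_tables(gm, data$truth$focal_groups,
                                 setdiff(colnames(gm),
                                         data$truth$focal_groups))
  s1 <- specific_signature(tables, 1, "both")
  expect_setequal(s1$up, data$truth$up_genes)
  expect_setequal(s1$down, data$truth$down_genes)
  s2 <- specific_signature(tables, 2, "both")
  expect_true(all(s2$up %in% s1$up) && all(s2$down %in% s1$down))
  s_inf <- specific_signature(tables, Inf, "both")
  expect_length(c(s_inf$up, s_inf$down), 0L)
})

test_that("top-k ranking sorts by magnitude with lexicographic tie-break", {
  tab <- fake_fold_table(c("A", "B", "C"), c(3, 2, -5), "TC5", "MSC")
  expect_identical(top_k_genes(tab, 2, "up"), c("A", "B"))
  expect_identical(top_k_genes(tab, 10, "down"), "C")
  tie <- fake_fold_table(c("Fhl2", "Capn2", "Zz"), c(2, 2, 0.5),
                         "TC5", "MSC")
  expect_identical(top_k_genes(tie, 2, "up"), c("Capn2", "Fhl2"))
  expect_error(top_k_genes(tab, 0, "up"), "k")
})

test_that("Pearson dissimilarity matches a hand-coded correlation oracle", {
  m <- tiny_matrix(cbind(c(1, 2, 3), c(1, 2, 3), c(3, 2, 1)),
                   scale = "log2")
  d <- pearson_dissimilarity(m)
  expect_equal(unname(d[1, 2]), 0)
  expect_equal(unname(d[1, 3]), 2)
  expect_equal(unname(diag(d)), rep(0, 3))

  set.seed(13)
  m <- tiny_matrix(matrix(rnorm(100), 20, 5), scale = "log2")
  d <- pearson_dissimilarity(m)
  expect_true(isSymmetric(d))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(d[i, j],
                 1 - oracle_pearson(m$values[, i], m$values[, j]),
                 tolerance = 1e-10)
  }
  flat <- tiny_matrix(cbind(c(1, 1), c(1, 2)), scale = "log2")
  expect_error(pearson_dissimilarity(flat), "s1")
})

test_that("agglomerative clustering matches hclust and breaks ties deterministically", {
  # two leaves: one merge at their distance
  d <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"),
                                                       c("a", "b")))
  hc <- hierarchical_cluster(d)
  expect_equal(hc$height, 0.4)
  expect_identical(nrow(hc$merge), 1L)

  # forced order: (A,B) at 1, then C joins at 10
  d3 <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc3 <- hierarchical_cluster(d3, "average")
  expect_equal(hc3$height, c(1, 10))
  expect_true(has_clade(hc3, c("A", "B")))

  set.seed(17)
  for (linkage in c("average", "complete", "single")) {
    x <- matrix(rnorm(8 * 5), 8, 5,
                dimnames = list(letters[1:8], NULL))
    d8 <- as.matrix(dist(x))
    ours <- hierarchical_cluster(d8, linkage)
    ref <- stats::hclust(stats::as.dist(d8), method = linkage)
    expect_equal(ours$height, ref$height, tolerance = 1e-12)
    expect_equal(length(ours$height), 7L)
    # same clades, up to hclust's internal ordering
    expect_setequal(vapply(hclust_clades(ours), paste, "",
                           collapse = "|"),
                    vapply(hclust_clades(ref), paste, "", collapse = "|"))
  }

  # deterministic lexicographic tie-break among equal-distance pairs
  dt <- matrix(1, 3, 3, dimnames = list(c("b", "a", "c"),
                                        c("b", "a", "c")))
  diag(dt) <- 0
  hct <- hierarchical_cluster(dt, "single")
  expect_true(has_clade(hct, c("a", "b")))
  expect_error(hierarchical_cluster(matrix(0, 1, 1)), "2 leaves")
})

test_that("average-linkage merge heights are monotone and export to Newick", {
  data <- generate_dataset(small_config(noise_sigma = 0.1,
                                        effect_ratio = 4))
  g <- collapse_probes_to_genes(filter_to_annotated(data$matrix,
                                                    data$annotation),
                                data$annotation)
  chr <- restrict_to_chromosome(g, data$annotation, "1")
  d <- pearson_dissimilarity(convert_scale(chr, "log2", 1))
  hc <- hierarchical_cluster(d)
  expect_true(all(diff(hc$height) >= -1e-12))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(hc, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, colnames(chr$values))
})
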