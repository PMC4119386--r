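test_that("group means average replicate columns per sample group", {
  v <- cbind(a1 = c(2, 1), a2 = c(4, 1), a3 = c(6, 1), b1 = c(10, 5))
  rownames(v) <- c("g1", "g2")
  m <- expr_matrix(v)
  meta <- data.frame(sample_id = colnames(v),
                     cell_type = c("A", "A", "A", "B"),
                     timepoint = "", dataset = "d1",
                     stringsAsFactors = FALSE)
  gm <- group_means(m, meta)
  expect_equal(unname(gm["g1", ]), c(4, 10))  # mean(2,4,6); singleton copied
  expect_error(group_means(m, meta[1:3, ]), "missing from metadata")
})

test_that("the fold statistic is a signed relative difference with pseudocount guard", {
  # a=4, b=2 with vanishing pseudocount: (4-2)/2 = +1
  expect_equal(fold_change(4, 2, eps = 1e-9), 1, tolerance = 1e-8)
  expect_identical(fold_change(5, 5, eps = 1), 0)
  expect_equal(fold_change(2, 4, eps = 1e-9), -1, tolerance = 1e-8)
  expect_error(fold_change(1, 1, eps = 0), "eps")

  set.seed(31)
  a <- runif(1000, 0, 100)
  b <- runif(1000, 0, 100)
  # antisymmetry
  expect_equal(fold_change(a, b), -fold_change(b, a))
  # threshold equivalence: fold > 1 iff (a + eps) > 2 (b + eps)
  expect_identical(fold_change(a, b, eps = 1) > 1, a + 1 > 2 * (b + 1))
  # continuity in the pseudocount
  expect_equal(fold_change(a, b, eps = 1),
               fold_change(a, b, eps = 1 + 1e-9), tolerance = 1e-6)

  # the literal printed formula is bounded above by 1: an up-threshold of
  # 1 is unsatisfiable under it, which is why it is not the default
  lit <- fold_change(a, b, eps = 1, variant = "literal")
  expect_true(all(lit < 1))
  expect_equal(fold_change(4, 2, eps = 1e-9, variant = "literal"), 0.5,
               tolerance = 1e-8)
})

test_that("pairwise fold tables cover the focal x other grid", {
  data <- generate_dataset(small_config())
  g <- collapse_probes_to_genes(filter_to_annotated(data$matrix,
                                                    data$annotation),
                                data$annotation)
  chr <- restrict_to_chromosome(g, data$annotation, "1")
  gm <- group_means(chr, data$metadata)
  focal <- data$truth$focal_groups
  others <- setdiff(colnames(gm), focal)
  tables <- pairwise_fold_tables(gm, focal, others, eps = 1e-6)
  expect_length(tables, 2L * 7L)
  expect_error(pairwise_fold_tables(gm, focal, c(focal[1], others)),
               "overlap")
  expect_error(pairwise_fold_tables(gm, c(focal, "NoSuch"), others),
               "absent")

  # planted up genes at ratio 3 have fold (3b - b)/b = +2 in every table
  for (tab in tables) {
    folds <- tab$fold[match(data$truth$up_genes, tab$gene)]
    expect_equal(folds, rep(2, 4), tolerance = 1e-6)
    down <- tab$fold[match(data$truth$down_genes, tab$gene)]
    expect_equal(down, rep(-2, 6), tolerance = 1e-6)
    expect_identical(sign(tab$fold),
                     unname(sign(gm[tab$gene, attr(tab, "focal")] -
                                   gm[tab$gene, attr(tab, "other")])))
  }
})

test_that("threshold counting is strict, nested, and both-timepoint aware", {
  t1 <- fake_fold_table(c("a", "b", "c"), c(1.5, 0.5, -2.5), "TC5", "MSC")
  t2 <- fake_fold_table(c("a", "b", "c"), c(1.5, 1.2, -0.5), "TC10", "MSC")
  counts <- threshold_counts(list(t1, t2), thresholds = c(1, 2))
  expect_identical(counts$comparison,
                   c("TC5 vs MSC", "TC10 vs MSC", "TCs vs MSC"))
  expect_identical(counts$up_gt_1, c(1, 2, 1))   # 'b' passes only in TC10
  expect_identical(counts$down_gt_1, c(1, 0, 0)) # 'c' fails in TC10
  expect_identical(counts$up_gt_2, c(0, 0, 0))
  # a fold equal to the threshold is not counted (strict >)
  t3 <- fake_fold_table("a", 1, "TC5", "Fb")
  expect_identical(threshold_counts(list(t3), 1)$up_gt_1, 0)
})

test_that("counts are non-increasing across thresholds on noisy data", {
  data <- generate_dataset(small_config(noise_sigma = 0.5, seed = 99))
  g <- collapse_probes_to_genes(filter_to_annotated(data$matrix,
                                                    data$annotation),
                                data$annotation)
  chr <- restrict_to_chromosome(g, data$annotation, "1")
  gm <- group_means(chr, data$metadata)
  tables <- pairwise_fold_tables(gm, data$truth$focal_groups,
                                 setdiff(colnames(gm),
                                         data$truth$focal_groups))
  counts <- threshold_counts(tables)
  up <- as.matrix(counts[, paste0("up_gt_", c(1, 2, 5, 10))])
  down <- as.matrix(counts[, paste0("down_gt_", c(1, 2, 5, 10))])
  expect_true(all(t(apply(up, 1, diff)) <= 0))
  expect_true(all(t(apply(down, 1, diff)) <= 0))
  expect_true(all(up <= nrow(chr$values)) && all(down <= nrow(chr$values)))
})

test_that("noiseless planted counts are exact with no background hits", {
  data <- generate_dataset(small_config(n_type_markers = 0L))
  g <- collapse_probes_to_genes(filter_to_annotated(data$matrix,
                                                    data$annotation),
                                data$annotation)
  chr <- restrict_to_chromosome(g, data$annotation, "1")
  gm <- group_means(chr, data$metadata)
  tables <- pairwise_fold_tables(gm, data$truth$focal_groups,
                                 setdiff(colnames(gm),
                                         data$truth$focal_groups),
                                 eps = 1e-6)
  counts <- threshold_counts(tables, thresholds = 1)
  expect_identical(unique(counts$up_gt_1), 4)
  expect_identical(unique(counts$down_gt_1), 6)
})
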