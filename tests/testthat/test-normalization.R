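test_that("quantile normalization follows the sorted-mean definition", {
  # identical columns are a fixed point
  m <- tiny_matrix(cbind(c(1, 5, 3), c(1, 5, 3)))
  expect_equal(quantile_normalize(m)$values, m$values)

  # 2x2 case: sorted-rank means are (mean(1,3), mean(5,7)) = (2, 6),
  # mapped back by each column's rank order (limma agrees)
  m <- tiny_matrix(rbind(c(1, 3), c(5, 7)))
  expect_equal(unname(quantile_normalize(m)$values),
               rbind(c(2, 2), c(6, 6)))
  expect_equal(unname(limma::normalizeQuantiles(m$values)),
               rbind(c(2, 2), c(6, 6)))

  expect_error(quantile_normalize(tiny_matrix(cbind(c(1, 2)))),
               "2 columns")
})

test_that("quantile normalization equalizes column multisets and is idempotent", {
  set.seed(21)
  m <- tiny_matrix(matrix(2^rnorm(300, 6, 2), 50, 6))
  q <- quantile_normalize(m)
  sorted <- apply(q$values, 2L, sort)
  for (j in 2:6) expect_equal(sorted[, j], sorted[, 1])
  q2 <- quantile_normalize(q)
  expect_equal(q2$values, q$values, tolerance = 1e-12)
  # permutation equivariance over columns
  perm <- c(3, 1, 6, 2, 5, 4)
  qp <- quantile_normalize(tiny_matrix(m$values[, perm]))
  expect_equal(unname(qp$values), unname(q$values[, perm]))
})

test_that("quantile normalization agrees with limma and spreads ties over their span", {
  set.seed(8)
  m <- tiny_matrix(matrix(rnorm(200), 25, 8), scale = "log2")
  ours <- quantile_normalize(m)$values
  ref <- limma::normalizeQuantiles(m$values, ties = TRUE)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)

  # a 3-way tie spans quantile targets 1..3 and receives their mean
  m <- tiny_matrix(cbind(c(4, 4, 4, 9), c(1, 2, 3, 4)))
  q <- quantile_normalize(m)
  target <- rowMeans(apply(m$values, 2, sort))
  expect_equal(unname(q$values[1:3, 1]), rep(mean(target[1:3]), 3))
  expect_equal(unname(q$values[4, 1]), unname(target[4]))
})

test_that("median polish matches the reference fit and handles degenerate blocks", {
  # single probe row returned unchanged
  block <- matrix(c(1, 2, 3), 1, 3,
                  dimnames = list("p", c("a", "b", "c")))
  expect_identical(median_polish_summarize(block),
                   c(a = 1, b = 2, c = 3))

  # exactly additive block: column effects recovered exactly
  r <- c(0, 1, 2)
  cc <- c(5, 6, 7, 8)
  add <- outer(r, cc, `+`)
  dimnames(add) <- list(paste0("p", 1:3), paste0("s", 1:4))
  fit <- median_polish_summarize(add)
  expect_equal(unname(fit - fit[1]), cc - cc[1])
  expect_equal(unname(fit), r[2] + cc)

  set.seed(5)
  for (rep in 1:5) {
    z <- matrix(rnorm(30), 5, 6,
                dimnames = list(paste0("p", 1:5), paste0("s", 1:6)))
    ref <- stats::medpolish(z, eps = 1e-13, maxiter = 500,
                            trace.iter = FALSE)
    expect_equal(unname(median_polish_summarize(z, tol = 1e-12,
                                                max_iter = 500L)),
                 unname(ref$overall + ref$col), tolerance = 1e-8)
  }
  expect_error(median_polish_summarize(matrix(c(1, Inf), 2, 1)), "finite")
})

test_that("housekeeping scaling implements Y, C, Z, E and their pinning rules", {
  data <- generate_dataset(small_config(
    batch_scales = c(own = 1, geo_atii = 2, geo_airway = 1, geo_t = 1)))
  g <- collapse_probes_to_genes(filter_to_annotated(data$matrix,
                                                    data$annotation),
                                data$annotation)
  ref_samples <- data$metadata$sample_id[data$metadata$dataset == "own"]
  spec <- housekeeping_spec(data$truth$housekeeping_genes, ref_samples)
  out <- housekeeping_scale(g, spec)
  rep <- out$report

  # reference samples are pinned to Z = 1 and left untouched
  expect_true(all(rep$Z[rep$is_reference] == 1))
  expect_equal(out$matrix$values[, ref_samples], g$values[, ref_samples])
  # the scaled dataset's factor is exactly its batch scale
  atii <- data$metadata$sample_id[data$metadata$dataset == "geo_atii"]
  expect_equal(unname(rep$Z[rep$sample_id %in% atii]), rep(2, length(atii)))
  # every non-reference housekeeping mean now equals C
  C <- attr(rep, "C")
  hk_means <- colMeans(out$matrix$values[spec$housekeeping, ])
  expect_equal(unname(hk_means[!names(hk_means) %in% ref_samples]),
               rep(C, sum(!rep$is_reference)))
  # within-column gene ratios unchanged
  v0 <- g$values
  v1 <- out$matrix$values
  expect_equal(v1[3, ] / v1[10, ], v0[3, ] / v0[10, ])
  # scaled group means recover the planted truth
  gm <- group_means(out$matrix, data$metadata)
  tr <- data$truth$group_means
  expect_equal(gm[rownames(tr), colnames(tr)], unclass(tr),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("housekeeping scaling is an identity on unit-batch data and validates inputs", {
  data <- generate_dataset(small_config())
  g <- collapse_probes_to_genes(filter_to_annotated(data$matrix,
                                                    data$annotation),
                                data$annotation)
  ref_samples <- data$metadata$sample_id[data$metadata$dataset == "own"]
  spec <- housekeeping_spec(data$truth$housekeeping_genes, ref_samples)
  out <- housekeeping_scale(g, spec)
  expect_equal(out$matrix$values, g$values, tolerance = 1e-12)
  expect_equal(out$report$Z, rep(1, ncol(g$values)), tolerance = 1e-12)

  expect_error(housekeeping_scale(g, housekeeping_spec("NotAGene",
                                                       ref_samples)),
               "NotAGene")
  expect_error(housekeeping_spec(character(0), ref_samples), "non-empty")
  zero <- g
  zero$values[data$truth$housekeeping_genes, 1] <- 0
  expect_error(housekeeping_scale(zero, spec), "zero")
})
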