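# Small generator configs and hand-built fixtures shared across tests.

small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_background_genes = 200L, n_focal_chrom_genes = 60L,
                   n_housekeeping = 5L, n_planted_up = 4L,
                   n_planted_down = 6L, n_type_markers = 2L,
                   replicates_per_group = 2L, noise_sigma = 0,
                   effect_ratio = 3, seed = 11L)
  do.call(synthetic_config, utils::modifyList(defaults, args))
}

tiny_matrix <- function(v, genes = NULL, samples = NULL, ...) {
  v <- as.matrix(v)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(v)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(v)))
  dimnames(v) <- list(genes, samples)
  expr_matrix(v, ...)
}

# hand-built fold table with the attributes pairwise_fold_tables sets
fake_fold_table <- function(genes, folds, focal, other, eps = 1) {
  tab <- data.frame(gene = genes, fold = folds, stringsAsFactors = FALSE)
  attr(tab, "focal") <- focal
  attr(tab, "other") <- other
  attr(tab, "eps") <- eps
  class(tab) <- c("fold_table", "data.frame")
  tab
}

# leaf label sets of every internal node of an hclust tree
hclust_clades <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", n - 1L)
  members <- function(id) {
    if (id < 0) return(hc$labels[-id])
    sets[[id]]
  }
  for (m in seq_len(n - 1L)) {
    sets[[m]] <- sort(c(members(hc$merge[m, 1L]),
                        members(hc$merge[m, 2L])))
  }
  sets
}

has_clade <- function(hc, labels) {
  any(vapply(hclust_clades(hc), function(s) setequal(s, labels),
             logical(1L)))
}

# independently coded Pearson correlation (no stats::cor)
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# exhaustive hypergeometric upper tail by enumeration of all draws
oracle_hyper_enum <- function(N, K, n, k) {
  universe <- seq_len(N)
  inset <- seq_len(K)
  draws <- utils::combn(N, n)
  mean(apply(draws, 2L, function(d) sum(d %in% inset) >= k))
}

recovery_stats <- function(sig, truth, universe_size) {
  tp <- length(intersect(sig$up, truth$up_genes)) +
    length(intersect(sig$down, truth$down_genes))
  planted <- length(truth$up_genes) + length(truth$down_genes)
  called <- length(sig$up) + length(sig$down)
  fp <- called - length(intersect(sig$up, truth$up_genes)) -
    length(intersect(sig$down, truth$down_genes))
  tn_denominator <- universe_size - planted
  list(sensitivity = tp / planted,
       specificity = (tn_denominator - fp) / tn_denominator)
}
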