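#' Focal-cell-type-specific signature by all-comparison intersection
#'
#' A gene enters the up signature only if its fold exceeds the threshold
#' against EVERY other cell group; the down signature is symmetric. When
#' the focal type was observed at two timepoints, `timepoint_rule` decides
#' whether the all-comparison condition must hold in both timepoints
#' (`"both"`, the default) or in at least one timepoint's complete set of
#' comparisons (`"either"`).
#'
#' @param tables list of fold tables from [pairwise_fold_tables()],
#'   covering every (focal timepoint, other group) pair.
#' @param threshold fold threshold, strict `>`; default 1.
#' @param timepoint_rule `"both"` or `"either"`.
#' @return a list of class `signature_set` with elements `up`, `down`
#'   (character vectors of symbols), `threshold`, `timepoint_rule`.
#' @export
specific_signature <- function(tables, threshold = 1,
                               timepoint_rule = c("both", "either")) {
  timepoint_rule <- match.arg(timepoint_rule)
  focal <- vapply(tables, attr, "", "focal")
  other <- vapply(tables, attr, "", "other")
  focal_groups <- unique(focal)
  other_groups <- unique(other)
  for (f in focal_groups) for (o in other_groups) {
    if (!any(focal == f & other == o))
      stop("missing comparison pair: ", f, " vs ", o, call. = FALSE)
  }
  genes <- tables[[1L]]$gene
  per_tp <- function(direction) {
    lapply(focal_groups, function(f) {
      pass <- rep(TRUE, length(genes))
      for (i in which(focal == f)) {
        tab <- tables[[i]]
        fold <- tab$fold[match(genes, tab$gene)]
        pass <- pass & if (direction == "up") fold > threshold
                       else fold < -threshold
      }
      pass
    })
  }
  combine <- function(per) {
    if (timepoint_rule == "both") Reduce(`&`, per) else Reduce(`|`, per)
  }
  up <- genes[combine(per_tp("up"))]
  down <- genes[combine(per_tp("down"))]
  clash <- intersect(up, down)
  if (length(clash)) {
    warning("gene(s) up in one timepoint and down in the other dropped: ",
            paste(clash, collapse = ", "))
    up <- setdiff(up, clash)
    down <- setdiff(down, clash)
  }
  structure(list(up = up, down = down, threshold = threshold,
                 timepoint_rule = timepoint_rule),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set: %d up, %d down (fold > %g, timepoints: %s)\n",
              length(x$up), length(x$down), x$threshold, x$timepoint_rule))
  invisible(x)
}

#' Write a signature as TSV
#'
#' Columns: `symbol`, `direction`, and `min_abs_fold`, the smallest |fold|
#' the gene attains across all comparisons (its weakest link).
#'
#' @param sig a `signature_set`.
#' @param tables the fold tables the signature was derived from.
#' @param path output file.
#' @export
write_signature <- function(sig, tables, path) {
  min_fold <- function(genes) {
    if (!length(genes)) return(numeric(0))
    folds <- vapply(tables, function(tab)
      abs(tab$fold[match(genes, tab$gene)]), numeric(length(genes)))
    apply(matrix(folds, nrow = length(genes)), 1L, min)
  }
  block <- function(genes, direction) {
    if (!length(genes))
      return(data.frame(symbol = character(0), direction = character(0),
                        min_abs_fold = numeric(0),
                        stringsAsFactors = FALSE))
    data.frame(symbol = genes, direction = direction,
               min_abs_fold = min_fold(genes), stringsAsFactors = FALSE)
  }
  out <- rbind(block(sig$up, "up"), block(sig$down, "down"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Top-k genes of one comparison by fold magnitude
#'
#' @param table a fold table.
#' @param k number of genes requested (fewer returned if fewer qualify).
#' @param direction `"up"` (fold > 0) or `"down"` (fold < 0).
#' @return character vector of symbols, |fold| descending, ties broken by
#'   symbol in C-locale lexicographic order.
#' @export
top_k_genes <- function(table, k, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  keep <- if (direction == "up") table$fold > 0 else table$fold < 0
  sub <- table[keep, , drop = FALSE]
  ord <- order(-abs(sub$fold), sub$gene, method = "radix")
  utils::head(sub$gene[ord], k)
}

#' Pearson dissimilarity between samples
#'
#' `d = 1 - r` over a gene subset, the conventional microarray sample
#' distance: symmetric, zero diagonal, range [0, 2].
#'
#' @param x an [expr_matrix].
#' @param rows gene subset (row ids) to correlate over; default all rows.
#' @return a symmetric sample x sample dissimilarity matrix.
#' @export
pearson_dissimilarity <- function(x, rows = rownames(x$values)) {
  missing <- setdiff(rows, rownames(x$values))
  if (length(missing))
    stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  v <- x$values[rows, , drop = FALSE]
  if (nrow(v) < 2L) stop("need >= 2 genes in the subset", call. = FALSE)
  if (ncol(v) < 2L) stop("need >= 2 samples", call. = FALSE)
  sds <- apply(v, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero variance within the gene subset for sample(s): ",
         paste(colnames(v)[sds == 0], collapse = ", "), call. = FALSE)
  d <- 1 - stats::cor(v)
  diag(d) <- 0
  d
}

#' Agglomerative hierarchical clustering with deterministic tie-breaking
#'
#' Standard bottom-up clustering over a dissimilarity matrix using
#' average (UPGMA), complete or single linkage. When several pairs attain
#' the minimal distance, the pair whose (ordered) cluster ids are
#' lexicographically smallest is merged, making the merge sequence fully
#' deterministic. The result is an `hclust`-compatible object (merge
#' matrix, heights, labels, order), so `plot()`, `stats::cutree()` and
#' `ape::as.phylo()` apply directly.
#'
#' @param d symmetric dissimilarity matrix with labelled rows/columns.
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return an object of classes `telosig_hclust` and `hclust`.
#' @export
hierarchical_cluster <- function(d, linkage = c("average", "complete",
                                                "single")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 leaves to cluster", call. = FALSE)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  # active clusters: id (hclust convention: -leaf or merge index),
  # lexicographic key = sorted member labels pasted, size
  active <- data.frame(id = -seq_len(n), key = labels,
                       size = 1L, stringsAsFactors = FALSE)
  dd <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (m in seq_len(n - 1L)) {
    k <- nrow(dd)
    best <- NULL
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      cand <- list(h = dd[i, j],
                   key = sort(c(active$key[i], active$key[j])))
      if (is.null(best) || cand$h < best$h ||
          (cand$h == best$h &&
           (cand$key[1L] < best$key[1L] ||
            (cand$key[1L] == best$key[1L] && cand$key[2L] < best$key[2L])))) {
        best <- cand
        bi <- i; bj <- j
      }
    }
    merge[m, ] <- sort(c(active$id[bi], active$id[bj]))
    height[m] <- best$h
    si <- active$size[bi]; sj <- active$size[bj]
    newd <- switch(linkage,
      average  = (si * dd[bi, ] + sj * dd[bj, ]) / (si + sj),
      complete = pmax(dd[bi, ], dd[bj, ]),
      single   = pmin(dd[bi, ], dd[bj, ]))
    keep <- setdiff(seq_len(k), c(bi, bj))
    dd <- rbind(cbind(dd[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    active <- rbind(active[keep, , drop = FALSE],
                    data.frame(id = m,
                               key = paste(sort(c(active$key[bi],
                                                  active$key[bj])),
                                           collapse = "\r"),
                               size = si + sj, stringsAsFactors = FALSE))
  }
  out <- structure(list(merge = merge, height = height,
                        order = hclust_leaf_order(merge),
                        labels = labels, method = linkage,
                        call = match.call(),
                        dist.method = "user-supplied"),
                   class = c("telosig_hclust", "hclust"))
  out
}

hclust_leaf_order <- function(merge) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1L]), expand(merge[node, 2L]))
  }
  expand(nrow(merge))
}

#' Export a dendrogram in Newick format
#'
#' Converts the clustering to a phylogenetic tree (branch lengths derived
#' from merge heights, each child branch spanning half the height gap as
#' in `ape::as.phylo.hclust`) and writes Newick text.
#'
#' @param hc an `hclust` object (e.g. from [hierarchical_cluster()]).
#' @param path output file.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
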