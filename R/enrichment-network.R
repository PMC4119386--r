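#' Read a gene-set collection in GMT format
#'
#' One set per line: name, description, then tab-separated member symbols.
#'
#' @param path GMT file.
#' @param universe character vector of symbols defining the testable
#'   universe; sets are intersected with it.
#' @return a list of class `gene_set_collection`: `sets` (named list of
#'   symbol vectors) and `universe`.
#' @export
read_gmt <- function(path, universe) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  gene_set_collection(sets, universe)
}

#' @rdname read_gmt
#' @param sets named list of symbol vectors.
#' @export
gene_set_collection <- function(sets, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("universe must be non-empty", call. = FALSE)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set needs a name", call. = FALSE)
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Write a gene-set collection in GMT format
#'
#' @param gsc a `gene_set_collection`.
#' @param path output file.
#' @param description description field written for every set.
#' @export
write_gmt <- function(gsc, path, description = "na") {
  lines <- vapply(names(gsc$sets), function(nm)
    paste(c(nm, description, gsc$sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation of a signature
#'
#' For each set of size K in a universe of size N, with a signature of
#' size n overlapping the set in k genes, computes the upper-tail
#' hypergeometric probability `P(X >= k)` for `X ~ Hypergeom(N, K, n)`
#' and Benjamini-Hochberg adjusted q-values across the collection.
#' Signature genes outside the universe are dropped with a warning.
#'
#' @param signature a `signature_set` or a character vector of symbols;
#'   for a `signature_set`, `direction` selects which genes are tested.
#' @param gsc a `gene_set_collection`.
#' @param direction `"both"` (up and down combined), `"up"` or `"down"`.
#' @return `data.frame` with columns `set`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   ordered by `p`.
#' @export
hypergeometric_enrichment <- function(signature, gsc,
                                      direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  stopifnot(inherits(gsc, "gene_set_collection"))
  genes <- if (inherits(signature, "signature_set")) {
    switch(direction, both = union(signature$up, signature$down),
           up = signature$up, down = signature$down)
  } else as.character(signature)
  if (!length(genes)) stop("empty signature", call. = FALSE)
  outside <- setdiff(genes, gsc$universe)
  if (length(outside)) {
    warning(length(outside), " signature gene(s) outside the universe dropped")
    genes <- intersect(genes, gsc$universe)
  }
  if (!length(genes))
    stop("no signature gene lies in the universe", call. = FALSE)
  N <- length(gsc$universe)
  n <- length(genes)
  rows <- lapply(names(gsc$sets), function(nm) {
    set <- gsc$sets[[nm]]
    K <- length(set)
    k <- length(intersect(set, genes))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p, out$set), , drop = FALSE]
}

#' Local co-expression network over a gene subset
#'
#' A stand-in for web-service association networks: nodes are genes,
#' with an undirected edge wherever the absolute Pearson correlation of
#' the two genes' expression across samples reaches `r_threshold`.
#' Zero-variance genes are excluded with a warning.
#'
#' @param x an [expr_matrix] with at least 3 samples.
#' @param genes symbols to include as candidate nodes.
#' @param r_threshold absolute-correlation cut in (0, 1].
#' @return list of class `coexpression_network`: `nodes`, `edges`
#'   (`data.frame` `from`, `to`, `weight`), `r_threshold`.
#' @export
coexpression_network <- function(x, genes, r_threshold = 0.8) {
  if (r_threshold <= 0 || r_threshold > 1)
    stop("r_threshold must lie in (0, 1]", call. = FALSE)
  if (ncol(x$values) < 3L) stop("need >= 3 samples", call. = FALSE)
  missing <- setdiff(genes, rownames(x$values))
  if (length(missing))
    stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  v <- x$values[genes, , drop = FALSE]
  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance gene(s) excluded: ",
            paste(genes[sds == 0], collapse = ", "))
    v <- v[sds > 0, , drop = FALSE]
  }
  nodes <- rownames(v)
  edges <- data.frame(from = character(0), to = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE)
  if (length(nodes) >= 2L) {
    r <- abs(stats::cor(t(v)))
    idx <- which(upper.tri(r) & r >= r_threshold, arr.ind = TRUE)
    if (nrow(idx)) {
      edges <- data.frame(from = nodes[idx[, 1L]], to = nodes[idx[, 2L]],
                          weight = r[idx], stringsAsFactors = FALSE)
      edges <- edges[order(edges$from, edges$to), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  structure(list(nodes = nodes, edges = edges, r_threshold = r_threshold),
            class = "coexpression_network")
}

#' Write a co-expression network
#'
#' Edge-list TSV (`from`, `to`, `weight`) and, optionally, GraphML via
#' igraph.
#'
#' @param net a `coexpression_network`.
#' @param path output file.
#' @param format `"tsv"` or `"graphml"`.
#' @export
write_network <- function(net, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Export a signature as a STRING multi-protein query list
#'
#' Writes the signature's symbols one per line, ready to paste into the
#' STRING web form; no network retrieval is performed.
#'
#' @param signature a `signature_set` or character vector of symbols.
#' @param path output file.
#' @param direction for a `signature_set`: which genes to export.
#' @export
export_string_query <- function(signature, path,
                                direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  genes <- if (inherits(signature, "signature_set")) {
    switch(direction, both = c(signature$up, signature$down),
           up = signature$up, down = signature$down)
  } else as.character(signature)
  if (!length(genes)) stop("empty signature", call. = FALSE)
  writeLines(genes, path)
  invisible(path)
}
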