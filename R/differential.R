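#' Per-group mean expression
#'
#' Averages replicate columns within each (cell type, timepoint) sample
#' group, yielding the "density of gene expression" table that all fold
#' computations work from. Group labels are the cell type with the
#' timepoint appended when one is recorded (e.g. `TC5`, `TC10`, `MSC`).
#'
#' @param x gene-level linear [expr_matrix].
#' @param meta sample metadata `data.frame` (see [read_sample_metadata()]).
#' @return a numeric matrix, genes x groups, with attribute `"groups"`
#'   mapping group label to cell type / timepoint.
#' @export
group_means <- function(x, meta) {
  check_metadata_covers(x, meta)
  meta <- meta[match(colnames(x$values), meta$sample_id), ]
  label <- paste0(meta$cell_type,
                  ifelse(nzchar(meta$timepoint), meta$timepoint, ""))
  groups <- unique(label)
  out <- vapply(groups, function(g) {
    cols <- which(label == g)
    if (!length(cols)) stop("sample group '", g, "' has zero columns",
                            call. = FALSE)
    rowMeans(x$values[, cols, drop = FALSE])
  }, numeric(nrow(x$values)))
  dimnames(out) <- list(rownames(x$values), groups)
  attr(out, "groups") <- unique(data.frame(
    group = label, cell_type = meta$cell_type, timepoint = meta$timepoint,
    stringsAsFactors = FALSE))
  out
}

#' Signed relative-difference fold statistic
#'
#' The per-gene fold between a focal group mean `a` and another group's
#' mean `b`. With pseudocount `eps` guarding zeros (`a' = a + eps`,
#' `b' = b + eps`), the default `"symmetric"` variant is
#' `+(a' - b') / b'` when `a' >= b'` and `-(b' - a') / a'` otherwise: the
#' relative difference taken over the smaller side, so that "up-regulated
#' more than onefold" (`f > 1`) is exactly a greater-than-twofold ratio,
#' and `fold(a, b) == -fold(b, a)`. The `"literal"` variant
#' `(a' - b') / a'` (difference over the focal mean) is retained for
#' comparison; note it is bounded above by 1 and cannot satisfy an
#' up-threshold of 1.
#'
#' @param a,b non-negative group means (vectorized).
#' @param eps pseudocount, strictly positive; default 1 linear intensity
#'   unit.
#' @param variant `"symmetric"` (default) or `"literal"`.
#' @return signed fold value(s); positive means up in the focal group.
#' @export
fold_change <- function(a, b, eps = 1, variant = c("symmetric", "literal")) {
  variant <- match.arg(variant)
  if (eps <= 0) stop("pseudocount eps must be > 0", call. = FALSE)
  ap <- a + eps
  bp <- b + eps
  if (variant == "literal") return((ap - bp) / ap)
  ifelse(ap >= bp, (ap - bp) / bp, -(bp - ap) / ap)
}

#' Fold tables for every focal-vs-other group pair
#'
#' @param gm group mean matrix from [group_means()].
#' @param focal_groups group labels of the focal cell type (one per
#'   timepoint, e.g. `c("TC5", "TC10")`).
#' @param other_groups labels of the comparison groups.
#' @param eps pseudocount passed to [fold_change()].
#' @param variant fold variant passed to [fold_change()].
#' @return list of `fold_table` objects, one per ordered (focal, other)
#'   pair in `focal_groups` x `other_groups` order; each is a `data.frame`
#'   (`gene`, `fold`) with attributes `focal`, `other` and `eps`.
#' @export
pairwise_fold_tables <- function(gm, focal_groups, other_groups, eps = 1,
                                 variant = c("symmetric", "literal")) {
  variant <- match.arg(variant)
  missing <- setdiff(c(focal_groups, other_groups), colnames(gm))
  if (length(missing))
    stop("group(s) absent from group means: ",
         paste(missing, collapse = ", "), call. = FALSE)
  overlap <- intersect(focal_groups, other_groups)
  if (length(overlap))
    stop("focal and other group sets overlap: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  tables <- list()
  for (f in focal_groups) {
    for (o in other_groups) {
      tab <- data.frame(gene = rownames(gm),
                        fold = fold_change(gm[, f], gm[, o], eps = eps,
                                           variant = variant),
                        row.names = NULL, stringsAsFactors = FALSE)
      attr(tab, "focal") <- f
      attr(tab, "other") <- o
      attr(tab, "eps") <- eps
      class(tab) <- c("fold_table", "data.frame")
      tables[[paste(f, "vs", o)]] <- tab
    }
  }
  tables
}

#' Multi-threshold up/down count table
#'
#' Counts genes exceeding each fold threshold (strict `>`) per comparison
#' and direction, in the layout of the published summary tables: one row
#' per `FOCAL vs OTHER` pair plus, when two focal timepoint groups are
#' present, a combined `<cell type>s vs OTHER` row counting only genes
#' that pass in both timepoints.
#'
#' @param tables list of fold tables from [pairwise_fold_tables()].
#' @param thresholds fold thresholds; default `c(1, 2, 5, 10)`.
#' @param combined_label label stem for the combined rows; default `"TCs"`.
#' @return a `data.frame` with columns `comparison`, then `up_gt_<t>` and
#'   `down_gt_<t>` for each threshold.
#' @export
threshold_counts <- function(tables, thresholds = c(1, 2, 5, 10),
                             combined_label = "TCs") {
  if (!length(tables)) stop("no fold tables supplied", call. = FALSE)
  focal <- vapply(tables, attr, "", "focal")
  other <- vapply(tables, attr, "", "other")
  rows <- list()
  count_row <- function(comparison, up_pass, down_pass) {
    r <- c(list(comparison = comparison),
           stats::setNames(as.list(colSums(up_pass)),
                           paste0("up_gt_", thresholds)),
           stats::setNames(as.list(colSums(down_pass)),
                           paste0("down_gt_", thresholds)))
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)
  }
  pass_mats <- function(tab) {
    up <- vapply(thresholds, function(t) tab$fold > t,
                 logical(nrow(tab)))
    down <- vapply(thresholds, function(t) tab$fold < -t,
                   logical(nrow(tab)))
    list(up = matrix(up, ncol = length(thresholds)),
         down = matrix(down, ncol = length(thresholds)))
  }
  for (o in unique(other)) {
    idx <- which(other == o)
    per_focal <- lapply(idx, function(i) pass_mats(tables[[i]]))
    for (k in seq_along(idx)) {
      rows[[length(rows) + 1L]] <-
        count_row(paste(focal[idx[k]], "vs", o),
                  per_focal[[k]]$up, per_focal[[k]]$down)
    }
    if (length(idx) > 1L) {
      up_all <- Reduce(`&`, lapply(per_focal, `[[`, "up"))
      down_all <- Reduce(`&`, lapply(per_focal, `[[`, "down"))
      rows[[length(rows) + 1L]] <-
        count_row(paste(combined_label, "vs", o), up_all, down_all)
    }
  }
  do.call(rbind, rows)
}

#' Write fold tables or count summaries as TSV
#'
#' @param x a `fold_table` or the `data.frame` from [threshold_counts()].
#' @param path output file.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
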