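#' Quantile normalization
#'
#' Forces every sample column to share one empirical distribution: the
#' row-wise mean of the column-sorted input. Values tied within a column
#' receive the mean of the quantile targets their ranks span, which keeps
#' the operation deterministic and preserves each column's sum of targets.
#' Row and column ids are untouched; idempotent.
#'
#' @param x an [expr_matrix] with at least two columns and no missing
#'   values.
#' @return the normalized [expr_matrix] (same scale/level flags).
#' @export
quantile_normalize <- function(x) {
  v <- x$values
  if (ncol(v) < 2L)
    stop("quantile normalization needs >= 2 columns (nothing to normalize against)",
         call. = FALSE)
  target <- rowMeans(apply(v, 2L, sort, method = "quick"))
  out <- v
  for (j in seq_len(ncol(v))) {
    col <- v[, j]
    q <- numeric(length(col))
    q[order(col)] <- target
    # ties: average the spanned quantile targets
    out[, j] <- stats::ave(q, match(col, col), FUN = mean)
  }
  replace_values(x, out)
}

#' Median-polish summarization of a probe block
#'
#' Fits the additive model `value ~ overall + probe + sample` to a log2
#' probe-by-sample block by alternating median sweeps over rows and
#' columns, and returns `overall + sample effect` as the gene's per-sample
#' log2 value — the summarization step of the RMA algorithm. Iteration
#' stops when the largest absolute change in the fitted residuals falls
#' below `tol` or after `max_iter` sweeps.
#'
#' @param block numeric matrix (probes x samples) on log2 scale, or an
#'   [expr_matrix] restricted to one symbol.
#' @param tol convergence tolerance on the residual sweep, default `1e-8`.
#' @param max_iter maximum number of sweep iterations, default 100.
#' @return named numeric vector of per-sample log2 summaries.
#' @export
median_polish_summarize <- function(block, tol = 1e-8, max_iter = 100L) {
  if (inherits(block, "expr_matrix")) block <- block$values
  block <- as.matrix(block)
  if (!all(is.finite(block)))
    stop("median polish requires finite inputs", call. = FALSE)
  if (nrow(block) == 1L) {
    out <- block[1L, ]
    names(out) <- colnames(block)
    return(out)
  }
  overall <- 0
  row_eff <- numeric(nrow(block))
  col_eff <- numeric(ncol(block))
  resid <- block
  for (iter in seq_len(max_iter)) {
    old <- resid
    rdelta <- apply(resid, 1L, stats::median)
    resid <- resid - rdelta
    row_eff <- row_eff + rdelta
    delta <- stats::median(col_eff)
    col_eff <- col_eff - delta
    overall <- overall + delta
    cdelta <- apply(resid, 2L, stats::median)
    resid <- sweep(resid, 2L, cdelta)
    col_eff <- col_eff + cdelta
    delta <- stats::median(row_eff)
    row_eff <- row_eff - delta
    overall <- overall + delta
    if (max(abs(resid - old)) < tol) break
  }
  out <- overall + col_eff
  names(out) <- colnames(block)
  out
}

#' Housekeeping specification
#'
#' Names the housekeeping gene rows (matrix H) and the reference samples
#' whose scale is held fixed during cross-dataset harmonization.
#'
#' @param housekeeping character vector of housekeeping gene symbols.
#' @param reference_samples character vector of sample ids whose scale
#'   factor is pinned to 1.
#' @return a list of class `housekeeping_spec`.
#' @export
housekeeping_spec <- function(housekeeping, reference_samples) {
  if (!length(housekeeping))
    stop("housekeeping set must be non-empty", call. = FALSE)
  if (!length(reference_samples))
    stop("reference sample set must be non-empty", call. = FALSE)
  structure(list(housekeeping = as.character(housekeeping),
                 reference_samples = as.character(reference_samples)),
            class = "housekeeping_spec")
}

#' Housekeeping-gene scaling across datasets
#'
#' Harmonizes samples from different platforms on the assumption that a
#' designated housekeeping set is equally expressed everywhere. With B the
#' full linear matrix and H its housekeeping rows: `Y_j` is the mean of
#' column j over H; `C` is the mean of `Y_j` over the reference samples;
#' the scale factor is `Z_j = 1` for reference samples and `Y_j / C`
#' otherwise; the rescaled matrix is `E_ij = B_ij / Z_j`. Afterwards every
#' non-reference column's housekeeping mean equals `C` exactly and the
#' reference columns are unchanged; within-column gene ratios are never
#' altered.
#'
#' @param x linear-scale [expr_matrix].
#' @param spec a [housekeeping_spec()].
#' @return list with `matrix` (the rescaled [expr_matrix] E) and `report`,
#'   a `data.frame` (`sample_id`, `Y`, `Z`, `is_reference`) carrying `C` as
#'   attribute `"C"`.
#' @export
housekeeping_scale <- function(x, spec) {
  stopifnot(inherits(spec, "housekeeping_spec"))
  if (x$scale != "linear")
    stop("housekeeping_scale operates on the linear scale", call. = FALSE)
  v <- x$values
  absent <- setdiff(spec$housekeeping, rownames(v))
  if (length(absent))
    stop("housekeeping symbol(s) absent from matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  absent <- setdiff(spec$reference_samples, colnames(v))
  if (length(absent))
    stop("reference sample(s) absent from matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  H <- v[spec$housekeeping, , drop = FALSE]
  Y <- colMeans(H)
  if (any(Y == 0))
    stop("housekeeping mean is zero for sample(s): ",
         paste(colnames(v)[Y == 0], collapse = ", "), call. = FALSE)
  is_ref <- colnames(v) %in% spec$reference_samples
  C <- mean(Y[is_ref])
  Z <- Y / C
  Z[is_ref] <- 1
  E <- sweep(v, 2L, Z, "/")
  report <- data.frame(sample_id = colnames(v), Y = Y, Z = Z,
                       is_reference = is_ref, row.names = NULL,
                       stringsAsFactors = FALSE)
  attr(report, "C") <- C
  list(matrix = replace_values(x, E), report = report)
}

#' Write a scaling report as TSV
#'
#' @param report the `report` element of [housekeeping_scale()].
#' @param path output file.
#' @export
write_scaling_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
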