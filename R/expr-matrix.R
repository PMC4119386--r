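#' Expression matrix container
#'
#' A light container for a genes/probes x samples abundance table carrying
#' two flags that the rest of the pipeline dispatches on: the measurement
#' scale (`"linear"` intensities, all non-negative, or real-valued `"log2"`)
#' and the row level (`"probe"` before summarization, `"gene"` after).
#'
#' @param values numeric matrix with unique row and column names.
#' @param scale `"linear"` or `"log2"`.
#' @param level `"probe"` or `"gene"`.
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `scale` and `level`.
#' @examples
#' m <- expr_matrix(matrix(1:6, 3, 2,
#'   dimnames = list(c("a", "b", "c"), c("s1", "s2"))))
#' dim(m)
#' @export
expr_matrix <- function(values, scale = c("linear", "log2"),
                        level = c("gene", "probe")) {
  scale <- match.arg(scale)
  level <- match.arg(level)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  x <- structure(list(values = values, scale = scale, level = level),
                 class = "expr_matrix")
  validate_expr_matrix(x)
  x
}

validate_expr_matrix <- function(x) {
  v <- x$values
  if ((nrow(v) > 0L && is.null(rownames(v))) ||
      (ncol(v) > 0L && is.null(colnames(v))))
    stop("expression matrix must have row and column names", call. = FALSE)
  dup <- rownames(v)[duplicated(rownames(v))]
  if (length(dup))
    stop("duplicate row id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  dup <- colnames(v)[duplicated(colnames(v))]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (anyNA(v))
    stop("expression matrix contains missing values (row ",
         rownames(v)[which(rowSums(is.na(v)) > 0)[1]], ")", call. = FALSE)
  if (!all(is.finite(v)))
    stop("expression matrix contains non-finite values", call. = FALSE)
  if (x$scale == "linear" && any(v < 0))
    stop("negative values in a linear-scale matrix (row ",
         rownames(v)[which(rowSums(v < 0) > 0)[1]], ")", call. = FALSE)
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
dimnames.expr_matrix <- function(x) dimnames(x$values)

#' @export
as.matrix.expr_matrix <- function(x, ...) x$values

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d %s(s) x %d sample(s), %s scale\n",
              nrow(x$values), x$level, ncol(x$values), x$scale))
  invisible(x)
}

# rebuild with new values, keeping flags unless overridden
replace_values <- function(x, values, scale = x$scale, level = x$level) {
  expr_matrix(values, scale = scale, level = level)
}

#' Convert an expression matrix between linear and log2 scale
#'
#' @param x an [expr_matrix].
#' @param scale target scale.
#' @param pseudocount added before taking log2 (linear -> log2 only) to
#'   guard exact zeros; default 0.
#' @return an [expr_matrix] on the requested scale.
#' @export
convert_scale <- function(x, scale = c("linear", "log2"), pseudocount = 0) {
  scale <- match.arg(scale)
  if (x$scale == scale) return(x)
  v <- if (scale == "log2") log2(x$values + pseudocount) else 2^x$values
  replace_values(x, v, scale = scale)
}
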