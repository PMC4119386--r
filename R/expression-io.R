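#' Read an expression table
#'
#' Reads a genes/probes x samples table into an [expr_matrix]. Two dialects
#' are supported: `plain_tsv` (header row of sample ids, first column the
#' row id) and `geo_series_matrix`, the NCBI GEO series-matrix layout in
#' which metadata lines begin with `!` and the numeric table sits between
#' the `!series_matrix_table_begin` and `!series_matrix_table_end` markers.
#'
#' @param path file to read.
#' @param dialect `"plain_tsv"` or `"geo_series_matrix"`.
#' @param scale,level flags recorded on the returned matrix.
#' @return an [expr_matrix].
#' @export
read_expression_table <- function(path,
                                  dialect = c("plain_tsv", "geo_series_matrix"),
                                  scale = c("linear", "log2"),
                                  level = c("probe", "gene")) {
  dialect <- match.arg(dialect)
  scale <- match.arg(scale)
  level <- match.arg(level)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "geo_series_matrix") {
    lines <- readLines(path)
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(beg) != 1L || length(end) != 1L || end <= beg)
      stop("malformed series matrix: table begin/end markers not found in ",
           path, call. = FALSE)
    body <- lines[(beg + 1L):(end - 1L)]
    body <- gsub('"', "", body, fixed = TRUE)
    tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                             check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
  }
  if (ncol(tab) < 2L)
    stop("expression table needs a row-id column plus at least one sample: ",
         path, call. = FALSE)
  ids <- as.character(tab[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    line <- which(duplicated(ids))[1L] + 1L  # +1 for the header line
    stop(sprintf("duplicated row id '%s' (line %d of table body) in %s",
                 dup[1L], line, path), call. = FALSE)
  }
  v <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(v)) {
    bad <- which(!vapply(tab[-1L], is.numeric, logical(1L)))[1L]
    stop("non-numeric sample column '", colnames(tab)[-1L][bad], "' in ",
         path, call. = FALSE)
  }
  if (anyNA(v)) {
    line <- which(rowSums(is.na(v)) > 0)[1L] + 1L
    stop(sprintf("missing value at table line %d of %s", line, path),
         call. = FALSE)
  }
  if (scale == "linear" && any(v < 0)) {
    line <- which(rowSums(v < 0) > 0)[1L] + 1L
    stop(sprintf("negative linear intensity at table line %d of %s",
                 line, path), call. = FALSE)
  }
  rownames(v) <- ids
  expr_matrix(v, scale = scale, level = level)
}

#' Write an expression table
#'
#' Emits the same dialects [read_expression_table()] accepts, so a
#' write-then-read round trip reproduces the in-memory matrix.
#'
#' @param x an [expr_matrix].
#' @param path output file.
#' @param dialect `"plain_tsv"` or `"geo_series_matrix"`.
#' @param id_column header of the row-id column.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path, dialect = c("plain_tsv",
                                                        "geo_series_matrix"),
                                   id_column = "ID_REF") {
  dialect <- match.arg(dialect)
  tab <- data.frame(rownames(x$values), x$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(tab)[1L] <- id_column
  con <- file(path, "w")
  on.exit(close(con))
  if (dialect == "geo_series_matrix") {
    writeLines(c("!Series_title\t\"synthetic export\"",
                 "!series_matrix_table_begin"), con)
  }
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  if (dialect == "geo_series_matrix")
    writeLines("!series_matrix_table_end", con)
  invisible(path)
}

#' Read / write a probe annotation table
#'
#' Tab-delimited with columns `probe_id`, `symbol`, `chromosome`. Empty
#' strings in `symbol` or `chromosome` mean "not annotated".
#'
#' @param path file to read or write.
#' @return a `data.frame` with one record per probe id.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("probe_id", "symbol", "chromosome")
  if (!all(need %in% colnames(ann)))
    stop("annotation must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  ann[is.na(ann)] <- ""
  dup <- unique(ann$probe_id[duplicated(ann$probe_id)])
  if (length(dup))
    stop("duplicate probe id(s) in annotation: ",
         paste(utils::head(dup, 3), collapse = ", "), call. = FALSE)
  ann[, need]
}

#' @rdname read_annotation
#' @param ann annotation `data.frame`.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the sample metadata table
#'
#' Tab-delimited with columns `sample_id`, `cell_type`, `timepoint`,
#' `dataset`. An empty `timepoint` means the cell type was observed once.
#'
#' @param path file to read or write.
#' @return a `data.frame`, one record per sample.
#' @export
read_sample_metadata <- function(path) {
  meta <- utils::read.delim(path, colClasses = "character",
                            check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "cell_type", "timepoint", "dataset")
  if (!all(need %in% colnames(meta)))
    stop("metadata must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  meta[is.na(meta)] <- ""
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample id(s) in metadata", call. = FALSE)
  meta[, need]
}

#' @rdname read_sample_metadata
#' @param meta metadata `data.frame`.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_metadata_covers <- function(x, meta) {
  missing <- setdiff(colnames(x$values), meta$sample_id)
  if (length(missing))
    stop("sample(s) missing from metadata: ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Keep only probes with an official symbol
#'
#' The first filter of the pipeline: probe rows whose annotation record has
#' an empty official symbol are discarded. Row order is preserved and the
#' operation is idempotent.
#'
#' @param x probe-level [expr_matrix].
#' @param ann annotation `data.frame` (see [read_annotation()]).
#' @return the filtered [expr_matrix].
#' @export
filter_to_annotated <- function(x, ann) {
  if (x$level != "probe")
    stop("filter_to_annotated expects a probe-level matrix", call. = FALSE)
  sym <- annotation_lookup(ann, rownames(x$values))$symbol
  keep <- !is.na(sym) & nzchar(sym)
  if (!any(keep))
    message("filter_to_annotated: no annotated probes remain")
  replace_values(x, x$values[keep, , drop = FALSE])
}

annotation_lookup <- function(ann, ids) {
  idx <- match(ids, ann$probe_id)
  data.frame(probe_id = ids,
             symbol = ifelse(is.na(idx), "", ann$symbol[idx]),
             chromosome = ifelse(is.na(idx), "", ann$chromosome[idx]),
             stringsAsFactors = FALSE)
}

#' Collapse probe rows to one row per gene symbol
#'
#' Many-to-one probe-to-gene maps are resolved either by the per-sample
#' arithmetic mean of the probe rows (`method = "mean"`, the default) or by
#' median-polish summarization on log2 scale (`method = "median_polish"`,
#' the RMA summarization rule), converting back to the input scale
#' afterwards. Output rows are ordered by first occurrence of each symbol.
#'
#' @param x probe-level [expr_matrix], all rows annotated.
#' @param ann annotation `data.frame`.
#' @param method `"mean"` or `"median_polish"`.
#' @return a gene-level [expr_matrix] whose row ids are official symbols.
#' @export
collapse_probes_to_genes <- function(x, ann, method = c("mean",
                                                        "median_polish")) {
  method <- match.arg(method)
  if (x$level != "probe")
    stop("collapse_probes_to_genes expects a probe-level matrix",
         call. = FALSE)
  sym <- annotation_lookup(ann, rownames(x$values))$symbol
  if (any(!nzchar(sym)))
    stop("unannotated probe(s) present; run filter_to_annotated first",
         call. = FALSE)
  symbols <- unique(sym)  # first-occurrence order
  v <- x$values
  out <- matrix(NA_real_, length(symbols), ncol(v),
                dimnames = list(symbols, colnames(v)))
  for (s in symbols) {
    block <- v[sym == s, , drop = FALSE]
    if (nrow(block) == 1L) {
      out[s, ] <- block
    } else if (method == "mean") {
      out[s, ] <- colMeans(block)
    } else {
      logblock <- if (x$scale == "linear") log2(block) else block
      fit <- median_polish_summarize(logblock)
      out[s, ] <- if (x$scale == "linear") 2^fit else fit
    }
  }
  replace_values(x, out, level = "gene")
}

#' Restrict a gene-level matrix to one chromosome
#'
#' @param x gene-level [expr_matrix] (row ids are official symbols).
#' @param ann annotation `data.frame`; symbols are looked up through it.
#' @param chromosome chromosome label, e.g. `"1"`.
#' @return the restricted [expr_matrix]; row order preserved.
#' @export
restrict_to_chromosome <- function(x, ann, chromosome) {
  if (x$level != "gene")
    stop("restrict_to_chromosome expects a gene-level matrix", call. = FALSE)
  available <- sort(unique(ann$chromosome[nzchar(ann$chromosome)]))
  if (!chromosome %in% available)
    stop("chromosome '", chromosome, "' not present in annotation; ",
         "available: ", paste(available, collapse = ", "), call. = FALSE)
  chr_of <- ann$chromosome[match(rownames(x$values), ann$symbol)]
  keep <- !is.na(chr_of) & chr_of == chromosome
  if (!any(keep))
    warning("no genes of the matrix lie on chromosome ", chromosome)
  replace_values(x, x$values[keep, , drop = FALSE])
}
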