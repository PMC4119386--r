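#' Pipeline configuration
#'
#' Bundles every choice of the end-to-end analysis: the input (a
#' [synthetic_config()] or paths to the three tables), the focal cell
#' type and its timepoint labels, the chromosome restriction, the
#' housekeeping specification, the fold statistic settings, the signature
#' rule, clustering and network parameters, and the output directory.
#' Every choice the underlying study left ambiguous surfaces here as a
#' named key with a documented default.
#'
#' @param synthetic a [synthetic_config()], or `NULL` when reading files.
#' @param input named list of paths (`matrix`, `annotation`, `metadata`)
#'   when `synthetic` is `NULL`; `matrix_dialect` selects the reader.
#' @param matrix_dialect `"plain_tsv"` or `"geo_series_matrix"`.
#' @param focal_type,timepoints focal cell type and its two timepoints.
#' @param other_groups comparison group labels; default: every non-focal
#'   sample group found in the metadata.
#' @param chromosome chromosome restriction label.
#' @param housekeeping `"auto"` (synthetic input only: use the generator's
#'   housekeeping set with the first dataset as reference), `NULL` to skip
#'   scaling, or a [housekeeping_spec()].
#' @param collapse_method probe collapse rule, `"mean"` or
#'   `"median_polish"`.
#' @param quantile_normalize quantile-normalize within each dataset block
#'   before cross-dataset scaling; default `TRUE`.
#' @param eps fold pseudocount.
#' @param fold_variant `"symmetric"` or `"literal"` (see [fold_change()]).
#' @param thresholds strictly increasing fold thresholds for the count
#'   table.
#' @param signature_threshold fold threshold of the specific signature.
#' @param timepoint_rule `"both"` or `"either"`.
#' @param top_k k of the per-comparison top-gene lists.
#' @param linkage clustering linkage.
#' @param r_threshold co-expression network |r| cut.
#' @param gene_sets optional path to a GMT file for enrichment.
#' @param outdir output directory.
#' @param seed integer seed forwarded to the generator.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            input = NULL,
                            matrix_dialect = "plain_tsv",
                            focal_type = "TC",
                            timepoints = c("5", "10"),
                            other_groups = NULL,
                            chromosome = "1",
                            housekeeping = "auto",
                            collapse_method = "mean",
                            quantile_normalize = TRUE,
                            eps = 1,
                            fold_variant = "symmetric",
                            thresholds = c(1, 2, 5, 10),
                            signature_threshold = 1,
                            timepoint_rule = "both",
                            top_k = 100L,
                            linkage = "average",
                            r_threshold = 0.8,
                            gene_sets = NULL,
                            outdir = tempfile("telosig_run_"),
                            seed = 1L) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  fail <- function(...) stop("invalid pipeline_config: ", ..., call. = FALSE)
  if (is.null(cfg$synthetic) && is.null(cfg$input))
    fail("either a synthetic config or input paths are required")
  if (!is.null(cfg$synthetic) && !inherits(cfg$synthetic, "synthetic_config"))
    fail("synthetic must be a synthetic_config")
  if (is.unsorted(cfg$thresholds, strictly = TRUE))
    fail("thresholds must be strictly increasing")
  focal_groups <- paste0(cfg$focal_type, cfg$timepoints)
  if (!is.null(cfg$other_groups)) {
    overlap <- intersect(focal_groups, cfg$other_groups)
    if (length(overlap))
      fail("focal and other group sets overlap: ",
           paste(overlap, collapse = ", "))
  }
  if (length(cfg$timepoints) != 2L)
    fail("exactly two focal timepoints are expected")
  if (cfg$eps <= 0) fail("eps must be > 0")
  if (cfg$top_k < 1) fail("top_k must be >= 1")
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a
#' `synthetic:` mapping is forwarded to [synthetic_config()] and a
#' `housekeeping:` mapping with `symbols` and `reference_samples` becomes
#' a [housekeeping_spec()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic))
    y$synthetic <- do.call(synthetic_config, y$synthetic)
  if (is.list(y$housekeeping))
    y$housekeeping <- housekeeping_spec(y$housekeeping$symbols,
                                        y$housekeeping$reference_samples)
  do.call(pipeline_config, y)
}

run_stage <- function(name, code) {
  tryCatch(code, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/ingest, annotation filtering, probe collapse,
#' within-dataset quantile normalization, cross-dataset housekeeping
#' scaling, chromosome restriction, group means, pairwise folds,
#' multi-threshold counts, the specific signature, top-k lists, sample
#' clustering over the union of differential genes, optional gene-set
#' enrichment, the co-expression network, and file export. Identical
#' configuration and seed give byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory results (`matrix`,
#'   `group_means`, `tables`, `counts`, `signature`, `dendrogram`,
#'   `scaling_report`, `truth` when synthetic) and `manifest`, the
#'   run record also written to `manifest.json`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_pipeline_config(config)
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  dims_log <- list()
  outputs <- character(0)
  note <- function(stage, x) {
    stages <<- c(stages, stage)
    if (inherits(x, "expr_matrix"))
      dims_log[[stage]] <<- paste0(nrow(x$values), " x ", ncol(x$values))
  }
  out_path <- function(name, file) {
    outputs[[name]] <<- file.path(outdir, file)
    outputs[[name]]
  }

  truth <- NULL
  if (!is.null(cfg$synthetic)) {
    syn <- cfg$synthetic
    syn$seed <- as.integer(cfg$seed)
    data <- run_stage("simulate", generate_dataset(syn))
    truth <- data$truth
    note("simulate", data$matrix)
  } else {
    data <- run_stage("ingest", list(
      matrix = read_expression_table(cfg$input$matrix,
                                     dialect = cfg$matrix_dialect),
      annotation = read_annotation(cfg$input$annotation),
      metadata = read_sample_metadata(cfg$input$metadata)))
    note("ingest", data$matrix)
  }
  ann <- data$annotation
  meta <- data$metadata

  m <- run_stage("filter_to_annotated",
                 filter_to_annotated(data$matrix, ann))
  note("filter_to_annotated", m)
  m <- run_stage("collapse_probes_to_genes",
                 collapse_probes_to_genes(m, ann, cfg$collapse_method))
  note("collapse_probes_to_genes", m)

  if (isTRUE(cfg$quantile_normalize)) {
    m <- run_stage("quantile_normalize_within_dataset", {
      check_metadata_covers(m, meta)
      v <- m$values
      for (ds in unique(meta$dataset)) {
        cols <- meta$sample_id[meta$dataset == ds]
        cols <- intersect(colnames(v), cols)
        if (length(cols) >= 2L) {
          sub <- replace_values(m, v[, cols, drop = FALSE])
          v[, cols] <- quantile_normalize(sub)$values
        }
      }
      replace_values(m, v)
    })
    note("quantile_normalize_within_dataset", m)
  }

  scaling_report <- NULL
  hk <- cfg$housekeeping
  if (identical(hk, "auto")) {
    if (is.null(truth))
      stop("housekeeping = 'auto' requires synthetic input", call. = FALSE)
    ref <- meta$sample_id[meta$dataset == meta$dataset[1L]]
    hk <- housekeeping_spec(truth$housekeeping_genes, ref)
  }
  if (!is.null(hk)) {
    scaled <- run_stage("housekeeping_scale", housekeeping_scale(m, hk))
    m <- scaled$matrix
    scaling_report <- scaled$report
    write_scaling_report(scaling_report,
                         out_path("scaling_report", "scaling_report.tsv"))
    note("housekeeping_scale", m)
  }

  chr <- run_stage("restrict_to_chromosome",
                   restrict_to_chromosome(m, ann, cfg$chromosome))
  note("restrict_to_chromosome", chr)

  gm <- run_stage("group_means", group_means(chr, meta))
  focal_groups <- paste0(cfg$focal_type, cfg$timepoints)
  other_groups <- cfg$other_groups
  if (is.null(other_groups))
    other_groups <- setdiff(colnames(gm), focal_groups)
  tables <- run_stage("pairwise_fold_tables",
                      pairwise_fold_tables(gm, focal_groups, other_groups,
                                           eps = cfg$eps,
                                           variant = cfg$fold_variant))
  note("pairwise_fold_tables", NULL)

  counts <- run_stage("threshold_counts",
                      threshold_counts(tables, cfg$thresholds,
                                       combined_label =
                                         paste0(cfg$focal_type, "s")))
  write_tsv_table(counts, out_path("counts", "threshold_counts.tsv"))
  note("threshold_counts", NULL)

  sig <- run_stage("specific_signature",
                   specific_signature(tables, cfg$signature_threshold,
                                      cfg$timepoint_rule))
  write_signature(sig, tables, out_path("signature", "signature.tsv"))
  if (length(sig$up) + length(sig$down) > 0)
    export_string_query(sig, out_path("string_query", "string_query.txt"))
  note("specific_signature", NULL)

  topk <- run_stage("top_k_genes", {
    do.call(rbind, lapply(names(tables), function(nm) {
      tab <- tables[[nm]]
      do.call(rbind, lapply(c("up", "down"), function(dir) {
        g <- top_k_genes(tab, cfg$top_k, dir)
        if (!length(g)) return(NULL)
        data.frame(comparison = nm, direction = dir,
                   rank = seq_along(g), symbol = g,
                   fold = tab$fold[match(g, tab$gene)],
                   stringsAsFactors = FALSE)
      }))
    }))
  })
  write_tsv_table(topk, out_path("top_k", "top_k_genes.tsv"))
  note("top_k_genes", NULL)

  diff_genes <- unique(unlist(lapply(tables, function(tab)
    tab$gene[abs(tab$fold) > cfg$signature_threshold])))
  dend <- NULL
  if (length(diff_genes) >= 2L) {
    dend <- run_stage("hierarchical_cluster", {
      logm <- convert_scale(chr, "log2", pseudocount = 1)
      d <- pearson_dissimilarity(logm, rows = diff_genes)
      hierarchical_cluster(d, linkage = cfg$linkage)
    })
    write_dendrogram_newick(dend, out_path("dendrogram", "dendrogram.nwk"))
    note("hierarchical_cluster", NULL)
  }

  enrichment <- NULL
  if (!is.null(cfg$gene_sets) &&
      length(sig$up) + length(sig$down) > 0) {
    enrichment <- run_stage("hypergeometric_enrichment", {
      gsc <- read_gmt(cfg$gene_sets, universe = rownames(chr$values))
      hypergeometric_enrichment(sig, gsc)
    })
    write_tsv_table(enrichment, out_path("enrichment", "enrichment.tsv"))
    note("hypergeometric_enrichment", NULL)
  }

  network <- NULL
  sig_genes <- c(sig$up, sig$down)
  if (length(sig_genes) >= 2L) {
    network <- run_stage("coexpression_network",
                         coexpression_network(chr, sig_genes,
                                              cfg$r_threshold))
    write_network(network, out_path("network_tsv", "network_edges.tsv"))
    write_network(network, out_path("network_graphml", "network.graphml"),
                  format = "graphml")
    note("coexpression_network", NULL)
  }

  manifest <- list(
    package = "telosig",
    version = as.character(utils::packageVersion("telosig")),
    seed = as.integer(cfg$seed),
    stage_order = stages,
    dimensions = dims_log,
    outputs = as.list(stats::setNames(basename(unlist(outputs)),
                                      names(outputs))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(matrix = chr, group_means = gm, tables = tables,
                 counts = counts, signature = sig, dendrogram = dend,
                 scaling_report = scaling_report, enrichment = enrichment,
                 network = network, truth = truth, manifest = manifest,
                 outdir = outdir))
}
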