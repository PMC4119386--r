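#' Configuration for the synthetic expression generator
#'
#' Describes a multi-cell-type microarray collection with one focal cell
#' type observed at two culture timepoints, a designated housekeeping set,
#' per-dataset multiplicative batch scale, log-normal measurement noise,
#' and planted focal-type-specific up-/down-regulated genes on a focal
#' chromosome. Defaults emulate the structure of the merged collection the
#' pipeline was designed for: eight cell types (the focal type plus seven
#' comparison types split over four dataset blocks), 645 genes on the
#' focal chromosome among 10,000 background genes, 14 planted up and 39
#' planted down genes at linear effect ratio 3, and sigma 0.2 log2 noise.
#'
#' @param n_background_genes genes off the focal chromosome.
#' @param n_focal_chrom_genes genes annotated to `focal_chromosome`.
#' @param focal_chromosome chromosome label of the restriction.
#' @param cell_types ordered cell-type labels; the first is focal.
#' @param focal_type the focal cell type (observed at both timepoints).
#' @param timepoints the two timepoint labels of the focal type.
#' @param replicates_per_group replicate samples per sample group.
#' @param n_housekeeping housekeeping genes (drawn from the background,
#'   equal true mean in every group).
#' @param n_planted_up,n_planted_down planted focal-specific genes on the
#'   focal chromosome.
#' @param effect_ratio linear ratio (> 1) of focal to other-group mean for
#'   planted up genes; planted down genes use its reciprocal.
#' @param effect_timepoints `"both"` (default) or one timepoint label:
#'   restricts the planted effect to that focal timepoint, for testing the
#'   both/either intersection rules.
#' @param n_type_markers up-regulated marker genes (at `effect_ratio`) on
#'   the focal chromosome for each non-focal cell type, making every cell
#'   type separable after chromosome restriction; 0 disables.
#' @param noise_sigma standard deviation of the log2 measurement noise.
#' @param datasets named list mapping dataset label to the cell types it
#'   contributes; the first dataset is the reference platform.
#' @param batch_scales named multiplicative scale (> 0) per dataset.
#' @param baseline_log2_mean,baseline_log2_sd baseline log2 expression
#'   distribution.
#' @param probes_per_gene optional k-probes-per-gene expansion (fixed
#'   per-probe log2 affinity offsets); 1 keeps one probe per gene.
#' @param n_unannotated extra probes carrying no official symbol, to
#'   exercise the annotation filter.
#' @param seed integer seed; generation is reproducible from it.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_background_genes = 10000L,
                             n_focal_chrom_genes = 645L,
                             focal_chromosome = "1",
                             cell_types = c("TC", "MSC", "Fb", "ATII",
                                            "ABC", "PAC", "T-BL", "T-LL"),
                             focal_type = cell_types[1L],
                             timepoints = c("5", "10"),
                             replicates_per_group = 3L,
                             n_housekeeping = 20L,
                             n_planted_up = 14L,
                             n_planted_down = 39L,
                             effect_ratio = 3,
                             effect_timepoints = "both",
                             n_type_markers = 10L,
                             noise_sigma = 0.2,
                             datasets = NULL,
                             batch_scales = NULL,
                             baseline_log2_mean = 8,
                             baseline_log2_sd = 2,
                             probes_per_gene = 1L,
                             n_unannotated = 0L,
                             seed = 1L) {
  if (is.null(datasets)) {
    others <- setdiff(cell_types, focal_type)
    if (identical(cell_types, c("TC", "MSC", "Fb", "ATII", "ABC", "PAC",
                                "T-BL", "T-LL")) &&
        identical(focal_type, "TC")) {
      # mirror the study design: own platform + three public series
      datasets <- list(own = c("TC", "MSC", "Fb"), geo_atii = "ATII",
                       geo_airway = c("ABC", "PAC"),
                       geo_t = c("T-BL", "T-LL"))
    } else {
      datasets <- list(own = c(focal_type,
                               others[seq_len(min(2, length(others)))]))
      rest <- setdiff(others, datasets$own)
      if (length(rest))
        datasets <- c(datasets,
                      split(rest, paste0("geo",
                                         ceiling(seq_along(rest) / 2))))
    }
  }
  if (is.null(batch_scales))
    batch_scales <- stats::setNames(rep(1, length(datasets)), names(datasets))
  cfg <- structure(list(
    n_background_genes = as.integer(n_background_genes),
    n_focal_chrom_genes = as.integer(n_focal_chrom_genes),
    focal_chromosome = focal_chromosome,
    cell_types = cell_types, focal_type = focal_type,
    timepoints = timepoints,
    replicates_per_group = as.integer(replicates_per_group),
    n_housekeeping = as.integer(n_housekeeping),
    n_planted_up = as.integer(n_planted_up),
    n_planted_down = as.integer(n_planted_down),
    effect_ratio = effect_ratio, effect_timepoints = effect_timepoints,
    n_type_markers = as.integer(n_type_markers),
    noise_sigma = noise_sigma, datasets = datasets,
    batch_scales = batch_scales,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    probes_per_gene = as.integer(probes_per_gene),
    n_unannotated = as.integer(n_unannotated),
    seed = as.integer(seed)), class = "synthetic_config")
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  fail <- function(...) stop("invalid synthetic_config: ", ...,
                             call. = FALSE)
  if (!cfg$focal_type %in% cfg$cell_types)
    fail("focal type must be one of cell_types")
  if (anyDuplicated(cfg$cell_types)) fail("cell_types must be unique")
  if (length(cfg$timepoints) != 2L)
    fail("the focal cell type must contribute exactly two timepoint groups")
  n_markers <- cfg$n_type_markers * (length(cfg$cell_types) - 1L)
  if (cfg$n_planted_up + cfg$n_planted_down > cfg$n_focal_chrom_genes)
    fail("n_planted_up + n_planted_down must not exceed n_focal_chrom_genes")
  if (cfg$n_planted_up + cfg$n_planted_down + n_markers >
      cfg$n_focal_chrom_genes)
    fail("planted genes plus per-type markers exceed n_focal_chrom_genes")
  if (cfg$n_housekeeping > cfg$n_background_genes)
    fail("housekeeping genes must fit in the background ",
         "(they are disjoint from planted genes)")
  if (cfg$effect_ratio <= 1) fail("effect_ratio must be > 1")
  if (cfg$noise_sigma < 0) fail("noise_sigma must be >= 0")
  if (any(cfg$batch_scales <= 0)) fail("batch_scales must be > 0")
  if (!setequal(unlist(cfg$datasets), cfg$cell_types))
    fail("datasets must partition cell_types")
  if (anyDuplicated(unlist(cfg$datasets)))
    fail("each cell type belongs to exactly one dataset")
  if (!cfg$effect_timepoints %in% c("both", cfg$timepoints))
    fail("effect_timepoints must be 'both' or one of the timepoints")
  if (cfg$probes_per_gene < 1L) fail("probes_per_gene must be >= 1")
  cfg
}

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

#' Generate a synthetic multi-cell-type expression dataset
#'
#' Builds the expression matrix, probe annotation, sample metadata and a
#' ground-truth record from a [synthetic_config()]. Each measured value is
#' `true group mean x dataset batch scale x 2^N(0, noise_sigma^2)`
#' (times a fixed per-probe affinity when `probes_per_gene > 1`). Planted
#' up genes have focal-group linear mean `effect_ratio` times the shared
#' other-group mean in the configured focal timepoints; planted down
#' genes the reciprocal; housekeeping genes share one mean everywhere
#' before batch scaling.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `matrix` (probe-level linear
#'   [expr_matrix]), `annotation`, `metadata` (data frames as read by
#'   [read_annotation()] / [read_sample_metadata()]) and `truth`, a list
#'   of class `planted_truth`: `up_genes`, `down_genes`,
#'   `housekeeping_genes`, `marker_genes` (per non-focal type),
#'   `group_means` (gene x group true linear means), `batch` (per-sample
#'   scale), `focal_groups`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  cfg <- validate_synthetic_config(config)
  with_seed(cfg$seed, {
    chrom_genes <- sprintf("C%sg%04d", cfg$focal_chromosome,
                           seq_len(cfg$n_focal_chrom_genes))
    bg_genes <- sprintf("Bg%05d", seq_len(cfg$n_background_genes))
    genes <- c(chrom_genes, bg_genes)
    up <- chrom_genes[seq_len(cfg$n_planted_up)]
    down <- chrom_genes[cfg$n_planted_up + seq_len(cfg$n_planted_down)]
    others <- setdiff(cfg$cell_types, cfg$focal_type)
    marker_genes <- list()
    off <- cfg$n_planted_up + cfg$n_planted_down
    for (ct in others) {
      marker_genes[[ct]] <- if (cfg$n_type_markers > 0)
        chrom_genes[off + seq_len(cfg$n_type_markers)] else character(0)
      off <- off + cfg$n_type_markers
    }
    hk <- bg_genes[seq_len(cfg$n_housekeeping)]

    groups <- c(paste0(cfg$focal_type, cfg$timepoints), others)
    focal_groups <- paste0(cfg$focal_type, cfg$timepoints)
    effect_groups <- if (cfg$effect_timepoints == "both") focal_groups
                     else paste0(cfg$focal_type, cfg$effect_timepoints)

    base <- 2^stats::rnorm(length(genes), cfg$baseline_log2_mean,
                           cfg$baseline_log2_sd)
    gm <- matrix(base, length(genes), length(groups),
                 dimnames = list(genes, groups))
    gm[up, effect_groups] <- gm[up, effect_groups] * cfg$effect_ratio
    gm[down, effect_groups] <- gm[down, effect_groups] / cfg$effect_ratio
    for (ct in others)
      gm[marker_genes[[ct]], ct] <- gm[marker_genes[[ct]], ct] *
        cfg$effect_ratio

    ct_of_group <- c(rep(cfg$focal_type, 2L), others)
    tp_of_group <- c(cfg$timepoints, rep("", length(others)))
    dataset_of_ct <- stats::setNames(
      rep(names(cfg$datasets), lengths(cfg$datasets)),
      unlist(cfg$datasets))
    meta <- do.call(rbind, lapply(seq_along(groups), function(i) {
      data.frame(
        sample_id = sprintf("%s_r%d", groups[i],
                            seq_len(cfg$replicates_per_group)),
        cell_type = ct_of_group[i], timepoint = tp_of_group[i],
        dataset = dataset_of_ct[[ct_of_group[i]]],
        stringsAsFactors = FALSE)
    }))
    rownames(meta) <- NULL
    batch <- cfg$batch_scales[meta$dataset]
    names(batch) <- meta$sample_id

    group_of_sample <- rep(groups, each = cfg$replicates_per_group)
    true_cols <- gm[, group_of_sample, drop = FALSE]
    noise <- matrix(stats::rnorm(length(true_cols), 0, cfg$noise_sigma),
                    nrow(true_cols))
    v <- sweep(true_cols, 2L, batch, "*") * 2^noise
    colnames(v) <- meta$sample_id

    # probe expansion and annotation
    k <- cfg$probes_per_gene
    probe_ids <- if (k == 1L) paste0(genes, "_at") else
      paste0(rep(genes, each = k), "_at", seq_len(k))
    if (k > 1L) {
      affinity <- stats::rnorm(length(probe_ids), 0, 0.5)
      v <- v[rep(seq_along(genes), each = k), , drop = FALSE] * 2^affinity
    }
    rownames(v) <- probe_ids
    ann <- data.frame(
      probe_id = probe_ids,
      symbol = rep(genes, each = k),
      chromosome = rep(c(rep(cfg$focal_chromosome,
                             cfg$n_focal_chrom_genes),
                         rep(c(as.character(2:19), "X"),
                             length.out = cfg$n_background_genes)),
                       each = k),
      stringsAsFactors = FALSE)
    if (cfg$n_unannotated > 0L) {
      junk_ids <- sprintf("junk_at%04d", seq_len(cfg$n_unannotated))
      junk <- matrix(2^stats::rnorm(cfg$n_unannotated * ncol(v),
                                    cfg$baseline_log2_mean,
                                    cfg$baseline_log2_sd),
                     cfg$n_unannotated, ncol(v),
                     dimnames = list(junk_ids, colnames(v)))
      v <- rbind(v, junk)
      ann <- rbind(ann, data.frame(probe_id = junk_ids, symbol = "",
                                   chromosome = "",
                                   stringsAsFactors = FALSE))
    }
    truth <- structure(list(
      up_genes = up, down_genes = down, housekeeping_genes = hk,
      marker_genes = marker_genes, group_means = gm, batch = batch,
      focal_groups = focal_groups, config = cfg),
      class = "planted_truth")
    list(matrix = expr_matrix(v, scale = "linear", level = "probe"),
         annotation = ann, metadata = meta, truth = truth)
  })
}

#' Write a generated dataset to tab-delimited files
#'
#' Emits `matrix.tsv`, `annotation.tsv`, `metadata.tsv`, plus the truth
#' record as `truth_sets.json` (gene sets, batch scales) and
#' `truth_group_means.tsv`.
#'
#' @param data the list returned by [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_synthetic_dataset <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(matrix = file.path(dir, "matrix.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth_sets = file.path(dir, "truth_sets.json"),
             truth_means = file.path(dir, "truth_group_means.tsv"))
  write_expression_table(data$matrix, paths["matrix"])
  write_annotation(data$annotation, paths["annotation"])
  write_sample_metadata(data$metadata, paths["metadata"])
  tr <- data$truth
  jsonlite::write_json(list(up_genes = tr$up_genes,
                            down_genes = tr$down_genes,
                            housekeeping_genes = tr$housekeeping_genes,
                            marker_genes = tr$marker_genes,
                            batch = as.list(tr$batch),
                            focal_groups = tr$focal_groups),
                       paths["truth_sets"], auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  gm <- data.frame(gene = rownames(tr$group_means), tr$group_means,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(gm, paths["truth_means"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
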