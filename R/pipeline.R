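#' Pipeline run configuration
#'
#' Bundles every stage's options with an output directory and a single seed.
#' The seed is expanded into per-stage child seeds by a counter scheme, so a
#' stage rerun in isolation reproduces its part of a full run.
#'
#' @param sim A [sim_config()] for the simulate stage.
#' @param thresholds A [qc_thresholds()].
#' @param criteria A [marker_criteria()].
#' @param policy A [clonotype_policy()].
#' @param composition List: `modes` (compartment denominators to report),
#'   `test`, `alternative`, `adjust` for [compare_groups()].
#' @param outdir Output directory.
#' @param seed Master seed; overrides `sim$seed` when given.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            thresholds = qc_thresholds(),
                            criteria = marker_criteria(),
                            policy = clonotype_policy(),
                            composition = list(modes = c("immune",
                                                         "non-immune"),
                                               test = "wilcoxon",
                                               alternative = "two.sided",
                                               adjust = FALSE),
                            outdir = file.path(tempdir(), "clonodyn_run"),
                            seed = NULL) {
  structure(list(sim = sim, thresholds = thresholds, criteria = criteria,
                 policy = policy, composition = composition,
                 outdir = outdir,
                 seed = if (is.null(seed)) sim$seed else as.integer(seed)),
            class = "pipeline_config")
}

stage_seed <- function(seed, k) {
  as.integer(bitwAnd(seed * 7919L + k * 104729L, 0x7FFFFFFFL))
}

log_stage <- function(...) message("[clonodyn] ", sprintf(...))

#' Simulate stage: write a synthetic cohort under `outdir/sim`
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the cohort directory.
#' @export
stage_simulate <- function(config) {
  sim <- config$sim
  sim$seed <- stage_seed(config$seed, 1L)
  log_stage("simulate: %d samples, seed %d",
            sum(sim$groups), sim$seed)
  cohort <- simulate_cohort(sim)
  dir <- file.path(config$outdir, "sim")
  write_cohort(cohort, dir)
  invisible(dir)
}

read_sim_sample <- function(config, sid, what = c("counts", "contigs")) {
  sdir <- file.path(config$outdir, "sim", "samples", sid)
  out <- list()
  if ("counts" %in% what) {
    mtx <- file.path(sdir, "matrix.mtx")
    if (!file.exists(mtx))
      stop(sprintf("sample %s: count matrix missing (%s)", sid, mtx),
           call. = FALSE)
    out$counts <- read_count_matrix(mtx, file.path(sdir, "features.tsv"),
                                    file.path(sdir, "barcodes.tsv"), sid)
  }
  if ("contigs" %in% what) {
    csv <- file.path(sdir, "contigs.csv")
    if (!file.exists(csv))
      stop(sprintf("sample %s: contig file missing (%s)", sid, csv),
           call. = FALSE)
    out$contigs <- read_contigs(csv, sid)
  }
  out
}

read_sim_meta <- function(config) {
  read_cell_meta(file.path(config$outdir, "sim", "meta.tsv"))
}

#' QC stage: filter every sample's matrix and write the telescoping report
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the QC directory.
#' @export
stage_qc <- function(config) {
  meta <- read_sim_meta(config)
  sample_ids <- sort(unique(meta$sample_id))
  qdir <- file.path(config$outdir, "qc")
  reports <- list(); retained <- list()
  for (sid in sample_ids) {
    m <- read_sim_sample(config, sid, "counts")$counts
    meta_s <- meta[meta$sample_id == sid, , drop = FALSE]
    res <- run_qc(m, config$thresholds, meta_s)
    sdir <- file.path(qdir, "samples", sid)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    write_count_matrix(res$matrix, file.path(sdir, "matrix.mtx"),
                       file.path(sdir, "features.tsv"),
                       file.path(sdir, "barcodes.tsv"), sample_id = sid)
    rep <- tibble::as_tibble(res$report[, setdiff(names(res$report),
                                                  "removed")])
    rep$sample_id <- sid
    reports[[sid]] <- rep
    retained[[sid]] <- tibble::tibble(cell = colnames(res$matrix))
    log_stage("qc %s: %d -> %d cells", sid, rep$cells_before[[1L]],
              rep$cells_after[[nrow(rep)]])
  }
  write_table(dplyr::bind_rows(reports), file.path(qdir, "qc_report.tsv"),
              sort_by = "sample_id")
  write_table(dplyr::bind_rows(retained), file.path(qdir,
                                                    "retained_cells.tsv"))
  invisible(qdir)
}

read_retained_cells <- function(config) {
  path <- file.path(config$outdir, "qc", "retained_cells.tsv")
  if (!file.exists(path)) return(NULL)
  data.table::fread(path, header = TRUE, sep = "\t",
                    showProgress = FALSE)[["cell"]]
}

#' Marker stage: pool the QC-filtered samples, normalize and detect markers
#'
#' Samples are pooled over their common retained genes (per-sample gene
#' filtering can drop different rare genes).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the marker table path.
#' @export
stage_markers <- function(config) {
  meta <- read_sim_meta(config)
  sample_ids <- sort(unique(meta$sample_id))
  mats <- lapply(sample_ids, function(sid) {
    sdir <- file.path(config$outdir, "qc", "samples", sid)
    if (!file.exists(file.path(sdir, "matrix.mtx")))
      stop(sprintf("sample %s: QC output missing; run stage_qc first", sid),
           call. = FALSE)
    read_count_matrix(file.path(sdir, "matrix.mtx"),
                      file.path(sdir, "features.tsv"),
                      file.path(sdir, "barcodes.tsv"), sid)
  })
  common <- Reduce(intersect, lapply(mats, rownames))
  pooled <- do.call(cbind, lapply(mats, function(m)
    m[common, , drop = FALSE]))
  log_stage("markers: %d cells x %d common genes", ncol(pooled),
            length(common))
  nm <- lognormalize(pooled)
  labels <- meta$subtype[match(colnames(nm), meta$cell)]
  markers <- find_markers(nm, labels, criteria = config$criteria)
  mdir <- file.path(config$outdir, "markers")
  dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(mdir, "markers.tsv")
  write_table(markers, path, sort_by = c("cluster", "gene"))
  invisible(path)
}

#' Clonotype stage: expansion and transition statistics plus network export
#'
#' Chains are assembled into clonotypes over the QC-retained cells (all cells
#' when QC has not been run), then per-sample expansion and transition
#' tables, group means and the exclusivity-flagged edge list are written.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the clonotype output directory.
#' @export
stage_clonotypes <- function(config) {
  meta <- read_sim_meta(config)
  retained <- read_retained_cells(config)
  if (!is.null(retained))
    meta <- meta[meta$cell %in% retained, , drop = FALSE]
  sample_ids <- sort(unique(meta$sample_id))
  chains <- dplyr::bind_rows(lapply(sample_ids, function(sid)
    read_sim_sample(config, sid, "contigs")$contigs))
  suppressWarnings(
    assignments <- assemble_clonotypes(chains, meta, config$policy))
  expansion <- clonal_expansion(assignments)
  transitions <- clonal_transitions(assignments)
  exp_means <- summarize_expansion(expansion)
  trans_means <- summarize_transitions(transitions)
  network <- transition_network(trans_means)

  cdir <- file.path(config$outdir, "clonotypes")
  dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
  write_table(expansion, file.path(cdir, "expansion_per_sample.tsv"),
              sort_by = c("subtype", "sample_id"))
  write_table(exp_means, file.path(cdir, "expansion_group_means.tsv"),
              sort_by = c("subtype", "group"))
  write_table(transitions, file.path(cdir, "transition_per_sample.tsv"),
              sort_by = c("subtype_a", "subtype_b", "sample_id"))
  write_table(trans_means, file.path(cdir, "transition_group_means.tsv"),
              sort_by = c("subtype_a", "subtype_b", "group"))
  write_edge_list(network, file.path(cdir, "network_edges.tsv"))
  log_stage("clonotypes: %d expansion rows, %d network edges",
            nrow(expansion), nrow(network))
  invisible(cdir)
}

#' Composition stage: per-sample proportions and group comparisons
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the composition output directory.
#' @export
stage_composition <- function(config) {
  meta <- read_sim_meta(config)
  retained <- read_retained_cells(config)
  if (!is.null(retained))
    meta <- meta[meta$cell %in% retained, , drop = FALSE]
  opts <- config$composition
  props <- list(); tests <- list()
  for (mode in opts$modes) {
    pt <- subtype_proportions(meta, mode = mode)
    pt$mode <- mode
    props[[mode]] <- pt
    tt <- compare_groups(pt, test = opts$test,
                         alternative = opts$alternative,
                         adjust = isTRUE(opts$adjust))
    tt$mode <- mode
    tests[[mode]] <- tt
  }
  odir <- file.path(config$outdir, "composition")
  dir.create(odir, recursive = TRUE, showWarnings = FALSE)
  write_table(dplyr::bind_rows(props), file.path(odir, "proportions.tsv"),
              sort_by = c("mode", "sample_id", "subtype"))
  write_table(dplyr::bind_rows(tests), file.path(odir, "tests.tsv"),
              sort_by = c("mode", "subtype"))
  invisible(odir)
}

write_manifest <- function(config) {
  files <- sort(list.files(config$outdir, recursive = TRUE,
                           full.names = FALSE))
  files <- setdiff(files, "manifest.tsv")
  md5 <- unname(tools::md5sum(file.path(config$outdir, files)))
  write_table(tibble::tibble(file = files, md5 = md5),
              file.path(config$outdir, "manifest.tsv"), sort_by = "file")
}

#' Run the full pipeline: simulate, QC, markers, clonotypes, composition
#'
#' Stages read their inputs from the previous stage's on-disk outputs, so a
#' full run equals the concatenation of stage-wise runs. A manifest of MD5
#' checksums plus the resolved configuration are written to the output
#' directory; a fixed seed yields a bytewise-identical output tree.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, `config$outdir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- lapply(unclass(config)[c("sim", "thresholds", "criteria", "policy",
                                  "composition")], unclass)
  cfg$seed <- config$seed
  yaml::write_yaml(cfg, file.path(config$outdir, "config.yaml"))
  stage_simulate(config)
  stage_qc(config)
  stage_markers(config)
  stage_clonotypes(config)
  stage_composition(config)
  write_manifest(config)
  log_stage("done: %s", config$outdir)
  invisible(config$outdir)
}
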