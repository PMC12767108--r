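#' Quality-control thresholds
#'
#' Defaults follow the common droplet scRNA-seq retention rules this package
#' implements: genes must be expressed in at least 3 cells; cells must have
#' 500-8000 detected features (boundary-inclusive, since the removal
#' conditions are "fewer than 500 or more than 8000"), a UMI total at or below
#' the per-sample 98th percentile, and at most 15% mitochondrial, 40%
#' ribosomal and 3% hemoglobin counts (strict inequalities remove). Gene-set
#' matchers default to the `MT-` prefix, the `RPS`/`RPL` prefixes and an
#' explicit hemoglobin symbol list; all are overridable.
#'
#' @param min_cells_per_gene Minimum expressing cells per retained gene.
#' @param min_features,max_features Inclusive detected-gene bounds per cell.
#' @param umi_quantile Per-sample quantile (0, 1) above which cells are
#'   removed; linear interpolation between order statistics.
#' @param max_mito_pct,max_ribo_pct,max_hb_pct Percentage caps (cells strictly
#'   above are removed).
#' @param mito_patterns,ribo_patterns Regexes resolved against gene names.
#' @param hb_genes Explicit hemoglobin symbols.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_cells_per_gene = 3L,
                          min_features = 500L,
                          max_features = 8000L,
                          umi_quantile = 0.98,
                          max_mito_pct = 15,
                          max_ribo_pct = 40,
                          max_hb_pct = 3,
                          mito_patterns = "^MT-",
                          ribo_patterns = c("^RPS", "^RPL"),
                          hb_genes = c("HBA1", "HBA2", "HBB", "HBD", "HBG1",
                                       "HBG2", "HBM", "HBQ1", "HBZ")) {
  stopifnot(umi_quantile > 0, umi_quantile < 1,
            min_features < max_features,
            max_mito_pct > 0, max_mito_pct <= 100,
            max_ribo_pct > 0, max_ribo_pct <= 100,
            max_hb_pct > 0, max_hb_pct <= 100)
  structure(list(min_cells_per_gene = min_cells_per_gene,
                 min_features = min_features, max_features = max_features,
                 umi_quantile = umi_quantile, max_mito_pct = max_mito_pct,
                 max_ribo_pct = max_ribo_pct, max_hb_pct = max_hb_pct,
                 mito_patterns = mito_patterns, ribo_patterns = ribo_patterns,
                 hb_genes = hb_genes),
            class = "qc_thresholds")
}

#' Resolve a gene set against a matrix's gene names
#'
#' @param genes Character vector of gene names.
#' @param patterns Regex patterns and/or exact gene symbols.
#' @return The matching gene names, in matrix order.
#' @export
resolve_gene_set <- function(genes, patterns) {
  hit <- rep(FALSE, length(genes))
  for (p in patterns) {
    hit <- hit | grepl(p, genes) | genes == p
  }
  genes[hit]
}

#' Remove genes expressed in fewer than `k` cells
#'
#' @param m Sparse gene x cell count matrix.
#' @param k Minimum number of expressing (nonzero) cells.
#' @return Filtered matrix; cell set unchanged.
#' @export
filter_genes_min_cells <- function(m, k = 3L) {
  stopifnot(k >= 0)
  keep <- Matrix::rowSums(m > 0) >= k
  if (!any(keep))
    warning("all genes removed by min-cell filter", call. = FALSE)
  m[keep, , drop = FALSE]
}

#' Retain cells whose detected-feature count lies within bounds
#'
#' Boundary-inclusive: a cell with exactly `lo` or `hi` detected genes is
#' kept (the removal conditions are "fewer than" / "more than").
#'
#' @param m Sparse gene x cell count matrix.
#' @param lo,hi Inclusive bounds on the per-cell nonzero gene count.
#' @return Filtered matrix; gene set unchanged.
#' @export
filter_cells_feature_bounds <- function(m, lo = 500L, hi = 8000L) {
  stopifnot(lo < hi)
  f <- Matrix::colSums(m > 0)
  m[, f >= lo & f <= hi, drop = FALSE]
}

#' Remove cells with UMI totals above a per-sample quantile
#'
#' The quantile is computed over this matrix's cells only (QC is per sample)
#' by linear interpolation between order statistics; cells strictly above it
#' are removed. Note this stage is not idempotent: re-applying it to its own
#' output recomputes the quantile over the survivors and may remove more
#' cells.
#'
#' @param m Sparse gene x cell count matrix for one sample.
#' @param q Quantile in (0, 1).
#' @return Filtered matrix.
#' @export
filter_cells_umi_quantile <- function(m, q = 0.98) {
  stopifnot(q > 0, q < 1)
  if (ncol(m) < 2L) {
    warning("fewer than 2 cells; UMI-quantile filter skipped", call. = FALSE)
    return(m)
  }
  totals <- Matrix::colSums(m)
  thr <- stats::quantile(totals, q, type = 7, names = FALSE)
  m[, totals <= thr, drop = FALSE]
}

#' Remove cells whose count share on a gene set exceeds a percentage
#'
#' The share is `100 * sum(counts on the set) / total counts` per cell
#' (the percentage-feature-set convention); removal is strict (`> max_pct`).
#'
#' @param m Sparse gene x cell count matrix.
#' @param gene_set Exact gene names and/or regex patterns.
#' @param max_pct Maximum retained percentage.
#' @return Filtered matrix.
#' @export
filter_cells_fraction <- function(m, gene_set, max_pct) {
  set <- resolve_gene_set(rownames(m), gene_set)
  if (length(set) == 0L) {
    warning("gene set resolved to no genes; filter skipped", call. = FALSE)
    return(m)
  }
  totals <- Matrix::colSums(m)
  share <- 100 * Matrix::colSums(m[set, , drop = FALSE]) / pmax(totals, 1)
  m[, share <= max_pct, drop = FALSE]
}

#' Remove cells flagged as doublets by an upstream caller
#'
#' The doublet detector itself is an external tool; this consumes its output
#' flag from the cell metadata.
#'
#' @param m Sparse gene x cell count matrix.
#' @param meta Cell metadata with `cell` and `doublet_flag` columns.
#' @param missing How to treat matrix cells without a flag: `"error"`
#'   (default) or `"keep"` (treat missing as singlet).
#' @return Filtered matrix.
#' @export
remove_doublets <- function(m, meta, missing = c("error", "keep")) {
  missing <- match.arg(missing)
  if (!"doublet_flag" %in% names(meta))
    stop("metadata carries no doublet_flag column", call. = FALSE)
  flag <- meta$doublet_flag[match(colnames(m), meta$cell)]
  if (anyNA(flag)) {
    if (missing == "error")
      stop(sprintf("%d matrix cells have no doublet flag", sum(is.na(flag))),
           call. = FALSE)
    flag[is.na(flag)] <- FALSE
  }
  extra <- sum(meta$doublet_flag %in% TRUE & !meta$cell %in% colnames(m))
  if (extra > 0L)
    warning(sprintf("%d flagged barcodes absent from the matrix; ignored",
                    extra), call. = FALSE)
  m[, !flag, drop = FALSE]
}

#' Drop the mitochondrial/ribosomal/hemoglobin gene sets from the gene axis
#'
#' Applied after cell filtering so the special gene groups no longer
#' contribute to downstream normalization; idempotent.
#'
#' @param m Sparse gene x cell count matrix.
#' @param sets List of pattern/symbol vectors (default: the three sets of
#'   [qc_thresholds()]).
#' @return Matrix without the resolved genes; cell set unchanged.
#' @export
drop_gene_sets <- function(m, sets = NULL) {
  if (is.null(sets)) {
    th <- qc_thresholds()
    sets <- list(th$mito_patterns, th$ribo_patterns, th$hb_genes)
  }
  drop <- unique(unlist(lapply(sets, resolve_gene_set,
                               genes = rownames(m))))
  m[!rownames(m) %in% drop, , drop = FALSE]
}

#' Run the full per-sample quality-control chain
#'
#' Stage order: gene min-cell filter, feature-count bounds, UMI-quantile cut,
#' doublet removal, mitochondrial / ribosomal / hemoglobin percentage filters,
#' then removal of those gene sets from the matrix. Returns the filtered
#' matrix together with a telescoping per-stage report recording dimensions
#' and the removed identifiers.
#'
#' @param m Sparse gene x cell count matrix for one sample.
#' @param thresholds A [qc_thresholds()].
#' @param meta Cell metadata (needed for the doublet stage); when `NULL`
#'   or without a `doublet_flag` column the doublet stage is skipped with a
#'   warning.
#' @param missing_doublet_flag Passed to [remove_doublets()].
#' @return A list `(matrix, report)`; `report` is a `qc_report` tibble with
#'   columns `stage`, `cells_before`, `cells_after`, `genes_before`,
#'   `genes_after`, `n_removed`, `removed` (list column of identifiers).
#' @export
run_qc <- function(m, thresholds = qc_thresholds(), meta = NULL,
                   missing_doublet_flag = "error") {
  th <- thresholds
  stages <- list(
    gene_min_cells = function(x)
      filter_genes_min_cells(x, th$min_cells_per_gene),
    feature_bounds = function(x)
      filter_cells_feature_bounds(x, th$min_features, th$max_features),
    umi_quantile = function(x) filter_cells_umi_quantile(x, th$umi_quantile),
    doublet = function(x) {
      if (is.null(meta) || !"doublet_flag" %in% names(meta)) {
        warning("no doublet flags supplied; doublet stage skipped",
                call. = FALSE)
        x
      } else remove_doublets(x, meta, missing = missing_doublet_flag)
    },
    mito_fraction = function(x)
      filter_cells_fraction(x, th$mito_patterns, th$max_mito_pct),
    ribo_fraction = function(x)
      filter_cells_fraction(x, th$ribo_patterns, th$max_ribo_pct),
    hb_fraction = function(x)
      filter_cells_fraction(x, th$hb_genes, th$max_hb_pct),
    drop_gene_sets = function(x)
      drop_gene_sets(x, list(th$mito_patterns, th$ribo_patterns,
                             th$hb_genes)))

  rows <- vector("list", length(stages))
  for (i in seq_along(stages)) {
    before_genes <- rownames(m); before_cells <- colnames(m)
    m2 <- stages[[i]](m)
    removed <- c(setdiff(before_genes, rownames(m2)),
                 setdiff(before_cells, colnames(m2)))
    rows[[i]] <- tibble::tibble(
      stage = names(stages)[[i]],
      cells_before = length(before_cells), cells_after = ncol(m2),
      genes_before = length(before_genes), genes_after = nrow(m2),
      n_removed = length(removed), removed = list(removed))
    m <- m2
  }
  report <- dplyr::bind_rows(rows)
  class(report) <- c("qc_report", class(report))
  attr(report, "thresholds") <- th
  attr(report, "quantile_method") <- "linear interpolation (type 7)"
  list(matrix = m, report = report)
}

#' @export
#' @method print qc_report
print.qc_report <- function(x, ...) {
  cat("<qc_report>  quantile:", attr(x, "quantile_method"), "\n")
  print(tibble::as_tibble(x[, setdiff(names(x), "removed")]), ...)
  invisible(x)
}
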