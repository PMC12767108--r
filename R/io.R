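#' @importFrom rlang .data %||%
#' @import Matrix
NULL

format_error <- function(path, line, msg) {
  stop(sprintf("%s:%s: %s", path, ifelse(is.na(line), "?", line), msg),
       call. = FALSE)
}

#' Qualify raw droplet barcodes with their sample of origin
#'
#' Raw 10x barcodes collide across samples once a cohort is pooled; every
#' function in this package therefore addresses cells by
#' `"<sample_id>:<barcode>"`.
#'
#' @param sample_id Sample label (length 1 or recycled).
#' @param barcode Character vector of raw barcodes.
#' @return Character vector of sample-qualified cell identifiers.
#' @export
qualify_barcode <- function(sample_id, barcode) {
  paste(sample_id, barcode, sep = ":")
}

#' Read a 10x-style MatrixMarket count matrix
#'
#' Parses the triplet MTX file together with its `features.tsv` and
#' `barcodes.tsv` sidecars into a sparse gene x cell integer matrix. Column
#' names are sample-qualified (see [qualify_barcode()]). The parser validates
#' the MatrixMarket banner, the declared dimensions, and that every stored
#' entry is a non-negative integer inside the declared bounds; violations
#' raise an error naming the file and line.
#'
#' @param mtx_path Path to the MatrixMarket coordinate file.
#' @param features_path Path to the features TSV (first column = gene id).
#' @param barcodes_path Path to the barcodes TSV (first column = barcode).
#' @param sample_id Sample label used to qualify barcodes.
#' @return A [Matrix::dgCMatrix-class] of counts, genes in rows.
#' @export
read_count_matrix <- function(mtx_path, features_path, barcodes_path, sample_id) {
  head_lines <- readLines(mtx_path, n = 200L)
  if (length(head_lines) == 0L)
    format_error(mtx_path, 1L, "empty MatrixMarket file")
  banner <- head_lines[[1L]]
  if (!grepl("^%%MatrixMarket[ \t]+matrix[ \t]+coordinate", banner))
    format_error(mtx_path, 1L, "malformed MatrixMarket banner")
  if (grepl("complex|pattern", banner))
    format_error(mtx_path, 1L, "unsupported MatrixMarket field type")
  n_comment <- 0L
  while (n_comment + 1L <= length(head_lines) &&
         startsWith(head_lines[[n_comment + 1L]], "%")) {
    n_comment <- n_comment + 1L
  }
  if (n_comment + 1L > length(head_lines))
    format_error(mtx_path, n_comment, "missing dimensions line")
  dims_line <- n_comment + 1L
  dims <- suppressWarnings(as.numeric(strsplit(trimws(head_lines[[dims_line]]),
                                               "[ \t]+")[[1L]]))
  if (length(dims) != 3L || anyNA(dims) || any(dims < 0) ||
      any(dims != floor(dims)))
    format_error(mtx_path, dims_line, "malformed dimensions line")
  n_genes <- as.integer(dims[[1L]])
  n_cells <- as.integer(dims[[2L]])
  n_entries <- dims[[3L]]

  trip <- data.table::fread(mtx_path, skip = dims_line, header = FALSE,
                            colClasses = "numeric", showProgress = FALSE)
  if (nrow(trip) != n_entries)
    format_error(mtx_path, dims_line,
                 sprintf("header declares %d entries but %d found",
                         n_entries, nrow(trip)))
  if (nrow(trip) > 0L && ncol(trip) != 3L)
    format_error(mtx_path, dims_line + 1L, "expected 3 columns per entry")
  if (nrow(trip) > 0L) {
    i <- trip[[1L]]; j <- trip[[2L]]; x <- trip[[3L]]
    bad <- which(i < 1 | i > n_genes | j < 1 | j > n_cells |
                   i != floor(i) | j != floor(j))
    if (length(bad))
      format_error(mtx_path, dims_line + bad[[1L]],
                   sprintf("entry addresses (%g, %g) outside declared %d x %d",
                           i[bad[[1L]]], j[bad[[1L]]], n_genes, n_cells))
    badx <- which(x < 0 | x != floor(x) | !is.finite(x))
    if (length(badx))
      format_error(mtx_path, dims_line + badx[[1L]],
                   sprintf("count %g is not a non-negative integer",
                           x[badx[[1L]]]))
  } else {
    i <- integer(); j <- integer(); x <- numeric()
  }

  genes <- data.table::fread(features_path, header = FALSE, sep = "\t",
                             showProgress = FALSE)[[1L]]
  barcodes <- data.table::fread(barcodes_path, header = FALSE, sep = "\t",
                                showProgress = FALSE)[[1L]]
  if (length(genes) != n_genes)
    format_error(features_path, NA,
                 sprintf("%d features but matrix declares %d rows",
                         length(genes), n_genes))
  if (length(barcodes) != n_cells)
    format_error(barcodes_path, NA,
                 sprintf("%d barcodes but matrix declares %d columns",
                         length(barcodes), n_cells))
  cells <- qualify_barcode(sample_id, barcodes)
  if (anyDuplicated(genes))
    format_error(features_path, NA, "duplicated gene identifiers")
  if (anyDuplicated(cells))
    format_error(barcodes_path, NA, "duplicated barcodes after qualification")
  m <- Matrix::sparseMatrix(i = as.integer(i), j = as.integer(j), x = x,
                            dims = c(n_genes, n_cells),
                            dimnames = list(genes, cells))
  methods::as(m, "CsparseMatrix")
}

#' Write a count matrix in 10x triplet convention
#'
#' Inverse of [read_count_matrix()]: emits an integer MatrixMarket file plus
#' `features.tsv`/`barcodes.tsv`. Triplets are written column-major (sorted by
#' cell, then gene) so output is bytewise deterministic.
#'
#' @param m Sparse gene x cell count matrix.
#' @param mtx_path,features_path,barcodes_path Output paths.
#' @param sample_id If non-`NULL`, this prefix (plus `":"`) is stripped from
#'   column names before writing, restoring raw per-sample barcodes.
#' @return Invisibly, `mtx_path`.
#' @export
write_count_matrix <- function(m, mtx_path, features_path, barcodes_path,
                               sample_id = NULL) {
  m <- methods::as(m, "CsparseMatrix")
  tm <- methods::as(m, "TsparseMatrix")
  ord <- order(tm@j, tm@i, method = "radix")
  trip <- data.table::data.table(i = tm@i[ord] + 1L, j = tm@j[ord] + 1L,
                                 x = as.integer(tm@x[ord]))
  header <- c("%%MatrixMarket matrix coordinate integer general",
              sprintf("%d %d %d", nrow(m), ncol(m), nrow(trip)))
  writeLines(header, mtx_path)
  if (nrow(trip) > 0L)
    data.table::fwrite(trip, mtx_path, sep = " ", col.names = FALSE,
                       append = TRUE)
  barcodes <- colnames(m)
  if (!is.null(sample_id))
    barcodes <- sub(paste0("^", sample_id, ":"), "", barcodes)
  writeLines(rownames(m), features_path)
  writeLines(barcodes, barcodes_path)
  invisible(mtx_path)
}

LOCI_RECOGNIZED <- c("TRA", "TRB")

#' Read a V(D)J contig annotation table
#'
#' Consumes the upstream V(D)J caller's per-contig CSV (the
#' `filtered_contig_annotations.csv` dialect). One row per contig; the `chain`
#' column is mapped to a locus (`TRA`/`TRB`, anything else retained as
#' `"other"`), and `productive` is parsed conservatively: any token other than
#' case-insensitive `"true"` is `FALSE`.
#'
#' @param csv_path Path to the contig CSV. Must contain columns `barcode`,
#'   `chain`, `cdr3`, `cdr3_nt`, `productive`, `umis`.
#' @param sample_id Sample label used to qualify barcodes.
#' @return A tibble of chain records with columns `cell`, `barcode`,
#'   `sample_id`, `locus`, `cdr3_aa`, `cdr3_nt`, `v_gene`, `j_gene`,
#'   `productive`, `umis`.
#' @export
read_contigs <- function(csv_path, sample_id) {
  dt <- data.table::fread(csv_path, header = TRUE, sep = ",",
                          colClasses = list(character = "barcode"),
                          showProgress = FALSE)
  required <- c("barcode", "chain", "cdr3", "cdr3_nt", "productive", "umis")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols))
    format_error(csv_path, 1L, paste0("missing required column(s): ",
                                      paste(missing_cols, collapse = ", ")))
  if (nrow(dt) == 0L) {
    warning(sprintf("%s: no contig rows for sample %s", csv_path, sample_id),
            call. = FALSE)
    return(tibble::tibble(cell = character(), barcode = character(),
                          sample_id = character(), locus = character(),
                          cdr3_aa = character(), cdr3_nt = character(),
                          v_gene = character(), j_gene = character(),
                          productive = logical(), umis = integer()))
  }
  umis <- suppressWarnings(as.numeric(dt[["umis"]]))
  if (anyNA(umis) || any(umis < 0) || any(umis != floor(umis)))
    format_error(csv_path, NA, "umis column must hold non-negative integers")
  locus <- ifelse(as.character(dt[["chain"]]) %in% LOCI_RECOGNIZED,
                  as.character(dt[["chain"]]), "other")
  out <- tibble::tibble(
    cell = qualify_barcode(sample_id, as.character(dt[["barcode"]])),
    barcode = as.character(dt[["barcode"]]),
    sample_id = sample_id,
    locus = locus,
    cdr3_aa = as.character(dt[["cdr3"]]),
    cdr3_nt = as.character(dt[["cdr3_nt"]]),
    v_gene = if ("v_gene" %in% names(dt)) as.character(dt[["v_gene"]]) else NA_character_,
    j_gene = if ("j_gene" %in% names(dt)) as.character(dt[["j_gene"]]) else NA_character_,
    productive = tolower(as.character(dt[["productive"]])) == "true",
    umis = as.integer(umis))
  out
}

#' Read per-cell metadata
#'
#' Tab-separated table with one row per cell: `barcode`, `sample_id`, `group`
#' (cohort arm), `subtype` (cell-type label) and optionally `doublet_flag`
#' (logical, from an upstream doublet caller) and `compartment`
#' (`immune`/`non-immune`). Duplicated `(barcode, sample_id)` pairs are an
#' error, as are subtype labels outside a supplied vocabulary.
#'
#' @param tsv_path Path to the metadata TSV.
#' @param subtype_levels Optional character vocabulary; unknown subtype labels
#'   raise an error listing the offenders.
#' @return A tibble with a sample-qualified `cell` column prepended.
#' @export
read_cell_meta <- function(tsv_path, subtype_levels = NULL) {
  dt <- data.table::fread(tsv_path, header = TRUE, sep = "\t",
                          colClasses = list(character = "barcode"),
                          showProgress = FALSE)
  required <- c("barcode", "sample_id", "group", "subtype")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols))
    format_error(tsv_path, 1L, paste0("missing required column(s): ",
                                      paste(missing_cols, collapse = ", ")))
  key <- paste(dt[["sample_id"]], dt[["barcode"]], sep = ":")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    format_error(tsv_path, NA,
                 paste0("duplicated (barcode, sample_id): ",
                        paste(utils::head(dup, 5L), collapse = ", ")))
  }
  if (!is.null(subtype_levels)) {
    unknown <- setdiff(unique(as.character(dt[["subtype"]])), subtype_levels)
    if (length(unknown))
      format_error(tsv_path, NA,
                   paste0("unknown subtype label(s): ",
                          paste(unknown, collapse = ", ")))
  }
  out <- tibble::as_tibble(dt)
  out$barcode <- as.character(out$barcode)
  out$cell <- qualify_barcode(out$sample_id, out$barcode)
  if ("doublet_flag" %in% names(out))
    out$doublet_flag <- as.logical(out$doublet_flag)
  dplyr::relocate(out, "cell")
}

#' Write a result table as deterministic TSV
#'
#' All result tables leave the package through this writer: tab-separated,
#' header row, UTF-8, rows sorted by the given key columns so a fixed seed
#' yields bytewise-identical files.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @param sort_by Columns to sort by (default: all columns, left to right).
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path, sort_by = names(rows)) {
  rows <- as.data.frame(rows)
  if (length(sort_by) && nrow(rows) > 1L) {
    ord <- do.call(order, c(unname(rows[sort_by]), list(method = "radix")))
    rows <- rows[ord, , drop = FALSE]
  }
  data.table::fwrite(rows, path, sep = "\t", quote = FALSE, na = "NA",
                     logical01 = FALSE, showProgress = FALSE)
  invisible(path)
}

#' Write a clonal-transition edge list for Cytoscape import
#'
#' Fixed five-column TSV: `source`, `target`, `weight_group1`,
#' `weight_group2`, `exclusive_to` (the group label when the edge's mean
#' transition is positive in exactly one group, else `"none"`). Group order is
#' taken from the network object's `groups` attribute.
#'
#' @param edges A [transition_network()] tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(edges, path) {
  groups <- attr(edges, "groups")
  if (is.null(groups)) {
    wcols <- grep("^weight_", names(edges), value = TRUE)
    groups <- sub("^weight_", "", wcols)
  }
  if (length(groups) != 2L)
    stop("write_edge_list expects a two-group network", call. = FALSE)
  out <- data.frame(
    source = edges$subtype_a,
    target = edges$subtype_b,
    weight_group1 = edges[[paste0("weight_", groups[[1L]])]],
    weight_group2 = edges[[paste0("weight_", groups[[2L]])]],
    exclusive_to = ifelse(is.na(edges$exclusive_to), "none", edges$exclusive_to),
    stringsAsFactors = FALSE)
  write_table(out, path, sort_by = c("source", "target"))
}
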