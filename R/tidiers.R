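#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a QC report into one row per stage
#'
#' @param x A `qc_report` from [run_qc()].
#' @param ... Unused.
#' @return Tibble without the list column of removed identifiers.
#' @method tidy qc_report
#' @export
tidy.qc_report <- function(x, ...) {
  tibble::as_tibble(x[, setdiff(names(x), "removed")])
}

#' One-row summary of a QC run
#'
#' @param x A `qc_report` from [run_qc()].
#' @param ... Unused.
#' @return Tibble: initial/final dimensions and total removals.
#' @method glance qc_report
#' @export
glance.qc_report <- function(x, ...) {
  tibble::tibble(
    cells_initial = x$cells_before[[1L]],
    cells_final = x$cells_after[[nrow(x)]],
    genes_initial = x$genes_before[[1L]],
    genes_final = x$genes_after[[nrow(x)]],
    cells_removed = x$cells_before[[1L]] - x$cells_after[[nrow(x)]],
    genes_removed = x$genes_before[[1L]] - x$genes_after[[nrow(x)]])
}

#' Tidy a rank-sum test result
#'
#' @param x A `ranksum_test` from [rank_sum_test()].
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `p.value`, `alternative`, `exact`,
#'   `n1`, `n2`.
#' @method tidy ranksum_test
#' @export
tidy.ranksum_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p.value,
                 alternative = x$alternative, exact = x$exact,
                 n1 = x$n[[1L]], n2 = x$n[[2L]])
}

#' Tidy a correlation test result
#'
#' @param x A `cor_test` from [correlate_frequencies()].
#' @param ... Unused.
#' @return One-row tibble: `estimate`, `p.value`, `n`, `exact`.
#' @method tidy cor_test
#' @export
tidy.cor_test <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, p.value = x$p.value, n = x$n,
                 exact = x$exact)
}

#' One-row summary of a simulated cohort
#'
#' @param x A `tcr_cohort` from [simulate_cohort()].
#' @param ... Unused.
#' @return Tibble: samples, cells, TCR-bearing cells, doublets, contigs.
#' @method glance tcr_cohort
#' @export
glance.tcr_cohort <- function(x, ...) {
  tibble::tibble(
    n_samples = length(unique(x$meta$sample_id)),
    n_cells = nrow(x$meta),
    n_tcr_cells = sum(!is.na(x$truth$cells$clonotype_id)),
    n_doublets = sum(x$meta$doublet_flag),
    n_contigs = if (is.null(x$chains)) 0L else nrow(x$chains))
}
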