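#' Clonotype assembly policy
#'
#' Controls how per-cell paired-CDR3 clonotype keys are built. By default a
#' cell has TCR information iff it carries at least one productive TRA *and*
#' one productive TRB contig; per locus the highest-UMI productive chain is
#' selected, ties broken by the lexicographically smaller CDR3, and the key is
#' the selected (CDR3alpha, CDR3beta) pair at amino-acid level. Keys are
#' compared within sample only.
#'
#' @param level `"aa"` (default) or `"nt"`: compare CDR3s at amino-acid or
#'   nucleotide level.
#' @param require_both If `FALSE`, a single productive chain suffices for TCR
#'   information; the missing side of the key is a fixed placeholder.
#' @return A `clonotype_policy` list.
#' @export
clonotype_policy <- function(level = c("aa", "nt"), require_both = TRUE) {
  structure(list(level = match.arg(level), require_both = require_both),
            class = "clonotype_policy")
}

#' Assemble per-cell paired-CDR3 clonotypes
#'
#' Cells sharing identical CDR3alpha and CDR3beta pairs within a sample form
#' a clonotype. Chains are joined to the cell metadata on the qualified cell
#' id; chains for cells absent from the metadata are dropped with a warning.
#'
#' @param chains Chain records as returned by [read_contigs()] or
#'   [simulate_repertoire()].
#' @param meta Cell metadata (must contain `cell`, `sample_id`, `group`,
#'   `subtype`).
#' @param policy A [clonotype_policy()].
#' @return A tibble with one row per metadata cell: `cell`, `sample_id`,
#'   `group`, `subtype`, `cdr3a`, `cdr3b`, `clonotype_key`, `has_tcr_info`.
#' @export
assemble_clonotypes <- function(chains, meta, policy = clonotype_policy()) {
  stopifnot(all(c("cell", "sample_id", "group", "subtype") %in% names(meta)))
  orphans <- setdiff(unique(chains$cell), meta$cell)
  if (length(orphans)) {
    warning(sprintf("%d chain-bearing barcodes absent from metadata; dropped",
                    length(orphans)), call. = FALSE)
    chains <- chains[!chains$cell %in% orphans, , drop = FALSE]
  }
  seq_col <- if (policy$level == "aa") "cdr3_aa" else "cdr3_nt"

  best <- chains |>
    dplyr::filter(.data$productive, .data$locus %in% c("TRA", "TRB")) |>
    dplyr::mutate(seq = .data[[seq_col]]) |>
    dplyr::arrange(.data$cell, .data$locus, dplyr::desc(.data$umis),
                   .data$seq) |>
    dplyr::distinct(.data$cell, .data$locus, .keep_all = TRUE) |>
    dplyr::select("cell", "locus", "seq") |>
    tidyr::pivot_wider(names_from = "locus", values_from = "seq")
  for (col in c("TRA", "TRB"))
    if (!col %in% names(best)) best[[col]] <- NA_character_

  out <- meta |>
    dplyr::select("cell", "sample_id", "group", "subtype") |>
    dplyr::left_join(best, by = "cell") |>
    dplyr::rename(cdr3a = "TRA", cdr3b = "TRB")
  if (policy$require_both) {
    out$has_tcr_info <- !is.na(out$cdr3a) & !is.na(out$cdr3b)
  } else {
    out$has_tcr_info <- !is.na(out$cdr3a) | !is.na(out$cdr3b)
  }
  key <- paste(ifelse(is.na(out$cdr3a), "-", out$cdr3a),
               ifelse(is.na(out$cdr3b), "-", out$cdr3b), sep = "|")
  out$clonotype_key <- ifelse(out$has_tcr_info, key, NA_character_)
  tibble::as_tibble(out)
}

# Sample-wide clonotype sizes over TCR-informative cells.
clone_sizes <- function(assignments) {
  assignments |>
    dplyr::filter(.data$has_tcr_info) |>
    dplyr::count(.data$sample_id, .data$clonotype_key, name = "clone_size")
}

#' Clonal expansion value of one subtype in one sample
#'
#' The fraction of the subtype's TCR-informative cells that are clonal,
#' where a cell is clonal when its clonotype is carried by at least two cells
#' *sample-wide* (a clonotype split across two subtypes with one cell each is
#' clonal). With `N` TCR-informative cells in the subtype and clonal
#' clonotypes `i = 1..k` of per-subtype size `n_i`, the value is
#' `sum(n_i) / N`; undefined (`NA`) when `N = 0`.
#'
#' @param cells Clonotype assignments ([assemble_clonotypes()] rows) for one
#'   subtype in one sample.
#' @param clone_totals Optional sample-wide clonotype sizes (named vector
#'   clonotype key -> total); defaults to sizes within `cells`, which is
#'   exact only when the subtype's clonotypes do not occur elsewhere in the
#'   sample.
#' @return A value in `[0, 1]`, or `NA_real_` when no cell has TCR
#'   information.
#' @export
expansion_value <- function(cells, clone_totals = NULL) {
  if (length(unique(cells$sample_id)) > 1L)
    stop("expansion_value expects cells from a single sample", call. = FALSE)
  tcr <- cells[cells$has_tcr_info, , drop = FALSE]
  n <- nrow(tcr)
  if (n == 0L) return(NA_real_)
  if (is.null(clone_totals))
    clone_totals <- table(tcr$clonotype_key)
  clonal <- clone_totals[tcr$clonotype_key] >= 2L
  sum(clonal) / n
}

#' Clonal transition value between two subtypes in one sample
#'
#' Qualifying clonotypes are those with at least one TCR-informative cell in
#' each of the two subtypes; the value is the fraction of the two subtypes'
#' combined TCR-informative cells that carry a qualifying clonotype:
#' `sum_i (n_i_A + n_i_B) / (N_A + N_B)`. Symmetric in its arguments;
#' undefined (`NA`) when both subtypes lack TCR-informative cells.
#'
#' @param cells_a,cells_b Clonotype assignments for two distinct subtypes of
#'   the same sample.
#' @return A value in `[0, 1]`, or `NA_real_`.
#' @export
transition_value <- function(cells_a, cells_b) {
  samples <- unique(c(cells_a$sample_id, cells_b$sample_id))
  if (length(samples) > 1L)
    stop("transition_value expects cells from a single sample", call. = FALSE)
  sub_a <- unique(cells_a$subtype); sub_b <- unique(cells_b$subtype)
  if (length(intersect(sub_a, sub_b)))
    stop("self-transitions (identical subtypes) are excluded", call. = FALSE)
  ta <- cells_a[cells_a$has_tcr_info, , drop = FALSE]
  tb <- cells_b[cells_b$has_tcr_info, , drop = FALSE]
  n <- nrow(ta) + nrow(tb)
  if (n == 0L) return(NA_real_)
  shared <- intersect(unique(ta$clonotype_key), unique(tb$clonotype_key))
  (sum(ta$clonotype_key %in% shared) + sum(tb$clonotype_key %in% shared)) / n
}

#' Per-sample clonal expansion table
#'
#' [expansion_value()] for every (subtype, sample) with at least one
#' TCR-informative cell, with clonal status determined sample-wide.
#'
#' @param assignments Output of [assemble_clonotypes()].
#' @return Tibble `subtype`, `sample_id`, `group`, `n_tcr`, `expansion`.
#' @export
clonal_expansion <- function(assignments) {
  assignments |>
    dplyr::filter(.data$has_tcr_info) |>
    dplyr::left_join(clone_sizes(assignments),
                     by = c("sample_id", "clonotype_key")) |>
    dplyr::group_by(.data$subtype, .data$sample_id, .data$group) |>
    dplyr::summarise(n_tcr = dplyr::n(),
                     expansion = mean(.data$clone_size >= 2L),
                     .groups = "drop") |>
    dplyr::arrange(.data$subtype, .data$sample_id)
}

#' Per-sample clonal transition table
#'
#' [transition_value()] for every unordered pair of subtypes that both have
#' TCR-informative cells in a sample. Pairs sharing no clonotype get value 0.
#'
#' @param assignments Output of [assemble_clonotypes()].
#' @return Tibble `subtype_a`, `subtype_b` (`subtype_a < subtype_b`),
#'   `sample_id`, `group`, `n_pair`, `transition`.
#' @export
clonal_transitions <- function(assignments) {
  tcr <- assignments[assignments$has_tcr_info, , drop = FALSE]
  per <- tcr |>
    dplyr::count(.data$sample_id, .data$group, .data$subtype,
                 .data$clonotype_key, name = "n_cells")
  totals <- per |>
    dplyr::group_by(.data$sample_id, .data$group, .data$subtype) |>
    dplyr::summarise(n_sub = sum(.data$n_cells), .groups = "drop")

  pair_grid <- totals |>
    dplyr::inner_join(totals, by = c("sample_id", "group"),
                      suffix = c("_a", "_b"),
                      relationship = "many-to-many") |>
    dplyr::filter(.data$subtype_a < .data$subtype_b)

  shared <- per |>
    dplyr::inner_join(per, by = c("sample_id", "group", "clonotype_key"),
                      suffix = c("_a", "_b"),
                      relationship = "many-to-many") |>
    dplyr::filter(.data$subtype_a < .data$subtype_b) |>
    dplyr::group_by(.data$sample_id, .data$group, .data$subtype_a,
                    .data$subtype_b) |>
    dplyr::summarise(n_shared_cells = sum(.data$n_cells_a + .data$n_cells_b),
                     .groups = "drop")

  pair_grid |>
    dplyr::left_join(shared,
                     by = c("sample_id", "group", "subtype_a", "subtype_b")) |>
    dplyr::mutate(
      n_pair = .data$n_sub_a + .data$n_sub_b,
      transition = dplyr::coalesce(.data$n_shared_cells, 0L) / .data$n_pair) |>
    dplyr::select("subtype_a", "subtype_b", "sample_id", "group", "n_pair",
                  "transition") |>
    dplyr::arrange(.data$subtype_a, .data$subtype_b, .data$sample_id)
}

#' Group-mean clonal expansion (heatmap table)
#'
#' Arithmetic mean of per-sample expansion values over the samples of each
#' group, skipping samples where the value is undefined; the number of
#' contributing samples is recorded.
#'
#' @param expansion Output of [clonal_expansion()].
#' @return An `expansion_summary` tibble: `subtype`, `group`,
#'   `mean_expansion`, `n_samples`.
#' @export
summarize_expansion <- function(expansion) {
  out <- expansion |>
    dplyr::group_by(.data$subtype, .data$group) |>
    dplyr::summarise(
      mean_expansion = if (any(!is.na(.data$expansion)))
        mean(.data$expansion, na.rm = TRUE) else NA_real_,
      n_samples = sum(!is.na(.data$expansion)), .groups = "drop") |>
    dplyr::arrange(.data$subtype, .data$group)
  class(out) <- c("expansion_summary", class(out))
  out
}

#' Group-mean clonal transitions (network table)
#'
#' @param transitions Output of [clonal_transitions()].
#' @return A `transition_summary` tibble: `subtype_a`, `subtype_b`, `group`,
#'   `mean_transition`, `n_samples`.
#' @export
summarize_transitions <- function(transitions) {
  out <- transitions |>
    dplyr::group_by(.data$subtype_a, .data$subtype_b, .data$group) |>
    dplyr::summarise(
      mean_transition = if (any(!is.na(.data$transition)))
        mean(.data$transition, na.rm = TRUE) else NA_real_,
      n_samples = sum(!is.na(.data$transition)), .groups = "drop") |>
    dplyr::arrange(.data$subtype_a, .data$subtype_b, .data$group)
  class(out) <- c("transition_summary", class(out))
  out
}

#' Build the clonal-transition network with group-exclusivity flags
#'
#' One edge per subtype pair whose mean transition exceeds `epsilon` in at
#' least one group, with one weight column per group. An edge is exclusive to
#' group `g` when its mean is `> epsilon` in `g` and `<= epsilon` in every
#' other group (the "transitions exclusive to one cohort arm" highlight).
#'
#' @param transition_means Output of [summarize_transitions()].
#' @param epsilon Exclusivity threshold (default 0).
#' @return A `transition_network` tibble: `subtype_a`, `subtype_b`, one
#'   `weight_<group>` column per group, `exclusive_to` (`NA` when not
#'   exclusive). The group order is kept in the `groups` attribute.
#' @export
transition_network <- function(transition_means, epsilon = 0) {
  groups <- unique(transition_means$group)
  wide <- transition_means |>
    dplyr::mutate(mean_transition = dplyr::coalesce(.data$mean_transition,
                                                    0)) |>
    dplyr::select("subtype_a", "subtype_b", "group", "mean_transition") |>
    tidyr::pivot_wider(names_from = "group", values_from = "mean_transition",
                       names_prefix = "weight_", values_fill = 0)
  wcols <- paste0("weight_", groups)
  w <- as.matrix(wide[, wcols, drop = FALSE])
  pos <- w > epsilon
  keep <- rowSums(pos) > 0L
  exclusive <- ifelse(rowSums(pos) == 1L,
                      groups[max.col(pos, ties.method = "first")],
                      NA_character_)
  out <- wide[keep, , drop = FALSE]
  out$exclusive_to <- exclusive[keep]
  out <- dplyr::arrange(out, .data$subtype_a, .data$subtype_b)
  class(out) <- c("transition_network", class(out))
  attr(out, "groups") <- groups
  attr(out, "epsilon") <- epsilon
  out
}
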