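#' Per-sample cell-type proportions
#'
#' Subtype abundance per sample, expressed relative to a compartment
#' denominator: all immune cells, all non-immune cells, or all cells of the
#' sample. Within a sample and mode the proportions over that compartment's
#' subtypes sum to 1. Subtypes absent from a sample get proportion 0.
#'
#' @param meta Cell metadata with `cell`, `sample_id`, `group`, `subtype`
#'   and, unless `mode = "all"`, a `compartment` column
#'   (`"immune"`/`"non-immune"`).
#' @param mode Denominator compartment: `"immune"`, `"non-immune"` or
#'   `"all"`.
#' @return Tibble `sample_id`, `group`, `subtype`, `n_cells`, `denominator`,
#'   `proportion`.
#' @export
subtype_proportions <- function(meta, mode = c("immune", "non-immune",
                                               "all")) {
  mode <- match.arg(mode)
  if (mode != "all") {
    if (!"compartment" %in% names(meta))
      stop("compartment column required unless mode = \"all\"", call. = FALSE)
    meta <- meta[meta$compartment == mode, , drop = FALSE]
  }
  samples <- dplyr::distinct(meta, .data$sample_id, .data$group)
  counts <- meta |>
    dplyr::count(.data$sample_id, .data$group, .data$subtype,
                 name = "n_cells") |>
    tidyr::complete(tidyr::nesting(!!rlang::sym("sample_id"),
                                   !!rlang::sym("group")),
                    .data$subtype, fill = list(n_cells = 0L))
  denom <- counts |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(denominator = sum(.data$n_cells), .groups = "drop")
  out <- counts |>
    dplyr::left_join(denom, by = "sample_id") |>
    dplyr::mutate(proportion = ifelse(.data$denominator > 0,
                                      .data$n_cells / .data$denominator,
                                      NA_real_)) |>
    dplyr::arrange(.data$sample_id, .data$subtype)
  if (any(out$denominator == 0))
    warning("sample(s) with empty denominator; proportions undefined",
            call. = FALSE)
  out
}

#' Compare subtype proportions between two cohort groups
#'
#' Per-sample proportions of each subtype are compared between groups with a
#' Wilcoxon rank-sum test ([rank_sum_test()]; exact for small samples) or a
#' Welch two-sample t-test, one- or two-sided. `alternative = "greater"`
#' tests whether the first group's proportions tend larger.
#'
#' @param proportions A [subtype_proportions()] table.
#' @param subtypes Subtypes to test (default: all present).
#' @param groups Length-2 group labels (default: the two groups present, in
#'   table order).
#' @param test `"wilcoxon"` or `"t"`.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @param adjust Apply Benjamini-Hochberg correction across the tested
#'   subtypes (off by default; per-subtype p-values are reported as such).
#' @return Tibble `subtype`, `group1`, `group2`, `n1`, `n2`, `statistic`,
#'   `p_value` (and `p_adj` when `adjust`).
#' @export
compare_groups <- function(proportions, subtypes = NULL, groups = NULL,
                           test = c("wilcoxon", "t"),
                           alternative = c("two.sided", "greater", "less"),
                           adjust = FALSE) {
  test <- match.arg(test)
  alternative <- match.arg(alternative)
  if (is.null(groups)) groups <- unique(proportions$group)
  if (length(groups) != 2L)
    stop("compare_groups needs exactly two groups", call. = FALSE)
  if (is.null(subtypes)) subtypes <- sort(unique(proportions$subtype))

  rows <- lapply(subtypes, function(s) {
    d <- proportions[proportions$subtype == s &
                       !is.na(proportions$proportion), , drop = FALSE]
    x <- d$proportion[d$group == groups[[1L]]]
    y <- d$proportion[d$group == groups[[2L]]]
    if (length(x) < 2L || length(y) < 2L)
      stop(sprintf("subtype %s: a group has fewer than 2 samples", s),
           call. = FALSE)
    if (test == "wilcoxon") {
      r <- rank_sum_test(x, y, alternative = alternative)
      stat <- r$statistic; p <- r$p.value
    } else {
      r <- stats::t.test(x, y, alternative = alternative, var.equal = FALSE)
      stat <- unname(r$statistic); p <- r$p.value
    }
    tibble::tibble(subtype = s, group1 = groups[[1L]], group2 = groups[[2L]],
                   n1 = length(x), n2 = length(y), statistic = stat,
                   p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  out$test <- test
  out$alternative <- alternative
  if (adjust) out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

#' Spearman correlation of paired per-sample frequencies
#'
#' The coefficient is the product-moment correlation of mid-ranks (tied
#' values receive average ranks). The p-value comes from the exact
#' permutation null when `n <= 8`, and from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` otherwise.
#'
#' @param x,y Paired numeric vectors, `length >= 3`.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return A `cor_test` list: `estimate` (rho), `p.value`, `n`, `exact`.
#' @export
correlate_frequencies <- function(x, y, alternative = c("two.sided",
                                                        "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; correlation undefined", call. = FALSE)
    return(structure(list(estimate = NA_real_, p.value = NA_real_, n = n,
                          exact = NA), class = "cor_test"))
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- stats::cor(rx, ry)
  if (n <= 8L) {
    perms <- all_permutations(n)
    null_rho <- apply(perms, 1L, function(idx) stats::cor(rx, ry[idx]))
    eps <- 1e-12
    p <- switch(alternative,
                two.sided = mean(abs(null_rho) >= abs(rho) - eps),
                greater = mean(null_rho >= rho - eps),
                less = mean(null_rho <= rho + eps))
    exact <- TRUE
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- switch(alternative,
                two.sided = 2 * stats::pt(-abs(tt), df = n - 2),
                greater = stats::pt(tt, df = n - 2, lower.tail = FALSE),
                less = stats::pt(tt, df = n - 2))
    exact <- FALSE
  }
  structure(list(estimate = rho, p.value = min(1, p), n = n, exact = exact),
            class = "cor_test")
}

#' @export
#' @method print cor_test
print.cor_test <- function(x, ...) {
  cat(sprintf("Spearman correlation: rho = %.4f, p = %.4g (%s, n = %d)\n",
              x$estimate, x$p.value,
              if (isTRUE(x$exact)) "exact permutation" else "t approximation",
              x$n))
  invisible(x)
}
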