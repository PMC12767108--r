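#' Log-normalize a count matrix
#'
#' Per-cell library-size normalization followed by a log transform:
#' `value = ln(1 + count * scale / cell_total)` with `scale = 1e4` by
#' default. Zero counts map to zero; applying the inverse transform and
#' summing a cell's column recovers `scale` exactly.
#'
#' @param m Sparse gene x cell count matrix.
#' @param scale Scale factor (counts-per-`scale`).
#' @return Sparse matrix of normalized values, same sparsity pattern.
#' @export
lognormalize <- function(m, scale = 1e4) {
  totals <- Matrix::colSums(m)
  if (any(totals == 0))
    stop(paste0("zero-total cell(s): ",
                paste(utils::head(colnames(m)[totals == 0], 5L),
                      collapse = ", ")), call. = FALSE)
  nm <- m %*% Matrix::Diagonal(x = scale / totals)
  nm@x <- log1p(nm@x)
  dimnames(nm) <- dimnames(m)
  methods::as(nm, "CsparseMatrix")
}

# Two-sided normal-approximation p for a rank-sum W (sum of ranks of the
# first group), with tie correction and continuity correction. `tie_adj` is
# sum(t^3 - t) over tied value groups.
ranksum_p_normal <- function(W, n_in, n_total, tie_adj,
                             alternative = "two.sided") {
  n_out <- n_total - n_in
  mu <- n_in * (n_total + 1) / 2
  sig2 <- n_in * n_out / 12 *
    ((n_total + 1) - tie_adj / (n_total * (n_total - 1)))
  if (sig2 <= 0) return(1)
  sig <- sqrt(sig2)
  cc <- 0.5
  switch(alternative,
         two.sided = min(1, 2 * stats::pnorm(max(abs(W - mu) - cc, 0) / sig,
                                             lower.tail = FALSE)),
         greater = stats::pnorm((W - mu - cc) / sig, lower.tail = FALSE),
         less = stats::pnorm((W - mu + cc) / sig, lower.tail = TRUE))
}

tie_adjustment <- function(x) {
  t <- tabulate(match(x, unique(x)))
  sum(t^3 - t)
}

#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum test implemented from first principles. For
#' `length(x) + length(y) <= 12` with no tied values the null distribution of
#' the rank sum is enumerated exactly (two-sided p is twice the smaller tail,
#' capped at 1); otherwise a tie-corrected normal approximation with
#' continuity correction is used.
#'
#' @param x,y Numeric samples (both non-empty).
#' @param alternative `"two.sided"` (default), `"greater"` (x tends larger)
#'   or `"less"`.
#' @return A `ranksum_test` list: `statistic` (rank sum of `x`), `p.value`,
#'   `exact`, `alternative`, `n`.
#' @export
rank_sum_test <- function(x, y, alternative = c("two.sided", "greater",
                                                "less")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  m <- length(x); n_total <- m + length(y)
  pooled <- c(x, y)
  r <- rank(pooled, ties.method = "average")
  W <- sum(r[seq_len(m)])
  ties <- anyDuplicated(pooled) > 0L
  if (n_total <= 12L && !ties) {
    combos <- utils::combn(n_total, m)
    null_w <- colSums(matrix(seq_len(n_total)[combos], nrow = m))
    p <- switch(alternative,
                two.sided = min(1, 2 * min(mean(null_w <= W),
                                           mean(null_w >= W))),
                greater = mean(null_w >= W),
                less = mean(null_w <= W))
    exact <- TRUE
  } else {
    p <- ranksum_p_normal(W, m, n_total, tie_adjustment(pooled), alternative)
    exact <- FALSE
  }
  structure(list(statistic = W, p.value = p, exact = exact,
                 alternative = alternative, n = c(m, n_total - m)),
            class = "ranksum_test")
}

#' @export
#' @method print ranksum_test
print.ranksum_test <- function(x, ...) {
  cat(sprintf("Rank-sum test (%s): W = %g, p = %.4g (%s, n = %d vs %d)\n",
              x$alternative, x$statistic, x$p.value,
              if (x$exact) "exact" else "normal approximation",
              x$n[[1L]], x$n[[2L]]))
  invisible(x)
}

#' Marker-detection criteria
#'
#' Marker genes for a cluster must show a Bonferroni-adjusted rank-sum
#' p-value below `alpha`, a log2 fold change above `logfc` and expression in
#' more than `min_pct` percent of cells on at least one side of the
#' comparison. For differential-expression screening use `min_pct = 10` and
#' filter with [deg_filter()].
#'
#' @param min_pct Percent-expressed pre-filter (either side).
#' @param logfc log2 fold-change threshold.
#' @param alpha Bonferroni-adjusted significance level.
#' @return A `marker_criteria` list.
#' @export
marker_criteria <- function(min_pct = 25, logfc = 0.25, alpha = 0.05) {
  structure(list(min_pct = min_pct, logfc = logfc, alpha = alpha),
            class = "marker_criteria")
}

#' Detect cluster markers by one-vs-rest rank-sum tests
#'
#' For each requested cluster, every gene expressed in more than
#' `criteria$min_pct` percent of cells inside or outside the cluster is
#' tested with a two-sided rank-sum test on the normalized values
#' (tie-corrected normal approximation; the cell numbers here are far beyond
#' the exact-enumeration regime). P-values are Bonferroni-adjusted by the
#' number of genes actually tested for that cluster. The log2 fold change is
#' computed on back-transformed means with pseudocount 1:
#' `log2((mean(expm1(in)) + 1) / (mean(expm1(out)) + 1))`.
#'
#' @param nm Log-normalized matrix ([lognormalize()]).
#' @param labels Cluster label per column of `nm`.
#' @param clusters Clusters to test (default: all).
#' @param criteria A [marker_criteria()].
#' @return Tibble with one row per tested (gene, cluster): `gene`, `cluster`,
#'   `p`, `p_bonf`, `log2FC`, `pct_in`, `pct_out`, `n_tested`,
#'   `passes_marker`.
#' @export
find_markers <- function(nm, labels, clusters = NULL,
                         criteria = marker_criteria()) {
  stopifnot(length(labels) == ncol(nm))
  labels <- as.character(labels)
  if (is.null(clusters)) clusters <- sort(unique(labels))
  unknown <- setdiff(clusters, labels)
  if (length(unknown))
    stop(paste0("unknown cluster label(s): ", paste(unknown, collapse = ", ")),
         call. = FALSE)

  n_cells <- ncol(nm)
  n_genes <- nrow(nm)
  memb <- vapply(clusters, function(cl) labels == cl,
                 logical(n_cells))                      # cells x clusters
  n_in <- colSums(memb)
  small <- clusters[n_in < 3L]
  if (length(small))
    stop(paste0("cluster(s) with fewer than 3 cells: ",
                paste(small, collapse = ", ")), call. = FALSE)

  # percent expressed and back-transformed means per cluster, via sparse ops
  pat <- nm
  pat@x <- rep(1, length(pat@x))
  in_nz <- as.matrix(pat %*% memb)                       # genes x clusters
  tot_nz <- Matrix::rowSums(pat)
  ex <- nm
  ex@x <- expm1(ex@x)
  in_sum <- as.matrix(ex %*% memb)
  tot_sum <- Matrix::rowSums(ex)

  pct_in <- sweep(in_nz, 2L, n_in, "/") * 100
  pct_out <- sweep(outer(tot_nz, rep(1, length(clusters))) - in_nz, 2L,
                   n_cells - n_in, "/") * 100
  mean_in <- sweep(in_sum, 2L, n_in, "/")
  mean_out <- sweep(outer(tot_sum, rep(1, length(clusters))) - in_sum, 2L,
                    n_cells - n_in, "/")
  log2fc <- log2((mean_in + 1) / (mean_out + 1))

  tested <- pct_in > criteria$min_pct | pct_out > criteria$min_pct
  genes_to_rank <- which(rowSums(tested) > 0L)

  # rank-sum p-values, exploiting sparsity: all zero entries of a gene share
  # one midrank, so only the nonzero values need sorting
  tnm <- Matrix::t(nm[genes_to_rank, , drop = FALSE])   # cells x genes
  ptr <- tnm@p; rows1 <- tnm@i + 1L; vals <- tnm@x
  p <- matrix(NA_real_, nrow = n_genes, ncol = length(clusters))
  for (gi in seq_along(genes_to_rank)) {
    g <- genes_to_rank[[gi]]
    span <- if (ptr[gi + 1L] > ptr[gi]) (ptr[gi] + 1L):ptr[gi + 1L] else
      integer()
    nz_rows <- rows1[span]
    v <- vals[span]
    k <- length(v)
    z <- n_cells - k
    r_nz <- z + rank(v, ties.method = "average")
    ta <- (z^3 - z) + tie_adjustment(v)
    msub <- memb[nz_rows, , drop = FALSE]
    n_in_nz <- colSums(msub)
    sum_r_in <- as.vector(crossprod(msub, r_nz))
    for (ci in which(tested[g, ])) {
      W <- (n_in[[ci]] - n_in_nz[[ci]]) * (z + 1) / 2 + sum_r_in[[ci]]
      p[g, ci] <- ranksum_p_normal(W, n_in[[ci]], n_cells, ta)
    }
  }

  n_tested <- colSums(tested)
  rows <- lapply(seq_along(clusters), function(ci) {
    sel <- which(tested[, ci])
    pvec <- p[sel, ci]
    tibble::tibble(
      gene = rownames(nm)[sel],
      cluster = clusters[[ci]],
      p = pvec,
      p_bonf = pmin(1, pvec * n_tested[[ci]]),
      log2FC = log2fc[sel, ci],
      pct_in = pct_in[sel, ci],
      pct_out = pct_out[sel, ci],
      n_tested = n_tested[[ci]])
  })
  out <- dplyr::bind_rows(rows)
  out$passes_marker <- out$p_bonf < criteria$alpha &
    out$log2FC > criteria$logfc
  dplyr::arrange(out, .data$cluster, .data$gene)
}

#' Filter marker results to differential-expression calls
#'
#' Retains genes expressed in more than `min_pct` percent of the cluster's
#' cells with a fold change above `fc_threshold` (fold change, not log2).
#'
#' @param results A [find_markers()] tibble (typically computed with
#'   `marker_criteria(min_pct = 10)`).
#' @param fc_threshold Fold-change threshold, conventionally 2 or 1.5.
#' @param min_pct Percent-expressed requirement inside the cluster.
#' @return The retained rows, with a `fold_change` column added.
#' @export
deg_filter <- function(results, fc_threshold = 2, min_pct = 10) {
  results |>
    dplyr::mutate(fold_change = 2^.data$log2FC) |>
    dplyr::filter(.data$pct_in > min_pct,
                  .data$fold_change > fc_threshold)
}
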