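# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's own data-flow (dplyr joins, sparse tricks): plain loops
# and dictionaries, so agreement is meaningful.

mk_counts <- function(mat, genes = NULL, cells = NULL) {
  genes <- genes %||% sprintf("G%03d", seq_len(nrow(mat)))
  cells <- cells %||% sprintf("s1:C%03d", seq_len(ncol(mat)))
  m <- Matrix::Matrix(mat, sparse = TRUE, dimnames = list(genes, cells))
  methods::as(m, "CsparseMatrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Assignment tibble straight from clonotype keys (bypasses chain assembly).
mk_assignments <- function(keys, subtypes, sample_id = "s1", group = "g1",
                           has_tcr = NULL) {
  n <- length(keys)
  has_tcr <- has_tcr %||% !is.na(keys)
  tibble::tibble(
    cell = sprintf("%s:BC%04d", sample_id, seq_len(n)),
    sample_id = sample_id, group = group,
    subtype = rep_len(subtypes, n),
    cdr3a = NA_character_, cdr3b = NA_character_,
    clonotype_key = ifelse(has_tcr, keys, NA_character_),
    has_tcr_info = has_tcr)
}

rand_repertoire <- function(n_cells = NULL, n_clonotypes = NULL,
                            n_subtypes = NULL, p_tcr = 0.9,
                            sample_id = "s1", group = "g1") {
  n_cells <- n_cells %||% sample(5:100, 1)
  n_clonotypes <- n_clonotypes %||% sample(1:30, 1)
  n_subtypes <- n_subtypes %||% sample(1:5, 1)
  keys <- sprintf("ct%02d", sample.int(n_clonotypes, n_cells, replace = TRUE))
  subs <- sprintf("S%d", sample.int(n_subtypes, n_cells, replace = TRUE))
  has <- stats::runif(n_cells) < p_tcr
  mk_assignments(keys, subs, sample_id, group, has_tcr = has)
}

# Expansion oracle: per-cell loop over a clonotype-count dictionary.
bf_expansion <- function(asg, sub) {
  tcr <- asg[asg$has_tcr_info, , drop = FALSE]
  dict <- list()
  for (k in tcr$clonotype_key) dict[[k]] <- (dict[[k]] %||% 0L) + 1L
  cells <- tcr[tcr$subtype == sub, , drop = FALSE]
  if (nrow(cells) == 0L) return(NA_real_)
  clonal <- 0L
  for (k in cells$clonotype_key) if (dict[[k]] >= 2L) clonal <- clonal + 1L
  clonal / nrow(cells)
}

# Transition oracle: explicit shared-clonotype enumeration.
bf_transition <- function(asg, a, b) {
  tcr <- asg[asg$has_tcr_info, , drop = FALSE]
  ca <- tcr$clonotype_key[tcr$subtype == a]
  cb <- tcr$clonotype_key[tcr$subtype == b]
  n <- length(ca) + length(cb)
  if (n == 0L) return(NA_real_)
  num <- 0L
  for (k in unique(c(ca, cb))) {
    na <- sum(ca == k); nb <- sum(cb == k)
    if (na >= 1L && nb >= 1L) num <- num + na + nb
  }
  num / n
}

# Rank-sum oracle via the Mann-Whitney U count over every split of the
# pooled values (pairwise-comparison statistic, not rank sums).
bf_ranksum_p <- function(x, y, alternative = "two.sided") {
  ustat <- function(xx, yy) {
    u <- 0
    for (xi in xx) for (yj in yy) {
      u <- u + (xi > yj) + 0.5 * (xi == yj)
    }
    u
  }
  pooled <- c(x, y)
  m <- length(x)
  obs <- ustat(x, y)
  splits <- utils::combn(length(pooled), m)
  null_u <- apply(splits, 2L, function(idx)
    ustat(pooled[idx], pooled[-idx]))
  switch(alternative,
         two.sided = min(1, 2 * min(mean(null_u <= obs),
                                    mean(null_u >= obs))),
         greater = mean(null_u >= obs),
         less = mean(null_u <= obs))
}

bf_spearman_p <- function(x, y) {
  rho <- stats::cor(rank(x), rank(y))
  perms <- NULL
  permute <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in permute(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  null_rho <- vapply(permute(seq_along(y)),
                     function(idx) stats::cor(rank(x), rank(y)[idx]),
                     numeric(1))
  list(rho = rho, p = mean(abs(null_rho) >= abs(rho) - 1e-12))
}

# Dirichlet parameters for arbitrary group names: first group gets the
# disease-style composition, the rest the control-style one.
dirichlet_for <- function(group_names) {
  base <- formals(sim_config)$dirichlet
  base <- eval(base)
  out <- c(base[1], rep(base[2], length(group_names) - 1L))
  names(out) <- group_names
  out
}

# Cohort configuration used by the QC-exactness fixture: 50 cells/sample so
# the 98th-percentile interpolation position exceeds n - 1 (exactly the
# planted outlier is above it), a 9000-gene panel so a >8000-feature violator
# is plantable, and baseline means floored high enough that no gene falls
# below 3 expressing cells by chance.
qc_fixture_config <- function(seed = 42L) {
  sim_config(groups = c(g1 = 1L, g2 = 1L),
             dirichlet = dirichlet_for(c("g1", "g2")),
             cells_per_sample = 50L,
             n_genes = 9000L,
             base_mean_meanlog = 0, base_mean_sdlog = 0.5,
             base_mean_range = c(0.8, 8),
             markers_per_subtype = 2L,
             violator_rates = c(mito = 1, ribo = 1, hb = 1, low_features = 1,
                                high_features = 1, umi = 1),
             n_rare_genes = 1L,
             doublet_rate = 0.04,
             sharing = list(),
             seed = seed)
}
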