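test_that("gene min-cell filter matches a naive prevalence scan", {
  set.seed(4)
  mat <- matrix(rpois(50 * 30, 0.4), 50, 30)
  m <- mk_counts(mat)
  for (k in c(0L, 2L, 3L, 5L)) {
    got <- rownames(filter_genes_min_cells(m, k))
    want <- rownames(m)[vapply(seq_len(nrow(mat)), function(g)
      sum(mat[g, ] > 0) >= k, logical(1))]
    expect_identical(got, want)
  }
  expect_identical(filter_genes_min_cells(m, 0L), m)
  # boundary: a gene in exactly 2 cells dies at k = 3
  mat2 <- rbind(rep(1, 10), c(1, 1, rep(0, 8)))
  m2 <- mk_counts(mat2)
  expect_identical(rownames(filter_genes_min_cells(m2, 3L)), "G001")
})

test_that("feature bounds are boundary-inclusive, matching the removal predicates", {
  # cell with exactly 500 detected genes is retained, 499 and 8001 removed
  n_genes <- 600L
  detected <- c(499L, 500L, 501L)
  mat <- matrix(0L, n_genes, 3L)
  for (j in 1:3) mat[seq_len(detected[j]), j] <- 1L
  m <- mk_counts(mat)
  kept <- colnames(filter_cells_feature_bounds(m, 500L, 8000L))
  expect_identical(kept, colnames(m)[2:3])

  set.seed(5)
  mat <- matrix(rpois(40 * 25, 0.6), 40, 25)
  m <- mk_counts(mat)
  got <- colnames(filter_cells_feature_bounds(m, 5L, 15L))
  f <- colSums(mat > 0)
  expect_identical(got, colnames(m)[f >= 5 & f <= 15])
  # idempotent in isolation
  once <- filter_cells_feature_bounds(m, 5L, 15L)
  expect_identical(filter_cells_feature_bounds(once, 5L, 15L), once)
})

test_that("UMI quantile cut uses linear interpolation per sample", {
  m <- mk_counts(matrix(1:100, nrow = 1))
  kept <- filter_cells_umi_quantile(m, 0.98)
  # threshold 98.02: totals 99 and 100 are strictly above
  expect_equal(ncol(kept), 98L)
  expect_false(any(c("s1:C099", "s1:C100") %in% colnames(kept)))

  # all totals equal: nothing removed
  m_eq <- mk_counts(matrix(5L, 1, 20))
  expect_equal(ncol(filter_cells_umi_quantile(m_eq, 0.98)), 20L)

  # not idempotent: the survivors define a new, lower quantile
  again <- filter_cells_umi_quantile(kept, 0.98)
  expect_lt(ncol(again), ncol(kept))

  expect_warning(filter_cells_umi_quantile(mk_counts(matrix(3L, 1, 1))),
                 "fewer than 2")
})

test_that("per-sample quantile application differs from pooled", {
  # sample A totals 1..50, sample B totals 101..150
  a <- mk_counts(matrix(1:50, nrow = 1), cells = sprintf("A:C%03d", 1:50))
  b <- mk_counts(matrix(101:150, nrow = 1), cells = sprintf("B:C%03d", 1:50))
  pooled <- cbind(a, b)
  kept_pooled <- colnames(filter_cells_umi_quantile(pooled, 0.98))
  kept_a <- colnames(filter_cells_umi_quantile(a, 0.98))
  # pooled keeps every A cell; per-sample removes A's top cell
  expect_true(all(colnames(a) %in% kept_pooled))
  expect_false("A:C050" %in% kept_a)
})

test_that("fraction filter removes strictly above the percentage cap", {
  mat <- matrix(0L, 2, 3,
                dimnames = list(c("MT-ND1", "G001"),
                                c("s1:C1", "s1:C2", "s1:C3")))
  mat["MT-ND1", ] <- c(16L, 15L, 10L)
  mat["G001", ] <- c(84L, 85L, 90L)
  m <- methods::as(Matrix::Matrix(mat, sparse = TRUE), "CsparseMatrix")
  kept <- colnames(filter_cells_fraction(m, "^MT-", 15))
  expect_identical(kept, c("s1:C2", "s1:C3"))   # exactly 15% is retained

  set.seed(6)
  big <- matrix(rpois(30 * 40, 2), 30, 40)
  genes <- c(sprintf("MT-%02d", 1:5), sprintf("G%03d", 1:25))
  m2 <- mk_counts(big, genes = genes)
  got <- colnames(filter_cells_fraction(m2, "^MT-", 20))
  share <- 100 * colSums(big[1:5, ]) / colSums(big)
  expect_identical(got, colnames(m2)[share <= 20])

  expect_warning(out <- filter_cells_fraction(m2, "^XX-", 20), "no genes")
  expect_identical(out, m2)
})

test_that("doublet removal consumes the metadata flag exactly", {
  m <- mk_counts(matrix(1L, 3, 4))
  meta <- tibble::tibble(cell = colnames(m),
                         doublet_flag = c(FALSE, TRUE, FALSE, TRUE))
  expect_identical(colnames(remove_doublets(m, meta)),
                   colnames(m)[c(1, 3)])
  meta0 <- meta; meta0$doublet_flag <- FALSE
  expect_identical(remove_doublets(m, meta0), m)

  # flag for a barcode absent from the matrix is ignored with a warning
  meta_extra <- dplyr::bind_rows(meta0, tibble::tibble(
    cell = "s1:GHOST", doublet_flag = TRUE))
  expect_warning(out <- remove_doublets(m, meta_extra), "absent")
  expect_identical(out, m)

  # missing flags: error by default, singlet under permissive mode
  meta_miss <- meta[1:2, ]
  expect_error(remove_doublets(m, meta_miss), "no doublet flag")
  kept <- remove_doublets(m, meta_miss, missing = "keep")
  expect_identical(colnames(kept), colnames(m)[c(1, 3, 4)])
})

test_that("gene-set drop removes the full special panel and is idempotent", {
  cfg <- sim_config()
  set.seed(1)
  panel <- clonodyn:::build_gene_panel(cfg)
  m <- mk_counts(matrix(1L, length(panel$genes), 2), genes = panel$genes)
  dropped <- drop_gene_sets(m)
  expect_equal(nrow(m) - nrow(dropped), 119L)
  expect_identical(drop_gene_sets(dropped), dropped)
  # matrix without any set member: identity
  plain <- mk_counts(matrix(1L, 5, 2), genes = sprintf("G%d", 1:5))
  expect_identical(drop_gene_sets(plain), plain)
})

test_that("full QC chain removes exactly the planted violators, stage by stage", {
  cfg <- qc_fixture_config()
  co <- simulate_cohort(cfg, components = "counts")
  truth <- co$truth$qc
  for (sid in names(co$counts)) {
    # cohort-wide metadata flags the other sample's doublets too
    res <- suppressWarnings(run_qc(co$counts[[sid]], qc_thresholds(),
                                   co$meta))
    rep <- res$report
    tr <- truth[truth$sample_id == sid, ]
    removed_at <- function(stage) rep$removed[[which(rep$stage == stage)]]
    # feature-bound stage removes exactly the low+high planted cells
    expect_setequal(removed_at("feature_bounds"),
                    tr$id[tr$stage %in% c("low_features", "high_features")])
    expect_setequal(removed_at("gene_min_cells"),
                    tr$id[tr$stage == "gene_min_cells"])
    expect_setequal(removed_at("umi_quantile"),
                    tr$id[tr$stage == "umi_quantile"])
    expect_setequal(removed_at("doublet"), tr$id[tr$stage == "doublet"])
    expect_setequal(removed_at("mito_fraction"),
                    tr$id[tr$stage == "mito_fraction"])
    expect_setequal(removed_at("ribo_fraction"),
                    tr$id[tr$stage == "ribo_fraction"])
    expect_setequal(removed_at("hb_fraction"),
                    tr$id[tr$stage == "hb_fraction"])
    # telescoping: after of stage k = before of stage k+1
    expect_identical(rep$cells_after[-nrow(rep)], rep$cells_before[-1])
    expect_identical(rep$genes_after[-nrow(rep)], rep$genes_before[-1])
    # removed cell identifiers are disjoint across stages
    cells_removed <- rep$removed[rep$stage != "gene_min_cells" &
                                   rep$stage != "drop_gene_sets"]
    expect_equal(anyDuplicated(unlist(cells_removed)), 0L)
  }
})

test_that("vacuous thresholds leave the matrix untouched", {
  m <- mk_counts(matrix(1L, 10, 8))   # equal totals: quantile removes none
  th <- qc_thresholds(min_cells_per_gene = 0L, min_features = 1L,
                      max_features = 10000L, umi_quantile = 0.98,
                      max_mito_pct = 100, max_ribo_pct = 100,
                      max_hb_pct = 100)
  meta <- tibble::tibble(cell = colnames(m), doublet_flag = FALSE)
  # the toy gene names match none of the special sets; those warnings are
  # the point of the vacuous configuration
  res <- suppressWarnings(run_qc(m, th, meta))
  expect_identical(as.matrix(res$matrix), as.matrix(m))
})

test_that("QC retention is invariant to cell and gene order", {
  cfg <- qc_fixture_config(seed = 77L)
  co <- simulate_cohort(cfg, components = "counts")
  m <- co$counts[[1L]]
  set.seed(8)
  perm <- m[sample(nrow(m)), sample(ncol(m))]
  r1 <- suppressWarnings(run_qc(m, qc_thresholds(), co$meta))
  r2 <- suppressWarnings(run_qc(perm, qc_thresholds(), co$meta))
  expect_setequal(colnames(r1$matrix), colnames(r2$matrix))
  expect_setequal(rownames(r1$matrix), rownames(r2$matrix))
})

test_that("qc_report tidiers summarise the chain", {
  m <- mk_counts(matrix(rpois(200, 1), 20, 10))
  meta <- tibble::tibble(cell = colnames(m), doublet_flag = FALSE)
  res <- suppressWarnings(run_qc(m, qc_thresholds(min_features = 1L), meta))
  td <- tidy(res$report)
  expect_false("removed" %in% names(td))
  gl <- glance(res$report)
  expect_equal(gl$cells_initial, 10L)
  expect_equal(gl$cells_final, ncol(res$matrix))
})
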