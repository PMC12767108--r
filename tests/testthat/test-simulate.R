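small_cfg <- function(...) {
  sim_config(groups = c(g1 = 2L, g2 = 2L),
             dirichlet = dirichlet_for(c("g1", "g2")),
             cells_per_sample = 200L,
             sharing = list(), doublet_rate = 0, chain_dropout = 0,
             n_rare_genes = 0L,
             violator_rates = c(mito = 0, ribo = 0, hb = 0, low_features = 0,
                                high_features = 0, umi = 0),
             ...)
}

test_that("a fixed seed fixes every emitted byte", {
  cfg <- sim_config(groups = c(g1 = 1L, g2 = 1L),
                    dirichlet = dirichlet_for(c("g1", "g2")),
                    sharing = list(list(subtype_a = "Trm", subtype_b = "Teff",
                                        group = "g1", n_clones = 2L,
                                        cells_per_side = c(2L, 3L))),
                    cells_per_sample = 120L, seed = 7L)
  c1 <- suppressWarnings(simulate_cohort(cfg))
  c2 <- suppressWarnings(simulate_cohort(cfg))
  expect_identical(c1$chains, c2$chains)
  expect_identical(c1$meta, c2$meta)
  expect_identical(lapply(c1$counts, as.matrix),
                   lapply(c2$counts, as.matrix))
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  write_cohort(c1, d1); write_cohort(c2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  md1 <- unname(tools::md5sum(file.path(d1, sort(f1))))
  md2 <- unname(tools::md5sum(file.path(d2, sort(f1))))
  expect_identical(md1, md2)
})

test_that("clonal-mass extremes produce saturated and empty expansion", {
  cells <- tibble::tibble(barcode = sprintf("BC%03d", 1:50),
                          sample_id = "s1", subtype = "Teff",
                          cell = sprintf("s1:BC%03d", 1:50))
  cfg0 <- small_cfg(expansion_mass = c(Teff = 0))
  set.seed(5)
  rp <- simulate_repertoire(cfg0, "s1", "g1", cells)
  expect_equal(length(unique(rp$assignment$clonotype_id)), 50L)

  cfg1 <- small_cfg(expansion_mass = c(Teff = 1))
  set.seed(5)
  rp1 <- simulate_repertoire(cfg1, "s1", "g1", cells)
  sizes <- table(rp1$assignment$clonotype_id)
  expect_true(all(sizes >= 2L))
})

test_that("realized clonal mass concentrates on its target", {
  cfg <- small_cfg(expansion_mass = c(Teff = 0.5))
  cells <- tibble::tibble(barcode = sprintf("BC%04d", 1:1000),
                          sample_id = "s1", subtype = "Teff",
                          cell = sprintf("s1:BC%04d", 1:1000))
  set.seed(11)
  realized <- replicate(100, {
    rp <- simulate_repertoire(cfg, "s1", "g1", cells)
    sizes <- table(rp$assignment$clonotype_id)
    mean(sizes[as.character(rp$assignment$clonotype_id)] >= 2L)
  })
  expect_lt(abs(mean(realized) - 0.5), 0.02)
})

test_that("shared clones appear only in the configured subtype pair and group", {
  cfg <- sim_config(groups = c(g1 = 3L, g2 = 3L),
                    dirichlet = dirichlet_for(c("g1", "g2")),
                    cells_per_sample = 300L,
                    doublet_rate = 0, chain_dropout = 0,
                    sharing = list(list(subtype_a = "Trm", subtype_b = "Teff",
                                        group = "g1", n_clones = 3L,
                                        cells_per_side = c(2L, 3L))),
                    seed = 9L)
  co <- simulate_cohort(cfg, components = "repertoire")
  sh <- co$truth$shared
  expect_true(all(grepl("^g1", sh$sample_id)))
  expect_true(all(sh$subtype_a == "Trm" & sh$subtype_b == "Teff"))

  asg <- assemble_clonotypes(co$chains, co$meta)
  tr <- clonal_transitions(asg)
  pos <- tr[tr$transition > 0, ]
  expect_true(all(pos$group == "g1"))
  expect_true(all(pos$subtype_a == "Teff" & pos$subtype_b == "Trm"))
})

test_that("doublets are cross-subtype sums and vanish at rate zero", {
  cfg0 <- small_cfg()
  co0 <- simulate_cohort(cfg0)
  expect_equal(sum(co0$meta$doublet_flag), 0L)

  cfg <- sim_config(groups = c(g1 = 1L),
                    dirichlet = dirichlet_for("g1"),
                    cells_per_sample = 150L,
                    doublet_rate = 0.1, sharing = list(),
                    n_rare_genes = 0L,
                    violator_rates = c(mito = 0, ribo = 0, hb = 0,
                                       low_features = 0, high_features = 0,
                                       umi = 0),
                    seed = 2L)
  set.seed(2)
  panel <- clonodyn:::build_gene_panel(cfg)
  cells <- tibble::tibble(barcode = sprintf("BC%03d", 1:150),
                          sample_id = "g101",
                          subtype = rep(c("Teff", "B", "NK"), each = 50))
  cells$cell <- qualify_barcode("g101", cells$barcode)
  sc <- simulate_counts(cells, cfg, panel, sample_id = "g101")
  expect_equal(nrow(sc$doublets), 15L)
  m <- as.matrix(sc$counts)
  for (i in seq_len(nrow(sc$doublets))) {
    d <- sc$doublets[i, ]
    expect_equal(m[, d$cell], m[, d$parent1] + m[, d$parent2])
    p1 <- cells$subtype[cells$cell == d$parent1]
    p2 <- cells$subtype[cells$cell == d$parent2]
    expect_true(p1 != p2)
  }
})

test_that("planted fraction violators exceed their thresholds when recomputed", {
  cfg <- qc_fixture_config(seed = 21L)
  co <- simulate_cohort(cfg, components = "counts")
  qc <- co$truth$qc
  for (sid in unique(qc$sample_id)) {
    m <- co$counts[[sid]]
    totals <- Matrix::colSums(m)
    mito <- resolve_gene_set(rownames(m), "^MT-")
    cell <- qc$id[qc$stage == "mito_fraction" & qc$sample_id == sid]
    expect_gt(100 * sum(m[mito, cell]) / totals[[cell]], 15)
    cell <- qc$id[qc$stage == "low_features" & qc$sample_id == sid]
    expect_lt(sum(m[, cell] > 0), 500)
    cell <- qc$id[qc$stage == "high_features" & qc$sample_id == sid]
    expect_gt(sum(m[, cell] > 0), 8000)
    cell <- qc$id[qc$stage == "umi_quantile" & qc$sample_id == sid]
    expect_equal(names(which.max(totals)), cell)
  }
})

test_that("planted markers are elevated about fourfold", {
  cfg <- sim_config(groups = c(g1 = 1L), cells_per_sample = 1200L,
                    dirichlet = list(g1 = c(naive = 1, Teff = 1, Tem = 1e-4,
                                            Trm = 1e-4, Tex = 1e-4, B = 1e-4,
                                            NK = 1e-4, TFC = 1e-4,
                                            endothelial = 1e-4)),
                    doublet_rate = 0, sharing = list(), n_rare_genes = 0L,
                    violator_rates = c(mito = 0, ribo = 0, hb = 0,
                                       low_features = 0, high_features = 0,
                                       umi = 0),
                    seed = 31L)
  set.seed(31)
  panel <- clonodyn:::build_gene_panel(cfg)
  cells <- tibble::tibble(barcode = sprintf("BC%04d", 1:1200),
                          sample_id = "s1",
                          subtype = rep(c("naive", "Teff"), each = 600))
  cells$cell <- qualify_barcode("s1", cells$barcode)
  sc <- simulate_counts(cells, cfg, panel, sample_id = "s1")
  m <- sc$counts
  teff_markers <- panel$markers$gene[panel$markers$subtype == "Teff"]
  in_cells <- cells$cell[cells$subtype == "Teff"]
  out_cells <- cells$cell[cells$subtype == "naive"]
  ratio <- vapply(teff_markers, function(g)
    mean(m[g, in_cells]) / mean(m[g, out_cells]), numeric(1))
  expect_true(all(ratio > 2 & ratio < 7))
  expect_lt(abs(mean(ratio) - 4), 1)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(subtypes = c("A", "A", "B")), "duplicate")
  expect_error(sim_config(dirichlet = list(GD = c(bad = 1),
                                           control = c(bad = 1))),
               "dirichlet")
  expect_error(sim_config(n_genes = 150L), "too small")
  expect_error(sim_config(chain_dropout = 1.5), "probabilities")
  expect_error(sim_config(sharing = list(list(subtype_a = "Trm"))),
               "sharing rule")
})

test_that("composition draws have the right shape and totals", {
  cfg <- small_cfg()
  set.seed(3)
  comp <- simulate_composition(cfg, "g1", 8L)
  expect_equal(dim(comp), c(8L, length(cfg$subtypes)))
  expect_true(all(rowSums(comp) == cfg$cells_per_sample))
})
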