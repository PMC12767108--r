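AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

MITO_GENES <- c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-CO3", "MT-ATP6",
                "MT-ATP8", "MT-CYB", "MT-ND3", "MT-ND4", "MT-ND4L", "MT-ND5",
                "MT-ND6")
HB_GENES <- c("HBA1", "HBA2", "HBB", "HBD", "HBG1", "HBG2")

#' Configuration of the synthetic scRNA+scTCR cohort
#'
#' Defaults describe a two-arm thyroid-infiltrate style cohort: 12 disease
#' (`GD`) and 10 control samples of ~1500 cells, nine cell subtypes (five
#' alpha/beta T subsets carrying TCR, B, NK, plus two non-immune populations),
#' a disease-shifted composition (B cells elevated ~5x in `GD`), per-subtype
#' clonal mass concentrated in effector T subsets, Trm-Teff clonotype sharing
#' planted only in the disease arm, 10% chain dropout, a 2000-gene negative
#' binomial panel with 13 mitochondrial + 100 ribosomal + 6 hemoglobin genes
#' and 10 planted 4-fold markers per subtype, 7.5% doublets, and low rates of
#' planted QC violators.
#'
#' @param groups Named integer vector: samples per cohort group.
#' @param subtypes Cell-subtype vocabulary.
#' @param compartment Named map subtype -> `"immune"`/`"non-immune"`.
#' @param tcr_subtypes Subtypes that carry alpha/beta TCR chains.
#' @param dirichlet Per-group named Dirichlet concentration parameters over
#'   `subtypes` (all > 0).
#' @param cells_per_sample Singlet cells drawn per sample.
#' @param expansion_mass Named map subtype -> target fraction of TCR-bearing
#'   cells placed in clones of size >= 2 (in `[0, 1]`).
#' @param sharing List of planted cross-subtype clone rules; each a list with
#'   `subtype_a`, `subtype_b`, `group`, `n_clones`, `cells_per_side`
#'   (length-2 integer range).
#' @param chain_dropout Probability a TCR-bearing cell loses one chain.
#' @param extra_chain_rate Probability a TCR-bearing cell carries an extra
#'   non-productive contig (exercises productive-chain filtering).
#' @param n_genes Panel size (includes the special gene blocks).
#' @param markers_per_subtype,marker_fold Planted marker genes per subtype and
#'   their mean fold elevation.
#' @param base_mean_meanlog,base_mean_sdlog,base_mean_range Log-normal law and
#'   clip range for per-gene baseline means.
#' @param special_fractions Target count-mass fractions of the mitochondrial,
#'   ribosomal and hemoglobin blocks in an ordinary cell.
#' @param violator_rates Named per-sample rates (values < 1) or absolute
#'   counts (values >= 1) of planted QC violators: `mito`, `ribo`, `hb`,
#'   `low_features`, `high_features`, `umi`.
#' @param low_feature_target Detected-gene count forced on a planted
#'   low-feature violator.
#' @param n_rare_genes Genes planted with prevalence 2 cells per sample (below
#'   the default min-cell gene filter).
#' @param doublet_rate Fraction of synthetic doublets appended per sample.
#' @param nb_dispersion Negative-binomial `size` (smaller = noisier).
#' @param libsize_sdlog Log-normal sd of the per-cell library-size factor.
#' @param seed Integer seed; fixing it fixes every emitted byte.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(groups = c(GD = 12L, control = 10L),
                       subtypes = c("naive", "Teff", "Tem", "Trm", "Tex",
                                    "B", "NK", "TFC", "endothelial"),
                       compartment = c(naive = "immune", Teff = "immune",
                                       Tem = "immune", Trm = "immune",
                                       Tex = "immune", B = "immune",
                                       NK = "immune", TFC = "non-immune",
                                       endothelial = "non-immune"),
                       tcr_subtypes = c("naive", "Teff", "Tem", "Trm", "Tex"),
                       dirichlet = list(
                         GD = c(naive = 20, Teff = 12, Tem = 8, Trm = 12,
                                Tex = 6, B = 15, NK = 6, TFC = 15,
                                endothelial = 14),
                         control = c(naive = 20, Teff = 8, Tem = 8, Trm = 12,
                                     Tex = 4, B = 3, NK = 6, TFC = 25,
                                     endothelial = 14)),
                       cells_per_sample = 1500L,
                       expansion_mass = c(naive = 0, Teff = 0.6, Tem = 0.4,
                                          Trm = 0.2, Tex = 0.3),
                       sharing = list(list(subtype_a = "Trm",
                                           subtype_b = "Teff",
                                           group = "GD", n_clones = 4L,
                                           cells_per_side = c(2L, 4L))),
                       chain_dropout = 0.1,
                       extra_chain_rate = 0.1,
                       n_genes = 2000L,
                       markers_per_subtype = 10L,
                       marker_fold = 4,
                       base_mean_meanlog = -1,
                       base_mean_sdlog = 1,
                       base_mean_range = c(0.05, 8),
                       special_fractions = c(mito = 0.05, ribo = 0.15,
                                             hb = 0.003),
                       violator_rates = c(mito = 0.01, ribo = 0.005,
                                          hb = 0.002, low_features = 0.01,
                                          high_features = 0, umi = 0.005),
                       low_feature_target = 300L,
                       n_rare_genes = 20L,
                       doublet_rate = 0.075,
                       nb_dispersion = 2,
                       libsize_sdlog = 0.2,
                       seed = 1L) {
  config <- list(groups = groups, subtypes = subtypes,
                 compartment = compartment, tcr_subtypes = tcr_subtypes,
                 dirichlet = dirichlet, cells_per_sample = cells_per_sample,
                 expansion_mass = expansion_mass, sharing = sharing,
                 chain_dropout = chain_dropout,
                 extra_chain_rate = extra_chain_rate, n_genes = n_genes,
                 markers_per_subtype = markers_per_subtype,
                 marker_fold = marker_fold,
                 base_mean_meanlog = base_mean_meanlog,
                 base_mean_sdlog = base_mean_sdlog,
                 base_mean_range = base_mean_range,
                 special_fractions = special_fractions,
                 violator_rates = violator_rates,
                 low_feature_target = low_feature_target,
                 n_rare_genes = n_rare_genes, doublet_rate = doublet_rate,
                 nb_dispersion = nb_dispersion,
                 libsize_sdlog = libsize_sdlog, seed = seed)
  validate_sim_config(config)
  structure(config, class = "sim_config")
}

validate_sim_config <- function(config) {
  with(config, {
    if (anyDuplicated(subtypes))
      stop("duplicate subtype labels in sim_config", call. = FALSE)
    if (!all(tcr_subtypes %in% subtypes))
      stop("tcr_subtypes must be a subset of subtypes", call. = FALSE)
    if (!setequal(names(compartment), subtypes))
      stop("compartment map must cover exactly the subtypes", call. = FALSE)
    for (g in names(groups)) {
      a <- dirichlet[[g]]
      if (is.null(a) || !setequal(names(a), subtypes) || any(a <= 0))
        stop(sprintf("dirichlet parameters for group %s must be > 0 and named by subtype", g),
             call. = FALSE)
    }
    probs <- c(chain_dropout, extra_chain_rate, doublet_rate,
               expansion_mass, special_fractions)
    if (any(probs < 0 | probs > 1))
      stop("all probabilities/fractions must lie in [0, 1]", call. = FALSE)
    if (!all(names(expansion_mass) %in% tcr_subtypes))
      stop("expansion_mass names must be TCR-bearing subtypes", call. = FALSE)
    n_special <- length(MITO_GENES) + 100L + length(HB_GENES)
    n_reserved <- n_special + markers_per_subtype * length(subtypes) +
      n_rare_genes
    if (n_genes < n_reserved + 10L)
      stop(sprintf("n_genes = %d too small for %d special/marker/rare genes",
                   n_genes, n_reserved), call. = FALSE)
    for (rule in sharing) {
      need <- c("subtype_a", "subtype_b", "group", "n_clones", "cells_per_side")
      if (!all(need %in% names(rule)))
        stop("each sharing rule needs subtype_a, subtype_b, group, n_clones, cells_per_side",
             call. = FALSE)
      if (!all(c(rule$subtype_a, rule$subtype_b) %in% tcr_subtypes))
        stop("sharing rules must name TCR-bearing subtypes", call. = FALSE)
      if (!rule$group %in% names(groups))
        stop(sprintf("sharing rule names unknown group %s", rule$group),
             call. = FALSE)
    }
  })
  invisible(config)
}

# Gene panel: ordinary block plus mito/ribo/hemoglobin blocks, planted
# subtype markers and (optionally) rare genes; baseline means are log-normal,
# clipped, with special blocks rescaled to their target count-mass fractions.
build_gene_panel <- function(config) {
  ribo <- c(sprintf("RPS%d", 1:50), sprintf("RPL%d", 1:50))
  special <- c(MITO_GENES, ribo, HB_GENES)
  n_ord <- config$n_genes - length(special)
  ordinary <- sprintf("GENE%05d", seq_len(n_ord))
  genes <- c(ordinary, special)
  category <- c(rep("ordinary", n_ord),
                rep("mito", length(MITO_GENES)),
                rep("ribo", length(ribo)),
                rep("hb", length(HB_GENES)))

  mu <- stats::rlnorm(config$n_genes, config$base_mean_meanlog,
                      config$base_mean_sdlog)
  mu <- pmin(pmax(mu, config$base_mean_range[[1L]]),
             config$base_mean_range[[2L]])
  f <- config$special_fractions
  s_ord <- sum(mu[category == "ordinary"])
  denom <- 1 - sum(f)
  for (cat in names(f)) {
    idx <- category == cat
    mu[idx] <- mu[idx] * (f[[cat]] / denom * s_ord / sum(mu[idx]))
  }

  n_mark <- config$markers_per_subtype * length(config$subtypes)
  marker_pool <- sample(ordinary, n_mark + config$n_rare_genes)
  markers <- tibble::tibble(
    gene = marker_pool[seq_len(n_mark)],
    subtype = rep(config$subtypes, each = config$markers_per_subtype),
    fold = config$marker_fold)
  rare <- if (config$n_rare_genes > 0L)
    marker_pool[n_mark + seq_len(config$n_rare_genes)] else character()

  mu_sub <- matrix(mu, nrow = config$n_genes, ncol = length(config$subtypes),
                   dimnames = list(genes, config$subtypes))
  for (s in config$subtypes) {
    gi <- match(markers$gene[markers$subtype == s], genes)
    mu_sub[gi, s] <- mu_sub[gi, s] * config$marker_fold
  }
  mu_sub[match(rare, genes), ] <- 0

  list(genes = genes, category = category, mu_sub = mu_sub,
       markers = markers, rare = rare,
       sets = list(mito = MITO_GENES, ribo = ribo, hb = HB_GENES))
}

# Dirichlet-multinomial subtype composition for one sample.
draw_sample_composition <- function(config, group) {
  alpha <- config$dirichlet[[group]][config$subtypes]
  p <- stats::rgamma(length(alpha), shape = alpha)
  p <- p / sum(p)
  n <- stats::rmultinom(1L, config$cells_per_sample, p)[, 1L]
  names(n) <- config$subtypes
  n
}

#' Draw per-sample subtype cell counts for many samples
#'
#' The Dirichlet-multinomial composition piece of the simulator in isolation;
#' used for composition-test calibration and power studies without generating
#' expression data.
#'
#' @param config A [sim_config()].
#' @param group Group label whose Dirichlet parameters to use.
#' @param n_samples Number of samples to draw.
#' @return Integer matrix, `n_samples` x subtypes.
#' @export
simulate_composition <- function(config, group, n_samples) {
  t(vapply(seq_len(n_samples),
           function(i) draw_sample_composition(config, group),
           integer(length(config$subtypes))))
}

random_cdr3 <- function(n) {
  lens <- sample(8:16, n, replace = TRUE)
  vapply(lens, function(l)
    paste0("C", paste(sample(AA_ALPHABET, l, replace = TRUE), collapse = ""),
           "F"), character(1))
}

random_nt <- function(aa) {
  vapply(nchar(aa), function(l)
    paste(sample(c("A", "C", "G", "T"), 3L * l, replace = TRUE),
          collapse = ""), character(1))
}

# Distinct CDR3 alpha/beta pairs for n clonotypes of one sample.
make_clonotype_defs <- function(n) {
  defs <- tibble::tibble(cdr3a = random_cdr3(n), cdr3b = random_cdr3(n))
  repeat {
    dup <- duplicated(paste(defs$cdr3a, defs$cdr3b, sep = "|"))
    if (!any(dup)) break
    defs$cdr3a[dup] <- random_cdr3(sum(dup))
    defs$cdr3b[dup] <- random_cdr3(sum(dup))
  }
  defs$cdr3a_nt <- random_nt(defs$cdr3a)
  defs$cdr3b_nt <- random_nt(defs$cdr3b)
  defs$va <- sprintf("TRAV%d", sample(1:45, n, replace = TRUE))
  defs$ja <- sprintf("TRAJ%d", sample(1:61, n, replace = TRUE))
  defs$vb <- sprintf("TRBV%d", sample(1:30, n, replace = TRUE))
  defs$jb <- sprintf("TRBJ%d", sample(1:14, n, replace = TRUE))
  defs
}

# Clone sizes (each >= 2) totalling exactly `target` cells, drawn geometric
# on {2, 3, ...} with mean ~3 and the last clone trimmed/merged to land on
# target.
draw_clone_sizes <- function(target) {
  if (target < 2L) return(integer())
  sizes <- integer()
  total <- 0L
  while (total < target) {
    s <- 2L + stats::rgeom(1L, 0.5)
    sizes <- c(sizes, s)
    total <- total + s
  }
  over <- total - target
  if (over > 0L) {
    last <- sizes[length(sizes)] - over
    if (last >= 2L) {
      sizes[length(sizes)] <- last
    } else if (length(sizes) >= 2L) {
      sizes <- sizes[-length(sizes)]
      sizes[length(sizes)] <- sizes[length(sizes)] + last
    } else {
      sizes <- target
    }
  }
  sizes
}

#' Simulate the TCR repertoire of one sample
#'
#' Every TCR-bearing cell receives a clonotype (a random paired CDR3
#' alpha/beta amino-acid string, `C...F` flanked, length 10-18). Within each
#' subtype a fraction `expansion_mass[subtype]` of cells is placed in clones
#' of size >= 2 (geometric sizes, mean ~3), the rest are singletons. Planted
#' shared clones put cells of one clonotype into two named subtypes, only in
#' samples of the named group. Chain dropout then removes one chain's records
#' per affected cell.
#'
#' @param config A [sim_config()].
#' @param sample_id,group Sample label and its cohort group.
#' @param cells Tibble of this sample's TCR-eligible cell draw: columns
#'   `cell`, `barcode`, `subtype` (non-TCR subtypes are ignored).
#' @return List with `chains` (contig-level tibble as [read_contigs()]
#'   returns), `assignment` (truth tibble `cell`, `subtype`, `clonotype_id`,
#'   `cdr3a`, `cdr3b`) and `shared` (registry of planted shared clones).
#' @export
simulate_repertoire <- function(config, sample_id, group, cells) {
  tcells <- cells[cells$subtype %in% config$tcr_subtypes, , drop = FALSE]
  n_t <- nrow(tcells)
  empty_chains <- tibble::tibble(cell = character(), barcode = character(),
                                 sample_id = character(), locus = character(),
                                 cdr3_aa = character(), cdr3_nt = character(),
                                 v_gene = character(), j_gene = character(),
                                 productive = logical(), umis = integer())
  if (n_t == 0L)
    return(list(chains = empty_chains,
                assignment = tibble::tibble(cell = character(),
                                            subtype = character(),
                                            clonotype_id = integer(),
                                            cdr3a = character(),
                                            cdr3b = character()),
                shared = tibble::tibble(sample_id = character(),
                                        clonotype_id = integer(),
                                        subtype_a = character(),
                                        subtype_b = character(),
                                        n_a = integer(), n_b = integer())))

  clone_of <- integer(n_t)            # 0 = unassigned
  next_clone <- 1L
  shared_rows <- list()

  # planted cross-subtype clones first (they consume cells from both pools)
  for (rule in config$sharing) {
    if (rule$group != group) next
    for (k in seq_len(rule$n_clones)) {
      pool_a <- which(clone_of == 0L & tcells$subtype == rule$subtype_a)
      pool_b <- which(clone_of == 0L & tcells$subtype == rule$subtype_b)
      rng <- rule$cells_per_side
      n_a <- min(sample(rng[[1L]]:rng[[2L]], 1L), length(pool_a))
      n_b <- min(sample(rng[[1L]]:rng[[2L]], 1L), length(pool_b))
      if (n_a < 1L || n_b < 1L) {
        warning(sprintf("sample %s: not enough free cells for shared clone %s-%s",
                        sample_id, rule$subtype_a, rule$subtype_b),
                call. = FALSE)
        next
      }
      take_a <- sample(pool_a, n_a)
      take_b <- sample(pool_b, n_b)
      clone_of[c(take_a, take_b)] <- next_clone
      shared_rows[[length(shared_rows) + 1L]] <- tibble::tibble(
        sample_id = sample_id, clonotype_id = next_clone,
        subtype_a = rule$subtype_a, subtype_b = rule$subtype_b,
        n_a = n_a, n_b = n_b)
      next_clone <- next_clone + 1L
    }
  }

  # within-subtype clonal mass, then singletons
  for (s in config$tcr_subtypes) {
    idx <- which(tcells$subtype == s)
    n_s <- length(idx)
    if (n_s == 0L) next
    f <- if (s %in% names(config$expansion_mass))
      config$expansion_mass[[s]] else 0
    target <- round(f * n_s)
    if (f > 0 && n_s < 2L) {
      warning(sprintf("sample %s: subtype %s has < 2 TCR-bearing cells; clonal mass set to 0",
                      sample_id, s), call. = FALSE)
      target <- 0L
    }
    already <- sum(clone_of[idx] != 0L)
    target <- max(0L, target - already)
    pool <- idx[clone_of[idx] == 0L]
    target <- min(target, length(pool))
    pool <- sample(pool)
    if (target >= 2L) {
      sizes <- draw_clone_sizes(target)
      at <- 0L
      for (sz in sizes) {
        clone_of[pool[(at + 1L):(at + sz)]] <- next_clone
        next_clone <- next_clone + 1L
        at <- at + sz
      }
      pool <- pool[-seq_len(at)]
    }
    for (i in pool) {
      clone_of[i] <- next_clone
      next_clone <- next_clone + 1L
    }
  }

  defs <- make_clonotype_defs(next_clone - 1L)
  assignment <- tibble::tibble(
    cell = tcells$cell, subtype = tcells$subtype, clonotype_id = clone_of,
    cdr3a = defs$cdr3a[clone_of], cdr3b = defs$cdr3b[clone_of])

  d <- defs[clone_of, ]
  umis_a <- 1L + stats::rpois(n_t, 3)
  umis_b <- 1L + stats::rpois(n_t, 3)
  chains <- tibble::tibble(
    cell = rep(tcells$cell, 2L),
    barcode = rep(tcells$barcode, 2L),
    sample_id = sample_id,
    locus = rep(c("TRA", "TRB"), each = n_t),
    cdr3_aa = c(d$cdr3a, d$cdr3b),
    cdr3_nt = c(d$cdr3a_nt, d$cdr3b_nt),
    v_gene = c(d$va, d$vb),
    j_gene = c(d$ja, d$jb),
    productive = TRUE,
    umis = c(umis_a, umis_b))

  # occasional extra non-productive contig (never alters the clonotype key)
  extra <- which(stats::runif(n_t) < config$extra_chain_rate)
  if (length(extra)) {
    ex_locus <- sample(c("TRA", "TRB"), length(extra), replace = TRUE)
    ex_cdr3 <- random_cdr3(length(extra))
    chains <- dplyr::bind_rows(chains, tibble::tibble(
      cell = tcells$cell[extra], barcode = tcells$barcode[extra],
      sample_id = sample_id, locus = ex_locus, cdr3_aa = ex_cdr3,
      cdr3_nt = random_nt(ex_cdr3),
      v_gene = ifelse(ex_locus == "TRA", "TRAV1", "TRBV1"),
      j_gene = ifelse(ex_locus == "TRA", "TRAJ1", "TRBJ1"),
      productive = FALSE, umis = 1L + stats::rpois(length(extra), 1)))
  }

  # chain dropout: an affected cell loses all records of one locus
  dropped <- which(stats::runif(n_t) < config$chain_dropout)
  if (length(dropped)) {
    lost_locus <- sample(c("TRA", "TRB"), length(dropped), replace = TRUE)
    lost <- paste(tcells$cell[dropped], lost_locus)
    chains <- chains[!(paste(chains$cell, chains$locus) %in% lost), ,
                     drop = FALSE]
  }

  shared <- if (length(shared_rows)) dplyr::bind_rows(shared_rows) else
    tibble::tibble(sample_id = character(), clonotype_id = integer(),
                   subtype_a = character(), subtype_b = character(),
                   n_a = integer(), n_b = integer())
  list(chains = chains, assignment = assignment, shared = shared)
}

#' Simulate the count matrix of one sample
#'
#' Negative-binomial counts per gene with subtype-specific marker elevation,
#' log-normal per-cell library factors, planted QC violators (library-size
#' outliers, low/high feature counts, mitochondrial/ribosomal/hemoglobin
#' percentage violators, rare genes), and appended cross-subtype doublets
#' formed by summing the count vectors of two cells of different subtypes.
#'
#' @param cells Tibble with `cell`, `barcode`, `subtype` for this sample's
#'   singlet cells.
#' @param config A [sim_config()].
#' @param panel Gene panel built once per cohort (internal structure); when
#'   `NULL` a fresh panel is drawn from `config`.
#' @param sample_id Sample label (for doublet barcodes).
#' @return List with `counts` (sparse genes x cells, doublet columns last),
#'   `doublets` (tibble `cell`, `barcode`, `subtype`, `parent1`, `parent2`)
#'   and `qc` (truth tibble `id`, `stage`).
#' @export
simulate_counts <- function(cells, config, panel = NULL, sample_id = "S1") {
  if (is.null(panel)) panel <- build_gene_panel(config)
  n <- nrow(cells)
  n_genes <- config$n_genes
  lf <- stats::rlnorm(n, 0, config$libsize_sdlog)

  v <- config$violator_rates
  n_of <- function(rate) if (rate < 1) as.integer(round(rate * n)) else
    as.integer(round(rate))
  cats <- c("umi", "low_features", "high_features", "mito", "ribo", "hb")
  wanted <- vapply(cats, function(cat)
    n_of(if (cat %in% names(v)) v[[cat]] else 0), integer(1))
  if (wanted[["high_features"]] > 0L && n_genes <= 8500L) {
    warning("high-feature violators need a panel larger than 8500 genes; skipping",
            call. = FALSE)
    wanted[["high_features"]] <- 0L
  }
  pool <- sample.int(n)
  viol <- list()
  at <- 0L
  for (cat in cats) {
    k <- min(wanted[[cat]], n - at)
    viol[[cat]] <- if (k > 0L) pool[(at + 1L):(at + k)] else integer()
    at <- at + k
  }
  sub_idx <- match(cells$subtype, config$subtypes)
  mu <- panel$mu_sub[, sub_idx, drop = FALSE] *
    rep(lf, each = n_genes)
  counts <- matrix(stats::rnbinom(n_genes * n, mu = as.vector(mu),
                                  size = config$nb_dispersion),
                   nrow = n_genes, ncol = n)

  # UMI outliers: scale counts after drawing, so the detected-gene pattern
  # (and hence the feature-bound stage) is untouched
  for (i in viol$umi) counts[, i] <- counts[, i] * 25L
  for (i in viol$low_features) {
    keep <- sample.int(n_genes, config$low_feature_target)
    zero <- setdiff(seq_len(n_genes), keep)
    counts[zero, i] <- 0L
  }
  for (i in viol$high_features) {
    idx <- sample.int(n_genes, min(n_genes, 8501L))
    counts[idx, i] <- pmax(counts[idx, i], 1L)
  }
  # fraction violators: move count mass onto the gene set while holding the
  # cell's total roughly constant, so no other QC stage is tripped
  set_fraction <- function(i, set_genes, target) {
    gi <- match(set_genes, panel$genes)
    tot <- sum(counts[, i])
    need <- as.integer(ceiling(target * tot))
    other <- sum(counts[-gi, i])
    if (other > 0)
      counts[-gi, i] <<- as.integer(round(counts[-gi, i] *
                                            (tot - need) / other))
    per <- need %/% length(gi)
    extra <- need %% length(gi)
    counts[gi, i] <<- per + c(rep(1L, extra), rep(0L, length(gi) - extra))
  }
  for (i in viol$mito) set_fraction(i, panel$sets$mito, 0.25)
  for (i in viol$ribo) set_fraction(i, panel$sets$ribo, 0.55)
  for (i in viol$hb) set_fraction(i, panel$sets$hb, 0.08)

  # doublets: sums of two clean cells of different subtypes
  clean <- setdiff(seq_len(n), unlist(viol))
  n_d <- as.integer(round(config$doublet_rate * n))
  parents <- matrix(NA_integer_, nrow = 0L, ncol = 2L)
  if (n_d > 0L && length(clean) >= 2L &&
      length(unique(cells$subtype[clean])) >= 2L) {
    for (k in seq_len(n_d)) {
      p1 <- sample(clean, 1L)
      mates <- clean[cells$subtype[clean] != cells$subtype[p1]]
      if (!length(mates)) next
      p2 <- if (length(mates) == 1L) mates else sample(mates, 1L)
      parents <- rbind(parents, c(p1, p2))
    }
  } else if (n_d > 0L) {
    warning("cannot form cross-subtype doublets; skipping", call. = FALSE)
  }
  n_d <- nrow(parents)
  if (n_d > 0L) {
    dbl <- counts[, parents[, 1L], drop = FALSE] +
      counts[, parents[, 2L], drop = FALSE]
    counts <- cbind(counts, dbl)
  }

  # rare genes: exactly two expressing cells each (below min-cell filter)
  for (g in panel$rare) {
    gi <- match(g, panel$genes)
    counts[gi, ] <- 0L
    counts[gi, sample.int(ncol(counts), 2L)] <- 1L
  }

  dbl_barcodes <- if (n_d > 0L) sprintf("DBLT%04d", seq_len(n_d)) else
    character()
  doublets <- tibble::tibble(
    cell = qualify_barcode(sample_id, dbl_barcodes),
    barcode = dbl_barcodes,
    subtype = if (n_d > 0L) cells$subtype[parents[, 1L]] else character(),
    parent1 = if (n_d > 0L) cells$cell[parents[, 1L]] else character(),
    parent2 = if (n_d > 0L) cells$cell[parents[, 2L]] else character())

  colnames(counts) <- c(cells$cell, doublets$cell)
  rownames(counts) <- panel$genes
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")

  qc <- dplyr::bind_rows(
    tibble::tibble(id = panel$rare,
                   stage = rep("gene_min_cells", length(panel$rare))),
    tibble::tibble(id = cells$cell[viol$low_features], stage = "low_features"),
    tibble::tibble(id = cells$cell[viol$high_features], stage = "high_features"),
    tibble::tibble(id = cells$cell[viol$umi], stage = "umi_quantile"),
    tibble::tibble(id = doublets$cell,
                   stage = rep("doublet", nrow(doublets))),
    tibble::tibble(id = cells$cell[viol$mito], stage = "mito_fraction"),
    tibble::tibble(id = cells$cell[viol$ribo], stage = "ribo_fraction"),
    tibble::tibble(id = cells$cell[viol$hb], stage = "hb_fraction"))
  qc$sample_id <- sample_id

  list(counts = m, doublets = doublets, qc = qc)
}

# Realized per-sample, per-subtype clonal expansion from the planted clone
# ledger: the truth analogue of clonal_expansion(), computed from clonotype
# ids rather than reconstructed CDR3 keys.
truth_expansion <- function(cells_ledger) {
  tcr <- cells_ledger[!is.na(cells_ledger$clonotype_id) &
                        !cells_ledger$doublet_flag, , drop = FALSE]
  sizes <- dplyr::count(tcr, .data$sample_id, .data$clonotype_id,
                        name = "clone_size")
  tcr |>
    dplyr::left_join(sizes, by = c("sample_id", "clonotype_id")) |>
    dplyr::group_by(.data$sample_id, .data$group, .data$subtype) |>
    dplyr::summarise(n_tcr = dplyr::n(),
                     expansion = mean(.data$clone_size >= 2L),
                     .groups = "drop") |>
    dplyr::arrange(.data$sample_id, .data$subtype)
}

#' Simulate a full multi-sample cohort with ground truth
#'
#' Draws per-sample subtype compositions (Dirichlet-multinomial with
#' group-specific parameters), then per sample the TCR repertoire
#' ([simulate_repertoire()]) and the count matrix ([simulate_counts()]).
#' Everything is deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @param components Which expensive parts to generate: subset of
#'   `c("repertoire", "counts")`. Composition and metadata are always drawn.
#' @return A `tcr_cohort` list: `counts` (named list of sparse matrices),
#'   `chains`, `meta` (tibbles), `truth` (list: `cells`, `expansion`,
#'   `shared`, `markers`, `qc`), and `config`.
#' @export
simulate_cohort <- function(config = sim_config(),
                            components = c("repertoire", "counts")) {
  components <- match.arg(components, several.ok = TRUE)
  set.seed(config$seed)
  panel <- if ("counts" %in% components) build_gene_panel(config) else NULL

  meta_l <- list(); chains_l <- list(); counts_l <- list()
  ledger_l <- list(); shared_l <- list(); qc_l <- list()
  for (g in names(config$groups)) {
    for (k in seq_len(config$groups[[g]])) {
      sid <- sprintf("%s%02d", g, k)
      comp <- draw_sample_composition(config, g)
      cells <- tibble::tibble(
        barcode = sprintf("BC%05d", seq_len(sum(comp))),
        sample_id = sid,
        subtype = rep(names(comp), comp))
      cells$cell <- qualify_barcode(sid, cells$barcode)

      assignment <- NULL
      if ("repertoire" %in% components) {
        rp <- simulate_repertoire(config, sid, g, cells)
        chains_l[[sid]] <- rp$chains
        shared_l[[sid]] <- rp$shared
        assignment <- rp$assignment
      }

      doublets <- tibble::tibble(cell = character(), barcode = character(),
                                 subtype = character())
      if ("counts" %in% components) {
        sc <- simulate_counts(cells, config, panel, sample_id = sid)
        counts_l[[sid]] <- sc$counts
        doublets <- sc$doublets
        qc_l[[sid]] <- sc$qc
      }

      meta <- tibble::tibble(
        cell = c(cells$cell, doublets$cell),
        barcode = c(cells$barcode, doublets$barcode),
        sample_id = sid, group = g,
        subtype = c(cells$subtype, doublets$subtype),
        doublet_flag = c(rep(FALSE, nrow(cells)),
                         rep(TRUE, nrow(doublets))))
      meta$compartment <- unname(config$compartment[meta$subtype])
      meta_l[[sid]] <- meta

      ledger <- meta[, c("cell", "sample_id", "group", "subtype",
                         "doublet_flag")]
      ledger$clonotype_id <- NA_integer_
      if (!is.null(assignment))
        ledger$clonotype_id <-
          assignment$clonotype_id[match(ledger$cell, assignment$cell)]
      ledger_l[[sid]] <- ledger
    }
  }

  ledger <- dplyr::bind_rows(ledger_l)
  truth <- list(
    cells = ledger,
    expansion = if ("repertoire" %in% components) truth_expansion(ledger) else
      NULL,
    shared = if (length(shared_l)) dplyr::bind_rows(shared_l) else NULL,
    markers = if (!is.null(panel)) panel$markers else NULL,
    qc = if (length(qc_l)) dplyr::bind_rows(qc_l) else NULL)

  structure(list(counts = counts_l,
                 chains = if (length(chains_l)) dplyr::bind_rows(chains_l) else
                   NULL,
                 meta = dplyr::bind_rows(meta_l),
                 truth = truth, config = config,
                 panel_sets = if (!is.null(panel)) panel$sets else NULL),
            class = "tcr_cohort")
}

#' @export
#' @method print tcr_cohort
print.tcr_cohort <- function(x, ...) {
  cat(sprintf("<tcr_cohort> %d samples, %d cells",
              length(unique(x$meta$sample_id)), nrow(x$meta)))
  if (!is.null(x$chains))
    cat(sprintf(", %d TCR contigs", nrow(x$chains)))
  if (length(x$counts))
    cat(sprintf(", %d-gene panel", nrow(x$counts[[1L]])))
  cat("\n")
  cat("groups:", paste(sprintf("%s=%d", names(x$config$groups),
                               x$config$groups), collapse = ", "), "\n")
  invisible(x)
}

#' Write a simulated cohort to disk in the formats the readers consume
#'
#' Emits, under `dir`: one folder per sample with `matrix.mtx`,
#' `features.tsv`, `barcodes.tsv` and `contigs.csv`; a cohort-level
#' `meta.tsv`; the ground-truth bundle under `truth/`; and the generating
#' configuration as `config.yaml`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sample_ids <- unique(cohort$meta$sample_id)
  for (sid in sample_ids) {
    sdir <- file.path(dir, "samples", sid)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(cohort$counts[[sid]]))
      write_count_matrix(cohort$counts[[sid]],
                         file.path(sdir, "matrix.mtx"),
                         file.path(sdir, "features.tsv"),
                         file.path(sdir, "barcodes.tsv"),
                         sample_id = sid)
    if (!is.null(cohort$chains)) {
      ch <- cohort$chains[cohort$chains$sample_id == sid, , drop = FALSE]
      out <- data.frame(barcode = ch$barcode, chain = ch$locus,
                        cdr3 = ch$cdr3_aa, cdr3_nt = ch$cdr3_nt,
                        v_gene = ch$v_gene, j_gene = ch$j_gene,
                        productive = ifelse(ch$productive, "True", "False"),
                        umis = ch$umis, stringsAsFactors = FALSE)
      ord <- order(out$barcode, out$chain, out$cdr3, method = "radix")
      data.table::fwrite(out[ord, ], file.path(sdir, "contigs.csv"),
                         sep = ",", quote = FALSE, showProgress = FALSE)
    }
  }
  meta_cols <- intersect(c("barcode", "sample_id", "group", "subtype",
                           "doublet_flag", "compartment"),
                         names(cohort$meta))
  write_table(cohort$meta[, meta_cols], file.path(dir, "meta.tsv"),
              sort_by = c("sample_id", "barcode"))
  tdir <- file.path(dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  write_table(cohort$truth$cells, file.path(tdir, "cells.tsv"),
              sort_by = c("sample_id", "cell"))
  for (nm in c("expansion", "shared", "markers", "qc")) {
    if (!is.null(cohort$truth[[nm]]))
      write_table(cohort$truth[[nm]], file.path(tdir, paste0(nm, ".tsv")))
  }
  cfg <- cohort$config
  attributes(cfg) <- list(names = names(cfg))
  yaml::write_yaml(lapply(cfg, function(x)
    if (is.numeric(x) || is.character(x) || is.logical(x) || is.list(x)) x else
      as.character(x)), file.path(dir, "config.yaml"))
  invisible(dir)
}
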