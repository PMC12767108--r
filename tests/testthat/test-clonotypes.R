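chain_row <- function(cell, locus, cdr3, umis, productive = TRUE,
                      cdr3_nt = NULL) {
  tibble::tibble(cell = cell, barcode = sub("^s1:", "", cell),
                 sample_id = "s1", locus = locus, cdr3_aa = cdr3,
                 cdr3_nt = cdr3_nt %||% paste0(cdr3, "NT"),
                 v_gene = "V1", j_gene = "J1",
                 productive = productive, umis = as.integer(umis))
}

meta_rows <- function(cells, subtype = "Teff") {
  tibble::tibble(cell = cells, barcode = sub("^s1:", "", cells),
                 sample_id = "s1", group = "g1",
                 subtype = rep_len(subtype, length(cells)))
}

test_that("clonotype keys require both productive chains and pick max-UMI", {
  chains <- dplyr::bind_rows(
    chain_row("s1:A", "TRA", "CAVRDTF", 6),
    chain_row("s1:A", "TRB", "CASSLGF", 9),
    chain_row("s1:B", "TRB", "CASSXF", 4),               # TRB only
    chain_row("s1:C", "TRA", "CAAAF", 7),
    chain_row("s1:C", "TRA", "CBBBF", 3),                # lower UMI loses
    chain_row("s1:C", "TRB", "CCCCF", 5),
    chain_row("s1:D", "TRA", "CZZF", 5),
    chain_row("s1:D", "TRA", "CAAF", 5),                 # tie: lexicographic
    chain_row("s1:D", "TRB", "CDDF", 2),
    chain_row("s1:E", "TRA", "CNOPE", 99, productive = FALSE),  # ignored
    chain_row("s1:E", "TRB", "CQQF", 3))
  meta <- meta_rows(sprintf("s1:%s", LETTERS[1:5]))
  asg <- assemble_clonotypes(chains, meta)
  expect_equal(asg$clonotype_key[asg$cell == "s1:A"], "CAVRDTF|CASSLGF")
  expect_false(asg$has_tcr_info[asg$cell == "s1:B"])
  expect_true(is.na(asg$clonotype_key[asg$cell == "s1:B"]))
  expect_equal(asg$cdr3a[asg$cell == "s1:C"], "CAAAF")
  expect_equal(asg$cdr3a[asg$cell == "s1:D"], "CAAF")
  expect_false(asg$has_tcr_info[asg$cell == "s1:E"])   # productive TRB only

  # single-chain policy: any productive chain grants TCR information
  asg1 <- assemble_clonotypes(chains, meta,
                              clonotype_policy(require_both = FALSE))
  expect_true(asg1$has_tcr_info[asg1$cell == "s1:B"])
  expect_equal(asg1$clonotype_key[asg1$cell == "s1:B"], "-|CASSXF")

  # nucleotide-level keys
  asgn <- assemble_clonotypes(chains, meta, clonotype_policy(level = "nt"))
  expect_equal(asgn$clonotype_key[asgn$cell == "s1:A"],
               "CAVRDTFNT|CASSLGFNT")
})

test_that("chains for cells absent from the metadata are dropped with warning", {
  chains <- dplyr::bind_rows(chain_row("s1:A", "TRA", "CAF", 1),
                             chain_row("s1:GHOST", "TRA", "CBF", 1))
  expect_warning(asg <- assemble_clonotypes(chains, meta_rows("s1:A")),
                 "absent from metadata")
  expect_equal(nrow(asg), 1L)
})

test_that("expansion value reproduces the worked repertoires", {
  # clonotype multiset [A, A, B, C] -> 2 clonal cells of 4
  asg <- mk_assignments(c("A", "A", "B", "C"), "Teff")
  expect_equal(expansion_value(asg), 0.5)
  expect_equal(clonal_expansion(asg)$expansion, 0.5)
  # all unique -> 0; all identical -> 1
  expect_equal(expansion_value(mk_assignments(letters[1:5], "Teff")), 0)
  expect_equal(expansion_value(mk_assignments(rep("x", 6), "Teff")), 1)
  # no TCR-informative cells -> undefined
  none <- mk_assignments(rep(NA_character_, 3), "Teff")
  expect_true(is.na(expansion_value(none)))
  # mixed samples rejected
  two <- dplyr::bind_rows(mk_assignments("a", "Teff", sample_id = "s1"),
                          mk_assignments("b", "Teff", sample_id = "s2"))
  expect_error(expansion_value(two), "single sample")
})

test_that("clonal status is determined sample-wide, not within subtype", {
  # one cell of clonotype x in each of two subtypes: both are clonal
  asg <- mk_assignments(c("x", "x", "y"), c("Trm", "Teff", "Teff"))
  tab <- clonal_expansion(asg)
  expect_equal(tab$expansion[tab$subtype == "Trm"], 1)
  expect_equal(tab$expansion[tab$subtype == "Teff"], 0.5)
  # expansion_value on the Trm cells alone would call it a singleton
  trm <- asg[asg$subtype == "Trm", ]
  expect_equal(expansion_value(trm), 0)
  expect_equal(expansion_value(trm, clone_totals = table(
    asg$clonotype_key[asg$has_tcr_info])), 1)
})

test_that("transition value reproduces the worked repertoires", {
  # A: [x, x, y], B: [x, z] -> (2 + 1) / 5
  asg <- mk_assignments(c("x", "x", "y", "x", "z"),
                        c("A", "A", "A", "B", "B"))
  expect_equal(transition_value(asg[asg$subtype == "A", ],
                                asg[asg$subtype == "B", ]), 0.6)
  # disjoint clonotype sets -> 0
  dj <- mk_assignments(c("a", "b", "c", "d"), c("A", "A", "B", "B"))
  expect_equal(transition_value(dj[dj$subtype == "A", ],
                                dj[dj$subtype == "B", ]), 0)
  # A: [x, x], B: [x] -> full sharing
  fs <- mk_assignments(c("x", "x", "x"), c("A", "A", "B"))
  expect_equal(transition_value(fs[fs$subtype == "A", ],
                                fs[fs$subtype == "B", ]), 1)
  # self-transition excluded
  expect_error(transition_value(asg[asg$subtype == "A", ],
                                asg[asg$subtype == "A", ]), "self")
})

test_that("expansion and transition match brute-force enumeration on random repertoires", {
  set.seed(123)
  for (rep in 1:60) {
    asg <- rand_repertoire()
    tab <- clonal_expansion(asg)
    for (s in unique(asg$subtype)) {
      want <- bf_expansion(asg, s)
      got <- tab$expansion[tab$subtype == s]
      if (is.na(want)) {
        expect_equal(length(got), 0L)
      } else {
        expect_equal(got, want)
        expect_gte(got, 0); expect_lte(got, 1)
      }
    }
    tr <- clonal_transitions(asg)
    subs <- sort(unique(asg$subtype[asg$has_tcr_info]))
    if (length(subs) >= 2L) {
      pairs <- utils::combn(subs, 2L)
      expect_equal(nrow(tr), ncol(pairs))
      for (k in seq_len(ncol(pairs))) {
        a <- pairs[1, k]; b <- pairs[2, k]
        want <- bf_transition(asg, a, b)
        got <- tr$transition[tr$subtype_a == a & tr$subtype_b == b]
        expect_equal(got, want)
        # symmetry of the pairwise statistic
        ca <- asg[asg$subtype == a, ]; cb <- asg[asg$subtype == b, ]
        expect_equal(transition_value(ca, cb), transition_value(cb, ca))
      }
    }
  }
})

test_that("joining a singleton to an existing clonotype never decreases expansion", {
  set.seed(99)
  for (rep in 1:20) {
    asg <- rand_repertoire(n_cells = 40, n_clonotypes = 15, n_subtypes = 3,
                           p_tcr = 1)
    sizes <- table(asg$clonotype_key)
    singles <- names(sizes)[sizes == 1L]
    others <- names(sizes)[sizes >= 1L]
    if (length(singles) == 0L || length(others) < 2L) next
    victim <- which(asg$clonotype_key == singles[[1L]])[[1L]]
    target <- setdiff(others, singles[[1L]])[[1L]]
    before <- clonal_expansion(asg)
    asg2 <- asg
    asg2$clonotype_key[victim] <- target
    after <- clonal_expansion(asg2)
    s <- asg$subtype[victim]
    expect_gte(after$expansion[after$subtype == s],
               before$expansion[before$subtype == s])
  }
})

test_that("per-sample tables cover every pair and omit absent subtypes", {
  asg <- mk_assignments(sprintf("c%d", 1:9), c("A", "B", "C"))
  tr <- clonal_transitions(asg)
  expect_equal(nrow(tr), choose(3, 2))
  # a subtype with no TCR-informative cells contributes no rows
  asg$has_tcr_info[asg$subtype == "C"] <- FALSE
  asg$clonotype_key[asg$subtype == "C"] <- NA
  expect_false("C" %in% clonal_expansion(asg)$subtype)
  tr2 <- clonal_transitions(asg)
  expect_equal(nrow(tr2), 1L)
})

test_that("group means average over samples and skip undefined entries", {
  rows <- tibble::tibble(
    subtype = "Teff",
    sample_id = c("a", "b", "c", "d"),
    group = c("g1", "g1", "g2", "g2"),
    n_tcr = c(10L, 10L, 10L, 0L),
    expansion = c(0.2, 0.4, 0.5, NA))
  sm <- summarize_expansion(rows)
  expect_equal(sm$mean_expansion[sm$group == "g1"], 0.3)
  expect_equal(sm$mean_expansion[sm$group == "g2"], 0.5)
  expect_equal(sm$n_samples[sm$group == "g2"], 1L)
})

test_that("network edges carry weights per group and exclusivity flags", {
  means <- tibble::tibble(
    subtype_a = c("Teff", "Teff", "Tem", "Tem", "Tex", "Tex"),
    subtype_b = c("Trm", "Trm", "Tex", "Tex", "Trm", "Trm"),
    group = rep(c("GD", "control"), 3),
    mean_transition = c(0.12, 0, 0.1, 0.1, 0, 0),
    n_samples = 2L)
  net <- transition_network(means)
  expect_equal(nrow(net), 2L)   # the all-zero Tex-Trm edge is omitted
  teff <- net[net$subtype_a == "Teff", ]
  expect_equal(teff$exclusive_to, "GD")
  expect_equal(teff$weight_GD, 0.12)
  expect_equal(teff$weight_control, 0)
  tem <- net[net$subtype_a == "Tem", ]
  expect_true(is.na(tem$exclusive_to))
  # epsilon raises the exclusivity floor
  net2 <- transition_network(means, epsilon = 0.11)
  expect_equal(nrow(net2), 1L)
  expect_equal(net2$exclusive_to, "GD")
})
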