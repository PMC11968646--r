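test_that("simulate_counts is deterministic and respects planted fractions", {
  cfg <- sim_config(n_genes = 100, tissues = "brain", replicates = 1,
                    seed = 3)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$matrix$counts, b$matrix$counts)
  expect_identical(a$truth$genes, b$truth$genes)

  cfg0 <- sim_config(n_genes = 100, tissues = "brain", replicates = 1,
                     morph_frac = 0, seed = 3)
  z <- simulate_counts(cfg0)
  expect_true(all(z$truth$genes$morph_lfc == 0))

  expect_error(sim_config(n_genes = 10), "seed")
  expect_error(sim_config(n_genes = 10, replicates = 0, seed = 1),
               "replicates")
  expect_error(sim_config(n_genes = 10, morph_frac = 1.2, seed = 1),
               "fractions")
})

test_that("NB variance law: Poisson limit at alpha -> 0", {
  # law: var = mu + alpha * mu^2; with alpha ~ 0 per-cell var ~ mean
  cfg <- sim_config(n_genes = 1000, tissues = "brain", replicates = 50,
                    stages = "I", conditions = "inseminated",
                    alpha = 1e-8, morph_frac = 0,
                    tissue_restricted_frac = 0, depth_range = c(1, 1),
                    baseline_meanlog = 5, baseline_sdlog = 0.3, seed = 8)
  sim <- simulate_counts(cfg)
  q <- sim$design$sample_id[sim$design$morph == "queen"]
  cellcounts <- sim$matrix$counts[, q]
  ratio <- apply(cellcounts, 1, stats::var) / rowMeans(cellcounts)
  # aggregate variance/mean ratio within 10% of 1
  expect_lt(abs(mean(ratio) - 1), 0.1)
})

test_that("simulate_families plants recoverable duplications", {
  cfg <- sim_config(n_genes = 200, n_families = 8, n_single_copy = 5,
                    scaffold_frac = 0, seed = 21)
  fams <- simulate_families(cfg)
  expect_equal(nrow(fams$truth), 8)
  expect_equal(length(fams$bundle$gene_trees), 8)
  # hand LCA check: an ingroup-MRCA plant maps to the ingroup node
  ev <- map_duplications(fams$bundle)
  mrca_fams <- fams$truth$orthogroup_id[fams$truth$placement ==
                                          "ingroup_mrca"]
  expect_true(all(ev$mapped_label[ev$orthogroup_id %in% mrca_fams] ==
                    "Ingroup"))
  # zero families -> empty bundle
  cfg0 <- sim_config(n_genes = 10, n_families = 0, n_single_copy = 2,
                     seed = 1)
  expect_equal(nrow(simulate_families(cfg0)$truth), 0)
})

test_that("tandem placement respects the configured gap exactly", {
  cfg <- sim_config(n_genes = 200, n_families = 10, n_single_copy = 0,
                    tandem_frac = 1, scaffold_frac = 0,
                    tandem_gap_range = c(2000, 2000), seed = 5)
  fams <- simulate_families(cfg)
  mem <- strsplit(fams$truth$members, ";")
  for (i in seq_along(mem)) {
    l <- fams$loci[mem[[i]], ]
    l <- l[order(l$start), ]
    gaps <- l$start[-1] - l$end[-nrow(l)] - 1
    expect_true(all(gaps == 2000))
  }
})

test_that("simulate_cds_pair follows the accept/reject rule", {
  # zero attempts -> identical pair
  p0 <- simulate_cds_pair(20, 1, seed = 4, attempts = 0)
  expect_identical(p0$seq_a, p0$seq_b)
  # determinism
  p1 <- simulate_cds_pair(20, 0.5, seed = 4)
  p2 <- simulate_cds_pair(20, 0.5, seed = 4)
  expect_identical(p1$seq_b, p2$seq_b)
  # omega ~ 0 -> all fixed differences synonymous
  code <- Biostrings::GENETIC_CODE
  p <- simulate_cds_pair(200, 1e-9, seed = 7, attempts = 400)
  ca <- substring(p$seq_a, seq(1, nchar(p$seq_a), 3),
                  seq(3, nchar(p$seq_a), 3))
  cb <- substring(p$seq_b, seq(1, nchar(p$seq_b), 3),
                  seq(3, nchar(p$seq_b), 3))
  diff <- which(ca != cb)
  expect_gt(length(diff), 0)
  expect_true(all(code[ca[diff]] == code[cb[diff]]))
  # no stop codons ever
  expect_false(any(code[cb] == "*"))
})

test_that("write_simulation emits a coherent, readable bundle", {
  dir <- tempfile()
  cfg <- sim_config(n_genes = 120, tissues = c("brain", "RT"),
                    replicates = 1, n_families = 4, n_single_copy = 6,
                    n_cds_pairs = 2, n_codons = 30, seed = 13)
  paths <- write_simulation(cfg, dir)
  m <- read_counts(paths$counts)
  d <- read_design(paths$design)
  expect_silent(check_design_matrix(m, d))
  loci <- read_gff_loci(paths$gff, readLines(paths$chromosomes))
  # focal family genes exist in the count matrix (unified ID space)
  expect_true(all(loci$gene_id %in% rownames(m$counts)))
  b <- read_orthology(paths$orthogroups, paths$species_tree,
                      paths$gene_tree_dir, "Ingroup", "Bsp01")
  expect_equal(length(b$gene_trees), 4)
  expect_equal(length(b$groups), 10)
})
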