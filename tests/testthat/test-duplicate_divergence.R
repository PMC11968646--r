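make_8subset_matrix <- function(base_a, delta) {
  tissues <- c("brain", "fat_body", "ovary", "RT")
  grid <- expand.grid(rep = 1:2, morph = c("queen", "worker"),
                      tissue = tissues, stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("%s_%s_%d", grid$tissue, grid$morph, grid$rep)
  counts <- rbind(a = base_a[match(paste(grid$tissue, grid$morph),
                                   names(base_a))],
                  b = base_a[match(paste(grid$tissue, grid$morph),
                                   names(base_a))] + delta)
  colnames(counts) <- grid$sample_id
  design <- sample_design(data.frame(
    sample_id = grid$sample_id, tissue = grid$tissue, morph = grid$morph,
    stage = "I", condition = "inseminated", stringsAsFactors = FALSE))
  m <- normalize_counts(expression_matrix(counts), s = rep(1, nrow(grid)))
  list(m = m, design = design)
}

subset_base <- stats::setNames(
  c(10, 20, 30, 40, 50, 60, 70, 80),
  as.vector(outer(c("brain", "fat_body", "ovary", "RT"),
                  c("queen", "worker"), paste)))

test_that("pair divergence: identity, +1 shift, symmetry", {
  fx <- make_8subset_matrix(subset_base, 0)
  expect_equal(pair_divergence("a", "b", fx$m, fx$design)$D, 0)
  fx1 <- make_8subset_matrix(subset_base, 1)
  expect_equal(pair_divergence("a", "b", fx1$m, fx1$design)$D, 8)
  expect_equal(pair_divergence("b", "a", fx1$m, fx1$design)$D, 8)
  # empty subset errors with the subset name
  fx2 <- make_8subset_matrix(subset_base, 1)
  keep <- fx2$design$sample_id[!(fx2$design$tissue == "RT" &
                                   fx2$design$morph == "queen")]
  m2 <- normalize_counts(
    expression_matrix(fx2$m$counts[, keep]), s = rep(1, length(keep)))
  expect_error(pair_divergence("a", "b", m2, fx2$design), "RT:queen")
})

test_that("concordance classes", {
  bias <- data.frame(gene_id = c("w1", "w2", "q1", "q2", "n1"),
                     bias = c("worker", "worker", "queen", "queen",
                              "none"), stringsAsFactors = FALSE)
  rownames(bias) <- bias$gene_id
  expect_equal(classify_concordance(c("w1", "w2"), bias)$class,
               "consistent_worker")
  expect_equal(classify_concordance(c("q1", "q2"), bias)$class,
               "consistent_queen")
  expect_equal(classify_concordance(c("w1", "q1"), bias)$class,
               "differential")
  expect_equal(classify_concordance(c("w1", "n1"), bias)$class,
               "partial")
  expect_equal(classify_concordance(c("n1", "n1"), bias)$class,
               "unbiased")
  # members missing from the table are ignored but counted
  cc <- classify_concordance(c("w1", "w2", "ghost"), bias)
  expect_equal(cc$class, "consistent_worker")
  expect_equal(cc$n_missing, 1)
  expect_error(classify_concordance(c("ghost"), bias), "no member")
})

test_that("paralog distance follows the inclusive-gap rule", {
  la <- data.frame(gene_id = "a", sequence_id = "NC_1", start = 100,
                   end = 200)
  lb <- data.frame(gene_id = "b", sequence_id = "NC_1", start = 500,
                   end = 900)
  # gap 201..499 inclusive = 299 bp
  expect_equal(paralog_distance(la, lb)$distance, 299)
  expect_equal(paralog_distance(lb, la)$distance, 299)  # order-invariant
  # overlap clamps to zero
  lc <- data.frame(gene_id = "c", sequence_id = "NC_1", start = 150,
                   end = 600)
  expect_equal(paralog_distance(la, lc)$distance, 0)
  # different chromosomes: undefined
  ld <- data.frame(gene_id = "d", sequence_id = "NC_2", start = 1,
                   end = 10)
  pd <- paralog_distance(la, ld)
  expect_true(is.na(pd$distance))
  expect_false(pd$same_chromosome)
  # start mode
  expect_equal(paralog_distance(la, lb, mode = "start")$distance, 400)
})

test_that("co-location null probability", {
  mk_loci <- function(counts) {
    ids <- unlist(lapply(seq_along(counts), function(i)
      sprintf("c%d_g%d", i, seq_len(counts[i]))))
    gene_loci(data.frame(
      gene_id = ids,
      sequence_id = rep(sprintf("chr%d", seq_along(counts)), counts),
      start = 1, end = 10, strand = "+", stringsAsFactors = FALSE),
      chromosome_ids = sprintf("chr%d", seq_along(counts)))
  }
  # g = (2, 2): p0 = 2 * (2/4) * (1/3) = 1/3
  ct <- colocation_test(c(TRUE, FALSE), mk_loci(c(2, 2)))
  expect_equal(ct$p0, 1 / 3)
  # single chromosome: p0 = 1, any outcome has p-value 1
  ct1 <- colocation_test(c(TRUE, TRUE), mk_loci(5))
  expect_equal(ct1$p0, 1)
  expect_equal(ct1$pvalue, 1)
  # concentrating genes onto fewer chromosomes never decreases p0
  p0s <- vapply(list(c(5, 5, 5, 5), c(10, 5, 5), c(15, 5), 20),
                function(g) colocation_test(TRUE, mk_loci(g))$p0,
                numeric(1))
  expect_true(all(diff(p0s) > 0))
  expect_error(colocation_test(TRUE, mk_loci(1)), ">= 2")
})

test_that("multicopy enrichment chi-square", {
  universe <- sprintf("g%d", 1:1000)
  multicopy <- universe[1:750]  # pi0 = 0.75
  # observed proportion == pi0 -> statistic 0, p = 1
  et0 <- multicopy_enrichment(c(universe[1:75], universe[751:775]),
                              multicopy, universe)
  expect_equal(et0$statistic, 0)
  expect_equal(et0$pvalue, 1)
  # doubling n with the same proportions doubles the statistic
  biased1 <- c(universe[1:85], universe[751:765])   # 85/100 multicopy
  biased2 <- c(universe[1:170], universe[751:780])  # 170/200
  e1 <- multicopy_enrichment(biased1, multicopy, universe)
  e2 <- multicopy_enrichment(biased2, multicopy, universe)
  expect_equal(e2$statistic, 2 * e1$statistic, tolerance = 1e-12)
  # the reported brain-scale configuration is overwhelmingly significant:
  # 204/215 observed vs expected proportion 0.75
  obs <- c(sprintf("m%d", 1:204), sprintf("s%d", 1:11))
  uni <- c(sprintf("m%d", 1:3000), sprintf("s%d", 1:1000))
  et <- multicopy_enrichment(obs, sprintf("m%d", 1:3000), uni)
  expect_equal(et$pi0, 0.75)
  expect_lt(et$pvalue, 1e-8)
  # degenerate expected cell
  expect_error(multicopy_enrichment("g1", multicopy, universe),
               "expected cell")
})

test_that("divergence-by-class comparison matches enumeration", {
  D <- c(1, 2, 3, 10, 11, 12)
  cls <- rep(c("consistent_queen", "differential"), each = 3)
  out <- compare_divergence_by_class(D, cls)
  expect_equal(out$pvalue, 0.1)  # exact, 20 assignments
  out_swapped <- compare_divergence_by_class(D, rev(cls))
  expect_equal(out$pvalue, out_swapped$pvalue)
  expect_warning(
    compare_divergence_by_class(c(1, 2, 3, 4), c("a", "a", "a", "b")),
    "skipping")
})
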