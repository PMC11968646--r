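# Divergence between duplicated genes: morph-bias concordance classes,
# the summed 8-subset (4 tissues x 2 morphs) pair expression-divergence
# statistic D, inter-paralogue genomic distances, the same-chromosome
# binomial co-location test and the multicopy chi-square enrichment test.

#' Classify a paralogue set by morph-bias concordance
#'
#' Members are looked up in a `BiasTable` (by convention the tissue with
#' the strongest morph signal, e.g. reproductive tissues). Classes:
#' `differential` (>= 1 worker- and >= 1 queen-biased member),
#' `consistent_worker` / `consistent_queen` (all members biased the same
#' way), `partial` (mix of biased and unbiased), `unbiased` (all none).
#' Members absent from the table (e.g. dropped by the count filter) are
#' ignored and flagged.
#'
#' @param members character vector of member gene IDs.
#' @param bias `BiasTable`.
#' @return list: class, labels (named), n_missing.
#' @export
classify_concordance <- function(members, bias) {
  present <- intersect(members, bias$gene_id)
  if (!length(present))
    stop("no member of the set overlaps the bias table")
  labels <- stats::setNames(bias[present, "bias"], present)
  has_w <- any(labels == "worker"); has_q <- any(labels == "queen")
  cls <- if (has_w && has_q) "differential"
  else if (has_w && all(labels == "worker")) "consistent_worker"
  else if (has_q && all(labels == "queen")) "consistent_queen"
  else if (has_w || has_q) "partial"
  else "unbiased"
  list(class = cls, labels = labels,
       n_missing = length(members) - length(present))
}

#' Classify every set in a table
#' @param sets `ParalogSets`. @param bias `BiasTable`.
#' @return data.frame: set_id, class, n_missing.
#' @export
classify_concordance_sets <- function(sets, bias) {
  mem <- set_members(sets)
  rows <- lapply(sets$set_id, function(id) {
    cc <- classify_concordance(mem[[id]], bias)
    data.frame(set_id = id, class = cc$class, n_missing = cc$n_missing,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Normalized counts layer (counts / size factor)
#' @param m `ExpressionMatrix`. @param s size factors (default computed on
#'   the full matrix, one normalization for all samples).
#' @return `ExpressionMatrix` with the `normalized` layer filled.
#' @export
normalize_counts <- function(m, s = size_factors(m)) {
  norm <- sweep(m$counts, 2, s, "/")
  expression_matrix(m$counts, normalized = norm, tpm = m$tpm,
                    size_factors = s)
}

#' Pair expression divergence across tissue-morph subsets
#'
#' For each of the 8 (tissue, morph) subsets, the mean normalized count of
#' each gene over the subset's samples is computed;
#' `D = sum_subsets |mean_a - mean_b|`. Symmetric in (a, b).
#'
#' @param a,b gene IDs present in the matrix.
#' @param m `ExpressionMatrix` with a `normalized` layer.
#' @param design `SampleDesign`.
#' @return list: D, subset_means (2 x subsets matrix).
#' @export
pair_divergence <- function(a, b, m, design) {
  stopifnot(!is.null(m$normalized))
  check_design_matrix(m, design)
  miss <- setdiff(c(a, b), rownames(m$normalized))
  if (length(miss)) stop("gene(s) not in matrix: ",
                         paste(miss, collapse = ", "))
  d <- design[colnames(m$normalized), , drop = FALSE]
  grp <- interaction(droplevels(d$tissue), droplevels(d$morph),
                     sep = ":", drop = FALSE)
  empty <- levels(grp)[tabulate(grp, nbins = nlevels(grp)) == 0]
  if (length(empty))
    stop("empty (tissue, morph) subset(s): ",
         paste(empty, collapse = ", "))
  means <- vapply(levels(grp), function(g) {
    cols <- grp == g
    c(mean(m$normalized[a, cols]), mean(m$normalized[b, cols]))
  }, numeric(2))
  rownames(means) <- c(a, b)
  list(D = sum(abs(means[1, ] - means[2, ])), subset_means = means)
}

#' Pair divergence for every unordered pair in every set
#' @param sets `ParalogSets`. @param m normalized `ExpressionMatrix`.
#' @param design `SampleDesign`.
#' @return data.frame: set_id, gene_a, gene_b, D.
#' @export
pair_divergence_sets <- function(sets, m, design) {
  mem <- set_members(sets)
  rows <- list()
  for (id in sets$set_id) {
    g <- intersect(mem[[id]], rownames(m$normalized))
    if (length(g) < 2) next
    cmb <- utils::combn(sort(g), 2)
    for (k in seq_len(ncol(cmb))) {
      pd <- pair_divergence(cmb[1, k], cmb[2, k], m, design)
      rows[[length(rows) + 1L]] <- data.frame(
        set_id = id, gene_a = cmb[1, k], gene_b = cmb[2, k], D = pd$D,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(set_id = character(0), gene_a = character(0),
                      gene_b = character(0), D = numeric(0)))
  do.call(rbind, rows)
}

#' Genomic distance between two paralogues
#'
#' Same chromosome: the inter-feature gap, i.e. the number of bases
#' strictly between the two genes (overlapping genes give 0). Different
#' sequences: NA with `same_chromosome = FALSE`. `mode = "start"` gives
#' the absolute start-to-start distance instead.
#'
#' @param locus_a,locus_b single-row locus data (gene_id, sequence_id,
#'   start, end).
#' @param mode "gap" (default) or "start".
#' @return list: distance (bp or NA), same_chromosome.
#' @export
paralog_distance <- function(locus_a, locus_b, mode = c("gap", "start")) {
  mode <- match.arg(mode)
  if (locus_a$sequence_id != locus_b$sequence_id)
    return(list(distance = NA_real_, same_chromosome = FALSE))
  dist <- if (mode == "start") {
    abs(locus_a$start - locus_b$start)
  } else {
    up <- if (locus_a$start <= locus_b$start) locus_a else locus_b
    dn <- if (locus_a$start <= locus_b$start) locus_b else locus_a
    max(0, dn$start - up$end - 1)
  }
  list(distance = dist, same_chromosome = TRUE)
}

#' Distances for every unordered pair in every set
#' @param sets `ParalogSets`. @param loci `GeneLoci`.
#' @param mode passed to [paralog_distance()].
#' @return data.frame: set_id, gene_a, gene_b, distance, same_chromosome.
#' @export
paralog_distance_sets <- function(sets, loci, mode = "gap") {
  mem <- set_members(sets)
  rows <- list()
  for (id in sets$set_id) {
    cmb <- utils::combn(sort(mem[[id]]), 2)
    for (k in seq_len(ncol(cmb))) {
      pd <- paralog_distance(loci[cmb[1, k], ], loci[cmb[2, k], ],
                             mode = mode)
      rows[[length(rows) + 1L]] <- data.frame(
        set_id = id, gene_a = cmb[1, k], gene_b = cmb[2, k],
        distance = pd$distance, same_chromosome = pd$same_chromosome,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Same-chromosome co-location test
#'
#' Null probability that a random gene pair shares a chromosome:
#' `p0 = sum_c (g_c / G) * ((g_c - 1) / (G - 1))` from background gene
#' counts per chromosome. One-sided (greater) exact binomial test of the
#' observed k same-chromosome sets out of n evaluable sets.
#'
#' @param same_chromosome logical vector, one per evaluable set (a
#'   multi-member set counts once; TRUE iff all members share one
#'   chromosome).
#' @param loci background `GeneLoci` (chromosome-level genes only are
#'   used).
#' @return list of class `ColocationTest`: n, k, p0, pvalue.
#' @export
colocation_test <- function(same_chromosome, loci) {
  bg <- loci[loci$is_chromosome, , drop = FALSE]
  g <- table(bg$sequence_id)
  G <- sum(g)
  if (G < 2) stop("background must contain >= 2 chromosome-level genes")
  p0 <- sum((g / G) * ((g - 1) / (G - 1)))
  n <- length(same_chromosome)
  if (n < 1) stop("no evaluable sets")
  k <- sum(same_chromosome)
  pv <- stats::binom.test(k, n, p = p0, alternative = "greater")$p.value
  structure(list(n = n, k = k, p0 = p0, pvalue = pv),
            class = "ColocationTest")
}

#' @export
print.ColocationTest <- function(x, ...) {
  cat(sprintf(
    "Co-location: %d/%d sets same-chromosome; p0 = %.4g; binomial P = %.3g\n",
    x$k, x$n, x$p0, x$pvalue))
  invisible(x)
}

#' Multicopy enrichment among biased genes
#'
#' Chi-square goodness of fit (df = 1, no continuity correction) of the
#' observed (multicopy, single-copy) split of biased genes against the
#' background multicopy proportion pi0 computed on the expressed-gene
#' universe.
#'
#' @param biased_genes gene IDs called biased in the tissue.
#' @param multicopy_genes gene IDs with > 1 copy (background membership).
#' @param universe background universe (expressed genes with known copy
#'   status).
#' @return list of class `EnrichmentTest`: n_biased, observed, expected,
#'   pi0, observed_prop, statistic, df, pvalue.
#' @export
multicopy_enrichment <- function(biased_genes, multicopy_genes, universe) {
  biased_genes <- intersect(biased_genes, universe)
  n_b <- length(biased_genes)
  if (n_b == 0) stop("no biased gene in the universe")
  pi0 <- mean(universe %in% multicopy_genes)
  obs <- sum(biased_genes %in% multicopy_genes)
  expected <- c(pi0, 1 - pi0) * n_b
  if (any(expected < 1))
    stop("expected cell < 1; chi-square test invalid")
  observed <- c(obs, n_b - obs)
  stat <- sum((observed - expected)^2 / expected)
  structure(list(n_biased = n_b, observed = obs, expected = expected[1],
                 pi0 = pi0, observed_prop = obs / n_b, statistic = stat,
                 df = 1L,
                 pvalue = stats::pchisq(stat, 1, lower.tail = FALSE)),
            class = "EnrichmentTest")
}

#' @export
print.EnrichmentTest <- function(x, ...) {
  cat(sprintf(
    "Multicopy enrichment: observed %.3f vs expected %.3f (n = %d); X2 = %.2f, P = %.3g\n",
    x$observed_prop, x$pi0, x$n_biased, x$statistic, x$pvalue))
  invisible(x)
}

#' Compare pair divergence D between concordance classes
#'
#' Pairwise two-sided Wilcoxon rank-sum tests (uncorrected) with medians,
#' for every class pair with >= 2 values each; undersized classes are
#' skipped with a warning.
#'
#' @param D numeric vector of pair divergences.
#' @param class concordance class per value.
#' @return data.frame: class1, class2, n1, n2, median1, median2,
#'   statistic, pvalue.
#' @export
compare_divergence_by_class <- function(D, class) {
  stopifnot(length(D) == length(class))
  classes <- sort(unique(class))
  rows <- list()
  if (length(classes) < 2) stop("need >= 2 classes")
  for (i in seq_along(classes)) for (j in seq_along(classes)) {
    if (j <= i) next
    x <- D[class == classes[i]]; y <- D[class == classes[j]]
    if (length(x) < 2 || length(y) < 2) {
      warning(sprintf("skipping %s vs %s: class with < 2 pairs",
                      classes[i], classes[j]))
      next
    }
    w <- stats::wilcox.test(x, y, alternative = "two.sided")
    rows[[length(rows) + 1L]] <- data.frame(
      class1 = classes[i], class2 = classes[j],
      n1 = length(x), n2 = length(y),
      median1 = stats::median(x), median2 = stats::median(y),
      statistic = unname(w$statistic), pvalue = w$p.value,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(class1 = character(0), class2 = character(0),
                      n1 = integer(0), n2 = integer(0),
                      median1 = numeric(0), median2 = numeric(0),
                      statistic = numeric(0), pvalue = numeric(0)))
  do.call(rbind, rows)
}
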