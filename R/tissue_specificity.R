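# Tau tissue-specificity: TPM normalization, bottom-decile expression
# filter, per-tissue means of log2(TPM + 1), and the tau index
# tau = sum_i(1 - x_i/max(x)) / (N - 1), 0 = ubiquitous, 1 = one tissue.

#' TPM-normalize a count matrix
#'
#' `rate_g = count_g / (length_g / 1000)`; each sample's rates are scaled
#' to sum to 1e6.
#'
#' @param m `ExpressionMatrix`. @param lengths named per-gene effective
#'   length in bp (> 0), covering all genes in `m`.
#' @return `ExpressionMatrix` with the `tpm` layer filled.
#' @export
tpm <- function(m, lengths) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  genes <- rownames(m$counts)
  miss <- setdiff(genes, names(lengths))
  if (length(miss)) stop("missing length for gene(s): ",
                         paste(utils::head(miss, 5), collapse = ", "))
  len <- lengths[genes]
  if (any(len <= 0)) stop("gene lengths must be > 0")
  rate <- m$counts / (len / 1000)
  tot <- colSums(rate)
  if (any(tot == 0))
    stop("all-zero sample(s): ",
         paste(colnames(m$counts)[tot == 0], collapse = ", "))
  layer <- sweep(rate, 2, tot, "/") * 1e6
  expression_matrix(m$counts, normalized = m$normalized, tpm = layer,
                    size_factors = m$size_factors)
}

#' Remove the bottom decile of mean expression
#'
#' Genes whose mean TPM across all samples is less than or equal to the
#' 10th percentile of mean TPM are removed (ties at the cutoff removed,
#' for determinism).
#'
#' @param m `ExpressionMatrix` with a `tpm` layer.
#' @return character vector of surviving gene IDs.
#' @export
filter_bottom_decile <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"), !is.null(m$tpm),
            nrow(m$tpm) >= 10)
  means <- rowMeans(m$tpm)
  cutoff <- stats::quantile(means, 0.1, names = FALSE)
  survivors <- rownames(m$tpm)[means > cutoff]
  if (!length(survivors))
    stop("degenerate expression: bottom-decile filter removed every gene")
  survivors
}

#' Per-tissue expression profiles on the log2(TPM + 1) scale
#'
#' For each gene, the mean of log2(TPM + 1) over the samples of each
#' tissue. Morphs, stages and conditions are pooled by default; set
#' `split_by_morph` to get one profile column per (tissue, morph).
#'
#' @param m `ExpressionMatrix` with a `tpm` layer.
#' @param design `SampleDesign`. @param genes optional subset of genes.
#' @param split_by_morph split tissue columns by morph.
#' @return numeric matrix, genes x tissues.
#' @export
tissue_profiles <- function(m, design, genes = rownames(m$tpm),
                            split_by_morph = FALSE) {
  stopifnot(!is.null(m$tpm))
  check_design_matrix(m, design)
  d <- design[colnames(m$tpm), , drop = FALSE]
  group <- if (split_by_morph)
    interaction(d$tissue, d$morph, drop = TRUE, sep = ":")
  else droplevels(d$tissue)
  logtpm <- log2(m$tpm[genes, , drop = FALSE] + 1)
  prof <- vapply(levels(group), function(g)
    rowMeans(logtpm[, group == g, drop = FALSE]),
    numeric(length(genes)))
  if (length(genes) == 1) prof <- matrix(prof, nrow = 1,
                                         dimnames = list(genes,
                                                         levels(group)))
  prof
}

#' Tau tissue-specificity index
#'
#' For each gene with per-tissue profile `x`, `tau = sum_i(1 -
#' x_i / max(x)) / (N - 1)`. Genes with `max(x) == 0` (expressed nowhere)
#' have undefined tau and are flagged excluded rather than set to 0.
#'
#' @param profiles genes x tissues matrix of mean log2(TPM + 1); requires
#'   >= 2 tissues and non-negative values.
#' @return data.frame of class `TauRecord`: gene_id, tau, max_x, excluded.
#' @export
tau <- function(profiles) {
  stopifnot(is.matrix(profiles), ncol(profiles) >= 2)
  if (any(profiles < 0)) stop("profiles must be non-negative")
  n <- ncol(profiles)
  mx <- apply(profiles, 1, max)
  t_val <- ifelse(mx > 0,
                  rowSums(1 - profiles / ifelse(mx > 0, mx, 1)) / (n - 1),
                  NA_real_)
  out <- data.frame(gene_id = rownames(profiles), tau = t_val,
                    max_x = mx, excluded = mx == 0,
                    stringsAsFactors = FALSE)
  rownames(out) <- out$gene_id
  class(out) <- c("TauRecord", "data.frame")
  out
}

#' Full tau workflow from counts
#'
#' TPM -> bottom-decile filter -> per-tissue log2(TPM + 1) means -> tau.
#'
#' @inheritParams tpm
#' @inheritParams tissue_profiles
#' @return `TauRecord` table for surviving genes.
#' @export
compute_tau <- function(m, design, lengths, split_by_morph = FALSE) {
  mt <- tpm(m, lengths)
  survivors <- filter_bottom_decile(mt)
  prof <- tissue_profiles(mt, design, genes = survivors,
                          split_by_morph = split_by_morph)
  tau(prof)
}

#' Compare tau distributions across bias categories
#'
#' Pairwise two-sided Wilcoxon rank-sum tests for (worker vs none,
#' queen vs none, worker vs queen) with Bonferroni adjustment (x3, capped
#' at 1). Pairs where either category has < 2 members are skipped with a
#' warning.
#'
#' @param tau_records `TauRecord` table (or any data.frame with gene_id
#'   and a value column).
#' @param bias `BiasTable` for the tissue being examined.
#' @param value name of the column in `tau_records` to compare.
#' @return data.frame: group1, group2, n1, n2, median1, median2,
#'   statistic, pvalue, padj.
#' @export
compare_tau_by_bias <- function(tau_records, bias, value = "tau") {
  merged <- merge(tau_records[, c("gene_id", value)],
                  bias[, c("gene_id", "bias")], by = "gene_id")
  merged <- merged[!is.na(merged[[value]]), ]
  pairs <- list(c("worker", "none"), c("queen", "none"),
                c("worker", "queen"))
  rows <- list()
  for (p in pairs) {
    x <- merged[[value]][merged$bias == p[1]]
    y <- merged[[value]][merged$bias == p[2]]
    if (length(x) < 2 || length(y) < 2) {
      warning(sprintf("skipping %s vs %s: category with < 2 members",
                      p[1], p[2]))
      next
    }
    w <- stats::wilcox.test(x, y, alternative = "two.sided", exact = NULL)
    rows[[length(rows) + 1L]] <- data.frame(
      group1 = p[1], group2 = p[2], n1 = length(x), n2 = length(y),
      median1 = stats::median(x), median2 = stats::median(y),
      statistic = unname(w$statistic), pvalue = w$p.value,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("fewer than 2 usable categories")
  out <- do.call(rbind, rows)
  out$padj <- pmin(out$pvalue * 3, 1)
  out
}
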