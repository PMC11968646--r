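# Per-tissue differential expression between queen and worker morphs:
# median-of-ratios normalization, method-of-moments dispersion, per-gene
# negative-binomial GLMs fit by IRLS with fixed dispersion, full-vs-reduced
# likelihood-ratio test for the morph term, Benjamini-Hochberg adjustment
# and bias classification at padj < 0.05, |log2FC| >= 1.

ALPHA_MIN <- 1e-8

#' Remove lowly expressed genes
#'
#' Genes whose count sum across all samples is below 10 are dropped;
#' survivor order is preserved.
#'
#' @param m an `ExpressionMatrix`.
#' @param min_total minimum row sum to keep (default 10; a row summing to
#'   exactly 10 is kept).
#' @return filtered `ExpressionMatrix`.
#' @export
filter_low_counts <- function(m, min_total = 10) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  keep <- rowSums(m$counts) >= min_total
  if (!any(keep)) stop("no gene passes the low-count filter")
  expression_matrix(m$counts[keep, , drop = FALSE])
}

#' Median-of-ratios size factors
#'
#' For each sample j, `s_j` is the median over genes (restricted to genes
#' with a positive geometric mean across samples) of
#' `count_gj / geomean_g`. No rescaling is applied afterwards.
#'
#' @param m an `ExpressionMatrix`.
#' @return positive numeric vector, one per sample.
#' @export
size_factors <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  counts <- m$counts
  loggeo <- rowMeans(log(counts))      # -Inf when any zero
  use <- is.finite(loggeo)
  if (!any(use))
    stop("no gene expressed in all samples; size factors undefined")
  s <- apply(counts[use, , drop = FALSE], 2, function(cnts)
    exp(stats::median(log(cnts) - loggeo[use])))
  if (any(!is.finite(s) | s <= 0))
    stop("degenerate size factor for sample(s): ",
         paste(colnames(counts)[!is.finite(s) | s <= 0], collapse = ", "))
  s
}

#' Per-gene dispersion estimation
#'
#' Without a design: the marginal method-of-moments estimator on
#' normalized counts, `alpha_g = max((var_g - mean_g) / mean_g^2,
#' alpha_min)`. With a design: Cox-Reid adjusted profile maximum
#' likelihood under the full model (stage + condition + morph) — the
#' standard gene-wise estimator of the established DE toolchains, still
#' strictly per-gene (no shrinkage across genes). The marginal estimator
#' must not be used for testing: it books real between-morph signal as
#' biological noise for exactly the biased genes, and its small-sample
#' noise badly miscalibrates the LRT. Genes with zero mean are floored
#' and flagged.
#'
#' @param m an `ExpressionMatrix`. @param s size factors.
#' @param design optional `SampleDesign` covering the matrix samples.
#' @param alpha_min dispersion floor. @param alpha_max search upper bound.
#' @return numeric vector of dispersions; attribute `flagged` lists
#'   zero-mean genes.
#' @export
estimate_dispersion <- function(m, s = size_factors(m), design = NULL,
                                alpha_min = ALPHA_MIN, alpha_max = 10) {
  stopifnot(inherits(m, "ExpressionMatrix"), ncol(m$counts) >= 2)
  norm <- sweep(m$counts, 2, s, "/")
  mu <- rowMeans(norm)
  if (is.null(design)) {
    v <- apply(norm, 1, stats::var)
    alpha <- ifelse(mu > 0, pmax((v - mu) / mu^2, alpha_min), alpha_min)
  } else {
    X <- full_model_matrix(m, design)
    offset <- log(s)
    if (ncol(m$counts) <= ncol(X))
      stop("need more samples than model coefficients")
    alpha <- numeric(nrow(m$counts))
    for (i in seq_len(nrow(m$counts))) {
      if (mu[i] == 0) { alpha[i] <- alpha_min; next }
      alpha[i] <- cr_apl_dispersion(m$counts[i, ], X, offset,
                                    alpha_min, alpha_max)
    }
  }
  names(alpha) <- rownames(m$counts)
  attr(alpha, "flagged") <- rownames(m$counts)[mu == 0]
  alpha
}

# Cox-Reid adjusted profile likelihood maximized over log dispersion:
# apl(a) = ll(y; mu_hat(a), a) - 0.5 * log det(X' W X), W = mu/(1+a*mu)
cr_apl_dispersion <- function(y, X, offset, alpha_min = ALPHA_MIN,
                              alpha_max = 10) {
  apl <- function(la) {
    a <- exp(la)
    fit <- nb_irls(y, X, offset, a, max_iter = 50)
    if (any(is.na(fit$beta))) return(-Inf)
    mu <- exp(pmin(pmax(drop(X %*% fit$beta) + offset, -30), 30))
    w <- mu / (1 + a * mu)
    as.numeric(nb_loglik(y, mu, a) -
                 0.5 * determinant(crossprod(X * sqrt(w)),
                                   logarithm = TRUE)$modulus)
  }
  opt <- stats::optimize(apl, c(log(max(alpha_min, 1e-6)),
                                log(alpha_max)),
                         maximum = TRUE, tol = 0.02)
  max(exp(opt$maximum), alpha_min)
}

# full-model design matrix (stage + condition + morph), dropping
# single-level covariates; shared by dispersion estimation and the LRT
full_model_matrix <- function(m, design) {
  check_design_matrix(m, design)
  d <- droplevels(as.data.frame(design[colnames(m$counts), ,
                                       drop = FALSE]))
  d$morph <- factor(as.character(d$morph), levels = MORPH_LEVELS)
  covars <- c("stage", "condition")
  covars <- covars[vapply(covars, function(v) nlevels(d[[v]]) > 1,
                          logical(1))]
  f <- stats::as.formula(paste(
    "~", paste(c(covars, "morph"), collapse = " + ")))
  stats::model.matrix(f, d)
}

# NB log-likelihood at fitted means (size = 1/alpha)
nb_loglik <- function(y, mu, alpha) {
  sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
}

# IRLS for a negative-binomial GLM with log link, fixed dispersion and
# offset. Returns coefficients, fitted loglik and a convergence flag.
nb_irls <- function(y, X, offset, alpha, max_iter = 100, tol = 1e-8) {
  eta <- log(pmax(y, 0.5)) # initialise at (clamped) observed rate
  dev_old <- Inf
  conv <- FALSE
  beta <- rep(NA_real_, ncol(X))
  for (it in seq_len(max_iter)) {
    mu <- exp(pmin(pmax(eta, -30), 30))
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- tryCatch({
      xtw <- t(X * w)
      solve(xtw %*% X, xtw %*% z)
    }, error = function(e) NULL)
    if (is.null(fit)) break
    beta <- drop(fit)
    eta <- drop(X %*% beta) + offset
    mu <- exp(pmin(pmax(eta, -30), 30))
    dev <- -2 * nb_loglik(y, mu, alpha)
    if (is.finite(dev) &&
        abs(dev - dev_old) < tol * (abs(dev) + 0.1)) {
      conv <- TRUE
      break
    }
    dev_old <- dev
  }
  mu <- exp(pmin(pmax(drop(X %*% beta) + offset, -30), 30))
  list(beta = beta, loglik = nb_loglik(y, mu, alpha), converged = conv)
}

#' Likelihood-ratio test for the morph term, per gene
#'
#' Fits, for every gene in the tissue subset, the full model
#' `log mu = log s_j + b0 + b_stage + b_condition + b_morph` and the
#' reduced model without the morph term, both by IRLS with the gene's
#' fixed dispersion, and computes `LRT = 2 * (ll_full - ll_reduced)`.
#' P-values use an F(1, n - p) reference (n samples, p full-model
#' coefficients) rather than the asymptotic chi-square df = 1: with the
#' study-scale 6 samples per morph the plug-in dispersion makes the
#' chi-square reference anti-conservative, while the small-sample F
#' reference is calibrated (see the methods vignette). The chi-square
#' p-value is kept in `pvalue_chisq`. `log2FC` is the worker-minus-queen morph
#' coefficient on the log2 scale (positive = worker-biased). Covariates
#' with a single observed level are dropped from both models.
#'
#' @param m `ExpressionMatrix` (already subset to one tissue and
#'   low-count filtered).
#' @param design `SampleDesign` covering the matrix samples.
#' @param s size factors. @param alpha per-gene dispersions.
#' @return data.frame of class `DEModelFit`: gene_id, log2FC, ll_full,
#'   ll_reduced, stat, df, pvalue, converged.
#' @export
lrt_morph <- function(m, design, s = size_factors(m),
                      alpha = estimate_dispersion(m, s)) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  check_design_matrix(m, design)
  d <- design[colnames(m$counts), , drop = FALSE]
  d <- droplevels(as.data.frame(d))
  d$morph <- factor(as.character(d$morph), levels = MORPH_LEVELS)
  if (nlevels(droplevels(d$morph)) < 2)
    stop("tissue subset must contain both morphs")
  if (min(table(d$morph)) < 2)
    stop("need >= 2 replicates per morph")

  covars <- c("stage", "condition")
  covars <- covars[vapply(covars, function(v) nlevels(d[[v]]) > 1,
                          logical(1))]
  f_red <- if (length(covars))
    stats::as.formula(paste("~", paste(covars, collapse = " + ")))
  else ~ 1
  f_full <- stats::update(f_red, ~ . + morph)
  X_full <- stats::model.matrix(f_full, d)
  X_red <- stats::model.matrix(f_red, d)
  morph_col <- grep("^morphworker$", colnames(X_full))
  offset <- log(s)

  genes <- rownames(m$counts)
  alpha <- alpha[genes]
  df2 <- ncol(m$counts) - ncol(X_full)
  if (df2 < 1) stop("no residual degrees of freedom for the full model")
  out <- data.frame(gene_id = genes, log2FC = NA_real_,
                    ll_full = NA_real_, ll_reduced = NA_real_,
                    stat = NA_real_, df = 1L, df2 = df2,
                    pvalue = NA_real_, pvalue_chisq = NA_real_,
                    converged = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    y <- m$counts[i, ]
    a <- max(alpha[i], ALPHA_MIN)
    full <- nb_irls(y, X_full, offset, a)
    red <- nb_irls(y, X_red, offset, a)
    if (!full$converged || !red$converged) next
    stat <- max(0, 2 * (full$loglik - red$loglik))
    out$log2FC[i] <- full$beta[morph_col] / log(2)
    out$ll_full[i] <- full$loglik
    out$ll_reduced[i] <- red$loglik
    out$stat[i] <- stat
    out$pvalue[i] <- stats::pf(stat, 1, df2, lower.tail = FALSE)
    out$pvalue_chisq[i] <- stats::pchisq(stat, df = 1,
                                         lower.tail = FALSE)
    out$converged[i] <- TRUE
  }
  class(out) <- c("DEModelFit", "data.frame")
  out
}

#' Classify genes as worker-, queen- or non-biased
#'
#' Benjamini-Hochberg adjustment is applied across the converged genes of
#' the tissue (non-converged genes are excluded from the multiple-testing
#' family and labelled NA). Labels follow the volcano-plot convention:
#' worker requires `padj < padj_threshold` and `log2FC >= lfc_threshold`;
#' queen the mirror image.
#'
#' @param fits `DEModelFit` from [lrt_morph()].
#' @param padj_threshold,lfc_threshold classification thresholds.
#' @return data.frame of class `BiasTable`: gene_id, log2FC, pvalue,
#'   padj, bias.
#' @export
classify_bias <- function(fits, padj_threshold = 0.05,
                          lfc_threshold = 1) {
  ok <- !is.na(fits$pvalue)
  if (!any(ok)) stop("no gene with a p-value")
  out <- fits[ok, c("gene_id", "log2FC", "pvalue"), drop = FALSE]
  out <- out[order(out$gene_id), , drop = FALSE]  # deterministic tie order
  out$padj <- stats::p.adjust(out$pvalue, method = "BH")
  out$bias <- "none"
  out$bias[out$padj < padj_threshold &
             out$log2FC >= lfc_threshold] <- "worker"
  out$bias[out$padj < padj_threshold &
             out$log2FC <= -lfc_threshold] <- "queen"
  rownames(out) <- out$gene_id
  class(out) <- c("BiasTable", "data.frame")
  out
}

#' Per-tissue differential expression, end to end
#'
#' Subsets samples of one tissue, applies the low-count filter within the
#' subset, computes size factors and dispersions, runs the morph LRT and
#' classifies bias.
#'
#' @param m full `ExpressionMatrix`. @param design `SampleDesign`.
#' @param tissue tissue label to analyse.
#' @param padj_threshold,lfc_threshold classification thresholds.
#' @return `BiasTable` with attributes `n_filtered`, `n_tested`,
#'   `n_unconverged`.
#' @export
run_de <- function(m, design, tissue, padj_threshold = 0.05,
                   lfc_threshold = 1) {
  check_design_matrix(m, design)
  keep <- design$sample_id[design$tissue == tissue]
  if (!length(keep)) stop("no samples for tissue '", tissue, "'")
  sub <- expression_matrix(m$counts[, keep, drop = FALSE])
  n0 <- nrow(sub$counts)
  sub <- filter_low_counts(sub)
  s <- size_factors(sub)
  alpha <- estimate_dispersion(sub, s, design = design)
  fits <- lrt_morph(sub, design, s, alpha)
  bias <- classify_bias(fits, padj_threshold, lfc_threshold)
  attr(bias, "n_filtered") <- n0 - nrow(sub$counts)
  attr(bias, "n_tested") <- nrow(bias)
  attr(bias, "n_unconverged") <- sum(!fits$converged)
  bias
}
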