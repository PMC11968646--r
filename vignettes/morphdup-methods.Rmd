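---
title: "Models and methods behind morphdup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind morphdup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

morphdup is a desk-scale pipeline for two linked questions about social
insects with discrete female morphs (queens and workers): which genes are
expressed differently between morphs in which tissues, and what role
lineage-specific gene duplications play in those differences. This
vignette explains the models, the tunable parameters, the synthetic data
generator that serves as the package's test bed, and the numerical and
design choices that were genuinely open.

## Differential expression between morphs

Counts for gene $g$ in sample $j$ are modelled as negative binomial,

$$ y_{gj} \sim \mathrm{NB}(\mu_{gj},\ \alpha_g), \qquad
   \mathrm{Var}(y_{gj}) = \mu_{gj} + \alpha_g \mu_{gj}^2, $$

$$ \log \mu_{gj} = \log s_j + \beta_0 + \beta_{\mathrm{stage}(j)} +
   \beta_{\mathrm{cond}(j)} + \beta_m \cdot \mathbf{1}[\mathrm{worker}_j]. $$

Size factors $s_j$ are median-of-ratios (the median over genes with a
positive geometric mean of $y_{gj}/\tilde y_g$), with no rescaling
afterwards — they are therefore defined only up to a common factor, which
the intercept absorbs. Ovarian development stage (3 unordered levels) and
insemination condition enter as covariates so that morph contrasts are not
confounded by development or mating status. Each gene is fit twice by
iteratively reweighted least squares with its dispersion held fixed —
the full model above and a reduced model without the morph term — and
tested with the likelihood ratio $\Lambda = 2(\ell_{\mathrm{full}} -
\ell_{\mathrm{red}})$. `log2FC` is the morph coefficient on the log2
scale; positive means worker-biased. Genes are labelled
worker-/queen-biased at Benjamini–Hochberg adjusted $p < 0.05$ and
$|\log_2 \mathrm{FC}| \ge 1$, adjusted per tissue (each tissue is an
independent analysis; non-converged genes are excluded from the
multiple-testing family).

Two choices here departed from the obvious defaults, both forced by
measurement on the package's own simulations:

* **Dispersion.** A marginal method-of-moments estimator
  ($\hat\alpha = \max((v - \bar y)/\bar y^2, 10^{-8})$ on normalized
  counts) is provided (`estimate_dispersion` without a design), but it is
  unusable for testing: it books real between-morph signal as biological
  noise for exactly the biased genes (measured sensitivity dropped from
  ~0.95 to ~0.6 on planted 2-unit log2 effects) and its sampling noise
  makes the LRT anti-conservative (~0.10 rejection at nominal 0.05).
  The testing path instead maximizes the Cox–Reid adjusted profile
  likelihood per gene under the full model — the standard gene-wise
  estimator of the mainstream DE tools — still strictly per gene, with
  no information sharing across genes.
* **Reference distribution.** Even with Cox–Reid dispersions, the
  asymptotic $\chi^2_1$ reference is slightly liberal at the package's
  stated world of 6 samples per morph (measured null rejection 0.072).
  P-values therefore use $F(1, n-p)$, in the tradition of quasi-likelihood
  F-tests; measured null rejection is 0.043 with a uniform p-value
  distribution (KS $p = 0.48$). The $\chi^2$ p-value is retained in the
  output column `pvalue_chisq` for comparison.

A caveat the test suite makes explicit: scaling a *single* sample's counts
by $c$ cannot leave the fitted fold changes exactly invariant (the scaled
sample's score contribution carries the factor $c$); what does hold
exactly is that its size factor gains the factor $c$ relative to the other
samples, and that whole-matrix scaling leaves fold changes unchanged in
the Poisson weighting limit.

## Tissue specificity (tau)

Expression is TPM-normalized (`rate = count / (length/10^3)`, scaled to
$10^6$ per sample), the bottom decile of mean TPM is removed (ties at the
cutoff removed, so the filter is deterministic), and each gene gets a
per-tissue profile $x_i$ = mean of $\log_2(\mathrm{TPM}+1)$ over that
tissue's samples, pooling morphs, stages and conditions (a
`split_by_morph` switch exposes the un-pooled variant; the pooling choice
is not documented in the source study). Then

$$ \tau = \frac{\sum_{i=1}^{N} (1 - x_i / \max_i x_i)}{N - 1}
   \in [0, 1], $$

with 0 = uniform expression and 1 = single-tissue expression. Genes with
$\max_i x_i = 0$ get an undefined $\tau$ and an `excluded` flag — never 0,
which would mislabel silence as ubiquity. Tau distributions across bias
classes are compared by two-sided Wilcoxon rank-sum tests with a
Bonferroni factor of 3 (the three planned pairs).

## Lineage-specific duplications

Gene-tree internal nodes are duplication events iff the species sets of
their two child subtrees overlap (the species-overlap rule, parameter
free). Each event maps to the species-tree LCA of the union of the two
sets, and is retained iff that node lies on the path from the ingroup
MRCA down to the focal-species tip, inclusive — duplications older than
the ingroup are excluded. Per orthogroup, the focal-species genes
descending from retained events form one merged candidate set (nested
duplications do not split sets), kept at $\ge 2$ members; its origin node
is the most basal retained contributing node. Multifurcations are
resolved deterministically (`ape::multi2di(random = FALSE)`) and flagged
rather than rejected. Orthogroups without a gene tree fall back to copy
numbers: focal species $\ge 2$ copies, at least `min_ingroup_species`
ingroup species $\ge 2$, every outgroup $\le 1$. Finally the
linkage-group filter keeps only sets whose members all lie on declared
chromosome-level sequences.

## Divergence between duplicates

* **Bias concordance** (by default in the reproductive-tissue bias table,
  where morph differences are strongest): `differential` if the set has
  both a worker- and a queen-biased member, `consistent_*` if all members
  share one bias, `partial` for a mix of biased and unbiased members (a
  class the source study does not describe; isolating it keeps the
  consistent/differential counts clean), `unbiased` otherwise.
* **Pair expression divergence**: for each gene the mean normalized count
  in each of the 8 (tissue × morph) subsets, then
  $D = \sum_{\mathrm{subsets}} |m_a - m_b|$, computed for every unordered
  pair; size factors come from one normalization of the full cross-tissue
  matrix.
* **Distance**: the inter-feature gap — bases strictly between the two
  genes (1-based inclusive coordinates, overlap clamps to 0); a
  `--distance-mode start` switch gives start-to-start instead, since the
  source study does not state its convention.
* **Co-location**: the probability that a random gene pair shares a
  chromosome is $p_0 = \sum_c \frac{g_c}{G}\cdot\frac{g_c - 1}{G - 1}$
  from background per-chromosome gene counts; observed same-chromosome
  sets out of evaluable sets are tested with a one-sided exact binomial
  test. $p_0$ is validated against Monte-Carlo pair sampling in the
  acceptance suite.
* **Multicopy enrichment**: $\chi^2$ goodness of fit (df = 1, no
  continuity correction) of the multicopy/single-copy split of biased
  genes against the background multicopy proportion.

## dN/dS by NG86 codon counting

Homologous pairs come from reciprocal best hits on global protein
alignment scores (BLOSUM62, gap open 11 / extend 1, minimum score 50 —
a raw-score threshold stands in for a database-dependent E-value; ties
for best hit drop the pair). The protein alignment is back-translated to
codon columns; columns opposite gaps, containing ambiguous bases, or
containing stop codons are dropped and counted. Per codon, the
synonymous site fraction at each position is (synonymous single-nucleotide
changes)/3 with changes to stops counted as nonsynonymous, so $S + N = 3$
per codon exactly; sites are averaged over the two sequences.
Multi-position codon differences average the synonymous/nonsynonymous
step counts over all minimal mutational pathways that avoid stop codons
(if every pathway is blocked, all pathways are used). Proportions are
Jukes–Cantor corrected, $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$, with
explicit validity flags: `dS_zero` when no synonymous difference was seen
(ω undefined) and `saturated` when $\tfrac{4}{3}p \ge 1$. This NG86
implementation replaces the Comeron-style counting used by the study's
toolchain: it is fully specified, testable by exhaustive enumeration, and
expected to shift absolute values slightly while preserving the rank
comparisons the downstream analysis uses. Only the standard genetic code
is wired in (insect nuclear genes); the table is selectable by NCBI code
ID internally.

## The synthetic stated world

The generator (`sim_config` + `simulate_*`) emulates the structure of the
study's data, not its content:

* **Counts**: 2 morphs × 4 tissues × 3 ovarian stages × 2 insemination
  conditions, with configurable replicates per cell (default 2 → 96
  samples); NB counts with log-normal baselines (natural-log mean 4,
  sd 1.5 — library-realistic medians around 50 counts), global dispersion
  0.1, per-sample depth multipliers uniform on [0.5, 2]. Planted morph
  effects: a 10% fraction at ±2 log2 units applied in all tissues, sign
  random. 5% of genes are tissue-restricted (expression dropped 10 log2
  units outside a home tissue); 20% get mild stage/condition effects
  (sd 0.5 log2). These magnitudes follow the acceptance criteria where
  stated and field-typical values elsewhere, chosen once.
* **Families**: a ladder species tree with 4 ingroup and 2 outgroup
  species; duplications planted at the ingroup MRCA, an internal ingroup
  node, the focal terminal branch, or above the ingroup (the negative
  control), cycled across families. Focal paralogues are placed tandemly
  (gap uniform on [2, 50] kb) or on distinct chromosomes; 10% of families
  get one member on an unplaced scaffold to exercise the linkage-group
  filter.
* **CDS pairs**: sequence B evolves from a random stop-free sequence A by
  single-nucleotide proposals — synonymous always accepted, nonsynonymous
  with probability $\min(1, \omega)$, stops always rejected. This crude
  accept/reject scheme tests sign and ordering recovery of ω; it has no
  transition/transversion or codon-frequency structure and is documented
  as approximate.

Everything is a pure function of the configuration (seed included);
sub-seeds per stage are derived deterministically. A green test on this
world establishes that the algorithms recover what was planted under the
model's own assumptions — it says nothing about read-level artifacts, GC
or length bias, assembly errors, or real gene-tree estimation noise, all
of which the study's upstream tools handle and morphdup deliberately does
not model.

## Numerical choices and degenerate inputs

IRLS: log-link, linear predictor clamped to [-30, 30], at most 100
iterations, convergence at relative deviance change $< 10^{-8}$;
non-converged genes are flagged, get `NA` p-values and leave the BH
family. Dispersion search: log-scale golden-section on
$[10^{-6}, 10]$, tolerance 0.02. BH ties are broken by gene ID order
(no effect on values). The bottom-decile TPM filter errors when every
gene ties at the cutoff (degenerate expression), `size_factors` errors
when no gene is expressed in all samples, `tau` is undefined (not 0) for
silent genes, and single-level covariates are dropped from both LRT
models rather than producing singular fits.

## Known limitations

No empirical-Bayes dispersion moderation (power at very small replicate
counts is below what shrinkage-based tools achieve); no shrunken fold
changes; the duplication mapper trusts the input gene trees; dN/dS is
pairwise NG86 only (no ML codon models, no branch/site tests); the CLI
orchestrates one species pair per run for dN/dS. Tandem-versus-dispersed
classification beyond same-chromosome distance is out of scope.
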