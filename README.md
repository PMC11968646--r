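# morphdup

Queen/worker (caste) biased gene expression across tissues, tau
tissue-specificity, lineage-specific gene duplications and codon-level
dN/dS — as one tested, end-to-end R pipeline.

Social insect queens and workers share a genome; their phenotypic
differences come from how that genome is used. morphdup is for
researchers asking, at desk scale, the questions a multi-tissue
bumblebee transcriptome study asks at full scale:

* Which genes are **morph-biased** per tissue? Per-gene negative-binomial
  GLMs (`log mu = log s_j + b0 + b_stage + b_condition + b_morph`), full
  vs reduced likelihood-ratio tests for the morph term, Benjamini–Hochberg
  adjustment, bias calls at `padj < 0.05`, `|log2FC| >= 1` (positive =
  worker-biased).
* Are biased genes **tissue-specific**? TPM → bottom-decile filter →
  per-tissue means of `log2(TPM+1)` → `tau = sum(1 - x/max(x))/(N-1)`
  in [0,1], compared across bias classes by Wilcoxon rank-sum tests.
* Which paralogue sets are **lineage-specific duplications**?
  Species-overlap mapping of gene-tree duplication nodes onto the species
  tree, retained on the ingroup-MRCA → focal-tip path, linkage-group
  (chromosome) filtering, origin-node dating.
* Do duplicates **diverge in usage**? Bias-concordance classes
  (consistent worker / consistent queen / differential / partial /
  unbiased), the 8-subset (4 tissues × 2 morphs) pair divergence
  `D = sum |m_a - m_b|`, inter-paralogue distances, a binomial
  same-chromosome co-location test and a chi-square multicopy enrichment
  test.
* How constrained are they? Reciprocal-best-hit pairing on protein
  alignment scores, codon alignment by back-translation, and **NG86**
  dN/dS with Jukes–Cantor correction (`d = -3/4 ln(1 - 4/3 p)`), with
  explicit `dS_zero`/`saturated` validity flags.

A first-class synthetic-data module generates the whole input bundle
(counts, design, GFF3, trees, orthogroups, CDS FASTA) with ground-truth
tables, so every stage is validated by planted-effect recovery.

## Worked example

```r
library(morphdup)

cfg <- sim_config(n_genes = 1000, replicates = 1, morph_frac = 0.1,
                  morph_lfc = 2, alpha = 0.1, seed = 7)
sim <- simulate_counts(cfg)
sim$matrix
#> ExpressionMatrix: 1000 genes x 48 samples
#> layers: counts

bias <- run_de(sim$matrix, sim$design, "RT")
head(bias[bias$bias != "none", c("gene_id", "log2FC", "padj", "bias")], 3)
#>             gene_id log2FC    padj   bias
#> gene00039 gene00039  -1.97 0.00322  queen
#> gene00042 gene00042  -2.26 0.00479  queen
#> gene00063 gene00063   1.89 0.02482 worker
```

953 genes survive the low-count filter in the reproductive-tissue (RT)
subset; 45 are called worker-biased and 31 queen-biased — the generator
planted ~10% of genes with a ±2 log2 morph effect, and the signs above
match the planted directions. Tau then quantifies how tissue-restricted
each gene's expression is:

```r
lengths <- setNames(rep(1000, 1000), rownames(sim$matrix$counts))
taus <- compute_tau(sim$matrix, sim$design, lengths)
compare_tau_by_bias(taus, bias)[, c("group1","group2","median1","median2","padj")]
#>   group1 group2 median1 median2   padj
#> 1 worker   none  0.0405  0.0431 0.2727
#> 2  queen   none  0.0550  0.0431 0.2502
#> 3 worker  queen  0.0405  0.0550 0.0545
```

(Medians near 0 and non-significant comparisons are correct here: this
simulation planted morph effects uniformly across tissues, not
tissue-restricted ones.) Finally, a codon pair evolved at omega = 0.2 is
recovered by NG86 counting:

```r
p <- simulate_cds_pair(n_codons = 300, omega = 0.2, seed = 7, attempts = 300)
ng86(codon_align(p$seq_a, p$seq_b))
#> NG86: 300 codons; S=213.83 N=686.17 Sd=55.50 Nd=46.50
#>       dS=0.3186 dN=0.0710 omega=0.223 [ok]
```

`S + N = 3 x 300` exactly; omega 0.223 against the planted 0.2.

## Whole pipeline

One JSON config drives simulate → DE → tau → duplications → divergence →
dN/dS with a machine-readable report; reruns are byte-identical:

```r
cfg <- list(seed = 1, out_dir = "run",
            simulation = list(n_genes = 600, seed = 1))
jsonlite::write_json(cfg, "cfg.json", auto_unbox = TRUE)
run_pipeline(validate_config("cfg.json"))
```

or from the shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/morphdup", package="morphdup"))')" \
    run --config cfg.json
```

Outputs land in `run/`: `bias_<tissue>.tsv`, `tau.tsv`,
`paralog_sets.tsv`, `concordance.tsv`, `pair_divergence.tsv`,
`pair_distances.tsv`, `divergence_tests.tsv`, `dnds.tsv`, `report.json`.

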