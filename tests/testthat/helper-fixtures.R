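# shared fixture builders; everything is generated in code at test time

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# minimal count TSV
counts_file <- function(df = NULL) {
  if (is.null(df))
    return(write_tmp(c("gene_id\ts1\ts2\ts3",
                       "g1\t5\t8\t2",
                       "g2\t0\t1\t7")))
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# an ExpressionMatrix built directly from a numeric matrix
em <- function(mat) {
  if (is.null(rownames(mat)))
    rownames(mat) <- sprintf("g%d", seq_len(nrow(mat)))
  if (is.null(colnames(mat)))
    colnames(mat) <- sprintf("s%d", seq_len(ncol(mat)))
  expression_matrix(mat)
}

# a single-tissue design with nq queens then nw workers, one stage and
# condition unless given
one_tissue_design <- function(nq, nw, tissue = "RT",
                              stage = "I", condition = "inseminated",
                              ids = NULL) {
  n <- nq + nw
  if (is.null(ids)) ids <- sprintf("s%d", seq_len(n))
  sample_design(data.frame(
    sample_id = ids, tissue = tissue,
    morph = rep(c("queen", "worker"), c(nq, nw)),
    stage = rep_len(stage, n), condition = rep_len(condition, n),
    stringsAsFactors = FALSE))
}

# two-species-ingroup + one-outgroup bundle with hand-built gene trees
toy_bundle <- function(gene_trees) {
  sp <- ape::read.tree(text = "((B1,B2)Ingroup,OUT)Root;")
  groups <- lapply(gene_trees, function(gt) {
    m <- list(B1 = character(0), B2 = character(0), OUT = character(0))
    for (tl in gt$tip.label) {
      parts <- strsplit(tl, "|", fixed = TRUE)[[1]]
      m[[parts[1]]] <- c(m[[parts[1]]], parts[2])
    }
    m
  })
  orthology_bundle(groups, sp, gene_trees, ingroup_node = "Ingroup",
                   focal = "B1")
}

nwk <- function(text) ape::read.tree(text = text)

write_cfg <- function(cfg) {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE)
  path
}

# deterministic RNG scope
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# independent oracle: synonymous sites of a codon by explicit enumeration
# of its nine single-nucleotide neighbours against the genetic code
oracle_syn_sites <- function(codon, code = Biostrings::GENETIC_CODE) {
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (p in 1:3) for (b in bases) {
    if (b == substr(codon, p, p)) next
    alt <- paste0(substr(codon, 1, p - 1), b, substr(codon, p + 1, 3))
    if (code[[alt]] == code[[codon]]) s <- s + 1 / 3
  }
  s
}

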