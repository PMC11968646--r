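# Readers/writers for every external format the pipeline touches.
# All readers validate aggressively so downstream stages can assume
# checked in-memory structures.  Coordinates are 1-based inclusive
# throughout (GFF3 convention); a 1 bp gene has start == end.

TISSUE_LEVELS    <- c("brain", "fat_body", "ovary", "RT")
MORPH_LEVELS     <- c("queen", "worker")
STAGE_LEVELS     <- c("I", "II", "IV")
CONDITION_LEVELS <- c("inseminated", "noninseminated")

#' Construct a validated expression matrix
#'
#' The central count container: an integer gene-by-sample matrix with
#' optional derived layers (median-of-ratios normalized counts, TPM) and
#' per-sample size factors.
#'
#' @param counts integer matrix, genes in rows, samples in columns; both
#'   dimensions must carry unique names.
#' @param normalized optional numeric matrix of normalized counts with the
#'   same dimnames as `counts`.
#' @param tpm optional numeric matrix; every column must sum to 1e6
#'   (relative tolerance 1e-9).
#' @param size_factors optional positive numeric vector, one per sample.
#' @return an object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(counts, normalized = NULL, tpm = NULL,
                              size_factors = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene IDs: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (any(!is.finite(counts)))
    stop("counts contain non-finite values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at gene '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at gene '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  storage.mode(counts) <- "double"  # keeps large counts exact, avoids int overflow
  counts <- round(counts)
  if (!is.null(tpm)) {
    cs <- colSums(tpm)
    if (any(abs(cs - 1e6) > 1e-3 + 1e6 * 1e-9))
      stop("TPM columns must each sum to 1e6")
  }
  if (!is.null(size_factors)) {
    if (length(size_factors) != ncol(counts) || any(size_factors <= 0))
      stop("size_factors must be positive, one per sample")
  }
  structure(list(counts = counts, normalized = normalized, tpm = tpm,
                 size_factors = size_factors),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  layers <- c("counts",
              if (!is.null(x$normalized)) "normalized",
              if (!is.null(x$tpm)) "tpm")
  cat("layers:", paste(layers, collapse = ", "), "\n")
  if (!is.null(x$size_factors))
    cat("size factors: present\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$counts)

#' Read a gene-by-sample count matrix from TSV
#'
#' First column holds gene IDs, header row holds sample IDs, cells must be
#' non-negative integers. Plain or gzip files accepted.
#'
#' @param path TSV file path.
#' @return [expression_matrix()] with the counts layer only.
#' @export
read_counts <- function(path) {
  df <- read_tsv_checked(path)
  if (ncol(df) < 2) stop("count file needs a gene column plus >=1 sample")
  gene_ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    for (j in seq_len(ncol(m))) {
      v <- suppressWarnings(as.numeric(m[, j]))
      if (any(is.na(v) & !is.na(m[, j])))
        stop(sprintf("non-numeric count at gene '%s', sample '%s'",
                     gene_ids[which(is.na(v))[1]], colnames(m)[j]))
      m[, j] <- v
    }
    storage.mode(m) <- "double"
  }
  rownames(m) <- gene_ids
  expression_matrix(m)
}

#' Write a count matrix to TSV
#'
#' Inverse of [read_counts()]; round-trips exactly.
#' @param m an `ExpressionMatrix`.
#' @param path output path (gzip if it ends in .gz).
#' @export
write_counts <- function(m, path) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  df <- data.frame(gene_id = rownames(m$counts),
                   m$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
  invisible(path)
}

#' Read a sample design table
#'
#' Columns: sample_id, tissue, morph, stage, condition. Factor values are
#' validated against declared level sets.
#'
#' @param path TSV file path.
#' @param levels named list of allowed levels for tissue, morph, stage,
#'   condition; defaults to the study's level sets.
#' @return data.frame of class `SampleDesign` with factor columns.
#' @export
read_design <- function(path,
                        levels = list(tissue = TISSUE_LEVELS,
                                      morph = MORPH_LEVELS,
                                      stage = STAGE_LEVELS,
                                      condition = CONDITION_LEVELS)) {
  df <- read_tsv_checked(path)
  need <- c("sample_id", "tissue", "morph", "stage", "condition")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("design missing column(s): ",
                         paste(miss, collapse = ", "))
  sample_design(df, levels = levels)
}

#' Construct a validated sample design
#' @param df data.frame with sample_id, tissue, morph, stage, condition.
#' @param levels named list of allowed factor levels.
#' @return `SampleDesign` data.frame.
#' @export
sample_design <- function(df,
                          levels = list(tissue = TISSUE_LEVELS,
                                        morph = MORPH_LEVELS,
                                        stage = STAGE_LEVELS,
                                        condition = CONDITION_LEVELS)) {
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "))
  for (col in names(levels)) {
    bad <- setdiff(unique(as.character(df[[col]])), levels[[col]])
    if (length(bad))
      stop(sprintf("unknown %s level(s): %s", col,
                   paste(bad, collapse = ", ")))
    df[[col]] <- factor(as.character(df[[col]]), levels = levels[[col]])
  }
  df$sample_id <- as.character(df$sample_id)
  rownames(df) <- df$sample_id
  class(df) <- c("SampleDesign", "data.frame")
  df
}

#' Check that a design covers a count matrix
#'
#' Every matrix sample must have exactly one design row. With
#' `exact = TRUE` (the file-reading join check) design rows without a
#' matrix sample are also an error.
#'
#' @param m `ExpressionMatrix`. @param design `SampleDesign`.
#' @param exact require the sample sets to match exactly.
#' @return invisibly TRUE; errors on mismatch.
#' @export
check_design_matrix <- function(m, design, exact = FALSE) {
  miss <- setdiff(colnames(m$counts), design$sample_id)
  if (length(miss))
    stop("samples missing from design: ", paste(miss, collapse = ", "))
  if (exact) {
    extra <- setdiff(design$sample_id, colnames(m$counts))
    if (length(extra))
      stop("design sample(s) missing from matrix: ",
           paste(extra, collapse = ", "))
  }
  invisible(TRUE)
}

#' Read gene loci from a GFF3 file
#'
#' Only `gene` features are consumed; every gene must carry an ID
#' attribute. `is_chromosome` records membership of the sequence in the
#' declared chromosome-level ID set (the linkage-group filter input).
#'
#' @param path GFF3 path (plain or gzip).
#' @param chromosome_ids character vector of chromosome-level sequence IDs.
#' @return data.frame: gene_id, sequence_id, start, end, strand,
#'   is_chromosome.
#' @export
read_gff_loci <- function(path, chromosome_ids) {
  g <- as.data.frame(rtracklayer::readGFF(
    path, columns = c("seqid", "source", "type", "start", "end", "strand"),
    tags = "ID"))
  g <- g[g$type == "gene", , drop = FALSE]
  if (nrow(g) == 0) stop("no gene features in ", path)
  if (any(is.na(g$ID) | g$ID == ""))
    stop("gene feature without ID attribute at line(s) for seqid ",
         paste(unique(g$seqid[is.na(g$ID) | g$ID == ""]), collapse = ", "))
  if (any(g$start > g$end)) {
    bad <- g$ID[g$start > g$end][1]
    stop("gene '", bad, "' has start > end")
  }
  if (any(g$start < 1)) stop("coordinates must be >= 1")
  gene_loci(data.frame(gene_id = as.character(g$ID),
                       sequence_id = as.character(g$seqid),
                       start = as.integer(g$start),
                       end = as.integer(g$end),
                       strand = as.character(g$strand),
                       stringsAsFactors = FALSE),
            chromosome_ids = chromosome_ids)
}

#' Construct a validated gene-locus table
#' @param df data.frame with gene_id, sequence_id, start, end, strand.
#' @param chromosome_ids declared chromosome-level sequence IDs.
#' @return `GeneLoci` data.frame with an is_chromosome flag.
#' @export
gene_loci <- function(df, chromosome_ids) {
  stopifnot(all(c("gene_id", "sequence_id", "start", "end", "strand")
                %in% names(df)))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in loci: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  if (any(df$start > df$end)) stop("locus with start > end")
  if (any(df$start < 1)) stop("coordinates must be >= 1")
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  df$is_chromosome <- df$sequence_id %in% chromosome_ids
  rownames(df) <- df$gene_id
  class(df) <- c("GeneLoci", "data.frame")
  df
}

#' Read orthology inputs into a bundle
#'
#' Reads the orthogroup membership table (one row per orthogroup, one
#' column per species, comma-separated gene lists), a rooted species tree
#' with labelled internal nodes, and optional per-orthogroup rooted gene
#' trees whose leaves are labelled `species<delim>gene`.
#'
#' @param orthogroup_path TSV path; first column `Orthogroup`.
#' @param species_tree_path newick path; must be rooted.
#' @param gene_tree_dir optional directory of `<orthogroup>.nwk` files.
#' @param ingroup_node internal node label designating the ingroup clade.
#' @param focal focal species ID (must be inside the ingroup).
#' @param delim delimiter between species and gene in gene-tree leaves.
#' @return list of class `OrthologyBundle`.
#' @export
read_orthology <- function(orthogroup_path, species_tree_path,
                           gene_tree_dir = NULL, ingroup_node, focal,
                           delim = "|") {
  og <- read_tsv_checked(orthogroup_path)
  if (names(og)[1] != "Orthogroup")
    names(og)[1] <- "Orthogroup"
  species <- names(og)[-1]
  groups <- lapply(seq_len(nrow(og)), function(i) {
    row <- lapply(species, function(sp) {
      cell <- og[[sp]][i]
      if (is.na(cell) || !nzchar(trimws(cell))) character(0)
      else trimws(strsplit(as.character(cell), ",")[[1]])
    })
    names(row) <- species
    row
  })
  names(groups) <- as.character(og$Orthogroup)

  sp_tree <- ape::read.tree(species_tree_path)
  gene_trees <- list()
  if (!is.null(gene_tree_dir)) {
    files <- list.files(gene_tree_dir, pattern = "\\.nwk$|\\.tree$|\\.txt$",
                        full.names = TRUE)
    for (f in files) {
      ogid <- sub("\\.(nwk|tree|txt)$", "", basename(f))
      gene_trees[[ogid]] <- ape::read.tree(f)
    }
  }
  orthology_bundle(groups, sp_tree, gene_trees, ingroup_node, focal, delim)
}

#' Construct a validated orthology bundle
#' @param groups named list: orthogroup -> species -> gene ID vector.
#' @param species_tree rooted `phylo` with node labels.
#' @param gene_trees named list of rooted `phylo`, leaf labels
#'   `species<delim>gene`; may omit orthogroups (copy-number fallback used).
#' @param ingroup_node label of the ingroup MRCA in the species tree.
#' @param focal focal species ID.
#' @param delim species/gene delimiter in gene-tree leaf labels.
#' @return `OrthologyBundle`.
#' @export
orthology_bundle <- function(groups, species_tree, gene_trees = list(),
                             ingroup_node, focal, delim = "|") {
  if (!ape::is.rooted(species_tree))
    stop("species tree must be rooted")
  if (is.null(species_tree$node.label) ||
      !(ingroup_node %in% species_tree$node.label))
    stop("ingroup node '", ingroup_node,
         "' is not a labelled internal node of the species tree")
  sp <- species_tree$tip.label
  ing_mrca <- length(sp) + match(ingroup_node, species_tree$node.label)
  ingroup_species <- sp[phylo_descendant_tips(species_tree, ing_mrca)]
  if (!(focal %in% ingroup_species))
    stop("focal species '", focal, "' not inside the ingroup clade")
  for (ogid in names(gene_trees)) {
    gt <- gene_trees[[ogid]]
    leaf_sp <- leaf_species(gt$tip.label, delim)
    bad <- setdiff(leaf_sp, sp)
    if (length(bad))
      stop(sprintf("gene tree '%s' leaf species not in species tree: %s",
                   ogid, paste(bad, collapse = ", ")))
  }
  structure(list(groups = groups, species_tree = species_tree,
                 gene_trees = gene_trees, ingroup_node = ingroup_node,
                 focal = focal, delim = delim,
                 ingroup_species = ingroup_species,
                 treeless = setdiff(names(groups), names(gene_trees))),
            class = "OrthologyBundle")
}

#' @export
print.OrthologyBundle <- function(x, ...) {
  cat(sprintf(
    "OrthologyBundle: %d orthogroups (%d with gene trees), %d species\n",
    length(x$groups), length(x$gene_trees),
    length(x$species_tree$tip.label)))
  cat("ingroup:", x$ingroup_node, " focal:", x$focal, "\n")
  invisible(x)
}

leaf_species <- function(labels, delim = "|") {
  vapply(strsplit(labels, delim, fixed = TRUE), `[[`, character(1), 1)
}

leaf_gene <- function(labels, delim = "|") {
  vapply(strsplit(labels, delim, fixed = TRUE),
         function(p) paste(p[-1], collapse = delim), character(1))
}

#' Read CDS sequences from FASTA
#'
#' @param path nucleotide FASTA (plain or gzip). IDs are the first
#'   whitespace-delimited token of each header and must be unique.
#' @return named character vector of uppercase sequences; attribute
#'   `frame_warning` flags records whose length is not divisible by 3.
#' @export
read_cds <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ID: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- toupper(as.character(seqs))
  names(out) <- ids
  ok <- grepl("^[ACGTRYSWKMBDHVN]*$", out)
  if (any(!ok))
    stop("non-IUPAC character in sequence(s): ",
         paste(ids[!ok], collapse = ", "))
  frame_bad <- nchar(out) %% 3L != 0L
  if (any(frame_bad))
    warning("length not divisible by 3 for: ",
            paste(ids[frame_bad], collapse = ", "))
  attr(out, "frame_warning") <- ids[frame_bad]
  out
}

#' Write sequences to FASTA
#' @param seqs named character vector. @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

# -- shared TSV plumbing ------------------------------------------------

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  df <- tryCatch(
    utils::read.delim(con, header = TRUE, sep = "\t",
                      check.names = FALSE, stringsAsFactors = FALSE,
                      colClasses = NA),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e)))
  if (nrow(df) == 0) stop("empty file: ", path)
  df
}

write_tsv_plain <- function(df, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
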