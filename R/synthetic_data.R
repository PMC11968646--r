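# Self-contained synthetic input generator with ground truth.
# The generator's defaults emulate the structure of the study design it
# stands in for: 2 morphs x 4 tissues x 3 ovarian stages x 2 insemination
# conditions, negative-binomial counts with planted morph effects,
# Bombus-like gene families with planted duplication nodes, and
# codon-evolved CDS pairs with controlled omega.

#' Build a simulation configuration
#'
#' All downstream simulators are pure functions of this object (seed
#' included). Fractions must lie in [0,1]; `alpha` is the NB dispersion in
#' the variance = mu + alpha * mu^2 parameterisation.
#'
#' @param n_genes number of genes.
#' @param tissues tissue labels to simulate.
#' @param stages,conditions covariate level sets.
#' @param replicates biological replicates per (tissue, morph, stage,
#'   condition) cell.
#' @param baseline_meanlog,baseline_sdlog natural-log-scale distribution of
#'   per-gene baseline expression.
#' @param alpha NB dispersion (global scalar or per-gene vector).
#' @param morph_frac fraction of genes with a planted morph effect.
#' @param morph_lfc magnitude of planted morph effects, log2 units (sign
#'   randomised; positive = worker-biased).
#' @param tissue_restricted_frac fraction of genes expressed in one tissue.
#' @param tissue_restricted_log2_drop log2 drop outside the home tissue.
#' @param tissue_effect_sd sd (log2) of mild per-gene tissue effects for
#'   unrestricted genes.
#' @param stage_effect_sd,condition_effect_sd sd (log2) of covariate
#'   effects planted on a random 20% of genes.
#' @param depth_range range of per-sample depth multipliers (uniform).
#' @param n_families,n_ingroup,n_outgroup gene-family simulation sizes.
#' @param placements duplication placements cycled over families; allowed:
#'   "ingroup_mrca", "internal", "focal_branch", "above_ingroup".
#' @param tandem_frac fraction of families placed tandemly (same
#'   chromosome); the rest are dispersed across chromosomes.
#' @param scaffold_frac fraction of families with one member on an
#'   unplaced scaffold (exercises the chromosome filter).
#' @param tandem_gap_range inter-gene gap range (bp) for tandem pairs.
#' @param n_single_copy single-copy background orthogroups.
#' @param n_chromosomes chromosome-level sequences in the toy assembly.
#' @param n_codons,omega,cds_attempts_per_codon codon-pair evolution
#'   settings; `omega` is the vector of planted dN/dS values cycled over
#'   pairs; attempts are per codon.
#' @param n_cds_pairs number of CDS pairs to simulate.
#' @param seed mandatory RNG seed.
#' @return list of class `SimulationConfig`.
#' @export
sim_config <- function(n_genes = 2000,
                       tissues = c("brain", "fat_body", "ovary", "RT"),
                       stages = c("I", "II", "IV"),
                       conditions = c("inseminated", "noninseminated"),
                       replicates = 2,
                       baseline_meanlog = 4, baseline_sdlog = 1.5,
                       alpha = 0.1,
                       morph_frac = 0.1, morph_lfc = 2,
                       tissue_restricted_frac = 0.05,
                       tissue_restricted_log2_drop = 10,
                       tissue_effect_sd = 0.25,
                       stage_effect_sd = 0.5,
                       condition_effect_sd = 0.5,
                       depth_range = c(0.5, 2),
                       n_families = 40, n_ingroup = 4, n_outgroup = 2,
                       placements = c("ingroup_mrca", "internal",
                                      "focal_branch", "above_ingroup"),
                       tandem_frac = 0.6, scaffold_frac = 0.1,
                       tandem_gap_range = c(2000, 50000),
                       n_single_copy = 200,
                       n_chromosomes = 18,
                       n_codons = 300, omega = c(0.2, 0.5, 1.0),
                       cds_attempts_per_codon = 1,
                       n_cds_pairs = 30,
                       seed = NULL) {
  if (is.null(seed)) stop("seed is mandatory")
  fracs <- c(morph_frac, tissue_restricted_frac, tandem_frac, scaffold_frac)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0,1]")
  if (any(alpha <= 0)) stop("alpha must be > 0")
  if (replicates < 1) stop("zero replicates in a design cell")
  bad <- setdiff(placements, c("ingroup_mrca", "internal", "focal_branch",
                               "above_ingroup"))
  if (length(bad)) stop("unknown placement(s): ", paste(bad, collapse = ", "))
  cfg <- as.list(environment())
  class(cfg) <- "SimulationConfig"
  cfg
}

# deterministic per-stage sub-seed, kept under 2^31
sub_seed <- function(seed, stage) {
  (as.integer(seed) * 1009L + stage * 7919L) %% 2147483562L
}

#' Simulate a count matrix with planted effects
#'
#' Counts are drawn per gene g and sample j from a negative binomial with
#' mean `depth_j * exp(b0_g + b_tissue + b_stage + b_condition +
#' b_morph * 1[worker])` and dispersion `alpha_g`
#' (variance = mu + alpha * mu^2). Planted morph effects apply in every
#' simulated tissue; their sign is randomised per gene.
#'
#' @param cfg a [sim_config()].
#' @return list with `matrix` ([expression_matrix()]), `design`
#'   ([sample_design()]) and `truth` (per-gene and per-sample tables).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sub_seed(cfg$seed, 1L))

  morphs <- c("queen", "worker")
  grid <- expand.grid(rep = seq_len(cfg$replicates),
                      condition = cfg$conditions, stage = cfg$stages,
                      morph = morphs, tissue = cfg$tissues,
                      stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("%s_%s_s%s_%s_r%d", grid$tissue, grid$morph,
                            grid$stage, substr(grid$condition, 1, 3),
                            grid$rep)
  ns <- nrow(grid)
  ng <- cfg$n_genes
  gene_ids <- sprintf("gene%05d", seq_len(ng))

  b0 <- stats::rnorm(ng, cfg$baseline_meanlog, cfg$baseline_sdlog)
  alpha <- rep_len(cfg$alpha, ng)

  # planted morph effects (log2, random sign), applied in all tissues
  is_de <- stats::runif(ng) < cfg$morph_frac
  lfc <- ifelse(is_de, cfg$morph_lfc * sample(c(-1, 1), ng, TRUE), 0)

  # tissue structure: restricted genes collapse outside a home tissue;
  # unrestricted genes get mild random tissue effects
  nt <- length(cfg$tissues)
  restricted <- stats::runif(ng) < cfg$tissue_restricted_frac
  home <- sample(cfg$tissues, ng, TRUE)
  tissue_eff <- matrix(stats::rnorm(ng * nt, 0, cfg$tissue_effect_sd),
                       ng, nt, dimnames = list(gene_ids, cfg$tissues))
  for (t in cfg$tissues) {
    drop <- restricted & home != t
    tissue_eff[drop, t] <- -cfg$tissue_restricted_log2_drop
    tissue_eff[restricted & home == t, t] <- 0
  }

  has_stage <- stats::runif(ng) < 0.2
  stage_eff <- matrix(0, ng, length(cfg$stages),
                      dimnames = list(gene_ids, cfg$stages))
  stage_eff[has_stage, -1] <- stats::rnorm(sum(has_stage) *
                                             (length(cfg$stages) - 1),
                                           0, cfg$stage_effect_sd)
  has_cond <- stats::runif(ng) < 0.2
  cond_eff <- matrix(0, ng, length(cfg$conditions),
                     dimnames = list(gene_ids, cfg$conditions))
  cond_eff[has_cond, -1] <- stats::rnorm(sum(has_cond) *
                                           (length(cfg$conditions) - 1),
                                         0, cfg$condition_effect_sd)

  depth <- stats::runif(ns, cfg$depth_range[1], cfg$depth_range[2])

  ln2 <- log(2)
  counts <- matrix(0, ng, ns, dimnames = list(gene_ids, grid$sample_id))
  for (j in seq_len(ns)) {
    eta <- b0 +
      ln2 * (tissue_eff[, grid$tissue[j]] +
               stage_eff[, grid$stage[j]] +
               cond_eff[, grid$condition[j]] +
               lfc * (grid$morph[j] == "worker"))
    mu <- depth[j] * exp(eta)
    counts[, j] <- stats::rnbinom(ng, size = 1 / alpha, mu = mu)
  }

  design <- sample_design(
    data.frame(sample_id = grid$sample_id, tissue = grid$tissue,
               morph = grid$morph, stage = grid$stage,
               condition = grid$condition, stringsAsFactors = FALSE),
    levels = list(tissue = unique(c(TISSUE_LEVELS, cfg$tissues)),
                  morph = MORPH_LEVELS,
                  stage = cfg$stages, condition = cfg$conditions))

  truth_genes <- data.frame(gene_id = gene_ids, morph_lfc = lfc,
                            tissue_restricted = restricted,
                            home_tissue = ifelse(restricted, home, NA),
                            alpha = alpha, stringsAsFactors = FALSE)
  truth_samples <- data.frame(sample_id = grid$sample_id, depth = depth,
                              stringsAsFactors = FALSE)
  list(matrix = expression_matrix(counts), design = design,
       truth = list(genes = truth_genes, samples = truth_samples))
}

#' Simulate gene families with planted duplication nodes
#'
#' Builds a rooted species tree (`n_ingroup` ingroup species, MRCA node
#' labelled "Ingroup"; `n_outgroup` outgroups), then for each family emits
#' a rooted gene tree in which the subtree below the planted duplication
#' node is doubled. Focal-species paralogues are placed tandemly (gap from
#' `tandem_gap_range`) or on distinct chromosomes; a `scaffold_frac`
#' fraction gets one member on an unplaced scaffold.
#'
#' @param cfg a [sim_config()].
#' @return list with `bundle` ([orthology_bundle()]), `loci`
#'   ([gene_loci()]) and `truth` (per-family table).
#' @export
simulate_families <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  if (cfg$n_ingroup < 2 || cfg$n_outgroup < 1)
    stop("need >=2 ingroup and >=1 outgroup species")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sub_seed(cfg$seed, 2L))

  ingroup <- sprintf("Bsp%02d", seq_len(cfg$n_ingroup))
  focal <- ingroup[1]
  outgroup <- sprintf("Out%02d", seq_len(cfg$n_outgroup))
  sp_tree <- build_species_tree(ingroup, outgroup)
  chroms <- sprintf("chr%02d", seq_len(cfg$n_chromosomes))

  groups <- list(); gene_trees <- list(); loci <- list(); truth <- list()
  placements <- rep_len(cfg$placements, cfg$n_families)
  if (cfg$n_families > 0) {
    n_tandem <- round(cfg$tandem_frac * cfg$n_families)
    n_scaf <- round(cfg$scaffold_frac * cfg$n_families)
    mode <- sample(c(rep("tandem", n_tandem),
                     rep("dispersed", cfg$n_families - n_tandem)))
    scaf <- seq_len(cfg$n_families) %in%
      sample(cfg$n_families, min(n_scaf, cfg$n_families))
  }

  pos <- stats::setNames(rep(1L, cfg$n_chromosomes), chroms)
  place_gene <- function(chrom, gap) {
    len <- sample(500:3000, 1)
    start <- pos[[chrom]] + gap
    pos[[chrom]] <<- start + len
    c(start = start, end = start + len - 1L)
  }

  for (i in seq_len(cfg$n_families)) {
    fam <- sprintf("FAM%04d", i)
    plc <- placements[i]
    gt <- build_family_tree(sp_tree, ingroup, outgroup, focal, plc, fam)
    gene_trees[[fam]] <- gt$tree
    groups[[fam]] <- gt$members
    focal_genes <- gt$members[[focal]]

    # physical placement of the focal paralogues
    n_m <- length(focal_genes)
    if (mode[i] == "tandem") {
      chrom <- sample(chroms, 1)
      gap1 <- sample(50000:200000, 1)
      gaps <- c(gap1, round(stats::runif(n_m - 1, cfg$tandem_gap_range[1],
                                         cfg$tandem_gap_range[2])))
      seqs <- rep(chrom, n_m)
    } else {
      seqs <- sample(chroms, n_m, replace = FALSE)
      gaps <- sample(50000:200000, n_m, replace = TRUE)
    }
    if (scaf[i]) seqs[n_m] <- sprintf("scaffold_%04d", i)
    for (k in seq_len(n_m)) {
      if (grepl("^scaffold", seqs[k])) {
        coords <- c(start = 1000L, end = 2500L)
      } else {
        # gap is the inter-feature spacing to the previous gene on chrom
        coords <- place_gene(seqs[k], gaps[k])
      }
      loci[[length(loci) + 1L]] <- data.frame(
        gene_id = focal_genes[k], sequence_id = seqs[k],
        start = coords[["start"]], end = coords[["end"]],
        strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
    }
    truth[[i]] <- data.frame(
      orthogroup_id = fam, placement = plc,
      members = paste(focal_genes, collapse = ";"),
      n_members = n_m, mode = if (scaf[i]) "scaffold" else mode[i],
      expected_retained = plc != "above_ingroup",
      expected_on_chromosomes = plc != "above_ingroup" && !scaf[i],
      stringsAsFactors = FALSE)
  }

  # single-copy background orthogroups (one gene per species)
  for (i in seq_len(cfg$n_single_copy)) {
    og <- sprintf("SC%05d", i)
    groups[[og]] <- stats::setNames(
      lapply(c(ingroup, outgroup), function(sp) sprintf("%s_%s", og, sp)),
      c(ingroup, outgroup))
    chrom <- sample(chroms, 1)
    coords <- place_gene(chrom, sample(20000:100000, 1))
    loci[[length(loci) + 1L]] <- data.frame(
      gene_id = sprintf("%s_%s", og, focal), sequence_id = chrom,
      start = coords[["start"]], end = coords[["end"]],
      strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
  }

  bundle <- orthology_bundle(groups, sp_tree, gene_trees,
                             ingroup_node = "Ingroup", focal = focal)
  loci_df <- if (length(loci)) do.call(rbind, loci) else
    data.frame(gene_id = character(0), sequence_id = character(0),
               start = integer(0), end = integer(0),
               strand = character(0))
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(orthogroup_id = character(0), placement = character(0),
               members = character(0), n_members = integer(0),
               mode = character(0), expected_retained = logical(0),
               expected_on_chromosomes = logical(0))
  list(bundle = bundle,
       loci = gene_loci(loci_df, chromosome_ids = chroms),
       chromosome_ids = chroms, truth = truth_df)
}

# ladder-shaped rooted species tree with labelled internal nodes:
# (((((B1,B2)N1,B3)N2,...)Ingroup, Out1)A1, Out2)Root
build_species_tree <- function(ingroup, outgroup) {
  nwk <- paste0("(", ingroup[1], ",", ingroup[2], ")")
  for (k in seq_len(length(ingroup) - 2))
    nwk <- paste0("(", nwk, "IN", k, ",", ingroup[k + 2], ")")
  nwk <- paste0(nwk, "Ingroup")
  for (k in seq_along(outgroup)) {
    lab <- if (k == length(outgroup)) "Root" else paste0("ANC", k)
    nwk <- paste0("(", nwk, ",", outgroup[k], ")", lab)
  }
  ape::read.tree(text = paste0(nwk, ";"))
}

# Gene tree for one family: species-tree topology with the subtree below
# the planted node doubled. Leaves are "species|<fam>_<species>_<copy>".
build_family_tree <- function(sp_tree, ingroup, outgroup, focal,
                              placement, fam) {
  leaf <- function(sp, copy)
    sprintf("%s|%s_%s_c%d", sp, fam, sp, copy)
  sub_nwk <- function(species, copy) {
    # ladder matching build_species_tree ordering
    s <- leaf(species[1], copy)
    if (length(species) > 1)
      for (k in 2:length(species))
        s <- paste0("(", s, ",", leaf(species[k], copy), ")")
    s
  }
  dup_species <- switch(placement,
    ingroup_mrca = ingroup,
    internal     = ingroup[1:2],          # node "IN*"/cherry inside ingroup
    focal_branch = focal,
    above_ingroup = c(ingroup, outgroup[1]))
  rest_in <- setdiff(ingroup, dup_species)
  rest_out <- setdiff(outgroup, if (placement == "above_ingroup")
    outgroup[1] else character(0))

  dup <- paste0("(", sub_nwk(rev(dup_species), 1), ",",
                sub_nwk(rev(dup_species), 2), ")")
  s <- dup
  for (spx in rest_in) s <- paste0("(", s, ",", leaf(spx, 1), ")")
  for (spx in rest_out) s <- paste0("(", s, ",", leaf(spx, 1), ")")
  tree <- ape::read.tree(text = paste0(s, ";"))

  members <- list()
  for (tl in tree$tip.label) {
    sp <- leaf_species(tl)
    members[[sp]] <- c(members[[sp]], leaf_gene(tl))
  }
  # every species in the tree gets its genes; absent species get none
  all_sp <- c(ingroup, outgroup)
  members <- stats::setNames(
    lapply(all_sp, function(spx) members[[spx]] %||% character(0)), all_sp)
  list(tree = tree, members = members)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a codon-evolved CDS pair with controlled omega
#'
#' `seq_a` is a random stop-free codon sequence; `seq_b` is derived from it
#' by proposing random single-nucleotide codon changes: synonymous
#' proposals are always accepted, nonsynonymous ones with probability
#' `min(1, omega)`, and proposals creating a stop codon are always
#' rejected. A crude accept/reject scheme — adequate for testing sign and
#' ordering recovery of omega, not absolute rates.
#'
#' @param n_codons codons per sequence (>= 1).
#' @param omega planted dN/dS acceptance ratio (> 0).
#' @param seed RNG seed.
#' @param attempts total substitution proposals (default one per codon).
#' @return list: `seq_a`, `seq_b`, `truth` row (omega, attempts, accepted).
#' @export
simulate_cds_pair <- function(n_codons, omega, seed,
                              attempts = n_codons) {
  if (omega <= 0) stop("omega must be > 0")
  if (n_codons < 1) stop("n_codons must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed %% 2147483562)

  code <- genetic_code_table()
  sense <- names(code)[code != "*"]
  codons_a <- sample(sense, n_codons, replace = TRUE)
  codons_b <- codons_a
  bases <- c("A", "C", "G", "T")
  accepted <- 0L
  for (k in seq_len(attempts)) {
    i <- sample.int(n_codons, 1)
    p <- sample.int(3L, 1)
    cod <- codons_b[i]
    alt <- sample(setdiff(bases, substr(cod, p, p)), 1)
    new <- cod
    substr(new, p, p) <- alt
    if (code[[new]] == "*") next
    syn <- code[[new]] == code[[cod]]
    if (syn || stats::runif(1) < min(1, omega)) {
      codons_b[i] <- new
      accepted <- accepted + 1L
    }
  }
  list(seq_a = paste(codons_a, collapse = ""),
       seq_b = paste(codons_b, collapse = ""),
       truth = data.frame(omega = omega, attempts = attempts,
                          accepted = accepted))
}

#' Simulate a batch of CDS pairs
#'
#' Planted omega values from `cfg$omega` are cycled over
#' `cfg$n_cds_pairs` pairs; per-pair seeds derive from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with FASTA-ready maps `cds_a`, `cds_b` and a `truth` table.
#' @export
simulate_cds_pairs <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  omega <- rep_len(cfg$omega, cfg$n_cds_pairs)
  a <- character(0); b <- character(0); rows <- list()
  for (i in seq_len(cfg$n_cds_pairs)) {
    p <- simulate_cds_pair(cfg$n_codons, omega[i],
                           seed = sub_seed(cfg$seed, 100L + i),
                           attempts = round(cfg$cds_attempts_per_codon *
                                              cfg$n_codons))
    id <- sprintf("cds%04d", i)
    a[[paste0(id, "_a")]] <- p$seq_a
    b[[paste0(id, "_b")]] <- p$seq_b
    rows[[i]] <- cbind(pair_id = id, p$truth)
  }
  list(cds_a = a, cds_b = b, truth = do.call(rbind, rows))
}

#' Write the full synthetic input bundle to a directory
#'
#' Emits counts TSV, design TSV, GFF3, newick trees, orthogroup TSV, CDS
#' FASTAs and truth TSVs — the complete file-level input surface of the
#' pipeline.
#'
#' @param cfg a [sim_config()]. @param dir output directory.
#' @return invisibly, a named list of written paths.
#' @export
write_simulation <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "gene_trees"), showWarnings = FALSE)
  sim <- simulate_counts(cfg)
  fams <- simulate_families(cfg)
  cds <- simulate_cds_pairs(cfg)

  # unify ID spaces: focal-species genes from the family simulator take
  # over the leading rows of the count matrix so expression, annotation
  # and orthology describe one coherent genome
  focal_ids <- fams$loci$gene_id
  if (length(focal_ids) > cfg$n_genes)
    stop("n_genes too small to host all focal family genes")
  if (length(focal_ids)) {
    rownames(sim$matrix$counts)[seq_along(focal_ids)] <- focal_ids
    sim$truth$genes$gene_id[seq_along(focal_ids)] <- focal_ids
  }

  paths <- list(
    counts = file.path(dir, "counts.tsv"),
    design = file.path(dir, "design.tsv"),
    gff = file.path(dir, "annotation.gff3"),
    orthogroups = file.path(dir, "orthogroups.tsv"),
    species_tree = file.path(dir, "species_tree.nwk"),
    gene_tree_dir = file.path(dir, "gene_trees"),
    cds_a = file.path(dir, "cds_a.fasta"),
    cds_b = file.path(dir, "cds_b.fasta"),
    chromosomes = file.path(dir, "chromosomes.txt"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    truth_samples = file.path(dir, "truth_samples.tsv"),
    truth_families = file.path(dir, "truth_families.tsv"),
    truth_cds = file.path(dir, "truth_cds.tsv"))

  write_counts(sim$matrix, paths$counts)
  write_tsv_plain(as.data.frame(sim$design), paths$design)
  write_gff3(fams$loci, paths$gff)
  write_orthogroups(fams$bundle, paths$orthogroups)
  ape::write.tree(fams$bundle$species_tree, paths$species_tree)
  for (og in names(fams$bundle$gene_trees))
    ape::write.tree(fams$bundle$gene_trees[[og]],
                    file.path(paths$gene_tree_dir, paste0(og, ".nwk")))
  write_fasta(cds$cds_a, paths$cds_a)
  write_fasta(cds$cds_b, paths$cds_b)
  writeLines(fams$chromosome_ids, paths$chromosomes)
  write_tsv_plain(sim$truth$genes, paths$truth_genes)
  write_tsv_plain(sim$truth$samples, paths$truth_samples)
  write_tsv_plain(fams$truth, paths$truth_families)
  write_tsv_plain(cds$truth, paths$truth_cds)
  invisible(paths)
}

#' Write gene loci as GFF3
#' @param loci `GeneLoci`. @param path output path.
#' @export
write_gff3 <- function(loci, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tmorphdup\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     loci$sequence_id, loci$start, loci$end, loci$strand,
                     loci$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Write an orthogroup membership table
#' @param bundle `OrthologyBundle`. @param path output path.
#' @export
write_orthogroups <- function(bundle, path) {
  species <- names(bundle$groups[[1]])
  rows <- vapply(names(bundle$groups), function(og) {
    paste(c(og, vapply(species, function(sp)
      paste(bundle$groups[[og]][[sp]], collapse = ", "), character(1))),
      collapse = "\t")
  }, character(1))
  writeLines(c(paste(c("Orthogroup", species), collapse = "\t"), rows),
             path)
  invisible(path)
}

# save/restore the global RNG state so simulators are pure
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
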