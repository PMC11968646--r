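# Lineage-specific paralogue sets: species-overlap mapping of gene-tree
# duplication nodes onto the species tree, restriction to the node path
# from the ingroup MRCA down to the focal terminal branch, chromosome
# (linkage-group) filtering, and origin-node dating.

# tips descending from a node (tip indices); node may itself be a tip
phylo_descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  sort(unlist(lapply(kids, function(k) phylo_descendant_tips(tree, k))))
}

# species-tree node numbers on the path ingroup-MRCA -> focal tip
# (inclusive of both ends)
retained_path_nodes <- function(species_tree, ingroup_node, focal) {
  ntip <- length(species_tree$tip.label)
  mrca <- ntip + match(ingroup_node, species_tree$node.label)
  tip <- match(focal, species_tree$tip.label)
  ape::nodepath(species_tree, mrca, tip)
}

sp_node_label <- function(species_tree, node) {
  ntip <- length(species_tree$tip.label)
  if (node <= ntip) species_tree$tip.label[node]
  else species_tree$node.label[node - ntip]
}

# edges from the root (for "most basal" comparisons)
sp_node_depth <- function(species_tree, node) {
  root <- length(species_tree$tip.label) + 1L
  length(ape::nodepath(species_tree, root, node)) - 1L
}

#' Map gene-tree duplication nodes onto the species tree
#'
#' For every internal node of every gene tree, the node is called a
#' duplication iff the species sets of its two child subtrees intersect
#' (species-overlap rule). The event is mapped to the species-tree LCA of
#' the union of the two sets and retained iff that LCA lies on the node
#' path from the ingroup MRCA to the focal-species tip (inclusive).
#' Multifurcating nodes are resolved deterministically
#' (`ape::multi2di(random = FALSE)`) and flagged.
#'
#' @param bundle an `OrthologyBundle` with gene trees.
#' @return data.frame of class `DuplicationEvents`: orthogroup_id, node,
#'   mapped_node, mapped_label, retained, focal_genes (";"-joined),
#'   multifurcation_resolved.
#' @export
map_duplications <- function(bundle) {
  stopifnot(inherits(bundle, "OrthologyBundle"))
  sp_tree <- bundle$species_tree
  path <- retained_path_nodes(sp_tree, bundle$ingroup_node, bundle$focal)
  rows <- list()
  for (ogid in sort(names(bundle$gene_trees))) {
    gt <- bundle$gene_trees[[ogid]]
    resolved <- FALSE
    if (!ape::is.binary(gt)) {
      gt <- ape::multi2di(gt, random = FALSE)
      resolved <- TRUE
    }
    ntip <- length(gt$tip.label)
    tip_sp <- leaf_species(gt$tip.label, bundle$delim)
    tip_gene <- leaf_gene(gt$tip.label, bundle$delim)
    for (node in (ntip + 1L):(ntip + gt$Nnode)) {
      kids <- gt$edge[gt$edge[, 1] == node, 2]
      sets <- lapply(kids, function(k)
        unique(tip_sp[phylo_descendant_tips(gt, k)]))
      if (length(sets) != 2) next
      if (!length(intersect(sets[[1]], sets[[2]]))) next
      union_sp <- sort(unique(unlist(sets)))
      mapped <- if (length(union_sp) == 1)
        match(union_sp, sp_tree$tip.label)
      else ape::getMRCA(sp_tree, union_sp)
      desc <- phylo_descendant_tips(gt, node)
      focal_genes <- tip_gene[desc][tip_sp[desc] == bundle$focal]
      rows[[length(rows) + 1L]] <- data.frame(
        orthogroup_id = ogid, node = node,
        mapped_node = mapped,
        mapped_label = sp_node_label(sp_tree, mapped),
        retained = mapped %in% path,
        focal_genes = paste(sort(unique(focal_genes)), collapse = ";"),
        multifurcation_resolved = resolved,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(orthogroup_id = character(0), node = integer(0),
               mapped_node = integer(0), mapped_label = character(0),
               retained = logical(0), focal_genes = character(0),
               multifurcation_resolved = logical(0))
  class(out) <- c("DuplicationEvents", "data.frame")
  out
}

#' Extract paralogue sets from retained duplication events
#'
#' Per orthogroup, one candidate set: the union of focal-species genes
#' descending from any retained duplication node. Kept iff it has >= 2
#' members. The origin node is the most basal (closest to the species-tree
#' root) retained duplication node contributing members.
#'
#' @param events `DuplicationEvents` from [map_duplications()].
#' @param bundle the `OrthologyBundle`.
#' @return data.frame of class `ParalogSets`: set_id, orthogroup_id,
#'   members (";"-joined), n_members, origin_node.
#' @export
extract_paralog_sets <- function(events, bundle) {
  rows <- list()
  for (ogid in sort(unique(events$orthogroup_id))) {
    ev <- events[events$orthogroup_id == ogid & events$retained &
                   nzchar(events$focal_genes), , drop = FALSE]
    if (!nrow(ev)) next
    members <- sort(unique(unlist(strsplit(ev$focal_genes, ";"))))
    if (length(members) < 2) next
    depth <- vapply(ev$mapped_node, function(n)
      sp_node_depth(bundle$species_tree, n), integer(1))
    origin <- ev$mapped_label[order(depth, ev$mapped_label)][1]
    rows[[length(rows) + 1L]] <- data.frame(
      orthogroup_id = ogid, members = paste(members, collapse = ";"),
      n_members = length(members), origin_node = origin,
      stringsAsFactors = FALSE)
  }
  finish_sets(rows)
}

#' Copy-number fallback for tree-less orthogroups
#'
#' A set is formed iff the focal species has >= 2 genes, at least
#' `min_ingroup_species` ingroup species have >= 2 genes, and every
#' outgroup species has <= 1 gene. Origin node is reported as the ingroup
#' MRCA (the finest claim copy numbers support).
#'
#' @param bundle `OrthologyBundle`.
#' @param min_ingroup_species minimum ingroup species with >= 2 copies.
#' @param orthogroups orthogroups to consider (default: tree-less ones).
#' @return `ParalogSets` data.frame.
#' @export
copy_number_fallback <- function(bundle, min_ingroup_species = 2,
                                 orthogroups = bundle$treeless) {
  rows <- list()
  out_sp <- setdiff(names(bundle$groups[[1]]), bundle$ingroup_species)
  for (ogid in sort(orthogroups)) {
    g <- bundle$groups[[ogid]]
    counts <- vapply(g, length, integer(1))
    if (counts[[bundle$focal]] < 2) next
    if (sum(counts[bundle$ingroup_species] >= 2) < min_ingroup_species)
      next
    if (length(out_sp) && any(counts[out_sp] > 1)) next
    members <- sort(g[[bundle$focal]])
    rows[[length(rows) + 1L]] <- data.frame(
      orthogroup_id = ogid, members = paste(members, collapse = ";"),
      n_members = length(members), origin_node = bundle$ingroup_node,
      stringsAsFactors = FALSE)
  }
  finish_sets(rows)
}

finish_sets <- function(rows) {
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(orthogroup_id = character(0), members = character(0),
               n_members = integer(0), origin_node = character(0))
  out$set_id <- sprintf("BSP%04d", seq_len(nrow(out)))
  out <- out[, c("set_id", "orthogroup_id", "members", "n_members",
                 "origin_node")]
  class(out) <- c("ParalogSets", "data.frame")
  out
}

set_members <- function(sets) {
  stats::setNames(strsplit(sets$members, ";"), sets$set_id)
}

#' Restrict paralogue sets to chromosome-level placements
#'
#' Keeps only sets in which every member lies on a declared chromosome
#' (linkage group); computes the `same_chromosome` flag.
#'
#' @param sets `ParalogSets`. @param loci `GeneLoci` covering all members.
#' @return `ParalogSets` with added columns chromosomes (";"-joined),
#'   all_on_chromosomes (all TRUE by construction) and same_chromosome.
#' @export
chromosome_filter <- function(sets, loci) {
  mem <- set_members(sets)
  miss <- setdiff(unlist(mem), loci$gene_id)
  if (length(miss))
    stop("no locus for gene(s): ", paste(miss, collapse = ", "))
  keep <- logical(nrow(sets))
  chroms <- character(nrow(sets))
  same <- logical(nrow(sets))
  for (i in seq_len(nrow(sets))) {
    l <- loci[mem[[i]], , drop = FALSE]
    keep[i] <- all(l$is_chromosome)
    chroms[i] <- paste(l$sequence_id, collapse = ";")
    same[i] <- length(unique(l$sequence_id)) == 1
  }
  out <- sets[keep, , drop = FALSE]
  out$chromosomes <- chroms[keep]
  out$all_on_chromosomes <- TRUE
  out$same_chromosome <- same[keep]
  rownames(out) <- NULL
  class(out) <- c("ParalogSets", "data.frame")
  out
}

#' Find all paralogue sets for a bundle
#'
#' Tree-based species-overlap mapping where gene trees exist, copy-number
#' fallback where they do not; set IDs are renumbered over the combined
#' result.
#'
#' @param bundle `OrthologyBundle`.
#' @param min_ingroup_species passed to [copy_number_fallback()].
#' @return list with `events` and `sets`.
#' @export
find_paralog_sets <- function(bundle, min_ingroup_species = 2) {
  events <- map_duplications(bundle)
  tree_sets <- extract_paralog_sets(events, bundle)
  fb_sets <- copy_number_fallback(bundle, min_ingroup_species)
  combined <- rbind(as.data.frame(tree_sets), as.data.frame(fb_sets))
  combined <- combined[order(combined$orthogroup_id), , drop = FALSE]
  sets <- finish_sets(split(combined, seq_len(nrow(combined))))
  list(events = events, sets = sets)
}
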