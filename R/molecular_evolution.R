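# Pairwise coding-sequence divergence: reciprocal-best-hit homolog
# pairing on global protein alignment scores, codon alignment by
# back-translation of the protein alignment, and dN/dS by NG86 codon
# counting with Jukes-Cantor correction.
#
# Site convention (NG86): at each codon position the synonymous site
# fraction is (# synonymous single-nucleotide changes)/3; changes to stop
# codons count as nonsynonymous, so S + N = 3 per codon exactly.

.ng86_cache <- new.env(parent = emptyenv())

genetic_code_table <- function(id = "1") {
  key <- paste0("code_", id)
  if (is.null(.ng86_cache[[key]])) {
    code <- Biostrings::getGeneticCode(id)
    .ng86_cache[[key]] <- code
  }
  .ng86_cache[[key]]
}

# per-codon synonymous site count (sum over the 3 positions of the
# synonymous fraction among the 3 single-nucleotide alternatives)
codon_syn_sites <- function(codon, code = genetic_code_table()) {
  key <- paste0("syn_", codon)
  if (!is.null(.ng86_cache[[key]])) return(.ng86_cache[[key]])
  bases <- c("A", "C", "G", "T")
  aa <- code[[codon]]
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(bases, substr(codon, p, p))) {
      alt <- codon
      substr(alt, p, p) <- b
      if (code[[alt]] == aa) s <- s + 1 / 3
    }
  }
  .ng86_cache[[key]] <- s
  s
}

# average synonymous/nonsynonymous difference counts between two codons
# over all minimal mutational pathways; pathways passing through a stop
# codon are excluded (unless all are blocked, in which case all pathways
# are used)
codon_diff_counts <- function(a, b, code = genetic_code_table()) {
  if (a == b) return(c(syn = 0, nonsyn = 0))
  key <- paste0("diff_", a, "_", b)
  if (!is.null(.ng86_cache[[key]])) return(.ng86_cache[[key]])
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  perms <- if (length(pos) == 1) list(pos) else
    apply(permutations_of(length(pos)), 1,
          function(ix) pos[ix], simplify = FALSE)
  paths <- list()
  for (ord in perms) {
    cur <- a; syn <- 0; nonsyn <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (code[[nxt]] == "*") { blocked <- TRUE; break }
      if (code[[nxt]] == code[[cur]]) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    paths[[length(paths) + 1L]] <- c(syn = syn, nonsyn = nonsyn,
                                     blocked = blocked)
  }
  pm <- do.call(rbind, paths)
  use <- pm[, "blocked"] == 0
  if (!any(use)) use <- rep(TRUE, nrow(pm))  # all pathways hit a stop
  res <- c(syn = mean(pm[use, "syn"]), nonsyn = mean(pm[use, "nonsyn"]))
  .ng86_cache[[key]] <- res
  res
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- permutations_of(n - 1)
    rest <- matrix(seq_len(n)[-i][rest], nrow(rest), n - 1)
    out <- rbind(out, cbind(i, rest))
  }
  unname(out)
}

split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# translate a CDS: trims to a codon multiple and strips one trailing stop;
# returns NA if an internal stop remains
translate_cds <- function(seq, code = genetic_code_table()) {
  seq <- toupper(seq)
  seq <- substr(seq, 1, (nchar(seq) %/% 3L) * 3L)
  cods <- split_codons(seq)
  aa <- vapply(cods, function(cd) {
    if (grepl("[^ACGT]", cd)) "X" else code[[cd]]
  }, character(1), USE.NAMES = FALSE)
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (any(aa == "*")) return(NA_character_)
  paste(aa, collapse = "")
}

protein_align_score <- function(prot_a, prot_b, matrix = "BLOSUM62",
                                gap_open = 11, gap_extend = 1) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(prot_a), Biostrings::AAString(prot_b),
    type = "global", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE)
}

#' Reciprocal-best-hit homolog pairing
#'
#' Scores every cross-species sequence pair by global protein alignment
#' (translated CDS; default BLOSUM62, gap open 11 / extend 1) and keeps
#' pairs that are mutual best hits with score >= `min_score`. Sequences
#' with internal stop codons are excluded with a warning; ties for best
#' hit drop the pair (logged via warning).
#'
#' @param cds_a,cds_b named character vectors of CDS (from [read_cds()]).
#' @param matrix substitution matrix name. @param gap_open,gap_extend
#'   affine gap penalties. @param min_score minimum score to keep a pair.
#' @return data.frame of class `RbhPairs`: gene_a, gene_b, score.
#' @export
rbh <- function(cds_a, cds_b, matrix = "BLOSUM62", gap_open = 11,
                gap_extend = 1, min_score = 50) {
  stopifnot(length(cds_a) > 0, length(cds_b) > 0)
  prot_a <- vapply(cds_a, translate_cds, character(1))
  prot_b <- vapply(cds_b, translate_cds, character(1))
  bad_a <- names(prot_a)[is.na(prot_a)]
  bad_b <- names(prot_b)[is.na(prot_b)]
  if (length(c(bad_a, bad_b)))
    warning("excluded untranslatable sequence(s): ",
            paste(c(bad_a, bad_b), collapse = ", "))
  prot_a <- prot_a[!is.na(prot_a)]
  prot_b <- prot_b[!is.na(prot_b)]
  if (!length(prot_a) || !length(prot_b))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0)))
  scores <- matrix(NA_real_, length(prot_a), length(prot_b),
                   dimnames = list(names(prot_a), names(prot_b)))
  for (j in seq_along(prot_b))
    scores[, j] <- protein_align_score(unname(prot_a), prot_b[[j]],
                                       matrix, gap_open, gap_extend)
  best_b_for_a <- apply(scores, 1, best_unique)
  best_a_for_b <- apply(scores, 2, best_unique)
  rows <- list()
  for (i in seq_along(prot_a)) {
    j <- best_b_for_a[i]
    if (is.na(j)) next
    if (is.na(best_a_for_b[j]) || best_a_for_b[j] != i) next
    if (scores[i, j] < min_score) next
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = names(prot_a)[i], gene_b = names(prot_b)[j],
      score = scores[i, j], stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(0), gene_b = character(0),
               score = numeric(0))
  class(out) <- c("RbhPairs", "data.frame")
  out
}

# index of the unique maximum, NA on ties
best_unique <- function(v) {
  m <- max(v)
  ix <- which(v == m)
  if (length(ix) != 1) NA_integer_ else ix
}

#' Codon alignment of a homologous CDS pair
#'
#' Translates both sequences (frame-trimmed, terminal stop stripped),
#' aligns the proteins globally and back-translates the alignment to
#' codon columns. Columns opposite a gap, containing an ambiguous base,
#' or containing a stop codon are dropped and counted.
#'
#' @param seq_a,seq_b nucleotide CDS strings (length >= 3).
#' @param matrix,gap_open,gap_extend protein alignment parameters.
#' @return list of class `CodonAlignment`: codons_a, codons_b (equal
#'   length character vectors of sense codons), dropped (named counts:
#'   gap, ambiguous, stop).
#' @export
codon_align <- function(seq_a, seq_b, matrix = "BLOSUM62", gap_open = 11,
                        gap_extend = 1) {
  stopifnot(nchar(seq_a) >= 3, nchar(seq_b) >= 3)
  code <- genetic_code_table()
  prep <- function(seq) {
    seq <- toupper(seq)
    seq <- substr(seq, 1, (nchar(seq) %/% 3L) * 3L)
    cods <- split_codons(seq)
    aa <- vapply(cods, function(cd) {
      if (grepl("[^ACGT]", cd)) "X"
      else code[[cd]]
    }, character(1), USE.NAMES = FALSE)
    # strip one terminal stop; internal stops stay and are dropped later
    if (length(aa) && aa[length(aa)] == "*") {
      aa <- aa[-length(aa)]; cods <- cods[-length(cods)]
    }
    aa[aa == "*"] <- "X"  # align internal stops as unknowns, drop below
    list(codons = cods, prot = paste(aa, collapse = ""))
  }
  pa <- prep(seq_a); pb <- prep(seq_b)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa$prot), Biostrings::AAString(pb$prot),
    type = "global", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  row_a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  row_b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- 0L; ib <- 0L
  keep_a <- character(0); keep_b <- character(0)
  dropped <- c(gap = 0L, ambiguous = 0L, stop = 0L)
  for (k in seq_along(row_a)) {
    ga <- row_a[k] == "-"; gb <- row_b[k] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (ga || gb) { dropped[["gap"]] <- dropped[["gap"]] + 1L; next }
    ca <- pa$codons[ia]; cb <- pb$codons[ib]
    if (grepl("[^ACGT]", ca) || grepl("[^ACGT]", cb)) {
      dropped[["ambiguous"]] <- dropped[["ambiguous"]] + 1L; next
    }
    if (code[[ca]] == "*" || code[[cb]] == "*") {
      dropped[["stop"]] <- dropped[["stop"]] + 1L; next
    }
    keep_a <- c(keep_a, ca); keep_b <- c(keep_b, cb)
  }
  if (!length(keep_a)) stop("zero retained codon columns")
  structure(list(codons_a = keep_a, codons_b = keep_b, dropped = dropped),
            class = "CodonAlignment")
}

#' NG86 dN/dS from a codon alignment
#'
#' Synonymous (S) and nonsynonymous (N) site counts are averaged over the
#' two sequences; multi-position codon differences are averaged over all
#' minimal mutational pathways not passing through stop codons. Proportions
#' are Jukes-Cantor corrected: `d = -3/4 * log(1 - 4/3 * p)`. Validity:
#' `dS_zero` when no synonymous difference was observed (omega undefined),
#' `saturated` when `4/3 * p >= 1` for either class, `ok` otherwise.
#'
#' @param aln a `CodonAlignment`.
#' @return list of class `DndsRecord`: S, N, Sd, Nd, pS, pN, dS, dN,
#'   omega, n_codons, validity.
#' @export
ng86 <- function(aln) {
  stopifnot(inherits(aln, "CodonAlignment"))
  code <- genetic_code_table()
  L <- length(aln$codons_a)
  sa <- vapply(aln$codons_a, codon_syn_sites, numeric(1), code = code)
  sb <- vapply(aln$codons_b, codon_syn_sites, numeric(1), code = code)
  S <- (sum(sa) + sum(sb)) / 2
  N <- 3 * L - S
  Sd <- 0; Nd <- 0
  for (i in seq_len(L)) {
    d <- codon_diff_counts(aln$codons_a[i], aln$codons_b[i], code)
    Sd <- Sd + d[["syn"]]; Nd <- Nd + d[["nonsyn"]]
  }
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  sat_S <- 4 / 3 * pS >= 1
  sat_N <- 4 / 3 * pN >= 1
  dS <- if (sat_S) NA_real_ else -3 / 4 * log(1 - 4 / 3 * pS)
  dN <- if (sat_N) NA_real_ else -3 / 4 * log(1 - 4 / 3 * pN)
  validity <- if (sat_S || sat_N) "saturated"
  else if (Sd == 0) "dS_zero"
  else "ok"
  omega <- if (validity == "ok") dN / dS else NA_real_
  structure(list(S = S, N = N, Sd = unname(Sd), Nd = unname(Nd),
                 pS = pS, pN = pN, dS = dS, dN = dN, omega = omega,
                 n_codons = L, validity = validity),
            class = "DndsRecord")
}

#' @export
print.DndsRecord <- function(x, ...) {
  cat(sprintf(
    "NG86: %d codons; S=%.2f N=%.2f Sd=%.2f Nd=%.2f dS=%.4f dN=%.4f omega=%s [%s]\n",
    x$n_codons, x$S, x$N, x$Sd, x$Nd,
    ifelse(is.na(x$dS), NaN, x$dS), ifelse(is.na(x$dN), NaN, x$dN),
    ifelse(is.na(x$omega), "NA", sprintf("%.3f", x$omega)), x$validity))
  invisible(x)
}

#' dN/dS for a batch of homologous pairs
#'
#' Runs [codon_align()] + [ng86()] per pair; per-pair failures become
#' flagged rows (`validity = "error"`) and never abort the batch.
#'
#' @param pairs data.frame with gene_a, gene_b (e.g. from [rbh()]).
#' @param cds_a,cds_b named CDS maps.
#' @param ... passed to [codon_align()].
#' @return data.frame of class `DndsTable`, one row per pair, with
#'   attribute `median_omega` (median over valid records).
#' @export
batch_dnds <- function(pairs, cds_a, cds_b, ...) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    rec <- tryCatch(ng86(codon_align(cds_a[[a]], cds_b[[b]], ...)),
                    error = function(e) NULL)
    if (is.null(rec))
      return(data.frame(gene_a = a, gene_b = b, S = NA, N = NA, Sd = NA,
                        Nd = NA, pS = NA, pN = NA, dS = NA, dN = NA,
                        omega = NA, n_codons = 0L, validity = "error",
                        stringsAsFactors = FALSE))
    data.frame(gene_a = a, gene_b = b, S = rec$S, N = rec$N, Sd = rec$Sd,
               Nd = rec$Nd, pS = rec$pS, pN = rec$pN, dS = rec$dS,
               dN = rec$dN, omega = rec$omega, n_codons = rec$n_codons,
               validity = rec$validity, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "median_omega") <-
    stats::median(out$omega[out$validity == "ok"], na.rm = TRUE)
  class(out) <- c("DndsTable", "data.frame")
  out
}
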