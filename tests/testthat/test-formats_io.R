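test_that("read_counts validates and round-trips", {
  m <- read_counts(counts_file())
  expect_s3_class(m, "ExpressionMatrix")
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(unname(m$counts["g2", "s3"]), 7)

  # round trip byte-identical modulo line endings
  out <- tempfile(fileext = ".tsv")
  write_counts(m, out)
  m2 <- read_counts(out)
  expect_identical(m$counts, m2$counts)

  # negative cell rejected with location
  bad <- write_tmp(c("gene_id\ts1\ts2", "g1\t3\t-1"))
  expect_error(read_counts(bad), "g1.*s2")
  # non-integer cell rejected
  bad2 <- write_tmp(c("gene_id\ts1", "g1\t2.5"))
  expect_error(read_counts(bad2), "non-integer")
  # duplicate gene IDs rejected; empty file rejected
  dup <- write_tmp(c("gene_id\ts1", "g1\t1", "g1\t2"))
  expect_error(read_counts(dup), "duplicate")
  expect_error(read_counts(write_tmp(character(0))), "empty|parse")
})

test_that("read_design enforces declared factor levels", {
  ok <- write_tmp(c("sample_id\ttissue\tmorph\tstage\tcondition",
                    "s1\tbrain\tqueen\tI\tinseminated",
                    "s2\tRT\tworker\tIV\tnoninseminated",
                    "s3\tovary\tqueen\tII\tinseminated",
                    "s4\tfat_body\tworker\tI\tnoninseminated"))
  d <- read_design(ok)
  expect_equal(nrow(d), 4)
  expect_s3_class(d$tissue, "factor")

  drone <- write_tmp(c("sample_id\ttissue\tmorph\tstage\tcondition",
                       "s1\tbrain\tdrone\tI\tinseminated"))
  expect_error(read_design(drone), "unknown morph")
  dup <- write_tmp(c("sample_id\ttissue\tmorph\tstage\tcondition",
                     "s1\tbrain\tqueen\tI\tinseminated",
                     "s1\tbrain\tworker\tI\tinseminated"))
  expect_error(read_design(dup), "duplicated sample_id")
  # join check against the matrix
  m <- read_counts(counts_file())
  expect_error(check_design_matrix(m, d, exact = TRUE),
               "missing from matrix")
  # the matrix samples themselves are uncovered too
  expect_error(check_design_matrix(m, d[0, ]), "missing from design")
})

test_that("read_gff_loci consumes gene rows and flags chromosomes", {
  gff <- write_tmp(c(
    "##gff-version 3",
    "NC_1\tsrc\tgene\t100\t900\t.\t+\t.\tID=geneA",
    "NC_1\tsrc\tmRNA\t100\t900\t.\t+\t.\tID=rnaA;Parent=geneA",
    "scaffold_7\tsrc\tgene\t5\t50\t.\t-\t.\tID=geneB",
    "NC_2\tsrc\tgene\t7\t7\t.\t+\t.\tID=gene1bp"), ext = ".gff3")
  loci <- read_gff_loci(gff, chromosome_ids = c("NC_1", "NC_2"))
  expect_equal(nrow(loci), 3)  # mRNA ignored
  expect_true(loci["geneA", "is_chromosome"])
  expect_false(loci["geneB", "is_chromosome"])
  # 1-based inclusive: a 1 bp gene has start == end, length 1
  expect_equal(loci["gene1bp", "end"] - loci["gene1bp", "start"] + 1, 1)

  bad <- write_tmp(c("##gff-version 3",
                     "NC_1\tsrc\tgene\t900\t100\t.\t+\t.\tID=geneX"),
                   ext = ".gff3")
  expect_error(read_gff_loci(bad, "NC_1"), "start > end")
})

test_that("orthology bundle validation", {
  og <- write_tmp(c("Orthogroup\tB1\tB2\tOUT",
                    "OG1\tg1, g2\tg3\tg4"))
  sp <- write_tmp("((B1,B2)Ingroup,OUT)Root;", ext = ".nwk")
  b <- read_orthology(og, sp, NULL, ingroup_node = "Ingroup",
                      focal = "B1")
  expect_equal(length(b$groups), 1)
  expect_equal(b$groups$OG1$B1, c("g1", "g2"))
  expect_equal(b$treeless, "OG1")  # no gene tree supplied -> flagged

  # leaf species not in species tree
  gt <- nwk("((B1|a,speciesX|b),OUT|c);")
  expect_error(toy_bundle(list(OG1 = gt)), "speciesX")
  # focal outside ingroup
  expect_error(
    orthology_bundle(list(), ape::read.tree(text = "((B1,B2)Ingroup,OUT)Root;"),
                     list(), "Ingroup", focal = "OUT"),
    "not inside the ingroup")
  # ingroup label must exist
  expect_error(
    orthology_bundle(list(), ape::read.tree(text = "((B1,B2)N,OUT)Root;"),
                     list(), "Ingroup", focal = "B1"),
    "not a labelled internal node")
})

test_that("read_cds validates FASTA and flags frame problems", {
  fa <- write_tmp(c(">a desc", "atgaaatTT", ">b", "ATGAAAATTG"),
                  ext = ".fasta")
  expect_warning(seqs <- read_cds(fa), "divisible by 3")
  expect_equal(length(seqs), 2)
  expect_equal(unname(seqs[["a"]]), "ATGAAATTT")  # uppercased
  expect_equal(attr(seqs, "frame_warning"), "b")

  dup <- write_tmp(c(">x", "ATG", ">x", "AAA"), ext = ".fasta")
  expect_error(read_cds(dup), "duplicate")
})

test_that("gzip input is accepted by the TSV readers", {
  gz <- tempfile(fileext = ".tsv.gz")
  con <- gzfile(gz, "w")
  writeLines(c("gene_id\ts1\ts2", "g1\t1\t2"), con)
  close(con)
  expect_equal(dim(read_counts(gz)), c(1L, 2L))
})
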