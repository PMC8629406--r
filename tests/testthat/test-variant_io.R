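test_that("TSV variant tables round-trip bitwise (AF to 1e-9)", {
  calls <- make_calls("S1", pos = c(100L, 200L, 300L),
                      ref = c("A", "A", "GT"), alt = c("T", "G", "G"),
                      depth = c(200L, 333L, 2500L),
                      alt_reads = c(10L, 7L, 111L),
                      gene = c("TP53", NA, "ATM"),
                      effect = c("non_synonymous", NA, "indel"),
                      callers = c("mutect", "varscan2", "mutect,varscan2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(calls, path)
  back <- read_variant_table(path)
  expect_equal(back$pos, calls$pos)
  expect_equal(back$ref, calls$ref)
  expect_equal(back$af, calls$af, tolerance = 1e-9)
  expect_equal(back$gene, calls$gene)
  expect_equal(back$effect, calls$effect)
  expect_equal(back$callers, calls$callers)
})

test_that("AF is computed from counts when the column is absent", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tchrom\tpos\tref\talt\tdepth\talt_reads",
               "S1\tchr1\t100\tA\tT\t200\t10"), path)
  calls <- read_variant_table(path)
  expect_equal(calls$af, 0.05)
})

test_that("duplicated (sample, locus) records and malformed rows error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tchrom\tpos\tref\talt\tdepth\talt_reads",
               "S1\tchr1\t100\tA\tT\t200\t10",
               "S1\tchr1\t100\tA\tT\t300\t20"), path)
  expect_error(read_variant_table(path), "duplicated")

  writeLines(c("sample_id\tchrom\tpos\tref\talt\tdepth\talt_reads",
               "S1\tchr1\t100\tA\tT\tdeep\t10"), path)
  expect_error(read_variant_table(path), "line 2")

  writeLines(c("sample_id\tchrom\tpos\tref\talt",
               "S1\tchr1\t100\tA\tT"), path)
  expect_error(read_variant_table(path), "depth")
})

test_that("call-table invariants are enforced", {
  expect_error(make_calls("S1", pos = 1L, depth = 10L, alt_reads = 20L),
               "alt_reads exceeds depth")
  expect_error(make_calls("S1", pos = 0L), "pos")
  expect_error(make_calls("S1", pos = 1L, ref = "A", alt = "A"), "differ")
  expect_error(make_calls("S1", pos = 1L, ref = "N", alt = "A"), "A/C/G/T")
  long <- paste(rep("A", 60), collapse = "")
  expect_error(make_calls("S1", pos = 1L, ref = paste0("C", long), alt = "C"),
               "50 bp")
})

test_that("VCF records are read per sample and multi-allelics split", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", sep = "\t"),
    paste("chr1", "100", ".", "A", "T,G", ".", "PASS", ".", "GT:DP:AD",
          "0/1:200:180,15,5", "0/0:150:150,0,0", sep = "\t"),
    paste("chr1", "200", ".", "A", "AT", ".", "PASS", ".", "GT:DP:AD",
          "0/1:100:90,10", "0/1:80:70,10", sep = "\t")), path)
  calls <- read_variant_table(path)
  s1 <- calls[calls$sample_id == "S1", ]
  # multi-allelic split into two calls at pos 100 for S1
  expect_equal(sum(s1$pos == 100L), 2L)
  expect_setequal(s1$alt[s1$pos == 100L], c("T", "G"))
  expect_equal(s1$af[s1$pos == 100L & s1$alt == "T"], 15 / 200)
  # the 1-bp insertion is classifiable as indel
  ins <- s1[s1$pos == 200L, ]
  expect_equal(classify_effect(ins$ref, ins$alt), "indel")
})

test_that("VCF without depth fields errors rather than silently zeroing", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    paste("chr1", "100", ".", "A", "T", ".", "PASS", ".", "GT", "0/1",
          sep = "\t")), path)
  expect_error(read_variant_table(path), "DP/AD")
})

test_that("sample sheets validate roles, sites, stages and blood uniqueness", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "sample_id\tpatient_id\trole\tsite\tstage\thistotype\tgrade\tpt_status",
    "20724-L-OV\t20724\ttumor\tovary\tprimary\tserous\thigh\tsensitive",
    "20724-BL\t20724\tblood\t\t\t\t\t"), path)
  meta <- read_sample_sheet(path)
  expect_equal(nrow(meta), 2L)
  expect_true(is.na(meta$site[meta$role == "blood"]))

  writeLines(c("sample_id\tpatient_id\trole\tsite\tstage",
               "S1\tP1\ttumor\tovary\tfourth"), path)
  expect_error(read_sample_sheet(path), "stage")

  writeLines(c("sample_id\tpatient_id\trole\tsite\tstage",
               "B1\tP1\tblood\t\t",
               "B2\tP1\tblood\t\t"), path)
  expect_error(read_sample_sheet(path), "blood")

  writeLines(c("sample_id\tpatient_id\trole\tsite\tstage",
               "S1\t\ttumor\tovary\tprimary"), path)
  expect_error(read_sample_sheet(path), "patient")
})

test_that("Newick write/read round-trips trees and labels", {
  tr <- ape::read.tree(text = "(A:1,B:2);")
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  expect_match(readLines(path), "^\\(A:1,B:2\\);$")

  tr2 <- ape::read.tree(
    text = "((20995-STO-2ME:1.5,20995-OV:2.25):0.5,CTRL:10);")
  write_newick(tr2, path)
  back <- read_newick(path)
  expect_setequal(back$tip.label, tr2$tip.label)
  expect_true("20995-STO-2ME" %in% back$tip.label)
  expect_equal(phangorn::RF.dist(ape::unroot(back), ape::unroot(tr2)), 0)
  d0 <- cophenetic(tr2)
  d1 <- cophenetic(back)[rownames(d0), colnames(d0)]
  expect_equal(d1, d0, tolerance = 1e-6)
})

test_that("locus identity is allele-aware by default, site-level on request", {
  a <- make_calls("S1", pos = 100L, ref = "A", alt = "T")
  b <- make_calls("S2", pos = 100L, ref = "A", alt = "G")
  expect_false(locus_key(a) == locus_key(b))
  expect_equal(locus_key(a, "site"), locus_key(b, "site"))
  # equal on all four fields compares equal regardless of sample/caller
  c2 <- make_calls("S3", pos = 100L, ref = "A", alt = "T",
                   callers = "varscan2")
  expect_equal(locus_key(a), locus_key(c2))
})

test_that("gene panels reject overlapping intervals and unmapped genes", {
  expect_error(gene_panel(
    data.frame(chrom = "chr1", start = c(0L, 100L), end = c(200L, 300L),
               gene = "G1"), c(G1 = "P")), "overlap")
  expect_error(gene_panel(
    data.frame(chrom = "chr1", start = 0L, end = 100L, gene = "G1"),
    c(G2 = "P")), "pathway")
  p <- tiny_panel()
  expect_s3_class(p, "gene_panel")
  bed <- withr::local_tempfile(fileext = ".bed")
  pwf <- withr::local_tempfile(fileext = ".tsv")
  write_gene_panel(p, bed, pwf)
  back <- read_gene_panel(bed, pwf)
  expect_equal(back$intervals$start, p$intervals$start)
  expect_equal(back$pathway_of, p$pathway_of)
})
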