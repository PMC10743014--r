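test_that("genotype table round-trips and parses unordered pairs", {
  panel <- atg16l1_panel()
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    paste(c("sample_id", "group", panel$loci$rs_id), collapse = "\t"),
    "S1\tcontrol\tT/C\tT/T\tA/A\tC/C",
    "S2\tpatient\tC/T\t./.\tA/T\tC/T",
    "S3\tcontrol\tC/C\tT/C\t\tT/T"), tsv)
  cc <- read_genotype_table(tsv, panel)
  expect_s3_class(cc, "cohort")
  # S1 heterozygous at rs1816753 only
  expect_equal(unname(cc$a1["S1", ]), c("C", "T", "A", "C"))
  expect_equal(unname(cc$a2["S1", ]), c("T", "T", "A", "C"))
  # "C/T" and "T/C" are the same unordered genotype
  expect_equal(cc$a1["S1", "rs1816753"], cc$a1["S2", "rs1816753"])
  expect_equal(cc$a2["S1", "rs1816753"], cc$a2["S2", "rs1816753"])
  # "./." and empty cells are missing
  expect_true(is.na(cc$a1["S2", "rs12476635"]))
  expect_true(is.na(cc$a1["S3", "rs74599577"]))
  # write-then-read reproduces every cell
  out <- tempfile(fileext = ".tsv")
  write_genotype_table(cc, out)
  cc2 <- read_genotype_table(out, panel)
  expect_identical(cc$a1, cc2$a1)
  expect_identical(cc$a2, cc2$a2)
  expect_identical(cc$group, cc2$group)
})

test_that("genotype table errors name the offending column or sample", {
  panel <- atg16l1_panel()
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgroup\trs1816753",
               "S1\tcontrol\tT/C"), tsv)
  expect_error(read_genotype_table(tsv, panel), "rs12476635")
  tsv2 <- tempfile(fileext = ".tsv")
  writeLines(c(
    paste(c("sample_id", "group", panel$loci$rs_id), collapse = "\t"),
    "S1\tcontrol\tT/G\tT/T\tA/A\tC/C"), tsv2)
  expect_error(read_genotype_table(tsv2, panel), "S1.*rs1816753")
})

test_that("cohort group sizes follow the file", {
  spec <- promoter_cohort_spec("ATG16L1")
  cc <- generate_cohort(spec, seed = 3)
  tsv <- tempfile(fileext = ".tsv")
  write_genotype_table(cc, tsv)
  back <- read_genotype_table(tsv, spec$panel)
  expect_equal(sum(back$group == "control"), 28)
  expect_equal(sum(back$group == "patient"), 56)
})

test_that("allele tallies equal twice the non-missing individuals", {
  spec <- promoter_cohort_spec("ATG16L1", missing_rate = 0.1)
  cc <- generate_cohort(spec, seed = 5)
  for (rs in cc$panel$loci$rs_id) {
    af <- allele_freqs(cc, rs)
    j <- match(rs, cc$panel$loci$rs_id)
    n_ok <- sum(!is.na(cc$a1[, j]))
    expect_equal(sum(af$count), 2 * n_ok)
  }
})

test_that("VCF records decode genotypes, missingness and phase-dropping", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "2\t233250963\trs1816753\tT\tC\t.\tPASS\t.\tGT\t0/1\t1|1\t./.",
    "2\t233251563\trs77820970\tC\tT\t.\tPASS\t.\tGT\t0/0\t0|1\t1/1"),
    vcf)
  cc <- read_vcf(vcf, c(S1 = "control", S2 = "patient", S3 = "patient"))
  expect_equal(unname(cc$a1[, "rs1816753"]), c("C", "C", NA))
  expect_equal(unname(cc$a2[, "rs1816753"]), c("T", "C", NA))
  expect_equal(unname(cc$a1["S3", "rs77820970"]), "T")
  expect_equal(unname(cc$a2["S2", "rs77820970"]), "T")
  expect_error(read_vcf(vcf, c(S1 = "control", S2 = "patient")),
               "S3")
})

test_that("multi-allelic VCF records are skipped with a warning", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t100\trs1\tA\tG,T\t.\tPASS\t.\tGT\t0/1",
    "1\t200\trs2\tA\tG\t.\tPASS\t.\tGT\t0/1"), vcf)
  expect_warning(cc <- read_vcf(vcf, c(S1 = "control")), "skipped")
  expect_equal(n_loci(cc$panel), 1)
})

test_that("VCF and TSV readers agree on equivalent content", {
  spec <- promoter_cohort_spec("ATG16L1")
  cc <- generate_cohort(spec, seed = 8)
  tsv <- tempfile(fileext = ".tsv")
  write_genotype_table(cc, tsv)
  from_tsv <- read_genotype_table(tsv, spec$panel)
  # express the same cohort as VCF
  panel <- spec$panel
  gt <- sapply(seq_len(n_loci(panel)), function(j) {
    alt <- panel$loci$alt[j]
    code1 <- as.integer(cc$a1[, j] == alt)
    code2 <- as.integer(cc$a2[, j] == alt)
    paste0(code1, "/", code2)
  })
  vcf <- tempfile(fileext = ".vcf")
  body <- sapply(seq_len(n_loci(panel)), function(j)
    paste(c(panel$loci$chrom[j], panel$loci$position[j],
            panel$loci$rs_id[j], panel$loci$ref[j], panel$loci$alt[j],
            ".", "PASS", ".", "GT", gt[, j]), collapse = "\t"))
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", cc$sample_id), collapse = "\t"),
    body), vcf)
  from_vcf <- read_vcf(vcf, stats::setNames(cc$group, cc$sample_id),
                       offsets = panel$loci$offset)
  expect_identical(from_tsv$a1, from_vcf$a1)
  expect_identical(from_tsv$a2, from_vcf$a2)
  expect_identical(from_tsv$group, from_vcf$group)
})

test_that("IUPAC encoding covers homozygotes and ambiguity codes", {
  expect_equal(encode_iupac("C", "T"), "Y")
  expect_equal(encode_iupac("T", "C"), "Y")
  expect_equal(encode_iupac("A", "G"), "R")
  expect_equal(encode_iupac("T", "T"), "T")
  expect_equal(encode_iupac(c("A", "G"), c("C", "T")), c("M", "K"))
  expect_error(encode_iupac("A", "N"), "A,C,G,T")
})

test_that("JASPAR PFM parsing validates shape and round-trips", {
  path <- tempfile(fileext = ".pfm")
  writeLines(c(">MA0000.1 TESTTF",
               "A  [ 10  2  0  4  1 ]",
               "C  [  0  8  1  2  0 ]",
               "G  [  1  0 11  3  2 ]",
               "T  [  2  3  0  4 10 ]"), path)
  m <- read_jaspar_pfm(path)
  expect_s3_class(m, "pfm")
  expect_equal(motif_length(m), 5)
  expect_equal(m$tf_name, "MA0000.1 TESTTF")
  out <- tempfile(fileext = ".pfm")
  write_jaspar_pfm(m, out)
  m2 <- read_jaspar_pfm(out)
  expect_equal(m2$counts, m$counts)
  # all-zero column rejected
  expect_error(pfm(rbind(c(1, 0), c(0, 0), c(0, 0), c(1, 0))),
               "all-zero")
  # wrong row count rejected
  bad <- tempfile(fileext = ".pfm")
  writeLines(c("A 1 2", "C 1 2", "G 1 2"), bad)
  expect_error(read_jaspar_pfm(bad), "4 count rows")
})

test_that("locus panel enforces its invariants", {
  expect_error(locus_panel("x", data.frame(
    rs_id = "rs1", chrom = "1", position = 1L, ref = "A", alt = "A",
    offset = 1L), c(0L, 0L)), "differ")
  expect_error(locus_panel("x", data.frame(
    rs_id = c("rs1", "rs1"), chrom = "1", position = c(1L, 2L),
    ref = "A", alt = "G", offset = c(1L, 2L)), c(0L, 0L)),
    "duplicate")
  expect_equal(n_loci(atg16l1_panel()), 4)
  expect_equal(n_loci(atg5_panel()), 2)
})
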