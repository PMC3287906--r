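test_that("TSV genotypes round-trip through write and read", {
  geno <- codes_matrix(c(0, 1, 2, 2, 1, 0, 0, 0, 2), 3, 3,
                       subjects = c("a", "b", "c"))
  path <- tempfile(fileext = ".tsv")
  write_genotypes(geno, path)
  back <- read_genotypes(path, "tsv")
  expect_identical(unname(back$codes), unname(geno$codes))
  expect_identical(back$subjects, geno$subjects)
  expect_identical(back$snps$id, geno$snps$id)
})

test_that("VCF and TSV encodings of the same data agree; missing GT maps to NA", {
  codes <- matrix(c(0, 1, 2, NA, 1, 0, 2, 2), 4, 2)
  geno <- genotype_matrix(codes, subjects = paste0("s", 1:4))
  vcf_path <- tempfile(fileext = ".vcf")
  tsv_path <- tempfile(fileext = ".tsv")
  write_genotypes(geno, vcf_path, "vcf")
  write_genotypes(geno, tsv_path, "tsv")
  from_vcf <- read_genotypes(vcf_path, "vcf")
  from_tsv <- read_genotypes(tsv_path, "tsv")
  expect_equal(unname(from_vcf$codes), unname(from_tsv$codes))
  expect_identical(from_vcf$subjects, from_tsv$subjects)
  expect_true(is.na(from_vcf$codes[4, 1]))
})

test_that("multiallelic VCF sites are skipped with a warning", {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    paste("1", "100", "rs1", "A", "C", ".", "PASS", ".", "GT",
          "0/1", "1/1", sep = "\t"),
    paste("1", "200", "rs2", "A", "C,G", ".", "PASS", ".", "GT",
          "0/1", "0/2", sep = "\t"))
  path <- write_tsv_fixture(lines, tempfile(fileext = ".vcf"))
  expect_warning(g <- read_genotypes(path, "vcf"), "multiallelic")
  expect_equal(ncol(g$codes), 1)
  expect_equal(unname(g$codes[, 1]), c(1, 2))
})

test_that("PLINK text counts the declared reference allele", {
  base <- tempfile()
  writeLines("1\trs1\t0\t500", paste0(base, ".map"))
  writeLines(c("F1 i1 0 0 1 -9 A A",
               "F2 i2 0 0 1 -9 A G",
               "F3 i3 0 0 2 -9 G G",
               "F4 i4 0 0 2 -9 0 0"), paste0(base, ".ped"))
  g <- read_genotypes(paste0(base, ".ped"), "plink_text",
                      ref_alleles = c(rs1 = "G"))
  # hand count of G copies: AA=0, AG=1, GG=2, missing
  expect_equal(unname(g$codes[, 1]), c(0, 1, 2, NA))
  # default convention: lexicographically later allele (G) — same here
  g2 <- read_genotypes(paste0(base, ".ped"), "plink_text")
  expect_equal(unname(g2$codes[, 1]), c(0, 1, 2, NA))
  expect_equal(unname(g2$metadata$counted_allele["rs1"]), "G")
})

test_that("SNP columns are ordered by chromosome and position", {
  codes <- matrix(c(0, 1, 1, 2, 2, 0), 2, 3)
  snps <- data.frame(id = c("c", "a", "b"), chrom = c(2, 1, 1),
                     pos = c(10, 500, 20))
  g <- genotype_matrix(codes, subjects = c("x", "y"), snps = snps)
  expect_identical(g$snps$id, c("b", "a", "c"))
  expect_equal(unname(g$codes[1, ]), c(2, 1, 0))
})

test_that("invalid genotype codes are rejected", {
  expect_error(codes_matrix(c(0, 1, 3, 2), 2, 2), "0, 1, 2")
})

test_that("phenotype reading expands categoricals and validates schema", {
  path <- write_tsv_fixture(c(
    "subject\ttrait\tage\tgroup",
    paste(paste0("s", 1:7), rnorm(7), 30 + 1:7,
          paste0("g", 1:7), sep = "\t")))
  ph <- read_phenotypes(path)
  # 7-level group -> 6 indicator columns (lexicographic reference g1)
  expect_equal(sum(grepl("^group_", names(ph$covariates))), 6)
  expect_false("group_g1" %in% names(ph$covariates))
  expect_true(all(vapply(ph$covariates, is.numeric, logical(1))))

  path2 <- write_tsv_fixture(c("subject\ttrait", "s1\t1.5", "s2\t-0.5"))
  ph2 <- read_phenotypes(path2)
  expect_equal(ncol(ph2$covariates), 0)

  dup <- write_tsv_fixture(c("subject\ttrait", "s1\t1", "s1\t2"))
  expect_error(read_phenotypes(dup), "duplicate")

  noto <- write_tsv_fixture(c("subject\tvalue", "s1\t1", "s2\t2"))
  expect_error(read_phenotypes(noto), "trait")
})

test_that("association reports are written with blanks for unselected models", {
  tab <- data.frame(snp = paste0("rs", 1:5), chromosome = 1,
                    position = 1:5 * 100, gene = NA,
                    univariate_estimate = runif(5), univariate_p = runif(5),
                    smcp_estimate = runif(5), smcp_loo_p = runif(5),
                    lasso_estimate = c(NA, NA, 0.1, 0.13, NA),
                    lasso_loo_p = c(NA, NA, 0.01, 0.02, NA))
  rep <- association_report(tab, metadata = list(eta = 0.1, seed = 3))
  path <- tempfile(fileext = ".tsv")
  write_report(rep, path)
  lines <- readLines(path)
  expect_length(lines, 6)   # header + 5 rows
  cells <- strsplit(lines[2], "\t")[[1]]
  expect_identical(cells[9], "")   # SNP not selected by LASSO: blank
  expect_true(file.exists(paste0(path, ".meta.json")))
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  expect_equal(meta$eta, 0.1)

  empty <- association_report(tab[0, ])
  path2 <- tempfile(fileext = ".tsv")
  write_report(empty, path2)
  expect_length(readLines(path2), 1)

  bad <- tab; bad$univariate_p[1] <- 1.5
  expect_error(association_report(bad), "\\[0, 1\\]")
})
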