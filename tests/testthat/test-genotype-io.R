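test_that("call normalization handles all accepted encodings and is idempotent", {
  expect_equal(normalize_calls("AA"), "AA")
  expect_equal(normalize_calls("A/T"), "AT")
  expect_equal(normalize_calls("A|T"), "AT")
  # IUPAC ambiguity codes for the six heterozygotes
  expect_equal(normalize_calls(c("R", "Y", "S", "W", "K", "M")),
               c("AG", "CT", "CG", "AT", "GT", "AC"))
  expect_equal(normalize_calls("A"), "AA")      # single-letter homozygote
  expect_equal(normalize_calls("TA"), "AT")     # allele order irrelevant
  expect_equal(normalize_calls("t/a"), "AT")    # case-insensitive
  expect_true(is.na(normalize_calls("--")))
  expect_true(is.na(normalize_calls("NA")))
  expect_true(is.na(normalize_calls("??", missing_tokens = "??")))
  # idempotence: normalizing canonical output is the identity
  raw <- c("AA", "G/T", "W", "CA", "--")
  once <- normalize_calls(raw)
  expect_equal(normalize_calls(once), once)
  expect_error(normalize_calls("A/TT"), "unparseable")
  expect_error(normalize_calls("Z!"), "unparseable")
})

test_that("genotype matrix construction validates ids and dimensions", {
  calls <- matrix(c("AA", "AG", "GG", "AA"), 2,
                  dimnames = list(c("m1", "m2"), c("i1", "i2")))
  gm <- genotype_matrix(calls)
  expect_s3_class(gm, "genotype_matrix")
  expect_equal(markers(gm), c("m1", "m2"))
  expect_equal(individuals(gm), c("i1", "i2"))
  dup <- calls; rownames(dup) <- c("m1", "m1")
  expect_error(genotype_matrix(dup), "duplicate marker id: m1")
  dup2 <- calls; colnames(dup2) <- c("i1", "i1")
  expect_error(genotype_matrix(dup2), "duplicate individual id: i1")
  # subsetting keeps the class and never drops dimensions
  expect_s3_class(gm[1, ], "genotype_matrix")
  expect_equal(dim(gm[1, 1]), c(1L, 1L))
})

test_that("genotype tables round-trip in both orientations", {
  gm <- toy_trio()
  for (orient in c("markers", "individuals")) {
    path <- withr::local_tempfile(fileext = ".tsv")
    write_genotype_table(gm, path, orientation = orient)
    back <- read_genotype_table(path, orientation = orient)
    expect_equal(unclass(back), unclass(gm))
  }
  # property: random matrices with missing calls round-trip exactly
  set.seed(101)
  for (rep in 1:5) {
    gm <- random_genotype_matrix(30, 8, p_missing = 0.1)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_genotype_table(gm, path)
    expect_equal(unclass(read_genotype_table(path)), unclass(gm))
  }
})

test_that("table reader reports duplicates, ragged rows and bad tokens with coordinates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ti1\ti2", "m1\tAA\tAG", "m1\tGG\tGG"), path)
  expect_error(read_genotype_table(path), "duplicate marker id: m1")
  writeLines(c("id\ti1\ti2", "m1\tAA\tAG", "m2\tGG"), path)
  expect_error(read_genotype_table(path), "ragged row 3")
  writeLines(c("id\ti1\ti2", "m1\tAA\tAG", "m2\tGG\tZ?"), path)
  expect_error(read_genotype_table(path), "row 2, column 2")
  expect_error(read_genotype_table(tempfile()), "file not found")
})

test_that("empty partitions still write valid tables with headers", {
  gm <- toy_trio()
  empty <- gm[integer(0), ]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_table(empty, path)
  expect_equal(readLines(path), "id\tP1\tP2\tO1\tO2")
})

test_that("marker map reader validates shape, uniqueness and positions", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("marker\tchrom\tpos", "m1\t17\t100", "m2\t17\t250",
               "m3\t5\t40"), path)
  map <- read_marker_map(path)
  expect_equal(nrow(map), 3)
  expect_equal(sort(unique(map$chrom)), c("17", "5"))
  writeLines(c("marker\tchrom\tpos", "m1\t17\t100", "m1\t5\t4"), path)
  expect_error(read_marker_map(path), "duplicate marker id")
  writeLines(c("marker\tchrom\tpos", "m1\t17\t-5"), path)
  expect_error(read_marker_map(path), "negative")
})

test_that("phenotype reader enforces complete numeric values", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("individual\tvalue", "L1\t3", "L2\t4.5"), path)
  ph <- read_phenotypes(path)
  expect_identical(ph$value, c(3, 4.5))
  writeLines(c("individual\tvalue", "L1\t3", "L2\tNA"), path)
  expect_error(read_phenotypes(path), "L2")
  writeLines(c("individual\tvalue", "L1\t3", "L1\t4"), path)
  expect_error(read_phenotypes(path), "duplicate individual id")
})

test_that("VCF import resolves GT indices, skips multiallelics, keeps 1-based positions", {
  samples <- c("S1", "S2", "S3")
  rec <- data.frame(
    chrom = c("1", "1", "2"), pos = c("1042", "2000", "77"),
    id = c("snp1", ".", "snp3"),
    ref = c("A", "C", "G"), alt = c("G", "T,A", "T"),
    S1 = c("0/0", "0/0", "0/1"),
    S2 = c("0/1", "1/1", "./."),
    S3 = c("1|1", "0/1", "./1"),
    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, rec, samples)
  expect_warning(res <- import_vcf(path), "1 multiallelic record")
  expect_equal(markers(res$genotypes), c("snp1", "snp3"))
  expect_equal(unname(unclass(res$genotypes)["snp1", ]),
               c("AA", "AG", "GG"))
  # half-missing and fully missing genotypes both coerce to missing
  expect_equal(unname(unclass(res$genotypes)["snp3", ]),
               c("GT", NA, NA))
  expect_equal(res$map$pos, c(1042, 77))
  expect_equal(res$map$chrom, c("1", "2"))
})

test_that("VCF import of a file synthesized from a known matrix recovers it", {
  set.seed(7)
  nuc <- c("A", "C", "G", "T")
  n <- 12; ids <- sprintf("v%02d", 1:n)
  ref <- sample(nuc, n, replace = TRUE)
  alt <- vapply(ref, function(x) sample(setdiff(nuc, x), 1), character(1))
  gt_num <- matrix(sample(c("0/0", "0/1", "1/1", "./."), n * 4, TRUE,
                          prob = c(.4, .2, .3, .1)), n)
  rec <- data.frame(chrom = "1", pos = as.character(seq(100, by = 50,
                    length.out = n)), id = ids, ref = ref, alt = unname(alt),
                    stringsAsFactors = FALSE)
  samples <- sprintf("S%d", 1:4)
  for (j in 1:4) rec[[samples[j]]] <- gt_num[, j]
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, rec, samples)
  res <- import_vcf(path)
  # expected calls derived directly from GT semantics
  expected <- matrix(NA_character_, n, 4, dimnames = list(ids, samples))
  for (i in 1:n) for (j in 1:4) {
    g <- gt_num[i, j]
    if (g == "0/0") expected[i, j] <- paste0(ref[i], ref[i])
    if (g == "1/1") expected[i, j] <- paste0(alt[i], alt[i])
    if (g == "0/1") expected[i, j] <- paste0(min(ref[i], alt[i]),
                                             max(ref[i], alt[i]))
  }
  expect_equal(unclass(res$genotypes), expected)
})
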