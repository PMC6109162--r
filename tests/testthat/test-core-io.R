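test_that("VCF round-trip reproduces dosages and polarization exactly", {
  set.seed(101)
  dos <- matrix(sample(c(0:2, NA), 40, replace = TRUE), nrow = 10)
  colnames(dos) <- paste0("S", 1:4)
  gm <- toy_gm(dos)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  gm2 <- read_vcf(path)
  expect_identical(unname(gm2$dosages), unname(gm$dosages))
  expect_equal(gm2$variants$ancestral_allele, gm$variants$ancestral_allele)
  expect_equal(gm2$variants$derived_allele, gm$variants$derived_allele)
  expect_true(all(gm2$variants$polarized))
})

test_that("polarization flips dosages when the ancestral allele is ALT", {
  # hand-built VCF: REF=A ALT=G with AA=G means derived is REF,
  # so dosage = 2 - ALT count
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"AA\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "1\t100\tv1\tA\tG\t.\tPASS\tAA=A\tGT\t0/1\t1/1",
    "1\t200\tv2\tA\tG\t.\tPASS\tAA=G\tGT\t0/1\t1/1",
    "1\t300\tv3\tA\tG\t.\tPASS\tAA=C\tGT\t0/0\t1/1"), path)
  gm <- read_vcf(path)
  # v1: AA=REF, dosage = ALT count
  expect_equal(unname(gm$dosages["v1", ]), c(1L, 2L))
  # v2: AA=ALT, dosage = 2 - ALT count; derived allele is REF (A)
  expect_equal(unname(gm$dosages["v2", ]), c(1L, 0L))
  expect_equal(gm$variants$derived_allele[2], "A")
  # v3: AA matches neither allele -> unpolarized, ALT-counted
  expect_false(gm$variants$polarized[3])
  expect_equal(unname(gm$dosages["v3", ]), c(0L, 2L))
})

test_that("multi-allelic records are skipped with a warning", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/1",
    "1\t200\tv2\tA\tG,T\t.\tPASS\t.\tGT\t0/2"), path)
  expect_warning(gm <- read_vcf(path), "skipped")
  expect_equal(nrow(gm$variants), 1L)
})

test_that("sample table validation enforces groups, duplicates, emptiness", {
  st <- toy_sample_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(st, path, sep = "\t", quote = FALSE, row.names = FALSE)
  st2 <- read_sample_table(path)
  expect_equal(table(st2$group)[c("Andean", "Amazonian", "Mesoamerican")],
               table(st$group)[c("Andean", "Amazonian", "Mesoamerican")])

  bad <- st; bad$group[1] <- "Altiplano"
  expect_error(as_sample_table(bad), "unknown group")
  dup <- st; dup$sample_id[2] <- dup$sample_id[1]
  expect_error(as_sample_table(dup), "duplicated")
  expect_error(as_sample_table(st[0, ]), "empty")
})

test_that("polymorphism filter keeps SNPs segregating in >= 2 groups", {
  st <- toy_sample_table(4, 4, 4)
  # rows: fixed-derived everywhere / segregating only in Andeans /
  #       segregating in Andeans+Amazonians, fixed in Mesoamericans /
  #       segregating everywhere
  dos <- rbind(
    rep(2L, 12),
    c(1L, 1L, 0L, 0L, rep(0L, 8)),
    c(1L, 0L, 1L, 0L, 1L, 1L, 0L, 0L, rep(2L, 4)),
    rep(c(0L, 1L), 6))
  colnames(dos) <- st$sample_id
  gm <- toy_gm(dos)
  kept <- filter_polymorphic(gm, st)
  expect_equal(kept$variants$id, c("rs003", "rs004"))
  # idempotence
  again <- filter_polymorphic(kept, st)
  expect_identical(again$dosages, kept$dosages)
})

test_that("allele counts handle missing data and sum over groups", {
  st <- toy_sample_table(3, 3, 3)
  dos <- matrix(sample(c(0:2, NA), 9 * 5, replace = TRUE,
                       prob = c(.3, .3, .3, .1)), nrow = 5)
  colnames(dos) <- st$sample_id
  gm <- toy_gm(dos)
  ac <- allele_counts(gm, st, "Andean")
  expect_true(all(ac$chrom_n == 2 * rowSums(!is.na(dos[, 1:3]))))
  expect_true(all(ac$derived >= 0 & ac$derived <= ac$chrom_n))

  # {0,1,2} in three samples -> (3, 6)
  dos2 <- matrix(c(0L, 1L, 2L, rep(0L, 6)), nrow = 1)
  colnames(dos2) <- st$sample_id
  ac2 <- allele_counts(toy_gm(dos2), st, "Andean")
  expect_equal(ac2$derived, 3L)
  expect_equal(ac2$chrom_n, 6L)

  # all-missing SNP flagged with (0, 0)
  dos3 <- matrix(c(NA, NA, NA, rep(0L, 6)), nrow = 1)
  colnames(dos3) <- st$sample_id
  ac3 <- allele_counts(toy_gm(dos3), st, "Andean")
  expect_equal(ac3$derived, 0L)
  expect_equal(ac3$chrom_n, 0L)
  expect_true(ac3$all_missing)

  # group-wise counts sum to the all-sample count
  tot_d <- 0L; tot_m <- 0L
  for (g in c("Andean", "Amazonian", "Mesoamerican")) {
    a <- allele_counts(gm, st, g)
    tot_d <- tot_d + a$derived
    tot_m <- tot_m + a$chrom_n
  }
  expect_equal(tot_d, as.integer(rowSums(gm$dosages, na.rm = TRUE)))
  expect_equal(tot_m, as.integer(2 * rowSums(!is.na(gm$dosages))))
})

test_that("BED intervals are validated, sorted, and 0-based half-open", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("1\t500\t900\tGENE_B", "1\t100\t300\tGENE_A"), path)
  bed <- read_bed(path)
  expect_equal(bed$name, c("GENE_A", "GENE_B"))
  # 1-based position 300 is the last base inside [100, 300)... the interval
  # covers 1-based 101..300
  expect_equal(assign_nearest_gene("1", 300, bed)$distance, 0)
  expect_equal(assign_nearest_gene("1", 100, bed)$gene, "GENE_A")
  expect_equal(assign_nearest_gene("1", 100, bed)$distance, 1)
})
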