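test_that("generation is deterministic under a fixed seed", {
  cfg <- generator_config(n_snps = 100, seed = 7)
  g1 <- generate_neutral_genotypes(cfg)
  g2 <- generate_neutral_genotypes(cfg)
  expect_identical(g1$gm$dosages, g2$gm$dosages)
  h1 <- generate_haplotypes(cfg)
  h2 <- generate_haplotypes(cfg)
  expect_identical(h1$haplotypes$Andean$haplotypes,
                   h2$haplotypes$Andean$haplotypes)
})

test_that("group sizes default to the 63/106/153 study design", {
  g <- generate_neutral_genotypes(generator_config(n_snps = 20, seed = 1))
  tab <- table(g$st$group)
  expect_equal(unname(tab[c("Andean", "Amazonian", "Mesoamerican")]),
               c(63L, 106L, 153L), ignore_attr = TRUE)
})

test_that("zero branch lengths give identical group frequencies (FST ~ 0)", {
  cfg <- generator_config(n_snps = 1500, seed = 9)
  # collapse all drift: splits at time zero
  cfg$model <- demographic_model("constant", t_meso_split_y = 0,
                                 t_and_amaz_split_y = 0)
  g <- generate_neutral_genotypes(cfg)
  expect_equal(g$freqs$Andean, g$freqs$Mesoamerican)
  rec <- pbs_records(filter_polymorphic(g$gm, g$st), g$st)
  # only sampling noise remains; the mean raw FST estimate is ~0
  expect_lt(abs(mean(rec$fst_and_meso, na.rm = TRUE)), 0.005)
})

test_that("hierarchical topology orders the mean pairwise FSTs", {
  # sister groups (Andean, Amazonian) are closer than either is to the
  # outgroup; brute-force means over a sizeable panel
  g <- generate_neutral_genotypes(generator_config(n_snps = 4000, seed = 11))
  rec <- pbs_records(filter_polymorphic(g$gm, g$st), g$st)
  expect_lt(mean(rec$fst_and_amaz, na.rm = TRUE),
            mean(rec$fst_and_meso, na.rm = TRUE))
  expect_lt(mean(rec$fst_and_amaz, na.rm = TRUE),
            mean(rec$fst_meso_amaz, na.rm = TRUE))
})

test_that("realized group frequencies are unbiased over replicates", {
  set.seed(33)
  err <- numeric(40)
  for (r in 1:40) {
    g <- generate_neutral_genotypes(generator_config(n_snps = 50,
                                                     seed = 600 + r))
    ac <- allele_counts(g$gm, g$st, "Andean")
    err[r] <- mean(ac$derived / ac$chrom_n - g$freqs$Andean)
  }
  # mean deviation across replicates is within Monte-Carlo error of zero
  expect_lt(abs(mean(err)), 3 * sd(err) / sqrt(length(err)))
})

test_that("sweep injection hits the requested frequencies", {
  cfg <- generator_config(n_snps = 60, seed = 13)
  g <- generate_neutral_genotypes(cfg)
  gm <- inject_sweep(g$gm, g$st, sweep_spec(30, 0.40, 0.05), seed = 99)
  ac <- allele_counts(gm, g$st, "Andean")
  # exact binomial 99.9% CI for 126 chromosomes at p = 0.40
  ci <- qbinom(c(0.0005, 0.9995), 126, 0.40)
  expect_gte(ac$derived[30], ci[1])
  expect_lte(ac$derived[30], ci[2])
  # other SNPs untouched
  expect_identical(gm$dosages[-30, ], g$gm$dosages[-30, ])
})

test_that("a fixed Andean sweep is the genome-wide PBS maximum", {
  cfg <- generator_config(n_snps = 400, seed = 17)
  g <- generate_neutral_genotypes(cfg)
  gm <- inject_sweep(g$gm, g$st, sweep_spec(200, 1.0, 0.0), seed = 3)
  # brute-force over ALL SNPs (a fixed difference is monomorphic within
  # every group, so it is deliberately outside the polymorphism filter)
  rec <- pbs_records(gm, g$st)
  expect_equal(rec$id[which.max(rec$pbs)], "snp00200")
  expect_equal(which.max(bf_pbs_all(gm, g$st)), 200L)
})

test_that("sweep haplotypes share an extended core; neutral ones decay", {
  cfg <- generator_config(n_snps = 300, seed = 19)
  # neutral: EHH decays toward background
  hn <- generate_haplotypes(cfg)
  hs <- hn$haplotypes$Andean
  core <- 150L
  allele <- as.integer(mean(hs$haplotypes[, core]) > 0.5)
  cv <- ehh_curve(hs, core, allele)
  expect_lt(min(cv$ehh), 0.3)

  # sweep at frequency 1 with a core spanning the whole region and no
  # mutations: all carriers are identical, EHH is exactly 1 everywhere
  region <- max(hn$variants$pos) - min(hn$variants$pos)
  cfg0 <- cfg
  cfg0$mut_rate <- 0
  hsw <- generate_haplotypes(cfg0, sweep_spec(150, 1.0, 0.05,
                                              core_bp = region))
  expect_error(generate_haplotypes(cfg, sweep_spec(150, 1.0, 0.05,
                                                   core_bp = 3e12)),
               "exceeds")
  cvs <- ehh_curve(hsw$haplotypes$Andean, 150L, 1L)
  pos <- hn$variants$pos
  inside <- abs(cvs$pos - pos[150]) <= region / 2
  expect_true(all(cvs$ehh[inside] == 1))
  expect_gt(sum(inside), 100)
})

test_that("Andean-restricted sweeps give positive raw XP-EHH at the target", {
  # sign check over seeded replicates, raw scores at the target SNP only
  signs <- numeric(20)
  for (r in 1:20) {
    cfg <- generator_config(n_snps = 120, seed = 800 + r)
    hg <- generate_haplotypes(cfg, sweep_spec(60, 0.40, 0.05))
    it <- andescan:::ihh_for(hg$haplotypes$Andean, 60L, NULL)$ihh
    ir <- andescan:::ihh_for(hg$haplotypes$Mesoamerican, 60L, NULL)$ihh
    signs[r] <- log(it / ir)
  }
  expect_gt(mean(signs > 0), 0.5)
  expect_gt(mean(signs), 0)
})

test_that("fixtures round-trip through the standard formats", {
  cfg <- generator_config(n_snps = 40, seed = 23)
  g <- generate_neutral_genotypes(cfg)
  hg <- generate_haplotypes(cfg)
  genes <- as_gene_annotation(data.frame(chrom = "1", start = 0L,
                                         end = 50000L, name = "GENE_X"))
  dir <- withr::local_tempdir()
  paths <- write_fixture(dir, g$gm, g$st, genes = genes,
                         haplotypes = hg$haplotypes, cfg = cfg)
  gm2 <- read_vcf(paths[["vcf"]])
  expect_identical(unname(gm2$dosages), unname(g$gm$dosages))
  st2 <- read_sample_table(paths[["samples"]])
  expect_equal(nrow(st2), nrow(g$st))
  bed <- read_bed(paths[["genes"]])
  expect_equal(bed$name, "GENE_X")
  haps <- read_haplotypes(paths[["haplotypes"]], st2)
  expect_identical(haps$Andean$haplotypes, hg$haplotypes$Andean$haplotypes)
  man <- yaml::read_yaml(paths[["manifest"]])
  expect_equal(man$seed, 23L)

  # same seed -> byte-identical VCF
  dir2 <- withr::local_tempdir()
  g2 <- generate_neutral_genotypes(cfg)
  paths2 <- write_fixture(dir2, g2$gm, g2$st, cfg = cfg)
  expect_identical(readLines(paths2[["vcf"]]), readLines(paths[["vcf"]]))
})
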