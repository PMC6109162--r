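test_that("Reynolds FST matches the hand-evaluated closed form", {
  # p1 = 0.5 (50 diploids), p2 = 0.25 (50 diploids):
  # hbar = (100*0.5 + 100*0.375)/198 = 87.5/198
  # a = 0.0625 - hbar*200/20000 = 0.0625 - 0.875/198
  # a + b = 0.0625 + 0.99*hbar = 0.5  =>  FST = 23/198
  expect_equal(reynolds_fst(50, 100, 25, 100), 23 / 198, tolerance = 1e-14)
  # identical frequencies -> estimate <= 0 (clamped downstream)
  expect_lte(reynolds_fst(30, 100, 30, 100), 0)
  # fixed difference -> 1
  expect_equal(reynolds_fst(100, 100, 0, 100), 1)
  # both fixed for the same allele -> 0 by convention
  expect_equal(reynolds_fst(100, 100, 100, 100), 0)
  # chromosome count < 2 -> NA
  expect_true(is.na(reynolds_fst(1, 1, 10, 20)))
  # alternative estimators agree at equal sample sizes (hudson) and are
  # finite (wc)
  expect_equal(reynolds_fst(50, 100, 25, 100, "hudson"), 23 / 198,
               tolerance = 1e-12)
  expect_true(is.finite(reynolds_fst(50, 100, 25, 80, "wc")))
})

test_that("PBS closed forms and sign behaviour", {
  expect_equal(pbs_snp(0.5, 0.5, 0)$pbs, -log(0.5), tolerance = 1e-13)
  expect_equal(pbs_snp(0, 0, 0)$pbs, 0)
  # drift concentrated on the outgroup branch -> negative PBS, not clamped
  expect_equal(pbs_snp(0.1, 0.1, 0.4)$pbs,
               (2 * (-log(0.9)) - (-log(0.6))) / 2, tolerance = 1e-13)
  expect_lt(pbs_snp(0.1, 0.1, 0.4)$pbs, 0)
})

test_that("per-SNP PBS equals the brute-force oracle", {
  set.seed(202)
  st <- toy_sample_table(10, 12, 14)
  dos <- matrix(rbinom(200 * nrow(st), 2, runif(200 * nrow(st), .1, .9)),
                nrow = 200)
  dos[sample(length(dos), 100)] <- NA
  colnames(dos) <- st$sample_id
  gm <- toy_gm(dos)
  gm <- filter_polymorphic(gm, st)
  rec <- pbs_records(gm, st)
  expect_lt(max(abs(rec$pbs - bf_pbs_all(gm, st))), 1e-12)
})

test_that("PBS is invariant to allele polarization", {
  set.seed(203)
  st <- toy_sample_table(8, 8, 8)
  dos <- matrix(rbinom(100 * nrow(st), 2, 0.4), nrow = 100)
  colnames(dos) <- st$sample_id
  gm <- toy_gm(dos)
  flipped <- toy_gm(2L - dos)
  expect_equal(pbs_records(gm, st)$pbs, pbs_records(flipped, st)$pbs,
               tolerance = 1e-12)
})

test_that("swapping the sister-group labels permutes the branch transforms", {
  set.seed(204)
  st <- toy_sample_table(8, 10, 12)
  dos <- matrix(rbinom(50 * nrow(st), 2, 0.3), nrow = 50)
  colnames(dos) <- st$sample_id
  gm <- toy_gm(dos)
  rec <- pbs_records(gm, st)
  st2 <- st
  st2$group[st$group == "Andean"] <- "Amazonian"
  st2$group[st$group == "Amazonian"] <- "Andean"
  rec2 <- pbs_records(gm, st2)
  # the focal/outgroup transform becomes the old outgroup/sister one and
  # the sister-pair transform is symmetric
  expect_equal(rec2$t_and_meso, rec$t_meso_amaz, tolerance = 1e-12)
  expect_equal(rec2$t_meso_amaz, rec$t_and_meso, tolerance = 1e-12)
  expect_equal(rec2$t_and_amaz, rec$t_and_amaz, tolerance = 1e-12)
})

test_that("window scan matches brute-force windowing and drops remainders", {
  set.seed(205)
  rec <- data.frame(id = sprintf("s%04d", 1:1000), chrom = "1",
                    pos = seq_len(1000) * 100L, pbs = rnorm(1000))
  w <- window_scan(rec, 20L, 5L)
  expect_equal(nrow(w), (1000 - 20) / 5 + 1)
  expect_lt(max(abs(w$mean_pbs - bf_window_means(rec$pbs, 20L, 5L))), 1e-12)

  # 100 SNPs -> 17 windows; constant PBS -> constant window means
  rec2 <- data.frame(id = sprintf("s%03d", 1:100), chrom = "1",
                     pos = seq_len(100) * 10L, pbs = rep(0.3, 100))
  w2 <- window_scan(rec2)
  expect_equal(nrow(w2), 17L)
  expect_true(all(abs(w2$mean_pbs - 0.3) < 1e-15))

  # windows never span chromosomes; short chromosomes yield none
  rec3 <- rec[1:45, ]
  rec3$chrom <- rep(c("1", "2", "3"), c(22, 19, 4))
  expect_message(w3 <- window_scan(rec3), "no windows")
  expect_equal(unique(w3$chrom), "1")
  expect_equal(nrow(w3), 1L)
})

test_that("peak calling flags ~0.5% of windows and finds the top SNP", {
  set.seed(206)
  rec <- data.frame(id = sprintf("s%04d", 1:2000), chrom = "1",
                    pos = seq_len(2000) * 100L, pbs = rnorm(2000, 0, 0.05))
  w <- window_scan(rec)
  pk <- call_peaks(w, rec)
  frac <- sum(w$mean_pbs > pk$thresholds["p99.5"]) / nrow(w)
  expect_lt(abs(frac - 0.005), 0.004)

  # injected outlier run: the peak's top SNP is the max-PBS SNP in span
  rec$pbs[1000] <- 5
  w <- window_scan(rec)
  pk <- call_peaks(w, rec)
  expect_true(nrow(pk$peaks) >= 1)
  hit <- pk$peaks[pk$peaks$start_idx <= 1000 & pk$peaks$end_idx >= 1000, ]
  expect_equal(hit$top_id, "s1000")
  expect_equal(hit$top_pbs, 5)
})

test_that("few windows trigger a threshold-stability warning", {
  rec <- data.frame(id = sprintf("s%03d", 1:100), chrom = "1",
                    pos = seq_len(100) * 10L, pbs = rnorm(100))
  w <- window_scan(rec)
  expect_warning(call_peaks(w, rec), "unstable")
})

test_that("nearest-gene assignment: containment, distance, tie rule", {
  bed <- as_gene_annotation(data.frame(
    chrom = "1", start = c(1000L, 3000L), end = c(2000L, 4000L),
    name = c("A", "B")))
  expect_equal(assign_nearest_gene("1", 1500, bed),
               list(gene = "A", distance = 0))
  # 100 bp right of A (ends at 2000), 900 bp left of B
  expect_equal(assign_nearest_gene("1", 2100, bed),
               list(gene = "A", distance = 100))
  # equidistant (2500): 500 right of A, 500 left of B -> smaller start
  expect_equal(assign_nearest_gene("1", 2500, bed)$gene, "A")
  # empty chromosome
  expect_equal(assign_nearest_gene("2", 100, bed),
               list(gene = "none", distance = Inf))
})

test_that("neutral data show no PBS excess at an arbitrary target index", {
  # exchangeability: PBS at a fixed index across replicates is distributed
  # like PBS anywhere else
  set.seed(207)
  target_vals <- numeric(60)
  pool <- list()
  for (r in 1:60) {
    g <- generate_neutral_genotypes(generator_config(n_snps = 80,
                                                     seed = 5000 + r))
    rec <- pbs_records(g$gm, g$st)
    target_vals[r] <- rec$pbs[40]
    pool[[r]] <- rec$pbs[-40]
  }
  ks <- suppressWarnings(stats::ks.test(target_vals, unlist(pool)))
  expect_gt(ks$p.value, 0.01)
})
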