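test_that("weighted group frequency is the size-weighted mean", {
  expect_equal(weighted_group_frequency(c(0.5, 0.0), c(10, 30)), 0.125)
  expect_equal(weighted_group_frequency(0.37, 12), 0.37)
  expect_equal(weighted_group_frequency(c(0.2, 0.6), c(5, 5)), 0.4)
  expect_error(weighted_group_frequency(numeric(0), numeric(0)), "no pop")
  # equals the pooled-count frequency when built from one genotype matrix
  st <- toy_sample_table(6, 8, 6)
  set.seed(501)
  dos <- matrix(rbinom(20 * nrow(st), 2, 0.3), nrow = 20)
  colnames(dos) <- st$sample_id
  gm <- toy_gm(dos)
  pf <- andescan:::population_frequencies(
    gm, st, 5, populations = unique(st$population[st$group == "Amazonian"]))
  pooled <- sum(dos[5, st$group == "Amazonian"]) /
    (2 * sum(st$group == "Amazonian"))
  expect_equal(weighted_group_frequency(pf$freq, pf$n), pooled)
})

test_that("bootstrap CI collapses under zero variance and is reproducible", {
  st <- toy_sample_table(4, 6, 4)
  dos <- matrix(2L, nrow = 3, ncol = nrow(st))
  colnames(dos) <- st$sample_id
  gm <- toy_gm(dos)
  b <- bootstrap_group_ci(gm, st, 1, "Amazonian", n_boot = 500, seed = 1)
  expect_equal(b$lower, 1)
  expect_equal(b$upper, 1)
  expect_equal(b$mean, 1)

  set.seed(502)
  dos2 <- matrix(rbinom(3 * nrow(st), 2, 0.3), nrow = 3)
  colnames(dos2) <- st$sample_id
  gm2 <- toy_gm(dos2)
  b1 <- bootstrap_group_ci(gm2, st, 2, "Amazonian", n_boot = 500, seed = 7)
  b2 <- bootstrap_group_ci(gm2, st, 2, "Amazonian", n_boot = 500, seed = 7)
  expect_identical(b1[c("lower", "upper", "mean")],
                   b2[c("lower", "upper", "mean")])
  expect_true(b1$lower <= b1$mean && b1$mean <= b1$upper)
})

test_that("bootstrap CI width shrinks with sample size", {
  width_at <- function(n_per_group, seed) {
    st <- toy_sample_table(4, n_per_group, 4)
    set.seed(seed)
    dos <- matrix(rbinom(1 * nrow(st), 2, 0.4), nrow = 1)
    colnames(dos) <- st$sample_id
    gm <- toy_gm(dos)
    b <- bootstrap_group_ci(gm, st, 1, "Amazonian", n_boot = 800,
                            seed = seed)
    b$upper - b$lower
  }
  # expectation over a few replicates: 4x the samples narrows the CI
  w_small <- mean(vapply(1:6, function(r) width_at(16L, 700 + r), 1))
  w_big <- mean(vapply(1:6, function(r) width_at(64L, 700 + r), 1))
  expect_lt(w_big, w_small)
})

test_that("altitude classification honors both cutoffs", {
  st <- toy_sample_table()
  cl <- classify_altitude(st)                 # 4,000 m contrast cutoff
  expect_true(all(cl$class[cl$group == "Andean"] == "highland"))
  expect_true(all(cl$class[cl$group != "Andean"] == "lowland"))
  st2 <- st
  st2$altitude_m[st2$population == "PopM1"] <- 2600
  cl2 <- classify_altitude(st2, cutoff_m = 2500)  # descriptive cutoff
  expect_equal(cl2$class[cl2$population == "PopM1"], "highland")
  expect_equal(classify_altitude(st2)$class[cl2$population == "PopM1"],
               "lowland")
})

test_that("IDW surface interpolates exactly, stays bounded, and is
           symmetric at equidistant cells", {
  pts <- data.frame(latitude = c(-10, 10), longitude = c(-70, -70),
                    freq = c(0.8, 0.2), n = c(5, 5))
  grid <- list(lat = c(-10, 0, 10), lon = c(-70))
  s <- idw_surface(pts, grid)
  expect_equal(s$values[1, 1], 0.8)   # coincident with a sample point
  expect_equal(s$values[3, 1], 0.2)
  expect_equal(s$values[2, 1], 0.5)   # equidistant -> mean of a and b
  expect_true(all(s$values >= 0.2 & s$values <= 0.8))

  # single point -> constant surface; equal values -> constant surface
  s1 <- idw_surface(data.frame(latitude = 0, longitude = -60, freq = 0.3),
                    list(lat = c(-5, 5), lon = c(-65, -55)))
  expect_true(all(s1$values == 0.3))
  sc <- idw_surface(data.frame(latitude = c(0, 5), longitude = c(-60, -55),
                               freq = c(0.4, 0.4)),
                    list(lat = 0:4, lon = -60:-56))
  expect_true(all(abs(sc$values - 0.4) < 1e-12))

  # populations under the min_n filter are dropped
  pts2 <- rbind(pts, data.frame(latitude = 0, longitude = -70, freq = 0.99,
                                n = 2))
  s2 <- idw_surface(pts2, grid)
  expect_equal(s2$values[2, 1], 0.5)
  # raster flattening preserves every cell
  r <- surface_to_raster(s)
  expect_equal(nrow(r), 3)
  expect_equal(r$value[r$latitude == 0], 0.5)
})

test_that("frequency table reports per-population rows and weighted totals", {
  st <- toy_sample_table(6, 6, 6)
  set.seed(503)
  dos <- matrix(rbinom(4 * nrow(st), 2, 0.35), nrow = 4)
  colnames(dos) <- st$sample_id
  gm <- toy_gm(dos)
  ft <- frequency_table(gm, st, c("rs001", "rs003"))
  tot <- ft[ft$population == "Total" & ft$group == "Andean", ]
  pooled <- sum(dos[1, st$group == "Andean"]) /
    (2 * sum(st$group == "Andean"))
  expect_equal(tot$rs001, pooled)
  expect_equal(tot$n, sum(st$group == "Andean"))
})
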