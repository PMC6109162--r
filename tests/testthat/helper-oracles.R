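# Independent brute-force oracles and tiny fixture builders.  These
# deliberately re-derive every quantity with straight-line scalar code so
# they share nothing with the package implementation.

# Reynolds coancestry FST for one SNP, scalar arithmetic written out
bf_fst_one <- function(d1, m1, d2, m2) {
  p1 <- d1 / m1
  p2 <- d2 / m2
  h1 <- 2 * p1 * (1 - p1)
  h2 <- 2 * p2 * (1 - p2)
  hbar <- (m1 * h1 + m2 * h2) / (m1 + m2 - 2)
  a <- (p1 - p2)^2 - hbar * (m1 + m2) / (2 * m1 * m2)
  if (a + hbar == 0) return(0)
  a / (a + hbar)
}

# PBS per SNP from raw group counts, one SNP at a time
bf_pbs_one <- function(d_and, m_and, d_amaz, m_amaz, d_meso, m_meso) {
  cl <- function(f) min(max(f, 0), 1 - 1e-9)
  t_am <- -log(1 - cl(bf_fst_one(d_and, m_and, d_meso, m_meso)))
  t_aa <- -log(1 - cl(bf_fst_one(d_and, m_and, d_amaz, m_amaz)))
  t_ma <- -log(1 - cl(bf_fst_one(d_meso, m_meso, d_amaz, m_amaz)))
  (t_am + t_aa - t_ma) / 2
}

# group counts by explicit per-sample counting (no matrix algebra)
bf_group_counts <- function(gm, st, group) {
  ids <- st$sample_id[st$group == group]
  n_snp <- nrow(gm$variants)
  derived <- integer(n_snp)
  chroms <- integer(n_snp)
  for (i in seq_len(n_snp)) {
    for (s in ids) {
      x <- gm$dosages[i, s]
      if (!is.na(x)) {
        derived[i] <- derived[i] + x
        chroms[i] <- chroms[i] + 2L
      }
    }
  }
  list(derived = derived, chroms = chroms)
}

bf_pbs_all <- function(gm, st) {
  an <- bf_group_counts(gm, st, "Andean")
  az <- bf_group_counts(gm, st, "Amazonian")
  me <- bf_group_counts(gm, st, "Mesoamerican")
  vapply(seq_len(nrow(gm$variants)), function(i) {
    bf_pbs_one(an$derived[i], an$chroms[i], az$derived[i], az$chroms[i],
               me$derived[i], me$chroms[i])
  }, numeric(1))
}

# windowed means by explicit looping
bf_window_means <- function(pbs, window = 20L, step = 5L) {
  n <- length(pbs)
  starts <- seq(1L, n - window + 1L, by = step)
  vapply(starts, function(s) mean(pbs[s:(s + window - 1L)]), numeric(1))
}

# EHH by pairwise string comparison over the stretch core..flank
bf_ehh <- function(hap, core, allele, flank) {
  rows <- which(hap[, core] == allele)
  n <- length(rows)
  if (n < 2) return(NA_real_)
  cols <- min(core, flank):max(core, flank)
  strings <- apply(hap[rows, cols, drop = FALSE], 1, paste, collapse = "")
  same <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (strings[i] == strings[j]) same <- same + 1
    }
  }
  same / (n * (n - 1) / 2)
}

# small in-memory sample table (two populations per group by default)
toy_sample_table <- function(n_and = 6L, n_amaz = 6L, n_meso = 6L) {
  mk <- function(pop, group, n, lat, lon, alt) {
    data.frame(sample_id = sprintf("%s_%02d", pop, seq_len(n)),
               population = pop, group = group, latitude = lat,
               longitude = lon, altitude_m = alt,
               stringsAsFactors = FALSE)
  }
  as_sample_table(rbind(
    mk("PopA1", "Andean", ceiling(n_and / 2), -16, -68, 4100),
    mk("PopA2", "Andean", floor(n_and / 2), -14, -71, 4200),
    mk("PopZ1", "Amazonian", ceiling(n_amaz / 2), -10, -63, 150),
    mk("PopZ2", "Amazonian", floor(n_amaz / 2), -4, -70, 100),
    mk("PopM1", "Mesoamerican", ceiling(n_meso / 2), 17, -96, 1500),
    mk("PopM2", "Mesoamerican", floor(n_meso / 2), 16, -89, 200)))
}

# genotype matrix from a dosage matrix with default variant metadata
toy_gm <- function(dos, pos = NULL) {
  n <- nrow(dos)
  variants <- data.frame(
    chrom = "1", pos = if (is.null(pos)) seq_len(n) * 1000L else pos,
    id = sprintf("rs%03d", seq_len(n)),
    ancestral_allele = rep(c("A", "C", "G", "T"), length.out = n),
    derived_allele = rep(c("G", "T", "A", "C"), length.out = n),
    polarized = TRUE, stringsAsFactors = FALSE)
  genotype_matrix(variants, dos)
}
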