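## Synthetic three-group fixtures with the hierarchical drift structure the
## scan assumes: ((Andean, Amazonian), Mesoamerican).
##
## Two genotype backends share one interface: a fast hierarchical
## Balding-Nichols model (group frequencies drawn around an ancestral
## frequency with per-branch drift F = 1 - exp(-t / 2Ne), branch lengths
## integrated over the demographic model's epochs) and the structured
## coalescent from the null module.  Haplotypes are built by mosaic copying
## from a founder panel so background linkage disequilibrium decays with
## distance; an optional hard sweep plants one founder haplotype, shared by
## all carriers over a core interval around the target SNP.

#' Generator configuration
#'
#' Defaults mirror the study design: 63 Andean, 106 Amazonian and 153
#' Mesoamerican individuals, an ascertained common-variant frequency
#' spectrum (Beta(0.8, 0.8) truncated to \[0.05, 0.95\], emulating a SNP
#' array), and the constant demographic model.
#'
#' @param n_snps number of SNPs (must be at least one window, 20).
#' @param n named sample sizes (diploid individuals) per group.
#' @param model demographic model label or [demographic_model()].
#' @param backend `"balding_nichols"` (fast) or `"coalescent"`.
#' @param spectrum list with Beta `shape1`, `shape2` and truncation bounds
#'   `lo`, `hi` for the ancestral frequency.
#' @param spacing_bp mean inter-SNP spacing in bp.
#' @param n_founders founder-panel size per group for haplotype mosaics.
#' @param block_bp mean mosaic copy-block length (bp).
#' @param mut_rate per-SNP flip probability on copied haplotype blocks.
#' @param seed integer seed recorded in all outputs.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_snps = 2000L,
                             n = c(Andean = 63L, Amazonian = 106L,
                                   Mesoamerican = 153L),
                             model = "constant",
                             backend = c("balding_nichols", "coalescent"),
                             spectrum = list(shape1 = 0.8, shape2 = 0.8,
                                             lo = 0.05, hi = 0.95),
                             spacing_bp = 10000L,
                             n_founders = 12L,
                             block_bp = 30000L,
                             mut_rate = 0.002,
                             seed = 1L) {
  backend <- match.arg(backend)
  if (n_snps < 20L) stop("n_snps must be >= 20 (one window)")
  if (any(n < 1L)) stop("sample sizes must be >= 1")
  if (is.character(model)) model <- demographic_model(model)
  structure(list(n_snps = as.integer(n_snps), n = n, model = model,
                 backend = backend, spectrum = spectrum,
                 spacing_bp = spacing_bp, n_founders = n_founders,
                 block_bp = block_bp, mut_rate = mut_rate,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Sweep specification
#'
#' Default magnitudes follow the frequency contrast of the scan's candidate
#' loci: derived frequency ~0.40 in the highland group against ~0.05 in
#' both lowland groups.
#'
#' @param target_index SNP index of the selected site.
#' @param andean_freq,lowland_freq target derived-allele frequencies.
#' @param core_bp length of the shared founder haplotype around the target.
#' @return list of class `sweep_spec`.
#' @export
sweep_spec <- function(target_index, andean_freq = 0.40,
                       lowland_freq = 0.05, core_bp = 600000L) {
  stopifnot(andean_freq >= 0, andean_freq <= 1,
            lowland_freq >= 0, lowland_freq <= 1, target_index >= 1L)
  structure(list(target_index = as.integer(target_index),
                 andean_freq = andean_freq, lowland_freq = lowland_freq,
                 core_bp = as.numeric(core_bp)),
            class = "sweep_spec")
}

## drift F = 1 - exp(-t/2Ne) accumulated over a population's epochs from
## time `from` to `to` (backwards generations)
branch_f <- function(epochs, from, to) {
  stopifnot(to >= from)
  starts <- epochs[, 1]; nes <- epochs[, 2]
  bounds <- sort(unique(c(from, to, starts[starts > from & starts < to])))
  acc <- 0
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i]; b <- bounds[i + 1L]
    ne <- nes[max(which(starts <= a))]
    acc <- acc + (b - a) / (2 * ne)
  }
  1 - exp(-acc)
}

## per-branch drift parameters implied by a demographic model
model_branch_f <- function(model) {
  g <- model$generation_time
  t_aa <- model$t_and_amaz_split_y / g
  t_meso <- model$t_meso_split_y / g
  list(
    andean = branch_f(model$epochs$Andean, 0, t_aa),
    amazonian = branch_f(model$epochs$Amazonian, 0, t_aa),
    mesoamerican = branch_f(model$epochs$Mesoamerican, 0, t_meso),
    anc_and_amaz = branch_f(model$epochs$AncAndAmaz, t_aa, t_meso))
}

## Balding-Nichols draw: Beta around p with drift F (F = 0 returns p)
bn_draw <- function(p, f) {
  stopifnot(length(f) == 1L)
  if (f <= 0) return(p)
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

draw_spectrum <- function(n, sp) {
  p <- stats::rbeta(n, sp$shape1, sp$shape2)
  pmin(pmax(p, sp$lo), sp$hi)
}

## default sub-population layout (exchangeable within groups); sizes are
## scaled to the configured group sizes so bootstrap weighting is exercised
default_populations <- function() {
  data.frame(
    population = c("Aymara", "Quechua",
                   "Karitiana", "Surui", "Ticuna", "Piapoco",
                   "Maya", "Mixe", "Mixtec", "Zapotec"),
    group = c("Andean", "Andean",
              rep("Amazonian", 4), rep("Mesoamerican", 4)),
    share = c(0.6, 0.4, 0.25, 0.2, 0.3, 0.25, 0.3, 0.2, 0.22, 0.28),
    latitude = c(-16.5, -13.5, -9.9, -11.1, -3.8, 4.2,
                 16.8, 17.0, 17.1, 16.9),
    longitude = c(-68.2, -72.0, -63.3, -60.7, -70.0, -69.8,
                  -89.1, -96.0, -97.7, -96.4),
    altitude_m = c(4050, 4150, 150, 200, 90, 120, 180, 1600, 1550, 1500),
    stringsAsFactors = FALSE)
}

build_sample_table <- function(n) {
  pops <- default_populations()
  rows <- list()
  for (g in names(n)) {
    pg <- pops[pops$group == g, , drop = FALSE]
    sizes <- floor(pg$share / sum(pg$share) * n[[g]])
    while (sum(sizes) < n[[g]]) {
      i <- which.max(pg$share - sizes / n[[g]])
      sizes[i] <- sizes[i] + 1L
    }
    for (i in seq_len(nrow(pg))) {
      if (sizes[i] == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("%s_%03d", pg$population[i], seq_len(sizes[i])),
        population = pg$population[i], group = g,
        latitude = pg$latitude[i], longitude = pg$longitude[i],
        altitude_m = pg$altitude_m[i], stringsAsFactors = FALSE)
    }
  }
  as_sample_table(do.call(rbind, rows))
}

random_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, n, replace = TRUE)
  der <- vapply(anc, function(a) sample(setdiff(bases, a), 1L), character(1))
  list(anc = anc, der = unname(der))
}

build_variants <- function(cfg) {
  pos <- cumsum(pmax(1L, stats::rgeom(cfg$n_snps, 1 / cfg$spacing_bp) + 1L))
  al <- random_alleles(cfg$n_snps)
  data.frame(chrom = "1", pos = as.integer(pos),
             id = sprintf("snp%05d", seq_len(cfg$n_snps)),
             ancestral_allele = al$anc, derived_allele = al$der,
             polarized = TRUE, stringsAsFactors = FALSE)
}

## group-level derived-allele frequencies under the hierarchical BN model
bn_group_freqs <- function(cfg) {
  fb <- model_branch_f(cfg$model)
  if (any(unlist(fb) < 0 | unlist(fb) >= 1)) {
    stop("infeasible drift parameters: F must be in [0, 1)")
  }
  p0 <- draw_spectrum(cfg$n_snps, cfg$spectrum)
  p_anc_aa <- bn_draw(p0, fb$anc_and_amaz)
  list(Andean = bn_draw(p_anc_aa, fb$andean),
       Amazonian = bn_draw(p_anc_aa, fb$amazonian),
       Mesoamerican = bn_draw(p0, fb$mesoamerican))
}

#' Generate neutral genotypes and a sample table
#'
#' @param cfg a [generator_config()].
#' @return list with `gm` (a [genotype_matrix()]), `st` (sample table) and
#'   `freqs` (the generating group frequencies, Balding-Nichols backend
#'   only).
#' @export
generate_neutral_genotypes <- function(cfg) {
  set.seed(cfg$seed)
  st <- build_sample_table(cfg$n)
  variants <- build_variants(cfg)
  n_ind <- vapply(GROUPS, function(g) sum(st$group == g), integer(1))
  freqs <- NULL
  dos <- matrix(NA_integer_, nrow = cfg$n_snps, ncol = nrow(st))
  colnames(dos) <- st$sample_id
  if (cfg$backend == "balding_nichols") {
    freqs <- bn_group_freqs(cfg)
    for (g in GROUPS) {
      cols <- which(st$group == g)
      dos[, cols] <- stats::rbinom(cfg$n_snps * length(cols), 2L,
                                   rep(freqs[[g]], length(cols)))
    }
  } else {
    m <- 2L * n_ind
    sim <- simulate_coalescent_counts(m, cfg$model$epochs, cfg$model$merges,
                                      n_reps = cfg$n_snps,
                                      require_poly2 = FALSE)
    for (gi in seq_along(GROUPS)) {
      cols <- which(st$group == GROUPS[gi])
      for (s in seq_len(cfg$n_snps)) {
        chroms <- integer(m[gi])
        if (sim$derived[s, gi] > 0L) {
          chroms[sample.int(m[gi], sim$derived[s, gi])] <- 1L
        }
        dos[s, cols] <- chroms[seq(1L, m[gi], by = 2L)] +
          chroms[seq(2L, m[gi], by = 2L)]
      }
    }
  }
  list(gm = genotype_matrix(variants, dos), st = st, freqs = freqs)
}

#' Inject a hard-sweep frequency pattern at one SNP
#'
#' The target SNP's genotypes are redrawn binomially: at `andean_freq` for
#' Andean samples and at `lowland_freq` for both lowland groups.  All other
#' SNPs are untouched.
#'
#' @param gm a [genotype_matrix()].
#' @param st the matching sample table.
#' @param spec a [sweep_spec()].
#' @param seed optional integer seed.
#' @return the modified [genotype_matrix()].
#' @export
inject_sweep <- function(gm, st, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  i <- spec$target_index
  if (i > nrow(gm$variants)) stop("target index outside the SNP table")
  and_cols <- which(st$group == "Andean")
  low_cols <- which(st$group %in% c("Amazonian", "Mesoamerican"))
  gm$dosages[i, and_cols] <- stats::rbinom(length(and_cols), 2L,
                                           spec$andean_freq)
  gm$dosages[i, low_cols] <- stats::rbinom(length(low_cols), 2L,
                                           spec$lowland_freq)
  gm
}

## one mosaic haplotype copied from a founder panel; switch probability per
## interval 1 - exp(-gap/block_bp) gives geometric block lengths in bp
mosaic_haplotype <- function(founders, pos, block_bp, mut_rate) {
  S <- length(pos)
  K <- nrow(founders)
  gaps <- diff(pos)
  switch_p <- 1 - exp(-gaps / block_bp)
  switches <- c(TRUE, stats::runif(S - 1L) < switch_p)
  seg <- cumsum(switches)
  src <- sample.int(K, max(seg), replace = TRUE)
  h <- founders[cbind(src[seg], seq_len(S))]
  flips <- stats::runif(S) < mut_rate
  h[flips] <- 1L - h[flips]
  h
}

#' Generate phased haplotypes per group
#'
#' Neutral haplotypes are mosaics over a founder panel drawn from the
#' group's generating frequencies, so extended homozygosity decays toward
#' the panel's background level with distance.  With a sweep, a fraction of
#' Andean haplotypes matching the target frequency carry one founder
#' haplotype (forced to the derived allele at the target) over the core
#' interval, with sparse mutations; lowland groups receive the target
#' frequency without any shared core.
#'
#' @param cfg a [generator_config()].
#' @param sweep optional [sweep_spec()].
#' @return list with `haplotypes` (named list of `haplotype_set` per
#'   group), `variants` and `st`.
#' @export
generate_haplotypes <- function(cfg, sweep = NULL) {
  set.seed(cfg$seed + 1L)
  st <- build_sample_table(cfg$n)
  variants <- build_variants(cfg)
  pos <- variants$pos
  freqs <- bn_group_freqs(cfg)
  if (!is.null(sweep)) {
    if (sweep$core_bp > max(pos) - min(pos)) {
      stop("sweep core length exceeds the simulated region")
    }
    if (sweep$target_index > cfg$n_snps) stop("target index out of range")
  }
  out <- list()
  for (g in GROUPS) {
    n_hap <- 2L * sum(st$group == g)
    founders <- matrix(stats::rbinom(cfg$n_founders * cfg$n_snps, 1L,
                                     rep(freqs[[g]], each = cfg$n_founders)),
                       nrow = cfg$n_founders)
    haps <- t(vapply(seq_len(n_hap), function(i) {
      mosaic_haplotype(founders, pos, cfg$block_bp, cfg$mut_rate)
    }, integer(cfg$n_snps)))
    if (!is.null(sweep)) {
      ti <- sweep$target_index
      f_target <- if (g == "Andean") sweep$andean_freq else
        sweep$lowland_freq
      n_car <- round(f_target * n_hap)
      carriers <- if (n_car > 0L) sample.int(n_hap, n_car) else integer(0)
      haps[, ti] <- 0L
      if (g == "Andean" && n_car > 0L) {
        ## carriers share founder 1 across the core, with sparse mutations
        core <- which(pos >= pos[ti] - sweep$core_bp / 2 &
                        pos <= pos[ti] + sweep$core_bp / 2)
        core_hap <- founders[1L, core]
        core_hap[core == ti] <- 1L
        for (h in carriers) {
          hap_core <- core_hap
          flips <- stats::runif(length(core)) < cfg$mut_rate / 2
          hap_core[flips] <- 1L - hap_core[flips]
          hap_core[core == ti] <- 1L
          haps[h, core] <- hap_core
        }
      } else if (n_car > 0L) {
        haps[carriers, ti] <- 1L
      }
    }
    out[[g]] <- haplotype_set(haps, pos, label = g)
  }
  list(haplotypes = out, variants = variants, st = st)
}

#' Write a generated fixture to disk
#'
#' Emits the dialects the readers consume: a genotype VCF, a sample TSV, a
#' gene BED and a YAML manifest recording the configuration and seed.
#' Optionally a phased haplotype VCF.
#'
#' @param dir output directory (created if needed).
#' @param gm genotype matrix.
#' @param st sample table.
#' @param genes optional gene annotation data.frame.
#' @param haplotypes optional named list of `haplotype_set` (written as a
#'   phased VCF whose sample columns pair consecutive haplotypes).
#' @param cfg the [generator_config()] used (recorded in the manifest).
#' @return named character vector of written paths.
#' @export
write_fixture <- function(dir, gm, st, genes = NULL, haplotypes = NULL,
                          cfg = NULL) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create fixture directory: ", dir)
  }
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             samples = file.path(dir, "samples.tsv"),
             manifest = file.path(dir, "manifest.yaml"))
  write_vcf(gm, paths[["vcf"]])
  utils::write.table(st, paths[["samples"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(genes)) {
    paths[["genes"]] <- file.path(dir, "genes.bed")
    write_bed(genes, paths[["genes"]])
  }
  if (!is.null(haplotypes)) {
    paths[["haplotypes"]] <- file.path(dir, "haplotypes.vcf")
    write_phased_vcf(haplotypes, gm$variants, paths[["haplotypes"]])
  }
  manifest <- list(
    package = "andescan",
    seed = if (!is.null(cfg)) cfg$seed else NA,
    config = if (!is.null(cfg)) {
      c(cfg[c("n_snps", "backend", "spacing_bp", "n_founders", "block_bp",
              "mut_rate")],
        list(n = as.list(cfg$n), model = cfg$model$label))
    })
  yaml::write_yaml(manifest, paths[["manifest"]])
  paths
}

## phased VCF for haplotype sets: sample columns pair haplotypes (2i-1, 2i)
write_phased_vcf <- function(haplotypes, variants, path) {
  cols <- list(); samples <- character(0)
  for (g in names(haplotypes)) {
    h <- haplotypes[[g]]$haplotypes
    n_ind <- nrow(h) %/% 2L
    for (i in seq_len(n_ind)) {
      cols[[length(cols) + 1L]] <-
        paste0(h[2L * i - 1L, ], "|", h[2L * i, ])
      samples <- c(samples, sprintf("%s_H%03d", g, i))
    }
  }
  gt <- do.call(cbind, cols)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=andescan-haplotypes",
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(variants$chrom, variants$pos, variants$id,
                variants$ancestral_allele, variants$derived_allele,
                ".", "PASS", paste0("AA=", variants$ancestral_allele), "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read phased haplotypes from a VCF
#'
#' Splits phased diploid genotypes (`a|b`) into two haplotype rows per
#' sample and groups them by the sample table's `group` column.
#'
#' @param path phased VCF.
#' @param st sample table covering the VCF's samples (sample ids matched by
#'   name; haplotype-VCF sample columns named `<Group>_H<i>` are matched by
#'   their group prefix instead).
#' @return named list of `haplotype_set` per group.
#' @export
read_haplotypes <- function(path, st) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  pos <- as.integer(as.data.frame(v@fix)$POS)
  if (!all(grepl("|", gt, fixed = TRUE))) {
    stop("haplotype input must be phased (GT separator '|')")
  }
  grp_of <- function(s) {
    if (s %in% st$sample_id) st$group[match(s, st$sample_id)]
    else sub("_H[0-9]+$", "", s)
  }
  groups <- vapply(colnames(gt), grp_of, character(1))
  out <- list()
  for (g in unique(groups)) {
    cols <- which(groups == g)
    h1 <- matrix(as.integer(substr(gt[, cols, drop = FALSE], 1L, 1L)),
                 nrow = nrow(gt))
    h2 <- matrix(as.integer(substr(gt[, cols, drop = FALSE], 3L, 3L)),
                 nrow = nrow(gt))
    haps <- matrix(0L, nrow = 2L * length(cols), ncol = nrow(gt))
    haps[seq(1L, nrow(haps), 2L), ] <- t(h1)
    haps[seq(2L, nrow(haps), 2L), ] <- t(h2)
    out[[g]] <- haplotype_set(haps, pos, label = g)
  }
  out
}
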