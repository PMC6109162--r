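## End-to-end orchestration: filter -> PBS scan -> peaks -> gene assignment
## -> coalescent nulls under the three demographic models -> haplotype
## statistics for peak SNPs -> bootstrap CIs and IDW surfaces.  Every stage
## draws its seed deterministically from the master seed, and a YAML
## manifest records the resolved configuration so a rerun is byte-identical.

#' Scan configuration
#'
#' Defaults are the scan's canonical parameters: 20-SNP windows advancing
#' by 5, outlier tiers at the 99.5th/99.9th percentiles, 10,000 coalescent
#' replicates per demographic model, 10,000 bootstrap replicates.
#'
#' @param vcf,samples,genes input paths (VCF genotypes, TSV sample table,
#'   BED annotation); leave `NULL` to use the synthetic generator.
#' @param haplotypes optional phased VCF for haplotype statistics.
#' @param synthetic list with `config` (a [generator_config()]) and
#'   optional `sweep` (a [sweep_spec()]); used when `vcf` is `NULL`.
#' @param window,step window length and step in SNPs.
#' @param percentiles outlier tiers.
#' @param models demographic model labels to simulate.
#' @param n_reps coalescent replicates per model.
#' @param n_boot bootstrap replicates.
#' @param ehh_cutoff,max_gap,ihs_bins haplotype-statistic parameters.
#' @param idw_power,idw_cells IDW surface parameters.
#' @param estimator FST estimator.
#' @param seed master seed; stage seeds are derived from it by hashing the
#'   stage name ([stage_seed()]).
#' @return list of class `scan_config`.
#' @export
scan_config <- function(vcf = NULL, samples = NULL, genes = NULL,
                        haplotypes = NULL, synthetic = NULL,
                        window = 20L, step = 5L,
                        percentiles = c(99.5, 99.9),
                        models = c("constant", "bottleneck",
                                   "bottleneck_expansion"),
                        n_reps = 10000L, n_boot = 10000L,
                        ehh_cutoff = 0.05, max_gap = 200000,
                        ihs_bins = 20L, idw_power = 2, idw_cells = 25L,
                        estimator = "reynolds", seed = 1L) {
  if (is.null(vcf) && is.null(synthetic)) {
    synthetic <- list(config = generator_config(seed = seed))
  }
  structure(list(vcf = vcf, samples = samples, genes = genes,
                 haplotypes = haplotypes, synthetic = synthetic,
                 window = as.integer(window), step = as.integer(step),
                 percentiles = percentiles, models = models,
                 n_reps = as.integer(n_reps), n_boot = as.integer(n_boot),
                 ehh_cutoff = ehh_cutoff, max_gap = max_gap,
                 ihs_bins = as.integer(ihs_bins), idw_power = idw_power,
                 idw_cells = as.integer(idw_cells), estimator = estimator,
                 seed = as.integer(seed)),
            class = "scan_config")
}

config_manifest <- function(cfg, stages) {
  list(package = "andescan",
       seed = cfg$seed,
       stage_seeds = stages,
       parameters = list(
         window = cfg$window, step = cfg$step,
         percentiles = as.list(cfg$percentiles),
         models = as.list(cfg$models),
         n_reps = cfg$n_reps, n_boot = cfg$n_boot,
         ehh_cutoff = cfg$ehh_cutoff, max_gap = cfg$max_gap,
         ihs_bins = cfg$ihs_bins, idw_power = cfg$idw_power,
         idw_cells = cfg$idw_cells, estimator = cfg$estimator),
       inputs = list(
         vcf = cfg$vcf %||% "synthetic", samples = cfg$samples %||%
           "synthetic", genes = cfg$genes %||% "none",
         synthetic = if (!is.null(cfg$synthetic)) list(
           n_snps = cfg$synthetic$config$n_snps,
           model = cfg$synthetic$config$model$label,
           backend = cfg$synthetic$config$backend,
           generator_seed = cfg$synthetic$config$seed,
           sweep = if (!is.null(cfg$synthetic$sweep)) {
             s <- cfg$synthetic$sweep
             list(target_index = s$target_index,
                  andean_freq = s$andean_freq,
                  lowland_freq = s$lowland_freq, core_bp = s$core_bp)
           } else "none") else "none"))
}

#' Run the full selection scan
#'
#' Executes the pipeline end to end and writes a report bundle to
#' `out_dir`: per-SNP PBS TSV, window TSV, peak TSV, a candidate table (one
#' row per peak top SNP with PBS, per-model simulation p-values and
#' standardized XP-EHH against each lowland group), a per-population
#' frequency table for the candidate SNPs, bootstrap CIs for the lowland
#' groups, an IDW raster per candidate SNP and a YAML manifest.  A rerun
#' with the same configuration is byte-identical.
#'
#' @param cfg a [scan_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with all in-memory stage results.
#' @export
run_full_scan <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "scan_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stages <- list(
    data = stage_seed(cfg$seed, "data"),
    null = stage_seed(cfg$seed, "null"),
    haplo = stage_seed(cfg$seed, "haplo"),
    bootstrap = stage_seed(cfg$seed, "bootstrap"))

  run_stage <- function(name, f) {
    tryCatch(f(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           " (partial outputs kept in ", out_dir, ")", call. = FALSE)
    })
  }

  ## --- inputs -----------------------------------------------------------
  dat <- run_stage("input", function() {
    if (!is.null(cfg$vcf)) {
      gm <- read_vcf(cfg$vcf)
      st <- read_sample_table(cfg$samples)
      genes <- if (!is.null(cfg$genes)) read_bed(cfg$genes) else NULL
      haps <- if (!is.null(cfg$haplotypes)) {
        read_haplotypes(cfg$haplotypes, st)
      } else NULL
      list(gm = gm, st = st, genes = genes, haps = haps)
    } else {
      gc <- cfg$synthetic$config
      gc$seed <- stages$data
      gen <- generate_neutral_genotypes(gc)
      gm <- gen$gm
      if (!is.null(cfg$synthetic$sweep)) {
        gm <- inject_sweep(gm, gen$st, cfg$synthetic$sweep,
                           seed = stages$data + 1L)
      }
      hg <- generate_haplotypes(gc, cfg$synthetic$sweep)
      genes <- if (!is.null(cfg$genes)) read_bed(cfg$genes) else NULL
      list(gm = gm, st = gen$st, genes = genes, haps = hg$haplotypes)
    }
  })
  haps <- dat$haps

  ## --- PBS scan ---------------------------------------------------------
  scan <- run_stage("pbs_scan", function() {
    gm_f <- filter_polymorphic(dat$gm, dat$st)
    records <- pbs_records(gm_f, dat$st, estimator = cfg$estimator)
    windows <- window_scan(records, cfg$window, cfg$step)
    pk <- call_peaks(windows, records, cfg$percentiles, dat$genes)
    list(gm = gm_f, records = records, windows = windows,
         thresholds = pk$thresholds, peaks = pk$peaks)
  })
  write_tsv(scan$records, file.path(out_dir, "pbs_per_snp.tsv"),
            comment = paste0("andescan per-SNP PBS; estimator=",
                             cfg$estimator, "; seed=", cfg$seed))
  write_tsv(scan$windows, file.path(out_dir, "pbs_windows.tsv"),
            comment = paste0("andescan windowed PBS; window=", cfg$window,
                             "; step=", cfg$step))
  write_tsv(scan$peaks, file.path(out_dir, "pbs_peaks.tsv"),
            comment = paste0("andescan outlier peaks; tiers=",
                             paste(cfg$percentiles, collapse = ",")))

  cand_ids <- scan$peaks$top_id
  cand_idx <- match(cand_ids, scan$records$id)

  ## --- neutral nulls ----------------------------------------------------
  n_ind <- vapply(GROUPS, function(g) sum(dat$st$group == g), integer(1))
  nulls <- run_stage("neutral_null", function() {
    out <- list()
    for (k in seq_along(cfg$models)) {
      out[[cfg$models[k]]] <- simulate_pbs_null(
        cfg$models[k], n = n_ind, n_reps = cfg$n_reps,
        seed = stages$null + k, estimator = cfg$estimator)
    }
    out
  })

  ## --- haplotype statistics for candidate SNPs --------------------------
  haplo <- run_stage("haplotype_stats", function() {
    if (is.null(haps) || length(cand_ids) == 0L) return(NULL)
    set.seed(stages$haplo)
    xp_meso <- xpehh_scores(haps$Andean, haps$Mesoamerican,
                            cfg$ehh_cutoff, cfg$max_gap)
    xp_amaz <- xpehh_scores(haps$Andean, haps$Amazonian,
                            cfg$ehh_cutoff, cfg$max_gap)
    xp_meso$p <- xpehh_pvalue(xp_meso)
    xp_amaz$p <- xpehh_pvalue(xp_amaz)
    list(xp_meso = xp_meso, xp_amaz = xp_amaz)
  })

  ## --- candidate table --------------------------------------------------
  candidates <- if (length(cand_ids)) {
    v <- scan$gm$variants[cand_idx, , drop = FALSE]
    out <- data.frame(
      snp = cand_ids,
      ancestral = v$ancestral_allele, derived = v$derived_allele,
      gene = if ("gene" %in% names(scan$peaks)) scan$peaks$gene else NA,
      chrom = v$chrom, pos = v$pos,
      pbs = scan$records$pbs[cand_idx], stringsAsFactors = FALSE)
    for (m in cfg$models) {
      out[[paste0("p_", m)]] <-
        empirical_pvalue(out$pbs, nulls[[m]])
    }
    if (!is.null(haplo)) {
      ## candidate SNP indices refer to the generator's SNP table; match by
      ## id through the filtered records' row order
      hap_idx <- match(cand_ids, dat$gm$variants$id)
      out$xpehh_meso <- haplo$xp_meso$xpehh_std[hap_idx]
      out$p_xpehh_meso <- haplo$xp_meso$p[hap_idx]
      out$xpehh_amaz <- haplo$xp_amaz$xpehh_std[hap_idx]
      out$p_xpehh_amaz <- haplo$xp_amaz$p[hap_idx]
    }
    out
  } else data.frame()
  write_tsv(candidates, file.path(out_dir, "candidates.tsv"),
            comment = "andescan candidate SNPs (peak top SNPs)")

  ## --- frequencies, bootstrap, IDW -------------------------------------
  freq_out <- run_stage("freq_geo", function() {
    if (length(cand_ids) == 0L) return(NULL)
    ft <- frequency_table(dat$gm, dat$st, cand_ids)
    boots <- list()
    set.seed(stages$bootstrap)
    for (s in cand_ids) {
      for (g in c("Amazonian", "Mesoamerican")) {
        b <- bootstrap_group_ci(dat$gm, dat$st, s, g, n_boot = cfg$n_boot)
        boots[[length(boots) + 1L]] <- data.frame(
          snp = s, group = g, mean = b$mean, lower = b$lower,
          upper = b$upper, n_boot = b$n_boot, stringsAsFactors = FALSE)
      }
    }
    boots <- do.call(rbind, boots)
    surfaces <- list()
    for (s in cand_ids) {
      pf <- population_frequencies(dat$gm, dat$st, s)
      pf <- merge(pf, unique(dat$st[, c("population", "latitude",
                                        "longitude")]), by = "population")
      pf <- pf[order(pf$population), , drop = FALSE]
      names(pf)[names(pf) == "freq"] <- "freq"
      surf <- idw_surface(pf, power = cfg$idw_power,
                          n_cells = cfg$idw_cells)
      surfaces[[s]] <- surf
      write_tsv(surface_to_raster(surf),
                file.path(out_dir, paste0("idw_", s, ".tsv")),
                comment = paste0("andescan IDW raster; power=",
                                 cfg$idw_power))
    }
    list(freq_table = ft, bootstraps = boots, surfaces = surfaces)
  })
  if (!is.null(freq_out)) {
    write_tsv(freq_out$freq_table, file.path(out_dir, "frequencies.tsv"),
              comment = "andescan per-population candidate frequencies")
    write_tsv(freq_out$bootstraps, file.path(out_dir, "bootstrap_ci.tsv"),
              comment = paste0("andescan lowland bootstrap CIs; n_boot=",
                               cfg$n_boot))
  }

  yaml::write_yaml(config_manifest(cfg, stages),
                   file.path(out_dir, "manifest.yaml"))
  invisible(list(data = dat, scan = scan, nulls = nulls, haplo = haplo,
                 candidates = candidates, freq_geo = freq_out,
                 stages = stages, out_dir = out_dir))
}
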