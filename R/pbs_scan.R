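## Per-SNP and windowed Population Branch Statistic.
##
## The focal (Andean) branch length on the three-population tree
## ((Andean, Amazonian), Mesoamerican) is
##
##   PBS = (T_AM + T_AA - T_MA) / 2,   T = -log(1 - FST)
##
## where T_AM is the Andean/Mesoamerican branch transform, T_AA
## Andean/Amazonian and T_MA Mesoamerican/Amazonian.  Large PBS means
## allele-frequency change concentrated on the focal branch.  Windows of 20
## SNPs advancing by 5 smooth the per-SNP values; outlier windows above the
## empirical 99.5th/99.9th percentiles are merged into peaks and each peak
## reports its top per-SNP PBS value and nearest gene.

#' Pairwise FST from allele counts
#'
#' Moment estimators of FST for two populations from per-SNP derived-allele
#' counts and (haploid) chromosome counts.  The default is the Reynolds
#' (1983) coancestry estimator `a / (a + b)` with the sample-size-weighted
#' pooled within-population heterozygosity
#' `hbar = (m1 h1 + m2 h2) / (m1 + m2 - 2)` (with `h = 2 p (1 - p)`):
#' `a = (p1 - p2)^2 - hbar (m1 + m2) / (2 m1 m2)` and `b = hbar`.
#' Hudson's estimator (Bhatia et al. parameterization) and the
#' Weir-Cockerham haploid two-population ANOVA estimator are available
#' behind `estimator`.  Estimates may be negative; clamping for the branch
#' transform happens downstream.
#'
#' @param d1,m1 derived and chromosome counts in population 1 (vectors).
#' @param d2,m2 same for population 2.
#' @param estimator `"reynolds"` (default), `"hudson"` or `"wc"`.
#' @return numeric vector of raw FST estimates (`NA` where a chromosome
#'   count is below 2).
#' @export
reynolds_fst <- function(d1, m1, d2, m2,
                         estimator = c("reynolds", "hudson", "wc")) {
  estimator <- match.arg(estimator)
  p1 <- d1 / m1
  p2 <- d2 / m2
  bad <- m1 < 2L | m2 < 2L | is.na(p1) | is.na(p2)
  fst <- switch(estimator,
    reynolds = {
      hbar <- (m1 * 2 * p1 * (1 - p1) + m2 * 2 * p2 * (1 - p2)) /
        (m1 + m2 - 2)
      a <- (p1 - p2)^2 - hbar * (m1 + m2) / (2 * m1 * m2)
      denom <- a + hbar
      ifelse(denom == 0, 0, a / denom)
    },
    hudson = {
      num <- (p1 - p2)^2 - p1 * (1 - p1) / (m1 - 1) -
        p2 * (1 - p2) / (m2 - 1)
      denom <- p1 * (1 - p2) + p2 * (1 - p1)
      ifelse(denom == 0, 0, num / denom)
    },
    wc = {
      ## haploid two-population ANOVA (r = 2)
      mbar <- (m1 + m2) / 2
      nc <- m1 + m2 - (m1^2 + m2^2) / (m1 + m2)
      pbar <- (m1 * p1 + m2 * p2) / (m1 + m2)
      msp <- m1 * (p1 - pbar)^2 + m2 * (p2 - pbar)^2
      msg <- (m1 * p1 * (1 - p1) + m2 * p2 * (1 - p2)) / (m1 + m2 - 2)
      denom <- msp + (nc - 1) * msg
      ifelse(denom == 0, 0, (msp - msg) / denom)
    })
  fst[bad] <- NA_real_
  fst
}

#' Branch transforms and PBS for one SNP (or vectors of SNPs)
#'
#' @param fst_and_meso,fst_and_amaz,fst_meso_amaz pairwise FST estimates.
#' @return data.frame with clamped branch transforms `t_and_meso`,
#'   `t_and_amaz`, `t_meso_amaz` and `pbs`.  Negative PBS is legitimate
#'   (drift concentrated off the focal branch) and is NOT clamped.
#' @export
pbs_snp <- function(fst_and_meso, fst_and_amaz, fst_meso_amaz) {
  t_am <- -log(1 - clamp_fst(fst_and_meso))
  t_aa <- -log(1 - clamp_fst(fst_and_amaz))
  t_ma <- -log(1 - clamp_fst(fst_meso_amaz))
  data.frame(t_and_meso = t_am, t_and_amaz = t_aa, t_meso_amaz = t_ma,
             pbs = (t_am + t_aa - t_ma) / 2)
}

#' Per-SNP PBS records for a genotype matrix
#'
#' Computes group-pooled allele counts, the three pairwise FSTs, branch
#' transforms and PBS for every SNP.
#'
#' @inheritParams allele_counts
#' @param estimator FST estimator, see [reynolds_fst()].
#' @return data.frame (class `pbs_records`) with one row per SNP: `id`,
#'   `chrom`, `pos`, raw FSTs, branch transforms and `pbs`.
#' @export
pbs_records <- function(gm, st, estimator = "reynolds") {
  ac <- allele_counts_by_group(gm, st)
  an <- ac$Andean; az <- ac$Amazonian; me <- ac$Mesoamerican
  if (is.null(an) || is.null(az) || is.null(me)) {
    stop("all three groups must be present to compute PBS")
  }
  f_am <- reynolds_fst(an$derived, an$chrom_n, me$derived, me$chrom_n,
                       estimator)
  f_aa <- reynolds_fst(an$derived, an$chrom_n, az$derived, az$chrom_n,
                       estimator)
  f_ma <- reynolds_fst(me$derived, me$chrom_n, az$derived, az$chrom_n,
                       estimator)
  out <- cbind(gm$variants[, c("id", "chrom", "pos")],
               data.frame(fst_and_meso = f_am, fst_and_amaz = f_aa,
                          fst_meso_amaz = f_ma),
               pbs_snp(f_am, f_aa, f_ma))
  rownames(out) <- NULL
  class(out) <- c("pbs_records", class(out))
  out
}

#' Sliding-window mean PBS
#'
#' Fixed-size windows of `window` SNPs advancing by `step` SNPs, restarted
#' at each chromosome; a trailing remainder shorter than `window` is
#' dropped.  Chromosomes with fewer than `window` SNPs yield no windows
#' (with a message).
#'
#' @param records a [pbs_records()] data.frame (must be position-sorted
#'   within chromosomes, as produced by the pipeline).
#' @param window,step window length and step in SNPs.
#' @return data.frame with one row per window: `chrom`, `start_idx`,
#'   `end_idx` (row indices into `records`), `first_id`, `last_id`,
#'   `first_pos`, `last_pos`, `mean_pbs`.
#' @export
window_scan <- function(records, window = 20L, step = 5L) {
  stopifnot(window >= 1L, step >= 1L)
  out <- list()
  for (ch in unique(records$chrom)) {
    idx <- which(records$chrom == ch)
    n <- length(idx)
    if (n < window) {
      message("chromosome ", ch, " has ", n, " SNPs (< ", window,
              "); no windows")
      next
    }
    starts <- seq.int(1L, n - window + 1L, by = step)
    mu <- vapply(starts, function(s) {
      mean(records$pbs[idx[s:(s + window - 1L)]], na.rm = TRUE)
    }, numeric(1))
    out[[ch]] <- data.frame(
      chrom = ch,
      start_idx = idx[starts], end_idx = idx[starts + window - 1L],
      first_id = records$id[idx[starts]],
      last_id = records$id[idx[starts + window - 1L]],
      first_pos = records$pos[idx[starts]],
      last_pos = records$pos[idx[starts + window - 1L]],
      mean_pbs = mu, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start_idx = integer(),
                      end_idx = integer(), first_id = character(),
                      last_id = character(), first_pos = integer(),
                      last_pos = integer(), mean_pbs = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call outlier peaks from windowed PBS
#'
#' Thresholds are empirical percentiles (type-7 linear interpolation) of the
#' window means over the whole scan.  Windows strictly above the lower tier
#' are outliers; runs of outlier windows whose SNP spans overlap or touch
#' are merged into peaks.  Each peak reports the tier of its best window and
#' the SNP with the maximum per-SNP PBS in its span.
#'
#' @param windows output of [window_scan()].
#' @param records the matching [pbs_records()].
#' @param percentiles outlier tiers, default `c(99.5, 99.9)`.
#' @param annotation optional gene annotation for nearest-gene assignment of
#'   each peak's top SNP.
#' @return list with `thresholds` (named numeric) and `peaks` (data.frame:
#'   `chrom`, `start_idx`, `end_idx`, `first_pos`, `last_pos`, `n_windows`,
#'   `max_window_pbs`, `tier`, `top_id`, `top_pos`, `top_pbs`, and `gene` /
#'   `gene_distance` when an annotation is given).
#' @export
call_peaks <- function(windows, records, percentiles = c(99.5, 99.9),
                       annotation = NULL) {
  percentiles <- sort(percentiles)
  if (nrow(windows) < 200L) {
    warning("only ", nrow(windows), " windows; the ",
            min(percentiles), "th percentile threshold is unstable")
  }
  thresholds <- stats::quantile(windows$mean_pbs, percentiles / 100,
                                names = FALSE, type = 7, na.rm = TRUE)
  names(thresholds) <- paste0("p", percentiles)
  out_w <- windows[windows$mean_pbs > thresholds[1L], , drop = FALSE]
  peaks <- list()
  if (nrow(out_w) > 0L) {
    out_w <- out_w[order(out_w$chrom, out_w$start_idx), , drop = FALSE]
    grp <- cumsum(c(TRUE, out_w$chrom[-1L] != out_w$chrom[-nrow(out_w)] |
                      out_w$start_idx[-1L] > out_w$end_idx[-nrow(out_w)] + 1L))
    for (g in unique(grp)) {
      w <- out_w[grp == g, , drop = FALSE]
      span <- seq.int(min(w$start_idx), max(w$end_idx))
      top <- span[which.max(records$pbs[span])]
      best <- max(w$mean_pbs)
      tier <- percentiles[max(which(best > thresholds | seq_along(thresholds) == 1L))]
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = w$chrom[1L], start_idx = min(w$start_idx),
        end_idx = max(w$end_idx),
        first_pos = records$pos[min(w$start_idx)],
        last_pos = records$pos[max(w$end_idx)],
        n_windows = nrow(w), max_window_pbs = best, tier = tier,
        top_id = records$id[top], top_pos = records$pos[top],
        top_pbs = records$pbs[top], stringsAsFactors = FALSE)
    }
  }
  peaks <- if (length(peaks)) do.call(rbind, peaks) else
    data.frame(chrom = character(), start_idx = integer(),
               end_idx = integer(), first_pos = integer(),
               last_pos = integer(), n_windows = integer(),
               max_window_pbs = numeric(), tier = numeric(),
               top_id = character(), top_pos = integer(),
               top_pbs = numeric())
  if (!is.null(annotation) && nrow(peaks) > 0L) {
    ga <- lapply(seq_len(nrow(peaks)), function(i) {
      assign_nearest_gene(peaks$chrom[i], peaks$top_pos[i], annotation)
    })
    peaks$gene <- vapply(ga, `[[`, character(1), "gene")
    peaks$gene_distance <- vapply(ga, `[[`, numeric(1), "distance")
  }
  list(thresholds = thresholds, peaks = peaks)
}

#' Nearest gene for a SNP position
#'
#' Distance 0 if the (1-based) position falls inside an interval; otherwise
#' the minimum bp distance to an interval boundary.  Ties are broken by the
#' smaller interval start.
#'
#' @param chrom chromosome label.
#' @param pos 1-based position.
#' @param annotation a gene annotation ([read_bed()]; 0-based half-open).
#' @return list with `gene` (name, or `"none"`) and `distance` (bp; `Inf`
#'   when the chromosome has no genes).
#' @export
assign_nearest_gene <- function(chrom, pos, annotation) {
  g <- annotation[annotation$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0L) return(list(gene = "none", distance = Inf))
  ## interval covers 1-based positions (start+1)..end
  lo <- g$start + 1L
  hi <- g$end
  dist <- ifelse(pos < lo, lo - pos, ifelse(pos > hi, pos - hi, 0L))
  best <- which(dist == min(dist))
  if (length(best) > 1L) best <- best[which.min(g$start[best])]
  list(gene = g$name[best], distance = as.numeric(min(dist)))
}
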