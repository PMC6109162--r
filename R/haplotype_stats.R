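## Extended haplotype homozygosity statistics from first principles.
##
## EHH at a flanking SNP is the probability that two randomly chosen core
## carriers are identical over the stretch from the core to that flank
## inclusive: partition the n carriers into extended-haplotype classes of
## sizes e_i and compute sum(C(e_i, 2)) / C(n, 2).  iHH integrates the EHH
## curve over physical distance (trapezoids), truncated at the first flank
## where EHH drops below a cutoff (default 0.05) and at gaps larger than
## max_gap (default 200 kb).  iHS is ln(iHH_ancestral / iHH_derived)
## standardized within derived-allele-frequency bins; XP-EHH is
## ln(iHH_test / iHH_ref) over allele-agnostic curves, standardized
## genome-wide.

#' Construct a phased haplotype set
#'
#' @param haplotypes binary matrix, haplotypes (rows) x SNPs (columns);
#'   0 = ancestral, 1 = derived.
#' @param positions strictly increasing physical positions (bp).
#' @param label population/group label.
#' @return object of class `haplotype_set`.
#' @export
haplotype_set <- function(haplotypes, positions, label = "") {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (!all(haplotypes %in% 0:1)) stop("haplotype entries must be 0/1")
  if (nrow(haplotypes) < 2L) stop("need at least 2 haplotypes")
  if (ncol(haplotypes) != length(positions)) {
    stop("positions must match the number of SNPs")
  }
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("positions must be strictly increasing")
  }
  structure(list(haplotypes = haplotypes, positions = as.numeric(positions),
                 label = label),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set:", nrow(x$haplotypes), "haplotypes x",
      ncol(x$haplotypes), "SNPs",
      if (nzchar(x$label)) paste0("(", x$label, ")"), "\n")
  invisible(x)
}

## homozygosity of a partition given class ids: sum C(e_i,2) / C(n,2)
partition_homozygosity <- function(ids) {
  n <- length(ids)
  e <- tabulate(ids)
  sum(e * (e - 1) / 2) / (n * (n - 1) / 2)
}

## refine class ids by one more SNP column; ids stay small integers
refine_ids <- function(ids, alleles) {
  key <- ids * 2L + alleles
  match(key, unique(key))
}

#' EHH at a single flanking SNP
#'
#' @param hs a [haplotype_set()].
#' @param core index of the core SNP.
#' @param allele core allele (0 ancestral, 1 derived) or `NULL` for the
#'   allele-agnostic version over all haplotypes (used by XP-EHH), in which
#'   case the core column itself participates in haplotype identity.
#' @param flank index of the flanking SNP (equal to `core` gives 1).
#' @return EHH value in \[0, 1\], or `NA` if fewer than 2 carriers.
#' @export
ehh_at <- function(hs, core, allele = 1L, flank = core) {
  h <- hs$haplotypes
  rows <- if (is.null(allele)) seq_len(nrow(h)) else
    which(h[, core] == allele)
  if (length(rows) < 2L) return(NA_real_)
  cols <- if (flank >= core) core:flank else flank:core
  if (!is.null(allele)) cols <- setdiff(cols, core)
  ids <- rep(1L, length(rows))
  for (j in cols) ids <- refine_ids(ids, h[rows, j])
  partition_homozygosity(ids)
}

#' Full EHH decay curve for one side (or both) of a core SNP
#'
#' Computed by successive partition refinement, which makes the curve
#' non-increasing by construction.  Stops early once EHH falls below
#' `stop_below` (the integration cutoff), recording that first
#' below-cutoff point.
#'
#' @inheritParams ehh_at
#' @param stop_below stop extending once EHH drops below this value
#'   (default 0, i.e. compute the full curve).
#' @return data.frame with `snp` (index), `pos`, `distance` (bp, signed),
#'   `ehh`; the core row has distance 0 and EHH 1.
#' @export
ehh_curve <- function(hs, core, allele = 1L, stop_below = 0) {
  h <- hs$haplotypes
  pos <- hs$positions
  rows <- if (is.null(allele)) seq_len(nrow(h)) else
    which(h[, core] == allele)
  if (length(rows) < 2L) {
    stop("fewer than 2 carriers of the core allele at SNP ", core)
  }
  one_side <- function(idx_seq) {
    ids <- rep(1L, length(rows))
    if (is.null(allele)) ids <- refine_ids(ids, h[rows, core])
    out_snp <- integer(0); out_ehh <- numeric(0)
    for (j in idx_seq) {
      ids <- refine_ids(ids, h[rows, j])
      e <- partition_homozygosity(ids)
      out_snp <- c(out_snp, j); out_ehh <- c(out_ehh, e)
      if (e < stop_below) break
    }
    data.frame(snp = out_snp, ehh = out_ehh)
  }
  left <- if (core > 1L) one_side((core - 1L):1L) else
    data.frame(snp = integer(0), ehh = numeric(0))
  right <- if (core < ncol(h)) one_side((core + 1L):ncol(h)) else
    data.frame(snp = integer(0), ehh = numeric(0))
  res <- rbind(left[rev(seq_len(nrow(left))), , drop = FALSE],
               data.frame(snp = core, ehh = 1),
               right)
  res$pos <- pos[res$snp]
  res$distance <- res$pos - pos[core]
  rownames(res) <- NULL
  res[, c("snp", "pos", "distance", "ehh")]
}

#' Integrated haplotype homozygosity (iHH)
#'
#' Trapezoidal integral of the EHH curve over physical distance, each side
#' truncated at the first flank where EHH drops below `cutoff` (that
#' segment is included) and at inter-SNP gaps larger than `max_gap` (that
#' segment is excluded).  If a side never decays below the cutoff before
#' the data end, the integral runs to the end and the result is flagged
#' censored.
#'
#' @param curve output of [ehh_curve()].
#' @param cutoff EHH truncation level (default 0.05).
#' @param max_gap maximum allowed inter-SNP gap in bp (default 200 kb).
#' @return list with `ihh` (bp) and logical `censored`.
#' @export
ihh <- function(curve, cutoff = 0.05, max_gap = 200000) {
  core_row <- which(curve$distance == 0)
  if (length(core_row) != 1L) stop("curve must contain the core (distance 0)")
  integrate_side <- function(rows) {
    ## rows ordered moving away from the core, starting at the core
    total <- 0; censored <- TRUE
    if (length(rows) < 2L) return(list(ihh = 0, censored = TRUE))
    for (k in 2:length(rows)) {
      a <- rows[k - 1L]; b <- rows[k]
      gap <- abs(curve$distance[b] - curve$distance[a])
      if (gap > max_gap) { censored <- FALSE; break }
      total <- total + gap * (curve$ehh[a] + curve$ehh[b]) / 2
      if (curve$ehh[b] < cutoff) { censored <- FALSE; break }
    }
    list(ihh = total, censored = censored)
  }
  left <- integrate_side(core_row:1L)
  right <- integrate_side(core_row:nrow(curve))
  list(ihh = left$ihh + right$ihh,
       censored = left$censored || right$censored)
}

## iHH for one core/allele in one pass (curve computed lazily to the cutoff)
ihh_for <- function(hs, core, allele, cutoff = 0.05, max_gap = 200000) {
  cv <- ehh_curve(hs, core, allele, stop_below = cutoff)
  ihh(cv, cutoff = cutoff, max_gap = max_gap)
}

#' Raw and standardized iHS scores
#'
#' For every polarized SNP with minor-allele frequency at least `min_maf`
#' and at least two carriers of each allele: raw
#' `iHS = ln(iHH_ancestral / iHH_derived)`; standardization subtracts the
#' mean and divides by the SD within derived-allele-frequency bins.
#'
#' @param hs a [haplotype_set()].
#' @param min_maf minimum minor-allele frequency (default 0.05).
#' @param cutoff,max_gap see [ihh()].
#' @param n_bins number of equal-width derived-frequency bins (default 20).
#' @return data.frame with `snp`, `derived_freq`, `ihh_ancestral`,
#'   `ihh_derived`, `ihs_raw`, `bin`, `ihs_std` and `skipped` reason (rows
#'   with a reason have `NA` scores).
#' @export
ihs_scores <- function(hs, min_maf = 0.05, cutoff = 0.05,
                       max_gap = 200000, n_bins = 20L) {
  h <- hs$haplotypes
  n <- nrow(h)
  freq <- colMeans(h)
  res <- data.frame(snp = seq_len(ncol(h)), derived_freq = freq,
                    ihh_ancestral = NA_real_, ihh_derived = NA_real_,
                    ihs_raw = NA_real_, skipped = "")
  for (j in seq_len(ncol(h))) {
    maf <- min(freq[j], 1 - freq[j])
    if (maf < min_maf) { res$skipped[j] <- "maf"; next }
    nd <- sum(h[, j]); na <- n - nd
    if (nd < 2L || na < 2L) { res$skipped[j] <- "carriers"; next }
    ia <- ihh_for(hs, j, 0L, cutoff, max_gap)$ihh
    id <- ihh_for(hs, j, 1L, cutoff, max_gap)$ihh
    if (ia <= 0 || id <= 0) { res$skipped[j] <- "zero_ihh"; next }
    res$ihh_ancestral[j] <- ia
    res$ihh_derived[j] <- id
    res$ihs_raw[j] <- log(ia / id)
  }
  standardize_ihs(res, n_bins)
}

#' Standardize iHS within derived-frequency bins
#'
#' Bins with fewer than `min_bin` scored SNPs are merged with their right
#' neighbor (the last group absorbs any small remainder): the bin mean and
#' SD cannot be estimated reliably from a handful of SNPs, and
#' standardizing against noisy moments injects spurious heavy tails.
#'
#' @param records data.frame with `derived_freq` and `ihs_raw`.
#' @param n_bins number of equal-width bins over (0, 1).
#' @param min_bin minimum scored SNPs per standardization stratum.
#' @return the records with `bin` (merged stratum id) and `ihs_std` columns
#'   added.
#' @export
standardize_ihs <- function(records, n_bins = 20L, min_bin = 20L) {
  raw_bin <- pmin(pmax(ceiling(records$derived_freq * n_bins), 1L), n_bins)
  scored <- !is.na(records$ihs_raw)
  counts <- vapply(seq_len(n_bins), function(b) sum(raw_bin[scored] == b),
                   integer(1))
  ## merge adjacent bins until each stratum holds >= min_bin scored SNPs
  stratum_of <- integer(n_bins)
  s <- 1L
  acc <- 0L
  for (b in seq_len(n_bins)) {
    stratum_of[b] <- s
    acc <- acc + counts[b]
    if (acc >= min_bin && b < n_bins) {
      s <- s + 1L
      acc <- 0L
    }
  }
  if (acc < min_bin && s > 1L) {
    ## fold an undersized final stratum into its left neighbor
    stratum_of[stratum_of == s] <- s - 1L
  }
  records$bin <- stratum_of[raw_bin]
  records$ihs_std <- NA_real_
  for (b in unique(records$bin[scored])) {
    sel <- records$bin == b & scored
    x <- records$ihs_raw[sel]
    sdev <- stats::sd(x)
    records$ihs_std[sel] <- if (length(x) >= 2L && sdev > 0) {
      (x - mean(x)) / sdev
    } else 0
  }
  records
}

#' Cross-population XP-EHH scores
#'
#' EHH is computed over all haplotypes at each site (allele-agnostic core)
#' separately in the test and reference populations; raw
#' `XP-EHH = ln(iHH_test / iHH_ref)` is standardized genome-wide.
#' Positive standardized values indicate extended homozygosity in the test
#' population.
#'
#' @param hs_test,hs_ref [haplotype_set()]s sharing SNPs and positions.
#' @param cutoff,max_gap see [ihh()].
#' @return data.frame with `snp`, `ihh_test`, `ihh_ref`, `xpehh_raw`,
#'   `xpehh_std` and `skipped`.
#' @export
xpehh_scores <- function(hs_test, hs_ref, cutoff = 0.05, max_gap = 200000) {
  if (!isTRUE(all.equal(hs_test$positions, hs_ref$positions))) {
    stop("test and reference sets must share SNPs and positions")
  }
  S <- ncol(hs_test$haplotypes)
  res <- data.frame(snp = seq_len(S), ihh_test = NA_real_,
                    ihh_ref = NA_real_, xpehh_raw = NA_real_,
                    skipped = "")
  for (j in seq_len(S)) {
    it <- ihh_for(hs_test, j, NULL, cutoff, max_gap)$ihh
    ir <- ihh_for(hs_ref, j, NULL, cutoff, max_gap)$ihh
    if (it <= 0 || ir <= 0) { res$skipped[j] <- "zero_ihh"; next }
    res$ihh_test[j] <- it
    res$ihh_ref[j] <- ir
    res$xpehh_raw[j] <- log(it / ir)
  }
  ok <- !is.na(res$xpehh_raw)
  mu <- mean(res$xpehh_raw[ok]); s <- stats::sd(res$xpehh_raw[ok])
  res$xpehh_std <- NA_real_
  res$xpehh_std[ok] <- if (isTRUE(s > 0)) (res$xpehh_raw[ok] - mu) / s else 0
  res
}

#' Empirical (or normal-tail) p-values for XP-EHH scores
#'
#' Default: one-sided empirical rank p, `(1 + #\{scores >= s\}) / (N + 1)`.
#' A standard-normal upper-tail alternative is available behind
#' `method = "normal"`.
#'
#' @param records output of [xpehh_scores()] (uses `xpehh_std`), or a
#'   numeric vector of scores.
#' @param method `"empirical"` or `"normal"`.
#' @return numeric vector of p-values aligned with the scores (NA scores
#'   give NA).
#' @export
xpehh_pvalue <- function(records, method = c("empirical", "normal")) {
  method <- match.arg(method)
  s <- if (is.data.frame(records)) records$xpehh_std else records
  if (method == "normal") return(stats::pnorm(s, lower.tail = FALSE))
  ok <- !is.na(s)
  N <- sum(ok)
  p <- rep(NA_real_, length(s))
  ## rank-based: p_i = (1 + #{other scores >= s_i}) / (N + 1); the max-tie
  ## rank from the top counts scores >= s_i including s_i itself
  r <- rank(-s[ok], ties.method = "max")
  p[ok] <- r / (N + 1)
  p
}
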