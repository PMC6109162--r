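## Weighted group allele frequencies, bootstrap confidence intervals and
## inverse-distance-weighted geographic frequency surfaces.

#' Sample-size-weighted mean allele frequency
#'
#' `sum(n_i * p_i) / sum(n_i)` over populations.
#'
#' @param freqs per-population allele frequencies.
#' @param sizes per-population sample sizes (same length).
#' @return the weighted mean frequency.
#' @export
weighted_group_frequency <- function(freqs, sizes) {
  if (length(freqs) == 0L) stop("no populations supplied")
  stopifnot(length(freqs) == length(sizes), all(sizes >= 1))
  sum(sizes * freqs) / sum(sizes)
}

## per-population derived-allele frequency at one SNP (missing excluded)
population_frequencies <- function(gm, st, snp, populations = NULL) {
  i <- if (is.character(snp)) match(snp, gm$variants$id) else snp
  if (is.na(i)) stop("unknown SNP: ", snp)
  pops <- populations %||% unique(st$population)
  out <- lapply(pops, function(p) {
    cols <- colnames(gm$dosages) %in% st$sample_id[st$population == p]
    d <- gm$dosages[i, cols]
    d <- d[!is.na(d)]
    data.frame(population = p, n = length(d),
               freq = if (length(d)) sum(d) / (2 * length(d)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Bootstrap confidence interval for a weighted group frequency
#'
#' Each replicate resamples individuals with replacement within each
#' population (preserving the observed per-population sample size, i.e. the
#' observed genotypic proportions are the resampling distribution), then
#' recomputes the sample-size-weighted group frequency.  The CI is the
#' 2.5th/97.5th percentile of the replicates.
#'
#' @param gm a [genotype_matrix()].
#' @param st sample table.
#' @param snp SNP id or index.
#' @param group group whose populations are resampled.
#' @param n_boot bootstrap replicates (default 10,000).
#' @param seed optional integer seed.
#' @param conf confidence level (default 0.95).
#' @return list of class `bootstrap_result`: `snp`, `group`, `mean`
#'   (observed weighted frequency), `lower`, `upper`, `n_boot`, `seed`.
#' @export
bootstrap_group_ci <- function(gm, st, snp, group, n_boot = 10000L,
                               seed = NULL, conf = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  i <- if (is.character(snp)) match(snp, gm$variants$id) else snp
  pops <- unique(st$population[st$group == group])
  if (length(pops) == 0L) stop("group has no populations: ", group)
  dos <- lapply(pops, function(p) {
    cols <- colnames(gm$dosages) %in% st$sample_id[st$population == p]
    d <- gm$dosages[i, cols]
    d[!is.na(d)]
  })
  sizes <- lengths(dos)
  if (any(sizes == 0L)) {
    pops <- pops[sizes > 0L]; dos <- dos[sizes > 0L]; sizes <- sizes[sizes > 0L]
  }
  obs <- weighted_group_frequency(
    vapply(dos, function(d) mean(d) / 2, numeric(1)), sizes)
  ## replicate matrix of weighted frequencies: resample within populations
  tot <- sum(sizes)
  reps <- numeric(n_boot)
  boot_sums <- matrix(0, nrow = n_boot, ncol = length(pops))
  for (k in seq_along(pops)) {
    idx <- matrix(sample.int(sizes[k], n_boot * sizes[k], replace = TRUE),
                  nrow = n_boot)
    boot_sums[, k] <- rowSums(matrix(dos[[k]][idx], nrow = n_boot))
  }
  ## weighted group frequency = pooled derived count / pooled chromosomes
  ## (weights n_i applied to per-population frequencies)
  reps <- rowSums(boot_sums) / (2 * tot)
  ci <- stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE, type = 7)
  structure(list(snp = gm$variants$id[i], group = group, mean = obs,
                 lower = ci[1], upper = ci[2], n_boot = n_boot,
                 seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap_result: %s / %s  mean %.4f  95%% CI [%.4f, %.4f]\n",
              x$snp, x$group, x$mean, x$lower, x$upper))
  invisible(x)
}

#' Classify populations by altitude
#'
#' The bootstrap contrast uses a 4,000 m cutoff (extreme high altitude vs
#' lowland); a 2,500 m descriptive cutoff is also in common use and can be
#' selected via `cutoff_m`.
#'
#' @param st sample table.
#' @param cutoff_m altitude cutoff in meters (default 4000).
#' @return data.frame with one row per population: `population`, `group`,
#'   `altitude_m`, `class` (`"highland"` / `"lowland"`).
#' @export
classify_altitude <- function(st, cutoff_m = 4000) {
  agg <- unique(st[, c("population", "group", "altitude_m")])
  miss <- is.na(agg$altitude_m)
  if (any(miss)) {
    warning("populations without altitude excluded: ",
            paste(agg$population[miss], collapse = ", "))
    agg <- agg[!miss, , drop = FALSE]
  }
  agg$class <- ifelse(agg$altitude_m > cutoff_m, "highland", "lowland")
  rownames(agg) <- NULL
  agg
}

#' Inverse-distance-weighted allele frequency surface
#'
#' Cell value `sum(w_i f_i) / sum(w_i)` with `w_i = d_i^(-power)` over the
#' sample points, using great-circle (haversine) distances.  A cell
#' coinciding with a sample point takes that point's value exactly, making
#' the surface an exact interpolator bounded by the sample extrema.  Only
#' populations with at least `min_n` samples contribute.
#'
#' @param points data.frame with `latitude`, `longitude`, `freq` and
#'   optionally `n` (sample size, used with `min_n`).
#' @param grid list with `lat` and `lon` axis vectors (degrees), or `NULL`
#'   for a default grid spanning the points with `n_cells` per axis.
#' @param power IDW power parameter (default 2).
#' @param min_n minimum per-point sample size (default 3).
#' @param n_cells default grid resolution per axis.
#' @return list of class `grid_surface`: `lat`, `lon` axes, `values`
#'   matrix (lat x lon), `power`, `points`.
#' @export
idw_surface <- function(points, grid = NULL, power = 2, min_n = 3L,
                        n_cells = 25L) {
  if ("n" %in% names(points)) {
    points <- points[points$n >= min_n, , drop = FALSE]
  }
  if (nrow(points) == 0L) stop("no sample points (after the min_n filter)")
  if (is.null(grid)) {
    pad <- 1
    grid <- list(
      lat = seq(min(points$latitude) - pad, max(points$latitude) + pad,
                length.out = n_cells),
      lon = seq(min(points$longitude) - pad, max(points$longitude) + pad,
                length.out = n_cells))
  }
  vals <- matrix(NA_real_, nrow = length(grid$lat), ncol = length(grid$lon))
  for (i in seq_along(grid$lat)) {
    for (j in seq_along(grid$lon)) {
      d <- geosphere::distHaversine(
        cbind(points$longitude, points$latitude),
        c(grid$lon[j], grid$lat[i]))
      hit <- which(d < 1)  # within a meter: exact interpolation
      if (length(hit)) {
        vals[i, j] <- points$freq[hit[1L]]
      } else {
        w <- d^(-power)
        vals[i, j] <- sum(w * points$freq) / sum(w)
      }
    }
  }
  structure(list(lat = grid$lat, lon = grid$lon, values = vals,
                 power = power, points = points),
            class = "grid_surface")
}

#' Flatten a grid surface to a (lat, lon, value) raster table
#'
#' @param surface a `grid_surface`.
#' @return data.frame with columns `latitude`, `longitude`, `value`.
#' @export
surface_to_raster <- function(surface) {
  data.frame(latitude = rep(surface$lat, times = length(surface$lon)),
             longitude = rep(surface$lon, each = length(surface$lat)),
             value = as.vector(surface$values))
}

#' Per-population and group frequency table for selected SNPs
#'
#' The layout mirrors a per-locus frequency report: one row per population
#' with its sample size and derived-allele frequency per SNP, plus one
#' weighted-average row per group.
#'
#' @param gm a [genotype_matrix()].
#' @param st sample table.
#' @param snps SNP ids or indices.
#' @return data.frame with `population`, `group`, `n` and one frequency
#'   column per SNP (group totals have population `"Total"`).
#' @export
frequency_table <- function(gm, st, snps) {
  ids <- if (is.character(snps)) snps else gm$variants$id[snps]
  rows <- list()
  for (g in unique(st$group)) {
    sub <- st[st$group == g, , drop = FALSE]
    pops <- unique(sub$population)
    per_pop <- lapply(ids, function(s) {
      population_frequencies(gm, st, s, populations = pops)
    })
    block <- data.frame(population = pops, group = g,
                        n = per_pop[[1L]]$n, stringsAsFactors = FALSE)
    for (k in seq_along(ids)) block[[ids[k]]] <- per_pop[[k]]$freq
    tot <- data.frame(population = "Total", group = g,
                      n = sum(per_pop[[1L]]$n), stringsAsFactors = FALSE)
    for (k in seq_along(ids)) {
      pp <- per_pop[[k]]
      ok <- !is.na(pp$freq) & pp$n > 0
      tot[[ids[k]]] <- weighted_group_frequency(pp$freq[ok], pp$n[ok])
    }
    rows[[g]] <- rbind(block, tot)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
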