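## Data model and readers/writers for the scan's standard formats.
##
## A `genotype_matrix` couples a variant table (chrom, pos, id, ancestral and
## derived alleles) with a variants x samples dosage matrix counting copies
## of the DERIVED allele (0/1/2, NA = missing).  Polarization happens at read
## time from the AA INFO tag (or a TSV override); records that cannot be
## polarized keep ALT-counted dosages and are flagged `polarized = FALSE`
## so haplotype statistics that need ancestral/derived labels can drop them
## while PBS keeps them.

#' Construct a genotype matrix
#'
#' @param variants data.frame with columns `chrom`, `pos`, `id`,
#'   `ancestral_allele`, `derived_allele` and logical `polarized`.
#' @param dosages integer matrix (variants x samples) of derived-allele
#'   dosages in `{0, 1, 2, NA}`; rownames are variant ids, colnames sample
#'   ids.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(variants, dosages) {
  stopifnot(is.data.frame(variants), nrow(variants) == nrow(dosages))
  req <- c("chrom", "pos", "id", "ancestral_allele", "derived_allele")
  if (!all(req %in% names(variants))) {
    stop("variant table must have columns: ", paste(req, collapse = ", "))
  }
  if (!"polarized" %in% names(variants)) variants$polarized <- TRUE
  if (anyDuplicated(variants$id)) stop("variant ids must be unique")
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("positions must be strictly increasing within chromosome ", ch)
    }
  }
  bad <- !is.na(dosages) & !(dosages %in% 0:2)
  if (any(bad)) stop("dosages must be in {0, 1, 2, NA}")
  dosages <- matrix(as.integer(dosages), nrow = nrow(dosages),
                    dimnames = list(variants$id, colnames(dosages)))
  structure(list(variants = variants, dosages = dosages),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$variants), "SNPs x",
      ncol(x$dosages), "samples;",
      sum(!x$variants$polarized), "unpolarized\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

## subset SNPs by logical/integer index, keeping variants and dosages in step
subset_snps <- function(gm, keep) {
  genotype_matrix(gm$variants[keep, , drop = FALSE],
                  gm$dosages[keep, , drop = FALSE])
}

#' Read biallelic SNP genotypes from a VCF file
#'
#' Parses a VCF (via vcfR), keeps biallelic SNP records, and polarizes
#' genotypes to derived-allele dosages using the `AA` INFO tag or an optional
#' ancestral-allele override table.  If the ancestral allele equals REF the
#' dosage is the ALT count; if it equals ALT the dosage is `2 - ALT count`.
#' Records without a usable ancestral assignment keep ALT-counted dosages and
#' are flagged `polarized = FALSE` (branch-length statistics such as PBS are
#' unaffected by polarization; iHS drops these records).
#'
#' @param path path to a VCF (v4.x) file.
#' @param ancestral optional data.frame (or TSV path) with columns `id` and
#'   `ancestral_allele`, overriding the AA tag.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, ancestral = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "") |
    nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L
  multi[is.na(multi)] <- TRUE
  if (any(multi)) {
    warning(sum(multi), " non-biallelic-SNP record(s) skipped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- fix[!multi, , drop = FALSE]
  gt <- gt[!multi, , drop = FALSE]
  if (nrow(fix) == 0L) stop("no biallelic SNP records in ", path)

  ## ALT allele count from diploid GT strings; anything else is missing
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  ok <- !is.na(gt) & nchar(gt) >= 3L &
    (a1 == "0" | a1 == "1") & (a2 == "0" | a2 == "1")
  alt_count <- (a1 == "1") + (a2 == "1")
  alt_count[!ok] <- NA
  alt_count <- matrix(as.integer(alt_count), nrow = nrow(fix),
                      dimnames = dimnames(gt))

  aa <- toupper(vcfR::extract.info(v, "AA")[!multi])
  if (!is.null(ancestral)) {
    if (is.character(ancestral)) {
      ancestral <- utils::read.delim(ancestral, stringsAsFactors = FALSE)
    }
    stopifnot(all(c("id", "ancestral_allele") %in% names(ancestral)))
    m <- match(fix$ID, ancestral$id)
    aa[!is.na(m)] <- toupper(ancestral$ancestral_allele[m[!is.na(m)]])
  }

  ref <- toupper(fix$REF); alt <- toupper(fix$ALT)
  pol_ref <- !is.na(aa) & aa == ref   # derived = ALT, dosage = ALT count
  pol_alt <- !is.na(aa) & aa == alt   # derived = REF, dosage = 2 - ALT count
  dos <- alt_count
  if (any(pol_alt)) {
    dos[pol_alt, ] <- 2L - alt_count[pol_alt, , drop = FALSE]
  }
  polarized <- pol_ref | pol_alt
  anc <- ifelse(polarized, aa, ref)
  der <- ifelse(pol_alt, ref, alt)

  id <- fix$ID
  if (any(is.na(id) | id == ".")) {
    fill <- is.na(id) | id == "."
    id[fill] <- paste0(fix$CHROM[fill], "_", fix$POS[fill])
  }
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         id = id, ancestral_allele = anc,
                         derived_allele = der, polarized = polarized,
                         stringsAsFactors = FALSE)
  genotype_matrix(variants, dos)
}

#' Write a genotype matrix to a plain-text VCF
#'
#' Emits VCF v4.2 with REF = ancestral allele, ALT = derived allele, an `AA`
#' INFO tag, and unphased diploid genotypes, so `read_vcf()` round-trips
#' dosages exactly.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_vcf <- function(gm, path) {
  v <- gm$variants
  gt <- matrix(c("0/0", "0/1", "1/1")[gm$dosages + 1L], nrow = nrow(v))
  gt[is.na(gm$dosages)] <- "./."
  samples <- colnames(gm$dosages) %||% paste0("S", seq_len(ncol(gm$dosages)))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=andescan",
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(v$chrom, v$pos, v$id, v$ancestral_allele, v$derived_allele,
                ".", "PASS", paste0("AA=", v$ancestral_allele), "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read and validate the sample table
#'
#' @param path TSV with columns `sample_id`, `population`, `group`,
#'   `latitude`, `longitude`, `altitude_m`.
#' @return a validated data.frame of class `sample_table`.
#' @export
read_sample_table <- function(path) {
  st <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_sample_table(st)
}

#' Validate a sample table held in memory
#'
#' @param st data.frame with the sample-table columns (see
#'   [read_sample_table()]).
#' @return the validated data.frame with class `sample_table` prepended.
#' @export
as_sample_table <- function(st) {
  req <- c("sample_id", "population", "group", "latitude", "longitude",
           "altitude_m")
  if (nrow(st) == 0L) stop("sample table is empty")
  if (!all(req %in% names(st))) {
    stop("sample table must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(st$sample_id)) {
    stop("duplicated sample_id: ",
         paste(unique(st$sample_id[duplicated(st$sample_id)]), collapse = ", "))
  }
  bad <- !(st$group %in% GROUPS)
  if (any(bad)) {
    stop("unknown group label(s) in rows ",
         paste(which(bad), collapse = ", "), ": ",
         paste(unique(st$group[bad]), collapse = ", "),
         " (allowed: ", paste(GROUPS, collapse = ", "), ")")
  }
  if (any(!is.na(st$altitude_m) & st$altitude_m < 0)) {
    stop("altitude_m must be >= 0")
  }
  class(st) <- unique(c("sample_table", class(st)))
  st
}

group_samples <- function(st, group) st$sample_id[st$group == group]

#' Per-SNP derived-allele and chromosome counts for one group
#'
#' Missing genotypes shrink the chromosome count SNP-wise (standard
#' array-data practice): the chromosome count is twice the number of
#' non-missing samples in the group.
#'
#' @param gm a [genotype_matrix()].
#' @param st a sample table.
#' @param group one of `"Andean"`, `"Amazonian"`, `"Mesoamerican"`.
#' @return data.frame with columns `id`, `derived`, `chrom_n` and logical
#'   `all_missing`.
#' @export
allele_counts <- function(gm, st, group) {
  if (!group %in% st$group) stop("group not present in sample table: ", group)
  cols <- colnames(gm$dosages) %in% group_samples(st, group)
  d <- gm$dosages[, cols, drop = FALSE]
  derived <- as.integer(rowSums(d, na.rm = TRUE))
  chrom_n <- as.integer(2L * rowSums(!is.na(d)))
  data.frame(id = gm$variants$id, derived = derived, chrom_n = chrom_n,
             all_missing = chrom_n == 0L, stringsAsFactors = FALSE)
}

## counts for all three groups at once: list of data.frames keyed by group
allele_counts_by_group <- function(gm, st) {
  grps <- GROUPS[GROUPS %in% unique(st$group)]
  stats::setNames(lapply(grps, function(g) allele_counts(gm, st, g)), grps)
}

#' Keep SNPs polymorphic in at least two of the three groups
#'
#' The scan's inclusion rule: a SNP is retained iff its derived-allele
#' frequency is strictly between 0 and 1 in two or more of the population
#' groups.  Idempotent.
#'
#' @inheritParams allele_counts
#' @return the filtered [genotype_matrix()].
#' @export
filter_polymorphic <- function(gm, st) {
  grps <- unique(st$group)
  for (g in grps) {
    if (sum(st$group == g) == 0L) stop("group with zero samples: ", g)
  }
  seg <- vapply(grps, function(g) {
    ac <- allele_counts(gm, st, g)
    ac$derived > 0L & ac$derived < ac$chrom_n
  }, logical(nrow(gm$variants)))
  subset_snps(gm, rowSums(seg) >= 2L)
}

#' Read a BED gene annotation
#'
#' BED is 0-based half-open; positions elsewhere in the package are 1-based.
#' Conversion happens at this boundary only.
#'
#' @param path BED file with at least 4 columns (chrom, start, end, name).
#' @return data.frame of class `gene_annotation`, sorted by (chrom, start),
#'   with 0-based half-open `start`/`end`.
#' @export
read_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 4L) stop("BED must have at least 4 columns")
  bed <- bed[, 1:4]
  names(bed) <- c("chrom", "start", "end", "name")
  as_gene_annotation(bed)
}

#' Validate an in-memory gene annotation
#'
#' @param bed data.frame with columns `chrom`, `start`, `end`, `name`
#'   (0-based half-open intervals).
#' @return the sorted, validated data.frame.
#' @export
as_gene_annotation <- function(bed) {
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(bed)))
  if (any(bed$start >= bed$end)) stop("BED intervals need start < end")
  bed <- bed[order(bed$chrom, bed$start), , drop = FALSE]
  rownames(bed) <- NULL
  class(bed) <- unique(c("gene_annotation", class(bed)))
  bed
}

write_bed <- function(bed, path) {
  utils::write.table(bed[, c("chrom", "start", "end", "name")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
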