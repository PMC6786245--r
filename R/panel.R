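#' Construct a table of SNP site metadata
#'
#' Sites are 1-based physical positions on named chromosomes with exactly two
#' allele labels; `allele1` plays the role of the VCF ALT allele and codes as
#' 1 in haplotype/dosage matrices.
#'
#' @param chrom character vector of chromosome labels.
#' @param pos integer vector of 1-based positions (bp).
#' @param site_id character vector of site identifiers.
#' @param allele0,allele1 allele labels (REF/ALT).
#' @return A `data.frame` with columns `chrom`, `pos`, `site_id`, `allele0`,
#'   `allele1`, validated so that positions are strictly increasing within
#'   each chromosome.
#' @export
site_info <- function(chrom, pos, site_id = NULL,
                      allele0 = "A", allele1 = "C") {
  n <- length(pos)
  if (is.null(site_id)) site_id <- paste0(chrom, "_", pos)
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   site_id = as.character(site_id),
                   allele0 = rep_len(as.character(allele0), n),
                   allele1 = rep_len(as.character(allele1), n),
                   stringsAsFactors = FALSE)
  if (any(df$pos < 1L)) stop("site positions must be >= 1")
  for (ch in unique(df$chrom)) {
    p <- df$pos[df$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  df
}

#' Construct a phased haplotype panel
#'
#' The central substrate for haplotype statistics: a 0/1 allele matrix with
#' one row per haplotype (two consecutive rows per diploid sample) and one
#' column per site. Missing alleles are not allowed -- inputs are assumed
#' fully phased.
#'
#' @param alleles integer matrix in \{0,1\}, `2 * length(samples)` rows,
#'   `nrow(sites)` columns. Rows `2k-1` and `2k` are the two haplotypes of
#'   sample `k`.
#' @param samples character vector of unique sample ids.
#' @param sample_pop named character vector mapping every sample id to a
#'   population label.
#' @param sites site table as returned by [site_info()].
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(alleles, samples, sample_pop, sites) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) %% 2L != 0L) stop("haplotype count must be even")
  if (nrow(alleles) != 2L * length(samples))
    stop("expected exactly 2 haplotype rows per sample")
  if (ncol(alleles) != nrow(sites))
    stop("allele matrix has ", ncol(alleles), " columns but ", nrow(sites),
         " sites")
  if (anyNA(alleles) || !all(alleles == 0L | alleles == 1L))
    stop("panel alleles must all be 0 or 1 (no missing after phasing)")
  if (anyDuplicated(samples)) stop("duplicated sample ids")
  sample_pop <- sample_pop[samples]
  if (anyNA(sample_pop))
    stop("every sample needs a population label; missing: ",
         paste(samples[is.na(sample_pop)], collapse = ", "))
  structure(list(alleles = alleles, samples = as.character(samples),
                 sample_pop = stats::setNames(as.character(sample_pop),
                                              samples),
                 sites = sites),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel:", nrow(x$alleles), "haplotypes (",
      length(x$samples), "samples ) x", nrow(x$sites), "sites;",
      "populations:", paste(sort(unique(x$sample_pop)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of haplotypes / sites in a panel
#' @param panel a `haplotype_panel`.
#' @return integer count.
#' @export
n_haplotypes <- function(panel) nrow(panel$alleles)

#' @rdname n_haplotypes
#' @export
n_sites <- function(panel) nrow(panel$sites)

#' Construct a genotype dosage matrix
#'
#' Dosages count copies of `allele1` (the ALT allele) per sample and site:
#' 0, 1, 2 or `NA` for a missing genotype. This is the substrate for the
#' genotype-level QC filters and summaries.
#'
#' @param dosage numeric matrix (`n_samples` x `n_sites`) with values in
#'   \{0, 1, 2, NA\}.
#' @inheritParams haplotype_panel
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, samples, sample_pop, sites) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) != length(samples))
    stop("dosage must have one row per sample")
  if (ncol(dosage) != nrow(sites)) stop("dosage/site dimension mismatch")
  ok <- dosage %in% c(0L, 1L, 2L) | is.na(dosage)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  if (anyDuplicated(samples)) stop("duplicated sample ids")
  sample_pop <- sample_pop[samples]
  if (anyNA(sample_pop)) stop("every sample needs a population label")
  structure(list(dosage = dosage, samples = as.character(samples),
                 sample_pop = stats::setNames(as.character(sample_pop),
                                              samples),
                 sites = sites),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage),
      "sites;", sum(is.na(x$dosage)), "missing genotypes\n")
  invisible(x)
}

#' Collapse a phased panel to genotype dosages
#'
#' Each sample's dosage at a site is the sum of its two haplotype alleles.
#'
#' @param panel a `haplotype_panel`.
#' @return A `genotype_matrix` with no missing entries.
#' @export
as_genotype_matrix <- function(panel) {
  h <- panel$alleles
  odd <- seq(1L, nrow(h), by = 2L)
  genotype_matrix(h[odd, , drop = FALSE] + h[odd + 1L, , drop = FALSE],
                  panel$samples, panel$sample_pop, panel$sites)
}

#' Restrict a panel to the samples of one population
#'
#' @param panel a `haplotype_panel`.
#' @param pop a population label present in `panel$sample_pop`.
#' @return A `haplotype_panel` holding exactly the haplotypes of samples
#'   labelled `pop`; the site list is unchanged.
#' @export
subset_by_population <- function(panel, pop) {
  keep <- which(panel$sample_pop == pop)
  if (length(keep) == 0L)
    stop("unknown population: ", pop)
  hap_rows <- as.vector(rbind(2L * keep - 1L, 2L * keep))
  haplotype_panel(panel$alleles[hap_rows, , drop = FALSE],
                  panel$samples[keep], panel$sample_pop[keep], panel$sites)
}

#' Restrict a genotype matrix to one population
#' @inheritParams subset_by_population
#' @param genotypes a `genotype_matrix`.
#' @return A `genotype_matrix` for the samples of `pop`.
#' @export
subset_genotypes_by_population <- function(genotypes, pop) {
  keep <- which(genotypes$sample_pop == pop)
  if (length(keep) == 0L) stop("unknown population: ", pop)
  genotype_matrix(genotypes$dosage[keep, , drop = FALSE],
                  genotypes$samples[keep], genotypes$sample_pop[keep],
                  genotypes$sites)
}

#' Restrict a panel or genotype matrix to a subset of site columns
#' @param x a `haplotype_panel` or `genotype_matrix`.
#' @param idx integer vector of site column indices to keep (in order).
#' @return Object of the same class restricted to those sites.
#' @export
subset_sites <- function(x, idx) {
  idx <- as.integer(idx)
  sites <- x$sites[idx, , drop = FALSE]
  rownames(sites) <- NULL
  if (inherits(x, "haplotype_panel")) {
    haplotype_panel(x$alleles[, idx, drop = FALSE], x$samples,
                    x$sample_pop, sites)
  } else if (inherits(x, "genotype_matrix")) {
    genotype_matrix(x$dosage[, idx, drop = FALSE], x$samples,
                    x$sample_pop, sites)
  } else stop("unsupported class")
}

#' Per-site ALT allele frequency of a genotype matrix
#' @param genotypes a `genotype_matrix`.
#' @return numeric vector of allele-1 frequencies over non-missing genotypes.
#' @export
allele_frequency <- function(genotypes) {
  colMeans(genotypes$dosage, na.rm = TRUE) / 2
}

#' Per-site minor allele frequency
#' @inheritParams allele_frequency
#' @return numeric vector, `pmin(p, 1 - p)`.
#' @export
minor_allele_frequency <- function(genotypes) {
  p <- allele_frequency(genotypes)
  pmin(p, 1 - p)
}
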