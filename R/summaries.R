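#' Per-population heterozygosity summary
#'
#' Per SNP and population: observed heterozygosity `H_O` (fraction of
#' non-missing genotypes that are heterozygous) and expected heterozygosity
#' `H_E = 2 p (1 - p)` with `p` the sample allele frequency. An optional
#' small-sample correction `2n/(2n-1)` can be applied to `H_E`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param populations populations to summarize (default: all present).
#' @param unbiased apply the `2n/(2n-1)` correction to `H_E` (default
#'   `FALSE`).
#' @return A list of per-population summaries, each with `population`,
#'   per-SNP vectors `ho` and `he`, and `mean_ho`, `sd_ho`, `mean_he`,
#'   `sd_he`; plus class `diversity_summary`.
#' @export
heterozygosity_summary <- function(genotypes,
                                   populations = NULL, unbiased = FALSE) {
  if (is.null(populations))
    populations <- sort(unique(genotypes$sample_pop))
  missing_pop <- setdiff(populations, genotypes$sample_pop)
  if (length(missing_pop))
    stop("population(s) absent: ", paste(missing_pop, collapse = ", "))
  out <- lapply(populations, function(pop) {
    g <- subset_genotypes_by_population(genotypes, pop)
    d <- g$dosage
    ho <- colMeans(d == 1L, na.rm = TRUE)
    p <- colMeans(d, na.rm = TRUE) / 2
    he <- 2 * p * (1 - p)
    if (unbiased) {
      n2 <- 2 * colSums(!is.na(d))
      he <- he * n2 / pmax(n2 - 1, 1)
    }
    list(population = pop, ho = ho, he = he,
         mean_ho = mean(ho, na.rm = TRUE), sd_ho = stats::sd(ho[!is.na(ho)]),
         mean_he = mean(he, na.rm = TRUE), sd_he = stats::sd(he[!is.na(he)]))
  })
  names(out) <- populations
  class(out) <- "diversity_summary"
  out
}

#' @export
print.diversity_summary <- function(x, ...) {
  for (s in x)
    cat(sprintf("%s: H_O = %.3f +/- %.3f, H_E = %.3f +/- %.3f\n",
                s$population, s$mean_ho, s$sd_ho, s$mean_he, s$sd_he))
  invisible(x)
}

#' Kruskal-Wallis comparison of per-SNP statistics across populations
#'
#' Rank-based H with tie correction and a chi-square p-value on `k - 1`
#' degrees of freedom (wraps `stats::kruskal.test`). Degenerate input where
#' every value is identical across all groups returns `H = 0, p = 1`.
#'
#' @param groups list of >= 2 non-empty numeric vectors (e.g. per-SNP `H_O`
#'   by population).
#' @return List with `H`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(lengths(groups) > 0L))
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1L)
    return(list(H = 0, df = length(groups) - 1L, p_value = 1))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Squared dosage correlation between two loci
#'
#' Composite LD: the squared Pearson correlation of genotype dosages over
#' jointly non-missing samples (the operation PLINK-style `r2` performs on
#' unphased genotypes).
#'
#' @param x,y dosage vectors of equal length.
#' @return `r2` in `[0, 1]`, or `NA` if either locus is constant among the
#'   jointly non-missing samples.
#' @export
genotype_r2 <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])^2
}

#' Binned LD-decay profile for one population
#'
#' `r2` is computed for every within-chromosome SNP pair (optionally capped
#' at `max_dist_kb`), assigned to contiguous distance bins of `bin_kb` kb
#' starting at 0, and averaged per bin. Pairs with undefined `r2`
#' (a constant locus) are excluded.
#'
#' @param genotypes a [genotype_matrix()] with sites sorted by position
#'   within chromosome.
#' @param population population label.
#' @param bin_kb bin width in kb (default 100).
#' @param max_dist_kb optional maximum pair distance in kb.
#' @return A `data.frame` with `bin_lo_kb`, `bin_hi_kb`, `mean_r2`,
#'   `n_pairs`; attribute `population`.
#' @export
ld_decay_profile <- function(genotypes, population, bin_kb = 100,
                             max_dist_kb = NULL) {
  g <- subset_genotypes_by_population(genotypes, population)
  bin_bp <- bin_kb * 1000
  dist_all <- numeric(0)
  r2_all <- numeric(0)
  for (ch in unique(g$sites$chrom)) {
    idx <- which(g$sites$chrom == ch)
    if (length(idx) < 2L) next
    d <- g$dosage[, idx, drop = FALSE]
    pos <- g$sites$pos[idx]
    r2m <- suppressWarnings(
      stats::cor(d, use = "pairwise.complete.obs"))^2
    dm <- abs(outer(pos, pos, "-"))
    ut <- upper.tri(r2m)
    keep <- ut & is.finite(r2m)
    if (!is.null(max_dist_kb)) keep <- keep & dm <= max_dist_kb * 1000
    dist_all <- c(dist_all, dm[keep])
    r2_all <- c(r2_all, r2m[keep])
  }
  if (length(r2_all) == 0L) {
    out <- data.frame(bin_lo_kb = numeric(0), bin_hi_kb = numeric(0),
                      mean_r2 = numeric(0), n_pairs = integer(0))
  } else {
    bin <- floor(dist_all / bin_bp)
    nb <- max(bin) + 1L
    cnt <- tabulate(bin + 1L, nbins = nb)
    sums <- vapply(seq_len(nb) - 1L,
                   function(b) sum(r2_all[bin == b]), numeric(1))
    out <- data.frame(bin_lo_kb = (seq_len(nb) - 1L) * bin_kb,
                      bin_hi_kb = seq_len(nb) * bin_kb,
                      mean_r2 = ifelse(cnt > 0, sums / cnt, NA_real_),
                      n_pairs = cnt)
  }
  attr(out, "population") <- population
  out
}

#' PCA of a genotype matrix
#'
#' Missing dosages are mean-imputed per SNP, columns are centered (and
#' optionally scaled by `sqrt(p(1-p))`), and the SVD taken; per-component
#' variance fractions are squared singular values over their total.
#'
#' @param genotypes a [genotype_matrix()] with >= 2 samples and >= 2 SNPs.
#' @param n_components number of components to return (default
#'   `min(n_samples, n_sites)`).
#' @param scale_freq divide each centered column by `sqrt(p(1-p))`
#'   (default `FALSE`).
#' @return List with `scores` (samples x components), `loadings`,
#'   `var_explained` (fractions, non-increasing), `populations`.
#' @export
pca_genotypes <- function(genotypes, n_components = NULL,
                          scale_freq = FALSE) {
  d <- genotypes$dosage
  stopifnot(nrow(d) >= 2L, ncol(d) >= 2L)
  storage.mode(d) <- "double"
  mu <- colMeans(d, na.rm = TRUE)
  for (j in which(colSums(is.na(d)) > 0L)) d[is.na(d[, j]), j] <- mu[j]
  x <- sweep(d, 2L, mu)
  if (scale_freq) {
    p <- mu / 2
    s <- sqrt(pmax(p * (1 - p), .Machine$double.eps))
    x <- sweep(x, 2L, s, "/")
  }
  if (all(abs(x) < .Machine$double.eps)) stop("zero-variance matrix")
  sv <- svd(x)
  k <- if (is.null(n_components)) length(sv$d) else
    min(n_components, length(sv$d))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  rownames(scores) <- genotypes$samples
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores,
       loadings = sv$v[, seq_len(k), drop = FALSE],
       var_explained = sv$d^2 / sum(sv$d^2),
       populations = genotypes$sample_pop)
}
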