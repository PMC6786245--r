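#' @name qc_filters
#' @title Marker and sample quality-control filters
#' @description Call-rate, minor-allele-frequency, Hardy-Weinberg and
#'   LD-pruning filters over a [genotype_matrix()]. Each filter returns the
#'   filtered matrix together with a `filter_report` recording stage name,
#'   input/output counts, removed ids and the threshold used.
NULL

.filter_report <- function(stage, n_in, n_out, removed, threshold,
                           cap = 200L) {
  stopifnot(n_out <= n_in, n_in - n_out == length(removed))
  list(stage = stage, n_in = n_in, n_out = n_out,
       removed = utils::head(removed, cap), n_removed = length(removed),
       threshold = threshold)
}

#' Filter on genotype call rate
#'
#' SNPs with call rate below `snp_min` are removed first; then samples with
#' call rate below `sample_min`, evaluated on the surviving SNPs.
#'
#' @param genotypes a [genotype_matrix()] (may contain missing dosages).
#' @param snp_min minimum per-SNP call rate (default 0.95).
#' @param sample_min minimum per-sample call rate (default 0.90).
#' @return List: `genotypes` (filtered) and `reports` (one per stage).
#' @export
filter_call_rate <- function(genotypes, snp_min = 0.95, sample_min = 0.90) {
  d <- genotypes$dosage
  snp_cr <- colMeans(!is.na(d))
  keep_snp <- snp_cr >= snp_min
  if (!any(keep_snp)) stop("all SNPs removed by call-rate filter")
  r1 <- .filter_report("snp_call_rate", ncol(d), sum(keep_snp),
                       genotypes$sites$site_id[!keep_snp], snp_min)
  g <- subset_sites(genotypes, which(keep_snp))
  sam_cr <- rowMeans(!is.na(g$dosage))
  keep_sam <- sam_cr >= sample_min
  if (!any(keep_sam)) stop("all samples removed by call-rate filter")
  r2 <- .filter_report("sample_call_rate", length(keep_sam), sum(keep_sam),
                       g$samples[!keep_sam], sample_min)
  g <- genotype_matrix(g$dosage[keep_sam, , drop = FALSE],
                       g$samples[keep_sam], g$sample_pop[keep_sam], g$sites)
  list(genotypes = g, reports = list(r1, r2))
}

#' Filter on minor allele frequency
#'
#' Retains SNPs with MAF strictly greater than `min_maf`. With
#' `scope = "pooled"` the frequency is computed on the combined sample;
#' with `scope = "each"` the MAF requirement must hold in every population
#' separately.
#'
#' @param genotypes a [genotype_matrix()].
#' @param min_maf exclusive MAF floor (default 0.05).
#' @param scope `"pooled"` or `"each"`.
#' @return List: `genotypes`, `report`.
#' @export
filter_maf <- function(genotypes, min_maf = 0.05,
                       scope = c("pooled", "each")) {
  scope <- match.arg(scope)
  if (ncol(genotypes$dosage) == 0L) stop("empty genotype matrix")
  if (scope == "pooled") {
    keep <- minor_allele_frequency(genotypes) > min_maf
  } else {
    keep <- rep(TRUE, ncol(genotypes$dosage))
    for (pop in unique(genotypes$sample_pop)) {
      gp <- subset_genotypes_by_population(genotypes, pop)
      keep <- keep & (minor_allele_frequency(gp) > min_maf)
    }
  }
  rep_ <- .filter_report(paste0("maf_", scope), length(keep), sum(keep),
                         genotypes$sites$site_id[!keep], min_maf)
  list(genotypes = subset_sites(genotypes, which(keep)), report = rep_)
}

#' Hardy-Weinberg exact test
#'
#' Exact two-sided p-value for deviation from Hardy-Weinberg proportions:
#' conditional on the observed allele counts, the number of heterozygotes
#' follows a hypergeometric-type distribution; the p-value is the summed
#' probability of all heterozygote counts no more probable than the observed
#' one. Monomorphic sites return `p = 1` by convention.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total >= 1).
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("need at least one genotype")
  n_A <- 2L * n_AA + n_Aa
  n_a <- 2L * n_aa + n_Aa
  if (n_A == 0L || n_a == 0L) return(1.0)
  rare <- min(n_A, n_a)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # log P(het = h | n, n_A) up to a common constant:
  #   log n! - log n_AA! - log h! - log n_aa! + h log 2
  homA <- (n_A - hets) %/% 2L
  homa <- (n_a - hets) %/% 2L
  lp <- hets * log(2) - lfactorial(homA) - lfactorial(hets) -
    lfactorial(homa)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Hardy-Weinberg filter over a genotype matrix
#'
#' Applies [hwe_exact_test()] per SNP on pooled genotype counts and removes
#' SNPs with p below `p_min`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param p_min exact-test p-value cutoff (default 1e-6).
#' @return List: `genotypes`, `report`.
#' @export
filter_hwe <- function(genotypes, p_min = 1e-6) {
  d <- genotypes$dosage
  p <- vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    hwe_exact_test(sum(x == 0L, na.rm = TRUE), sum(x == 1L, na.rm = TRUE),
                   sum(x == 2L, na.rm = TRUE))
  }, numeric(1))
  keep <- p >= p_min
  rep_ <- .filter_report("hwe_exact", length(keep), sum(keep),
                         genotypes$sites$site_id[!keep], p_min)
  list(genotypes = subset_sites(genotypes, which(keep)), report = rep_,
       p_values = p)
}

#' Greedy sliding-window LD pruning
#'
#' Within each window of `window_snps` surviving SNPs, while any pair has
#' squared dosage correlation above `r2_max`, the member of the worst
#' (highest-r2) pair with the lower MAF is removed (tie: the later
#' position). Windows advance by `step` SNPs. The result has no surviving
#' within-window pair with r2 above the threshold.
#'
#' @param genotypes a [genotype_matrix()] with >= 2 SNPs.
#' @param r2_max maximum tolerated r2 (default 0.4).
#' @param window_snps window size in SNPs (default 50).
#' @param step window advance in SNPs (default 5).
#' @return List: `genotypes`, `report`.
#' @export
ld_prune <- function(genotypes, r2_max = 0.4, window_snps = 50L, step = 5L) {
  d <- genotypes$dosage
  L <- ncol(d)
  if (L < 2L) stop("need >= 2 SNPs to prune")
  maf <- minor_allele_frequency(genotypes)
  alive <- rep(TRUE, L)
  chrom <- genotypes$sites$chrom
  prune_window <- function(win) {
    # greedily remove one member of the worst pair until no pair exceeds
    # r2_max; returns indices removed
    gone <- integer(0)
    while (length(win) >= 2L) {
      r2 <- suppressWarnings(
        stats::cor(d[, win, drop = FALSE],
                   use = "pairwise.complete.obs"))^2
      r2[!is.finite(r2)] <- 0
      diag(r2) <- 0
      worst <- max(r2)
      if (worst <= r2_max) break
      hit <- which(r2 == worst, arr.ind = TRUE)
      hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE][1L, ]
      i <- win[hit[1L]]; j <- win[hit[2L]]
      # drop the lower-MAF member; tie -> later position
      drop <- if (maf[i] < maf[j]) i else if (maf[j] < maf[i]) j else
        max(i, j)
      gone <- c(gone, drop)
      win <- setdiff(win, drop)
    }
    gone
  }
  # windows slide over the surviving SNPs; repeat whole passes until a pass
  # removes nothing, so the pruned set is a fixpoint
  repeat {
    removed_any <- FALSE
    surv <- which(alive)
    anchor <- 1L
    while (anchor <= length(surv)) {
      win <- surv[anchor:min(anchor + window_snps - 1L, length(surv))]
      win <- win[alive[win] & chrom[win] == chrom[win[1L]]]
      gone <- prune_window(win)
      if (length(gone)) {
        alive[gone] <- FALSE
        removed_any <- TRUE
      }
      anchor <- anchor + step
    }
    if (!removed_any) break
  }
  rep_ <- .filter_report("ld_prune", L, sum(alive),
                         genotypes$sites$site_id[!alive], r2_max)
  list(genotypes = subset_sites(genotypes, which(alive)), report = rep_)
}
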