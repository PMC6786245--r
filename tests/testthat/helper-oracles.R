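# Fixture builders and independent brute-force oracles. Oracles are written
# against the definitions, not the package internals, so they stay
# independent of the code paths they check.

# small deterministic panel: n_hap haplotypes x L sites on one chromosome
toy_panel <- function(alleles, pos = NULL, chrom = "1",
                      pops = NULL) {
  alleles <- as.matrix(alleles)
  n_hap <- nrow(alleles)
  stopifnot(n_hap %% 2 == 0)
  L <- ncol(alleles)
  if (is.null(pos)) pos <- seq_len(L) * 10000L
  samples <- paste0("s", seq_len(n_hap %/% 2))
  if (is.null(pops)) pops <- rep("popA", length(samples))
  haplotype_panel(alleles, samples,
                  stats::setNames(pops, samples),
                  site_info(rep(chrom, L), pos))
}

make_geno <- function(dosage, pops = NULL, pos = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage); L <- ncol(dosage)
  samples <- paste0("s", seq_len(n))
  if (is.null(pops)) pops <- rep("A", n)
  if (is.null(pos)) pos <- seq_len(L) * 1000L
  genotype_matrix(dosage, samples, stats::setNames(pops, samples),
                  site_info(rep("1", L), pos))
}

random_panel <- function(n_hap, L, seed, maf_lo = 0.1) {
  set.seed(seed)
  f <- runif(L, maf_lo, 1 - maf_lo)
  alle <- matrix(rbinom(n_hap * L, 1, rep(f, each = n_hap)), n_hap, L)
  toy_panel(alle, pos = sort(sample.int(5e6, L)))
}

# Brute-force EHH on one side: for each marker outward, hash the full
# core-to-marker allele strings of the carriers and count identical pairs.
ehh_oracle_side <- function(alleles, core, carriers, dir) {
  L <- ncol(alleles)
  n <- length(carriers)
  denom <- choose(n, 2)
  idx <- if (dir > 0) seq(core + 1L, L) else rev(seq_len(core - 1L))
  if (core + dir < 1 || core + dir > L) return(numeric(0))
  vapply(seq_along(idx), function(k) {
    span <- if (dir > 0) core:(core + k) else (core - k):core
    key <- apply(alleles[carriers, span, drop = FALSE], 1, paste,
                 collapse = "")
    sum(choose(table(key), 2)) / denom
  }, numeric(1))
}

# truncate an oracle side the way the profile reports it: stop after the
# first value below the cutoff
truncate_side <- function(e, cutoff) {
  below <- which(e < cutoff)
  if (length(below)) e[seq_len(below[1])] else e
}

# exact Hardy-Weinberg p-value by full enumeration of heterozygote counts,
# probabilities from plain factorials
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_A <- 2 * n_AA + n_Aa
  if (n_A == 0 || n_A == 2 * n) return(1)
  hets <- seq(n_A %% 2, min(n_A, 2 * n - n_A), by = 2)
  pr <- vapply(hets, function(h) {
    aa <- (n_A - h) / 2
    bb <- n - aa - h
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
          h * log(2))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[hets == n_Aa]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# all-pairs LD decay computed naively from first principles
ld_profile_oracle <- function(geno, population, bin_kb = 100) {
  keep <- names(geno$sample_pop)[geno$sample_pop == population]
  d <- geno$dosage[match(keep, geno$samples), , drop = FALSE]
  res <- list()
  for (ch in unique(geno$sites$chrom)) {
    j <- which(geno$sites$chrom == ch)
    for (x in seq_along(j)) for (y in seq_along(j)) {
      if (x >= y) next
      a <- d[, j[x]]; b <- d[, j[y]]
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < 2 || var(a[ok]) == 0 || var(b[ok]) == 0) next
      res[[length(res) + 1L]] <-
        c(dist = abs(geno$sites$pos[j[x]] - geno$sites$pos[j[y]]),
          r2 = cor(a[ok], b[ok])^2)
    }
  }
  if (!length(res)) return(NULL)
  m <- do.call(rbind, res)
  bin <- floor(m[, "dist"] / (bin_kb * 1000))
  tapply(m[, "r2"], bin, mean)
}

write_lines_vcf <- function(body_lines, samples = c("s1", "s2")) {
  f <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t"),
               body_lines), f)
  f
}
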