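#' Assemble a per-site scan result
#'
#' Common container for the three scans (iHS, XP-EHH, F_ST outlier): one row
#' per site with the raw score, the standardized score, a -log10 p-value (or
#' posterior quantity on the same column), and a validity flag with a reason
#' code for sites the statistic could not be computed at.
#'
#' @param test one of `"iHS"`, `"XP-EHH"`, `"FST-outlier"`.
#' @param population population label, or `"obs/ref"` pair label for
#'   two-population tests.
#' @param sites site table ([site_info()]).
#' @param raw,standardized,neglog10_p numeric vectors (NA where invalid).
#' @param valid logical vector.
#' @param reason character reason codes for invalid sites ("" where valid).
#' @return A `scan_result`: a `data.frame` with columns `chrom`, `pos`,
#'   `site_id`, `raw`, `standardized`, `neglog10_p`, `valid`, `reason` and
#'   attributes `test` and `population`.
#' @export
scan_result <- function(test, population, sites, raw, standardized,
                        neglog10_p, valid, reason = NULL) {
  test <- match.arg(test, c("iHS", "XP-EHH", "FST-outlier"))
  n <- nrow(sites)
  if (is.null(reason)) reason <- ifelse(valid, "", "invalid")
  stopifnot(length(raw) == n, length(standardized) == n,
            length(neglog10_p) == n, length(valid) == n)
  if (any(neglog10_p[valid] < 0, na.rm = TRUE))
    stop("neglog10_p must be >= 0 where valid")
  if (any(valid & !is.na(reason) & nzchar(reason)))
    reason[valid] <- ""
  if (any(!valid & !nzchar(reason)))
    stop("invalid sites must carry a reason code")
  out <- data.frame(chrom = sites$chrom, pos = sites$pos,
                    site_id = sites$site_id, raw = raw,
                    standardized = standardized, neglog10_p = neglog10_p,
                    valid = valid, reason = reason,
                    stringsAsFactors = FALSE)
  attr(out, "test") <- test
  attr(out, "population") <- population
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Region container for candidate selected intervals
#'
#' @param population population (or contrast) label.
#' @param chrom chromosome.
#' @param start,end 1-based positions of the outermost significant SNPs.
#' @param n_sig_snps number of significant SNPs in the region (>= 2).
#' @param peak_score maximum |standardized score| in the region.
#' @param peak_neglog10p maximum -log10 p in the region.
#' @return A `data.frame` with one row per region, including `size_kb`
#'   computed by [region_size_kb()].
#' @export
region_table <- function(population, chrom, start, end, n_sig_snps,
                         peak_score, peak_neglog10p) {
  if (any(end < start)) stop("region end < start")
  if (any(n_sig_snps < 2L)) stop("regions need n_sig_snps >= 2")
  data.frame(population = population, chrom = chrom,
             start = as.integer(start), end = as.integer(end),
             n_sig_snps = as.integer(n_sig_snps),
             peak_score = peak_score, peak_neglog10p = peak_neglog10p,
             size_kb = region_size_kb(start, end),
             stringsAsFactors = FALSE)
}
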