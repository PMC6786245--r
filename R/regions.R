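#' Region size in kb, 1 decimal
#'
#' `(end - start) / 1000` rounded half-away-from-zero to one decimal (the
#' convention the region tables print).
#'
#' @param start,end 1-based positions, `end >= start` (vectorized).
#' @return Size in kb with 1 decimal.
#' @export
region_size_kb <- function(start, end) {
  if (any(end < start)) stop("end < start")
  floor((end - start) / 100 + 0.5) / 10
}

#' Select significant sites from a scan result
#'
#' iHS / XP-EHH rule: `-log10 p >= threshold` (default 3, i.e.
#' p <= 0.001). For XP-EHH the call can be restricted by sign of the
#' standardized score: positive scores point to selection in the observed
#' population, negative scores to the reference.
#'
#' @param result a [scan_result()].
#' @param threshold minimum `-log10 p` (inclusive; default 3).
#' @param sign `"both"` (default), `"positive"`, or `"negative"`.
#' @return A `data.frame` of significant sites sorted by (chrom, pos) with
#'   columns `chrom`, `pos`, `site_id`, `standardized`, `neglog10_p`.
#' @export
call_significant <- function(result, threshold = 3,
                             sign = c("both", "positive", "negative")) {
  sign <- match.arg(sign)
  df <- as.data.frame(result)
  keep <- df$valid & df$neglog10_p >= threshold
  if (sign == "positive") keep <- keep & df$standardized > 0
  if (sign == "negative") keep <- keep & df$standardized < 0
  out <- df[keep, c("chrom", "pos", "site_id", "standardized",
                    "neglog10_p")]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select significant loci from the F_ST outlier posterior
#'
#' Directional-selection rule: posterior odds `PO >= po_min` (default 32)
#' AND posterior mean alpha > 0.
#'
#' @param summary a [posterior_summaries()] result.
#' @param po_min posterior-odds threshold (default 32).
#' @return A `data.frame` of significant loci sorted by (chrom, pos), with
#'   `standardized` set to the posterior mean alpha and `neglog10_p` to
#'   `-log10 q` (q floored at one posterior error unit).
#' @export
call_significant_fst <- function(summary, po_min = 32) {
  df <- summary$loci
  keep <- df$PO >= po_min & !is.na(df$alpha_mean) & df$alpha_mean > 0
  out <- df[keep, , drop = FALSE]
  qfloor <- 0.5 / summary$n_samples
  out <- data.frame(chrom = out$chrom, pos = out$pos,
                    site_id = out$site_id, standardized = out$alpha_mean,
                    neglog10_p = -log10(pmax(out$q, qfloor)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster significant SNPs into candidate regions
#'
#' Within a chromosome, consecutive significant SNPs at most `max_gap_bp`
#' apart (inclusive) chain into one cluster; clusters with at least
#' `min_snps` SNPs become regions bounded by their outermost significant
#' SNPs, with peak statistics taken over the cluster.
#'
#' @param sig significant-site `data.frame` from [call_significant()] or
#'   [call_significant_fst()], sorted by (chrom, pos).
#' @param population population or contrast label for the output.
#' @param max_gap_bp maximum inter-SNP gap (default 500000).
#' @param min_snps minimum SNPs per region (default 2).
#' @return A region `data.frame` ([region_table()]); empty if no cluster
#'   qualifies.
#' @export
cluster_regions <- function(sig, population = "pop",
                            max_gap_bp = 500000, min_snps = 2L) {
  empty <- region_table(character(0), character(0), integer(0),
                        integer(0), integer(0), numeric(0), numeric(0))
  if (nrow(sig) == 0L) return(empty)
  sig <- sig[order(sig$chrom, sig$pos), , drop = FALSE]
  new_cluster <- c(TRUE, sig$chrom[-1L] != sig$chrom[-nrow(sig)] |
                     diff(sig$pos) > max_gap_bp)
  cl <- cumsum(new_cluster)
  keep <- as.vector(table(cl)) >= min_snps
  ids <- unique(cl)[keep]
  if (length(ids) == 0L) return(empty)
  rows <- lapply(ids, function(k) {
    sub <- sig[cl == k, , drop = FALSE]
    region_table(population, sub$chrom[1L], min(sub$pos), max(sub$pos),
                 nrow(sub), max(abs(sub$standardized)),
                 max(sub$neglog10_p))
  })
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Merge overlapping or bookended regions
#'
#' Regions on the same chromosome whose intervals overlap or touch
#' (`end >= next start`) are merged; the merged region sums `n_sig_snps`
#' and takes the maximum peak statistics. Idempotent; output is sorted and
#' non-overlapping.
#'
#' @param regions region `data.frame`, sorted by (chrom, start).
#' @return Merged region `data.frame`.
#' @export
merge_regions <- function(regions) {
  if (nrow(regions) <= 1L) return(regions)
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  out <- regions[1L, , drop = FALSE]
  for (k in 2L:nrow(regions)) {
    r <- regions[k, ]
    last <- nrow(out)
    if (r$chrom == out$chrom[last] && out$end[last] >= r$start) {
      out$end[last] <- max(out$end[last], r$end)
      out$n_sig_snps[last] <- out$n_sig_snps[last] + r$n_sig_snps
      out$peak_score[last] <- max(out$peak_score[last], r$peak_score)
      out$peak_neglog10p[last] <- max(out$peak_neglog10p[last],
                                      r$peak_neglog10p)
      out$size_kb[last] <- region_size_kb(out$start[last], out$end[last])
    } else {
      out <- rbind(out, r)
    }
  }
  rownames(out) <- NULL
  out
}
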