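#' Read a phased VCF into a haplotype panel
#'
#' Parses a VCF (via vcfR) and keeps biallelic SNP records whose genotypes
#' are fully phased (`"|"` separator) and non-missing in every sample.
#' Multiallelic records, non-SNP alleles, and records with any unphased or
#' missing genotype are skipped and tallied in a skip report. Records that
#' repeat an already-seen position on the same chromosome are skipped with a
#' warning (haplotype statistics require strictly increasing positions).
#'
#' @param path path to a VCF 4.x file (plain or gzipped).
#' @param sample_pop optional named character vector mapping sample id to
#'   population label; defaults to a single population `"pop1"`.
#' @return A list with elements `panel` (a [haplotype_panel()]) and
#'   `skip_report` (named integer vector with counts for `multiallelic`,
#'   `non_snp`, `unphased_or_missing`, `duplicate_position`).
#' @export
read_phased_vcf <- function(path, sample_pop = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))  # single-record VCFs come back as a bare vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  if (is.null(fix) || nrow(fix) == 0L) stop("no parsable records in ", path)
  gt <- v@gt
  samples <- colnames(gt)[-1L]
  if (anyDuplicated(samples))
    stop("duplicated sample ids in VCF: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))

  # first colon-separated field of each genotype entry
  gt_field <- sub(":.*$", "", gt[, -1L, drop = FALSE])

  skip <- c(multiallelic = 0L, non_snp = 0L, unphased_or_missing = 0L,
            duplicate_position = 0L)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  skip["multiallelic"] <- sum(multi)
  snp <- !multi & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  skip["non_snp"] <- sum(!snp & !multi)
  phased <- rowSums(matrix(grepl("^[01]\\|[01]$", gt_field),
                           nrow = nrow(gt_field))) == length(samples)
  skip["unphased_or_missing"] <- sum(snp & !phased)
  keep <- which(snp & phased)

  chrom <- fix[keep, "CHROM"]; pos <- as.integer(fix[keep, "POS"])
  dup <- duplicated(paste(chrom, pos))
  if (any(dup)) {
    warning(sum(dup), " record(s) at duplicated positions skipped")
    skip["duplicate_position"] <- sum(dup)
    keep <- keep[!dup]; chrom <- chrom[!dup]; pos <- pos[!dup]
  }
  if (length(keep) == 0L) stop("no phased biallelic SNP records in ", path)

  gk <- gt_field[keep, , drop = FALSE]
  # haplotype matrix: 2 rows per sample, sites as columns
  h1 <- matrix(as.integer(substr(gk, 1L, 1L)), nrow = length(keep))
  h2 <- matrix(as.integer(substr(gk, 3L, 3L)), nrow = length(keep))
  alle <- matrix(0L, nrow = 2L * length(samples), ncol = length(keep))
  alle[seq(1L, nrow(alle), 2L), ] <- t(h1)
  alle[seq(2L, nrow(alle), 2L), ] <- t(h2)

  ids <- fix[keep, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(chrom, "_", pos)[is.na(ids) | ids == "."]
  sites <- site_info(chrom, pos, ids, fix[keep, "REF"], fix[keep, "ALT"])
  if (is.null(sample_pop))
    sample_pop <- stats::setNames(rep("pop1", length(samples)), samples)
  list(panel = haplotype_panel(alle, samples, sample_pop, sites),
       skip_report = skip)
}

#' Write a haplotype panel as a plain-text phased VCF
#'
#' Minimal deterministic VCF 4.2 serializer (uncompressed text) used for
#' round-trip tests and pipeline output; genotypes are written as phased
#' `"h1|h2"` calls.
#'
#' @param panel a [haplotype_panel()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=haplosweep",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$samples), collapse = "\t")),
             con)
  h <- panel$alleles
  odd <- seq(1L, nrow(h), 2L)
  gt <- matrix(paste0(h[odd, , drop = FALSE], "|", h[odd + 1L, , drop = FALSE]),
               nrow = length(odd))  # samples x sites
  s <- panel$sites
  lines <- paste(s$chrom, s$pos, s$site_id, s$allele0, s$allele1, ".",
                 "PASS", ".", "GT",
                 apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a sample-to-population map
#'
#' Two-column tab-separated file `(sample_id, population)`; a header row is
#' detected (and dropped) when its first field looks like a column name
#' (`sample`, `id`, `indiv`..., case-insensitive). Exact duplicate rows are
#' deduplicated with a warning; the same sample mapped to two different
#' populations is an error.
#'
#' @param path path to the TSV file.
#' @return Named character vector `sample id -> population`, with an
#'   attribute `small_pops`: populations with fewer than 2 samples.
#' @export
read_pop_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "#")
  if (ncol(df) < 2L) stop("population map needs two tab-separated columns")
  if (grepl("^(sample|id|indiv|animal)", df[1L, 1L], ignore.case = TRUE) &&
      grepl("^(pop|group|strain)", df[1L, 2L], ignore.case = TRUE))
    df <- df[-1L, , drop = FALSE]
  if (nrow(df) == 0L) stop("empty population map")
  key <- paste(df[[1L]], df[[2L]], sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate sample rows deduplicated in population map")
    df <- df[!duplicated(key), , drop = FALSE]
  }
  if (anyDuplicated(df[[1L]])) {
    bad <- unique(df[[1L]][duplicated(df[[1L]])])
    stop("sample(s) mapped to conflicting populations: ",
         paste(bad, collapse = ", "))
  }
  map <- stats::setNames(df[[2L]], df[[1L]])
  tab <- table(map)
  small <- names(tab)[tab < 2L]
  if (length(small))
    warning("population(s) with < 2 samples: ", paste(small, collapse = ", "))
  attr(map, "small_pops") <- small
  map
}

#' Write a scan result as a TSV table
#'
#' One row per site with a fixed column order
#' (`chrom, pos, site_id, raw, standardized, neglog10_p, valid, reason`);
#' score fields of invalid sites are left empty and the reason code is kept.
#'
#' @param result a [scan_result()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_table <- function(result, path) {
  df <- as.data.frame(result)
  num <- function(x) ifelse(is.na(x), "", formatC(x, digits = 6, format = "g"))
  out <- data.frame(chrom = df$chrom, pos = df$pos, site_id = df$site_id,
                    raw = num(ifelse(df$valid, df$raw, NA)),
                    standardized = num(ifelse(df$valid, df$standardized, NA)),
                    neglog10_p = num(ifelse(df$valid, df$neglog10_p, NA)),
                    valid = df$valid, reason = df$reason,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write candidate regions as a BED file
#'
#' Intervals are converted from the internal 1-based inclusive convention to
#' BED's 0-based half-open convention (`start - 1`, `end`). The name field is
#' `pop|test|n_sig|size_kb`; the score field is `peak_neglog10p * 100` capped
#' at 1000.
#'
#' @param regions region table ([region_table()]), sorted by (chrom, start).
#' @param path output path.
#' @param test test label recorded in the name field.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path, test = "scan") {
  if (nrow(regions) > 0L) {
    o <- order(regions$chrom, regions$start)
    if (!identical(o, seq_len(nrow(regions))))
      stop("regions must be sorted by (chrom, start)")
    name <- paste(regions$population, test, regions$n_sig_snps,
                  regions$size_kb, sep = "|")
    score <- pmin(round(regions$peak_neglog10p * 100), 1000)
    lines <- paste(regions$chrom, regions$start - 1L, regions$end, name,
                   score, sep = "\t")
  } else lines <- character(0)
  writeLines(lines, path)
  invisible(path)
}
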