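#' Configuration for haplotype scans
#'
#' Tunable parameters shared by [ihs_scan()] and [xpehh_scan()].
#'
#' @param maf_min minor-allele-frequency floor; sites with MAF at or below
#'   it are not scored (default 0.05, the array-data convention).
#' @param ehh_cutoff EHH level at which haplotype integration stops
#'   (default 0.05).
#' @param freq_bin_width width of the minor-allele-frequency bins used to
#'   standardize iHS (default 0.025).
#' @param min_snps_per_bin bins with fewer scored sites are merged with the
#'   neighbouring bin before standardization (default 10).
#' @param max_extension_bp optional cap on how far EHH profiles extend from
#'   the core; a side that hits the cap before decaying below `ehh_cutoff`
#'   is treated like one that hit the chromosome end (site invalid).
#' @param one_sided if `TRUE`, p-values use the upper-tail convention
#'   `-log10(1 - Phi(|z|))` instead of the default two-sided form.
#' @return A list of class `ihs_config`.
#' @export
ihs_config <- function(maf_min = 0.05, ehh_cutoff = 0.05,
                       freq_bin_width = 0.025, min_snps_per_bin = 10,
                       max_extension_bp = NULL, one_sided = FALSE) {
  stopifnot(ehh_cutoff > 0, ehh_cutoff < 1,
            freq_bin_width > 0, freq_bin_width <= 0.5)
  structure(list(maf_min = maf_min, ehh_cutoff = ehh_cutoff,
                 freq_bin_width = freq_bin_width,
                 min_snps_per_bin = min_snps_per_bin,
                 max_extension_bp = max_extension_bp,
                 one_sided = one_sided),
            class = "ihs_config")
}

#' Extended haplotype homozygosity profile around a core site
#'
#' EHH at marker t (on one side of the core) is the probability that two
#' randomly chosen carrier haplotypes are identical at every marker from the
#' core out to t inclusive: partition the carriers by their allele vector
#' over that span and compute `sum_g C(k_g,2) / C(n,2)`. The profile is
#' computed marker by marker outward on each side until EHH falls below
#' `ehh_cutoff` or the chromosome (or `max_extension_bp`) ends.
#'
#' @param panel a [haplotype_panel()].
#' @param core site column index of the core SNP.
#' @param target `0` or `1` to anchor on carriers of that allele at the
#'   core, or `"site"` to use all haplotypes (site-EHH, as in XP-EHH).
#' @param ehh_cutoff,max_extension_bp see [ihs_config()].
#' @return An `ehh_profile`: list with `core`, `core_pos`, `chrom`,
#'   `target`, `n_carriers`, per-side lists (`left`, `right`) holding marker
#'   indices, positions, EHH values and truncation flags (`reached_cutoff`,
#'   `hit_end`), plus `valid`/`reason`.
#' @export
ehh_profile <- function(panel, core, target = "site", ehh_cutoff = 0.05,
                        max_extension_bp = NULL) {
  sites <- panel$sites
  stopifnot(core >= 1, core <= nrow(sites))
  chrom <- sites$chrom[core]
  core_pos <- sites$pos[core]
  if (identical(target, "site")) {
    carriers <- seq_len(nrow(panel$alleles))
  } else {
    stopifnot(target %in% c(0L, 1L))
    carriers <- which(panel$alleles[, core] == target)
  }
  out <- list(core = core, core_pos = core_pos, chrom = chrom,
              target = target, n_carriers = length(carriers))
  if (length(carriers) < 2L) {
    out$valid <- FALSE
    out$reason <- "mono/insufficient carriers"
    class(out) <- "ehh_profile"
    return(out)
  }
  on_chrom <- which(sites$chrom == chrom)
  lo <- min(on_chrom); hi <- max(on_chrom)
  if (!is.null(max_extension_bp)) {
    ok <- on_chrom[abs(sites$pos[on_chrom] - core_pos) <= max_extension_bp]
    lo <- min(ok); hi <- max(ok)
  }
  side <- function(dir) {
    r <- cpp_ehh_side(panel$alleles, core, carriers, dir, ehh_cutoff, lo, hi)
    list(idx = as.integer(r$cols), pos = sites$pos[as.integer(r$cols)],
         ehh = as.numeric(r$ehh), reached_cutoff = isTRUE(r$reached_cutoff),
         hit_end = !isTRUE(r$reached_cutoff))
  }
  out$left <- side(-1L)
  out$right <- side(1L)
  out$valid <- TRUE
  out$reason <- ""
  class(out) <- "ehh_profile"
  out
}

#' @export
print.ehh_profile <- function(x, ...) {
  cat("ehh_profile: core", x$core, "(", x$chrom, ":", x$core_pos, ") target",
      format(x$target), "with", x$n_carriers, "carriers\n")
  if (x$valid)
    cat("  left:", length(x$left$ehh), "markers; right:",
        length(x$right$ehh), "markers\n")
  else cat("  invalid:", x$reason, "\n")
  invisible(x)
}

# Trapezoid area of one side down to the interpolated cutoff crossing.
# Returns NA if the side never decays below the cutoff.
.ihh_side <- function(pos, ehh, core_pos, cutoff) {
  d <- abs(pos - core_pos)
  e <- ehh
  prev_d <- 0; prev_e <- 1
  area <- 0
  for (k in seq_along(e)) {
    if (e[k] < cutoff) {
      # linear interpolation to the point where EHH = cutoff
      dd <- (d[k] - prev_d) * (prev_e - cutoff) / (prev_e - e[k])
      area <- area + (prev_e + cutoff) / 2 * dd
      return(area)
    }
    area <- area + (prev_e + e[k]) / 2 * (d[k] - prev_d)
    prev_d <- d[k]; prev_e <- e[k]
  }
  NA_real_
}

#' Integrate an EHH profile into iHH
#'
#' Trapezoid integration of EHH against physical distance from the core,
#' outward on each side, truncated at the linearly interpolated point where
#' EHH crosses `cutoff`; the two sides are summed. A side that hits the
#' chromosome end (or extension cap) before decaying below the cutoff makes
#' the result invalid (`"uncapped decay"`) -- an unbounded integral is not
#' comparable across sites.
#'
#' @param profile an [ehh_profile()].
#' @param cutoff integration cutoff (default 0.05; must match the cutoff the
#'   profile was computed with or be larger).
#' @return List with `ihh` (bp x EHH units, or `NA`), `valid`, `reason`.
#' @export
integrate_ehh <- function(profile, cutoff = 0.05) {
  if (!profile$valid)
    return(list(ihh = NA_real_, valid = FALSE, reason = profile$reason))
  a_l <- .ihh_side(profile$left$pos, profile$left$ehh, profile$core_pos,
                   cutoff)
  a_r <- .ihh_side(profile$right$pos, profile$right$ehh, profile$core_pos,
                   cutoff)
  if (is.na(a_l) || is.na(a_r))
    return(list(ihh = NA_real_, valid = FALSE, reason = "uncapped decay"))
  list(ihh = a_l + a_r, valid = TRUE, reason = "")
}

#' Map a standardized score to -log10 p under the normal null
#'
#' Default is the two-sided form `-log10(2 * (1 - Phi(|z|)))`, computed on
#' the log scale (`pnorm(..., log.p = TRUE)`) so far tails do not suffer
#' `1 - CDF` cancellation. A one-sided upper-tail variant is available.
#'
#' @param z finite standardized score(s).
#' @param one_sided use `-log10(1 - Phi(|z|))` instead.
#' @return `-log10 p`, same length as `z`.
#' @export
neglog10_p_from_z <- function(z, one_sided = FALSE) {
  if (any(!is.finite(z))) stop("non-finite standardized score")
  lp <- stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE)
  if (!one_sided) lp <- lp + log(2)
  pmax(0, -lp / log(10))
}

# iHH for one allele class at a core site; returns list(ihh, valid, reason)
.site_ihh <- function(panel, core, target, config) {
  pr <- ehh_profile(panel, core, target, config$ehh_cutoff,
                    config$max_extension_bp)
  integrate_ehh(pr, config$ehh_cutoff)
}

#' Within-population iHS scan
#'
#' For each site with minor-allele frequency above `maf_min`, the raw score
#' is `ln(iHH_major / iHH_minor)`: the log ratio of integrated EHH anchored
#' on the major (taken as a proxy for the ancestral state) versus the minor
#' allele. Raw scores are standardized to z-scores within
#' minor-allele-frequency bins (width `freq_bin_width`, small bins merged),
#' and `-log10 p` is attached via [neglog10_p_from_z()]. A frequency tie at
#' exactly 0.5 resolves the major allele to allele 0 (REF).
#'
#' @param panel a single-population [haplotype_panel()].
#' @param config an [ihs_config()].
#' @return A [scan_result()] with `test = "iHS"`.
#' @export
ihs_scan <- function(panel, config = ihs_config()) {
  L <- n_sites(panel)
  f1 <- colMeans(panel$alleles)
  maf <- pmin(f1, 1 - f1)
  raw <- rep(NA_real_, L)
  valid <- rep(FALSE, L)
  reason <- rep("", L)
  for (s in seq_len(L)) {
    if (maf[s] <= config$maf_min) {
      reason[s] <- "maf_below_min"
      next
    }
    major <- if (f1[s] > 0.5) 1L else 0L  # tie at 0.5 -> allele 0
    ih_major <- .site_ihh(panel, s, major, config)
    ih_minor <- .site_ihh(panel, s, 1L - major, config)
    if (!ih_major$valid || !ih_minor$valid) {
      reason[s] <- if (!ih_major$valid) ih_major$reason else ih_minor$reason
      next
    }
    raw[s] <- log(ih_major$ihh / ih_minor$ihh)
    valid[s] <- TRUE
  }
  std <- .standardize_by_maf_bin(raw, maf, valid, config)
  bad_bin <- valid & is.na(std)
  valid[bad_bin] <- FALSE
  reason[bad_bin] <- "bin_too_small"
  nlp <- rep(NA_real_, L)
  nlp[valid] <- neglog10_p_from_z(std[valid], config$one_sided)
  pop <- unique(panel$sample_pop)
  scan_result("iHS", if (length(pop) == 1L) pop else "mixed", panel$sites,
              raw, std, nlp, valid, reason)
}

# z-standardization of raw scores within MAF bins; returns NA for sites
# whose (merged) bin has < 2 scored members.
.standardize_by_maf_bin <- function(raw, maf, valid, config) {
  std <- rep(NA_real_, length(raw))
  if (!any(valid)) return(std)
  bin <- pmin(floor(maf / config$freq_bin_width),
              floor(0.5 / config$freq_bin_width)) + 1L
  bin[!valid] <- NA
  present <- sort(unique(bin[valid]))
  counts <- vapply(present, function(b) sum(bin == b, na.rm = TRUE),
                   integer(1))
  # merge undersized bins with the better-populated adjacent bin
  groups <- as.list(present)
  while (length(groups) > 1L) {
    sizes <- vapply(groups, function(g) sum(counts[match(g, present)]),
                    numeric(1))
    k <- which(sizes < config$min_snps_per_bin)
    if (length(k) == 0L) break
    k <- k[which.min(sizes[k])]
    nb <- c(if (k > 1L) k - 1L, if (k < length(groups)) k + 1L)
    nb <- nb[which.max(sizes[nb])]
    groups[[min(k, nb)]] <- c(groups[[min(k, nb)]], groups[[max(k, nb)]])
    groups[[max(k, nb)]] <- NULL
  }
  for (g in groups) {
    idx <- which(valid & bin %in% g)
    if (length(idx) < 2L) next
    m <- mean(raw[idx]); s <- stats::sd(raw[idx])
    if (s > 0) std[idx] <- (raw[idx] - m) / s
  }
  std
}

#' Cross-population XP-EHH scan
#'
#' For each shared site, site-EHH (all haplotypes) is integrated in the
#' observed and the reference population; the raw score is
#' `ln(I_obs / I_ref)`. Raw scores are standardized genome-wide and mapped
#' to `-log10 p`. Positive standardized scores point to selection in the
#' observed population, negative scores to the reference population.
#'
#' @param panel_obs,panel_ref single-population [haplotype_panel()]s over
#'   the identical site list.
#' @param config an [ihs_config()] (`maf_min` applies to the pooled MAF).
#' @return A [scan_result()] with `test = "XP-EHH"` and population label
#'   `"obs/ref"`.
#' @export
xpehh_scan <- function(panel_obs, panel_ref, config = ihs_config()) {
  if (!identical(panel_obs$sites[c("chrom", "pos")],
                 panel_ref$sites[c("chrom", "pos")]))
    stop("panels must share an identical site list")
  L <- n_sites(panel_obs)
  n_o <- nrow(panel_obs$alleles); n_r <- nrow(panel_ref$alleles)
  f_pool <- (colSums(panel_obs$alleles) + colSums(panel_ref$alleles)) /
    (n_o + n_r)
  maf <- pmin(f_pool, 1 - f_pool)
  raw <- rep(NA_real_, L)
  valid <- rep(FALSE, L)
  reason <- rep("", L)
  for (s in seq_len(L)) {
    if (maf[s] <= config$maf_min) {
      reason[s] <- "maf_below_min"
      next
    }
    i_o <- .site_ihh(panel_obs, s, "site", config)
    i_r <- .site_ihh(panel_ref, s, "site", config)
    if (!i_o$valid || !i_r$valid) {
      reason[s] <- if (!i_o$valid) i_o$reason else i_r$reason
      next
    }
    raw[s] <- log(i_o$ihh / i_r$ihh)
    valid[s] <- TRUE
  }
  std <- rep(NA_real_, L)
  if (sum(valid) >= 2L) {
    m <- mean(raw[valid]); s0 <- stats::sd(raw[valid])
    if (s0 > 0) std[valid] <- (raw[valid] - m) / s0
  }
  bad <- valid & is.na(std)
  valid[bad] <- FALSE
  reason[bad] <- "degenerate_standardization"
  nlp <- rep(NA_real_, L)
  nlp[valid] <- neglog10_p_from_z(std[valid], config$one_sided)
  po <- unique(panel_obs$sample_pop); pr <- unique(panel_ref$sample_pop)
  lab <- paste0(if (length(po) == 1L) po else "obs", "/",
                if (length(pr) == 1L) pr else "ref")
  scan_result("XP-EHH", lab, panel_obs$sites, raw, std, nlp, valid, reason)
}
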