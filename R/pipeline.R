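#' Default pipeline configuration
#'
#' Returns the fully populated default configuration for
#' [run_full_pipeline()]; pass overrides as a (possibly nested) list or a
#' YAML file with the same keys. Either `input` (paths `vcf` + `pop_map`)
#' or `simulation` must be supplied.
#'
#' @param ... top-level overrides merged over the defaults.
#' @return A nested configuration list.
#' @export
pipeline_config <- function(...) {
  base <- list(
    seed = 1L,
    input = NULL,          # list(vcf =, pop_map =)
    simulation = NULL,     # list(sweep = <sweep_spec args>,
                           #      inject = list(carrier_fraction, taper_bp,
                           #                    populations))
    contrasts = list(),    # list of list(obs =, ref =)
    ihs_populations = NULL,  # default: all populations
    stages = list(diversity = TRUE, ld_decay = TRUE, pca = TRUE,
                  ihs = TRUE, xpehh = TRUE, bayescan = TRUE,
                  regions = TRUE),
    scan_filter = list(maf_min = 0.05, scope = "pooled"),
    structure_filter = list(maf_min = 0.05, hwe_p_min = 1e-6,
                            r2_max = 0.4, window_snps = 50, step = 5),
    thresholds = list(neglog10p_min = 3, po_min = 32,
                      max_gap_bp = 500000, min_snps = 2),
    ehh = list(maf_min = 0.05, ehh_cutoff = 0.05, freq_bin_width = 0.025,
               min_snps_per_bin = 10),
    mcmc = list(burn_in = 5000, iterations = 10000, thinning = 10,
                prior_odds = 10))
  ov <- list(...)
  # one-level merge: named sub-lists are merged key-wise, anything else
  # (including unnamed lists such as `contrasts`) replaces the default
  for (nm in names(ov)) {
    b <- base[[nm]]; v <- ov[[nm]]
    base[[nm]] <- if (is.list(b) && is.list(v) && length(v) &&
                        !is.null(names(v)) && all(nzchar(names(v))))
      utils::modifyList(b, v) else v
  }
  base
}

.read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  do.call(pipeline_config, config)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  path
}

#' Run the full selection-signature pipeline
#'
#' Orchestrates simulate/load -> QC -> diversity, LD decay, PCA ->
#' iHS, XP-EHH, F_ST outlier scans -> region calling, writing
#' tab-separated outputs plus a run manifest (config hash, seed, package
#' version, output checksums) into `out_dir`. All randomness flows from the
#' single top-level seed through named per-stage substreams, so identical
#' config + seed reproduces byte-identical outputs.
#'
#' @param config configuration list or YAML path (see [pipeline_config()]).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the panel, filtered sets, scan results,
#'   region tables and the manifest.
#' @export
run_full_pipeline <- function(config, out_dir) {
  cfg <- .read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # ---- validate before any compute ----
  if (is.null(cfg$input) && is.null(cfg$simulation))
    stop("config needs either input (vcf + pop_map) or simulation")
  if (!is.null(cfg$input)) {
    if (!file.exists(cfg$input$vcf)) stop("missing VCF: ", cfg$input$vcf)
    if (!file.exists(cfg$input$pop_map))
      stop("missing population map: ", cfg$input$pop_map)
  }

  set.seed(as.integer(cfg$seed))
  stage_seed <- stats::setNames(sample.int(.Machine$integer.max, 4L),
                                c("simulate", "inject", "mcmc", "spare"))

  message("[haplosweep] stage: input")
  truth <- NULL
  if (!is.null(cfg$simulation)) {
    spec <- do.call(sweep_spec, cfg$simulation$sweep %||% list())
    sim <- simulate_wf_sweep(spec, stage_seed["simulate"],
                             pop_names = cfg$simulation$pop_names)
    panel <- sim$panel
    truth <- sim$truth
    inj <- cfg$simulation$inject
    if (!is.null(inj)) {
      set.seed(stage_seed["inject"])
      pops <- inj$populations %||% unique(panel$sample_pop)[1L]
      rows_of <- function(p) which(rep(panel$sample_pop, each = 2L) == p)
      for (p in pops) {
        sub <- subset_by_population(panel, p)
        sw <- inject_sweep(sub, truth$selected_pos,
                           inj$carrier_fraction %||% 0.6,
                           inj$taper_bp %||% 5e5)
        panel$alleles[rows_of(p), ] <- sw$alleles
      }
      truth$injected_pops <- pops
    }
    write_phased_vcf(panel, file.path(out_dir, "simulated.vcf"))
    .write_tsv(data.frame(sample = panel$samples,
                          population = unname(panel$sample_pop)),
               file.path(out_dir, "pop_map.tsv"))
    .write_tsv(data.frame(what = c("selected_pos", "selected_site"),
                          value = c(truth$selected_pos,
                                    truth$selected_site)),
               file.path(out_dir, "truth.tsv"))
  } else {
    pop_map <- read_pop_map(cfg$input$pop_map)
    panel <- read_phased_vcf(cfg$input$vcf, pop_map)$panel
  }

  pops <- sort(unique(panel$sample_pop))
  for (ct in cfg$contrasts)
    for (side in c("obs", "ref"))
      if (!(ct[[side]] %in% pops))
        stop("unknown population in contrast: ", ct[[side]])
  ihs_pops <- cfg$ihs_populations %||% pops
  if (!all(ihs_pops %in% pops))
    stop("unknown population in ihs_populations: ",
         paste(setdiff(ihs_pops, pops), collapse = ", "))

  geno <- as_genotype_matrix(panel)

  # ---- two marker sets: scan filter (MAF only) and structure filter
  # (MAF + HWE + LD pruning) ----
  message("[haplosweep] stage: qc")
  scan_keep <- which(minor_allele_frequency(geno) >
                       cfg$scan_filter$maf_min)
  scan_panel <- subset_sites(panel, scan_keep)
  scan_geno <- subset_sites(geno, scan_keep)
  sf <- cfg$structure_filter
  struct <- filter_maf(geno, sf$maf_min)$genotypes
  struct <- filter_hwe(struct, sf$hwe_p_min)$genotypes
  if (ncol(struct$dosage) >= 2L)
    struct <- ld_prune(struct, sf$r2_max, sf$window_snps,
                       sf$step)$genotypes
  .write_tsv(data.frame(
    set = c("input", "scan", "structure"),
    n_snps = c(n_sites(panel), length(scan_keep),
               ncol(struct$dosage))),
    file.path(out_dir, "marker_sets.tsv"))

  results <- list(panel = panel, truth = truth, scan_panel = scan_panel,
                  structure_genotypes = struct)

  if (isTRUE(cfg$stages$diversity)) {
    message("[haplosweep] stage: diversity")
    div <- heterozygosity_summary(scan_geno)
    kw <- kruskal_wallis(lapply(div, `[[`, "ho"))
    .write_tsv(data.frame(
      population = names(div),
      mean_ho = vapply(div, `[[`, 0, "mean_ho"),
      sd_ho = vapply(div, `[[`, 0, "sd_ho"),
      mean_he = vapply(div, `[[`, 0, "mean_he"),
      sd_he = vapply(div, `[[`, 0, "sd_he"),
      kw_H = kw$H, kw_p = kw$p_value),
      file.path(out_dir, "diversity.tsv"))
    results$diversity <- div
    results$kruskal_wallis <- kw
  }

  if (isTRUE(cfg$stages$ld_decay)) {
    message("[haplosweep] stage: ld_decay")
    prof <- lapply(pops, function(p) {
      pr <- ld_decay_profile(scan_geno, p)
      if (nrow(pr)) cbind(population = p, pr) else NULL
    })
    .write_tsv(do.call(rbind, prof), file.path(out_dir, "ld_decay.tsv"))
    results$ld_decay <- prof
  }

  if (isTRUE(cfg$stages$pca) && ncol(struct$dosage) >= 2L) {
    message("[haplosweep] stage: pca")
    pca <- pca_genotypes(struct)
    .write_tsv(data.frame(sample = rownames(pca$scores),
                          population = unname(struct$sample_pop),
                          round(pca$scores[, seq_len(min(4L,
                            ncol(pca$scores))), drop = FALSE], 6)),
               file.path(out_dir, "pca_scores.tsv"))
    .write_tsv(data.frame(component = seq_along(pca$var_explained),
                          var_explained = round(pca$var_explained, 6)),
               file.path(out_dir, "pca_variance.tsv"))
    results$pca <- pca
  }

  ehh_cfg <- do.call(ihs_config, cfg$ehh)
  th <- cfg$thresholds
  regions_all <- list()

  if (isTRUE(cfg$stages$ihs)) {
    for (p in ihs_pops) {
      message("[haplosweep] stage: ihs ", p)
      res <- ihs_scan(subset_by_population(scan_panel, p), ehh_cfg)
      write_scan_table(res, file.path(out_dir,
                                      paste0("ihs_", p, ".tsv")))
      results$ihs[[p]] <- res
      if (isTRUE(cfg$stages$regions)) {
        reg <- merge_regions(cluster_regions(
          call_significant(res, th$neglog10p_min), p,
          th$max_gap_bp, th$min_snps))
        regions_all[[paste0("ihs_", p)]] <- reg
        .write_tsv(reg, file.path(out_dir,
                                  paste0("regions_ihs_", p, ".tsv")))
        write_regions_bed(reg, file.path(out_dir,
                                         paste0("regions_ihs_", p,
                                                ".bed")), "iHS")
      }
    }
  }

  for (ct in cfg$contrasts) {
    lab <- paste0(ct$obs, "_vs_", ct$ref)
    if (isTRUE(cfg$stages$xpehh)) {
      message("[haplosweep] stage: xpehh ", lab)
      res <- xpehh_scan(subset_by_population(scan_panel, ct$obs),
                        subset_by_population(scan_panel, ct$ref), ehh_cfg)
      write_scan_table(res, file.path(out_dir,
                                      paste0("xpehh_", lab, ".tsv")))
      results$xpehh[[lab]] <- res
      if (isTRUE(cfg$stages$regions)) {
        reg <- merge_regions(cluster_regions(
          call_significant(res, th$neglog10p_min), lab,
          th$max_gap_bp, th$min_snps))
        regions_all[[paste0("xpehh_", lab)]] <- reg
        .write_tsv(reg, file.path(out_dir,
                                  paste0("regions_xpehh_", lab, ".tsv")))
        write_regions_bed(reg, file.path(out_dir,
                                         paste0("regions_xpehh_", lab,
                                                ".bed")), "XP-EHH")
      }
    }
    if (isTRUE(cfg$stages$bayescan)) {
      message("[haplosweep] stage: bayescan ", lab)
      counts <- count_alleles(scan_geno, c(ct$obs, ct$ref))
      mc <- do.call(mcmc_config,
                    c(cfg$mcmc, list(seed = stage_seed["mcmc"])))
      ps <- posterior_summaries(rjmcmc_run(counts, mc), th$po_min)
      .write_tsv(cbind(ps$loci[c("chrom", "pos", "site_id")],
                       round(ps$loci[c("P", "PO", "alpha_mean", "q")], 6),
                       decision = ps$loci$decision),
                 file.path(out_dir, paste0("bayescan_", lab, ".tsv")))
      .write_tsv(ps$populations,
                 file.path(out_dir, paste0("bayescan_", lab,
                                           "_populations.tsv")))
      results$bayescan[[lab]] <- ps
      if (isTRUE(cfg$stages$regions)) {
        reg <- merge_regions(cluster_regions(
          call_significant_fst(ps, th$po_min), lab,
          th$max_gap_bp, th$min_snps))
        regions_all[[paste0("bayescan_", lab)]] <- reg
        .write_tsv(reg, file.path(out_dir,
                                  paste0("regions_bayescan_", lab,
                                         ".tsv")))
      }
    }
  }
  results$regions <- regions_all

  # ---- manifest ----
  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg[order(names(cfg))], cfg_file)
  outputs <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_file)),
    seed = as.integer(cfg$seed),
    package_version = as.character(utils::packageVersion("haplosweep")),
    outputs = as.list(tools::md5sum(file.path(out_dir, outputs))))
  names(manifest$outputs) <- outputs
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
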