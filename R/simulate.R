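#' Specification of an island-model divergence simulation
#'
#' Populations derive from one ancestral pool; locus-by-population F_ST is
#' `logistic(alpha_i + beta_j)` with a locus effect `alpha_i` (nonzero at
#' planted outliers) and a population effect `beta_j` (drift). Subpopulation
#' allele frequencies are Beta-distributed around the ancestral frequency
#' with concentration `theta_ij = (1 - F_ST_ij) / F_ST_ij`, and observed
#' allele counts are binomial draws from them.
#'
#' @param n_pops number of populations (>= 2).
#' @param n_loci number of loci (>= 1).
#' @param beta per-population baseline effect on logit F_ST (recycled);
#'   default `logit(0.05)` for every population.
#' @param alpha per-locus effect; default 0 everywhere (neutral).
#' @param n_diploid diploid sample size per population (recycled).
#' @param anc_bounds lower/upper bound of the uniform ancestral-frequency
#'   sampler (default `c(0.05, 0.95)`).
#' @return A list of class `island_model_spec`.
#' @export
island_model_spec <- function(n_pops = 4, n_loci = 2000,
                              beta = stats::qlogis(0.05), alpha = 0,
                              n_diploid = 50,
                              anc_bounds = c(0.05, 0.95)) {
  stopifnot(n_pops >= 2, n_loci >= 1,
            anc_bounds[1] > 0, anc_bounds[2] < 1,
            anc_bounds[1] < anc_bounds[2])
  spec <- list(n_pops = as.integer(n_pops), n_loci = as.integer(n_loci),
               beta = rep_len(beta, n_pops),
               alpha = rep_len(alpha, n_loci),
               n_diploid = rep_len(as.integer(n_diploid), n_pops),
               anc_bounds = anc_bounds)
  fst <- stats::plogis(outer(spec$alpha, spec$beta, "+"))
  if (any(!is.finite(fst)) || any(fst <= 0) || any(fst >= 1))
    stop("implied F_ST outside (0,1)")
  class(spec) <- "island_model_spec"
  spec
}

#' Simulate allele counts under the island model
#'
#' @param spec an [island_model_spec()].
#' @param seed integer seed; the generator is a pure function of
#'   `(spec, seed)`.
#' @return List with `counts` (an [allele_count_table()]) and `truth`
#'   (ancestral frequencies `p`, `alpha`, `beta`, logical `outlier` flags,
#'   and the implied per-population neutral `fst`).
#' @export
simulate_island_model <- function(spec, seed) {
  stopifnot(inherits(spec, "island_model_spec"))
  set.seed(as.integer(seed))
  I <- spec$n_loci; J <- spec$n_pops
  p <- stats::runif(I, spec$anc_bounds[1], spec$anc_bounds[2])
  fst <- stats::plogis(outer(spec$alpha, spec$beta, "+"))
  theta <- (1 - fst) / fst
  a <- matrix(0L, I, J)
  n <- matrix(rep(2L * spec$n_diploid, each = I), I, J)
  for (j in seq_len(J)) {
    q <- stats::rbeta(I, theta[, j] * p, theta[, j] * (1 - p))
    q <- pmin(pmax(q, 0), 1)
    a[, j] <- stats::rbinom(I, n[, j], q)
  }
  pops <- paste0("pop", seq_len(J))
  sites <- site_info(rep("1", I), seq_len(I) * 1000L,
                     paste0("locus_", seq_len(I)))
  list(counts = allele_count_table(a, n, sites, pops),
       truth = list(p = p, alpha = spec$alpha, beta = spec$beta,
                    outlier = spec$alpha != 0,
                    fst = stats::plogis(spec$beta)))
}

#' Specification of a forward Wright-Fisher sweep simulation
#'
#' An ancestral pool of diploids is built from independent site draws on a
#' neutral frequency spectrum (density proportional to `1/f`, truncated to
#' the MAF-floor-compatible range), mixed by `g_burnin` generations of
#' random mating with Poisson recombination, then split into populations
#' that evolve independently for `generations` generations. At the selected
#' site, a designated allele has additive fitness (1, `1+s`, `1+2s`).
#'
#' @param n_haplotypes haplotypes sampled per population (even; recycled).
#' @param pop_diploid census diploid size of each evolving population
#'   (recycled; default `5 * n_haplotypes / 2`, so the output is a sample,
#'   not the whole population -- whole-population output would carry
#'   unrealistically many recently coalesced, near-identical haplotype
#'   pairs).
#' @param chrom_length_bp chromosome length in bp (default 10 Mb).
#' @param n_sites number of segregating sites placed on the chromosome.
#' @param recomb_rate per-bp per-generation crossover rate. The default
#'   `8e-7`, together with the default ancestral size, is a scaled-down
#'   parameterization: the population-scaled recombination rate
#'   `4 * n_anc * recomb_rate` (4.8e-4 per bp) matches that of an effective
#'   population in the low thousands at a field-typical 1 cM/Mb, which is
#'   what keeps forward simulation at desk scale while preserving the LD
#'   structure the haplotype statistics see.
#' @param selected_pos position of the selected site (made a site if not
#'   already one); `NULL` places it mid-chromosome.
#' @param s selection coefficient (0 = neutral).
#' @param generations generations of independent evolution after the split.
#' @param target_freq optional minimum final frequency of the selected
#'   allele per population; populations falling short are re-evolved (up to
#'   `max_attempts`) when `s > 0`.
#' @param n_anc diploid size of the ancestral pool (default 150).
#' @param g_burnin burn-in generations before the split (default `n_anc`:
#'   long enough for drift to build background LD at the sub-Mb scale;
#'   markedly longer mutation-free burn-ins fix most founder variation and
#'   leave panels dominated by a few haplotype clades).
#' @param selected_start_freq founder frequency of the selected allele
#'   (default 0.2).
#' @param spectrum_bounds truncation of the `1/f` founder spectrum
#'   (default `c(0.05, 0.95)`).
#' @param max_attempts retry cap for lost/short selected alleles.
#' @return A list of class `sweep_spec`.
#' @export
sweep_spec <- function(n_haplotypes = c(100, 100), chrom_length_bp = 1e7,
                       n_sites = 2000, recomb_rate = 8e-7,
                       selected_pos = NULL, s = 0.1, generations = 10,
                       target_freq = NULL, pop_diploid = NULL,
                       n_anc = 150, g_burnin = NULL,
                       selected_start_freq = 0.2,
                       spectrum_bounds = c(0.05, 0.95), max_attempts = 20) {
  n_haplotypes <- as.integer(n_haplotypes)
  stopifnot(all(n_haplotypes %% 2L == 0L), all(n_haplotypes >= 4L),
            n_sites >= 2, recomb_rate >= 0, s >= -0.5)
  if (is.null(selected_pos)) selected_pos <- round(chrom_length_bp / 2)
  stopifnot(selected_pos >= 1, selected_pos <= chrom_length_bp)
  if (!is.null(target_freq))
    stopifnot(target_freq >= 0, target_freq <= 1)
  if (is.null(pop_diploid)) pop_diploid <- 5L * n_haplotypes %/% 2L
  pop_diploid <- rep_len(as.integer(pop_diploid), length(n_haplotypes))
  stopifnot(all(2L * pop_diploid >= n_haplotypes))
  if (is.null(g_burnin)) g_burnin <- as.integer(n_anc)
  structure(list(n_haplotypes = n_haplotypes, pop_diploid = pop_diploid,
                 chrom_length_bp = chrom_length_bp,
                 n_sites = as.integer(n_sites), recomb_rate = recomb_rate,
                 selected_pos = as.integer(selected_pos), s = s,
                 generations = as.integer(generations),
                 target_freq = target_freq, n_anc = as.integer(n_anc),
                 g_burnin = as.integer(g_burnin),
                 selected_start_freq = selected_start_freq,
                 spectrum_bounds = spectrum_bounds,
                 max_attempts = as.integer(max_attempts)),
            class = "sweep_spec")
}

# one generation of Wright-Fisher reproduction with recombination;
# haps: 2N x L integer matrix, rows 2k-1/2k = individual k
.wf_generation <- function(haps, pos, chrom_length_bp, recomb_rate,
                           fitness) {
  n_hap <- nrow(haps)
  n_ind <- n_hap %/% 2L
  parent <- sample.int(n_ind, n_hap, replace = TRUE, prob = fitness)
  n_co <- stats::rpois(n_hap, recomb_rate * chrom_length_bp)
  first <- sample.int(2L, n_hap, replace = TRUE)  # which parental hap leads
  out <- haps
  plain <- n_co == 0L
  out[plain, ] <- haps[2L * (parent[plain] - 1L) + first[plain], ,
                       drop = FALSE]
  for (g in which(!plain)) {
    cuts <- sort(stats::runif(n_co[g], 0, chrom_length_bp))
    seg <- findInterval(pos, cuts)  # 0,1,2,... segment index
    use_first <- seg %% 2L == 0L
    h1 <- haps[2L * (parent[g] - 1L) + first[g], ]
    h2 <- haps[2L * (parent[g] - 1L) + (3L - first[g]), ]
    out[g, ] <- ifelse(use_first, h1, h2)
  }
  out
}

.wf_evolve <- function(haps, pos, spec, sel_idx, n_gen, s) {
  freq <- numeric(n_gen)
  for (g in seq_len(n_gen)) {
    if (s != 0) {
      odd <- seq(1L, nrow(haps), 2L)
      dose <- haps[odd, sel_idx] + haps[odd + 1L, sel_idx]
      w <- 1 + s * dose
    } else w <- rep(1, nrow(haps) %/% 2L)
    haps <- .wf_generation(haps, pos, spec$chrom_length_bp,
                           spec$recomb_rate, w)
    freq[g] <- mean(haps[, sel_idx])
  }
  list(haps = haps, freq = freq)
}

#' Simulate phased panels with a forward Wright-Fisher model
#'
#' @param spec a [sweep_spec()].
#' @param seed integer seed; the generator is a pure function of
#'   `(spec, seed)`.
#' @param pop_names population labels (default `"pop1"`, `"pop2"`, ...).
#' @return List with `panel` (a [haplotype_panel()] holding the
#'   final-generation samples of every population) and `truth`
#'   (`selected_site` column index, `selected_pos`, per-population selected
#'   allele frequency `trajectories` and `final_freq`, founder frequencies).
#' @export
simulate_wf_sweep <- function(spec, seed, pop_names = NULL) {
  stopifnot(inherits(spec, "sweep_spec"))
  set.seed(as.integer(seed))
  J <- length(spec$n_haplotypes)
  if (is.null(pop_names)) pop_names <- paste0("pop", seq_len(J))

  # site positions: uniform draws plus the selected site, sorted
  pos <- sort(sample.int(spec$chrom_length_bp, spec$n_sites - 1L))
  pos <- sort(unique(c(pos, spec$selected_pos)))
  while (length(pos) < spec$n_sites) {
    extra <- sample.int(spec$chrom_length_bp,
                        spec$n_sites - length(pos))
    pos <- sort(unique(c(pos, extra)))
  }
  sel_idx <- match(spec$selected_pos, pos)
  L <- length(pos)

  # founder pool from the truncated 1/f spectrum
  lo <- spec$spectrum_bounds[1]; hi <- spec$spectrum_bounds[2]
  f <- lo * (hi / lo)^stats::runif(L)
  f[sel_idx] <- spec$selected_start_freq
  n_anc_hap <- 2L * spec$n_anc
  founders <- matrix(stats::rbinom(n_anc_hap * L, 1L, rep(f, each = n_anc_hap)),
                     nrow = n_anc_hap, ncol = L)
  storage.mode(founders) <- "integer"

  anc <- .wf_evolve(founders, pos, spec, sel_idx, spec$g_burnin, 0)$haps

  panels <- vector("list", J)
  traj <- vector("list", J)
  for (j in seq_len(J)) {
    nh <- spec$n_haplotypes[j]
    # found population j by resampling whole individuals from the pool
    ind <- sample.int(nrow(anc) %/% 2L, spec$pop_diploid[j],
                      replace = TRUE)
    start <- anc[as.vector(rbind(2L * ind - 1L, 2L * ind)), , drop = FALSE]
    attempt <- 0L
    repeat {
      attempt <- attempt + 1L
      ev <- .wf_evolve(start, pos, spec, sel_idx, spec$generations, spec$s)
      fin <- if (spec$generations > 0) ev$freq[spec$generations] else
        mean(start[, sel_idx])
      ok <- spec$s == 0 ||
        (fin > 0 && (is.null(spec$target_freq) ||
                       fin >= spec$target_freq))
      if (ok) break
      if (attempt >= spec$max_attempts)
        stop("selected allele lost/short of target in population ",
             pop_names[j], " after ", attempt, " attempts")
    }
    # draw the output panel as a sample of individuals, not the census
    pick <- sample.int(spec$pop_diploid[j], nh %/% 2L)
    panels[[j]] <- ev$haps[as.vector(rbind(2L * pick - 1L, 2L * pick)), ,
                           drop = FALSE]
    traj[[j]] <- ev$freq
  }

  alle <- do.call(rbind, panels)
  n_dip <- spec$n_haplotypes %/% 2L
  samples <- unlist(lapply(seq_len(J), function(j)
    paste0(pop_names[j], "_ind", seq_len(n_dip[j]))))
  sample_pop <- stats::setNames(rep(pop_names, n_dip), samples)
  sites <- site_info(rep("1", L), pos)
  names(traj) <- pop_names
  list(panel = haplotype_panel(alle, samples, sample_pop, sites),
       truth = list(selected_site = sel_idx,
                    selected_pos = spec$selected_pos,
                    trajectories = traj,
                    final_freq = vapply(traj, function(t)
                      t[length(t)], numeric(1)),
                    founder_freq = f))
}

#' Plant a deterministic extended-haplotype sweep into a panel
#'
#' Copies one donor haplotype onto a fraction of haplotypes over a window
#' centred on `core_pos`; each carrier's half-width is an independent
#' Exponential draw with mean `taper_bp`, so carrier haplotypes share a
#' long core segment that frays with distance -- the footprint of a partial
#' sweep. Randomness (donor, carriers, half-widths) is drawn from R's RNG
#' stream, so wrap calls in `set.seed()` for reproducibility.
#'
#' @param panel a [haplotype_panel()].
#' @param core_pos position of the sweep core; must match a panel site.
#' @param carrier_fraction fraction of haplotypes turned into carriers
#'   (0 < fraction <= 1).
#' @param taper_bp mean of the exponential half-width (bp); `Inf` copies
#'   the donor over the whole chromosome.
#' @return A modified copy of `panel`, with attributes `core_site` (column
#'   index), `donor` and `carriers` (haplotype row indices).
#' @export
inject_sweep <- function(panel, core_pos, carrier_fraction,
                         taper_bp = 5e5) {
  stopifnot(carrier_fraction > 0, carrier_fraction <= 1)
  core <- which(panel$sites$pos == core_pos)
  if (length(core) != 1L)
    stop("core_pos ", core_pos, " does not match a unique panel site")
  chrom <- panel$sites$chrom[core]
  n_hap <- nrow(panel$alleles)
  n_car <- max(2L, ceiling(carrier_fraction * n_hap))
  # donor carries the rarer core allele, so the swept allele ends near
  # carrier_fraction in frequency instead of being driven to fixation
  f1 <- mean(panel$alleles[, core])
  rare <- if (f1 <= 0.5) 1L else 0L
  pool <- which(panel$alleles[, core] == rare)
  donor <- if (length(pool) > 0L) pool[sample.int(length(pool), 1L)] else
    sample.int(n_hap, 1L)
  carriers <- c(donor, sample(setdiff(seq_len(n_hap), donor), n_car - 1L))
  hw <- if (is.finite(taper_bp)) stats::rexp(n_car, 1 / taper_bp) else
    rep(Inf, n_car)
  alle <- panel$alleles
  # the swept allele is the rarer core allele, carried (or adopted) by the
  # donor, so the post-injection core frequency lands near carrier_fraction
  alle[donor, core] <- rare
  on_chrom <- panel$sites$chrom == chrom
  dist <- abs(panel$sites$pos - core_pos)
  for (k in seq_len(n_car)) {
    win <- which(on_chrom & dist <= hw[k])
    win <- union(win, core)
    alle[carriers[k], win] <- alle[donor, win]
  }
  out <- haplotype_panel(alle, panel$samples, panel$sample_pop, panel$sites)
  attr(out, "core_site") <- core
  attr(out, "donor") <- donor
  attr(out, "carriers") <- sort(carriers)
  out
}
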