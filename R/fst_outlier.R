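#' Per-locus, per-population allele count table
#'
#' Substrate for the Bayesian F_ST outlier model: for locus `i` and
#' population `j`, the count `a[i, j]` of allele 1 out of `n[i, j]` sampled
#' alleles.
#'
#' @param a integer matrix of allele-1 counts (loci x populations).
#' @param n integer matrix of total allele counts (same shape).
#' @param sites site table ([site_info()]), one row per locus.
#' @param populations population labels (columns).
#' @param allow_odd allow odd total counts (default `FALSE`: diploid
#'   samples have even totals).
#' @return An object of class `allele_count_table`.
#' @export
allele_count_table <- function(a, n, sites, populations,
                               allow_odd = FALSE) {
  a <- as.matrix(a); n <- as.matrix(n)
  storage.mode(a) <- "integer"; storage.mode(n) <- "integer"
  stopifnot(all(dim(a) == dim(n)), nrow(a) == nrow(sites),
            ncol(a) == length(populations))
  if (any(a < 0L) || any(a > n)) stop("need 0 <= a_ij <= n_ij")
  if (!allow_odd && any(n %% 2L != 0L))
    stop("odd total allele counts; set allow_odd = TRUE if intended")
  colnames(a) <- colnames(n) <- populations
  structure(list(a = a, n = n, sites = sites,
                 populations = as.character(populations)),
            class = "allele_count_table")
}

#' @export
print.allele_count_table <- function(x, ...) {
  cat("allele_count_table:", nrow(x$a), "loci x", ncol(x$a),
      "populations (", paste(x$populations, collapse = ", "), ")\n")
  invisible(x)
}

#' Build an allele count table from a genotype matrix
#'
#' @param genotypes a [genotype_matrix()].
#' @param populations populations to include (default all, sorted).
#' @return An [allele_count_table()]; missing genotypes reduce `n_ij`.
#' @export
count_alleles <- function(genotypes, populations = NULL) {
  if (is.null(populations))
    populations <- sort(unique(genotypes$sample_pop))
  a <- n <- matrix(0L, ncol(genotypes$dosage), length(populations))
  for (j in seq_along(populations)) {
    g <- subset_genotypes_by_population(genotypes, populations[j])
    a[, j] <- as.integer(colSums(g$dosage, na.rm = TRUE))
    n[, j] <- 2L * as.integer(colSums(!is.na(g$dosage)))
  }
  allele_count_table(a, n, genotypes$sites, populations)
}

#' F_ST from locus and population effects
#'
#' The logit-linear decomposition
#' `F_ST_ij = 1 / (1 + exp(-(alpha_i + beta_j)))`: a locus-specific effect
#' `alpha` (selection) plus a population-specific effect `beta` (drift).
#'
#' @param alpha,beta finite effect values (vectorized).
#' @return `F_ST` in (0, 1).
#' @export
fst_from_effects <- function(alpha, beta) {
  stopifnot(all(is.finite(alpha)), all(is.finite(beta)))
  stats::plogis(alpha + beta)
}

#' Beta-binomial log-likelihood of an allele count
#'
#' Marginal likelihood of `a` copies of allele 1 in `n` sampled alleles
#' when the subpopulation frequency is Beta-distributed with shapes
#' `theta * p` and `theta * (1 - p)` around ancestral frequency `p`
#' (`theta = (1 - F_ST) / F_ST`); evaluated with log-gamma functions.
#'
#' @param a,n allele-1 count and total count (vectorized).
#' @param p ancestral frequency, strictly inside (0, 1).
#' @param theta concentration parameter, > 0.
#' @return Log-likelihood value(s).
#' @export
betabinom_loglik <- function(a, n, p, theta) {
  if (any(p <= 0) || any(p >= 1))
    stop("ancestral frequency must be interior to (0,1)")
  if (any(theta <= 0)) stop("theta must be > 0")
  A <- theta * p
  B <- theta * (1 - p)
  lchoose(n, a) + lbeta(a + A, n - a + B) - lbeta(A, B)
}

#' MCMC configuration for the F_ST outlier model
#'
#' @param burn_in burn-in iterations (default 5000).
#' @param iterations post-burn-in iterations (default 10000).
#' @param thinning thinning interval (must divide `iterations`; default 10,
#'   so 1000 samples are retained).
#' @param prior_odds prior odds neutral:selected for each locus
#'   (default 10; prior inclusion probability `1/(1+prior_odds)`).
#' @param alpha_sd prior SD of the locus effect (mean 0; default 1).
#' @param beta_mean,beta_sd prior of the population effect
#'   (default -1 and 1.8).
#' @param prop_p,prop_alpha,prop_beta initial proposal SDs (adaptively
#'   tuned to 25-45% acceptance during burn-in, then frozen).
#' @param adapt enable burn-in adaptation (default `TRUE`).
#' @param seed integer seed for the sampler.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(burn_in = 5000, iterations = 10000, thinning = 10,
                        prior_odds = 10, alpha_sd = 1.0,
                        beta_mean = -1.0, beta_sd = 1.8,
                        prop_p = 0.4, prop_alpha = 0.4, prop_beta = 0.15,
                        adapt = TRUE, seed = 1) {
  stopifnot(burn_in >= 0, iterations > 0, thinning > 0,
            iterations %% thinning == 0, prior_odds > 0,
            alpha_sd > 0, beta_sd > 0)
  structure(list(burn_in = as.integer(burn_in),
                 iterations = as.integer(iterations),
                 thinning = as.integer(thinning), prior_odds = prior_odds,
                 alpha_sd = alpha_sd, beta_mean = beta_mean,
                 beta_sd = beta_sd, prop_p = prop_p,
                 prop_alpha = prop_alpha, prop_beta = prop_beta,
                 adapt = adapt, seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Run the reversible-jump MCMC for the F_ST outlier model
#'
#' Metropolis-Hastings updates of ancestral frequencies (logit random
#' walk), population effects `beta_j` and locus effects `alpha_i`, plus a
#' reversible-jump move toggling each locus's inclusion indicator
#' `delta_i` (`delta_i = 0` forces `alpha_i = 0`), with prior inclusion
#' probability `1/(1 + prior_odds)`. Every `thinning`-th post-burn-in state
#' is retained. Fully seeded and deterministic.
#'
#' @param counts an [allele_count_table()] with >= 2 populations and >= 2
#'   loci.
#' @param config an [mcmc_config()].
#' @param likelihood_on internal hook: `FALSE` switches the likelihood off
#'   so the chain samples the prior (used to validate the sampler).
#' @return A list of class `fst_chain`: thinned sample matrices `delta`
#'   (S x loci), `alpha`, `beta` (S x pops), posterior mean `p_mean`,
#'   acceptance-rate diagnostics, the frozen proposal SDs, `sites` and
#'   `populations`.
#' @export
rjmcmc_run <- function(counts, config = mcmc_config(),
                       likelihood_on = TRUE) {
  stopifnot(inherits(counts, "allele_count_table"),
            ncol(counts$a) >= 2L, nrow(counts$a) >= 2L)
  fixed0 <- colSums(counts$a) == 0L
  fixed1 <- colSums(counts$a == counts$n) == nrow(counts$a)
  if (any(fixed0 | fixed1))
    stop("degenerate counts: population(s) fixed at every locus: ",
         paste(counts$populations[fixed0 | fixed1], collapse = ", "))
  set.seed(config$seed)
  res <- cpp_rjmcmc(counts$a, counts$n, config$burn_in, config$iterations,
                    config$thinning, 1 / (1 + config$prior_odds),
                    config$alpha_sd, config$beta_mean, config$beta_sd,
                    config$prop_p, config$prop_alpha, config$prop_beta,
                    likelihood_on, config$adapt)
  res$sites <- counts$sites
  res$populations <- counts$populations
  res$config <- config
  class(res) <- "fst_chain"
  res
}

#' @export
print.fst_chain <- function(x, ...) {
  cat("fst_chain:", nrow(x$delta), "retained samples over",
      ncol(x$delta), "loci,", ncol(x$beta), "populations\n")
  cat("  acceptance rates:",
      paste(names(x$accept), round(x$accept, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Posterior summaries and selection decisions
#'
#' Per locus: inclusion probability `P_i` (posterior mean of `delta_i`),
#' posterior odds `PO_i = P_i / (1 - P_i)` (capped at `(S - 0.5)/0.5` and
#' flagged when `P_i = 1` with `S` retained samples), posterior mean
#' `alpha_i` conditional on inclusion, q-value, and decision:
#' `"directional"` iff `PO >= po_min` and mean alpha > 0,
#' `"balancing/purifying"` iff `PO >= po_min` and mean alpha < 0, else
#' `"neutral"`. Per population: posterior mean and 95% interval of
#' `beta_j` and the implied neutral `F_ST_j = logistic(beta_j)`.
#'
#' @param chain an `fst_chain` from [rjmcmc_run()].
#' @param po_min posterior-odds decision threshold (default 32,
#'   i.e. posterior probability 32/33 ~ 0.97, log10 ~ 1.5).
#' @return List of class `posterior_summary` with data.frames `loci` and
#'   `populations`.
#' @export
posterior_summaries <- function(chain, po_min = 32) {
  S <- nrow(chain$delta)
  P <- colMeans(chain$delta)
  po_cap <- (S - 0.5) / 0.5
  po <- ifelse(P >= 1, po_cap, P / (1 - P))
  capped <- P >= 1
  incl <- colSums(chain$delta)
  alpha_mean <- ifelse(incl > 0, colSums(chain$alpha) / pmax(incl, 1),
                       NA_real_)
  q <- qvalues(P)
  decision <- rep("neutral", length(P))
  decision[po >= po_min & !is.na(alpha_mean) & alpha_mean > 0] <-
    "directional"
  decision[po >= po_min & !is.na(alpha_mean) & alpha_mean < 0] <-
    "balancing/purifying"
  loci <- data.frame(chain$sites[c("chrom", "pos", "site_id")],
                     P = P, PO = po, po_capped = capped,
                     alpha_mean = alpha_mean, q = q, decision = decision,
                     stringsAsFactors = FALSE)
  bq <- apply(chain$beta, 2L, stats::quantile, probs = c(0.025, 0.975))
  populations <- data.frame(
    population = chain$populations,
    beta_mean = colMeans(chain$beta),
    beta_lo = bq[1L, ], beta_hi = bq[2L, ],
    fst = colMeans(stats::plogis(chain$beta)),
    stringsAsFactors = FALSE)
  structure(list(loci = loci, populations = populations, n_samples = S,
                 po_min = po_min),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("posterior_summary:", nrow(x$loci), "loci;",
      sum(x$loci$decision != "neutral"), "called at PO >=", x$po_min, "\n")
  print(x$populations, row.names = FALSE)
  invisible(x)
}

#' q-values from posterior inclusion probabilities
#'
#' Loci are ranked by decreasing `P`; the q-value at rank `k` is the mean
#' posterior error probability `1 - P` over the top `k` loci, made
#' monotone non-decreasing down the ranking.
#'
#' @param P vector of posterior inclusion probabilities in `[0, 1]`.
#' @return q-values in the original locus order.
#' @export
qvalues <- function(P) {
  stopifnot(all(P >= 0), all(P <= 1))
  o <- order(P, decreasing = TRUE)
  q_sorted <- cummax(cumsum(1 - P[o]) / seq_along(P))
  q <- numeric(length(P))
  q[o] <- q_sorted
  q
}

#' Weir-Cockerham F_ST from allele counts
#'
#' Method-of-moments ANOVA estimator on allele counts (alleles as the
#' sampling units): per locus
#' `theta = (MSP - MSG) / (MSP + (n_c - 1) MSG)`, and the standard
#' multilocus ratio-of-averages. Used as the frequentist cross-check of the
#' Bayesian model's implied F_ST.
#'
#' @param counts an [allele_count_table()].
#' @return List with `per_locus` theta vector and `overall`
#'   ratio-of-averages theta.
#' @export
wc_fst <- function(counts) {
  a <- counts$a; n <- counts$n
  r <- ncol(a)
  N <- rowSums(n)
  pj <- a / n
  pbar <- rowSums(a) / N
  ssb <- rowSums(n * (pj - pbar)^2)
  ssw <- rowSums(n * pj * (1 - pj))
  msp <- ssb / (r - 1)
  msg <- ssw / (N - r)
  nc <- (N - rowSums(n^2) / N) / (r - 1)
  denom <- msp + (nc - 1) * msg
  list(per_locus = ifelse(denom > 0, (msp - msg) / denom, NA_real_),
       overall = sum(msp - msg) / sum(denom))
}
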