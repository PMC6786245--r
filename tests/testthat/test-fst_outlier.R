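test_that("logit decomposition of F_ST behaves as the model requires", {
  expect_equal(fst_from_effects(1, -1), 0.5)
  expect_equal(fst_from_effects(0, qlogis(0.05)), 0.05)
  a <- seq(-3, 3, 0.5)
  expect_true(all(diff(fst_from_effects(a, 0.3)) > 0))
  expect_error(fst_from_effects(Inf, 0))
})

test_that("beta-binomial likelihood: binomial limit, quadrature, and
           normalization", {
  # theta -> infinity collapses to the binomial
  expect_equal(betabinom_loglik(3, 10, 0.4, 1e6),
               dbinom(3, 10, 0.4, log = TRUE), tolerance = 1e-3)
  # (a=1, n=2, p=0.5, theta=2): Beta(1,1) mixing density is uniform
  quad <- integrate(function(q) dbinom(1, 2, q), 0, 1)$value
  expect_equal(exp(betabinom_loglik(1, 2, 0.5, 2)), quad,
               tolerance = 1e-9)
  # probabilities over the support sum to one
  expect_equal(sum(exp(betabinom_loglik(0:4, 4, 0.3, 1.7))), 1,
               tolerance = 1e-10)
  expect_error(betabinom_loglik(1, 2, 0, 2), "interior")
  expect_error(betabinom_loglik(1, 2, 0.5, -1), "theta")
})

test_that("q-values average posterior error probabilities down the
           ranking", {
  expect_equal(qvalues(0.97), 0.03)
  expect_equal(qvalues(c(1, 1, 1)), c(0, 0, 0))
  expect_equal(qvalues(c(0.9, 0.8)), c(0.1, 0.15))
  # monotone non-decreasing in rank order regardless of input order
  set.seed(1)
  P <- runif(50)
  q <- qvalues(P)
  o <- order(P, decreasing = TRUE)
  expect_true(all(diff(q[o]) >= -1e-12))
})

test_that("posterior odds map to the documented probability and log10
           thresholds", {
  expect_equal((32 / 33) / (1 - 32 / 33), 32)
  expect_equal(log10(32), 1.5, tolerance = 0.01)
  # synthetic chain: P = 0.97 crosses the PO >= 32 boundary, 0.96 does not
  S <- 1000
  mk_chain <- function(p_incl, alpha_val) {
    delta <- matrix(0L, S, 2)
    delta[seq_len(round(S * p_incl)), 1] <- 1L
    alpha <- delta * alpha_val
    structure(list(delta = delta, alpha = alpha,
                   beta = matrix(-2, S, 2), p_mean = c(0.5, 0.5),
                   sites = site_info(c("1", "1"), c(1L, 2L)),
                   populations = c("A", "B")), class = "fst_chain")
  }
  ps <- posterior_summaries(mk_chain(0.97, 1.5))
  expect_equal(ps$loci$PO[1], 0.97 / 0.03, tolerance = 1e-9)
  expect_equal(ps$loci$decision[1], "directional")
  expect_equal(posterior_summaries(mk_chain(0.96, 1.5))$loci$decision[1],
               "neutral")
  # negative alpha at high PO is balancing/purifying, never directional
  expect_equal(posterior_summaries(mk_chain(0.99, -1))$loci$decision[1],
               "balancing/purifying")
  # P = 1 gives the capped, flagged odds
  full <- posterior_summaries(mk_chain(1, 2))
  expect_true(full$loci$po_capped[1])
  expect_equal(full$loci$PO[1], (S - 0.5) / 0.5)
  expect_equal(posterior_summaries(mk_chain(0.5, 1))$loci$PO[1], 1)
})

test_that("prior-only chain recovers the prior inclusion probability and
           the alpha prior", {
  spec <- island_model_spec(n_pops = 2, n_loci = 60, n_diploid = 20)
  counts <- simulate_island_model(spec, 4)$counts
  cfg <- mcmc_config(burn_in = 500, iterations = 2000, thinning = 2,
                     prior_odds = 10, seed = 9)
  ch <- rjmcmc_run(counts, cfg, likelihood_on = FALSE)
  P <- colMeans(ch$delta)
  se <- sd(P) / sqrt(length(P))
  expect_lt(abs(mean(P) - 1 / 11), 3 * se + 0.01)
  # alpha samples, conditional on inclusion, follow the N(0,1) prior
  a <- ch$alpha[ch$delta == 1]
  expect_lt(abs(mean(a)), 0.15)
  expect_lt(abs(sd(a) - 1), 0.15)
})

test_that("the sampler is seeded-deterministic and rejects degenerate
           input", {
  spec <- island_model_spec(n_pops = 2, n_loci = 30, n_diploid = 10)
  counts <- simulate_island_model(spec, 2)$counts
  cfg <- mcmc_config(burn_in = 200, iterations = 400, thinning = 4,
                     seed = 3)
  ch1 <- rjmcmc_run(counts, cfg)
  ch2 <- rjmcmc_run(counts, cfg)
  expect_identical(ch1$delta, ch2$delta)
  expect_identical(ch1$beta, ch2$beta)

  bad <- counts
  bad$a[, 2] <- 0L
  expect_error(rjmcmc_run(bad, cfg), "degenerate")
})

test_that("allele-label swap at a locus leaves its inclusion probability
           unchanged within Monte-Carlo error", {
  spec <- island_model_spec(n_pops = 3, n_loci = 80, n_diploid = 30,
                            alpha = c(2.5, rep(0, 79)))
  counts <- simulate_island_model(spec, 12)$counts
  cfg <- mcmc_config(burn_in = 1000, iterations = 3000, thinning = 3,
                     seed = 5)
  P1 <- colMeans(rjmcmc_run(counts, cfg)$delta)
  swapped <- counts
  swapped$a[1, ] <- swapped$n[1, ] - swapped$a[1, ]
  P2 <- colMeans(rjmcmc_run(swapped, cfg)$delta)
  expect_lt(abs(P1[1] - P2[1]), 0.15)
})

test_that("posterior per-population F_ST recovers island-model truth", {
  spec <- island_model_spec(n_pops = 3, n_loci = 600,
                            beta = qlogis(c(0.03, 0.08, 0.15)),
                            n_diploid = 50)
  counts <- simulate_island_model(spec, 21)$counts
  ch <- rjmcmc_run(counts, mcmc_config(burn_in = 2000, iterations = 4000,
                                       thinning = 10, seed = 6))
  ps <- posterior_summaries(ch)
  expect_true(all(abs(ps$populations$fst - c(0.03, 0.08, 0.15)) <= 0.02))
})
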