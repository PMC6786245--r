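test_that("EHH is 1 at the core and over fully identical windows", {
  p <- toy_panel(matrix(rep(c(0L, 1L), each = 4 * 5), 4, 10))
  pr <- ehh_profile(p, 3, "site")
  expect_equal(pr$left$ehh, rep(1, 2))
  expect_true(all(pr$right$ehh[1:6] == 1))
})

test_that("EHH counts identical pairs: groups {2,1,1} of 4 carriers give
           1/6", {
  # 8 haplotypes; rows 1-4 carry allele 1 at the core (column 1)
  alle <- rbind(c(1, 1, 0),
                c(1, 1, 0),
                c(1, 1, 1),
                c(1, 0, 1),
                c(0, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, 1, 1))
  p <- toy_panel(alle)
  pr <- ehh_profile(p, 1, 1L)
  expect_equal(pr$n_carriers, 4L)
  # at first marker: carriers have alleles (1,1,1,0) -> groups {3,1} -> 3/6
  expect_equal(pr$right$ehh[1], 0.5)
  # at second marker: (0,0,1,1)&(1,1,1,0) -> groups {2,1,1} -> 1/6
  expect_equal(pr$right$ehh[2], 1 / 6)
})

test_that("sites with fewer than two carriers are invalid with a reason", {
  alle <- matrix(0L, 4, 3)
  alle[1, 2] <- 1L
  pr <- ehh_profile(toy_panel(alle), 2, 1L)
  expect_false(pr$valid)
  expect_match(pr$reason, "carriers")
})

test_that("EHH profiles equal the brute-force pair-enumeration oracle and
           are monotone non-increasing", {
  for (seed in 1:12) {
    p <- random_panel(2 * sample(3:16, 1), sample(20:80, 1), seed)
    core <- sample(n_sites(p), 1)
    target <- sample(list(0L, 1L, "site"), 1)[[1]]
    pr <- ehh_profile(p, core, target, ehh_cutoff = 0.05)
    if (!pr$valid) next
    carriers <- if (identical(target, "site")) seq_len(nrow(p$alleles))
    else which(p$alleles[, core] == target)
    for (dir in c(-1, 1)) {
      side <- if (dir > 0) pr$right else pr$left
      oracle <- truncate_side(
        ehh_oracle_side(p$alleles, core, carriers, dir), 0.05)
      expect_equal(side$ehh, oracle, tolerance = 1e-12)
      expect_true(all(diff(side$ehh) <= 1e-12))
    }
  }
})

test_that("iHH integration matches the hand trapezoid with interpolated
           cutoff crossing", {
  # per side: EHH 1 at 0 bp, 0.5 at 10 kb, 0.04 at 20 kb; cutoff 0.05;
  # the profile is mirrored so the sum is twice the one-sided area
  side <- function(sign) list(idx = c(2L, 3L),
                              pos = sign * c(10000L, 20000L),
                              ehh = c(0.5, 0.04), reached_cutoff = TRUE,
                              hit_end = FALSE)
  prof <- structure(list(
    core = 1L, core_pos = 0L, chrom = "1", target = "site",
    n_carriers = 10L, valid = TRUE, reason = "",
    left = side(-1), right = side(1)), class = "ehh_profile")
  out <- integrate_ehh(prof)
  d_interp <- 10000 * (0.5 - 0.05) / (0.5 - 0.04)
  one_side <- 7500 + (0.5 + 0.05) / 2 * d_interp
  expect_equal(one_side, 10190.217, tolerance = 1e-6)
  expect_equal(out$ihh, 2 * one_side)

  # doubling all distances doubles the integral
  prof2 <- prof
  prof2$right$pos <- prof$right$pos * 2L
  prof2$left$pos <- prof$left$pos * 2L
  expect_equal(integrate_ehh(prof2)$ihh, 2 * out$ihh)

  # a side that never decays below the cutoff is invalid
  prof3 <- prof
  prof3$right$ehh <- c(0.5, 0.4)
  prof3$right$reached_cutoff <- FALSE
  prof3$right$hit_end <- TRUE
  out3 <- integrate_ehh(prof3)
  expect_false(out3$valid)
  expect_equal(out3$reason, "uncapped decay")
})

test_that("z to -log10 p uses the two-sided normal form with accurate
           tails", {
  expect_equal(neglog10_p_from_z(0), 0)
  expect_equal(neglog10_p_from_z(1.959964), -log10(0.05),
               tolerance = 1e-6)
  # symmetric in sign
  expect_equal(neglog10_p_from_z(-3), neglog10_p_from_z(3))
  # far tails: no 1-CDF cancellation
  expect_equal(neglog10_p_from_z(10),
               -(log(2) + pnorm(10, lower.tail = FALSE, log.p = TRUE)) /
                 log(10))
  expect_gt(neglog10_p_from_z(40), 300)
  expect_error(neglog10_p_from_z(NaN), "non-finite")
  # one-sided option halves the p-value
  expect_equal(neglog10_p_from_z(2, one_sided = TRUE),
               neglog10_p_from_z(2) + log10(2))
})

test_that("iHS is zero under major/minor mirror symmetry and resolves the
           0.5 tie toward allele 0", {
  set.seed(21)
  half <- matrix(rbinom(6 * 30, 1, 0.5), 6, 30)
  alle <- rbind(half, 1L - half)  # complement: perfect mirror classes
  p <- toy_panel(alle)
  res <- ihs_scan(p, ihs_config(min_snps_per_bin = 1))
  expect_gt(sum(!is.na(res$raw)), 0)
  expect_true(all(abs(res$raw[!is.na(res$raw)]) < 1e-12))
  # every column has frequency 0.5: tie -> major is allele 0, so the raw
  # score is ln(iHH_0 / iHH_1); check the orientation on an asymmetric site
  f1 <- colMeans(alle)
  expect_true(all(f1 == 0.5))
})

test_that("iHS is invariant to sample relabeling/permutation", {
  p <- random_panel(20, 60, 31)
  res <- ihs_scan(p, ihs_config(min_snps_per_bin = 2))
  perm <- sample(10)
  hap_rows <- as.vector(rbind(2L * perm - 1L, 2L * perm))
  p2 <- haplotype_panel(p$alleles[hap_rows, ], paste0("t", 1:10),
                        stats::setNames(rep("popA", 10),
                                        paste0("t", 1:10)),
                        p$sites)
  res2 <- ihs_scan(p2, ihs_config(min_snps_per_bin = 2))
  expect_equal(res$raw, res2$raw)
  expect_equal(res$standardized, res2$standardized)
})

test_that("XP-EHH is zero against an identical reference and antisymmetric
           under swapping", {
  p <- random_panel(16, 50, 41)
  pb <- haplotype_panel(p$alleles, p$samples,
                        stats::setNames(rep("popB", 8), p$samples),
                        p$sites)
  res <- xpehh_scan(p, pb)
  expect_gt(sum(!is.na(res$raw)), 0)
  expect_true(all(abs(res$raw[!is.na(res$raw)]) < 1e-12))

  q <- random_panel(16, 50, 42)
  qb <- haplotype_panel(q$alleles[c(9:16, 1:8), ], q$samples,
                        stats::setNames(rep("popB", 8), q$samples),
                        q$sites)
  ab <- xpehh_scan(q, qb)
  ba <- xpehh_scan(qb, q)
  expect_equal(ab$raw, -ba$raw)

  q2 <- random_panel(16, 49, 43)
  expect_error(xpehh_scan(q, q2), "identical site list")
})

test_that("an injected sweep drives the genome-wide |iHS| peak into its
           footprint with the core highly ranked", {
  hits_peak <- 0; hits_core <- 0; n_rep <- 3
  for (seed in 1:n_rep) {
    sw <- simulate_wf_sweep(sweep_spec(n_haplotypes = 100, s = 0,
                                       generations = 10), seed)
    set.seed(seed + 500)
    swp <- inject_sweep(sw$panel, sw$truth$selected_pos, 0.5, 5e5)
    res <- ihs_scan(swp)
    v <- which(res$valid)
    peak <- v[which.max(abs(res$standardized[v]))]
    hits_peak <- hits_peak +
      (abs(res$pos[peak] - sw$truth$selected_pos) <= 1e6)
    core <- attr(swp, "core_site")
    if (res$valid[core]) {
      rk <- rank(-abs(res$standardized[v]))[match(core, v)]
      hits_core <- hits_core + (rk <= ceiling(0.05 * length(v)))
    }
  }
  expect_gte(hits_peak, n_rep - 1)
  expect_gte(hits_core, n_rep - 1)
})

test_that("XP-EHH flags a one-population sweep with a positive
           standardized peak near the core", {
  sw <- simulate_wf_sweep(sweep_spec(n_haplotypes = c(100, 100), s = 0,
                                     generations = 10), 6)
  pA <- subset_by_population(sw$panel, "pop1")
  pB <- subset_by_population(sw$panel, "pop2")
  set.seed(99)
  pAs <- inject_sweep(pA, sw$truth$selected_pos, 0.8, 5e5)
  res <- xpehh_scan(pAs, pB)
  v <- which(res$valid)
  peak <- v[which.max(res$standardized[v])]
  expect_lte(abs(res$pos[peak] - sw$truth$selected_pos), 1e6)
  expect_gt(res$standardized[peak], 3)
})
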