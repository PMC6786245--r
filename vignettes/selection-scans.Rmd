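---
title: "Haplotype and F_ST selection scans: models, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype and F_ST selection scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the statistics it implements,
the conventions and numerical choices behind them, what the synthetic
data generators do and do not emulate, and the limitations a user should
know before trusting a scan.

## The statistics

### EHH and its integral

For a core SNP and a set of carrier haplotypes (all haplotypes carrying
one allele, or every haplotype for the site-level version), the extended
haplotype homozygosity at marker $t$ is the probability that two
carriers drawn at random are identical at every marker from the core out
to $t$ inclusive:

$$\mathrm{EHH}(t) = \frac{\sum_g \binom{k_g}{2}}{\binom{n}{2}},$$

where the $k_g$ are the sizes of the groups sharing the same allele
vector over the span. `ehh_profile()` computes this outward marker by
marker on each side of the core until EHH drops below a cutoff (default
0.05) or the chromosome ends. Identity includes the core column itself,
which only matters for the site-level target; the profile's value at
distance zero is 1 by definition. EHH is non-increasing with distance by
construction, a property the test suite checks against a brute-force
enumeration of identical pairs.

`integrate_ehh()` turns a profile into iHH by trapezoid integration of
EHH against physical distance, separately per side, truncated at the
linearly interpolated point where EHH crosses the cutoff. Interpolation
makes the integral insensitive to marker spacing near the crossing. A
side that reaches the chromosome end (or a configured extension cap)
while still above the cutoff yields an *invalid* site ("uncapped
decay") rather than an extrapolated value: an unbounded integral is not
comparable across sites, and silently capping it would bias the scan
toward chromosome edges. Physical distance (bp) is used throughout; no
genetic map is assumed.

### iHS

Per site, the raw score is $\ln(\mathrm{iHH}_{major}/\mathrm{iHH}_{minor})$.
Without an outgroup the major allele stands in for the ancestral state; a
frequency tie at exactly 0.5 resolves the "major" label to allele 0
(the REF allele) — an arbitrary but deterministic and documented choice.
Raw scores are standardized to z-scores within minor-allele-frequency
bins (width 0.025 by default) because the expectation and spread of the
raw score depend strongly on allele frequency. Bins with fewer than 10
scored SNPs are merged with their better-populated neighbour before
standardization; the sample standard deviation is used. Sites whose MAF
is at or below 0.05 are not scored (`maf_below_min`), matching the
array-data convention of the scan marker set.

### XP-EHH

Site-level EHH (all haplotypes) is integrated in an observed and a
reference population over the identical site list; the raw score is
$\ln(I_{obs}/I_{ref})$, standardized genome-wide (mean/SD over valid
sites). Positive standardized scores indicate unusually long, frequent
haplotypes in the observed population; negative scores point to the
reference. Standardization is genome-wide rather than frequency-binned
because the ratio is computed at the same SNP in both populations, which
cancels most of the frequency dependence.

### The p-value convention

Both haplotype scans report
$-\log_{10}\!\big(2(1 - \Phi(|z|))\big)$ — the two-sided normal form —
computed on the log scale via `pnorm(..., log.p = TRUE)` so that far
tails do not suffer $1 - \mathrm{CDF}$ cancellation. The two-sided form
is the one consistent with published (score, $-\log p$) pairs in this
literature, even where the accompanying text says "one-tailed"; a
one-sided variant is available behind `ihs_config(one_sided = TRUE)`.
The significance rule for region calling is $-\log_{10} p \ge 3$
($p \le 0.001$), inclusive at the boundary.

### The Bayesian F_ST outlier model

Allele counts $a_{ij}$ of locus $i$ in population $j$ follow a
beta-binomial: the subpopulation frequency is Beta-distributed around an
ancestral frequency $p_i$ with concentration
$\theta_{ij} = (1 - F_{ij})/F_{ij}$, and

$$\mathrm{logit}(F_{ij}) = \alpha_i + \beta_j,$$

a locus-specific effect (selection, shared across populations) plus a
population-specific effect (drift). A reversible-jump MCMC samples the
posterior over models with and without each $\alpha_i$: per iteration it
updates every $p_i$ by a logit random walk (uniform prior kept interior,
with the Jacobian term), every $\beta_j$ and every included $\alpha_i$
by Gaussian random walks, and proposes toggling each inclusion indicator
$\delta_i$, drawing $\alpha_i$ from its prior on birth so the proposal
density cancels and the acceptance ratio reduces to the likelihood ratio
times the prior inclusion odds. Priors are $\alpha_i \sim N(0,1)$,
$\beta_j \sim N(-1, 1.8)$, prior odds 10 for neutrality — the
conventional defaults of this model family, all configurable. Proposal
SDs adapt toward 25–45% acceptance during burn-in only, then freeze, so
the post-burn-in chain is a valid fixed-kernel sampler. The default
schedule (5,000 burn-in, 10,000 iterations, thinning 10, hence 1,000
retained samples) follows the published practice for this analysis.

Per locus the summary reports the inclusion probability $P_i$ (posterior
mean of $\delta_i$), posterior odds $P_i/(1-P_i)$ — capped at
$(S-0.5)/0.5$ and flagged when $P_i = 1$ with $S$ samples, since odds
are then only bounded below — the posterior mean $\alpha_i$ conditional
on inclusion, and a q-value: rank loci by decreasing $P_i$ and average
the posterior error probabilities $1 - P$ over the top $k$, enforcing
monotonicity. The decision rule is posterior odds $\ge 32$
(equivalently $P \ge 32/33 \approx 0.97$, $\log_{10} \approx 1.5$) with
mean $\alpha > 0$ for directional selection; negative $\alpha$ at the
same odds indicates balancing/purifying selection and is never reported
as directional.

### Region calling

Significant SNPs are chained per chromosome: consecutive significant
SNPs at most 500 kb apart join one cluster (the gap rule applies to
*consecutive* SNPs, not the cluster span — only chaining can produce the
multi-megabase regions such scans report), clusters need at least two
SNPs, and region boundaries are the outermost significant SNPs.
Overlapping or bookended regions merge, summing SNP counts and taking
peak statistics. Sizes print as $(end - start)/1000$ rounded
half-away-from-zero to one decimal.

## The synthetic data generators

### Island model

`simulate_island_model()` draws, per locus, an ancestral frequency
(uniform on [0.05, 0.95], mirroring an array's usable-MAF floor), then
per population a Beta frequency with the $\theta_{ij}$ implied by the
chosen effects, then binomial allele counts. It returns the full truth
(effects, outlier flags, implied F_ST), so recovery and error rates can
be measured exactly. Defaults (4 populations, 2,000 loci, 50 diploids
each) are the scale at which the acceptance checks run.

One caveat the acceptance numbers make visible: the *realized*
divergence of a planted outlier is random. With $\alpha = 3$ and four
populations of 50 diploids, the per-population Beta draws land close to
the ancestral frequency often enough that roughly four in ten outlier
loci carry little evidence — the exact marginal Bayes factor (computed
by quadrature, independently of the sampler) agrees with the sampler's
posterior on such loci. Detection power at posterior odds 32 is
therefore bounded near 55% at these sample sizes regardless of sampler
quality, while the neutral false-positive rate stays well under 1%.
Power claims for this design should be read against that bound.

### Forward Wright–Fisher panels

`simulate_wf_sweep()` builds an ancestral pool of diploids from
independent site draws on a truncated $1/f$ frequency spectrum (the
neutral shape, truncated to [0.05, 0.95] so the pipeline's MAF floor
does not empty panels), mixes it by generations of random mating with
Poisson-recombined gametes, then splits it into populations that evolve
independently, optionally with additive selection (fitness 1, $1+s$,
$1+2s$) at a designated site; output panels are phased by construction
and the selected-allele trajectory is recorded. A forward model was
chosen over a coalescent because the artifact tests detection behaviour,
not demographic realism, and forward simulation keeps selection exact.

Three design choices matter and were made once, on first principles
plus diagnosis of the mutation-free model's pathologies:

- **Burn-in of $1 \times N_{anc}$ generations** (default $N_{anc}=150$
  diploids). Without mutation, a burn-in of $4N$ fixes the large
  majority of founder variation and leaves panels dominated by a few
  genome-wide haplotype clades, whose EHH plateaus above the integration
  cutoff; $1N$ builds drift LD at the sub-megabase scale while retaining
  a usable MAF spectrum.
- **Census larger than the sample**: populations evolve at five times
  the sampled size, and the panel is a sample of individuals. Sampling a
  whole tiny population yields many pairs that coalesced within a couple
  of generations — genome-length identical haplotypes no real array
  sample contains — which again stalls EHH decay.
- **Scaled-down recombination**: a 10-Mb chromosome with
  $r = 8 \times 10^{-7}$ per bp per generation gives a population-scaled
  rate $4 N_{anc} r \approx 4.8 \times 10^{-4}$ per bp, the value an
  effective population in the low thousands would have at a field-typical
  ~1 cM/Mb. This reproduces fast empirical LD decay at desk-scale cost;
  positions and distances remain in ordinary bp units.

What the generator does **not** emulate: array ascertainment bias beyond
the MAF floor, mutation after the founder generation, varying
recombination along the chromosome, overlapping generations, and any
phasing error (panels are perfectly phased, so scans on real,
statistically phased data will be somewhat noisier than the tests
suggest).

### Injected sweeps

`inject_sweep()` plants a deterministic partial-sweep footprint: a
donor haplotype carrying the rarer core allele is copied onto a chosen
fraction of haplotypes over windows whose per-haplotype half-width is
exponential (mean `taper_bp`), so carriers share a long core segment
that frays with distance. The swept allele ends near the carrier
fraction in frequency, keeping the core scoreable. A property of this
construction worth knowing: the strongest standardized scores typically
sit at *shoulder* sites flanking the core — where the donor allele is
locally rare and one-sided haplotype identity is extreme — rather than
at the core SNP itself, because the core's carrier class frays on both
sides at once. Sweep recovery should therefore be judged at the region
level (does a called region span the planted site), which is how the
end-to-end checks are framed.

## Numerical and edge-case conventions

- Monomorphic sites: Hardy–Weinberg exact test returns $p = 1$; r²
  against a constant locus is undefined and excluded from LD profiles;
  EHH targets with fewer than two carriers are invalid with reason
  `mono/insufficient carriers`.
- The HWE test is the exact conditional test on heterozygote counts
  (two-sided: summed probability of outcomes no more probable than the
  observed), validated against full enumeration for all totals up to 30.
- LD pruning slides windows (50 SNPs, step 5 by default) over surviving
  SNPs within chromosomes, removing the lower-MAF member of the worst
  pair above the r² ceiling (tie: later position), and repeats passes to
  a fixpoint, so re-running the filter removes nothing.
- MAF filtering is strictly exclusive at the floor (a SNP at exactly
  0.05 is removed); the "among all populations" reading defaults to the
  pooled sample, with a per-population mode (`scope = "each"`) because
  the phrase is genuinely ambiguous.
- PCA mean-imputes missing dosages per SNP, centers, and takes the SVD;
  frequency scaling is off by default and available as an option.
- Duplicated positions on a chromosome: first record kept, rest skipped
  with a warning (strictly increasing positions are required for EHH
  integration).
- All generators and the MCMC are pure functions of (spec, seed); the
  pipeline derives per-stage substreams from one top-level seed and
  produces byte-identical outputs for identical config and seed.

## Problem sizes used by the checks

The test suite and acceptance script run at the scales the analysis is
designed for: neutral iHS calibration on one 5,000-site, 100-haplotype
panel; EHH-oracle agreement on 200 random panels up to 64 haplotypes ×
200 sites; the Bayesian model on 2,000 loci × 4 populations with the
full 5,000/10,000/10 MCMC schedule; end-to-end sweep recovery over 10
seeded replicates of three 100-haplotype populations. Smaller sizes are
used for unit-level properties where the property itself does not
depend on scale.

## Known limitations

- The iHS ancestral-state proxy (major allele) misorients truly derived
  major alleles; scores are interpretable in absolute value, and the
  region caller uses $|z|$ via the two-sided p-value.
- XP-EHH standardization assumes most of the genome is neutral; in
  simulations with a single planted sweep this holds, but scans of
  panels under pervasive selection would need a robust location/scale
  estimate.
- The q-value convention (averaged posterior error probabilities) is one
  of several in use for this model family; thresholds on posterior odds
  are primary, q-values are reported for plotting and ranking.
- The command-line surface is R functions plus `run_full_pipeline()`
  with a YAML config; there is no shell executable, as the package is
  meant to be driven from R or Rscript.
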