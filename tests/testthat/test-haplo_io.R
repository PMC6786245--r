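test_that("phased VCF records become panel columns; bad records are skipped
           and tallied", {
  f <- write_lines_vcf(c(
    "1\t100\trs1\tA\tC\t.\tPASS\t.\tGT\t0|1\t1|1",
    "1\t200\trs2\tA\tC\t.\tPASS\t.\tGT\t0/1\t1|1",
    "1\t300\trs3\tA\tT,G\t.\tPASS\t.\tGT\t0|1\t1|1",
    "1\t400\trs4\tAT\tC\t.\tPASS\t.\tGT\t0|1\t1|1",
    "1\t500\trs5\tG\tT\t.\tPASS\t.\tGT\t.|1\t1|1"))
  out <- read_phased_vcf(f)
  expect_equal(unname(out$panel$alleles[, 1]), c(0L, 1L, 1L, 1L))
  expect_equal(out$panel$sites$site_id, "rs1")
  expect_equal(unname(out$skip_report[c("unphased_or_missing",
                                        "multiallelic", "non_snp")]),
               c(2L, 1L, 1L))
})

test_that("VCF reading rejects duplicate samples and keeps first of
           duplicated positions", {
  f <- write_lines_vcf("1\t100\t.\tA\tC\t.\tPASS\t.\tGT\t0|1\t1|1",
                       samples = c("s1", "s1"))
  expect_error(read_phased_vcf(f), "duplicated sample")
  f2 <- write_lines_vcf(c("1\t100\ta\tA\tC\t.\tPASS\t.\tGT\t0|1\t1|1",
                          "1\t100\tb\tG\tT\t.\tPASS\t.\tGT\t1|1\t0|0"))
  expect_warning(out <- read_phased_vcf(f2), "duplicated positions")
  expect_equal(out$panel$sites$site_id, "a")
  expect_equal(unname(out$skip_report["duplicate_position"]), 1L)
})

test_that("panel -> VCF -> panel round trip is exact", {
  for (seed in 1:5) {
    p <- random_panel(2 * sample(2:8, 1), sample(5:40, 1), seed)
    f <- tempfile(fileext = ".vcf")
    write_phased_vcf(p, f)
    rt <- read_phased_vcf(f, p$sample_pop)
    expect_identical(unname(rt$panel$alleles), unname(p$alleles))
    expect_equal(rt$panel$sites$pos, p$sites$pos)
  }
})

test_that("population map reading: dedup, conflicts, small populations", {
  f <- tempfile()
  writeLines(c("s1\tPopA", "s2\tPopB", "s3\tPopB"), f)
  expect_warning(m <- read_pop_map(f), "< 2 samples")
  expect_equal(length(m), 3L)
  expect_equal(attr(m, "small_pops"), "PopA")
  writeLines(c("s1\tPopA", "s1\tPopA"), f)
  expect_warning(expect_warning(m2 <- read_pop_map(f), "duplicate"),
                 "< 2 samples")
  expect_equal(length(m2), 1L)
  writeLines(c("s1\tPopA", "s1\tPopB"), f)
  expect_error(suppressWarnings(read_pop_map(f)), "conflicting")
  writeLines(c("sample_id\tpopulation", "s1\tPopA", "s2\tPopA"), f)
  expect_equal(length(read_pop_map(f)), 2L)
})

test_that("population subsetting keeps exactly that population's
           haplotypes and is idempotent", {
  p <- random_panel(10, 8, 1)
  p$sample_pop[] <- c("A", "A", "A", "B", "B")
  a <- subset_by_population(p, "A")
  expect_equal(n_haplotypes(a), 6L)
  expect_identical(a$sites, p$sites)
  expect_identical(subset_by_population(a, "A"), a)
  expect_error(subset_by_population(p, "Z"), "unknown population")
})

test_that("genotype matrix derived from a panel equals haplotype-pair
           sums", {
  for (seed in 1:3) {
    p <- random_panel(12, 20, seed)
    g <- as_genotype_matrix(p)
    odd <- seq(1, 11, 2)
    expect_identical(unname(g$dosage),
                     unname(p$alleles[odd, ] + p$alleles[odd + 1, ]))
  }
})

test_that("scan tables have a stable layout with empty score fields on
           invalid rows", {
  s <- site_info(rep("1", 3), c(100L, 200L, 300L))
  res <- scan_result("iHS", "A", s, c(0.4, NA, -0.2), c(1.1, NA, -0.6),
                     c(0.5, NA, 0.2), c(TRUE, FALSE, TRUE),
                     c("", "maf_below_min", ""))
  f <- tempfile()
  write_scan_table(res, f)
  lines <- readLines(f)
  expect_equal(length(lines), 4L)
  expect_match(lines[1], "^chrom\tpos\tsite_id\traw\tstandardized")
  expect_match(lines[3], "\t\t\t\tFALSE\tmaf_below_min$")
  empty <- scan_result("iHS", "A", s[0, ], numeric(0), numeric(0),
                       numeric(0), logical(0), character(0))
  write_scan_table(empty, f)
  expect_equal(length(readLines(f)), 1L)
})

test_that("BED output is 0-based half-open and inverts back to region
           coordinates", {
  reg <- region_table("PopA", "1", 35662318L, 35684677L, 4L, 3.8634,
                      3.9515)
  f <- tempfile()
  write_regions_bed(reg, f, "iHS")
  parts <- strsplit(readLines(f), "\t")[[1]]
  expect_equal(as.integer(parts[2:3]), c(35662317L, 35684677L))
  # back to 1-based inclusive
  expect_equal(as.integer(parts[2]) + 1L, reg$start)
  expect_equal(as.integer(parts[3]), reg$end)
  expect_equal(parts[4], "PopA|iHS|4|22.4")
  expect_equal(as.numeric(parts[5]), 395)

  write_regions_bed(reg[0, ], f)
  expect_equal(length(readLines(f)), 0L)

  one <- region_table("P", "1", 100L, 100L, 2L, 1, 1)
  write_regions_bed(one, f)
  parts <- strsplit(readLines(f), "\t")[[1]]
  expect_equal(as.integer(parts[3]) - as.integer(parts[2]), 1L)

  two <- rbind(region_table("P", "1", 500L, 600L, 2L, 1, 1),
               region_table("P", "1", 100L, 200L, 2L, 1, 1))
  expect_error(write_regions_bed(two, f), "sorted")
})
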