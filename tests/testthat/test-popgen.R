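test_that("MAF counts two alleles per called sample and folds at 0.5", {
  sheet <- tiny_sheet(n_dh = 11, pops = c(P1 = 25, P2 = 25))  # 61 samples
  gt0 <- matrix(0L, 1, 61)
  gt_het <- matrix(1L, 1, 61)
  gt30 <- matrix(0L, 1, 61); gt30[1, 1:15] <- 2L  # 30 alt alleles of 122
  s <- make_sites("chr1", 1:3, n_samples = 61, gt = rbind(gt0, gt_het, gt30))
  expect_equal(minor_allele_frequency(s, sheet), c(0, 0.5, 30 / 122))
})

test_that("the MAF spectrum partitions sites and matches a closed-form mixture", {
  sheet <- tiny_sheet(n_dh = 2, pops = c(P1 = 3))
  empty <- maf_spectrum(make_sites("chr1", 1, gt = matrix(0L, 1, 5),
                                   n_samples = 5)[0, ], sheet)
  expect_true(all(empty$count == 0))

  set.seed(21)
  sites <- random_variant_table(500, sheet)
  spec <- maf_spectrum(sites, sheet)
  expect_equal(sum(spec$count), sum(!is.na(minor_allele_frequency(sites, sheet))))

  # uniform allele-frequency draws: the share of sites below MAF 0.05 matches
  # the binomial-mixture expectation within Monte-Carlo error
  ns <- 61
  sheet61 <- tiny_sheet(n_dh = 11, pops = c(P1 = 25, P2 = 25))
  n_sites <- 3000
  p <- runif(n_sites)
  gt <- matrix(rbinom(n_sites * ns, 2, rep(p, ns)), n_sites, ns)
  s <- make_sites("chr1", seq_len(n_sites), n_samples = ns, gt = gt)
  got <- attr(maf_spectrum(s, sheet61), "prop_below_05")
  # closed form: P(min(X, 2n-X)/2n < 0.05), X ~ Binom(2n, p), p ~ U(0,1)
  grid <- seq(0.0005, 0.9995, by = 0.001)
  cut <- ceiling(0.05 * 2 * ns) - 1   # allele counts 0..6 of 122
  p_below <- mean(vapply(grid, function(pp) {
    sum(dbinom(c(0:cut, (2 * ns - cut):(2 * ns)), 2 * ns, pp))
  }, numeric(1)))
  expect_equal(got, p_below, tolerance = 0.05)
})

test_that("population polymorphism summarises full-data sites per population", {
  sheet <- tiny_sheet(n_dh = 2, pops = c(Pop = 4))
  # 6 sites x 4 fish, hand-designed:
  #  s1 poly (1 het), s2 monomorphic ref, s3 missing one fish,
  #  s4 poly (alt hom + hets), s5 monomorphic alt, s6 poly (all het)
  pop_gt <- rbind(
    c(0L, 1L, 0L, 0L),
    c(0L, 0L, 0L, 0L),
    c(1L, NA, 0L, 0L),
    c(2L, 1L, 1L, 0L),
    c(2L, 2L, 2L, 2L),
    c(1L, 1L, 1L, 1L)
  )
  gt <- cbind(matrix(0L, 6, 2), pop_gt)
  s <- make_sites("chr1", 1:6, n_samples = 6, gt = gt)
  res <- population_polymorphism(s, sheet)
  pop <- res[res$population == "Pop", ]
  expect_equal(pop$n_fish, 4)
  expect_equal(pop$n_sites_full_data, 5)   # s3 dropped
  expect_equal(pop$n_polymorphic, 3)       # s1, s4, s6
  expect_equal(pop$pct_polymorphic, 60)
  expect_equal(pop$mean_maf_polymorphic,
               round(mean(c(1 / 8, min(4 / 8, 0.5), 0.5)), 2))
  expect_equal(pop$mean_ho_polymorphic, round(mean(c(1 / 4, 2 / 4, 1)), 2))
  # the DH group is reported as its own row
  expect_true("DH" %in% res$population)

  # published per-population ratios reproduce under the integer convention
  t5 <- trout_population_polymorphism()
  pct <- round(100 * t5$n_polymorphic / t5$n_sites_full_data)
  expect_equal(pct[t5$population == "Dworshak"], 28)
  expect_equal(pct[t5$population == "DH Line"], 48)
})

test_that("windowed nucleotide diversity follows the unbiased estimator", {
  sheet <- tiny_sheet(n_dh = 0, pops = c(P1 = 2))
  build <- genome_build("chr1", "chr1", 0, 60000)
  # one site, p = 0.5 from n = 4 alleles, alone in its 20 kb window
  gt <- matrix(c(1L, 1L), 1, 2)
  s <- make_sites("chr1", 25000, n_samples = 2, gt = gt)
  pw <- nucleotide_diversity_windows(s, sheet, build, window = 20000, subset = NULL)
  expect_equal(nrow(pw), 3)
  expect_equal(pw$pi[1], 0)                          # empty window
  expect_equal(pw$pi[2], (4 / 3) * 2 * 0.5 * 0.5 / 20000)
  expect_equal(pi_genome_mean(pw), mean(pw$pi))

  # pi is invariant to swapping ref/alt labels
  set.seed(14)
  sheet5 <- tiny_sheet(n_dh = 1, pops = c(P1 = 4))
  sites <- random_variant_table(200, sheet5)
  build2 <- genome_build("chr1", "chr1", 0, max(sites$pos) + 10)
  flipped <- sites
  flipped$gt <- 2L - flipped$gt
  pw1 <- nucleotide_diversity_windows(sites, sheet5, build2)
  pw2 <- nucleotide_diversity_windows(flipped, sheet5, build2)
  expect_equal(pw1$pi, pw2$pi)

  # a trailing partial window is normalised by its true width
  s_end <- make_sites("chr1", 59999, n_samples = 2, gt = gt)
  pw3 <- nucleotide_diversity_windows(s_end, sheet, build, window = 25000, subset = NULL)
  expect_equal(pw3$end[3] - pw3$start[3], 10000)
  expect_equal(pw3$pi[3], (4 / 3) * 0.5 / 10000)
})

test_that("SNP density uses truncated integer spacing", {
  # the printed per-chromosome rates pin truncation (52.79 would round to 53)
  expect_equal(snp_rate_bp(66052243, 765805), 86)
  expect_equal(snp_rate_bp(48550143, 919605), 52)
  expect_equal(snp_rate_bp(100, 100), 1)
  expect_true(is.na(snp_rate_bp(100, 0)))

  t2 <- trout_chromosome_snps()
  chroms <- t2[t2$chrom != "unplaced", ]
  tab <- density_table_with_total(chroms)
  expect_equal(tab$rate_bp[tab$chrom == "all"],
               floor(sum(chroms$length) / sum(chroms$n_snps)))
  expect_equal(tab$rate_bp[tab$chrom == "all"], 64)
  expect_equal(attr(tab, "snps_per_kb"), 15.6)

  # counting route: sites assigned per chromosome
  build <- genome_build(c("c1", "c2"), c("c1", "c2"), c(0, 0), c(100, 50))
  s <- make_sites(c("c1", "c1", "c2"), c(10, 20, 30))
  tab2 <- snp_density_table(s, build)
  expect_equal(tab2$n_snps, c(2L, 1L, 3L))
  expect_equal(tab2$rate_bp, c(50, 50, 50))
})
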