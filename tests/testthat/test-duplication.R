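test_that("DH heterozygote counting ignores missing genotypes", {
  sheet <- tiny_sheet(n_dh = 11, pops = c(P1 = 2))
  gt <- matrix(0L, 3, 13)
  gt[2, c(1, 5)] <- 1L              # 2 of 11 DH lines het
  gt[2, 12] <- 1L                   # outbred het does not count
  gt[3, 1:11] <- NA                 # all DH missing
  gt[3, 12:13] <- 1L
  s <- make_sites("chr1", 1:3, n_samples = 13, gt = gt)
  expect_equal(dh_het_count(s, sheet), c(0L, 2L, 0L))
  expect_equal(classify_psv(s, sheet),
               c("retained_snp", "putative_psv_msv", "retained_snp"))
  # one residual het is tolerated at the default threshold, not at 1
  gt1 <- matrix(0L, 1, 13); gt1[1, 3] <- 1L
  s1 <- make_sites("chr1", 1, n_samples = 13, gt = gt1)
  expect_equal(classify_psv(s1, sheet), "retained_snp")
  expect_equal(classify_psv(s1, sheet, threshold = 1), "putative_psv_msv")
})

test_that("exact HWE test matches direct enumeration and handles edge cases", {
  expect_equal(hwe_exact_test(50, 0, 0), 1)        # monomorphic
  expect_equal(hwe_exact_test(25, 50, 25), hwe_oracle(25, 50, 25))
  expect_lt(hwe_exact_test(0, 50, 0), 1e-6)        # extreme het excess
  expect_error(hwe_exact_test(-1, 2, 3), ">= 0")

  set.seed(6)
  for (i in 1:50) {
    n <- sample(1:120, 1)
    counts <- as.vector(stats::rmultinom(1, n, c(0.4, 0.3, 0.3)))
    p <- hwe_exact_test(counts[1], counts[2], counts[3])
    expect_gte(p, 0)
    expect_lte(p, 1)
    expect_equal(p, hwe_oracle(counts[1], counts[2], counts[3]),
                 tolerance = 1e-8)
  }
  # the het-count distribution sums to one and matches the oracle weights
  d <- hwe_het_distribution(50, 37)
  expect_equal(sum(d$prob), 1)
  expect_equal(d$het, seq(1, 37, by = 2))
})

test_that("observed heterozygosity counts called genotypes within the subset", {
  sheet <- tiny_sheet(n_dh = 2, pops = c(P1 = 2, P2 = 2))
  gt <- rbind(
    rep(1L, 6),                      # all het
    rep(c(0L, 2L), 3),               # no het
    c(1L, 0L, 1L, NA, 0L, 1L)        # mixed with a missing call
  )
  s <- make_sites("chr1", 1:3, n_samples = 6, gt = gt)
  expect_equal(observed_heterozygosity(s, sheet, NULL), c(1, 0, 3 / 5))
  expect_equal(observed_heterozygosity(s, sheet, "non_dh"), c(1, 0, 2 / 3))
  expect_equal(observed_heterozygosity(s, sheet, "dh"), c(1, 0, 1 / 2))
  expect_equal(observed_heterozygosity(s, sheet, "P2"), c(1, 0, 1 / 2))
})

test_that("threshold sweep reproduces a hand-built panel and nests flag sets", {
  sheet <- tiny_sheet(n_dh = 3, pops = c(P1 = 4))
  # DH het counts by design: 0, 1, 2, 3, 2
  dh_gt <- rbind(c(0L, 0L, 0L), c(1L, 0L, 0L), c(1L, 1L, 0L),
                 c(1L, 1L, 1L), c(1L, 1L, 0L))
  out_gt <- rbind(c(0L, 0L, 0L, 0L), c(0L, 1L, 0L, 0L), c(1L, 1L, 1L, 1L),
                  c(1L, 1L, 1L, 1L), c(0L, 1L, 1L, 0L))
  s <- make_sites("chr1", 1:5, n_samples = 7, gt = cbind(dh_gt, out_gt))
  sw <- threshold_sweep(s, sheet)
  expect_equal(sw$threshold, 1:3)
  expect_equal(sw$label, c("Het > 0", "Het > 1", "Het = 3"))
  expect_equal(sw$n_flagged, c(4L, 3L, 1L))
  # hand means of outbred Ho over the flagged loci
  expect_equal(sw$mean_outbred_ho,
               c(mean(c(1/4, 1, 1, 2/4)), mean(c(1, 1, 2/4)), 1))
  # HWE-deviation percentages recomputed through the enumeration oracle
  p_by_site <- c(hwe_oracle(3, 1, 0), hwe_oracle(0, 4, 0), hwe_oracle(0, 4, 0),
                 hwe_oracle(2, 2, 0))  # sites 2..5
  dev <- p_by_site < 0.05
  expect_equal(sw$pct_hwe_dev, round(100 * c(mean(dev), mean(dev[2:4]), mean(dev[3]))))

  # nesting: the set flagged at k+1 is a subset of the set flagged at k
  screen <- dh_screen(s, sheet, threshold = 1)
  for (k in 1:2) {
    flag_k <- screen$dh_het_count >= k
    flag_k1 <- screen$dh_het_count >= k + 1
    expect_true(all(which(flag_k1) %in% which(flag_k)))
  }
  # beyond n_DH nothing is flagged
  expect_equal(threshold_sweep(s, sheet, thresholds = 4)$n_flagged, 0L)
})

test_that("the DH screen partitions sites and flags excess heterozygosity on simulated data", {
  sim <- get_default_sim()
  res <- apply_filter_cascade(
    sim$callsets$a, mask_genome(sim$genome),
    filter_config(n_samples = nrow(sim$sheet)),
    indels = dplyr::bind_rows(indel_positions(sim$callsets$a),
                              indel_positions(sim$callsets$b))
  )
  screen <- dh_screen(res$sites, sim$sheet)
  expect_equal(nrow(screen), nrow(res$sites))
  flagged <- screen$classification == "putative_psv_msv"
  expect_equal(sum(flagged) + sum(!flagged), nrow(res$sites))
  # flagged loci show the PSV signature among outbred fish: excess Ho and
  # far more HWE deviation than retained loci
  expect_gt(mean(screen$outbred_ho[flagged], na.rm = TRUE),
            mean(screen$outbred_ho[!flagged], na.rm = TRUE))
  expect_gt(mean(screen$hwe_p[flagged] < 0.05, na.rm = TRUE),
            2 * mean(screen$hwe_p[!flagged] < 0.05, na.rm = TRUE))
})

test_that("arm density separates duplicated from non-duplicated arms", {
  build <- genome_build(c("c1", "c1"), c("p", "q"), c(0, 100), c(100, 300),
                        duplicated = c(TRUE, FALSE))
  none <- arm_density(tibble::tibble(chrom = character(0), pos = numeric(0)), build)
  expect_equal(none$n_flagged, c(0L, 0L))
  one_arm <- arm_density(tibble::tibble(chrom = "c1", pos = c(5, 50, 99)), build)
  expect_equal(one_arm$n_flagged, c(3L, 0L))

  # simulated PSVs/MSVs concentrate on the duplicated arms
  sim <- get_default_sim()
  dup_sites <- sim$truth[sim$truth$class %in% c("psv", "msv"), ]
  dens <- arm_density(dup_sites, sim$build)
  expect_gt(mean(dens$density[dens$duplicated]),
            mean(dens$density[!dens$duplicated]))
})
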