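no_masks <- tibble::tibble(chrom = character(0), start = numeric(0), end = numeric(0))
no_indels <- tibble::tibble(chrom = character(0), pos = numeric(0))

test_that("QUAL stage enforces bi-allelic SNPs, strict QUAL, and indel distance", {
  cfg <- filter_config(n_samples = 4)
  qual_cases <- make_sites("chr1", c(100, 200, 300, 400, 500),
                           alt = c("G", "G", "G,T", "GT", "G"),
                           qual = c(31, 30, 50, 50, 30.0001))
  indels <- tibble::tibble(chrom = "chr1", pos = 510)
  got <- site_passes_qual(qual_cases, indels, cfg)
  expect_equal(got, c(TRUE,   # qual 31, nearest indel 10 bp away
                      FALSE,  # qual 30 exactly: strict inequality
                      FALSE,  # multi-allelic
                      FALSE,  # indel ALT
                      TRUE))  # just above threshold

  # indel proximity is |delta| <= 4 on the anchor position
  near <- make_sites("chr1", c(96, 95, 104, 105, 100), qual = 50)
  got <- site_passes_qual(near, tibble::tibble(chrom = "chr1", pos = 100), cfg)
  expect_equal(got, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  # indels on another chromosome do not count
  got <- site_passes_qual(near, tibble::tibble(chrom = "chr9", pos = 100), cfg)
  expect_true(all(got))
})

test_that("DUST masking matches a brute-force window scorer and masks repeats", {
  # a homopolymer is maximal-score low complexity
  expect_equal(dust_mask(strrep("A", 64)), tibble::tibble(start = 0, end = 64))
  # dinucleotide repeat: only two distinct triplets, fully masked
  expect_equal(dust_mask(strrep("AC", 32)), tibble::tibble(start = 0, end = 64))
  # a maximally triplet-diverse window scores low and is not masked
  set.seed(9)
  diverse <- diverse_dna_string(64)
  expect_equal(nrow(dust_mask(diverse)), 0)

  # oracle equivalence on a random corpus with embedded repeats
  set.seed(31)
  for (i in 1:40) {
    L <- sample(3:200, 1)
    s <- random_dna_string(L)
    if (i %% 3 == 0) { # splice in a repeat tract
      tract <- strrep(sample(c("A", "AC", "AG"), 1), 40)
      at <- sample.int(max(1, L - 10), 1)
      s <- paste0(substr(s, 1, at), substr(tract, 1, min(80, L)), substr(s, at + 1, L))
    }
    if (i %% 7 == 0) { # N run
      s <- paste0(substr(s, 1, 2), strrep("N", 5), substr(s, 8, nchar(s)))
    }
    expect_equal(dust_mask(s), dust_oracle(s), info = paste("case", i))
  }

  expect_error(dust_mask("ACGT", window = 2), "window")
})

test_that("LC stage agrees with a linear point-in-interval scan", {
  masks <- tibble::tibble(chrom = "chr1", start = 0, end = 10)
  s <- make_sites("chr1", c(5, 10, 11))
  # BED is 0-based half-open: 1-based positions 1..10 are inside
  expect_equal(site_passes_lc(s, masks), c(FALSE, FALSE, TRUE))

  set.seed(12)
  m <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 30, replace = TRUE),
                      start = sample.int(900, 30))
  m$end <- m$start + sample.int(40, 30, replace = TRUE)
  m <- merge_regions(m)
  sites <- make_sites(sample(c("chr1", "chr2"), 1000, replace = TRUE),
                      sample.int(1000, 1000, replace = TRUE))
  scan <- vapply(seq_len(nrow(sites)), function(i) {
    any(m$chrom == sites$chrom[i] &
          m$start <= sites$pos[i] - 1 & sites$pos[i] - 1 < m$end)
  }, logical(1))
  expect_equal(site_passes_lc(sites, m), !scan)
})

test_that("DP stage caps summed depth at the threshold inclusively", {
  cfg <- filter_config(n_samples = 4)
  s <- make_sites("chr1", c(1, 2, 3),
                  ref_ad = matrix(c(375, 375, 0, 375, 375, 0, 375, 375, 0,
                                    375, 376, 0), 3, 4),
                  alt_ad = matrix(0L, 3, 4))
  expect_equal(site_total_depth(s), c(1500, 1501, 0))
  expect_equal(site_passes_depth(s, cfg), c(TRUE, FALSE, TRUE))
})

test_that("genotype calling follows the read-support rule", {
  expect_equal(call_genotype(1, 2), 1L)          # >=2 alt + >=1 ref: het
  expect_equal(call_genotype(0, 1), NA_integer_) # below every threshold
  expect_equal(call_genotype(10, 0), 0L)         # symmetric homozygote rule
  expect_equal(call_genotype(0, 5), 2L)
  expect_equal(call_genotype(1, 0), NA_integer_) # one ref read is not enough
  expect_equal(call_genotype(NA, 5), NA_integer_)
  m <- call_genotype(matrix(c(1, 0, 10, 0), 2, 2), matrix(c(2, 1, 0, 5), 2, 2))
  expect_equal(m, matrix(c(1L, NA, 0L, 2L), 2, 2))
})

test_that("NS stage requires the minimum number of callable samples", {
  sheet <- tiny_sheet(n_dh = 11, pops = c(P1 = 25, P2 = 25))  # 61 samples
  cfg <- filter_config(n_samples = 61)
  expect_equal(cfg$min_samples, 58)
  gt58 <- matrix(0L, 1, 61); gt58[1, 1:3] <- NA
  gt57 <- matrix(0L, 1, 61); gt57[1, 1:4] <- NA
  s <- make_sites("chr1", c(1, 2, 3), n_samples = 61,
                  gt = rbind(gt58, gt57, matrix(NA_integer_, 1, 61)))
  expect_equal(site_passes_ns(s, cfg), c(TRUE, FALSE, FALSE))
  # the default scales as ceiling(0.95 n) away from the 61-sample design
  expect_equal(filter_config(n_samples = 40)$min_samples, 38)
})

test_that("the cascade removes exactly the designed violations, in order", {
  sheet <- tiny_sheet(n_dh = 1, pops = c(P1 = 2))  # 3 samples, min_samples 3
  cfg <- filter_config(n_samples = 3)
  ok_ad <- matrix(10L, 1, 3)
  bad_ns_ref <- matrix(c(10L, 0L, 10L), 1, 3)  # middle sample uncallable
  bad_ns_alt <- matrix(c(10L, 1L, 10L), 1, 3)
  deep <- matrix(400L, 1, 3)                   # 2400 reads total
  sites <- variant_table(
    chrom = rep("chr1", 10),
    pos = c(100, 200, 300, 400, 500, 600, 700, 800, 900, 1000),
    ref = rep("A", 10),
    alt = c("G", "G", "G", "AT", "G", "G", "G", "G", "G", "G"),
    qual = c(50, 30, 50, 50, 50, 50, 50, 50, 50, 50),
    ref_ad = do.call(rbind, list(ok_ad, ok_ad, ok_ad, ok_ad, ok_ad, ok_ad,
                                 deep, ok_ad, bad_ns_ref, ok_ad)),
    alt_ad = do.call(rbind, list(ok_ad, ok_ad, ok_ad, ok_ad, ok_ad, ok_ad,
                                 deep, ok_ad, bad_ns_alt, ok_ad))
  )
  masks <- tibble::tibble(chrom = "chr1", start = 450, end = 550) # hits pos 500
  res <- apply_filter_cascade(sites, masks, cfg)
  # designed losses: 200 (QUAL=30) and 400 (indel record) at QUAL,
  # 500 (masked) at LC, 700 (excess depth) at DP, 900 (2 callable) at NS
  expect_equal(res$sites$pos, c(100, 300, 600, 800, 1000))
  expect_equal(res$ledger$stage, c("QUAL", "LC", "DP", "NS"))
  expect_equal(res$ledger$entering, c(10, 8, 7, 6))
  expect_equal(res$ledger$passing, c(8, 7, 6, 5))
  expect_equal(res$ledger$removed, c(2, 1, 1, 1))
  # survivors carry re-called genotypes (10 ref / 10 alt reads: het)
  expect_equal(unname(res$sites$gt[1, ]), rep(1L, 3))

  # empty input: empty output, all-zero ledger
  res0 <- apply_filter_cascade(sites[0, ], masks, cfg)
  expect_equal(nrow(res0$sites), 0)
  expect_true(all(res0$ledger$entering == 0))

  # tidy/glance accessors
  expect_equal(broom::tidy(res), res$ledger)
  expect_equal(broom::glance(res)$n_out, 5)
})

test_that("the surviving set is invariant to stage order", {
  sheet <- tiny_sheet(n_dh = 2, pops = c(P1 = 3))
  set.seed(77)
  sites <- random_variant_table(300, sheet)
  sites$alt[sample(300, 20)] <- "AT"                 # indels
  masks <- tibble::tibble(chrom = "chr1", start = c(0, 5000), end = c(800, 6000))
  cfg <- filter_config(n_samples = 5, max_depth = 90)
  cascade <- apply_filter_cascade(sites, masks, cfg)

  # apply the four predicates independently and intersect
  indels <- indel_positions(sites)
  recalled <- recall_genotypes(sites, cfg)
  keep <- site_passes_qual(sites, indels, cfg) &
    site_passes_lc(sites, masks) &
    site_passes_depth(sites, cfg) &
    site_passes_ns(recalled, cfg)
  expect_equal(cascade$sites$pos, sites$pos[keep])

  # cascade monotonicity: each stage enters what the previous stage passed
  expect_true(all(cascade$ledger$passing <= cascade$ledger$entering))
  expect_equal(cascade$ledger$entering[-1], cascade$ledger$passing[-4])
})

test_that("almost all adequately covered true SNPs survive an artifact-free cascade", {
  cfg <- small_sim_config(
    lc_tract_rate = 0, indel_density = 0, high_depth_rate = 0,
    subqual_rate = 0, dropout = 0, coverage_mean = 20, coverage_min = 12
  )
  sim <- simulate_study(cfg, seed = 303)
  truth_snps <- sim$truth[sim$truth$class == "true_snp", ]
  res <- apply_filter_cascade(sim$sites, mask_genome(sim$genome),
                              filter_config(n_samples = nrow(sim$sheet)))
  surviving <- truth_key(res$sites)
  rate <- mean(truth_key(truth_snps) %in% surviving)
  expect_gte(rate, 0.99)
})
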