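#' Count heterozygous doubled-haploid genotypes per site
#'
#' Doubled-haploid (DH) individuals are expected homozygous at every
#' single-copy locus, so called heterozygotes in DH lines mark collapsed
#' paralogs. Missing DH genotypes do not count.
#'
#' @param sites A [variant_table()] with genotypes called.
#' @param sheet The matching [sample_sheet()].
#' @return Integer vector: heterozygous DH count per site.
#' @export
dh_het_count <- function(sites, sheet) {
  idx <- dh_index(sheet)
  if (length(idx) == 0) abort("sample sheet has no DH lines")
  g <- sites$gt[, idx, drop = FALSE]
  as.integer(rowSums(g == 1L, na.rm = TRUE))
}

#' Classify sites as retained SNPs or putative PSVs/MSVs
#'
#' A site heterozygous in at least `threshold` DH lines is flagged as a
#' putative paralogous sequence variant / multisite variant. The default
#' threshold of 2 tolerates rare residual maternal heterozygosity in single
#' DH lines.
#'
#' @inheritParams dh_het_count
#' @param threshold Minimum DH heterozygote count to flag (default 2).
#' @return Character vector: `"retained_snp"` or `"putative_psv_msv"`.
#' @export
classify_psv <- function(sites, sheet, threshold = 2) {
  ifelse(dh_het_count(sites, sheet) >= threshold,
         "putative_psv_msv", "retained_snp")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided conditional exact test: given the allele counts, the p-value is
#' the summed probability of all heterozygote counts (of the same parity)
#' whose conditional probability does not exceed that of the observed
#' configuration. Valid at the small per-population sample sizes (4-12) where
#' the chi-square approximation breaks down. Probabilities are computed by
#' the standard mode-anchored recurrence and normalised.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (vectorised).
#' @return p-values in `[0, 1]`; monomorphic input gives 1.
#' @examples
#' hwe_exact_test(25, 50, 25)
#' hwe_exact_test(0, 50, 0) # extreme heterozygote excess
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- cbind(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0, na.rm = TRUE)) abort("genotype counts must be >= 0")
  hwe_exact_vec(counts)
}

#' Conditional distribution of heterozygote counts under HWE
#'
#' Probability of each possible heterozygote count given `n` diploid
#' individuals and `n_minor` copies of the minor allele, conditional on the
#' allele counts. Exposed because the exact test, the threshold sweep, and
#' exhaustive verification all reuse it.
#'
#' @param n Number of individuals.
#' @param n_minor Minor allele count (0..n).
#' @return Tibble with `het` and `prob` (sums to 1).
#' @export
hwe_het_distribution <- function(n, n_minor) {
  if (n_minor > n) abort("n_minor must be <= n (minor allele count)")
  n1 <- n_minor
  hets <- seq(n1 %% 2, n1, by = 2)
  hets <- hets[hets >= 2 * n1 - 2 * n]   # hom_common >= 0 always holds for minor allele
  probs <- numeric(length(hets))
  probs[1] <- 1
  if (length(hets) > 1) {
    for (j in 2:length(hets)) {
      h <- hets[j - 1]
      hom_r <- (n1 - h) / 2
      hom_c <- n - h - hom_r
      # P(h+2)/P(h) = 4 * hom_r * hom_c / ((h+1)(h+2))
      probs[j] <- probs[j - 1] * 4 * hom_r * hom_c / ((h + 1) * (h + 2))
    }
  }
  probs <- probs / sum(probs)
  tibble(het = as.integer(hets), prob = probs)
}

#' Observed heterozygosity per site
#'
#' Fraction of called genotypes that are heterozygous within a sample subset.
#'
#' @inheritParams dh_het_count
#' @param subset `NULL` (all samples), `"dh"`, `"non_dh"`, or population
#'   label(s).
#' @return Numeric vector per site (NaN where no genotype is called).
#' @export
observed_heterozygosity <- function(sites, sheet, subset = "non_dh") {
  idx <- subset_index(sheet, subset)
  g <- sites$gt[, idx, drop = FALSE]
  rowSums(g == 1L, na.rm = TRUE) / rowSums(!is.na(g))
}

# genotype counts within a subset -> matrix with columns hom_ref, het, hom_alt
genotype_counts <- function(sites, sheet, subset = "non_dh") {
  idx <- subset_index(sheet, subset)
  g <- sites$gt[, idx, drop = FALSE]
  cbind(
    hom_ref = rowSums(g == 0L, na.rm = TRUE),
    het = rowSums(g == 1L, na.rm = TRUE),
    hom_alt = rowSums(g == 2L, na.rm = TRUE)
  )
}

#' Screen sites with doubled-haploid heterozygosity
#'
#' The fifth filter stage: classifies every site by its DH heterozygote count
#' and annotates each with the observed heterozygosity and exact
#' Hardy-Weinberg p-value among the outbred (non-DH) samples — the two
#' quantities that diagnose PSVs/MSVs (flagged loci show excess
#' heterozygosity and HWE deviation).
#'
#' @inheritParams classify_psv
#' @return Tibble: `chrom`, `pos`, `dh_het_count`, `classification`,
#'   `outbred_ho`, `hwe_p`.
#' @export
dh_screen <- function(sites, sheet, threshold = 2) {
  counts <- genotype_counts(sites, sheet, "non_dh")
  tibble(
    chrom = sites$chrom, pos = sites$pos,
    dh_het_count = dh_het_count(sites, sheet),
    classification = classify_psv(sites, sheet, threshold),
    outbred_ho = observed_heterozygosity(sites, sheet, "non_dh"),
    hwe_p = hwe_exact_vec(counts)
  )
}

# vectorised exact test with caching on (n, n_minor): screening thousands of
# sites hits few distinct allele-count configurations. The tie tolerance
# absorbs floating-point noise between symmetric configurations.
hwe_exact_vec <- function(counts) {
  n <- rowSums(counts)
  n1 <- pmin(2 * counts[, 1] + counts[, 2], 2 * counts[, 3] + counts[, 2])
  out <- rep(NA_real_, nrow(counts))
  valid <- which(!is.na(n) & n >= 1)
  key <- paste(n[valid], n1[valid])
  for (k in unique(key)) {
    sel <- valid[key == k]
    d <- hwe_het_distribution(n[sel[1]], n1[sel[1]])
    p_by_het <- vapply(d$prob, function(p) sum(d$prob[d$prob <= p * (1 + 1e-7)]),
                       numeric(1))
    out[sel] <- p_by_het[match(counts[sel, 2], d$het)]
  }
  out
}

#' Sweep the DH heterozygosity threshold
#'
#' For every threshold `k`, flags the loci with DH heterozygote count `>= k`
#' and summarises the flagged set: size, mean outbred observed
#' heterozygosity, and percentage of loci deviating from Hardy-Weinberg
#' equilibrium (exact p < 0.05) among the outbred samples. Rows are labelled
#' `Het > k-1` (and `Het = n_DH` for the maximal threshold).
#'
#' @inheritParams dh_het_count
#' @param thresholds Integer thresholds to sweep (default `1:n_DH`).
#' @return Tibble with `threshold`, `label`, `n_flagged`, `mean_outbred_ho`,
#'   `pct_hwe_dev`.
#' @export
threshold_sweep <- function(sites, sheet, thresholds = NULL) {
  n_dh <- length(dh_index(sheet))
  thresholds <- thresholds %||% seq_len(n_dh)
  screen <- dh_screen(sites, sheet, threshold = min(thresholds))
  map(thresholds, function(k) {
    flagged <- screen$dh_het_count >= k
    tibble(
      threshold = k,
      label = if (k == n_dh) paste0("Het = ", n_dh) else paste0("Het > ", k - 1),
      n_flagged = sum(flagged),
      mean_outbred_ho = if (any(flagged)) mean(screen$outbred_ho[flagged], na.rm = TRUE) else NA_real_,
      pct_hwe_dev = if (any(flagged)) pct_int(sum(screen$hwe_p[flagged] < 0.05, na.rm = TRUE),
                                              sum(flagged)) else NA_real_
    )
  }) |> list_rbind()
}

#' Flagged-locus density per chromosome arm
#'
#' Counts flagged (putative PSV/MSV) sites per chromosome arm and divides by
#' arm length. In a genome with residual tetraploidy the duplicated
#' (delayed-rediploidization) arm pairs carry a much higher density.
#'
#' @param flagged_sites Tibble with `chrom`, `pos` of flagged loci (e.g. the
#'   flagged rows of [dh_screen()]).
#' @param build A [genome_build()].
#' @return Tibble: `arm`, `chrom`, `length`, `n_flagged`, `density`,
#'   `duplicated`.
#' @export
arm_density <- function(flagged_sites, build) {
  arm <- assign_arm(flagged_sites$chrom, flagged_sites$pos, build)
  counts <- table(factor(arm, levels = build$arm))
  tibble(
    arm = build$arm, chrom = build$chrom, length = build$length,
    n_flagged = as.integer(counts[build$arm]),
    density = as.integer(counts[build$arm]) / build$length,
    duplicated = build$duplicated
  )
}
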