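#' Minor allele frequency per site
#'
#' Alternate-allele copies are counted over `2 x` the non-missing genotypes in
#' the chosen subset (every diploid sample contributes two alleles); the MAF
#' is the folded frequency `min(f, 1 - f)`.
#'
#' @param sites A [variant_table()] with genotypes called.
#' @param sheet The matching [sample_sheet()].
#' @param subset `NULL` (all samples, the database convention), `"dh"`,
#'   `"non_dh"`, or population label(s).
#' @return Numeric vector of MAFs in `[0, 0.5]` (NaN with no called genotypes).
#' @export
minor_allele_frequency <- function(sites, sheet, subset = NULL) {
  f <- alt_allele_frequency(sites, sheet, subset)
  pmin(f, 1 - f)
}

alt_allele_frequency <- function(sites, sheet, subset = NULL) {
  idx <- subset_index(sheet, subset)
  g <- sites$gt[, idx, drop = FALSE]
  rowSums(g, na.rm = TRUE) / (2 * rowSums(!is.na(g)))
}

#' Minor allele frequency spectrum
#'
#' Histogram of per-site MAFs on fixed bins, plus the proportion of sites
#' below 0.05 (the share of population-specific rare variants).
#'
#' @inheritParams minor_allele_frequency
#' @param breaks Bin edges over `[0, 0.5]`.
#' @return Tibble with `bin`, `lower`, `upper`, `count`, `prop`; the
#'   proportion of sites with MAF < 0.05 is attached as attribute
#'   `prop_below_05`.
#' @export
maf_spectrum <- function(sites, sheet, breaks = seq(0, 0.5, by = 0.05),
                         subset = NULL) {
  maf <- minor_allele_frequency(sites, sheet, subset)
  maf <- maf[!is.na(maf)]
  h <- hist(maf, breaks = breaks, plot = FALSE, right = FALSE,
            include.lowest = TRUE)
  # hist(right = FALSE) uses [lo, hi) bins but closes the last bin
  out <- tibble(
    bin = paste0("[", head(breaks, -1), ",", tail(breaks, -1),
                 c(rep(")", length(breaks) - 2), "]")),
    lower = head(breaks, -1), upper = tail(breaks, -1),
    count = h$counts,
    prop = if (length(maf) > 0) h$counts / length(maf) else rep(0, length(h$counts))
  )
  attr(out, "prop_below_05") <- if (length(maf) > 0) mean(maf < 0.05) else 0
  out
}

#' Per-population polymorphism summary
#'
#' For every population (and the DH group), restricts to sites with genotype
#' data for every fish in the population and reports how many are polymorphic
#' (both alleles observed among the called genotypes), the percentage, and
#' the mean MAF and mean observed heterozygosity over the polymorphic sites.
#' Percentages are rounded to integers and means to two decimals, the
#' conventional table precision.
#'
#' @inheritParams minor_allele_frequency
#' @return Tibble with one row per population: `population`, `n_fish`,
#'   `n_sites_full_data`, `n_polymorphic`, `pct_polymorphic`,
#'   `mean_maf_polymorphic`, `mean_ho_polymorphic`.
#' @export
population_polymorphism <- function(sites, sheet) {
  groups <- split(seq_len(nrow(sheet)), ifelse(sheet$is_dh, "DH", sheet$population))
  imap(groups, function(idx, pop) {
    g <- sites$gt[, idx, drop = FALSE]
    full <- rowSums(!is.na(g)) == length(idx)
    gf <- g[full, , drop = FALSE]
    alt <- rowSums(gf)
    poly <- alt > 0 & alt < 2 * length(idx)
    f <- alt[poly] / (2 * length(idx))
    maf <- pmin(f, 1 - f)
    ho <- rowMeans(gf[poly, , drop = FALSE] == 1L)
    tibble(
      population = pop, n_fish = length(idx),
      n_sites_full_data = sum(full), n_polymorphic = sum(poly),
      pct_polymorphic = pct_int(sum(poly), sum(full)),
      mean_maf_polymorphic = round(mean(maf), 2),
      mean_ho_polymorphic = round(mean(ho), 2)
    )
  }) |> list_rbind() |> arrange(.data$population)
}

#' Windowed nucleotide diversity
#'
#' Per-site diversity uses the unbiased estimator
#' `pi_site = (n / (n - 1)) * 2 * p * (1 - p)` with `n` the called allele
#' count and `p` the alternate allele frequency; window diversity is the sum
#' of site values divided by the window width in bp (trailing partial windows
#' are normalised by their true width). The genome mean is the mean over
#' windows.
#'
#' @inheritParams minor_allele_frequency
#' @param build A [genome_build()] giving chromosome lengths.
#' @param window Window width in bp (default 20,000).
#' @return Tibble of windows (`chrom`, `start`, `end`, `n_snps`, `pi`); the
#'   mean over windows is attached as attribute `genome_mean` and returned by
#'   [pi_genome_mean()].
#' @export
nucleotide_diversity_windows <- function(sites, sheet, build, window = 20000,
                                         subset = NULL) {
  idx <- subset_index(sheet, subset)
  g <- sites$gt[, idx, drop = FALSE]
  n_alleles <- 2 * rowSums(!is.na(g))
  p <- rowSums(g, na.rm = TRUE) / n_alleles
  pi_site <- ifelse(n_alleles > 1, n_alleles / (n_alleles - 1) * 2 * p * (1 - p), 0)

  lens <- chrom_lengths(build)
  out <- map(seq_len(nrow(lens)), function(i) {
    chr <- lens$chrom[i]
    starts <- seq(0, lens$length[i] - 1, by = window)
    ends <- pmin(starts + window, lens$length[i])
    sel <- sites$chrom == chr
    wi <- findInterval(sites$pos[sel] - 1, starts)
    tibble(
      chrom = chr, start = starts, end = ends,
      n_snps = as.integer(table(factor(wi, levels = seq_along(starts)))),
      pi = as.numeric(tapply(pi_site[sel], factor(wi, levels = seq_along(starts)),
                             sum, default = 0)) / (ends - starts)
    )
  }) |> list_rbind()
  out$pi[is.na(out$pi)] <- 0
  attr(out, "genome_mean") <- mean(out$pi)
  out
}

#' @rdname nucleotide_diversity_windows
#' @param windows Output of [nucleotide_diversity_windows()].
#' @export
pi_genome_mean <- function(windows) {
  attr(windows, "genome_mean") %||% mean(windows$pi)
}

#' Integer SNP spacing
#'
#' Average spacing in bp between SNPs, truncated (not rounded) to an integer:
#' `floor(length / n_snps)`.
#'
#' @param length_bp Sequence length in bp.
#' @param n_snps SNP count.
#' @return Integer spacing (NA when `n_snps` is 0).
#' @export
snp_rate_bp <- function(length_bp, n_snps) {
  ifelse(n_snps > 0, floor(length_bp / n_snps), NA_real_)
}

#' SNP density by chromosome
#'
#' Per-chromosome SNP counts and integer average spacing, plus a genome-wide
#' row over all chromosomes (`floor(sum(length) / sum(n))`) and the matching
#' SNPs-per-kb figure (`round(1000 / rate, 1)`).
#'
#' @param sites A [variant_table()] (or any tibble with `chrom`, `pos`).
#' @param build A [genome_build()].
#' @return Tibble with `chrom`, `length`, `n_snps`, `rate_bp`; the genome-wide
#'   row has `chrom = "all"`, and its SNPs-per-kb value is attached as
#'   attribute `snps_per_kb`.
#' @export
snp_density_table <- function(sites, build) {
  lens <- chrom_lengths(build)
  n <- table(factor(sites$chrom, levels = lens$chrom))
  per_chrom <- tibble(
    chrom = lens$chrom, length = lens$length,
    n_snps = as.integer(n),
    rate_bp = snp_rate_bp(lens$length, as.integer(n))
  )
  density_table_with_total(per_chrom)
}

#' @rdname snp_density_table
#' @param per_chrom Tibble with `chrom`, `length`, `n_snps` (pre-counted, e.g.
#'   a published survey table); the rate column is (re)computed.
#' @export
density_table_with_total <- function(per_chrom) {
  per_chrom$rate_bp <- snp_rate_bp(per_chrom$length, per_chrom$n_snps)
  total <- tibble(
    chrom = "all", length = sum(per_chrom$length),
    n_snps = sum(per_chrom$n_snps),
    rate_bp = snp_rate_bp(sum(per_chrom$length), sum(per_chrom$n_snps))
  )
  out <- bind_rows(per_chrom, total)
  attr(out, "snps_per_kb") <- round(1000 / total$rate_bp, 1)
  out
}

#' @importFrom graphics hist
NULL
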