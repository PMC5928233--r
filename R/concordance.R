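#' Classify agreement between two call sets
#'
#' Joins two bi-allelic SNP call sets by (chrom, pos) and classifies every
#' position present in either set: called by A only, by B only, by both with
#' the same alternate allele, or by both with different alternate alleles.
#' Sites are keyed by position only; a REF mismatch at a shared position is
#' classified as `same_site_diff_alt`, since both callers share one reference
#' and a mismatch reflects representation differences.
#'
#' @param callset_a,callset_b [variant_table()] tibbles sorted by
#'   (chrom, pos), bi-allelic SNPs only.
#' @return Tibble with `chrom`, `pos`, `category` (one of `a_only`, `b_only`,
#'   `same_site_same_alt`, `same_site_diff_alt`), `alt_a`, `alt_b`.
#' @export
classify_sites <- function(callset_a, callset_b) {
  if (!is_sorted_sites(callset_a) || !is_sorted_sites(callset_b)) {
    abort("call sets must be sorted by (chrom, pos)")
  }
  a <- tibble(chrom = callset_a$chrom, pos = callset_a$pos, alt_a = callset_a$alt)
  b <- tibble(chrom = callset_b$chrom, pos = callset_b$pos, alt_b = callset_b$alt)
  full_join(a, b, by = c("chrom", "pos")) |>
    mutate(category = dplyr::case_when(
      is.na(.data$alt_b) ~ "a_only",
      is.na(.data$alt_a) ~ "b_only",
      .data$alt_a == .data$alt_b ~ "same_site_same_alt",
      TRUE ~ "same_site_diff_alt"
    )) |>
    arrange(.data$chrom, .data$pos) |>
    select("chrom", "pos", "category", "alt_a", "alt_b")
}

#' Summarise concordance records
#'
#' Reports the four category counts and the two percentages of the standard
#' accounting convention: the share of same-site-same-ALT calls out of the
#' total combined set (all four categories; printed as an integer percent)
#' and the share of ALT disagreements out of the sites called by both
#' pipelines (printed to three decimals).
#'
#' @param records Output of [classify_sites()].
#' @return One-row tibble with counts and both percentages.
#' @examples
#' # the accounting convention on published final-step counts:
#' concordance_counts_summary(5799376, 2855191, 31441105, 1205)
#' @export
concordance_summary <- function(records) {
  concordance_counts_summary(
    sum(records$category == "a_only"),
    sum(records$category == "b_only"),
    sum(records$category == "same_site_same_alt"),
    sum(records$category == "same_site_diff_alt")
  )
}

#' @rdname concordance_summary
#' @param n_a_only,n_b_only,n_same_alt,n_diff_alt Category counts.
#' @export
concordance_counts_summary <- function(n_a_only, n_b_only, n_same_alt, n_diff_alt) {
  combined <- n_a_only + n_b_only + n_same_alt + n_diff_alt
  shared <- n_same_alt + n_diff_alt
  tibble(
    n_a_only = n_a_only, n_b_only = n_b_only,
    n_same_alt = n_same_alt, n_diff_alt = n_diff_alt,
    pct_same_alt_of_combined = pct_int(n_same_alt, combined),
    pct_diff_alt_of_shared = if (shared > 0) pct_dec(n_diff_alt, shared, 3) else 0
  )
}

#' SNP yield by number of genotyped samples
#'
#' For each level `n` in `ns_levels`, counts the sites whose callable-sample
#' count equals `n`, per call set and for their same-site-same-ALT
#' intersection. This is the accounting used to judge how fast the SNP yield
#' decays as the minimum-sample threshold is relaxed.
#'
#' @param callset_a,callset_b [variant_table()] tibbles with genotypes
#'   (re)called.
#' @param ns_levels Integer vector of callable-sample counts to report.
#' @return Tibble with `n_samples`, `n_a`, `n_b`, `n_both`.
#' @export
missingness_accumulation <- function(callset_a, callset_b,
                                     ns_levels = NULL) {
  ns_levels <- ns_levels %||% sort(unique(c(
    rowSums(!is.na(callset_a$gt)), rowSums(!is.na(callset_b$gt))
  )), decreasing = TRUE)
  key <- function(s) paste(s$chrom, s$pos, s$alt, sep = ":")
  ns_a <- rowSums(!is.na(callset_a$gt))
  ns_b <- rowSums(!is.na(callset_b$gt))
  shared <- intersect(key(callset_a), key(callset_b))
  in_both_a <- key(callset_a) %in% shared
  map(ns_levels, function(n) {
    tibble(
      n_samples = n,
      n_a = sum(ns_a == n),
      n_b = sum(ns_b == n),
      n_both = sum(in_both_a & ns_a == n)
    )
  }) |> list_rbind()
}
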