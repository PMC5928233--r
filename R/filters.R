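#' Filter cascade configuration
#'
#' Thresholds for the five-stage SNP filter cascade. Defaults follow the
#' discovery design this package implements: bi-allelic SNPs with
#' `QUAL > 30` and no indel within 4 bp; low-complexity masking with a
#' 64-base DUST window; summed read depth at most 1,500 (24.6 reads per
#' sample for 61 samples); genotype support of at least two alternate and one
#' reference read; and callable genotypes in at least 58 of 61 samples. When
#' the panel has `n_samples != 61`, `min_samples` defaults to
#' `ceiling(0.95 * n_samples)` (58/61 is 95%).
#'
#' @param min_qual Phred QUAL threshold; sites must exceed it strictly.
#' @param indel_distance Maximum distance (bp) to an indel that disqualifies a
#'   SNP (inclusive).
#' @param max_depth Maximum read depth summed over samples.
#' @param min_samples Minimum count of samples with a called genotype.
#' @param min_alt_reads,min_ref_reads Read support required to call a
#'   heterozygote (and, symmetrically, `min_alt_reads` reads of the observed
#'   allele with zero of the other for a homozygote).
#' @param dust_window,dust_threshold Low-complexity masking parameters, see
#'   [dust_mask()].
#' @param n_samples Panel size used to derive the `min_samples` default.
#'
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_qual = 30, indel_distance = 4, max_depth = 1500,
                          min_samples = NULL, min_alt_reads = 2,
                          min_ref_reads = 1, dust_window = 64,
                          dust_threshold = 2, n_samples = 61) {
  min_samples <- min_samples %||% ceiling(0.95 * n_samples)
  cfg <- list(
    min_qual = min_qual, indel_distance = indel_distance,
    max_depth = max_depth, min_samples = min_samples,
    min_alt_reads = min_alt_reads, min_ref_reads = min_ref_reads,
    dust_window = dust_window, dust_threshold = dust_threshold
  )
  if (any(unlist(cfg) < 0)) abort("filter thresholds must be >= 0")
  structure(cfg, class = "filter_config")
}

#' Extract indel anchor positions from a call set
#'
#' Indel proximity is judged against the raw call set before SNP extraction,
#' using the VCF anchor position of each indel record.
#'
#' @param sites A [variant_table()].
#' @return Tibble with `chrom`, `pos` of indel records.
#' @export
indel_positions <- function(sites) {
  sites |> filter(.data$is_indel) |> select("chrom", "pos")
}

#' Stage 1: quality / bi-allelic / indel proximity
#'
#' A site passes if it is a bi-allelic SNP (single-base REF and a single
#' single-base ALT), has `QUAL` strictly greater than `min_qual`, and no indel
#' anchor lies within `indel_distance` bases (`|pos_indel - pos| <=
#' indel_distance`).
#'
#' @param sites A [variant_table()].
#' @param indels Tibble of indel positions (`chrom`, `pos`), e.g. from
#'   [indel_positions()].
#' @param cfg A [filter_config()].
#' @return Logical vector, one element per site.
#' @export
site_passes_qual <- function(sites, indels, cfg = filter_config()) {
  ok <- is_biallelic_snp(sites) & !sites$is_indel & sites$qual > cfg$min_qual
  if (nrow(indels) > 0 && any(ok)) {
    near <- logical(nrow(sites))
    for (chr in unique(sites$chrom)) {
      ip <- sort(indels$pos[indels$chrom == chr])
      if (length(ip) == 0) next
      sel <- which(sites$chrom == chr)
      # nearest indel position via binary search on the sorted anchors
      idx <- findInterval(sites$pos[sel], ip)
      lo <- pmax(idx, 1L)
      hi <- pmin(idx + 1L, length(ip))
      d <- pmin(abs(sites$pos[sel] - ip[lo]), abs(sites$pos[sel] - ip[hi]))
      near[sel] <- d <= cfg$indel_distance
    }
    ok <- ok & !near
  }
  ok
}

#' Stage 2: low-complexity mask
#'
#' @param sites A [variant_table()].
#' @param masks Merged mask regions (`chrom`, `start`, `end`, 0-based
#'   half-open), from [mask_genome()] or [read_bed()].
#' @return Logical vector: `TRUE` where the site is outside every mask.
#' @export
site_passes_lc <- function(sites, masks) {
  !in_mask(sites$chrom, sites$pos, masks)
}

#' Stage 3: maximum summed depth
#'
#' Total reads over all samples must not exceed `max_depth`; excess depth
#' marks likely repeats or collapsed multi-copy regions.
#'
#' @inheritParams site_passes_qual
#' @return Logical vector.
#' @export
site_passes_depth <- function(sites, cfg = filter_config()) {
  site_total_depth(sites) <= cfg$max_depth
}

#' Call genotypes from allele read support
#'
#' A heterozygote needs at least `min_alt_reads` reads supporting the
#' alternate allele and `min_ref_reads` supporting the reference. Homozygotes
#' are called symmetrically: at least `min_alt_reads` reads of the observed
#' allele and zero of the other. Anything else is missing.
#'
#' @param ref_reads,alt_reads Integer vectors or matrices of read counts.
#' @param cfg A [filter_config()].
#' @return Genotype codes (0 hom-ref, 1 het, 2 hom-alt, NA missing) with the
#'   shape of the input.
#' @examples
#' call_genotype(c(1, 0, 10, 0), c(2, 1, 0, 5))
#' @export
call_genotype <- function(ref_reads, alt_reads, cfg = filter_config()) {
  g <- ifelse(alt_reads >= cfg$min_alt_reads & ref_reads >= cfg$min_ref_reads, 1L,
       ifelse(alt_reads >= cfg$min_alt_reads & ref_reads == 0L, 2L,
       ifelse(ref_reads >= cfg$min_alt_reads & alt_reads == 0L, 0L, NA_integer_)))
  g[is.na(ref_reads) | is.na(alt_reads)] <- NA_integer_
  if (is.matrix(ref_reads)) dimnames(g) <- dimnames(ref_reads)
  g
}

#' Re-call all genotypes of a variant table from read support
#'
#' @param sites A [variant_table()].
#' @inheritParams call_genotype
#' @return The table with its `gt` matrix replaced.
#' @export
recall_genotypes <- function(sites, cfg = filter_config()) {
  sites$gt <- call_genotype(sites$ref_ad, sites$alt_ad, cfg)
  sites
}

#' Stage 4: minimum genotyped samples
#'
#' @inheritParams site_passes_qual
#' @return Logical vector: `TRUE` where at least `min_samples` genotypes are
#'   non-missing.
#' @export
site_passes_ns <- function(sites, cfg = filter_config()) {
  rowSums(!is.na(sites$gt)) >= cfg$min_samples
}

#' Apply the filter cascade
#'
#' Runs the four site-level stages in order QUAL -> LC -> DP -> NS with
#' per-stage accounting; the DH paralog screen (stage five) lives in
#' [dh_screen()]. Genotypes are re-called from read support (see
#' [call_genotype()]) before the NS stage unless `recall = FALSE`, in which
#' case the genotypes carried in the input (e.g. the callers' own GT fields)
#' are used.
#'
#' @param sites A [variant_table()]; the raw call set, indel records included
#'   (they are used for the proximity test, then dropped by stage 1).
#' @param masks Merged low-complexity mask regions.
#' @param cfg A [filter_config()].
#' @param recall Re-call genotypes from AD before the NS stage (default TRUE).
#' @param indels Indel anchor positions for the proximity test; defaults to
#'   the indel records of `sites` itself, but a pipeline intersecting two
#'   call sets should pass the union of both callers' indels.
#' @return An object of class `filter_cascade`: a list with `sites` (the
#'   surviving variant table, genotypes filled in) and `ledger` (tibble with
#'   `stage`, `entering`, `passing`, `removed`).
#' @export
apply_filter_cascade <- function(sites, masks, cfg = filter_config(),
                                 recall = TRUE, indels = NULL) {
  indels <- indels %||% indel_positions(sites)
  ledger <- tibble(stage = character(0), entering = integer(0),
                   passing = integer(0))
  stage <- function(name, keep) {
    ledger <<- bind_rows(ledger, tibble(
      stage = name, entering = nrow(sites), passing = sum(keep)
    ))
    sites[keep, , drop = FALSE]
  }
  sites <- stage("QUAL", site_passes_qual(sites, indels, cfg))
  sites <- stage("LC", site_passes_lc(sites, masks))
  sites <- stage("DP", site_passes_depth(sites, cfg))
  if (recall) sites <- recall_genotypes(sites, cfg)
  sites <- stage("NS", site_passes_ns(sites, cfg))
  ledger$removed <- ledger$entering - ledger$passing
  structure(list(sites = sites, ledger = ledger), class = "filter_cascade")
}

#' @export
print.filter_cascade <- function(x, ...) {
  cat("SNP filter cascade:", nrow(x$sites), "sites surviving\n")
  print(x$ledger)
  invisible(x)
}

#' Tidy a filter cascade into its stage ledger
#'
#' @param x A `filter_cascade` object.
#' @param ... Unused.
#' @return The stage ledger tibble.
#' @export
tidy.filter_cascade <- function(x, ...) x$ledger

#' One-row summary of a filter cascade
#'
#' @param x A `filter_cascade` object.
#' @param ... Unused.
#' @return Tibble with `n_in`, `n_out`, `pct_retained`.
#' @export
glance.filter_cascade <- function(x, ...) {
  n_in <- x$ledger$entering[1]
  n_out <- tail(x$ledger$passing, 1)
  tibble(n_in = n_in, n_out = n_out, pct_retained = pct_int(n_out, n_in))
}

#' Write a filter ledger as TSV
#'
#' @param cascade A `filter_cascade` object or its ledger tibble.
#' @param path Output path.
#' @export
write_ledger <- function(cascade, path) {
  ledger <- if (inherits(cascade, "filter_cascade")) cascade$ledger else cascade
  readr::write_tsv(ledger, path)
  invisible(path)
}
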