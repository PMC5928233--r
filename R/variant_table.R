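#' Construct a variant site table
#'
#' The central container of the package: one row per candidate variant site,
#' with per-sample read support and genotypes held as matrix columns whose
#' columns follow the sample-sheet order. Matrix columns keep the table a
#' plain tibble (pipe-friendly, filterable by row) while making the
#' across-sample arithmetic of the filters vectorisable.
#'
#' Genotypes are coded as integers: `0` hom-ref, `1` het, `2` hom-alt,
#' `NA` missing.
#'
#' @param chrom,pos,ref,alt,qual Per-site vectors: chromosome, 1-based
#'   position, reference allele, alternate allele(s) (comma-separated when
#'   multi-allelic), phred-scaled variant quality.
#' @param ref_ad,alt_ad Integer matrices (sites x samples) of reads supporting
#'   the reference / alternate allele.
#' @param gt Integer matrix (sites x samples) of genotype codes, or `NULL` to
#'   mark all genotypes missing.
#'
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `is_indel`, `ref_ad`, `alt_ad`, `gt`.
#' @export
variant_table <- function(chrom, pos, ref, alt, qual, ref_ad, alt_ad, gt = NULL) {
  n <- length(chrom)
  ref_ad <- as_site_matrix(ref_ad, n)
  alt_ad <- as_site_matrix(alt_ad, n)
  if (is.null(gt)) {
    gt <- matrix(NA_integer_, n, ncol(ref_ad), dimnames = dimnames(ref_ad))
  }
  gt <- as_site_matrix(gt, n)
  if (any(pos < 1, na.rm = TRUE)) abort("pos must be >= 1")
  if (any(qual < 0, na.rm = TRUE)) abort("qual must be >= 0")
  tibble(
    chrom = as.character(chrom),
    pos = as.numeric(pos),
    ref = as.character(ref),
    alt = as.character(alt),
    qual = as.numeric(qual),
    is_indel = nchar(ref) > 1L | vapply(strsplit(as.character(alt), ","),
                                        function(a) any(nchar(a) > 1L), logical(1)),
    ref_ad = ref_ad,
    alt_ad = alt_ad,
    gt = gt
  )
}

as_site_matrix <- function(x, n) {
  if (!is.matrix(x)) x <- matrix(x, nrow = n)
  storage.mode(x) <- "integer"
  if (nrow(x) != n) abort("per-sample matrix rows must match number of sites")
  x
}

empty_variant_table <- function(sheet) {
  m <- matrix(integer(0), 0, nrow(sheet), dimnames = list(NULL, sheet$sample_id))
  variant_table(character(0), numeric(0), character(0), character(0),
                numeric(0), m, m, m)
}

n_samples <- function(sites) ncol(sites$ref_ad)

# total read depth per site, summed over samples (the DP filter quantity)
site_total_depth <- function(sites) {
  ra <- sites$ref_ad; aa <- sites$alt_ad
  ra[is.na(ra)] <- 0L; aa[is.na(aa)] <- 0L
  rowSums(ra) + rowSums(aa)
}

is_sorted_sites <- function(sites) {
  if (nrow(sites) < 2) return(TRUE)
  # chromosome blocks must be contiguous, positions non-decreasing within block
  r <- rle(sites$chrom)
  if (anyDuplicated(r$values)) return(FALSE)
  all(unlist(tapply(sites$pos, factor(sites$chrom, levels = r$values),
                    function(p) !is.unsorted(p), simplify = FALSE)))
}

sort_sites <- function(sites) {
  sites[order(sites$chrom, sites$pos), , drop = FALSE]
}

# single-base ref, exactly one single-base alt
is_biallelic_snp <- function(sites) {
  nchar(sites$ref) == 1L & !grepl(",", sites$alt, fixed = TRUE) &
    nchar(sites$alt) == 1L
}
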