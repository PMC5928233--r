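#' Read a VCF call set into a variant table
#'
#' Parses a VCF 4.x file with `vcfR` and converts it to the package's site
#' tibble (see [variant_table()]). Per-sample read support is taken from the
#' `AD` FORMAT field; when `AD` is absent the counts are marked unknown and
#' depth-dependent filters fall back on `DP`. Genotypes are parsed from `GT`
#' when present, else marked missing. Sample columns are reordered to the
#' sample-sheet order; a sheet sample missing from the VCF is an error.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param sheet A [sample_sheet()] tibble.
#' @return A [variant_table()] tibble in file order.
#' @export
read_vcf <- function(path, sheet) {
  validate_sample_sheet(sheet)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  vcf_samples <- colnames(v@gt)[-1]
  missing <- setdiff(sheet$sample_id, vcf_samples)
  if (length(missing) > 0) {
    abort(paste0("samples in sheet but not in VCF: ", paste(missing, collapse = ", ")))
  }
  fix <- v@fix
  n <- nrow(fix)
  if (is.null(n) || n == 0) return(empty_variant_table(sheet))

  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  qual[is.na(qual)] <- 0

  fmt <- vcfR::vcf_field_names(v, tag = "FORMAT")$ID
  if ("AD" %in% fmt) {
    ad <- vcfR::extract.gt(v, element = "AD")[, sheet$sample_id, drop = FALSE]
    ref_ad <- vcfR::masplit(ad, record = 1, sort = 0, decreasing = 0)
    alt_ad <- vcfR::masplit(ad, record = 2, sort = 0, decreasing = 0)
  } else if ("DP" %in% fmt) {
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)[, sheet$sample_id, drop = FALSE]
    ref_ad <- matrix(NA_integer_, n, nrow(sheet))
    alt_ad <- ref_ad
    attr_dp <- dp
  } else {
    abort("VCF carries neither AD nor DP per-sample fields")
  }

  gt_codes <- if ("GT" %in% fmt) {
    gt_raw <- vcfR::extract.gt(v, element = "GT")[, sheet$sample_id, drop = FALSE]
    parse_gt_codes(gt_raw)
  } else NULL

  sites <- variant_table(
    chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"], qual = qual,
    ref_ad = ref_ad, alt_ad = alt_ad, gt = gt_codes
  )
  colnames(sites$ref_ad) <- colnames(sites$alt_ad) <- colnames(sites$gt) <- sheet$sample_id
  if (exists("attr_dp", inherits = FALSE)) {
    storage.mode(attr_dp) <- "integer"
    sites$dp <- attr_dp
  }
  sites
}

parse_gt_codes <- function(gt_raw) {
  code1 <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
    a <- suppressWarnings(as.integer(strsplit(g, "[/|]")[[1]]))
    if (length(a) != 2 || anyNA(a) || any(a > 1L)) return(NA_integer_)
    sum(a)
  }
  m <- matrix(vapply(gt_raw, code1, integer(1)), nrow = nrow(gt_raw))
  dimnames(m) <- dimnames(gt_raw)
  m
}

#' Write a variant table as VCF 4.2
#'
#' Emits a plain-text VCF with `GT:AD:DP` per-sample fields, round-tripping
#' through [read_vcf()] losslessly for the fields the site tibble carries.
#'
#' @param sites A [variant_table()] tibble sorted by (chrom, pos).
#' @param sheet The matching [sample_sheet()].
#' @param path Output path.
#' @param sort Sort `sites` before writing instead of erroring on unsorted
#'   input.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(sites, sheet, path, sort = FALSE) {
  validate_sample_sheet(sheet)
  if (n_samples(sites) != nrow(sheet)) abort("sites/sheet sample count mismatch")
  if (!is_sorted_sites(sites)) {
    if (!sort) abort("sites are not sorted by (chrom, pos); use sort = TRUE")
    sites <- sort_sites(sites)
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=paralogsift",
    paste0("##contig=<ID=", unique(sites$chrom), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Read depth per allele\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sheet$sample_id), collapse = "\t")
  )
  if (nrow(sites) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  gt_str <- matrix(c("0/0", "0/1", "1/1")[sites$gt + 1L], nrow = nrow(sites))
  gt_str[is.na(gt_str)] <- "./."
  ad_str <- matrix(
    ifelse(is.na(sites$ref_ad) | is.na(sites$alt_ad), ".",
           paste0(sites$ref_ad, ",", sites$alt_ad)),
    nrow = nrow(sites)
  )
  dp <- sites$ref_ad + sites$alt_ad
  dp_str <- matrix(ifelse(is.na(dp), ".", as.character(dp)), nrow = nrow(sites))
  sample_cols <- matrix(paste(gt_str, ad_str, dp_str, sep = ":"), nrow = nrow(sites))
  records <- paste(
    sites$chrom, format_vcf_number(sites$pos), ".", sites$ref, sites$alt,
    format_vcf_number(sites$qual), "PASS", ".", "GT:AD:DP",
    apply(sample_cols, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, records), path)
  invisible(path)
}

format_vcf_number <- function(x) {
  out <- format(x, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
  out[is.na(x)] <- "."
  out
}

#' Read / write BED3 mask regions
#'
#' BED intervals are 0-based half-open. `write_bed()` merges overlapping
#' regions per chromosome before writing; [merge_regions()] exposes the same
#' merge on its own.
#'
#' @param path File path.
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                       col_types = "cdd")
  if (any(x$start >= x$end)) {
    abort("BED parse error: start >= end")
  }
  as_tibble(x)
}

#' @rdname read_bed
#' @param regions Tibble of mask regions (`chrom`, `start`, `end`).
#' @export
write_bed <- function(regions, path) {
  merged <- merge_regions(regions)
  readr::write_tsv(merged, path, col_names = FALSE)
  invisible(path)
}

#' @rdname read_bed
#' @export
merge_regions <- function(regions) {
  if (nrow(regions) == 0) {
    return(tibble(chrom = character(0), start = numeric(0), end = numeric(0)))
  }
  if (any(regions$start >= regions$end)) abort("mask region start must be < end")
  split(regions, regions$chrom) |>
    imap(function(r, chr) {
      ir <- IRanges::reduce(IRanges::IRanges(start = r$start + 1, end = r$end))
      tibble(chrom = chr, start = IRanges::start(ir) - 1, end = IRanges::end(ir))
    }) |>
    list_rbind() |>
    arrange(.data$chrom, .data$start)
}

#' Read / write FASTA
#'
#' @param path File path.
#' @return `read_fasta()` returns a named character vector of sequences in
#'   file order.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
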