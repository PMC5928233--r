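#' Describe a genome build by chromosome arms
#'
#' A genome build is a tibble of chromosome arms with 0-based half-open
#' coordinates and a flag for arms belonging to duplicated (delayed
#' re-diploidization) pairs. Arm boundaries drive the per-arm PSV density
#' summary; when only whole chromosomes are known, pass one "arm" per
#' chromosome.
#'
#' @param chrom Chromosome name per arm.
#' @param arm Arm name (unique across the build).
#' @param start,end 0-based half-open arm boundaries on the chromosome.
#' @param duplicated Logical; `TRUE` for arms in a duplicated pair.
#'
#' @return A tibble with columns `chrom`, `arm`, `start`, `end`,
#'   `length`, `duplicated`.
#' @export
genome_build <- function(chrom, arm, start, end, duplicated = FALSE) {
  build <- tibble(
    chrom = as.character(chrom), arm = as.character(arm),
    start = as.numeric(start), end = as.numeric(end),
    duplicated = rep_len(as.logical(duplicated), length(chrom))
  )
  if (any(build$start >= build$end)) abort("arm start must be < end")
  if (anyDuplicated(build$arm)) abort("arm names must be unique")
  build$length <- build$end - build$start
  build[, c("chrom", "arm", "start", "end", "length", "duplicated")]
}

#' Chromosome lengths of a genome build
#'
#' @param build A [genome_build()] tibble.
#' @return Tibble with `chrom`, `length`.
#' @export
chrom_lengths <- function(build) {
  build |>
    group_by(.data$chrom) |>
    summarise(length = max(.data$end), .groups = "drop")
}

#' Read / write an arm table
#'
#' Tab-separated columns: `chrom`, `arm`, `start`, `end`, `duplicated` (0/1).
#'
#' @param path File path.
#' @return `read_arm_table()` returns a [genome_build()] tibble.
#' @export
read_arm_table <- function(path) {
  x <- readr::read_tsv(path, col_types = "ccddi")
  genome_build(x$chrom, x$arm, x$start, x$end, x$duplicated == 1L)
}

#' @rdname read_arm_table
#' @param build A [genome_build()] tibble.
#' @export
write_arm_table <- function(build, path) {
  readr::write_tsv(
    tibble(chrom = build$chrom, arm = build$arm, start = build$start,
           end = build$end, duplicated = as.integer(build$duplicated)),
    path
  )
  invisible(path)
}

# assign site positions (1-based) to arms; returns arm name or NA
assign_arm <- function(chrom, pos, build) {
  out <- rep(NA_character_, length(chrom))
  for (i in seq_len(nrow(build))) {
    hit <- chrom == build$chrom[i] & (pos - 1) >= build$start[i] & (pos - 1) < build$end[i]
    out[hit] <- build$arm[i]
  }
  out
}
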