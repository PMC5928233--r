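#' Build a sample sheet
#'
#' The sample sheet assigns every sequenced sample to a population and marks
#' doubled-haploid (DH) lines. Its row order defines the per-sample column
#' order of every read-count and genotype matrix in the package, so the same
#' sheet must be used for reading, filtering and summarising a call set.
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param population Character vector of population labels (same length).
#' @param is_dh Logical vector; `TRUE` for doubled-haploid lines.
#'
#' @return A tibble with columns `sample_id`, `population`, `is_dh`.
#' @examples
#' sample_sheet(c("DH1", "W1", "W2"), c("DH", "Elwha", "Elwha"), c(TRUE, FALSE, FALSE))
#' @export
sample_sheet <- function(sample_id, population, is_dh) {
  sheet <- tibble(
    sample_id = as.character(sample_id),
    population = as.character(population),
    is_dh = as.logical(is_dh)
  )
  validate_sample_sheet(sheet)
  sheet
}

validate_sample_sheet <- function(sheet) {
  if (!all(c("sample_id", "population", "is_dh") %in% names(sheet))) {
    abort("sample sheet needs columns sample_id, population, is_dh")
  }
  if (anyDuplicated(sheet$sample_id)) {
    abort("sample_id values must be unique")
  }
  if (any(is.na(sheet$is_dh))) abort("is_dh must be TRUE/FALSE")
  invisible(sheet)
}

#' Read / write a sample sheet
#'
#' Three-column tab-separated file: `sample_id`, `population`, `dh` (0/1).
#'
#' @param path File path.
#' @return `read_sample_sheet()` returns the sheet tibble;
#'   `write_sample_sheet()` returns `path` invisibly.
#' @export
read_sample_sheet <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    population = readr::col_character(),
    dh = readr::col_integer()
  ))
  sample_sheet(x$sample_id, x$population, x$dh == 1L)
}

#' @rdname read_sample_sheet
#' @param sheet A sample sheet tibble.
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  readr::write_tsv(
    tibble(sample_id = sheet$sample_id, population = sheet$population,
           dh = as.integer(sheet$is_dh)),
    path
  )
  invisible(path)
}

# index helpers
dh_index <- function(sheet) which(sheet$is_dh)
outbred_index <- function(sheet) which(!sheet$is_dh)

# resolve a subset argument to sample indices: NULL = all samples,
# "dh"/"non_dh" = the DH / outbred partition, anything else = population label
subset_index <- function(sheet, subset = NULL) {
  if (is.null(subset)) return(seq_len(nrow(sheet)))
  if (length(subset) == 1 && subset %in% c("dh", "non_dh")) {
    return(if (subset == "dh") dh_index(sheet) else outbred_index(sheet))
  }
  idx <- which(sheet$population %in% subset)
  if (length(idx) == 0) abort(paste0("no samples match subset '", paste(subset, collapse = ","), "'"))
  idx
}
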