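#' DUST-style low-complexity masking
#'
#' Scores every sliding window of `window` bases by its trinucleotide
#' composition: with `c_i` the count of triplet `i` among the `window - 2`
#' triplets in the window, the score is `sum(c_i * (c_i - 1) / 2) / (window - 3)`.
#' A homopolymer scores `(window - 2) / 2`; a perfectly triplet-diverse window
#' scores 0; random sequence scores about 0.5. Windows scoring strictly above
#' `threshold` are masked and overlapping masked windows are merged. Runs of
#' `N` are always masked.
#'
#' @param sequence A nucleotide string over `A,C,G,T,N`.
#' @param window Window width in bases (default 64).
#' @param threshold Score cutoff (default 2); windows with score `> threshold`
#'   are masked.
#' @return Tibble of mask regions with 0-based half-open `start`, `end`.
#' @export
dust_mask <- function(sequence, window = 64, threshold = 2) {
  if (window < 3) abort("window must be at least 3")
  L <- nchar(sequence)
  if (L < 3) return(tibble(start = numeric(0), end = numeric(0)))
  codes <- base_codes(sequence)

  # triplet integer codes at each start (NA where any base is N)
  trip <- 16L * codes[1:(L - 2)] + 4L * codes[2:(L - 1)] + codes[3:L]

  w <- min(window, L)
  nt <- w - 2L                       # triplets per window
  den <- max(w - 3, 1)               # score normaliser
  starts <- seq_len(L - w + 1L)
  masked <- logical(length(starts))

  # incremental sliding-window pair count: raw score S = sum c_i*(c_i-1)/2;
  # adding a triplet with current count c adds c; removing one with count c
  # removes c - 1.
  counts <- integer(64)
  raw <- 0
  n_valid <- 0L
  add <- function(t) {
    if (is.na(t)) return(invisible())
    raw <<- raw + counts[t + 1L]
    counts[t + 1L] <<- counts[t + 1L] + 1L
    n_valid <<- n_valid + 1L
  }
  drop1 <- function(t) {
    if (is.na(t)) return(invisible())
    counts[t + 1L] <<- counts[t + 1L] - 1L
    raw <<- raw - counts[t + 1L]
    n_valid <<- n_valid - 1L
  }
  for (j in 1:nt) add(trip[j])
  masked[1] <- raw / den > threshold
  if (length(starts) > 1) {
    for (s in 2:length(starts)) {
      drop1(trip[s - 1L])
      add(trip[s + nt - 1L])
      masked[s] <- raw / den > threshold
    }
  }

  regions <- tibble(
    start = as.numeric(starts[masked] - 1),
    end = as.numeric(starts[masked] - 1 + w)
  )
  # N runs are always masked
  n_run <- rle(is.na(codes))
  if (any(n_run$values)) {
    ends <- cumsum(n_run$lengths)
    begins <- ends - n_run$lengths
    regions <- bind_rows(regions, tibble(
      start = as.numeric(begins[n_run$values]),
      end = as.numeric(ends[n_run$values])
    ))
  }
  if (nrow(regions) == 0) return(regions)
  m <- merge_regions(mutate(regions, chrom = "x"))
  m[, c("start", "end")]
}

base_codes <- function(sequence) {
  v <- strsplit(toupper(sequence), "")[[1]]
  c(A = 0L, C = 1L, G = 2L, T = 3L)[v]
}

#' Mask a whole genome
#'
#' Runs [dust_mask()] on every chromosome of a genome and returns the merged
#' mask set keyed by chromosome.
#'
#' @param seqs Named character vector of chromosome sequences.
#' @inheritParams dust_mask
#' @return Tibble with `chrom`, `start`, `end`.
#' @export
mask_genome <- function(seqs, window = 64, threshold = 2) {
  imap(seqs, function(s, chr) {
    m <- dust_mask(s, window = window, threshold = threshold)
    if (nrow(m) == 0) return(tibble(chrom = character(0), start = numeric(0), end = numeric(0)))
    mutate(m, chrom = chr)[, c("chrom", "start", "end")]
  }) |> list_rbind()
}

# is each (chrom, pos[1-based]) inside a mask region?
in_mask <- function(chrom, pos, masks) {
  out <- logical(length(chrom))
  if (nrow(masks) == 0 || length(chrom) == 0) return(out)
  for (chr in unique(chrom)) {
    mk <- masks[masks$chrom == chr, , drop = FALSE]
    if (nrow(mk) == 0) next
    sel <- which(chrom == chr)
    p0 <- pos[sel] - 1  # BED is 0-based half-open
    ir <- IRanges::IRanges(start = mk$start + 1, end = mk$end)
    hits <- IRanges::countOverlaps(IRanges::IRanges(p0 + 1, p0 + 1), ir) > 0
    out[sel] <- hits
  }
  out
}
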