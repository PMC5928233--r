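# independent oracles shared between unit and acceptance tests

# direct multinomial enumeration oracle for the exact HWE test, independent of
# the recurrence the implementation uses
hwe_oracle <- function(hom_ref, het, hom_alt) {
  n <- hom_ref + het + hom_alt
  n1 <- min(2 * hom_ref + het, 2 * hom_alt + het)
  n2 <- 2 * n - n1
  lf <- c(0, cumsum(log(seq_len(max(2 * n, 1)))))
  lfac <- function(k) lf[k + 1]
  hets <- seq(n1 %% 2, n1, by = 2)
  logp <- vapply(hets, function(h) {
    hr <- (n1 - h) / 2; hc <- n - h - hr
    lfac(n) - lfac(hr) - lfac(h) - lfac(hc) + h * log(2) +
      lfac(n1) + lfac(n2) - lfac(2 * n)
  }, numeric(1))
  p <- exp(logp)
  p <- p / sum(p)
  p_obs <- p[hets == het]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# brute-force oracle: score every window by direct triplet tabulation
dust_oracle <- function(s, window = 64, threshold = 2) {
  L <- nchar(s)
  if (L < 3) return(tibble::tibble(start = numeric(0), end = numeric(0)))
  w <- min(window, L)
  hits <- list()
  for (st in 1:(L - w + 1)) {
    win <- substr(s, st, st + w - 1)
    trips <- substring(win, 1:(w - 2), 3:w)
    trips <- trips[!grepl("N", trips)]
    cc <- table(trips)
    score <- sum(cc * (cc - 1) / 2) / max(w - 3, 1)
    if (score > threshold) hits[[length(hits) + 1]] <- c(st - 1, st - 1 + w)
  }
  v <- strsplit(s, "")[[1]]
  nrun <- rle(v == "N")
  ends <- cumsum(nrun$lengths); begins <- ends - nrun$lengths
  for (k in which(nrun$values)) hits[[length(hits) + 1]] <- c(begins[k], ends[k])
  if (length(hits) == 0) return(tibble::tibble(start = numeric(0), end = numeric(0)))
  m <- do.call(rbind, hits)
  merge_regions(tibble::tibble(chrom = "x", start = m[, 1], end = m[, 2]))[, c("start", "end")]
}

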