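# shared fixture builders; everything is generated in code

tiny_sheet <- function(n_dh = 2, pops = c(P1 = 2, P2 = 2)) {
  out <- purrr::imap(as.list(pops), function(n, p) {
    tibble::tibble(sample_id = paste0(p, "_", seq_len(n)), population = p,
                   is_dh = FALSE)
  }) |> purrr::list_rbind()
  dh_ids <- if (n_dh > 0) paste0("DH", seq_len(n_dh)) else character(0)
  sample_sheet(
    c(dh_ids, out$sample_id),
    c(rep("DH", n_dh), out$population),
    c(rep(TRUE, n_dh), out$is_dh)
  )
}

# a variant table from compact per-site specs
make_sites <- function(chrom, pos, ref = "A", alt = "G", qual = 50,
                       ref_ad = NULL, alt_ad = NULL, gt = NULL, n_samples = 4) {
  n <- length(pos)
  chrom <- rep_len(chrom, n); ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  qual <- rep_len(qual, n)
  if (is.null(ref_ad)) ref_ad <- matrix(10L, n, n_samples)
  if (is.null(alt_ad)) alt_ad <- matrix(10L, n, n_samples)
  variant_table(chrom, pos, ref, alt, qual, ref_ad, alt_ad, gt)
}

random_variant_table <- function(n, sheet, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ns <- nrow(sheet)
  pos <- sort(sample.int(n * 50, n))
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1))
  ref_ad <- matrix(rpois(n * ns, 8), n, ns, dimnames = list(NULL, sheet$sample_id))
  alt_ad <- matrix(rpois(n * ns, 8), n, ns, dimnames = list(NULL, sheet$sample_id))
  gt <- matrix(sample(c(0L, 1L, 2L, NA), n * ns, replace = TRUE), n, ns,
               dimnames = list(NULL, sheet$sample_id))
  variant_table(rep("chr1", n), pos, ref, alt, qual = round(runif(n, 1, 500), 1),
                ref_ad = ref_ad, alt_ad = alt_ad, gt = gt)
}

# reduced-size simulation config for unit tests (fast, same structure)
small_sim_config <- function(...) {
  sim_config(
    arms = genome_build(c("chr1", "chr1", "chr2", "chr2"),
                        c("1p", "1q", "2p", "2q"),
                        c(0, 20000, 0, 20000),
                        c(20000, 45000, 20000, 40000),
                        c(TRUE, FALSE, TRUE, FALSE)),
    ...
  )
}

# the full default-condition study, simulated once and shared across tests
default_sim_cache <- new.env(parent = emptyenv())
get_default_sim <- function(seed = 20260924) {
  key <- paste0("sim", seed)
  if (is.null(default_sim_cache[[key]])) {
    default_sim_cache[[key]] <- simulate_study(sim_config(), seed = seed)
  }
  default_sim_cache[[key]]
}
get_default_run <- function(seed = 20260924) {
  key <- paste0("run", seed)
  if (is.null(default_sim_cache[[key]])) {
    sim <- get_default_sim(seed)
    default_sim_cache[[key]] <- run_pipeline(
      sim$callsets$a, sim$callsets$b, sim$sheet, sim$build,
      genome = sim$genome, sweep = TRUE
    )
  }
  default_sim_cache[[key]]
}

truth_key <- function(x) paste(x$chrom, x$pos)

random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# greedy construction of a triplet-diverse sequence (avoids reusing triplets
# whenever possible), for the "evenly spread trinucleotides" masking case
diverse_dna_string <- function(n) {
  bases <- c("A", "C", "G", "T")
  v <- sample(bases, 3, replace = TRUE)
  seen <- paste(v, collapse = "")
  for (i in 4:n) {
    cand <- sample(bases)
    trip <- paste0(v[i - 2], v[i - 1], cand)
    pick <- cand[match(TRUE, !trip %in% seen, nomatch = 1)]
    v[i] <- pick
    seen <- c(seen, paste0(v[i - 2], v[i - 1], pick))
  }
  paste(v, collapse = "")
}

# integer-percent rounding as the printed tables use it (round-half-even)
pct_int_ref <- function(num, den) round(100 * num / den)
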