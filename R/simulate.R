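#' Simulation configuration
#'
#' Parameters of the synthetic resequencing study the pipeline is exercised
#' on. The defaults emulate the study design the package targets: a small
#' genome (two chromosomes, four arms, 280 kb) with one duplicated
#' (delayed-rediploidization) arm pair, 61 samples (11 doubled-haploid lines,
#' seven populations of four fish, one population of ten, and a 12-fish
#' aquaculture population), mean coverage 15x with minimum 8x, and two
#' variant callers that agree at about 80% of combined sites.
#'
#' All rates are per bp or per Bernoulli trial. The caller-model defaults
#' follow from the target concordance: with per-caller drop rate `d`,
#' per-caller false-unique rate `f` and ALT disagreement rate `a`, the
#' expected same-site-same-ALT share of the combined set is
#' `(1-d)^2 (1-a) / ((1-d^2) + 2f)`, which is 0.80 at the defaults.
#'
#' @param arms Arm layout tibble (`chrom`, `arm`, `start`, `end`,
#'   `duplicated`); duplicated arms must come in consecutive pairs of equal
#'   length.
#' @param duplicated_pairs List of length-2 character vectors naming the
#'   paralogous arm pairs.
#' @param paralog_divergence Fixed-difference rate between paralog copies
#'   (these differences are the planted PSVs).
#' @param true_snp_density,msv_density Planted true-SNP rate genome-wide and
#'   MSV rate on duplicated arms, per bp.
#' @param af_beta Beta parameters of the ancestral allele-frequency
#'   distribution of true SNPs.
#' @param fst Population differentiation used to draw per-population
#'   frequencies around the ancestral frequency (Balding-Nichols).
#' @param msv_af_beta Beta parameters of the allele frequency of the variant
#'   on the duplicated copy; skewed high because only MSVs at appreciable
#'   frequency are observable in a small panel.
#' @param pop_sizes Named integer vector of outbred population sizes.
#' @param n_dh Number of doubled-haploid lines.
#' @param residual_dh_het Residual maternal heterozygosity rate per DH sample
#'   per true-SNP site.
#' @param coverage_mean,coverage_min Per-sample mean genome coverage.
#' @param base_error Per-read base miscall rate (after base-quality
#'   filtering); a miscall lands on a specific other base at a third of this
#'   rate.
#' @param psv_mix_beta Beta parameters of the per-locus cross-mapping
#'   fraction at collapsed (PSV/MSV) sites: the share of reads at the site
#'   that originate from the other paralog copy. Heterogeneity across loci is
#'   what spreads DH heterozygote counts over the full 0..n_DH range.
#' @param dropout Per site-sample probability of zero coverage.
#' @param high_depth_rate Fraction of true-SNP sites placed in collapsed
#'   repeats with ~6x the normal depth (removed by the DP filter).
#' @param caller_drop_rate,caller_unique_rate,alt_disagree_rate,subqual_rate
#'   Two-caller emulation: per-caller site drop rate, per-caller false-unique
#'   rate (relative to the truth-site count), ALT disagreement rate at shared
#'   sites, and fraction of sites drawn with QUAL below 30.
#' @param lc_tract_rate,lc_tract_mean_len Low-complexity tract rate (tracts
#'   per bp) and geometric mean tract length; the defaults lead to ~10% of
#'   the genome masked once the DUST windows' flanking extension is counted.
#' @param indel_density Indel rate per bp.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(
    arms = NULL, duplicated_pairs = list(c("1p", "2p")),
    paralog_divergence = 0.005,
    true_snp_density = 0.008, msv_density = 0.001,
    af_beta = c(0.4, 0.4), fst = 0.1, msv_af_beta = c(3, 1),
    pop_sizes = c(Dworshak = 4, Quinault = 4, LQuinault = 4, Elwha = 4,
                  Skamania = 4, BigCreek = 4, Klamath = 4, Misc = 10,
                  Aquagen = 12),
    n_dh = 11, residual_dh_het = 0.005,
    coverage_mean = 15, coverage_min = 8,
    base_error = 5e-4, psv_mix_beta = c(2, 2),
    dropout = 0.01, high_depth_rate = 0.002,
    caller_drop_rate = 0.08, caller_unique_rate = 0.032,
    alt_disagree_rate = 0.002, subqual_rate = 0.05,
    lc_tract_rate = 3e-4, lc_tract_mean_len = 200,
    indel_density = 2e-4) {
  arms <- arms %||% genome_build(
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    arm = c("1p", "1q", "2p", "2q"),
    start = c(0, 70000, 0, 70000),
    end = c(70000, 150000, 70000, 130000),
    duplicated = c(TRUE, FALSE, TRUE, FALSE)
  )
  cfg <- list(
    arms = arms, duplicated_pairs = duplicated_pairs,
    paralog_divergence = paralog_divergence,
    true_snp_density = true_snp_density, msv_density = msv_density,
    af_beta = af_beta, fst = fst, msv_af_beta = msv_af_beta,
    pop_sizes = pop_sizes, n_dh = n_dh, residual_dh_het = residual_dh_het,
    coverage_mean = coverage_mean, coverage_min = coverage_min,
    base_error = base_error, psv_mix_beta = psv_mix_beta, dropout = dropout,
    high_depth_rate = high_depth_rate,
    caller_drop_rate = caller_drop_rate,
    caller_unique_rate = caller_unique_rate,
    alt_disagree_rate = alt_disagree_rate, subqual_rate = subqual_rate,
    lc_tract_rate = lc_tract_rate, lc_tract_mean_len = lc_tract_mean_len,
    indel_density = indel_density
  )
  rates <- c(paralog_divergence, true_snp_density, msv_density, fst,
             residual_dh_het, base_error, dropout, high_depth_rate,
             caller_drop_rate, caller_unique_rate, alt_disagree_rate,
             subqual_rate, lc_tract_rate, indel_density)
  if (any(rates < 0 | rates > 1)) abort("all rates must lie in [0, 1]")
  structure(cfg, class = "sim_config")
}

#' Sample sheet of the simulated study
#'
#' @param cfg A [sim_config()].
#' @return A [sample_sheet()] tibble: DH lines first, then outbred
#'   populations.
#' @export
sim_sample_sheet <- function(cfg) {
  dh <- tibble(sample_id = paste0("DH", sprintf("%02d", seq_len(cfg$n_dh))),
               population = "DH", is_dh = TRUE)
  out <- imap(as.list(cfg$pop_sizes), function(n, pop) {
    tibble(sample_id = paste0(pop, "_", seq_len(n)), population = pop,
           is_dh = FALSE)
  }) |> list_rbind()
  sample_sheet(c(dh$sample_id, out$sample_id),
               c(dh$population, out$population),
               c(dh$is_dh, out$is_dh))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

other_base <- function(base) {
  vapply(base, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
         character(1), USE.NAMES = FALSE)
}

#' Simulate the reference genome
#'
#' Builds arm sequences, embeds low-complexity repeat tracts, copies each
#' duplicated arm pair with point divergence (recording the divergent
#' positions, which become the planted PSVs), and scatters indel positions.
#' Consumes the current RNG stream; see [simulate_study()] for the seeded
#' end-to-end wrapper.
#'
#' @param cfg A [sim_config()].
#' @return List with `genome` (named chromosome sequences), `build` (the arm
#'   table), `lc_tracts` (tibble `chrom`, `start`, `end`), `divergent`
#'   (tibble `arm_a`, `arm_b`, `offset` of inter-copy differences, 0-based
#'   within-arm), and `indels` (tibble `chrom`, `pos`).
#' @export
simulate_genome <- function(cfg) {
  build <- cfg$arms
  arm_seq <- list()
  tracts <- list()
  # independent arms first
  for (i in seq_len(nrow(build))) {
    L <- build$length[i]
    s <- random_dna(L)
    # embed low-complexity tracts
    n_tr <- rpois(1, cfg$lc_tract_rate * L)
    tr <- list()
    if (n_tr > 0) {
      starts <- sort(sample.int(L, n_tr))
      lens <- pmax(80, rgeom(n_tr, 1 / cfg$lc_tract_mean_len))
      units <- sample(c("A", "AC", "AG", "AT", "CT"), n_tr, replace = TRUE)
      for (k in seq_len(n_tr)) {
        lo <- starts[k]; hi <- min(L, starts[k] + lens[k] - 1)
        rep_seq <- substr(strrep(units[k], ceiling((hi - lo + 1) / nchar(units[k]))),
                          1, hi - lo + 1)
        substr(s, lo, hi) <- rep_seq
        tr[[k]] <- tibble(arm = build$arm[i], start = lo - 1, end = hi)
      }
    }
    arm_seq[[build$arm[i]]] <- s
    tracts[[build$arm[i]]] <- list_rbind(tr)
  }
  # duplicated pairs: second copy = first copy diverged at the configured rate
  divergent <- list()
  for (pair in cfg$duplicated_pairs) {
    a <- pair[1]; b <- pair[2]
    La <- nchar(arm_seq[[a]])
    if (nchar(arm_seq[[b]]) != La) abort("duplicated arms must have equal length")
    n_div <- rpois(1, cfg$paralog_divergence * La)
    off <- sort(sample.int(La, min(n_div, La)))
    sb <- arm_seq[[a]]
    for (p in off) {
      substr(sb, p, p) <- other_base(substr(sb, p, p))
    }
    arm_seq[[b]] <- sb
    divergent[[paste(a, b)]] <- tibble(arm_a = a, arm_b = b, offset = off - 1)
    tracts[[b]] <- tracts[[a]] |> mutate(arm = b)
  }
  # assemble chromosomes in arm order
  genome <- vapply(split(build, factor(build$chrom, unique(build$chrom))),
                   function(ba) paste(unlist(arm_seq[ba$arm]), collapse = ""),
                   character(1))
  arm_off <- setNames(build$start, build$arm)
  arm_chrom <- setNames(build$chrom, build$arm)
  lc_tracts <- list_rbind(tracts[!vapply(tracts, is.null, logical(1))])
  lc_tracts <- if (nrow(lc_tracts) > 0) {
    merge_regions(tibble(chrom = arm_chrom[lc_tracts$arm],
                         start = lc_tracts$start + arm_off[lc_tracts$arm],
                         end = lc_tracts$end + arm_off[lc_tracts$arm]))
  } else tibble(chrom = character(0), start = numeric(0), end = numeric(0))
  total_len <- sum(build$length)
  n_ind <- rpois(1, cfg$indel_density * total_len)
  gpos <- sort(sample.int(total_len, min(n_ind, total_len)))
  cum <- cumsum(build$length)
  arm_i <- findInterval(gpos - 1, c(0, cum))
  indels <- tibble(
    chrom = build$chrom[arm_i],
    pos = build$start[arm_i] + (gpos - c(0, cum)[arm_i])
  ) |> arrange(.data$chrom, .data$pos)
  list(genome = genome, build = build, lc_tracts = lc_tracts,
       divergent = list_rbind(divergent), indels = indels)
}

#' Plant truth variants
#'
#' True SNPs are scattered genome-wide with Beta-distributed ancestral allele
#' frequencies; PSVs are the fixed inter-copy differences of each duplicated
#' arm pair, planted at both mirrored positions (reads from both collapsed
#' copies pile up at both); MSVs are variants segregating on one paralog copy
#' of a duplicated arm.
#'
#' @param cfg A [sim_config()].
#' @param sim Output of [simulate_genome()].
#' @return Truth tibble: `chrom`, `pos`, `class` (`true_snp`/`psv`/`msv`),
#'   `ref`, `alt`, `p_anc` (ancestral frequency; NA for PSVs),
#'   `high_depth` flag.
#' @export
plant_variants <- function(cfg, sim) {
  build <- sim$build
  genome <- sim$genome
  base_at <- function(chrom, pos) {
    vapply(seq_along(chrom),
           function(i) substr(genome[[chrom[i]]], pos[i], pos[i]), character(1))
  }
  arm_off <- setNames(build$start, build$arm)
  arm_chrom <- setNames(build$chrom, build$arm)

  # PSVs: mirrored fixed differences
  psv <- list()
  if (nrow(sim$divergent) > 0) {
    d <- sim$divergent
    pos_a <- arm_off[d$arm_a] + d$offset + 1
    pos_b <- arm_off[d$arm_b] + d$offset + 1
    chr_a <- arm_chrom[d$arm_a]; chr_b <- arm_chrom[d$arm_b]
    # at each copy the "alt" is the other copy's base
    psv <- tibble(
      chrom = c(chr_a, chr_b), pos = c(pos_a, pos_b),
      class = "psv",
      ref = c(base_at(chr_a, pos_a), base_at(chr_b, pos_b)),
      alt = c(base_at(chr_b, pos_b), base_at(chr_a, pos_a)),
      p_anc = NA_real_
    )
  }

  # true SNPs genome-wide
  total_len <- sum(build$length)
  n_snp <- rpois(1, cfg$true_snp_density * total_len)
  cum <- cumsum(build$length)
  gpos <- sort(sample.int(total_len, min(n_snp, total_len)))
  arm_i <- findInterval(gpos - 1, c(0, cum))
  snp <- tibble(
    chrom = build$chrom[arm_i],
    pos = build$start[arm_i] + (gpos - c(0, cum)[arm_i]),
    class = "true_snp", p_anc = rbeta(length(gpos), cfg$af_beta[1], cfg$af_beta[2])
  )
  snp$ref <- base_at(snp$chrom, snp$pos)
  snp$alt <- other_base(snp$ref)

  # MSVs on duplicated arms
  dup <- build |> filter(.data$duplicated)
  msv <- list()
  if (nrow(dup) > 0) {
    msv <- map(seq_len(nrow(dup)), function(i) {
      n <- rpois(1, cfg$msv_density * dup$length[i])
      if (n == 0) return(NULL)
      p <- dup$start[i] + sample.int(dup$length[i], n)
      tibble(chrom = dup$chrom[i], pos = p, class = "msv",
             p_anc = rbeta(n, cfg$msv_af_beta[1], cfg$msv_af_beta[2]))
    }) |> list_rbind()
    if (nrow(msv) > 0) {
      msv$ref <- base_at(msv$chrom, msv$pos)
      msv$alt <- other_base(msv$ref)
    }
  }

  truth <- bind_rows(if (length(psv)) psv else NULL, snp,
                     if (length(msv)) msv else NULL) |>
    distinct(.data$chrom, .data$pos, .keep_all = TRUE) |>
    arrange(.data$chrom, .data$pos)
  # avoid colliding with indel anchors
  truth <- anti_join(truth, sim$indels, by = c("chrom", "pos"))
  truth$high_depth <- truth$class == "true_snp" &
    runif(nrow(truth)) < cfg$high_depth_rate
  truth[, c("chrom", "pos", "class", "ref", "alt", "p_anc", "high_depth")]
}

#' Simulate per-sample genotypes and read counts
#'
#' Outbred genotypes are Hardy-Weinberg draws at population frequencies
#' derived from the ancestral frequency by a Balding-Nichols Beta; DH
#' genotypes are doubled gametes (homozygous) with rare residual
#' heterozygosity. PSV sites present as a 50/50 read mixture in every sample
#' (reads from both collapsed copies); MSV sites mix reads from the invariant
#' copy and the segregating copy. Read depths are Poisson at each sample's
#' mean coverage (reads split between the two reference copies at collapsed
#' sites, so depth stays ~1x), allele counts are binomial with the base error
#' rate folded in.
#'
#' @param cfg A [sim_config()].
#' @param truth Output of [plant_variants()].
#' @param sheet The study sample sheet ([sim_sample_sheet()]).
#' @return List with `sites` (a [variant_table()] carrying read counts and
#'   truth genotypes in `gt`), and `truth` (the input truth with a
#'   `true_gt` matrix column attached).
#' @export
simulate_samples <- function(cfg, truth, sheet) {
  n_site <- nrow(truth)
  n_smp <- nrow(sheet)
  pops <- unique(sheet$population[!sheet$is_dh])
  bn <- function(p) {
    # Balding-Nichols population frequency around ancestral p
    a <- p * (1 - cfg$fst) / cfg$fst
    b <- (1 - p) * (1 - cfg$fst) / cfg$fst
    rbeta(length(p), a, b)
  }
  # per-population frequencies (true SNPs); DH group gets its own draw
  freq <- matrix(NA_real_, n_site, length(pops) + 1,
                 dimnames = list(NULL, c(pops, "DH")))
  is_snp <- truth$class == "true_snp"
  is_msv <- truth$class == "msv"
  for (g in colnames(freq)) {
    freq[is_snp, g] <- bn(truth$p_anc[is_snp])
    freq[is_msv, g] <- truth$p_anc[is_msv]  # frequency on the duplicated copy
  }

  gt <- matrix(NA_integer_, n_site, n_smp, dimnames = list(NULL, sheet$sample_id))
  for (j in seq_len(n_smp)) {
    grp <- if (sheet$is_dh[j]) "DH" else sheet$population[j]
    g <- integer(n_site)
    if (sheet$is_dh[j]) {
      g[is_snp | is_msv] <- 2L * rbinom(sum(is_snp | is_msv), 1, freq[is_snp | is_msv, grp])
      res <- is_snp & runif(n_site) < cfg$residual_dh_het
      g[res] <- 1L
    } else {
      g[is_snp | is_msv] <- rbinom(sum(is_snp | is_msv), 2, freq[is_snp | is_msv, grp])
    }
    g[truth$class == "psv"] <- 1L
    gt[, j] <- g
  }

  # read counts
  mean_cov <- cfg$coverage_min +
    rgamma(n_smp, shape = 2.45, scale = (cfg$coverage_mean - cfg$coverage_min) / 2.45)
  # collapsed paralog sites keep ~1x depth: with both copies in the reference,
  # reads split between them and the PSV signal is the cross-mapped mixture
  depth_factor <- ifelse(truth$high_depth, 6, 1)
  e <- cfg$base_error
  # per-locus cross-mapping fraction at collapsed sites
  mix <- rbeta(n_site, cfg$psv_mix_beta[1], cfg$psv_mix_beta[2])
  ref_ad <- matrix(0L, n_site, n_smp, dimnames = list(NULL, sheet$sample_id))
  alt_ad <- ref_ad
  for (j in seq_len(n_smp)) {
    d <- rpois(n_site, mean_cov[j] * depth_factor)
    d[runif(n_site) < cfg$dropout] <- 0L
    f <- ifelse(truth$class == "psv", mix,
         ifelse(truth$class == "msv", mix * gt[, j] / 2, gt[, j] / 2))
    # a miscall lands on one specific other base a third of the time
    f <- f * (1 - e) + (1 - f) * e / 3
    a <- rbinom(n_site, d, f)
    alt_ad[, j] <- a
    ref_ad[, j] <- d - a
  }

  sites <- variant_table(
    chrom = truth$chrom, pos = truth$pos, ref = truth$ref, alt = truth$alt,
    qual = rep(50, n_site), ref_ad = ref_ad, alt_ad = alt_ad, gt = gt
  )
  truth$true_gt <- gt
  list(sites = sites, truth = truth, mean_coverage = mean_cov)
}

#' Emit two discordant caller VCF call sets
#'
#' Each caller independently drops a fraction of the underlying sites, adds
#' its own false unique sites, and (for caller B) reports a different ALT at
#' a small fraction of shared sites. QUAL scores are drawn so a configured
#' fraction falls below 30. Indel records are appended to both call sets so
#' the indel-proximity filter sees them.
#'
#' @param cfg A [sim_config()].
#' @param sim Output of [simulate_genome()].
#' @param sampled Output of [simulate_samples()].
#' @param sheet The study sample sheet.
#' @return List with variant tables `a` and `b`.
#' @export
emit_callsets <- function(cfg, sim, sampled, sheet) {
  sites <- sampled$sites
  n <- nrow(sites)
  draw_qual <- function(m) {
    ifelse(runif(m) < cfg$subqual_rate, runif(m, 2, 30), 30.5 + rexp(m, 1 / 300))
  }
  keep_a <- runif(n) >= cfg$caller_drop_rate
  keep_b <- runif(n) >= cfg$caller_drop_rate
  a <- sites[keep_a, , drop = FALSE]
  b <- sites[keep_b, , drop = FALSE]
  a$qual <- draw_qual(nrow(a))
  b$qual <- draw_qual(nrow(b))
  # ALT disagreement in caller B at shared sites
  swap <- runif(nrow(b)) < cfg$alt_disagree_rate
  b$alt[swap] <- vapply(which(swap), function(i) {
    sample(setdiff(c("A", "C", "G", "T"), c(b$ref[i], b$alt[i])), 1)
  }, character(1))
  # caller-unique false sites
  uniq <- function() {
    m <- rpois(1, cfg$caller_unique_rate * n)
    if (m == 0) return(NULL)
    build <- sim$build
    cum <- cumsum(build$length)
    gpos <- sample.int(sum(build$length), m)
    arm_i <- findInterval(gpos - 1, c(0, cum))
    chrom <- build$chrom[arm_i]
    pos <- build$start[arm_i] + (gpos - c(0, cum)[arm_i])
    ref <- vapply(seq_len(m), function(i) substr(sim$genome[[chrom[i]]], pos[i], pos[i]),
                  character(1))
    keep <- ref %in% c("A", "C", "G", "T")
    m <- sum(keep)
    if (m == 0) return(NULL)
    chrom <- chrom[keep]; pos <- pos[keep]; ref <- ref[keep]
    n_smp <- nrow(sheet)
    d <- matrix(rpois(m * n_smp, cfg$coverage_mean), m, n_smp)
    alt_ad <- matrix(rbinom(m * n_smp, as.vector(d), 0.12), m, n_smp,
                     dimnames = list(NULL, sheet$sample_id))
    ref_ad <- d - alt_ad
    variant_table(chrom, pos, ref, other_base(ref), draw_qual(m),
                  ref_ad, alt_ad)
  }
  # indel records carried by both callers
  indel_records <- function() {
    ind <- sim$indels
    if (nrow(ind) == 0) return(NULL)
    ref <- vapply(seq_len(nrow(ind)),
                  function(i) substr(sim$genome[[ind$chrom[i]]], ind$pos[i], ind$pos[i]),
                  character(1))
    keep <- ref %in% c("A", "C", "G", "T")
    ind <- ind[keep, ]; ref <- ref[keep]
    m <- nrow(ind)
    n_smp <- nrow(sheet)
    d <- matrix(rpois(m * n_smp, cfg$coverage_mean), m, n_smp)
    alt_ad <- matrix(rbinom(m * n_smp, as.vector(d), 0.3), m, n_smp,
                     dimnames = list(NULL, sheet$sample_id))
    variant_table(ind$chrom, ind$pos, ref,
                  paste0(ref, sample(c("A", "C", "G", "T"), m, replace = TRUE)),
                  draw_qual(m), d - alt_ad, alt_ad)
  }
  ind <- indel_records()
  a <- bind_rows(a, uniq(), ind) |> distinct(.data$chrom, .data$pos, .keep_all = TRUE)
  b <- bind_rows(b, uniq(), ind) |> distinct(.data$chrom, .data$pos, .keep_all = TRUE)
  list(a = sort_sites(a), b = sort_sites(b))
}

#' Run the full simulator
#'
#' Seeds the RNG (restoring the caller's RNG state afterwards), simulates the
#' genome, plants variants, draws samples and read counts, and emits the two
#' caller call sets. With `outdir`, writes `reference.fa`, `samples.tsv`,
#' `arms.tsv`, `truth.tsv`, `callerA.vcf`, `callerB.vcf`, `lc_tracts.bed` and
#' `genes.gff3`. Fixed seed gives byte-identical outputs.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param outdir Optional output directory.
#' @return List: `cfg`, `sheet`, `genome`, `build`, `lc_tracts`, `indels`,
#'   `truth`, `sites`, `callsets` (list `a`, `b`), `gff` (gene-model file
#'   path or lines), and `paths` when `outdir` is given.
#' @export
simulate_study <- function(cfg = sim_config(), seed = 1, outdir = NULL) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  sheet <- sim_sample_sheet(cfg)
  sim <- simulate_genome(cfg)
  gm <- sim_gene_models(sim$build)
  sim$genome <- patch_start_stop_codons(sim$genome, gm$patch)
  truth <- plant_variants(cfg, sim)
  # re-read ref bases after codon patching
  truth$ref <- vapply(seq_len(nrow(truth)), function(i)
    substr(sim$genome[[truth$chrom[i]]], truth$pos[i], truth$pos[i]), character(1))
  same <- truth$ref == truth$alt
  truth$alt[same] <- other_base(truth$ref[same])
  sampled <- simulate_samples(cfg, truth, sheet)
  callsets <- emit_callsets(cfg, sim, sampled, sheet)
  out <- list(cfg = cfg, sheet = sheet, genome = sim$genome, build = sim$build,
              lc_tracts = sim$lc_tracts, indels = sim$indels,
              truth = sampled$truth, sites = sampled$sites,
              callsets = callsets, gff_lines = gm$gff)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    write_fasta(out$genome, p("reference.fa"))
    write_sample_sheet(sheet, p("samples.tsv"))
    write_arm_table(out$build, p("arms.tsv"))
    readr::write_tsv(select(out$truth, -"true_gt"), p("truth.tsv"))
    write_vcf(callsets$a, sheet, p("callerA.vcf"))
    write_vcf(callsets$b, sheet, p("callerB.vcf"))
    write_bed(out$lc_tracts, p("lc_tracts.bed"))
    writeLines(gm$gff, p("genes.gff3"))
    out$paths <- vapply(c("reference.fa", "samples.tsv", "arms.tsv",
                          "truth.tsv", "callerA.vcf", "callerB.vcf",
                          "lc_tracts.bed", "genes.gff3"), p, character(1))
  }
  out
}

# toy gene models on the non-duplicated arms: per arm one plus-strand and one
# minus-strand coding gene plus one non-coding transcript; CDS length 999
sim_gene_models <- function(build) {
  gff <- c("##gff-version 3")
  patch <- list()
  k <- 0
  for (i in which(!build$duplicated)) {
    chr <- build$chrom[i]
    for (strand in c("+", "-")) {
      k <- k + 1
      g0 <- build$start[i] + if (strand == "+") 5000 else 20000
      gid <- paste0("gene", k); tid <- paste0("tx", k)
      exon1 <- c(g0 + 1, g0 + 401)
      exon2 <- c(g0 + 1001, g0 + 1600)
      exon3 <- c(g0 + 2201, g0 + 3000)
      cds <- list(c(g0 + 201, g0 + 401), c(g0 + 1001, g0 + 1600),
                  c(g0 + 2201, g0 + 2398))
      utr5 <- c(g0 + 1, g0 + 200); utr3 <- c(g0 + 2399, g0 + 3000)
      if (strand == "-") { # mirror the feature roles, same coordinates
        utr3 <- c(g0 + 1, g0 + 200); utr5 <- c(g0 + 2399, g0 + 3000)
        cds <- list(c(g0 + 201, g0 + 401), c(g0 + 1001, g0 + 1600),
                    c(g0 + 2201, g0 + 2398))
        # shift CDS so its length stays 999 with correct phase from the right
        cds <- list(c(g0 + 204, g0 + 401), c(g0 + 1001, g0 + 1600),
                    c(g0 + 2201, g0 + 2401))
        utr5 <- c(g0 + 2402, g0 + 3000); utr3 <- c(g0 + 1, g0 + 203)
        exon3 <- c(g0 + 2201, g0 + 3000)
      }
      row <- function(type, s, e, id = NULL, parent = NULL) {
        attrs <- paste0(c(if (!is.null(id)) paste0("ID=", id),
                          if (!is.null(parent)) paste0("Parent=", parent)),
                        collapse = ";")
        paste(chr, "sim", type, s, e, ".", strand, ".", attrs, sep = "\t")
      }
      gff <- c(gff,
        row("gene", g0 + 1, g0 + 3000, id = gid),
        row("mRNA", g0 + 1, g0 + 3000, id = tid, parent = gid),
        row("exon", exon1[1], exon1[2], parent = tid),
        row("exon", exon2[1], exon2[2], parent = tid),
        row("exon", exon3[1], exon3[2], parent = tid),
        row("five_prime_UTR", utr5[1], utr5[2], parent = tid),
        unlist(lapply(cds, function(cc) row("CDS", cc[1], cc[2], parent = tid))),
        row("three_prime_UTR", utr3[1], utr3[2], parent = tid)
      )
      patch[[length(patch) + 1]] <- list(chrom = chr, strand = strand, cds = cds)
    }
    # a non-coding transcript
    k <- k + 1
    n0 <- build$start[i] + 35000
    gid <- paste0("gene", k); tid <- paste0("tx", k)
    gff <- c(gff,
      paste(chr, "sim", "gene", n0 + 1, n0 + 2000, ".", "+", ".",
            paste0("ID=", gid), sep = "\t"),
      paste(chr, "sim", "ncRNA", n0 + 1, n0 + 2000, ".", "+", ".",
            paste0("ID=", tid, ";Parent=", gid), sep = "\t"),
      paste(chr, "sim", "exon", n0 + 1, n0 + 500, ".", "+", ".",
            paste0("Parent=", tid), sep = "\t"),
      paste(chr, "sim", "exon", n0 + 1501, n0 + 2000, ".", "+", ".",
            paste0("Parent=", tid), sep = "\t"))
  }
  list(gff = gff, patch = patch)
}

# force a start codon at the CDS 5' end and a stop at its 3' end so the toy
# genes translate sensibly
patch_start_stop_codons <- function(genome, patches) {
  for (p in patches) {
    s <- genome[[p$chrom]]
    first <- p$cds[[1]]; last <- p$cds[[length(p$cds)]]
    if (p$strand == "+") {
      substr(s, first[1], first[1] + 2) <- "ATG"
      substr(s, last[2] - 2, last[2]) <- "TAA"
    } else {
      substr(s, last[2] - 2, last[2]) <- revcomp("ATG")
      substr(s, first[1], first[1] + 2) <- revcomp("TAA")
    }
    genome[[p$chrom]] <- s
  }
  genome
}
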