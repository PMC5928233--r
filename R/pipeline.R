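#' Run the full SNP-discovery QC pipeline
#'
#' Orchestrates the analysis end to end: classify two-caller agreement, keep
#' the trusted core (same site, same alternate allele), apply the filter
#' cascade (QUAL -> LC -> DP -> NS) with indels pooled from both call sets,
#' screen the survivors with doubled-haploid heterozygosity, and summarise
#' the retained database (MAF spectrum, per-population polymorphism, windowed
#' nucleotide diversity, SNP density, optional effect annotation).
#'
#' @param callset_a,callset_b [variant_table()] call sets (or paths to VCF
#'   files) from the two callers, sorted by (chrom, pos).
#' @param sheet The [sample_sheet()].
#' @param build A [genome_build()].
#' @param genome Named chromosome sequences; used to compute low-complexity
#'   masks when `masks` is not given, and for effect annotation.
#' @param masks Pre-computed mask regions (`chrom`, `start`, `end`); computed
#'   from `genome` with [mask_genome()] when `NULL`.
#' @param cfg A [filter_config()].
#' @param dh_threshold DH heterozygote count at which a site is flagged.
#' @param models Optional gene models from [read_gene_models()] for effect
#'   annotation.
#' @param pi_window Window width for nucleotide diversity.
#' @param sweep Also run the DH threshold sweep over all thresholds.
#' @param outdir Optional directory for the output files (retained and
#'   flagged VCFs plus all summary TSVs).
#' @return An object of class `run_manifest`: a list with the per-stage
#'   counts, the concordance summary, the cascade ledger, the DH screen,
#'   retained/flagged site tables, the summary tables, and output paths when
#'   `outdir` is given.
#' @export
run_pipeline <- function(callset_a, callset_b, sheet, build, genome = NULL,
                         masks = NULL, cfg = filter_config(n_samples = nrow(sheet)),
                         dh_threshold = 2, models = NULL, pi_window = 20000,
                         sweep = FALSE, outdir = NULL) {
  if (is.character(callset_a)) callset_a <- read_vcf(callset_a, sheet)
  if (is.character(callset_b)) callset_b <- read_vcf(callset_b, sheet)
  masks <- masks %||% if (!is.null(genome)) {
    mask_genome(genome, cfg$dust_window, cfg$dust_threshold)
  } else {
    tibble(chrom = character(0), start = numeric(0), end = numeric(0))
  }

  # stage 1: two-caller agreement on the SNP-extracted sets
  snps_a <- callset_a[is_biallelic_snp(callset_a), , drop = FALSE]
  snps_b <- callset_b[is_biallelic_snp(callset_b), , drop = FALSE]
  records <- classify_sites(snps_a, snps_b)
  concordance <- concordance_summary(records)

  # stage 2: intersect — keep the same-site-same-ALT core, fields from caller A
  core_key <- records |> filter(.data$category == "same_site_same_alt")
  keep <- paste(snps_a$chrom, snps_a$pos) %in% paste(core_key$chrom, core_key$pos)
  core <- snps_a[keep, , drop = FALSE]

  # stage 3: filter cascade with indels pooled from both raw call sets
  indels <- bind_rows(indel_positions(callset_a), indel_positions(callset_b)) |>
    distinct() |> arrange(.data$chrom, .data$pos)
  cascade <- apply_filter_cascade(core, masks, cfg, indels = indels)
  survivors <- cascade$sites

  # stage 4: DH screen
  screen <- dh_screen(survivors, sheet, threshold = dh_threshold)
  flagged <- survivors[screen$classification == "putative_psv_msv", , drop = FALSE]
  retained <- survivors[screen$classification == "retained_snp", , drop = FALSE]
  ledger <- bind_rows(cascade$ledger, tibble(
    stage = "DH", entering = nrow(survivors), passing = nrow(retained),
    removed = nrow(flagged)
  ))
  stopifnot(nrow(retained) + nrow(flagged) == nrow(survivors))

  # stage 5: characterisation of the retained database
  stats <- list(
    maf_spectrum = maf_spectrum(retained, sheet),
    population_polymorphism = population_polymorphism(retained, sheet),
    pi_windows = nucleotide_diversity_windows(retained, sheet, build,
                                              window = pi_window,
                                              subset = "non_dh"),
    density = snp_density_table(retained, build),
    arm_density = arm_density(flagged, build)
  )
  sweep_tbl <- if (sweep) threshold_sweep(survivors, sheet) else NULL
  effects <- if (!is.null(models) && !is.null(genome) && nrow(retained) > 0) {
    effect_summary(annotate_sites(retained, models, genome))
  } else NULL

  manifest <- structure(list(
    ledger = ledger, concordance = concordance, screen = screen,
    retained = retained, flagged = flagged, stats = stats,
    sweep = sweep_tbl, effects = effects,
    n_input = c(a = nrow(callset_a), b = nrow(callset_b)),
    n_intersection = nrow(core), n_retained = nrow(retained),
    n_flagged = nrow(flagged),
    pi_genome_mean = pi_genome_mean(stats$pi_windows),
    # audit trail: every threshold actually applied in this run
    config = c(unclass(cfg), dh_threshold = dh_threshold,
               pi_window = pi_window)
  ), class = "run_manifest")

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    write_vcf(retained, sheet, p("retained.vcf"))
    write_vcf(flagged, sheet, p("flagged_psv_msv.vcf"))
    write_ledger(ledger, p("ledger.tsv"))
    readr::write_tsv(concordance, p("concordance.tsv"))
    readr::write_tsv(stats$density, p("snp_density.tsv"))
    readr::write_tsv(stats$population_polymorphism, p("population_polymorphism.tsv"))
    readr::write_tsv(stats$maf_spectrum, p("maf_spectrum.tsv"))
    readr::write_tsv(stats$arm_density, p("arm_density.tsv"))
    if (!is.null(sweep_tbl)) readr::write_tsv(sweep_tbl, p("threshold_sweep.tsv"))
    if (!is.null(effects)) readr::write_tsv(effects, p("effect_summary.tsv"))
    pw <- stats$pi_windows
    readr::write_tsv(tibble(chrom = pw$chrom,
                            start = format(pw$start, scientific = FALSE, trim = TRUE),
                            end = format(pw$end, scientific = FALSE, trim = TRUE),
                            pi = pw$pi),
                     p("pi_windows.bedgraph"), col_names = FALSE)
    manifest$paths <- list.files(outdir, full.names = TRUE)
  }
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("SNP discovery pipeline run\n")
  cat("  input sites:      A =", x$n_input["a"], ", B =", x$n_input["b"], "\n")
  cat("  same-site-same-ALT core:", x$n_intersection,
      sprintf("(%s%% of combined)\n", x$concordance$pct_same_alt_of_combined))
  cat("  retained SNPs:   ", x$n_retained, "\n")
  cat("  flagged PSV/MSV: ", x$n_flagged, "\n")
  invisible(x)
}

#' Tidy a pipeline manifest into its stage ledger
#'
#' @param x A `run_manifest`.
#' @param ... Unused.
#' @return The ledger tibble (stage, entering, passing, removed).
#' @export
tidy.run_manifest <- function(x, ...) x$ledger

#' One-row summary of a pipeline run
#'
#' @param x A `run_manifest`.
#' @param ... Unused.
#' @return Tibble with core counts, concordance percentage and genome-mean
#'   nucleotide diversity.
#' @export
glance.run_manifest <- function(x, ...) {
  tibble(
    n_input_a = unname(x$n_input["a"]), n_input_b = unname(x$n_input["b"]),
    n_intersection = x$n_intersection,
    pct_same_alt_of_combined = x$concordance$pct_same_alt_of_combined,
    n_retained = x$n_retained, n_flagged = x$n_flagged,
    pi_genome_mean = x$pi_genome_mean
  )
}
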