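#' @importFrom ggplot2 ggplot aes geom_col geom_point geom_line labs
#'   scale_colour_manual autoplot theme_minimal
NULL

#' Plot a minor allele frequency spectrum
#'
#' @param spectrum Output of [maf_spectrum()].
#' @return A ggplot.
#' @export
plot_maf_spectrum <- function(spectrum) {
  ggplot(spectrum, aes(x = .data$lower + 0.025, y = .data$count)) +
    geom_col(width = 0.045, fill = "steelblue") +
    labs(x = "minor allele frequency", y = "number of SNPs") +
    theme_minimal()
}

#' Plot flagged-locus counts against arm length
#'
#' Scatter of putative PSV/MSV counts per chromosome arm versus arm length,
#' colouring duplicated (delayed-rediploidization) arms; in a genome with
#' residual tetraploidy those arms sit far above the trend.
#'
#' @param arm_density Output of [arm_density()].
#' @return A ggplot.
#' @export
plot_arm_density <- function(arm_density) {
  ggplot(arm_density, aes(x = .data$length, y = .data$n_flagged,
                          colour = .data$duplicated)) +
    geom_point(size = 3) +
    scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
                        name = "duplicated arm") +
    labs(x = "chromosome arm length (bp)", y = "putative PSVs/MSVs") +
    theme_minimal()
}

#' Plot a DH threshold sweep
#'
#' @param sweep Output of [threshold_sweep()].
#' @return A ggplot with flagged counts (log scale) and mean outbred
#'   heterozygosity against the threshold.
#' @export
plot_threshold_sweep <- function(sweep) {
  ggplot(sweep, aes(x = .data$threshold)) +
    geom_col(aes(y = .data$n_flagged), fill = "grey70") +
    geom_line(aes(y = .data$mean_outbred_ho * max(.data$n_flagged)),
              colour = "firebrick") +
    geom_point(aes(y = .data$mean_outbred_ho * max(.data$n_flagged)),
               colour = "firebrick") +
    labs(x = "minimum DH heterozygote count",
         y = "flagged loci (bars); mean outbred Ho (red, scaled)") +
    theme_minimal()
}

#' Plot a filter-cascade ledger
#'
#' @param object A `filter_cascade` object.
#' @param ... Unused.
#' @return A ggplot of surviving site counts per stage.
#' @export
autoplot.filter_cascade <- function(object, ...) {
  ledger <- object$ledger
  ledger$stage <- factor(ledger$stage, levels = ledger$stage)
  ggplot(ledger, aes(x = .data$stage, y = .data$passing)) +
    geom_col(fill = "steelblue") +
    labs(x = "filter stage", y = "sites passing") +
    theme_minimal()
}

#' Plot the stage counts of a pipeline run
#'
#' @param object A `run_manifest`.
#' @param ... Unused.
#' @return A ggplot of surviving site counts per stage.
#' @export
autoplot.run_manifest <- function(object, ...) {
  ledger <- object$ledger
  ledger$stage <- factor(ledger$stage, levels = ledger$stage)
  ggplot(ledger, aes(x = .data$stage, y = .data$passing)) +
    geom_col(fill = "steelblue") +
    labs(x = "pipeline stage", y = "sites passing") +
    theme_minimal()
}
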