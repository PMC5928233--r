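#' Published rainbow trout resequencing survey tables
#'
#' Summary tables from a 61-sample rainbow trout whole-genome resequencing
#' SNP survey (reference assembly GCA_002163495.1), bundled as inputs for the
#' package's accounting conventions: per-chromosome SNP counts, per-filter
#' two-caller agreement counts, SNP yield by number of genotyped samples,
#' per-population polymorphism counts, and the DH heterozygosity threshold
#' sweep. The package's summary functions reproduce the derived columns
#' (rates, percentages) of these tables from the raw counts.
#'
#' @return A tibble (see each function's columns).
#' @name trout_tables
NULL

#' @rdname trout_tables
#' @export
trout_chromosome_snps <- function() {
  tibble(
    chrom = c(paste0("omy", sprintf("%02d", 1:29)), "unplaced"),
    length = c(84884017, 85480851, 84937469, 85056421, 92202553, 82930723,
               79763776, 83778284, 68467736, 71056191, 80278304, 89655008,
               66052243, 80358725, 63368167, 70896079, 76527837, 61719220,
               59576373, 41412012, 51929587, 48550143, 49041849, 40362479,
               82601656, 40182520, 45316876, 40943904, 42631536, 229020432),
    n_snps = c(1359811, 1344028, 1228012, 1418468, 1502172, 1223031, 1256322,
               1337003, 1111656, 1102388, 1334513, 1323418, 765805, 1123544,
               1007882, 1158190, 1167740, 922176, 972098, 729603, 712355,
               919605, 830851, 642785, 1326472, 485126, 688717, 679933,
               628383, 1139018)
  )
}

#' @rdname trout_tables
#' @export
trout_caller_agreement <- function() {
  tibble(
    stage = c("QUAL", "LC", "DP", "NS", "DH"),
    n_a_only = c(7265023, 6525505, 6146820, 7190818, 5799376),
    n_b_only = c(3580043, 3014395, 4137345, 3054380, 2855191),
    n_same_alt = c(43220392, 42444371, 39629341, 34120907, 31441105),
    n_diff_alt = c(7073, 6083, 4155, 2006, 1205)
  )
}

#' @rdname trout_tables
#' @export
trout_sample_accumulation <- function() {
  tibble(
    n_samples = c(61, 60, 59, 58),
    n_a = c(31333183, 3768527, 1375968, 764008),
    n_b = c(29310209, 3100183, 1180917, 706192),
    n_both = c(27561442, 2733564, 792937, 353162)
  )
}

#' @rdname trout_tables
#' @export
trout_population_polymorphism <- function() {
  tibble(
    population = c("Dworshak", "Quinault", "L. Quinault", "Elwha", "Skamania",
                   "Big Creek", "Klamath", "Aquagen", "DH Line"),
    type = c("H", "H", "H", "W", "H", "W", "W", "A", "DH"),
    n_fish = c(4, 4, 4, 4, 4, 4, 4, 12, 11),
    n_sites_full_data = c(31356857, 31336970, 31352692, 31389210, 31346034,
                          31071820, 30742045, 30856284, 29951350),
    n_polymorphic = c(8642206, 9414415, 9622312, 11149740, 9408390, 11504243,
                      10469080, 11908286, 14423126)
  )
}

#' @rdname trout_tables
#' @export
trout_dh_threshold_sweep <- function() {
  tibble(
    label = c(paste0("Het > ", 0:9), "Het = 11"),
    n_flagged = c(2767612, 1733481, 1187715, 836278, 596329, 429862, 311629,
                  224252, 155617, 97433, 45757),
    mean_outbred_ho = c(0.35, 0.44, 0.51, 0.57, 0.62, 0.66, 0.71, 0.75, 0.78,
                        0.82, 0.85),
    pct_hwe_dev = c(28, 39, 49, 58, 67, 75, 81, 85, 89, 92, 95)
  )
}

#' @rdname trout_tables
#' @export
trout_survey_constants <- function() {
  list(
    n_samples = 61, n_dh = 11, n_outbred = 50,
    total_snps = 31441105,
    n_maf_below_05 = 17530182,
    n_maf_above_25 = 4042723,
    max_depth = 1500,
    array_matched = 49155, array_validated = 43603
  )
}
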