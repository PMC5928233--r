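#' Sequence Ontology terms and impact tiers emitted by the annotator
#'
#' The 20-term scheme used by the effect summary, in its conventional order,
#' with the impact tier paired to each term.
#'
#' @return Tibble with `so_term`, `impact`.
#' @export
so_term_impacts <- function() {
  tibble(
    so_term = c(
      "stop_gained", "splice_donor_variant", "splice_acceptor_variant",
      "stop_lost", "start_lost", "missense_variant", "splice_region_variant",
      "synonymous_variant", "5_prime_UTR_premature_start_codon_gain_variant",
      "stop_retained_variant", "initiator_codon_variant",
      "non_coding_transcript_variant", "intron_variant", "intergenic_region",
      "upstream_gene_variant", "downstream_gene_variant", "3_prime_UTR_variant",
      "intragenic_variant", "5_prime_UTR_variant",
      "non_coding_transcript_exon_variant"
    ),
    impact = c("HIGH", "HIGH", "HIGH", "HIGH", "HIGH", "MODERATE", "LOW",
               "LOW", "LOW", "LOW", "LOW", "MODIFIER", "MODIFIER", "MODIFIER",
               "MODIFIER", "MODIFIER", "MODIFIER", "MODIFIER", "MODIFIER",
               "MODIFIER")
  )
}

GENETIC_CODE_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L", CTA = "L",
  CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M", GTT = "V", GTC = "V",
  GTA = "V", GTG = "V", TCT = "S", TCC = "S", TCA = "S", TCG = "S", CCT = "P",
  CCC = "P", CCA = "P", CCG = "P", ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*",
  TAG = "*", CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E", TGT = "C",
  TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R", GGT = "G", GGC = "G", GGA = "G",
  GGG = "G"
)

START_CODONS <- c("ATG", "CTG", "TTG")

revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", vapply(
    strsplit(x, ""), function(v) paste(rev(v), collapse = ""), character(1)
  ))
}

#' Classify a single-base codon change
#'
#' @param ref_codon,alt_codon Three-base codons on the coding strand.
#' @param is_initiator Is this the first codon of the CDS?
#' @return The SO term for the change.
#' @export
classify_codon_change <- function(ref_codon, alt_codon, is_initiator = FALSE) {
  aa_ref <- GENETIC_CODE_TABLE[[ref_codon]]
  aa_alt <- GENETIC_CODE_TABLE[[alt_codon]]
  if (is_initiator && ref_codon %in% START_CODONS) {
    if (alt_codon %in% START_CODONS) return("initiator_codon_variant")
    return("start_lost")
  }
  if (aa_ref != "*" && aa_alt == "*") return("stop_gained")
  if (aa_ref == "*" && aa_alt != "*") return("stop_lost")
  if (aa_ref == "*" && aa_alt == "*") return("stop_retained_variant")
  if (aa_ref == aa_alt) return("synonymous_variant")
  "missense_variant"
}

#' Read gene models from GFF3
#'
#' Parses `gene`, `mRNA` (and non-coding `transcript`/`ncRNA`), `exon`, `CDS`,
#' `five_prime_UTR` and `three_prime_UTR` features into the transcript table
#' the annotator consumes. Coordinates are kept 1-based inclusive as in GFF.
#'
#' @param path GFF3 file path.
#' @return A list with `genes` (tibble: `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `n_tx`) and `transcripts` (tibble with list-columns `exons` and
#'   `cds`, each a tibble of `start`, `end` ordered by position).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  d <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = gr$ID %||% NA_character_,
    parent = vapply(as.list(gr$Parent %||% rep("", length(gr))),
                    function(p) if (length(p)) p[[1]] else NA_character_,
                    character(1))
  )
  genes <- d |> filter(.data$type == "gene")
  tx_types <- c("mRNA", "transcript", "ncRNA", "lnc_RNA", "rRNA", "tRNA")
  txs <- d |> filter(.data$type %in% tx_types)
  transcripts <- map(seq_len(nrow(txs)), function(i) {
    tx <- txs[i, ]
    kids <- d |> filter(.data$parent == tx$id)
    exons <- kids |> filter(.data$type == "exon") |>
      arrange(.data$start) |> select("start", "end")
    cds <- kids |> filter(.data$type == "CDS") |>
      arrange(.data$start) |> select("start", "end")
    utr5 <- kids |> filter(.data$type == "five_prime_UTR") |>
      arrange(.data$start) |> select("start", "end")
    utr3 <- kids |> filter(.data$type == "three_prime_UTR") |>
      arrange(.data$start) |> select("start", "end")
    tibble(
      tx_id = tx$id, gene_id = tx$parent, chrom = tx$chrom,
      strand = tx$strand, start = tx$start, end = tx$end,
      coding = nrow(cds) > 0,
      exons = list(exons), cds = list(cds), utr5 = list(utr5), utr3 = list(utr3)
    )
  }) |> list_rbind()
  n_tx <- table(factor(transcripts$gene_id, levels = genes$id))
  list(
    genes = tibble(gene_id = genes$id, chrom = genes$chrom,
                   strand = genes$strand, start = genes$start, end = genes$end,
                   n_tx = as.integer(n_tx[genes$id])),
    transcripts = transcripts
  )
}

in_spans <- function(pos, spans) {
  nrow(spans) > 0 && any(pos >= spans$start & pos <= spans$end)
}

#' Annotate SNPs with predicted effects
#'
#' Assigns Sequence Ontology effect terms and impact tiers to bi-allelic SNPs
#' given gene models and the reference sequence, one record per overlapping
#' transcript feature. Coding changes are classified by strand-aware codon
#' comparison (stop gained/lost/retained, start lost, initiator codon,
#' missense, synonymous); the first/last two intronic bases are splice
#' donor/acceptor sites (HIGH); intronic bases 3-8 and exonic bases 1-3 from
#' a junction are splice region; UTR, intron, upstream/downstream (within
#' `flank` bp of the gene) and intergenic fall through as printed. A SNP in a
#' 5' UTR that creates an upstream ATG is a premature-start-gain. Every SNP
#' receives at least one record (`intergenic_region` is the fallback).
#'
#' @param sites A [variant_table()] of bi-allelic SNPs.
#' @param models Gene models from [read_gene_models()].
#' @param genome Named character vector of chromosome sequences.
#' @param flank Upstream/downstream distance in bp (default 5000).
#' @return Tibble: `chrom`, `pos`, `ref`, `alt`, `gene_id`, `tx_id`,
#'   `so_term`, `impact`.
#' @export
annotate_sites <- function(sites, models, genome, flank = 5000) {
  stopifnot(all(is_biallelic_snp(sites)))
  impacts <- setNames(so_term_impacts()$impact, so_term_impacts()$so_term)
  recs <- map(seq_len(nrow(sites)), function(i) {
    annotate_one(sites$chrom[i], sites$pos[i], sites$ref[i], sites$alt[i],
                 models, genome, flank)
  }) |> list_rbind()
  recs$impact <- unname(impacts[recs$so_term])
  recs
}

annotate_one <- function(chrom, pos, ref, alt, models, genome, flank) {
  base <- substr(genome[[chrom]], pos, pos)
  if (toupper(base) != toupper(ref)) {
    abort(paste0("REF allele mismatch at ", chrom, ":", pos,
                 " (reference has ", base, ", site says ", ref, ")"))
  }
  rec <- function(term, gene = NA_character_, tx = NA_character_) {
    tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
           gene_id = gene, tx_id = tx, so_term = term)
  }
  out <- list()
  txs <- models$transcripts |> filter(.data$chrom == !!chrom)
  genes <- models$genes |> filter(.data$chrom == !!chrom)
  for (i in seq_len(nrow(txs))) {
    tx <- txs[i, ]
    if (pos >= tx$start && pos <= tx$end) {
      out <- c(out, list(annotate_in_transcript(tx, chrom, pos, ref, alt,
                                                genome, rec)))
    } else if (pos >= tx$start - flank && pos <= tx$end + flank) {
      before <- pos < tx$start
      term <- if ((before && tx$strand == "+") || (!before && tx$strand == "-"))
        "upstream_gene_variant" else "downstream_gene_variant"
      out <- c(out, list(rec(term, tx$gene_id, tx$tx_id)))
    }
  }
  # genes without any transcript: intragenic
  lone <- genes |> filter(.data$n_tx == 0, pos >= .data$start, pos <= .data$end)
  for (g in lone$gene_id) out <- c(out, list(rec("intragenic_variant", g)))
  if (length(out) == 0) return(rec("intergenic_region"))
  list_rbind(out)
}

annotate_in_transcript <- function(tx, chrom, pos, ref, alt, genome, rec) {
  exons <- tx$exons[[1]]
  cds <- tx$cds[[1]]
  in_exon <- in_spans(pos, exons)
  out <- list()
  if (!tx$coding) {
    term <- if (in_exon) "non_coding_transcript_exon_variant" else
      "non_coding_transcript_variant"
    return(rec(term, tx$gene_id, tx$tx_id))
  }
  if (in_exon) {
    if (in_spans(pos, cds)) {
      out <- c(out, list(rec(classify_cds_change(tx, pos, alt, genome[[chrom]]),
                             tx$gene_id, tx$tx_id)))
    } else if (in_spans(pos, tx$utr5[[1]])) {
      term <- if (gains_upstream_start(tx, pos, alt, genome[[chrom]]))
        "5_prime_UTR_premature_start_codon_gain_variant" else "5_prime_UTR_variant"
      out <- c(out, list(rec(term, tx$gene_id, tx$tx_id)))
    } else if (in_spans(pos, tx$utr3[[1]])) {
      out <- c(out, list(rec("3_prime_UTR_variant", tx$gene_id, tx$tx_id)))
    } else {
      out <- c(out, list(rec("intron_variant", tx$gene_id, tx$tx_id)))
    }
    # exonic 1-3 bp from a junction (junctions with a neighbouring intron only)
    if (exonic_splice_region(pos, exons, tx)) {
      out <- c(out, list(rec("splice_region_variant", tx$gene_id, tx$tx_id)))
    }
  } else {
    out <- c(out, list(rec(intronic_term(pos, exons, tx$strand),
                           tx$gene_id, tx$tx_id)))
  }
  list_rbind(out)
}

# distance from pos to the intron boundaries; introns are the gaps between
# consecutive exons
intron_of <- function(pos, exons) {
  for (j in seq_len(nrow(exons) - 1)) {
    lo <- exons$end[j] + 1; hi <- exons$start[j + 1] - 1
    if (pos >= lo && pos <= hi) return(c(lo, hi))
  }
  NULL
}

intronic_term <- function(pos, exons, strand) {
  b <- intron_of(pos, exons)
  if (is.null(b)) return("intron_variant")
  d_left <- pos - b[1]; d_right <- b[2] - pos       # 0-based offsets into intron
  d5 <- if (strand == "+") d_left else d_right      # from donor end
  d3 <- if (strand == "+") d_right else d_left      # from acceptor end
  if (d5 <= 1) return("splice_donor_variant")
  if (d3 <= 1) return("splice_acceptor_variant")
  if (d5 <= 7 || d3 <= 7) return("splice_region_variant")  # intronic bases 3-8
  "intron_variant"
}

exonic_splice_region <- function(pos, exons, tx) {
  for (j in seq_len(nrow(exons))) {
    has_left_intron <- j > 1
    has_right_intron <- j < nrow(exons)
    if (pos >= exons$start[j] && pos <= exons$end[j]) {
      if (has_left_intron && pos - exons$start[j] <= 2) return(TRUE)
      if (has_right_intron && exons$end[j] - pos <= 2) return(TRUE)
    }
  }
  FALSE
}

# coding-strand CDS sequence and the transcript-strand coordinate of pos
cds_context <- function(tx, pos, genomeseq) {
  cds <- tx$cds[[1]]
  pieces <- vapply(seq_len(nrow(cds)),
                   function(j) substr(genomeseq, cds$start[j], cds$end[j]),
                   character(1))
  seq_plus <- paste(pieces, collapse = "")
  offsets <- cumsum(c(0, head(cds$end - cds$start + 1, -1)))
  j <- which(pos >= cds$start & pos <= cds$end)[1]
  idx_plus <- offsets[j] + (pos - cds$start[j]) + 1
  if (tx$strand == "+") {
    list(seq = toupper(seq_plus), idx = idx_plus)
  } else {
    list(seq = toupper(revcomp(seq_plus)), idx = nchar(seq_plus) - idx_plus + 1)
  }
}

classify_cds_change <- function(tx, pos, alt, genomeseq) {
  ctx <- cds_context(tx, pos, genomeseq)
  codon_i <- (ctx$idx - 1) %/% 3
  codon_start <- codon_i * 3 + 1
  ref_codon <- substr(ctx$seq, codon_start, codon_start + 2)
  if (nchar(ref_codon) < 3) return("synonymous_variant")  # truncated terminal codon
  alt_base <- if (tx$strand == "+") toupper(alt) else revcomp(toupper(alt))
  alt_codon <- ref_codon
  substr(alt_codon, ctx$idx - codon_start + 1, ctx$idx - codon_start + 1) <- alt_base
  classify_codon_change(ref_codon, alt_codon, is_initiator = codon_i == 0)
}

# does the substitution create an ATG on the coding strand within the 5' UTR?
gains_upstream_start <- function(tx, pos, alt, genomeseq) {
  for (off in 0:2) {
    lo <- pos - off; hi <- lo + 2
    triplet <- substr(genomeseq, lo, hi)
    substr(triplet, off + 1, off + 1) <- toupper(alt)
    tri <- if (tx$strand == "+") triplet else revcomp(triplet)
    covered <- in_spans(lo, tx$utr5[[1]]) && in_spans(hi, tx$utr5[[1]])
    if (covered && toupper(tri) == "ATG") return(TRUE)
  }
  FALSE
}

#' Tabulate effect records
#'
#' Counts effect records per SO term in the standard 20-term order,
#' zero-filled. Counts sum to the number of effect records, not sites: a SNP
#' can have several effects.
#'
#' @param records Output of [annotate_sites()].
#' @return Tibble with `so_term`, `impact`, `n_effects`.
#' @export
effect_summary <- function(records) {
  scheme <- so_term_impacts()
  n <- table(factor(records$so_term, levels = scheme$so_term))
  mutate(scheme, n_effects = as.integer(n[scheme$so_term]))
}
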