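# a hand-designed toy annotation set: one plus-strand coding gene, one
# minus-strand coding gene, one non-coding transcript, one transcript-less
# gene, with codons planted at known positions so every effect category has a
# site whose classification can be worked out by hand.
toy_annotation <- function() {
  L <- 40000
  set.seed(424)
  g <- random_dna_string(L)
  put <- function(s, at, what) {
    substr(s, at, at + nchar(what) - 1) <- what
    s
  }

  # gene A (+): gene 2001-5000; exons 2001-2400 / 3001-3600 / 4201-5000;
  # 5'UTR 2001-2200; CDS 2201-2400, 3001-3600, 4201-4399 (999 bp); 3'UTR 4400-5000
  g <- put(g, 2201, "ATG")        # start codon (codon 1)
  g <- put(g, 2216, "TGG")        # codon 6: TGG -> TGA = stop_gained
  g <- put(g, 2219, "GCT")        # codon 7: GCT -> GCC = synonymous
  g <- put(g, 2228, "AAA")        # codon 10: AAA -> AAC = missense
  g <- put(g, 4397, "TAA")        # final codon: TAA -> TCA = stop_lost
  g <- put(g, 2149, "CAAGC")      # 5'UTR: A->T at 2151 creates ATG
  g <- put(g, 2099, "CCCCC")      # plain 5'UTR site, no start gain possible
  # cross-junction codon 67 = coding 199-201 = genome 2399,2400 | 3001
  g <- put(g, 2399, "GG"); g <- put(g, 3001, "T")  # GGT -> AGT missense

  # gene B (-): gene 18001-21000; exons 18001-18401 / 19001-19600 / 20201-21000
  # CDS 18204-18401, 19001-19600, 20201-20401 (999 bp);
  # 5'UTR 20402-21000; 3'UTR 18001-18203
  g <- put(g, 20399, "CAT")       # revcomp start codon
  g <- put(g, 18204, "TTA")       # revcomp stop codon
  g <- put(g, 19598, "CCA")       # coding codon 68 = TGG; C->T at 19598 -> TGA
  g <- put(g, 20498, "CCCCC")     # plain 5'UTR site on the minus strand

  gff <- c(
    "##gff-version 3",
    gff_row("toy", "gene", 2001, 5000, "+", "ID=geneA"),
    gff_row("toy", "mRNA", 2001, 5000, "+", "ID=txA;Parent=geneA"),
    gff_row("toy", "exon", 2001, 2400, "+", "Parent=txA"),
    gff_row("toy", "exon", 3001, 3600, "+", "Parent=txA"),
    gff_row("toy", "exon", 4201, 5000, "+", "Parent=txA"),
    gff_row("toy", "five_prime_UTR", 2001, 2200, "+", "Parent=txA"),
    gff_row("toy", "CDS", 2201, 2400, "+", "Parent=txA"),
    gff_row("toy", "CDS", 3001, 3600, "+", "Parent=txA"),
    gff_row("toy", "CDS", 4201, 4399, "+", "Parent=txA"),
    gff_row("toy", "three_prime_UTR", 4400, 5000, "+", "Parent=txA"),
    gff_row("toy", "gene", 18001, 21000, "-", "ID=geneB"),
    gff_row("toy", "mRNA", 18001, 21000, "-", "ID=txB;Parent=geneB"),
    gff_row("toy", "exon", 18001, 18401, "-", "Parent=txB"),
    gff_row("toy", "exon", 19001, 19600, "-", "Parent=txB"),
    gff_row("toy", "exon", 20201, 21000, "-", "Parent=txB"),
    gff_row("toy", "three_prime_UTR", 18001, 18203, "-", "Parent=txB"),
    gff_row("toy", "CDS", 18204, 18401, "-", "Parent=txB"),
    gff_row("toy", "CDS", 19001, 19600, "-", "Parent=txB"),
    gff_row("toy", "CDS", 20201, 20401, "-", "Parent=txB"),
    gff_row("toy", "five_prime_UTR", 20402, 21000, "-", "Parent=txB"),
    gff_row("toy", "gene", 32001, 34000, "+", "ID=geneC"),
    gff_row("toy", "ncRNA", 32001, 34000, "+", "ID=txC;Parent=geneC"),
    gff_row("toy", "exon", 32001, 32500, "+", "Parent=txC"),
    gff_row("toy", "exon", 33501, 34000, "+", "Parent=txC"),
    gff_row("toy", "gene", 36001, 36500, "+", "ID=geneD")
  )
  list(genome = c(toy = g), gff = gff)
}

gff_row <- function(chrom, type, s, e, strand, attrs) {
  paste(chrom, "toy", type, s, e, ".", strand, ".", attrs, sep = "\t")
}

# the hand-worked expectations: position, alt allele, and the effect records
# (per transcript feature) each SNP must receive
toy_expected_effects <- function() {
  tibble::tribble(
    ~pos,   ~alt_rule,          ~terms,
    2218,   "A",                c("stop_gained"),                 # TGG -> TGA
    2221,   "C",                c("synonymous_variant"),          # GCT -> GCC
    2230,   "C",                c("missense_variant"),            # AAA -> AAC
    4398,   "C",                c("stop_lost"),                   # TAA -> TCA
    2202,   "C",                c("start_lost"),                  # ATG -> ACG
    2201,   "C",                c("initiator_codon_variant"),     # ATG -> CTG
    2401,   NA,                 c("splice_donor_variant"),
    3000,   NA,                 c("splice_acceptor_variant"),
    2405,   NA,                 c("splice_region_variant"),       # intron base 5
    2700,   NA,                 c("intron_variant"),
    2151,   "T",                c("5_prime_UTR_premature_start_codon_gain_variant"),
    2100,   "G",                c("5_prime_UTR_variant"),
    4500,   NA,                 c("3_prime_UTR_variant"),
    1500,   NA,                 c("upstream_gene_variant"),
    5500,   NA,                 c("downstream_gene_variant"),
    11000,  NA,                 c("intergenic_region"),
    # minus-strand gene B
    # 2 bp from the exon2/intron junction: codon effect plus splice region
    19598,  "T",                c("stop_gained", "splice_region_variant"),
    20500,  "G",                c("5_prime_UTR_variant"),
    18100,  NA,                 c("3_prime_UTR_variant"),
    20200,  NA,                 c("splice_donor_variant"),
    19601,  NA,                 c("splice_acceptor_variant"),
    21500,  NA,                 c("upstream_gene_variant"),
    # exonic base 2 of exon1's right junction: coding + splice region
    2399,   "A",                c("missense_variant", "splice_region_variant"),
    # non-coding transcript and transcript-less gene
    32100,  NA,                 c("non_coding_transcript_exon_variant"),
    33000,  NA,                 c("non_coding_transcript_variant"),
    # gene D has no transcript; the site is also 2.2 kb past gene C's ncRNA
    36200,  NA,                 c("intragenic_variant", "downstream_gene_variant")
  )
}

toy_sites <- function(toy, expected) {
  ref <- vapply(expected$pos, function(p) substr(toy$genome[["toy"]], p, p),
                character(1))
  alt <- ifelse(is.na(expected$alt_rule),
                vapply(ref, function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                       character(1)),
                expected$alt_rule)
  make_sites("toy", expected$pos, ref = ref, alt = alt, n_samples = 2)
}
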