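test_that("codon-change classification is forced by the genetic code", {
  expect_equal(classify_codon_change("TGG", "TGA"), "stop_gained")
  expect_equal(classify_codon_change("GCT", "GCC"), "synonymous_variant")
  expect_equal(classify_codon_change("AAA", "AAC"), "missense_variant")
  expect_equal(classify_codon_change("TAA", "TCA"), "stop_lost")
  expect_equal(classify_codon_change("TAA", "TGA"), "stop_retained_variant")
  expect_equal(classify_codon_change("ATG", "ACG", is_initiator = TRUE), "start_lost")
  expect_equal(classify_codon_change("ATG", "CTG", is_initiator = TRUE),
               "initiator_codon_variant")
})

test_that("codon classification agrees with translation for all single-base changes", {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  for (ref_codon in codons) {
    for (p in 1:3) {
      for (b in setdiff(bases, substr(ref_codon, p, p))) {
        alt_codon <- ref_codon
        substr(alt_codon, p, p) <- b
        got <- classify_codon_change(ref_codon, alt_codon)
        # independent oracle: translate both codons with Biostrings
        aa <- as.character(Biostrings::translate(
          Biostrings::DNAStringSet(c(ref_codon, alt_codon)),
          no.init.codon = TRUE))
        expected <- if (aa[1] != "*" && aa[2] == "*") "stop_gained"
        else if (aa[1] == "*" && aa[2] != "*") "stop_lost"
        else if (aa[1] == "*" && aa[2] == "*") "stop_retained_variant"
        else if (aa[1] == aa[2]) "synonymous_variant"
        else "missense_variant"
        expect_equal(got, expected, info = paste(ref_codon, "->", alt_codon))
      }
    }
  }
})

test_that("the toy genome is classified exactly as hand-worked", {
  toy <- toy_annotation()
  gff_path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(toy$gff, gff_path)
  models <- read_gene_models(gff_path)
  expected <- toy_expected_effects()
  sites <- toy_sites(toy, expected)
  records <- annotate_sites(sites, models, toy$genome)

  scheme <- so_term_impacts()
  for (i in seq_len(nrow(expected))) {
    got <- sort(records$so_term[records$pos == expected$pos[i]])
    expect_equal(got, sort(expected$terms[[i]]),
                 info = paste("pos", expected$pos[i]))
  }
  # every record's impact follows the fixed (term, impact) pairing
  expect_equal(records$impact,
               scheme$impact[match(records$so_term, scheme$so_term)])
  # every SNP receives at least one record
  expect_true(all(sites$pos %in% records$pos))

  # the summary is zero-filled over the 20-term scheme and counts effects
  smry <- effect_summary(records)
  expect_equal(smry$so_term, scheme$so_term)
  expect_equal(sum(smry$n_effects), nrow(records))
  expect_equal(smry$n_effects[smry$so_term == "stop_gained"], 2L)
  expect_equal(effect_summary(records[0, ])$n_effects, rep(0L, 20))

  # a REF/reference mismatch is a named error
  bad <- sites; bad$ref[1] <- setdiff(c("A", "C", "G", "T"),
                                      c(bad$ref[1], bad$alt[1]))[1]
  expect_error(annotate_sites(bad[1, ], models, toy$genome), "REF allele mismatch")
})

test_that("effect summaries are invariant under reverse-complementing the genome", {
  toy <- toy_annotation()
  L <- nchar(toy$genome[["toy"]])
  expected <- toy_expected_effects()
  sites <- toy_sites(toy, expected)

  # mirror the world: revcomp genome, flip coordinates and strands
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  genome_rc <- c(toy = rc(toy$genome[["toy"]]))
  flip_gff <- vapply(toy$gff, function(line) {
    if (startsWith(line, "#")) return(line)
    f <- strsplit(line, "\t")[[1]]
    s <- as.numeric(f[4]); e <- as.numeric(f[5])
    f[4] <- as.character(L - e + 1); f[5] <- as.character(L - s + 1)
    f[7] <- if (f[7] == "+") "-" else "+"
    paste(f, collapse = "\t")
  }, character(1), USE.NAMES = FALSE)
  sites_rc <- sites
  sites_rc$pos <- L - sites$pos + 1
  sites_rc$ref <- chartr("ACGT", "TGCA", sites$ref)
  sites_rc$alt <- chartr("ACGT", "TGCA", sites$alt)
  sites_rc <- sort_sites(sites_rc)

  p1 <- withr::local_tempfile(fileext = ".gff3")
  p2 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(toy$gff, p1); writeLines(flip_gff, p2)
  s1 <- effect_summary(annotate_sites(sites, read_gene_models(p1), toy$genome))
  s2 <- effect_summary(annotate_sites(sites_rc, read_gene_models(p2), genome_rc))
  expect_equal(s1, s2)
})
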