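test_that("inclusive spans and point distances use distinct conventions", {
  expect_equal(inclusive_span(28583267, 28583299), 33)
  expect_equal(inclusive_span(5, 5), 1)
  expect_equal(inclusive_span(1, 10), 10)
  expect_error(inclusive_span(10, 1))
  expect_error(inclusive_span(0, 5))
  for (L in c(1, 2, 17, 1000)) {
    expect_equal(inclusive_span(42, 42 + L - 1), L)
  }

  expect_equal(position_distance(26872019, 26872024), 5)
  expect_equal(position_distance(7, 7), 0)
  expect_equal(position_distance(3, 11), position_distance(11, 3))
  # a span is one longer than the distance between its endpoints
  expect_equal(inclusive_span(100, 105), position_distance(100, 105) + 1)
})

test_that("gene models validate their coding sequence", {
  g <- toy_gene()
  expect_equal(g$protein_length, 30L)
  expect_error(toy_gene(codon11 = "TAA"), "internal stop")
  expect_error(gene_model("x", "chr1", "+",
                          exons = data.frame(start = 1, end = 9),
                          cds = data.frame(start = 1, end = 9),
                          cds_seq = "ATGATGATG"),  # no stop at end
               "stop")
  expect_error(gene_model("x", "chr1", "+",
                          exons = data.frame(start = 1, end = 8),
                          cds = data.frame(start = 1, end = 8),
                          cds_seq = "ATGTAA"), "does not match")
})

test_that("SNV consequences are classified through codon translation", {
  g <- toy_gene(cds_start = 1001)  # codon 11 = TGG at 1031-1033
  # TGG -> TGA: stopgain at codon 11
  ann <- annotate_variant(g, "chr1", 1033, "G", "A")
  expect_equal(ann$category, "stopgain")
  expect_equal(ann$codon_index, 11L)
  expect_equal(ann$truncated_length, 10L)
  # TGG -> TGC: nonsynonymous (Trp -> Cys)
  expect_equal(annotate_variant(g, "chr1", 1033, "G", "C")$category,
               "nonsynonymous")
  # GGC -> GGA at codon 2 third base: synonymous
  expect_equal(annotate_variant(g, "chr1", 1006, "C", "A")$category,
               "synonymous")
  # final stop codon TAA -> CAA: stoploss
  expect_equal(annotate_variant(g, "chr1", 1091, "T", "C")$category,
               "stoploss")
  expect_error(annotate_variant(g, "chr1", 1033, "C", "A"), "mismatch")
  expect_error(annotate_variant(g, "chr2", 1033, "G", "A"))
})

test_that("every synonymous third-position wobble annotates as synonymous", {
  g <- toy_gene()
  code <- Biostrings::GENETIC_CODE
  for (codon_i in seq_len(30)) {
    at <- (codon_i - 1) * 3 + 3          # third base, CDS offset
    pos <- g$cds$start + at - 1
    codon <- substr(g$cds_seq, at - 2, at)
    ref <- substr(codon, 3, 3)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      mutant <- paste0(substr(codon, 1, 2), alt)
      if (code[[mutant]] == code[[codon]]) {
        expect_equal(annotate_variant(g, "chr1", pos, ref, alt)$category,
                     "synonymous")
      }
    }
  }
})

test_that("CDS indels are classified by length modulo 3", {
  g <- toy_gene()
  expect_equal(annotate_variant(g, "chr1", 1010, "CGG", "")$category,
               "nonframeshift_indel")
  expect_equal(annotate_variant(g, "chr1", 1010, "CG", "")$category,
               "frameshift_indel")
  expect_equal(annotate_variant(g, "chr1", 1010, "C", "CTT")$category,
               "frameshift_indel")
})

test_that("non-coding positions get noncoding/upstream/downstream calls", {
  g <- toy_gene(cds_start = 1001)  # exons 901..1193
  expect_equal(annotate_variant(g, "chr1", 950, "A", "T")$category,
               "noncoding")  # 5' UTR exon space
  up <- annotate_variant(g, "chr1", 800, "A", "T")
  expect_equal(up$category, "upstream")
  expect_equal(up$distance_bp, 101)
  dn <- annotate_variant(g, "chr1", 1300, "A", "T")
  expect_equal(dn$category, "downstream")
  expect_equal(dn$distance_bp, 107)
  # on the minus strand the roles flip
  gm <- toy_gene(strand = "-")
  expect_equal(annotate_variant(gm, "chr1", 800, "A", "T")$category,
               "downstream")
})

test_that("minus-strand annotation complements alleles into mRNA space", {
  # CDS sequence is in mRNA orientation; genomic plus-strand base at the
  # last genomic CDS position corresponds to the first mRNA base
  g <- toy_gene(strand = "-", cds_start = 2001)
  cds_end <- g$cds$end
  # mRNA base 1 is "A" (ATG); genomic base there is its complement "T"
  ann <- annotate_variant(g, "chr1", cds_end, "T", "C")
  expect_equal(ann$codon_index, 1L)
  # A->G at mRNA position 1: ATG -> GTG (Met -> Val)
  expect_equal(ann$category, "nonsynonymous")
  # stopgain on the minus strand: codon 11 TGG, third mRNA base ->A means
  # genomic plus-strand C->T at cds_end - 32
  ann2 <- annotate_variant(g, "chr1", cds_end - 32, "C", "T")
  expect_equal(ann2$category, "stopgain")
  expect_equal(ann2$codon_index, 11L)
})

test_that("truncated protein length is the retained codon count", {
  g <- toy_gene()
  expect_equal(truncated_protein_length(g, "chr1", 1033, "G", "A"), 10L)
  for (k in c(11)) {
    ann <- annotate_variant(g, "chr1", 1001 + (k - 1) * 3 + 2, "G", "A")
    expect_equal(ann$truncated_length, k - 1L)
  }
  # ATG codon 1 cannot become a stop by one substitution in this model;
  # build a gene whose codon 2 is CAA -> TAA via C>T
  codons <- c("ATG", "CAA", rep("GGC", 27), "TAA")
  g2 <- gene_model("t2", "chr1", "+",
                   exons = data.frame(start = 1, end = 90),
                   cds = data.frame(start = 1, end = 90),
                   cds_seq = paste(codons, collapse = ""))
  expect_equal(truncated_protein_length(g2, "chr1", 4, "C", "T"), 1L)
  # synonymous input is rejected
  expect_error(truncated_protein_length(g, "chr1", 1006, "C", "A"),
               "not a stopgain")
  # replacing the natural stop with another stop is not a truncation
  expect_error(truncated_protein_length(g, "chr1", 1092, "A", "G"),
               "not a stopgain")
})

test_that("severity ranks truncating above other coding effects", {
  expect_equal(effect_severity(c("stopgain", "frameshift_indel",
                                 "nonsynonymous", "synonymous")),
               c(1L, 1L, 2L, 3L))
})
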