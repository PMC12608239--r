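test_that("genotype classification follows the frequency bands", {
  expect_equal(classify_genotype(20, 0), "hom_ref")
  expect_equal(classify_genotype(9, 11), "het")     # f = 0.55
  expect_equal(classify_genotype(1, 0), "no_call")  # below min_depth 4
  expect_equal(classify_genotype(0, 30), "hom_alt")
  expect_equal(classify_genotype(3, 1), "het")      # f = 0.25, depth 4
  expect_equal(classify_genotype(1, 9), "no_call")  # f = 0.9 between bands
  expect_equal(classify_genotype(c(20, 9, 1), c(0, 11, 0)),
               c("hom_ref", "het", "no_call"))
  expect_error(genotype_thresholds(t_low = 0.3, het_lo = 0.2))
  expect_error(genotype_thresholds(min_depth = 0))
  expect_error(classify_genotype(-1, 3))
})

test_that("segregation-pattern filter retains the causal configuration", {
  libs <- c(P1 = NA, P2 = NA, CE = NA, NE = NA)
  af <- rbind(
    causal = c(P1 = 0.5, P2 = 0.5, CE = 1.0, NE = 0.33),
    lowdaf = c(0.5, 0.5, 0.72, 0.33),   # dAF 0.39 < 0.5
    homparent = c(1.0, 0.5, 1.0, 0.33),
    inhibitor = c(0.5, 0.5, 0.0, 0.67)  # opposite fixation direction
  )
  tab <- make_table(af)
  cross <- cross_libraries(c("P1", "P2"), "CE", "NE")
  rec <- candidate_mutation_filter(tab, cross, keep_all = TRUE)
  expect_equal(rec$pass, c(TRUE, FALSE, FALSE, TRUE))
  expect_false(rec$daf_ok[2])
  expect_false(rec$parents_het[3])

  kept <- candidate_mutation_filter(tab, cross)
  expect_equal(nrow(kept), 2)
  expect_error(candidate_mutation_filter(
    tab, cross_libraries(c("P1", "missing"), "CE", "NE")))
})

test_that("filter is invariant to a global ref/alt label swap", {
  set.seed(5)
  af <- matrix(runif(4 * 50), 50, 4,
               dimnames = list(NULL, c("P1", "P2", "CE", "NE")))
  tab <- make_table(af)
  swapped <- allele_count_table(
    within(tab$sites, {tmp <- ref; ref <- alt; alt <- tmp; rm(tmp)}),
    tab$alt, tab$ref, tab$libraries)
  cross <- cross_libraries(c("P1", "P2"), "CE", "NE")
  a <- candidate_mutation_filter(tab, cross, keep_all = TRUE)
  b <- candidate_mutation_filter(swapped, cross, keep_all = TRUE)
  expect_equal(a$pass, b$pass)
})

test_that("retained set shrinks as the dAF threshold rises", {
  set.seed(6)
  af <- matrix(runif(4 * 200), 200, 4,
               dimnames = list(NULL, c("P1", "P2", "CE", "NE")))
  af[, "P1"] <- af[, "P2"] <- runif(200, 0.3, 0.7)
  tab <- make_table(af)
  cross <- cross_libraries(c("P1", "P2"), "CE", "NE")
  ns <- vapply(c(0, 0.25, 0.5, 0.75, 0.9), function(d) {
    nrow(candidate_mutation_filter(tab, cross, daf_min = d))
  }, 0L)
  expect_true(all(diff(ns) <= 0))
})

test_that("few null sites pass the filter at default thresholds", {
  # no causal structure: pools are random halves of the same offspring
  ex <- cached_experiment(1)
  off <- ex$crosses$cross1
  idx <- sample(seq_along(off$phenotype))
  half <- split(idx, rep(1:2, length.out = length(idx)))
  af_a <- rowMeans(off$dosage[, half[[1]], drop = FALSE]) / 2
  af_b <- rowMeans(off$dosage[, half[[2]], drop = FALSE]) / 2
  set.seed(31)
  mk <- function(af, d) {
    dep <- rpois(length(af), d)
    alt <- rbinom(length(af), dep, af)
    list(ref = dep - alt, alt = alt)
  }
  p1 <- mk(rowSums(ex$founders$parents$NEM) / 2, 10)
  p2 <- mk(rowSums(ex$founders$parents$NEF1) / 2, 10)
  ce <- mk(af_a, 30)
  ne <- mk(af_b, 30)
  tab <- allele_count_table(
    ex$founders$sites,
    cbind(p1$ref, p2$ref, ce$ref, ne$ref),
    cbind(p1$alt, p2$alt, ce$alt, ne$alt),
    data.frame(id = c("P1", "P2", "CE", "NE"), role = "unknown"))
  hits <- candidate_mutation_filter(tab, cross_libraries(c("P1", "P2"),
                                                         "CE", "NE"))
  expect_lt(nrow(hits) / nrow(tab$sites), 0.01)
})

test_that("cross intersection keys on chrom/pos/alleles", {
  r1 <- data.frame(chrom = "chr1", pos = c(100, 200), ref = "A", alt = "T",
                   daf = c(0.6, 0.7))
  r2 <- data.frame(chrom = "chr1", pos = c(200, 300), ref = "A", alt = "T",
                   daf = c(0.65, 0.8))
  both <- intersect_crosses(r1, r2)
  expect_equal(both$pos, 200)
  expect_equal(both$daf_cross2, 0.65)
  expect_equal(nrow(intersect_crosses(r1, r1)), 2)
  disjoint <- data.frame(chrom = "chr2", pos = 100, ref = "A", alt = "T",
                         daf = 0.9)
  expect_equal(nrow(intersect_crosses(r1, disjoint)), 0)

  reg1 <- data.frame(chrom = "chr1", start = 1, end = 1000)
  reg2 <- data.frame(chrom = "chr1", start = 500, end = 1500)
  ov <- attr(intersect_crosses(r1, r2, reg1, reg2), "region_overlap")
  expect_equal(ov$overlap_bp, 501)
})

test_that("SV pattern filter applies the seven-library criterion", {
  base <- data.frame(sv_id = c("sv1", "sv2", "sv3", "sv4"),
                     P1 = c("het", "het", "het", "het"),
                     P2 = c("het", "het", "het", "het"),
                     P3 = c("het", "het", "het", "no_call"),
                     NE1 = c("het", "het", "het", "het"),
                     NE2 = c("het", "het", "het", "het"),
                     CE1 = c("het", "hom_alt", "hom_ref", "hom_alt"),
                     CE2 = c("het", "hom_alt", "hom_ref", "hom_alt"),
                     stringsAsFactors = FALSE)
  out <- sv_pattern_filter(base, parents = c("P1", "P2", "P3"),
                           unaffected_pools = c("NE1", "NE2"),
                           affected_pools = c("CE1", "CE2"),
                           keep_all = TRUE)
  expect_equal(out$pass, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(out$reason[1], "pattern_mismatch")
  expect_equal(out$reason[4], "insufficient_evidence")
  expect_error(sv_pattern_filter(base, parents = "absent",
                                 unaffected_pools = "NE1",
                                 affected_pools = "CE1"))
})
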