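test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(c(10, 20, 30, 40, 50), 5, 3)
  expect_equal(size_factors(m), rep(1, 3), ignore_attr = TRUE)

  m2 <- cbind(c(10, 20, 30, 40, 50), c(20, 40, 60, 80, 100))
  sf <- size_factors(m2)
  expect_equal(sf[2] / sf[1], 2)

  m3 <- matrix(c(4, 9), 1, 2)
  expect_equal(size_factors(m3), c(4 / 6, 9 / 6), ignore_attr = TRUE)

  m4 <- rbind(c(5, 0), c(0, 5))
  expect_error(size_factors(m4), "nonzero")
  expect_error(size_factors(matrix(-1, 2, 2)))
})

test_that("size factors agree with the DESeq reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(17)
  m <- matrix(rnbinom(600, mu = 200 * rep(runif(6, 0.5, 2), each = 100),
                      size = 10), 100, 6)
  # DESeq2 takes the median on the log scale; with an even number of
  # usable genes the two medians differ in the 5th decimal
  expect_equal(size_factors(m),
               DESeq2::estimateSizeFactorsForMatrix(m),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("BH adjustment matches the literal step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)))
  expect_error(bh_adjust(-0.1))

  set.seed(23)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  # monotone in input ranks
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_true(all(adj >= p))
})

test_that("hypergeometric ORA matches combinatorial enumeration", {
  uni <- paste0("g", 1:10)
  res <- ora_hypergeom(uni[1:4], list(s = uni[1:5]), uni)
  expect_equal(res$p, 5 / 210, tolerance = 1e-12)

  res0 <- ora_hypergeom(uni[6:7], list(s = uni[1:2]), uni)
  expect_gt(res0$p, 0.5)
  resall <- ora_hypergeom(uni, list(s = uni[1:5]), uni)
  expect_equal(resall$p, 1)
  expect_error(ora_hypergeom("g1", list(s = "g1"), character(0)))
  expect_error(ora_hypergeom("zz", list(s = uni[1:2]), uni))

  set.seed(29)
  for (i in 1:1000) {
    N <- sample(5:30, 1)
    uni <- paste0("g", seq_len(N))
    deg <- sample(uni, sample(1:N, 1))
    gs <- sample(uni, sample(1:N, 1))
    got <- ora_hypergeom(deg, list(s = gs), uni)
    want <- oracle_hyper_upper(got$k, got$K, got$n, got$N)
    expect_equal(got$p, want, tolerance = 1e-12)
  }
})

test_that("the NB Wald test behaves on degenerate and null inputs", {
  m <- matrix(rep(c(100, 200, 150), 6), 3, 6,
              dimnames = list(paste0("g", 1:3), NULL))
  groups <- rep(c("affected", "unaffected"), each = 3)
  d <- de_test(m, groups)
  expect_equal(d$log2fc, rep(0, 3))
  expect_equal(d$direction, rep("ns", 3))
  expect_error(de_test(m[, 1:3], rep(c("affected", "unaffected"), c(2, 1))))
  expect_error(de_test(m, rep("caseA", 6)))

  # all-zero genes flagged, not dropped
  m2 <- rbind(m, g4 = 0)
  d2 <- de_test(m2, groups)
  expect_equal(nrow(d2), 4)
  expect_true(is.na(d2$p[4]))
  expect_equal(attr(d2, "all_zero"), "g4")
  expect_true(all(d2$padj >= d2$p, na.rm = TRUE))
})

test_that("detection power increases with the true fold change", {
  set.seed(37)
  G <- 400
  n_de <- 50  # DE genes embedded in a mostly-null matrix
  power_at <- vapply(c(0.5, 1.5, 3), function(lfc) {
    hits <- 0
    for (r in 1:3) {
      mu0 <- c(rep(500, n_de), rlnorm(G - n_de, log(300), 1))
      mu1 <- mu0 * 2^c(rep(lfc, n_de), rep(0, G - n_de))
      counts <- cbind(matrix(rnbinom(G * 3, mu = rep(mu1, 3), size = 20), G, 3),
                      matrix(rnbinom(G * 3, mu = rep(mu0, 3), size = 20), G, 3))
      rownames(counts) <- paste0("g", 1:G)
      d <- de_test(counts, rep(c("affected", "unaffected"), each = 3))
      hits <- hits + mean(d$direction[1:n_de] == "up")
    }
    hits / 3
  }, 0)
  expect_true(all(diff(power_at) >= 0))
  expect_gte(power_at[3], 0.95)
})

test_that("candidate prioritization applies the three retention rules", {
  deg <- data.frame(gene = c("gA", "gB", "gC", "gD", "gE"),
                    base_mean = 100,
                    log2fc = c(-2.5, 1.6, -1.8, 2.2, 0.1),
                    p = 0.001, padj = 0.01,
                    direction = c("down", "up", "down", "up", "ns"))
  fm <- data.frame(
    gene = c("gA", "gB", "gC", "gC", "gE"),
    chrom = "chr1",
    pos = c(100, 200, 300, 310, 500),
    category = c("stopgain", "nonsynonymous", "nonsynonymous",
                 "frameshift_indel", "nonsynonymous"))
  refs <- data.frame(chrom = "chr1", pos = c(100, 200, 300, 310, 500),
                     r1 = c("hom_ref", "het", "hom_ref", "no_call", "het"),
                     r2 = c("hom_ref", "hom_ref", "hom_alt", "no_call", "het"),
                     r3 = c("no_call", "hom_ref", "hom_ref", "no_call", "het"))
  out <- prioritize_candidates(c("gA", "gB", "gC", "gD", "gE"),
                               deg, fm, refs)
  # gB: het reference; gC: hom-mutant reference; gD: no functional
  # mutation; gE: not differentially expressed
  expect_equal(out$gene, "gA")
  excl <- attr(out, "excluded")
  expect_equal(excl[["gB"]], "mutant_allele_in_unaffected_reference")
  expect_equal(excl[["gC"]], "mutant_allele_in_unaffected_reference")
  expect_equal(excl[["gD"]], "no_functional_mutation")
  expect_equal(excl[["gE"]], "not_differentially_expressed")

  # no-coverage reference genotypes are non-informative
  refs2 <- refs
  refs2[refs2$pos == 200, c("r1", "r2", "r3")] <- "no_call"
  out2 <- prioritize_candidates(c("gA", "gB"), deg, fm, refs2)
  expect_equal(out2$gene, c("gA", "gB"))  # stopgain ranks first

  # deterministic and order-independent
  out3 <- prioritize_candidates(rev(c("gA", "gB")), deg,
                                fm[rev(seq_len(nrow(fm))), ], refs2)
  expect_equal(out3$gene, out2$gene)
})
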