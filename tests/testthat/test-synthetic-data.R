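# smaller configuration for fast generator tests
small_config <- function(seed = 1, n_snps = 500, ...) {
  sim_config(seed = seed, chrom_length_bp = 5e6, n_snps = n_snps,
             causal_pos = 2.5e6, n_offspring_per_cross = 300,
             pool_sizes = c(affected_1 = 30, affected_2 = 30,
                            unaffected = 40),
             ibd_flank_bp = 1e6, ...)
}

test_that("configuration invariants are enforced", {
  expect_error(sim_config(causal_pos = 0), "causal_pos")
  expect_error(sim_config(n_snps = 0), "SNP")
  expect_error(sim_config(depth = c(pool = 0, parent = 10,
                                    outside_individual = 4)), "depth")
  expect_error(sim_config(pool_sizes = c(affected_1 = 0, affected_2 = 5,
                                         unaffected = 5)), "pool")
  expect_error(sim_config(farms_sharing_ibd = 9), "farms")
  expect_error(sim_config(expression = list(dispersion = 0)), "dispersion")
  expect_error(sim_config(seq_error = 0.7), "seq_error")
})

test_that("founders are heterozygous at the causal site and deterministic", {
  cfg <- small_config()
  f1 <- simulate_founders(cfg)
  ci <- which(f1$sites$is_causal)
  expect_length(ci, 1)
  for (p in f1$parents) expect_equal(sum(p[ci, ]), 1L)
  f2 <- simulate_founders(small_config())
  expect_identical(f1$sites, f2$sites)
  expect_identical(f1$parents, f2$parents)
  # one-site genome: just the causal site
  f3 <- simulate_founders(sim_config(n_snps = 1))
  expect_equal(nrow(f3$sites), 1)
  expect_true(f3$sites$is_causal)
})

test_that("cross phenotypes follow the recessive rule exactly", {
  cfg <- small_config()
  f <- simulate_founders(cfg)
  off <- simulate_cross(f, cfg, n = 10000)
  ci <- which(f$sites$is_causal)
  # definitional: affected offspring are exactly the homozygous mutants
  expect_identical(off$phenotype == "affected", off$dosage[ci, ] == 2L)
  frac <- mean(off$phenotype == "affected")
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))
})

test_that("the dominant-inhibitor hypothesis flips the affected rule", {
  cfg <- small_config(hypothesis = "dominant_inhibitor")
  f <- simulate_founders(cfg)
  off <- simulate_cross(f, cfg, n = 4000)
  ci <- which(f$sites$is_causal)
  expect_identical(off$phenotype == "affected", off$dosage[ci, ] == 0L)
  expect_lt(abs(mean(off$phenotype == "affected") - 0.25),
            3 * sqrt(0.25 * 0.75 / 4000))
})

test_that("zero recombination transmits unbroken parental haplotypes", {
  cfg <- small_config(recomb_rate = 0)
  f <- simulate_founders(cfg)
  off <- simulate_cross(f, cfg, n = 50)
  pa <- f$parents$NEM
  for (j in 1:50) {
    g <- off$hap_a[, j]
    expect_true(identical(g, unname(pa[, 1])) ||
                  identical(g, unname(pa[, 2])))
  }
})

test_that("a non-heterozygous parent is rejected", {
  cfg <- small_config()
  f <- simulate_founders(cfg)
  ci <- which(f$sites$is_causal)
  f$parents$NEF1[ci, ] <- c(1L, 1L)
  expect_error(simulate_cross(f, cfg, c("NEM", "NEF1")),
               "not heterozygous")
})

test_that("pool sequencing reflects member dosages", {
  cfg <- small_config(seq_error = 0)
  f <- simulate_founders(cfg)
  off <- simulate_cross(f, cfg)
  ci <- which(f$sites$is_causal)
  pools <- simulate_pools(off, f, cfg, affected_size = 30,
                          unaffected_size = 40)
  expect_equal(library_af(pools, "Pool_CE")[ci], 1)  # fixation
  m <- attr(pools, "members")
  true_af <- rowMeans(off$dosage[, m$unaffected, drop = FALSE]) / 2
  obs <- library_af(pools, "Pool_NE")
  expect_lt(max(abs(obs - true_af), na.rm = TRUE), 0.5)
  expect_error(simulate_pools(off, f, cfg, affected_size = 0),
               "empty pool")
  expect_error(simulate_pools(off, f, cfg, affected_size = 1e6))
})

test_that("pool frequencies converge to dosage means at extreme depth", {
  cfg <- small_config(seq_error = 0,
                      depth = c(pool = 10000, parent = 10,
                                outside_individual = 4))
  f <- simulate_founders(cfg)
  off <- simulate_cross(f, cfg)
  pools <- simulate_pools(off, f, cfg, affected_size = 30,
                          unaffected_size = 40)
  m <- attr(pools, "members")
  for (lib in c("Pool_CE", "Pool_NE")) {
    who <- if (lib == "Pool_CE") m$affected else m$unaffected
    true_af <- rowMeans(off$dosage[, who, drop = FALSE]) / 2
    dev <- abs(library_af(pools, lib) - true_af)
    expect_lt(mean(dev), 0.01)
    expect_lt(max(dev), 0.05)
  }
})

test_that("pool allele frequencies at the causal site are calibrated", {
  # replicated pooling of one cross: affected pool ~ 1, unaffected ~ 1/3
  cfg <- small_config(n_snps = 50)
  f <- simulate_founders(cfg)
  off <- simulate_cross(f, cfg)
  ci <- which(f$sites$is_causal)
  af_ce <- af_ne <- numeric(100)
  for (r in 1:100) {
    pools <- simulate_pools(off, f, cfg, affected_size = 30,
                            unaffected_size = 40, stage = paste0("rep", r))
    af_ce[r] <- library_af(pools, "Pool_CE")[ci]
    af_ne[r] <- library_af(pools, "Pool_NE")[ci]
  }
  expect_lt(abs(mean(af_ce) - 1), 0.02)
  expect_lt(abs(mean(af_ne) - 1 / 3), 0.05)
})

test_that("farm individuals carry or lack the causal haplotype as configured", {
  cfg <- small_config()
  f <- simulate_founders(cfg)
  farms <- simulate_farms(f, cfg)
  ci <- which(f$sites$is_causal)
  expect_equal(unname(farms$dosage[ci, farms$sharing]),
               rep(2L, sum(farms$sharing)))
  expect_equal(unname(farms$dosage[ci, !farms$sharing]),
               rep(0L, sum(!farms$sharing)))
  # non-sharing farms are fixed for their own causal allele elsewhere
  ci2 <- farms$second_causal_index
  expect_true(all(farms$dosage[ci2, !farms$sharing] == 2L))
  # within the shared flank, sharing individuals equal the causal haplotype
  flank <- f$sites$chrom == cfg$causal_chrom &
    abs(f$sites$pos - cfg$causal_pos) <= cfg$ibd_flank_bp
  k <- which(farms$sharing)[1]
  expect_equal(unname(farms$dosage[flank, k]),
               2L * f$causal_hap[flank])
})

test_that("zero divergence and sharing gives near-zero causal-region distance", {
  cfg <- small_config(background_divergence = 0)
  ex <- simulate_experiment(cfg)
  region <- data.frame(chrom = "chr1", start = cfg$causal_pos - 5e5,
                       end = cfg$causal_pos + 5e5)
  shar <- ex$farms$ids[ex$farms$sharing][1]
  d <- region_distance(ex$table, "Pool_CE1", shar, region, min_sites = 3)
  expect_lt(as.numeric(d), 0.1)
})

test_that("diverged non-sharing farms sit far from the affected pools", {
  ds <- numeric(0)
  for (s in 1:5) {
    cfg <- small_config(seed = s)
    ex <- simulate_experiment(cfg)
    region <- data.frame(chrom = "chr1", start = cfg$causal_pos - 5e5,
                         end = cfg$causal_pos + 5e5)
    non <- ex$farms$ids[!ex$farms$sharing][1:3]
    ds <- c(ds, vapply(non, function(id) {
      as.numeric(region_distance(ex$table, "Pool_CE1", id, region,
                                 min_sites = 3))
    }, 0))
  }
  expect_gt(mean(ds), 0.1)
})

test_that("expression simulation is deterministic with NB structure", {
  cfg <- small_config()
  de <- data.frame(gene = c("g1", "g2"), log2fc = c(2, -2))
  e1 <- simulate_expression(cfg, de, gene_ids = sprintf("g%d", 1:300))
  e2 <- simulate_expression(cfg, de, gene_ids = sprintf("g%d", 1:300))
  expect_identical(e1$counts, e2$counts)
  expect_equal(dim(e1$counts), c(300L, 6L))
  expect_error(simulate_expression(
    sim_config(expression = list(dispersion = -1)), de))
  # null genes with large means rarely show |log2FC| > 1
  cfg2 <- small_config(seed = 3)
  e3 <- simulate_expression(cfg2, data.frame(gene = character(),
                                             log2fc = numeric(),
                                             base_mean = numeric()),
                            gene_ids = sprintf("n%03d", 1:200))
  sf <- size_factors(e3$counts)
  norm <- sweep(e3$counts, 2, sf, "/")
  lfc <- log2((rowMeans(norm[, 1:3]) + 0.5) / (rowMeans(norm[, 4:6]) + 0.5))
  big <- e3$truth$base_mean > 100
  expect_gte(mean(abs(lfc[big]) < 1), 0.95)
})

test_that("an all-zero count matrix is flagged downstream, not dropped", {
  zero <- matrix(0L, 10, 6,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  expect_error(de_test(zero, rep(c("affected", "unaffected"), each = 3)),
               "zero")
})

test_that("the assembled experiment is seed-deterministic", {
  e1 <- simulate_experiment(small_config(seed = 7))
  e2 <- simulate_experiment(small_config(seed = 7))
  expect_identical(e1$table$ref, e2$table$ref)
  expect_identical(e1$table$alt, e2$table$alt)
  expect_identical(e1$expression$counts, e2$expression$counts)
  expect_identical(e1$reference_genotypes, e2$reference_genotypes)
  e3 <- simulate_experiment(small_config(seed = 8))
  expect_false(identical(e1$table$alt, e3$table$alt))
})

test_that("the causal gene model carries the causal SNP as a stopgain", {
  ex <- simulate_experiment(small_config(seed = 2))
  ci <- which(ex$founders$sites$is_causal)
  v <- ex$founders$sites[ci, ]
  g <- ex$genes$geneC
  ann <- annotate_variant(g, v$chrom, v$pos, v$ref, v$alt)
  expect_equal(ann$category, "stopgain")
  expect_equal(truncated_protein_length(g, v$chrom, v$pos, v$ref, v$alt),
               10L)
  # references are never carriers at the causal site
  refs <- ex$reference_genotypes[ci, c("ref1", "ref2", "ref3")]
  expect_true(all(unlist(refs) %in% c("hom_ref", "no_call")))
})
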