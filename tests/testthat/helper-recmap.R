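# Shared fixtures and independent brute-force oracles.

# small allele count table built directly from frequencies at high depth,
# so genotype classes are deterministic
make_table <- function(af_by_lib, pos = NULL, depth = 1000,
                       roles = NULL, chrom = "chr1") {
  af <- as.matrix(af_by_lib)
  S <- nrow(af)
  k <- ncol(af)
  if (is.null(pos)) pos <- seq_len(S) * 100
  ids <- colnames(af) %||% paste0("lib", seq_len(k))
  alt <- round(af * depth)
  ref <- depth - alt
  libs <- data.frame(id = ids,
                     role = roles %||% rep("unknown", k),
                     cross = NA_integer_, pool_size = 1L,
                     stringsAsFactors = FALSE)
  allele_count_table(
    data.frame(chrom = rep(chrom, S), pos = pos,
               ref = rep("A", S), alt = rep("T", S),
               stringsAsFactors = FALSE),
    matrix(as.integer(ref), S, k), matrix(as.integer(alt), S, k), libs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# toy plus-strand gene: 31 codons incl. stop, single CDS exon
toy_gene <- function(id = "toy", cds_start = 1001, strand = "+",
                     codon11 = "TGG") {
  codons <- c("ATG", rep("GGC", 9), codon11, rep("CTA", 19), "TAA")
  seq <- paste(codons, collapse = "")
  cds_end <- cds_start + nchar(seq) - 1
  gene_model(id, "chr1", strand,
             exons = data.frame(start = cds_start - 100,
                                end = cds_end + 100),
             cds = data.frame(start = cds_start, end = cds_end),
             cds_seq = seq)
}

# --- independent oracles -------------------------------------------------

# closed-form per-site F_ST: (p1-p2)^2/2 over total heterozygosity
oracle_fst <- function(p1, p2) {
  pbar <- (p1 + p2) / 2
  den <- 2 * pbar * (1 - pbar)
  if (den <= 0) return(0)
  max(min(((p1 - p2)^2 / 2) / den, 1), 0)
}

# Pearson goodness-of-fit chi-square from first principles
oracle_chi2 <- function(obs, weights) {
  e <- sum(obs) * weights / sum(weights)
  stat <- sum((obs - e)^2 / e)
  list(chi2 = stat, p = stats::pchisq(stat, df = length(obs) - 1,
                                      lower.tail = FALSE))
}

# literal BH step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# hypergeometric upper tail by direct combinatorial enumeration
oracle_hyper_upper <- function(k, K, n, N) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# brute-force window scan (explicit loop; chrom_length must be
# step-aligned so that all windows are full-width)
oracle_window_scan <- function(table, a, b, window, step, min_depth,
                               chrom_length, min_snps = 1) {
  stopifnot((chrom_length - window) %% step == 0)
  p1 <- library_af(table, a, min_depth)
  p2 <- library_af(table, b, min_depth)
  rows <- list()
  for (start in seq(1, chrom_length - window + 1, by = step)) {
    end <- start + window - 1
    in_w <- table$sites$pos >= start & table$sites$pos <= end &
      !is.na(p1) & !is.na(p2)
    n <- sum(in_w)
    f <- if (n >= min_snps && n > 0) {
      mean(mapply(oracle_fst, p1[in_w], p2[in_w]))
    } else NA_real_
    rows[[length(rows) + 1]] <- data.frame(start = start, end = end,
                                           n_snps = n, fst = f)
  }
  do.call(rbind, rows)
}

# cached simulated experiments for the heavier property suites
.exp_cache <- new.env(parent = emptyenv())
cached_experiment <- function(seed) {
  key <- paste0("s", seed)
  if (is.null(.exp_cache[[key]])) {
    .exp_cache[[key]] <- simulate_experiment(sim_config(seed = seed))
  }
  .exp_cache[[key]]
}
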