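#' Median-of-ratios size factors
#'
#' Per-sample normalization factor: the median, over genes with nonzero
#' counts in every sample, of the sample count divided by the gene's
#' geometric mean across samples.
#'
#' @param counts genes x samples non-negative integer matrix.
#' @return Positive numeric vector of length `ncol(counts)`.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  all_nonzero <- rowSums(counts == 0) == 0
  if (!any(all_nonzero)) {
    stop("no gene has nonzero counts in all samples; ",
         "size factors are undefined (filter or pool samples first)")
  }
  lg <- log(counts[all_nonzero, , drop = FALSE])
  geo <- exp(rowMeans(lg))
  apply(counts[all_nonzero, , drop = FALSE], 2,
        function(col) stats::median(col / geo))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (validated wrapper over the standard
#' implementation): sort ascending, multiply `p(i)` by `n/i`, take the
#' cumulative minimum from the largest rank down, cap at 1, restore input
#' order.
#'
#' @param pvalues numeric vector in `[0, 1]` (NA allowed, preserved).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0) || any(pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Negative-binomial Wald test for differential expression
#'
#' A compact NB test for small designs: median-of-ratios normalization,
#' method-of-moments dispersion from the pooled within-group variance of
#' normalized counts, log2 fold change (affected vs unaffected) from
#' normalized group means with a pseudocount of 0.5, and a Wald statistic
#' on the log2 scale referred to a t distribution with `n1 + n2 - 2`
#' degrees of freedom (small-sample conservatism). P-values are
#' BH-adjusted; genes are flagged `up`/`down` only when
#' `|log2FC| > lfc_min` and `padj < alpha`, else `ns`.
#'
#' With a handful of samples the raw per-gene moment estimate of
#' dispersion is extremely noisy, so by default it is replaced by a
#' parametric mean-dispersion trend `a0 + a1/mu` fitted across genes
#' (information sharing in the spirit of DESeq's fitted dispersions);
#' `dispersion = "per_gene"` keeps the raw estimates.
#'
#' @param counts genes x samples non-negative integer matrix with rownames.
#' @param groups character/factor of length `ncol(counts)` with levels
#'   `affected` and `unaffected` (at least 2 samples each).
#' @param lfc_min,alpha DEG thresholds (defaults 1 and 0.05).
#' @param dispersion `"trend"` (default) or `"per_gene"`.
#' @return data.frame of class `deg_table`: `gene`, `base_mean`,
#'   `log2fc`, `p`, `padj`, `direction`. All-zero genes are kept with NA
#'   statistics and flagged in attribute `"all_zero"` rather than dropped.
#' @export
de_test <- function(counts, groups, lfc_min = 1, alpha = 0.05,
                    dispersion = c("trend", "per_gene")) {
  dispersion <- match.arg(dispersion)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  }
  groups <- as.character(groups)
  if (!all(groups %in% c("affected", "unaffected"))) {
    stop("groups must be 'affected' or 'unaffected'")
  }
  n1 <- sum(groups == "affected")
  n0 <- sum(groups == "unaffected")
  if (n1 < 2 || n0 < 2) stop("need at least 2 samples per group")
  if (all(counts == 0)) stop("all counts are zero")

  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  a <- norm[, groups == "affected", drop = FALSE]
  u <- norm[, groups == "unaffected", drop = FALSE]
  m1 <- rowMeans(a)
  m0 <- rowMeans(u)
  base_mean <- rowMeans(norm)

  # pooled within-group variance; MoM dispersion alpha = (var - mu)/mu^2
  v_within <- (rowSums((a - m1)^2) + rowSums((u - m0)^2)) / (n1 + n0 - 2)
  mu_bar <- (m1 * n1 + m0 * n0) / (n1 + n0)
  disp <- pmax((v_within - mu_bar) / pmax(mu_bar, 1e-8)^2, 1e-8)
  if (dispersion == "trend") {
    use <- mu_bar > 0 & is.finite(disp)
    if (sum(use) >= 10) {
      fit <- stats::lm(disp[use] ~ I(1 / mu_bar[use]))
      fitted <- pmax(stats::coef(fit)[1] + stats::coef(fit)[2] / mu_bar,
                     1e-8)
      disp <- ifelse(mu_bar > 0, fitted, disp)
    }
  }

  log2fc <- log2((m1 + 0.5) / (m0 + 0.5))
  # delta method on log2 of a mean of NB draws: var(mean) = (mu + a mu^2)/n
  v1 <- (m1 + disp * m1^2) / n1
  v0 <- (m0 + disp * m0^2) / n0
  se <- sqrt(v1 / pmax(m1 + 0.5, 0.5)^2 + v0 / pmax(m0 + 0.5, 0.5)^2) / log(2)
  tstat <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * stats::pt(-abs(tstat), df = n1 + n0 - 2)

  all_zero <- rowSums(counts) == 0
  p[all_zero] <- NA_real_
  log2fc[all_zero] <- NA_real_
  padj <- bh_adjust(p)
  direction <- rep("ns", nrow(counts))
  sig <- !is.na(padj) & padj < alpha & abs(log2fc) > lfc_min
  direction[sig & log2fc > 0] <- "up"
  direction[sig & log2fc < 0] <- "down"

  out <- data.frame(gene = rownames(counts), base_mean = base_mean,
                    log2fc = log2fc, p = p, padj = padj,
                    direction = direction, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "all_zero") <- rownames(counts)[all_zero]
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Hypergeometric over-representation analysis
#'
#' One-sided upper-tail enrichment of a DEG set in user-supplied gene
#' sets: `P(X >= k)` with `k` the overlap, drawing `n = |deg|` from a
#' universe of `N` genes containing `K = |set|` members; BH-adjusted
#' across sets.
#'
#' @param deg_set character vector of selected (e.g. differentially
#'   expressed) genes, a subset of `universe`.
#' @param gene_sets named list of gene-id vectors (each a subset of
#'   `universe`).
#' @param universe character vector of all testable genes.
#' @return data.frame: `set`, `k`, `K`, `n`, `N`, `p`, `padj`.
#' @export
ora_hypergeom <- function(deg_set, gene_sets, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  deg_set <- unique(deg_set)
  if (!all(deg_set %in% universe)) stop("deg_set must be within the universe")
  if (!is.list(gene_sets)) gene_sets <- list(set = gene_sets)
  N <- length(universe)
  n <- length(deg_set)
  res <- lapply(names(gene_sets) %||% seq_along(gene_sets), function(nm) {
    gs <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(gs)
    k <- length(intersect(deg_set, gs))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- bh_adjust(out$p)
  out
}

#' Prioritize candidate genes
#'
#' Final funnel stage: a target-region gene is retained iff (a) it is
#' differentially expressed, (b) it carries at least one coding/functional
#' candidate mutation, and (c) no independent unaffected reference sample
#' is heterozygous or homozygous-mutant at any of its informative
#' functional mutations (a true-breeding unaffected population should
#' carry no causal allele; `no_call` reference genotypes are
#' non-informative and never exclude a gene). Retained genes are ranked by
#' mutation severity (truncating before other coding) then `|log2fc|`.
#'
#' @param target_genes character vector of genes in the target regions.
#' @param deg_table a [de_test()] result.
#' @param functional_mutations data.frame with columns `gene`, `chrom`,
#'   `pos`, `category` (effect categories; only coding categories count as
#'   functional).
#' @param reference_genotypes data.frame with columns `chrom`, `pos`, and
#'   one genotype-class column per reference sample (or a `genotype`
#'   column), classes in `hom_ref`/`het`/`hom_alt`/`no_call`.
#' @return data.frame of retained genes, ranked: `gene`, `severity`,
#'   `log2fc`, `n_functional`, plus attribute `"excluded"` with per-gene
#'   exclusion reasons.
#' @export
prioritize_candidates <- function(target_genes, deg_table,
                                  functional_mutations,
                                  reference_genotypes = NULL) {
  coding <- c("stopgain", "stoploss", "frameshift_indel",
              "nonframeshift_indel", "nonsynonymous")
  target_genes <- sort(unique(target_genes))
  deg <- deg_table[deg_table$direction != "ns", , drop = FALSE]
  fm <- functional_mutations[functional_mutations$category %in% coding, ,
                             drop = FALSE]

  excluded <- character(0)
  rows <- list()
  for (g in target_genes) {
    if (!(g %in% deg$gene)) {
      excluded[g] <- "not_differentially_expressed"
      next
    }
    muts <- fm[fm$gene == g, , drop = FALSE]
    if (!nrow(muts)) {
      excluded[g] <- "no_functional_mutation"
      next
    }
    if (!is.null(reference_genotypes) && nrow(reference_genotypes)) {
      gt_cols <- setdiff(names(reference_genotypes), c("chrom", "pos", "gene"))
      key <- paste(reference_genotypes$chrom, reference_genotypes$pos)
      hit <- match(paste(muts$chrom, muts$pos), key)
      ref_gt <- as.matrix(reference_genotypes[hit[!is.na(hit)], gt_cols,
                                              drop = FALSE])
      if (length(ref_gt) && any(ref_gt %in% c("het", "hom_alt"))) {
        excluded[g] <- "mutant_allele_in_unaffected_reference"
        next
      }
    }
    sev <- min(effect_severity(muts$category))
    lfc <- deg$log2fc[match(g, deg$gene)]
    rows[[g]] <- data.frame(gene = g, severity = sev, log2fc = lfc,
                            n_functional = nrow(muts),
                            stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), severity = integer(),
               log2fc = numeric(), n_functional = integer())
  out <- out[order(out$severity, -abs(out$log2fc), out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
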