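#' Simulation configuration
#'
#' Parameters of the synthetic mapping experiment: two het x het F2
#' crosses from three shared-origin parents segregating one causal SNP on
#' one chromosome, phenotype-defined offspring pools, low-coverage outside
#' individuals from several farms that do or do not share the causal
#' haplotype, toy gene models and a 3 vs 3 expression matrix. Defaults
#' mirror the emulated study design: affected pools of 59 and 64 fish,
#' unaffected pools of 80, pool coverage 30x, parents 10x, outside
#' individuals 4x, 5 farms of 10 individuals with 2 farms sharing the
#' causal haplotype.
#'
#' @param seed integer; fully determines every simulated output.
#' @param n_chrom number of chromosomes.
#' @param chrom_length_bp chromosome length (bp).
#' @param n_snps SNP sites per chromosome.
#' @param causal_chrom,causal_pos location of the causal SNP (1-based).
#' @param hypothesis `"recessive_causal"` (affected = homozygous
#'   alternate) or `"dominant_inhibitor"` (affected = carries no copy of
#'   the segregating inhibitor allele).
#' @param n_offspring_per_cross F2 family size per cross.
#' @param pool_sizes named vector: `affected_1`, `affected_2`,
#'   `unaffected` pool membership counts.
#' @param depth named vector of mean sequencing coverage per library kind:
#'   `pool`, `parent`, `outside_individual`.
#' @param n_farms,n_per_farm outside-individual sampling design.
#' @param farms_sharing_ibd indices of farms whose individuals carry the
#'   founder causal haplotype.
#' @param recomb_rate expected crossovers per chromosome per meiosis.
#' @param background_divergence Balding-Nichols F between the founder
#'   population and each farm / reference population.
#' @param seq_error per-read allele flip probability.
#' @param ibd_flank_bp half-width of the interval over which sharing-farm
#'   individuals carry the founder causal haplotype.
#' @param second_causal_pos position of the independent causal allele
#'   carried by non-sharing farms (`NULL`: auto-placed at the SNP nearest
#'   `causal_pos + chrom_length_bp/4`).
#' @param expression list of expression-simulation parameters:
#'   `n_background_genes`, `n_per_group`, `dispersion`, `mean_log`,
#'   `sd_log`, `causal_log2fc`, `decoy_log2fc`, `frac_background_de`.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 1L,
                       chrom_length_bp = 25e6,
                       n_snps = 5000L,
                       causal_chrom = "chr1",
                       causal_pos = 12.5e6,
                       hypothesis = c("recessive_causal", "dominant_inhibitor"),
                       n_offspring_per_cross = 629L,
                       pool_sizes = c(affected_1 = 59L, affected_2 = 64L,
                                      unaffected = 80L),
                       depth = c(pool = 30, parent = 10,
                                 outside_individual = 4),
                       n_farms = 5L,
                       n_per_farm = 10L,
                       farms_sharing_ibd = c(1L, 2L),
                       recomb_rate = 1,
                       background_divergence = 0.3,
                       seq_error = 0.002,
                       ibd_flank_bp = 3e6,
                       second_causal_pos = NULL,
                       expression = list()) {
  hypothesis <- match.arg(hypothesis)
  expr_defaults <- list(n_background_genes = 500L, n_per_group = 3L,
                        dispersion = 0.05, mean_log = log(300), sd_log = 1,
                        causal_log2fc = -2, decoy_log2fc = 1.5,
                        frac_background_de = 0.2)
  expression <- utils::modifyList(expr_defaults, expression)
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              chrom_length_bp = chrom_length_bp, n_snps = as.integer(n_snps),
              causal_chrom = causal_chrom, causal_pos = causal_pos,
              hypothesis = hypothesis,
              n_offspring_per_cross = as.integer(n_offspring_per_cross),
              pool_sizes = pool_sizes, depth = depth,
              n_farms = as.integer(n_farms),
              n_per_farm = as.integer(n_per_farm),
              farms_sharing_ibd = as.integer(farms_sharing_ibd),
              recomb_rate = recomb_rate,
              background_divergence = background_divergence,
              seq_error = seq_error, ibd_flank_bp = ibd_flank_bp,
              second_causal_pos = second_causal_pos,
              expression = expression)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  if (!cfg$causal_chrom %in% chroms) {
    stop("causal_chrom must be one of ", paste(chroms, collapse = ", "))
  }
  if (cfg$causal_pos < 1 || cfg$causal_pos > cfg$chrom_length_bp) {
    stop("causal_pos must lie within [1, chrom_length_bp]")
  }
  if (cfg$n_snps < 1) stop("need at least one SNP on the causal chromosome")
  if (any(cfg$depth <= 0)) stop("all depths must be positive")
  if (any(cfg$pool_sizes < 1)) stop("pool sizes must be >= 1")
  if (!all(c("affected_1", "affected_2", "unaffected") %in%
           names(cfg$pool_sizes))) {
    stop("pool_sizes must name affected_1, affected_2, unaffected")
  }
  if (!all(c("pool", "parent", "outside_individual") %in% names(cfg$depth))) {
    stop("depth must name pool, parent, outside_individual")
  }
  if (length(cfg$farms_sharing_ibd) &&
      !all(cfg$farms_sharing_ibd %in% seq_len(cfg$n_farms))) {
    stop("farms_sharing_ibd must be a subset of 1..n_farms")
  }
  if (cfg$recomb_rate < 0) stop("recomb_rate must be non-negative")
  if (cfg$background_divergence < 0 || cfg$background_divergence >= 1) {
    stop("background_divergence must lie in [0, 1)")
  }
  if (cfg$seq_error < 0 || cfg$seq_error >= 0.5) {
    stop("seq_error must lie in [0, 0.5)")
  }
  if (cfg$expression$dispersion <= 0) stop("dispersion must be positive")
  invisible(cfg)
}
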