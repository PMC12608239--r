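#' Simulate founder haplotypes and the site table
#'
#' Builds the biallelic SNP map (positions uniform per chromosome, the
#' causal position always a site), founder-population allele frequencies
#' (Uniform(0.05, 0.95) at background sites, 0 for the causal allele in
#' the base population), one shared causal haplotype, and three parents
#' (`NEM`, `NEF1`, `NEF2`) that each carry the causal haplotype over one
#' chromosome copy — so all three are heterozygous at the causal site, as
#' F1 siblings from affected x affected grandparents would be.
#'
#' @param config a [sim_config()].
#' @return A `founders` list: `sites` (chrom, pos, ref, alt, founder_af,
#'   is_causal), `causal_hap` (0/1 over sites), `parents` (list of
#'   sites x 2 haplotype matrices), `config`.
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stage_seed(config$seed, "founders", {
    chroms <- paste0("chr", seq_len(config$n_chrom))
    site_list <- lapply(chroms, function(ch) {
      pos <- sort(sample.int(config$chrom_length_bp, config$n_snps))
      if (ch == config$causal_chrom && !(config$causal_pos %in% pos)) {
        pos[which.min(abs(pos - config$causal_pos))] <- config$causal_pos
        pos <- sort(pos)
      }
      data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
    })
    sites <- do.call(rbind, site_list)
    S <- nrow(sites)
    bases <- c("A", "C", "G", "T")
    sites$ref <- sample(bases, S, replace = TRUE)
    sites$alt <- vapply(sites$ref,
                        function(r) sample(setdiff(bases, r), 1), "")
    sites$founder_af <- stats::runif(S, 0.05, 0.95)
    sites$is_causal <- sites$chrom == config$causal_chrom &
      sites$pos == config$causal_pos
    if (sum(sites$is_causal) != 1) {
      stop("no SNP available on the causal chromosome")
    }
    # causal change fixed to G>A so a TGG->TGA stopgain codon can be framed
    ci <- which(sites$is_causal)
    sites$ref[ci] <- "G"
    sites$alt[ci] <- "A"
    sites$founder_af[ci] <- 0

    draw_hap <- function() {
      h <- as.integer(stats::rbinom(S, 1, sites$founder_af))
      h[ci] <- 0L
      h
    }
    causal_hap <- draw_hap()
    causal_hap[ci] <- 1L
    parents <- lapply(c(NEM = 1, NEF1 = 2, NEF2 = 3), function(i) {
      cbind(hap1 = causal_hap, hap2 = draw_hap())
    })
    structure(list(sites = sites, causal_hap = causal_hap,
                   parents = parents, config = config),
              class = "founders")
  })
}

# gametes from one parent: crossover count ~ Poisson(rate) per chromosome,
# positions uniform, random starting haplotype
make_gametes <- function(hap, sites, n, rate, chrom_length) {
  S <- nrow(hap)
  out <- matrix(0L, S, n)
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    pos <- sites$pos[idx]
    k <- stats::rpois(n, rate)
    s <- sample.int(2, n, replace = TRUE)
    for (j in seq_len(n)) {
      if (k[j] == 0) {
        out[idx, j] <- hap[idx, s[j]]
      } else {
        xo <- sort(stats::runif(k[j], 0, chrom_length))
        pick <- (s[j] - 1 + findInterval(pos, xo)) %% 2 + 1
        out[idx, j] <- hap[cbind(idx, pick)]
      }
    }
  }
  out
}

#' Simulate one F2 cross
#'
#' Each offspring receives one recombinant gamete from each parent;
#' phenotype follows the configured hypothesis (recessive causal: affected
#' iff homozygous alternate at the causal site; dominant inhibitor:
#' affected iff carrying no copy of the segregating inhibitor allele).
#'
#' @param founders a [simulate_founders()] result.
#' @param config a [sim_config()].
#' @param parents length-2 character, the parent ids to cross.
#' @param n number of offspring (default `config$n_offspring_per_cross`).
#' @param stage seed substream label (distinct per cross).
#' @return An `offspring` list: `hap_a`, `hap_b` (sites x n gamete
#'   matrices), `dosage`, `phenotype` (`affected`/`unaffected`), `parents`.
#' @export
simulate_cross <- function(founders, config, parents = c("NEM", "NEF1"),
                           n = config$n_offspring_per_cross,
                           stage = paste(parents, collapse = "x")) {
  stopifnot(inherits(founders, "founders"), length(parents) == 2)
  ci <- which(founders$sites$is_causal)
  for (p in parents) {
    h <- founders$parents[[p]]
    if (is.null(h)) stop("unknown parent: ", p)
    if (sum(h[ci, ]) != 1L) {
      stop("parent ", p, " is not heterozygous at the causal site")
    }
  }
  with_stage_seed(config$seed, paste0("cross_", stage), {
    hap_a <- make_gametes(founders$parents[[parents[1]]], founders$sites, n,
                          config$recomb_rate, config$chrom_length_bp)
    hap_b <- make_gametes(founders$parents[[parents[2]]], founders$sites, n,
                          config$recomb_rate, config$chrom_length_bp)
    dosage <- hap_a + hap_b
    hyp <- cross_hypothesis(config$hypothesis)
    affected <- hyp$affected_rule(dosage[ci, ])
    structure(list(hap_a = hap_a, hap_b = hap_b, dosage = dosage,
                   phenotype = ifelse(affected, "affected", "unaffected"),
                   parents = parents),
              class = "offspring")
  })
}

# Poisson depth + binomial read sampling around a per-site allele
# frequency, with a per-read error flip
sequence_counts <- function(af, mean_depth, seq_error) {
  S <- length(af)
  depth <- stats::rpois(S, mean_depth)
  f <- af * (1 - seq_error) + (1 - af) * seq_error
  alt <- stats::rbinom(S, depth, f)
  cbind(ref = depth - alt, alt = alt)
}

#' Simulate pooled sequencing for one cross
#'
#' Pool members are chosen by phenotype (the affected pool from affected
#' offspring, the unaffected pool as a uniform random subset of unaffected
#' offspring); the pool allele frequency at a site is the mean genotype
#' dosage / 2 over members (equimolar pooling), read depth is
#' Poisson(mean depth) and alternate reads Binomial(depth, frequency)
#' with the configured per-read error.
#'
#' @param offspring a [simulate_cross()] result.
#' @param founders the matching [simulate_founders()] result.
#' @param config a [sim_config()].
#' @param affected_size,unaffected_size pool membership counts.
#' @param ids length-2 character: affected and unaffected pool library ids.
#' @param stage seed substream label.
#' @return An [allele_count_table()] with the two pool libraries;
#'   attribute `"members"` records the sampled member indices.
#' @export
simulate_pools <- function(offspring, founders, config,
                           affected_size = config$pool_sizes[["affected_1"]],
                           unaffected_size = config$pool_sizes[["unaffected"]],
                           ids = c("Pool_CE", "Pool_NE"),
                           stage = ids[1]) {
  stopifnot(inherits(offspring, "offspring"))
  aff <- which(offspring$phenotype == "affected")
  una <- which(offspring$phenotype == "unaffected")
  if (affected_size < 1 || unaffected_size < 1) stop("empty pool")
  if (length(aff) < affected_size) {
    stop("only ", length(aff), " affected offspring for a pool of ",
         affected_size)
  }
  if (length(una) < unaffected_size) {
    stop("only ", length(una), " unaffected offspring for a pool of ",
         unaffected_size)
  }
  with_stage_seed(config$seed, paste0("pools_", stage), {
    m_aff <- aff[sample.int(length(aff), affected_size)]
    m_una <- una[sample.int(length(una), unaffected_size)]
    af_aff <- rowMeans(offspring$dosage[, m_aff, drop = FALSE]) / 2
    af_una <- rowMeans(offspring$dosage[, m_una, drop = FALSE]) / 2
    ca <- sequence_counts(af_aff, config$depth[["pool"]], config$seq_error)
    cu <- sequence_counts(af_una, config$depth[["pool"]], config$seq_error)
    libs <- data.frame(id = ids, role = c("affected_pool", "unaffected_pool"),
                       cross = NA_integer_,
                       pool_size = c(affected_size, unaffected_size),
                       stringsAsFactors = FALSE)
    tab <- allele_count_table(founders$sites,
                              cbind(ca[, "ref"], cu[, "ref"]),
                              cbind(ca[, "alt"], cu[, "alt"]), libs)
    attr(tab, "members") <- list(affected = m_aff, unaffected = m_una)
    tab
  })
}

#' Simulate outside individuals from several farms
#'
#' Individuals from sharing farms are homozygous for the founder causal
#' haplotype over `ibd_flank_bp` either side of the causal site, with
#' farm-drifted background elsewhere; non-sharing farms carry an
#' independent causal allele at a different position (allelic/locus
#' heterogeneity) and are homozygous reference at the primary causal site.
#' Farm allele frequencies drift from the founder frequencies by a
#' Balding-Nichols draw with F = `background_divergence`.
#'
#' @param founders a [simulate_founders()] result.
#' @param config a [sim_config()].
#' @return A `farms` list: `dosage` (sites x individuals), `ids`, `farm`
#'   (farm index per individual), `sharing` (logical per individual),
#'   `second_causal_index` (site index of the alternative causal allele).
#' @export
simulate_farms <- function(founders, config) {
  stopifnot(inherits(founders, "founders"))
  sites <- founders$sites
  S <- nrow(sites)
  ci <- which(sites$is_causal)
  with_stage_seed(config$seed, "farms", {
    # alternative causal site for non-sharing farms
    if (!is.null(config$second_causal_pos)) {
      target <- config$second_causal_pos
    } else {
      target <- (config$causal_pos + config$chrom_length_bp / 4 - 1) %%
        config$chrom_length_bp + 1
    }
    on_ch <- which(sites$chrom == config$causal_chrom)
    ci2 <- on_ch[which.min(abs(sites$pos[on_ch] - target))]

    in_flank <- sites$chrom == config$causal_chrom &
      abs(sites$pos - config$causal_pos) <= config$ibd_flank_bp

    F <- config$background_divergence
    drift <- function(p) {
      if (F == 0) return(p)
      a <- p * (1 - F) / F
      b <- (1 - p) * (1 - F) / F
      q <- stats::rbeta(length(p), pmax(a, 1e-6), pmax(b, 1e-6))
      q
    }
    n_ind <- config$n_farms * config$n_per_farm
    dosage <- matrix(0L, S, n_ind)
    farm <- rep(seq_len(config$n_farms), each = config$n_per_farm)
    sharing <- farm %in% config$farms_sharing_ibd
    col <- 0L
    for (f in seq_len(config$n_farms)) {
      p_farm <- drift(sites$founder_af)
      p_farm[ci] <- 0
      for (k in seq_len(config$n_per_farm)) {
        col <- col + 1L
        g <- as.integer(stats::rbinom(S, 2, p_farm))
        if (sharing[col]) {
          g[in_flank] <- 2L * founders$causal_hap[in_flank]
          g[ci] <- 2L
        } else {
          g[ci] <- 0L
          g[ci2] <- 2L
        }
        dosage[, col] <- g
      }
    }
    ids <- sprintf("farm%d_%02d", farm, rep(seq_len(config$n_per_farm),
                                            config$n_farms))
    structure(list(dosage = dosage, ids = ids, farm = farm,
                   sharing = sharing, second_causal_index = ci2),
              class = "farms")
  })
}

#' Simulate toy gene models along the causal chromosome
#'
#' Places single-CDS genes along the causal chromosome: one causal gene
#' whose CDS contains the causal SNP as a TGG->TGA stopgain, a few "decoy"
#' genes near the causal locus whose CDS each contain one linked SNP as a
#' GCA->ACA nonsynonymous change, and background genes elsewhere. The site
#' table's ref/alt base labels are overridden at SNPs that fall inside a
#' CDS so that gene sequence and site table agree (0/1 allele identities
#' are untouched).
#'
#' @param founders a [simulate_founders()] result (its `sites` are
#'   updated in the returned value).
#' @param config a [sim_config()].
#' @param n_genes total positional genes.
#' @param n_decoys decoy genes within 1 Mb of the causal locus.
#' @return list: `genes` (list of [gene_model()]), `sites` (updated site
#'   table), `truth` (data.frame gene/role/coding SNP index).
#' @export
simulate_gene_models <- function(founders, config, n_genes = 40,
                                 n_decoys = 3) {
  stopifnot(inherits(founders, "founders"))
  sites <- founders$sites
  ci <- which(sites$is_causal)
  codons_ok <- setdiff(names(Biostrings::GENETIC_CODE)
                       [Biostrings::GENETIC_CODE != "*"], c("TGG"))

  with_stage_seed(config$seed, "genes", {
    random_cds <- function(n_codons) {
      body <- sample(codons_ok, n_codons - 1, replace = TRUE)
      paste(c(body, "TAA"), collapse = "")
    }
    build_gene <- function(id, cds_start, n_codons = 31,
                           forced = NULL) {
      # forced: list(codon_index, codon) to pin one codon's sequence
      cds_len <- n_codons * 3
      cds_end <- cds_start + cds_len - 1
      seq <- random_cds(n_codons)
      if (!is.null(forced)) {
        at <- (forced$codon_index - 1) * 3 + 1
        substr(seq, at, at + 2) <- forced$codon
      }
      gene_model(id, config$causal_chrom, "+",
                 exons = data.frame(start = cds_start - 50,
                                    end = cds_end + 50),
                 cds = data.frame(start = cds_start, end = cds_end),
                 cds_seq = seq)
    }

    genes <- list()
    truth <- list()

    # causal gene: causal SNP at the 3rd base of codon 11 (TGG ref, ->TGA)
    causal_codon <- 11L
    cds_start_c <- sites$pos[ci] - causal_codon * 3 + 1
    g <- build_gene("geneC", cds_start_c,
                    forced = list(codon_index = causal_codon, codon = "TGG"))
    genes[[g$id]] <- g
    truth[[g$id]] <- data.frame(gene = g$id, role = "causal", snp_index = ci)

    # decoy genes near the locus: one linked SNP at codon 11 base 1,
    # GCA (Ala) ref -> ACA (Thr) alt
    on_ch <- which(sites$chrom == config$causal_chrom & !sites$is_causal)
    offsets <- (seq_len(n_decoys)) * 3e5
    used <- ci
    for (d in seq_len(n_decoys)) {
      target <- config$causal_pos + offsets[d] * (-1)^d
      cand <- setdiff(on_ch, used)
      sd_i <- cand[which.min(abs(sites$pos[cand] - target))]
      used <- c(used, sd_i)
      cds_start_d <- sites$pos[sd_i] - (10L * 3)  # codon 11, base 1
      g <- build_gene(paste0("decoy", d), cds_start_d,
                      forced = list(codon_index = 11L, codon = "GCA"))
      genes[[g$id]] <- g
      truth[[g$id]] <- data.frame(gene = g$id, role = "decoy",
                                  snp_index = sd_i)
    }

    # background genes spread along the chromosome, kept clear of the SNPs
    n_bg <- n_genes - length(genes)
    starts <- round(seq(5e5, config$chrom_length_bp - 5e5,
                        length.out = n_bg))
    for (b in seq_len(n_bg)) {
      g <- build_gene(sprintf("gene%02d", b), starts[b])
      genes[[g$id]] <- g
      truth[[g$id]] <- data.frame(gene = g$id, role = "background",
                                  snp_index = NA_integer_)
    }

    # reconcile site base labels with every CDS they fall into
    for (g in genes) {
      hit <- which(sites$chrom == g$chrom & sites$pos >= g$cds$start &
                     sites$pos <= g$cds$end)
      for (i in hit) {
        off <- cds_offset(g, sites$pos[i])
        base <- substr(g$cds_seq, off, off)
        sites$ref[i] <- base
        alt_choices <- setdiff(c("A", "C", "G", "T"), base)
        if (sites$is_causal[i]) {
          sites$alt[i] <- "A"  # TGG -> TGA
        } else if (!(sites$alt[i] %in% alt_choices)) {
          sites$alt[i] <- sample(alt_choices, 1)
        }
      }
    }
    list(genes = genes, sites = sites, truth = do.call(rbind, truth))
  })
}

#' Simulate a gene expression count matrix
#'
#' Negative-binomial counts for a two-group comparison (default 3 vs 3),
#' gene base means log-normal, constant dispersion, true log2 fold changes
#' applied to the affected group.
#'
#' @param config a [sim_config()] (expression parameters are taken from
#'   `config$expression`).
#' @param de_genes data.frame with columns `gene`, `log2fc` — the true
#'   differential-expression table; genes absent from it have fold change
#'   0. An optional `base_mean` column pins a gene's baseline mean
#'   (otherwise log-normal).
#' @param gene_ids character vector of all genes in the matrix (defaults
#'   to `de_genes$gene` plus background filler genes).
#' @return list: `counts` (genes x samples), `groups`, `truth`
#'   (gene/base_mean/log2fc).
#' @export
simulate_expression <- function(config, de_genes,
                                gene_ids = NULL) {
  ex <- config$expression
  if (ex$dispersion <= 0) stop("dispersion must be positive")
  if (is.null(gene_ids)) {
    gene_ids <- c(de_genes$gene,
                  sprintf("bg%04d", seq_len(ex$n_background_genes)))
  }
  gene_ids <- unique(gene_ids)
  with_stage_seed(config$seed, "expression", {
    G <- length(gene_ids)
    lfc <- stats::setNames(rep(0, G), gene_ids)
    lfc[de_genes$gene] <- de_genes$log2fc
    base <- stats::rlnorm(G, ex$mean_log, ex$sd_log)
    if (!is.null(de_genes$base_mean)) {
      pin <- !is.na(de_genes$base_mean)
      base[match(de_genes$gene[pin], gene_ids)] <- de_genes$base_mean[pin]
    }
    n <- ex$n_per_group
    groups <- rep(c("affected", "unaffected"), each = n)
    mu <- cbind(matrix(base * 2^lfc, G, n), matrix(base, G, n))
    counts <- matrix(
      stats::rnbinom(G * 2 * n, mu = mu, size = 1 / ex$dispersion),
      G, 2 * n)
    dimnames(counts) <- list(gene_ids,
                             paste0(rep(c("CE", "NE"), each = n),
                                    rep(seq_len(n), 2)))
    list(counts = counts, groups = groups,
         truth = data.frame(gene = gene_ids, base_mean = base,
                            log2fc = unname(lfc)))
  })
}

#' Simulate reference genotypes of independent unaffected samples
#'
#' Genotype classes of a few samples from an outside true-breeding
#' unaffected population: homozygous reference at the causal site, drawn
#' from drifted founder frequencies elsewhere, with a small no-call rate
#' (emulating patchy RNA-seq coverage).
#'
#' @param founders a [simulate_founders()] result.
#' @param config a [sim_config()].
#' @param n_refs number of reference samples.
#' @param no_call_rate per-genotype no-call probability.
#' @return data.frame: `chrom`, `pos`, then one genotype-class column per
#'   reference sample.
#' @export
simulate_reference_genotypes <- function(founders, config, n_refs = 3,
                                         no_call_rate = 0.05) {
  sites <- founders$sites
  S <- nrow(sites)
  ci <- which(sites$is_causal)
  with_stage_seed(config$seed, "references", {
    F <- config$background_divergence
    p <- if (F == 0) sites$founder_af else {
      stats::rbeta(S, pmax(sites$founder_af * (1 - F) / F, 1e-6),
                   pmax((1 - sites$founder_af) * (1 - F) / F, 1e-6))
    }
    p[ci] <- 0
    out <- data.frame(chrom = sites$chrom, pos = sites$pos,
                      stringsAsFactors = FALSE)
    classes <- c("hom_ref", "het", "hom_alt")
    for (r in seq_len(n_refs)) {
      g <- stats::rbinom(S, 2, p)
      cls <- classes[g + 1]
      cls[stats::runif(S) < no_call_rate] <- "no_call"
      out[[paste0("ref", r)]] <- cls
    }
    out
  })
}

#' Simulate the complete mapping experiment
#'
#' Composes the full synthetic study under one seed: founders and gene
#' models, two F2 crosses, pooled and individual sequencing of the seven
#' mapping-population libraries, outside-farm individuals, the expression
#' matrix and the unaffected reference genotypes.
#'
#' @param config a [sim_config()].
#' @return An `experiment` list: `table` (one [allele_count_table()] over
#'   all libraries), `founders`, `crosses`, `farms`, `genes`,
#'   `expression`, `reference_genotypes`, `truth`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  founders <- simulate_founders(config)
  gm <- simulate_gene_models(founders, config)
  founders$sites <- gm$sites

  cross1 <- simulate_cross(founders, config, c("NEM", "NEF1"),
                           stage = "cross1")
  cross2 <- simulate_cross(founders, config, c("NEM", "NEF2"),
                           stage = "cross2")
  farms <- simulate_farms(founders, config)

  pool_plan <- list(
    Pool_CE1 = list(cross = cross1, idx = 1L, role = "affected_pool",
                    size = config$pool_sizes[["affected_1"]]),
    Pool_NE1 = list(cross = cross1, idx = 1L, role = "unaffected_pool",
                    size = config$pool_sizes[["unaffected"]]),
    Pool_CE2 = list(cross = cross2, idx = 2L, role = "affected_pool",
                    size = config$pool_sizes[["affected_2"]]),
    Pool_NE2 = list(cross = cross2, idx = 2L, role = "unaffected_pool",
                    size = config$pool_sizes[["unaffected"]])
  )

  with_stage_seed(config$seed, "sequencing", {
    lib_ids <- character(0)
    roles <- character(0)
    crosses <- integer(0)
    sizes <- integer(0)
    ref_m <- NULL
    alt_m <- NULL
    add_lib <- function(id, role, cross, size, counts) {
      lib_ids <<- c(lib_ids, id)
      roles <<- c(roles, role)
      crosses <<- c(crosses, cross)
      sizes <<- c(sizes, size)
      ref_m <<- cbind(ref_m, counts[, "ref"])
      alt_m <<- cbind(alt_m, counts[, "alt"])
    }
    for (p in names(founders$parents)) {
      af <- rowSums(founders$parents[[p]]) / 2
      add_lib(p, "parent", NA_integer_, 1L,
              sequence_counts(af, config$depth[["parent"]],
                              config$seq_error))
    }
    members <- list()
    for (id in names(pool_plan)) {
      pp <- pool_plan[[id]]
      off <- pp$cross
      pick_from <- which(off$phenotype ==
                           if (pp$role == "affected_pool") "affected"
                         else "unaffected")
      if (length(pick_from) < pp$size) {
        stop("cross ", pp$idx, " has too few ",
             sub("_pool", "", pp$role), " offspring for pool ", id)
      }
      m <- pick_from[sample.int(length(pick_from), pp$size)]
      members[[id]] <- m
      af <- rowMeans(off$dosage[, m, drop = FALSE]) / 2
      add_lib(id, pp$role, pp$idx, pp$size,
              sequence_counts(af, config$depth[["pool"]],
                              config$seq_error))
    }
    for (k in seq_along(farms$ids)) {
      af <- farms$dosage[, k] / 2
      add_lib(farms$ids[k], "outside_individual", NA_integer_, 1L,
              sequence_counts(af, config$depth[["outside_individual"]],
                              config$seq_error))
    }
    libs <- data.frame(id = lib_ids, role = roles, cross = crosses,
                       pool_size = sizes, stringsAsFactors = FALSE)
    table <- allele_count_table(founders$sites, ref_m, alt_m, libs)

    gene_truth <- gm$truth
    # the causal gene emulates a well-expressed receptor whose truncation
    # is clearly differentially expressed; decoys are linked DE genes
    de_genes <- rbind(
      data.frame(gene = "geneC",
                 log2fc = config$expression$causal_log2fc,
                 base_mean = 500),
      if (any(gene_truth$role == "decoy")) {
        data.frame(gene = gene_truth$gene[gene_truth$role == "decoy"],
                   log2fc = config$expression$decoy_log2fc,
                   base_mean = 300)
      }
    )
    n_bg_de <- round(config$expression$frac_background_de *
                       config$expression$n_background_genes)
    if (n_bg_de > 0) {
      bg_ids <- sprintf("bg%04d", sample.int(
        config$expression$n_background_genes, n_bg_de))
      de_genes <- rbind(de_genes, data.frame(
        gene = bg_ids,
        log2fc = sample(c(-1, 1), n_bg_de, replace = TRUE) *
          stats::runif(n_bg_de, 1.5, 4),
        base_mean = NA_real_))
    }
    expr <- simulate_expression(
      config, de_genes,
      gene_ids = c(gene_truth$gene,
                   sprintf("bg%04d",
                           seq_len(config$expression$n_background_genes))))
    refs <- simulate_reference_genotypes(founders, config)

    ci <- which(founders$sites$is_causal)
    truth <- list(
      causal = founders$sites[ci, , drop = FALSE],
      causal_gene = "geneC",
      gene_truth = gene_truth,
      de_truth = expr$truth,
      pool_members = members,
      farm_sharing = farms$sharing
    )
    structure(list(table = table, founders = founders,
                   crosses = list(cross1 = cross1, cross2 = cross2),
                   farms = farms, genes = gm$genes, expression = expr,
                   reference_genotypes = refs, truth = truth,
                   config = config),
              class = "experiment")
  })
}
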