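#' Per-library dosage-aware allele frequency for distance computation
#'
#' Pools and parents use the raw read frequency; low-coverage outside
#' individuals use genotype-class dosage/2 (a hard call is more robust than
#' a 4x read fraction). Sites below the role-appropriate depth cutoff are
#' `NA`.
#'
#' @param table an [allele_count_table()].
#' @param id library id.
#' @param pool_thresholds,individual_thresholds [genotype_thresholds()] for
#'   the two library kinds (defaults: min_depth 4 for pools/parents, 2 for
#'   outside individuals).
#' @return numeric vector of allele frequencies with `NA` at uncallable
#'   sites.
#' @export
distance_af <- function(table, id,
                        pool_thresholds = genotype_thresholds(min_depth = 4),
                        individual_thresholds = genotype_thresholds(min_depth = 2)) {
  i <- lib_index(table, id)
  role <- table$libraries$role[i]
  if (role == "outside_individual") {
    gt <- classify_genotype(table$ref[, i], table$alt[, i],
                            individual_thresholds)
    c(hom_ref = 0, het = 0.5, hom_alt = 1, no_call = NA_real_)[gt]
  } else {
    library_af(table, id, min_depth = pool_thresholds$min_depth)
  }
}

#' Pairwise genetic distance within a region
#'
#' Mean absolute allele-frequency difference over sites callable in both
#' libraries inside the region (for haploid frequencies this is the average
#' pairwise difference). Returns `NA` when fewer than `min_sites` shared
#' callable sites exist.
#'
#' @param table an [allele_count_table()].
#' @param lib_i,lib_j library ids.
#' @param region list/row with `chrom`, `start`, `end` (1-based inclusive).
#' @param min_sites minimum shared callable sites.
#' @param ... passed to [distance_af()].
#' @return A single distance in `[0, 1]` with attribute `n_sites_used`,
#'   or `NA`.
#' @export
region_distance <- function(table, lib_i, lib_j, region, min_sites = 1, ...) {
  sub <- subset_region(table, region$chrom, region$start, region$end)
  ai <- distance_af(sub, lib_i, ...)
  aj <- distance_af(sub, lib_j, ...)
  ok <- !is.na(ai) & !is.na(aj)
  n <- sum(ok)
  d <- if (n >= min_sites) mean(abs(ai[ok] - aj[ok])) else NA_real_
  attr(d, "n_sites_used") <- n
  d
}

#' Pairwise distance matrix for a region
#'
#' @param table an [allele_count_table()].
#' @param libs library ids (default: affected pools plus all outside
#'   individuals).
#' @param region a region row (`chrom`, `start`, `end`).
#' @param min_sites minimum shared callable sites per pair.
#' @param ... passed to [distance_af()].
#' @return A `region_distance_matrix`: symmetric matrix `d` with zero
#'   diagonal, matrix `n_sites`, the region, and the library ids.
#' @export
region_distance_matrix <- function(table, libs = NULL, region,
                                   min_sites = 1, ...) {
  if (is.null(libs)) {
    libs <- table$libraries$id[table$libraries$role %in%
                                 c("affected_pool", "outside_individual")]
  }
  sub <- subset_region(table, region$chrom, region$start, region$end)
  af <- sapply(libs, function(l) distance_af(sub, l, ...))
  if (!is.matrix(af)) af <- matrix(af, ncol = length(libs),
                                   dimnames = list(NULL, libs))
  k <- length(libs)
  d <- matrix(0, k, k, dimnames = list(libs, libs))
  n <- matrix(0L, k, k, dimnames = list(libs, libs))
  for (i in seq_len(k)) {
    n[i, i] <- sum(!is.na(af[, i]))
    for (j in seq_len(k)[-seq_len(i)]) {
      ok <- !is.na(af[, i]) & !is.na(af[, j])
      n[i, j] <- n[j, i] <- sum(ok)
      d[i, j] <- d[j, i] <- if (sum(ok) >= min_sites) {
        mean(abs(af[ok, i] - af[ok, j]))
      } else NA_real_
    }
  }
  structure(list(region = region, libraries = libs, d = d, n_sites = n),
            class = "region_distance_matrix")
}

#' Retain outside individuals close to the affected pools
#'
#' An outside individual is retained for a region iff its distance to
#' EVERY reference affected pool is defined and at most `d_max` (any
#' larger — or unassessable — distance excludes it, the conservative
#' reading of the exclusion rule). Reference pools are always retained.
#'
#' @param dmat a [region_distance_matrix()].
#' @param reference_pools ids of the affected pools.
#' @param d_max exclusion threshold (default 0.1).
#' @return list with `retained` (pools first, then retained individuals),
#'   `excluded`, and the per-individual maximum pool distance `max_d`.
#' @export
retain_samples <- function(dmat, reference_pools, d_max = 0.1) {
  stopifnot(inherits(dmat, "region_distance_matrix"))
  if (!all(reference_pools %in% dmat$libraries)) {
    stop("reference pools missing from distance matrix")
  }
  others <- setdiff(dmat$libraries, reference_pools)
  if (length(others)) {
    dd <- dmat$d[others, reference_pools, drop = FALSE]
    max_d <- apply(dd, 1, function(x) if (anyNA(x)) NA_real_ else max(x))
    keep <- !is.na(max_d) & max_d <= d_max
  } else {
    max_d <- numeric(0)
    keep <- logical(0)
  }
  list(retained = c(reference_pools, others[keep]),
       excluded = others[!keep],
       max_d = max_d)
}

#' Screen target mutations within candidate regions
#'
#' For each candidate region, keeps candidate variants that are fixed in
#' every retained affected library (the affected pools plus the retained
#' outside individuals): all callable genotype classes homozygous in the
#' same direction (`hom_alt` for a causal mutant allele, `hom_ref` for the
#' inhibitor-hypothesis direction), with both affected pools callable.
#' `no_call` genotypes in individuals are non-informative and skipped.
#' Regions with at least one surviving variant are reported as target
#' regions.
#'
#' @param candidates variant records (from [candidate_mutation_filter()] or
#'   [intersect_crosses()]), with `chrom`, `pos`, `ref`, `alt`.
#' @param table an [allele_count_table()] containing all libraries.
#' @param regions candidate-region table ([call_candidate_regions()]).
#' @param retained named list (one element per region row) of retained
#'   library ids, e.g. from [retain_samples()]; pools must be included.
#' @param affected_pools ids of the affected pools (must be callable).
#' @param pool_thresholds,individual_thresholds genotype thresholds per
#'   library kind.
#' @return list with `target_mutations` (records plus `region_index` and
#'   `direction`) and `target_regions` (regions with `n_target_mutations`
#'   and `span_mb`).
#' @export
screen_target_mutations <- function(candidates, table, regions, retained,
                                    affected_pools,
                                    pool_thresholds = genotype_thresholds(min_depth = 4),
                                    individual_thresholds = genotype_thresholds(min_depth = 2)) {
  stopifnot(length(retained) == nrow(regions))
  keep_rows <- list()
  n_per_region <- integer(nrow(regions))
  for (r in seq_len(nrow(regions))) {
    reg <- regions[r, ]
    in_reg <- candidates$chrom == reg$chrom &
      candidates$pos >= reg$start & candidates$pos <= reg$end
    cand <- candidates[in_reg, , drop = FALSE]
    if (!nrow(cand)) next
    libs <- retained[[r]]
    site_idx <- match(paste(cand$chrom, cand$pos),
                      paste(table$sites$chrom, table$sites$pos))
    if (anyNA(site_idx)) stop("candidate variant absent from count table")
    gt <- sapply(libs, function(l) {
      i <- lib_index(table, l)
      th <- if (table$libraries$role[i] == "outside_individual") {
        individual_thresholds
      } else pool_thresholds
      classify_genotype(table$ref[site_idx, i], table$alt[site_idx, i], th)
    })
    if (!is.matrix(gt)) gt <- matrix(gt, nrow = length(site_idx),
                                     dimnames = list(NULL, libs))
    pools_gt <- gt[, affected_pools, drop = FALSE]
    pools_alt <- rowSums(pools_gt == "hom_alt") == length(affected_pools)
    pools_ref <- rowSums(pools_gt == "hom_ref") == length(affected_pools)
    inds <- setdiff(libs, affected_pools)
    ind_gt <- gt[, inds, drop = FALSE]
    fixed_alt <- pools_alt &
      rowSums(ind_gt != "hom_alt" & ind_gt != "no_call") == 0
    fixed_ref <- pools_ref &
      rowSums(ind_gt != "hom_ref" & ind_gt != "no_call") == 0
    sel <- fixed_alt | fixed_ref
    if (any(sel)) {
      rows <- cand[sel, , drop = FALSE]
      rows$region_index <- r
      rows$direction <- ifelse(fixed_alt[sel], "alt", "ref")
      keep_rows[[length(keep_rows) + 1]] <- rows
      n_per_region[r] <- sum(sel)
    }
  }
  tm <- if (length(keep_rows)) do.call(rbind, keep_rows) else
    cbind(candidates[0, , drop = FALSE],
          data.frame(region_index = integer(), direction = character()))
  tr <- regions[n_per_region > 0, , drop = FALSE]
  if (nrow(tr)) {
    tr$n_target_mutations <- n_per_region[n_per_region > 0]
    tr$span_mb <- mapply(region_span_mb, tr$start, tr$end)
  } else {
    tr$n_target_mutations <- integer(0)
    tr$span_mb <- numeric(0)
  }
  list(target_mutations = tm, target_regions = tr)
}

#' Region span in megabases
#'
#' 1-based inclusive span `(end - start + 1) / 1e6`; summaries report it to
#' one decimal.
#'
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @return Span in Mb.
#' @export
region_span_mb <- function(start, end) {
  if (any(start > end)) stop("start must not exceed end")
  (end - start + 1) / 1e6
}
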