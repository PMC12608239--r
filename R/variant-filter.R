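#' Genotype-classification thresholds
#'
#' Allele-frequency bands used to call a genotype class from read counts.
#' With `f = alt/(ref+alt)`: `hom_ref` when `f <= t_low`, `hom_alt` when
#' `f >= t_high`, `het` when `het_lo <= f <= het_hi`, otherwise `no_call`;
#' also `no_call` when depth < `min_depth`. For a pool, "het" means an
#' intermediate pool allele frequency (a pool has no diploid genotype);
#' the same band is used by default.
#'
#' @param t_low,t_high homozygous cutoffs.
#' @param het_lo,het_hi heterozygous band.
#' @param min_depth minimum depth for a call (4 suits ~10-30x libraries,
#'   2 suits ~4x individual libraries).
#' @return A `genotype_thresholds` list.
#' @export
genotype_thresholds <- function(t_low = 0.05, t_high = 0.95,
                                het_lo = 0.20, het_hi = 0.80, min_depth = 4) {
  if (!(t_low < het_lo && het_lo <= het_hi && het_hi < t_high)) {
    stop("inconsistent thresholds: need t_low < het_lo <= het_hi < t_high")
  }
  if (min_depth < 1) stop("min_depth must be >= 1")
  structure(list(t_low = t_low, t_high = t_high, het_lo = het_lo,
                 het_hi = het_hi, min_depth = min_depth),
            class = "genotype_thresholds")
}

#' Classify genotypes from read counts
#'
#' @param ref_count,alt_count non-negative read counts (vectorized).
#' @param thresholds a [genotype_thresholds()] object.
#' @return Character vector in
#'   `c("hom_ref", "het", "hom_alt", "no_call")`.
#' @export
classify_genotype <- function(ref_count, alt_count,
                              thresholds = genotype_thresholds()) {
  if (any(ref_count < 0) || any(alt_count < 0)) {
    stop("counts must be non-negative")
  }
  th <- thresholds
  depth <- ref_count + alt_count
  f <- ifelse(depth > 0, alt_count / depth, NA_real_)
  out <- rep("no_call", length(f))
  callable <- depth >= th$min_depth
  out[callable & f <= th$t_low] <- "hom_ref"
  out[callable & f >= th$t_high] <- "hom_alt"
  out[callable & f >= th$het_lo & f <= th$het_hi] <- "het"
  out
}

#' Cross library manifest
#'
#' Names the four libraries of one mapping cross used by the
#' segregation-pattern filter.
#'
#' @param parents character vector of the two parent library ids.
#' @param affected_pool,unaffected_pool pool library ids.
#' @return A named list of class `cross_libraries`.
#' @export
cross_libraries <- function(parents, affected_pool, unaffected_pool) {
  stopifnot(length(parents) == 2, length(affected_pool) == 1,
            length(unaffected_pool) == 1)
  structure(list(parents = parents, affected_pool = affected_pool,
                 unaffected_pool = unaffected_pool),
            class = "cross_libraries")
}

#' Segregation-pattern candidate-mutation filter
#'
#' Retains variants whose allele-frequency pattern across one cross matches
#' a segregating single-locus mutation: allele-frequency difference (dAF)
#' between the phenotype pools above `daf_min`, heterozygous in both
#' parents and in the unaffected pool, and homozygous (either direction,
#' covering both the recessive-causal and dominant-inhibitor hypotheses)
#' in the affected pool. A `no_call` in any required library rejects the
#' variant (conservative; no automated rescue).
#'
#' @param table an [allele_count_table()].
#' @param cross a [cross_libraries()] manifest.
#' @param daf_min retain only dAF strictly greater than this (default 0.5;
#'   the theoretical causal-site dAF is 2/3, the margin absorbs pooling and
#'   sequencing noise).
#' @param thresholds genotype thresholds for parents and pools.
#' @param keep_all return all variants with verdict columns instead of the
#'   passing subset.
#' @return data.frame of variant records: site columns, per-library allele
#'   frequency (`af_*`) and genotype class (`gt_*`), `daf`, per-rule
#'   verdicts and `pass`.
#' @export
candidate_mutation_filter <- function(table, cross, daf_min = 0.5,
                                      thresholds = genotype_thresholds(),
                                      keep_all = FALSE) {
  stopifnot(inherits(cross, "cross_libraries"))
  libs <- c(cross$parents, cross$affected_pool, cross$unaffected_pool)
  idx <- lib_index(table, libs)  # errors on missing library
  th <- thresholds

  af <- sapply(libs, function(l) library_af(table, l, th$min_depth))
  gt <- sapply(libs, function(l) {
    i <- lib_index(table, l)
    classify_genotype(table$ref[, i], table$alt[, i], th)
  })
  if (nrow(table$sites) == 1) {
    af <- matrix(af, nrow = 1, dimnames = list(NULL, libs))
    gt <- matrix(gt, nrow = 1, dimnames = list(NULL, libs))
  }
  daf <- abs(af[, cross$affected_pool] - af[, cross$unaffected_pool])

  parents_het <- gt[, cross$parents[1]] == "het" &
    gt[, cross$parents[2]] == "het"
  ne_het <- gt[, cross$unaffected_pool] == "het"
  ce_hom <- gt[, cross$affected_pool] %in% c("hom_ref", "hom_alt")
  daf_ok <- !is.na(daf) & daf > daf_min
  pass <- parents_het & ne_het & ce_hom & daf_ok

  rec <- cbind(
    table$sites,
    stats::setNames(as.data.frame(af), paste0("af_", libs)),
    stats::setNames(as.data.frame(gt, stringsAsFactors = FALSE),
                    paste0("gt_", libs))
  )
  rec$daf <- as.numeric(daf)
  rec$parents_het <- parents_het
  rec$unaffected_het <- ne_het
  rec$affected_hom <- ce_hom
  rec$daf_ok <- daf_ok
  rec$pass <- pass
  rownames(rec) <- NULL
  if (keep_all) rec else rec[pass, , drop = FALSE]
}

#' Intersect candidate mutations between two crosses
#'
#' Variants passing the segregation-pattern filter in both crosses, keyed
#' by (chrom, pos, ref, alt). The returned data.frame carries the records
#' of the first cross plus the second cross's dAF; a region-level overlap
#' report is attached as attribute `"region_overlap"` when both region
#' tables are supplied.
#'
#' @param records1,records2 outputs of [candidate_mutation_filter()].
#' @param regions1,regions2 optional candidate-region tables
#'   ([call_candidate_regions()]) for the overlap report.
#' @return data.frame of shared candidate variants.
#' @export
intersect_crosses <- function(records1, records2,
                              regions1 = NULL, regions2 = NULL) {
  key <- function(r) paste(r$chrom, r$pos, r$ref, r$alt, sep = ":")
  shared <- records1[key(records1) %in% key(records2), , drop = FALSE]
  if (nrow(shared)) {
    m <- match(key(shared), key(records2))
    shared$daf_cross2 <- records2$daf[m]
  } else {
    shared$daf_cross2 <- numeric(0)
  }
  if (!is.null(regions1) && !is.null(regions2)) {
    attr(shared, "region_overlap") <- region_overlap(regions1, regions2)
  }
  shared
}

# bp of overlap between two candidate-region tables, per chromosome
region_overlap <- function(regions1, regions2) {
  chroms <- union(regions1$chrom, regions2$chrom)
  do.call(rbind, lapply(chroms, function(ch) {
    a <- regions1[regions1$chrom == ch, , drop = FALSE]
    b <- regions2[regions2$chrom == ch, , drop = FALSE]
    ov <- 0
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
      ov <- ov + max(0, min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]) + 1)
    }
    data.frame(chrom = ch, overlap_bp = ov)
  }))
}

#' Structural-variant segregation-pattern filter
#'
#' Applies the mapping-population pattern to SV genotype classes across the
#' seven libraries (three parents, two unaffected pools, two affected
#' pools): heterozygous in all parents and unaffected pools, homozygous
#' (either direction) in both affected pools. SVs with a `no_call` in any
#' required library are rejected and flagged `insufficient_evidence`
#' rather than retained.
#'
#' @param sv_table data.frame with an `sv_id` column plus one genotype-class
#'   column per library.
#' @param parents,unaffected_pools,affected_pools library column names.
#' @param keep_all return all rows with verdicts instead of the subset.
#' @return Retained subset (or full table when `keep_all`) with `pass` and
#'   `reason` columns.
#' @export
sv_pattern_filter <- function(sv_table, parents, unaffected_pools,
                              affected_pools, keep_all = FALSE) {
  libs <- c(parents, unaffected_pools, affected_pools)
  missing <- setdiff(libs, names(sv_table))
  if (length(missing)) {
    stop("missing library columns: ", paste(missing, collapse = ", "))
  }
  gt <- as.matrix(sv_table[, libs, drop = FALSE])
  any_nc <- apply(gt == "no_call", 1, any)
  het_ok <- apply(gt[, c(parents, unaffected_pools), drop = FALSE] == "het",
                  1, all)
  hom_mat <- matrix(gt[, affected_pools, drop = FALSE] %in%
                      c("hom_ref", "hom_alt"), nrow = nrow(gt))
  hom_ok <- rowSums(hom_mat) == length(affected_pools)
  pass <- !any_nc & het_ok & hom_ok
  reason <- ifelse(pass, "pass",
                   ifelse(any_nc, "insufficient_evidence", "pattern_mismatch"))
  out <- sv_table
  out$pass <- pass
  out$reason <- reason
  if (keep_all) out else out[pass, , drop = FALSE]
}
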