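#' Allele count table
#'
#' The central data container: per-site, per-library reference and alternate
#' read counts (the content of a Popoolation2 sync file), together with the
#' library manifest. Sites are biallelic SNPs (or SV pseudo-sites) with
#' 1-based positions, strictly increasing within each chromosome.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (single bases, or ids for SV pseudo-sites).
#' @param ref_counts,alt_counts integer matrices, sites x libraries, with
#'   column names equal to `libraries$id`.
#' @param libraries data.frame manifest with columns `id`, `role` (one of
#'   `parent`, `affected_pool`, `unaffected_pool`, `outside_individual`),
#'   `cross` (integer or NA), `pool_size`.
#' @return An object of class `allele_count_table`.
#' @export
allele_count_table <- function(sites, ref_counts, alt_counts, libraries) {
  stopifnot(
    is.data.frame(sites),
    all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
    is.matrix(ref_counts), is.matrix(alt_counts),
    nrow(ref_counts) == nrow(sites), nrow(alt_counts) == nrow(sites),
    identical(dim(ref_counts), dim(alt_counts)),
    is.data.frame(libraries),
    all(c("id", "role") %in% names(libraries)),
    ncol(ref_counts) == nrow(libraries)
  )
  if (any(ref_counts < 0) || any(alt_counts < 0)) {
    stop("read counts must be non-negative")
  }
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  ref_counts <- ref_counts[ord, , drop = FALSE]
  alt_counts <- alt_counts[ord, , drop = FALSE]
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (anyDuplicated(p)) stop("duplicate positions on ", ch)
  }
  rownames(sites) <- NULL
  colnames(ref_counts) <- colnames(alt_counts) <- libraries$id
  structure(
    list(sites = sites, ref = ref_counts, alt = alt_counts,
         libraries = libraries),
    class = "allele_count_table"
  )
}

#' @export
print.allele_count_table <- function(x, ...) {
  cat("<allele_count_table> ", nrow(x$sites), " sites x ",
      nrow(x$libraries), " libraries\n", sep = "")
  cat("  chromosomes:", paste(unique(x$sites$chrom), collapse = ", "), "\n")
  cat("  roles:", paste(sprintf("%s=%d", names(table(x$libraries$role)),
                                table(x$libraries$role)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.allele_count_table <- function(x) c(nrow(x$sites), nrow(x$libraries))

lib_index <- function(table, id) {
  i <- match(id, table$libraries$id)
  if (anyNA(i)) {
    stop("library not found: ", paste(id[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  i
}

#' Per-library allele frequencies and depths
#'
#' Read-frequency estimate `alt / (ref + alt)` for one library, with `NA`
#' below the depth cutoff.
#'
#' @param table an [allele_count_table()].
#' @param id library id.
#' @param min_depth minimum read depth for a callable site.
#' @return numeric vector of alternate-allele frequencies (NA where depth
#'   is below `min_depth`).
#' @export
library_af <- function(table, id, min_depth = 1) {
  i <- lib_index(table, id)
  pool_allele_freq(table$ref[, i], table$alt[, i], min_depth = min_depth)
}

#' Subset an allele count table to a genomic region
#'
#' @param table an [allele_count_table()].
#' @param chrom chromosome id.
#' @param start,end 1-based inclusive bounds.
#' @return An `allele_count_table` restricted to sites in the region.
#' @export
subset_region <- function(table, chrom, start, end) {
  stopifnot(start <= end)
  keep <- table$sites$chrom == chrom &
    table$sites$pos >= start & table$sites$pos <= end
  allele_count_table(
    table$sites[keep, , drop = FALSE],
    table$ref[keep, , drop = FALSE],
    table$alt[keep, , drop = FALSE],
    table$libraries
  )
}
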