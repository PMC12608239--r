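#' Pool allele frequency from read counts
#'
#' @param ref_count,alt_count non-negative read counts (vectorized).
#' @param min_depth minimum total depth; below it the frequency is `NA`.
#' @return Alternate-allele read frequency, `NA` where depth < `min_depth`.
#' @export
pool_allele_freq <- function(ref_count, alt_count, min_depth = 1) {
  if (any(ref_count < 0, na.rm = TRUE) || any(alt_count < 0, na.rm = TRUE)) {
    stop("counts must be non-negative")
  }
  depth <- ref_count + alt_count
  f <- ifelse(depth >= pmax(min_depth, 1), alt_count / depth, NA_real_)
  as.numeric(f)
}

#' Per-site F_ST between two pools
#'
#' Classical heterozygosity-based estimator. With `H(p) = 2p(1-p)`,
#' within-pool diversity `pi_w = (H(p1)+H(p2))/2` and total diversity
#' `pi_t = H((p1+p2)/2)`, the per-site fixation index is
#' `(pi_t - pi_w)/pi_t` when `pi_t > 0` and 0 otherwise, clamped to
#' `[0, 1]`. Optionally applies a small-depth correction factor
#' `d/(d-1)` to each pool's heterozygosity.
#'
#' @param p1,p2 allele frequencies in `[0, 1]` (vectorized; NA propagates).
#' @param depth1,depth2 optional read depths for the finite-depth
#'   correction; ignored unless `depth_correction = TRUE`.
#' @param depth_correction apply the `d/(d-1)` correction (default off).
#' @return F_ST values in `[0, 1]`.
#' @export
site_fst <- function(p1, p2, depth1 = NULL, depth2 = NULL,
                     depth_correction = FALSE) {
  ok1 <- is.na(p1) | (p1 >= 0 & p1 <= 1)
  ok2 <- is.na(p2) | (p2 >= 0 & p2 <= 1)
  if (!all(ok1) || !all(ok2)) stop("allele frequencies must lie in [0, 1]")
  H <- function(p) 2 * p * (1 - p)
  h1 <- H(p1)
  h2 <- H(p2)
  if (depth_correction) {
    if (is.null(depth1) || is.null(depth2)) {
      stop("depth_correction requires depth1 and depth2")
    }
    h1 <- h1 * ifelse(depth1 > 1, depth1 / (depth1 - 1), NA_real_)
    h2 <- h2 * ifelse(depth2 > 1, depth2 / (depth2 - 1), NA_real_)
  }
  pi_w <- (h1 + h2) / 2
  pi_t <- H((p1 + p2) / 2)
  fst <- ifelse(pi_t > 0, (pi_t - pi_w) / pi_t, 0)
  pmin(pmax(fst, 0), 1)
}

window_starts <- function(chrom_length, window, step) {
  if (window <= 0) stop("window must be positive")
  if (step <= 0) stop("step must be positive")
  if (chrom_length < window) return(1)
  n_full <- floor((chrom_length - window) / step) + 1
  starts <- 1 + step * (0:(n_full - 1))
  # trailing truncated window when the chromosome is not step-aligned
  if ((chrom_length - window) %% step != 0) {
    starts <- c(starts, 1 + step * n_full)
  }
  starts
}

#' Sliding-window F_ST scan between two pools
#'
#' Windows are anchored at position 1 on each chromosome (default 50 kb
#' windows, 10 kb step); a trailing truncated window is emitted when the
#' chromosome length is not step-aligned. The window statistic is the mean
#' of per-site F_ST over sites callable in both pools (negative per-site
#' values are already clamped at 0 by [site_fst()]); windows with fewer
#' than `min_snps` callable sites carry `NA`.
#'
#' @param table an [allele_count_table()].
#' @param pool_a,pool_b library ids of the two pools.
#' @param window,step window size and step in bp.
#' @param min_snps minimum callable sites for a defined window value.
#' @param min_depth per-pool depth cutoff for a callable site.
#' @param chrom_lengths named vector of chromosome lengths; defaults to the
#'   maximum observed position per chromosome.
#' @param stat `"mean"` (mean of per-site F_ST, the default) or
#'   `"ratio"` (ratio of summed numerators to summed denominators).
#' @return data.frame of class `window_stats`: `chrom`, `start`, `end`
#'   (1-based inclusive), `n_snps`, `fst`.
#' @export
window_scan <- function(table, pool_a, pool_b, window = 50000, step = 10000,
                        min_snps = 1, min_depth = 4, chrom_lengths = NULL,
                        stat = c("mean", "ratio")) {
  stat <- match.arg(stat)
  if (window <= 0) stop("window must be positive")
  p1 <- library_af(table, pool_a, min_depth = min_depth)
  p2 <- library_af(table, pool_b, min_depth = min_depth)
  callable <- !is.na(p1) & !is.na(p2)
  H <- function(p) 2 * p * (1 - p)
  num <- H((p1 + p2) / 2) - (H(p1) + H(p2)) / 2
  den <- H((p1 + p2) / 2)
  fst_site <- site_fst(p1, p2)

  chroms <- unique(table$sites$chrom)
  out <- vector("list", length(chroms))
  for (k in seq_along(chroms)) {
    ch <- chroms[k]
    in_ch <- table$sites$chrom == ch
    pos <- table$sites$pos[in_ch]
    L <- if (!is.null(chrom_lengths) && !is.na(chrom_lengths[ch])) {
      as.numeric(chrom_lengths[ch])
    } else if (length(pos)) max(pos) else 0
    if (L == 0) next
    starts <- window_starts(L, window, step)
    ends <- pmin(starts + window - 1, L)
    use <- callable[in_ch]
    pos_ok <- pos[use]
    f_ok <- fst_site[in_ch][use]
    n_ok <- pmax(num[in_ch][use], 0)
    d_ok <- den[in_ch][use]
    # cumulative sums over sorted site positions give O(1) window sums
    cs_f <- c(0, cumsum(f_ok))
    cs_n <- c(0, cumsum(n_ok))
    cs_d <- c(0, cumsum(d_ok))
    lo <- findInterval(starts - 1, pos_ok)      # sites strictly before start
    hi <- findInterval(ends, pos_ok)            # sites up to end
    n_snps <- hi - lo
    fst <- if (stat == "mean") {
      ifelse(n_snps > 0, (cs_f[hi + 1] - cs_f[lo + 1]) / n_snps, NA_real_)
    } else {
      d_sum <- cs_d[hi + 1] - cs_d[lo + 1]
      ifelse(d_sum > 0, pmin(pmax((cs_n[hi + 1] - cs_n[lo + 1]) / d_sum, 0), 1),
             NA_real_)
    }
    fst[n_snps < min_snps] <- NA_real_
    out[[k]] <- data.frame(chrom = ch, start = starts, end = ends,
                           n_snps = n_snps, fst = fst,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_snps = integer(), fst = numeric())
  }
  class(res) <- c("window_stats", "data.frame")
  res
}

#' Genome-wide Z-transformation of window F_ST
#'
#' Standardizes window F_ST values using the mean and sample (n-1)
#' standard deviation over all windows with a defined value, across all
#' chromosomes. Windows without a defined F_ST get `NA`.
#'
#' @param windows output of [window_scan()].
#' @return `windows` with an added `zfst` column.
#' @export
zfst_transform <- function(windows) {
  f <- windows$fst
  defined <- !is.na(f)
  if (sum(defined) < 2) stop("need at least 2 windows with defined F_ST")
  s <- stats::sd(f[defined])
  if (s == 0) stop("degenerate scan: window F_ST has zero variance")
  windows$zfst <- (f - mean(f[defined])) / s
  windows
}

#' Call candidate regions from standardized window scores
#'
#' Windows with `zfst` above `z_threshold` are selected and overlapping or
#' near-abutting window spans (gap <= `merge_gap` bp) are merged into
#' candidate regions.
#'
#' @param windows output of [zfst_transform()].
#' @param z_threshold ZF_ST cutoff; windows strictly above it qualify.
#' @param merge_gap maximum gap in bp between merged window spans.
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive),
#'   `peak_zfst`, `n_windows`, `size_bp`.
#' @export
call_candidate_regions <- function(windows, z_threshold = 11, merge_gap = 0) {
  if (is.null(windows$zfst)) stop("windows must carry zfst; run zfst_transform")
  hit <- windows[!is.na(windows$zfst) & windows$zfst > z_threshold, ,
                 drop = FALSE]
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      peak_zfst = numeric(), n_windows = integer(),
                      size_bp = numeric())
  if (nrow(hit) == 0) return(empty)
  hit <- hit[order(hit$chrom, hit$start), , drop = FALSE]
  out <- list()
  cur <- NULL
  flush <- function(cur) {
    data.frame(chrom = cur$chrom, start = cur$start, end = cur$end,
               peak_zfst = cur$peak, n_windows = cur$n,
               size_bp = cur$end - cur$start + 1)
  }
  for (i in seq_len(nrow(hit))) {
    w <- hit[i, ]
    if (!is.null(cur) && w$chrom == cur$chrom &&
        w$start <= cur$end + 1 + merge_gap) {
      cur$end <- max(cur$end, w$end)
      cur$peak <- max(cur$peak, w$zfst)
      cur$n <- cur$n + 1L
    } else {
      if (!is.null(cur)) out[[length(out) + 1]] <- flush(cur)
      cur <- list(chrom = w$chrom, start = w$start, end = w$end,
                  peak = w$zfst, n = 1L)
    }
  }
  out[[length(out) + 1]] <- flush(cur)
  do.call(rbind, out)
}
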