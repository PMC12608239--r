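#' Read a Popoolation2 sync file
#'
#' Columns: chrom, pos, reference base, then one `A:T:C:G:N:del` count
#' field per library. Sites are reduced to biallelic records: the
#' alternate allele is the most frequent non-reference base summed across
#' libraries; `N` and deletion counts are treated as uncallable depth and
#' dropped. A leading `#`-comment header written by [write_sync()] names
#' the libraries; otherwise they are `lib1..libk`.
#'
#' @param path sync file path.
#' @param libraries optional library manifest data.frame (`id`, `role`,
#'   ...); inferred ids otherwise, with role `unknown`.
#' @return An [allele_count_table()].
#' @export
read_sync <- function(path, libraries = NULL) {
  lines <- readLines(path)
  header_ids <- NULL
  if (length(lines) && startsWith(lines[1], "#")) {
    hdr <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
    if (length(hdr) > 3) header_ids <- hdr[-(1:3)]
    lines <- lines[-1]
  }
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    libs <- libraries %||% data.frame(id = character(), role = character())
    return(allele_count_table(
      data.frame(chrom = character(), pos = numeric(), ref = character(),
                 alt = character()),
      matrix(0L, 0, nrow(libs)), matrix(0L, 0, nrow(libs)), libs))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (length(unique(ncols)) != 1 || ncols[1] < 4) {
    bad <- which(ncols != max(ncols[1], 4))[1]
    stop("malformed sync line ", bad, ": expected ", max(ncols[1], 4),
         " tab-separated columns, found ", ncols[bad])
  }
  k <- ncols[1] - 3
  chrom <- vapply(fields, `[[`, "", 1)
  pos <- as.numeric(vapply(fields, `[[`, "", 2))
  ref <- toupper(vapply(fields, `[[`, "", 3))
  counts <- array(0, dim = c(length(lines), k, 6))
  for (j in seq_len(k)) {
    cell <- vapply(fields, `[[`, "", 3 + j)
    parts <- strsplit(cell, ":", fixed = TRUE)
    if (any(lengths(parts) != 6)) {
      stop("malformed sync line ", which(lengths(parts) != 6)[1],
           ": count field must have 6 colon-separated values (A:T:C:G:N:del)")
    }
    counts[, j, ] <- matrix(as.numeric(unlist(parts)), ncol = 6,
                            byrow = TRUE)
  }
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("positions not strictly increasing on ", ch, " (line ",
           which(chrom == ch)[which(diff(p) <= 0)[1] + 1], ")")
    }
  }
  base_order <- c("A", "T", "C", "G")
  ref_idx <- match(ref, base_order)
  if (anyNA(ref_idx)) stop("reference base must be one of A, T, C, G")
  total <- apply(counts[, , 1:4, drop = FALSE], c(1, 3), sum)
  alt_tot <- total
  alt_tot[cbind(seq_along(ref_idx), ref_idx)] <- -1
  alt_idx <- max.col(alt_tot, ties.method = "first")
  alt <- base_order[alt_idx]
  ref_counts <- matrix(0L, length(lines), k)
  alt_counts <- matrix(0L, length(lines), k)
  for (j in seq_len(k)) {
    ref_counts[, j] <- as.integer(counts[cbind(seq_along(ref_idx), j,
                                               ref_idx)])
    alt_counts[, j] <- as.integer(counts[cbind(seq_along(alt_idx), j,
                                               alt_idx)])
  }
  ids <- header_ids %||% paste0("lib", seq_len(k))
  libs <- libraries %||% data.frame(id = ids, role = "unknown",
                                    stringsAsFactors = FALSE)
  if (nrow(libs) != k) stop("library manifest does not match column count")
  allele_count_table(
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE),
    ref_counts, alt_counts, libs)
}

#' Write an allele count table as a sync file
#'
#' @param table an [allele_count_table()].
#' @param path output path.
#' @param header write a `#chrom pos ref <ids>` comment header (read back
#'   by [read_sync()]).
#' @export
write_sync <- function(table, path, header = TRUE) {
  base_order <- c("A", "T", "C", "G")
  S <- nrow(table$sites)
  k <- nrow(table$libraries)
  ref_i <- match(table$sites$ref, base_order)
  alt_i <- match(table$sites$alt, base_order)
  if (anyNA(ref_i) || anyNA(alt_i)) {
    stop("sync output requires single-base ref/alt in A, T, C, G")
  }
  cols <- character(k)
  lines <- rep("", S)
  cells <- matrix("", S, k)
  for (j in seq_len(k)) {
    m <- matrix(0L, S, 6)
    m[cbind(seq_len(S), ref_i)] <- as.integer(table$ref[, j])
    m[cbind(seq_len(S), alt_i)] <- as.integer(table$alt[, j])
    cells[, j] <- paste(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5], m[, 6],
                        sep = ":")
  }
  body <- paste(table$sites$chrom, table$sites$pos, table$sites$ref,
                apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  if (S == 0) body <- character(0)
  out <- body
  if (header) {
    out <- c(paste0("#", paste(c("chrom", "pos", "ref",
                                 table$libraries$id), collapse = "\t")),
             out)
  }
  writeLines(out, path)
  invisible(path)
}

#' Write variant records as a minimal VCF
#'
#' VCF v4.2 subset: CHROM POS ID REF ALT QUAL FILTER INFO FORMAT plus
#' GT:AD per library when count columns are supplied.
#'
#' @param records data.frame with `chrom`, `pos`, `ref`, `alt`; optional
#'   `gt_*` genotype-class columns (encoded as 0/0, 0/1, 1/1, ./.).
#' @param path output path.
#' @param table optional [allele_count_table()] supplying AD counts.
#' @export
write_vcf_lite <- function(records, path, table = NULL) {
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
               no_call = "./.")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">")
  gt_cols <- grep("^gt_", names(records), value = TRUE)
  samples <- sub("^gt_", "", gt_cols)
  head_cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO")
  if (length(samples)) head_cols <- c(head_cols, "FORMAT", samples)
  rows <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    fixed <- c(records$chrom[i], records$pos[i], ".", records$ref[i],
               records$alt[i], ".", "PASS", ".")
    if (length(samples)) {
      cells <- vapply(seq_along(samples), function(s) {
        gt <- gt_code[[records[[gt_cols[s]]][i]]]
        ad <- if (!is.null(table)) {
          si <- match(paste(records$chrom[i], records$pos[i]),
                      paste(table$sites$chrom, table$sites$pos))
          li <- match(samples[s], table$libraries$id)
          if (!is.na(si) && !is.na(li)) {
            paste(table$ref[si, li], table$alt[si, li], sep = ",")
          } else "."
        } else "."
        paste(gt, ad, sep = ":")
      }, "")
      fixed <- c(fixed, "GT:AD", cells)
    }
    rows[i] <- paste(fixed, collapse = "\t")
  }
  writeLines(c(hdr, paste(head_cols, collapse = "\t"), rows), path)
  invisible(path)
}

#' Read a minimal GT:AD VCF written by [write_vcf_lite()]
#'
#' @param path VCF path.
#' @return data.frame: `chrom`, `pos`, `ref`, `alt`, and per-sample
#'   genotype-class columns `gt_<sample>`.
#' @export
read_vcf_lite <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  head_i <- grep("^#CHROM", lines)
  if (!length(head_i)) stop("missing #CHROM header line")
  cols <- strsplit(lines[head_i], "\t")[[1]]
  body <- lines[-seq_len(head_i)]
  gt_decode <- c("0/0" = "hom_ref", "0/1" = "het", "1/0" = "het",
                 "1/1" = "hom_alt", "./." = "no_call")
  recs <- lapply(body, function(l) strsplit(l, "\t")[[1]])
  out <- data.frame(
    chrom = vapply(recs, `[[`, "", 1),
    pos = as.numeric(vapply(recs, `[[`, "", 2)),
    ref = vapply(recs, `[[`, "", 4),
    alt = vapply(recs, `[[`, "", 5),
    stringsAsFactors = FALSE
  )
  if (length(cols) > 9) {
    for (s in 10:length(cols)) {
      gts <- vapply(recs, function(r) strsplit(r[s], ":")[[1]][1], "")
      out[[paste0("gt_", cols[s])]] <- unname(gt_decode[gts])
    }
  }
  out
}

#' Write gene models as GFF3
#'
#' Uses rtracklayer for the format itself; each gene becomes
#' gene/mRNA/exon/CDS features.
#'
#' @param genes list of [gene_model()] objects.
#' @param path output path.
#' @export
write_gff3 <- function(genes, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("write_gff3 requires the rtracklayer package")
  }
  feats <- list()
  for (g in genes) {
    span <- gene_span(g)
    feats[[length(feats) + 1]] <- data.frame(
      chrom = g$chrom, start = span[1], end = span[2], type = "gene",
      strand = g$strand, ID = g$id, Parent = NA)
    feats[[length(feats) + 1]] <- data.frame(
      chrom = g$chrom, start = span[1], end = span[2], type = "mRNA",
      strand = g$strand, ID = paste0(g$id, ".t1"), Parent = g$id)
    for (i in seq_len(nrow(g$exons))) {
      feats[[length(feats) + 1]] <- data.frame(
        chrom = g$chrom, start = g$exons$start[i], end = g$exons$end[i],
        type = "exon", strand = g$strand, ID = NA,
        Parent = paste0(g$id, ".t1"))
    }
    # phase: leading CDS interval starts in frame 0; later intervals
    # carry the running codon offset
    lens <- g$cds$end - g$cds$start + 1
    phases <- cumsum(c(0, lens))[seq_len(nrow(g$cds))] %% 3
    if (g$strand == "-") phases <- rev(phases)
    for (i in seq_len(nrow(g$cds))) {
      feats[[length(feats) + 1]] <- data.frame(
        chrom = g$chrom, start = g$cds$start[i], end = g$cds$end[i],
        type = "CDS", strand = g$strand, ID = NA,
        Parent = paste0(g$id, ".t1"), phase = phases[i])
    }
  }
  for (i in seq_along(feats)) {
    if (is.null(feats[[i]]$phase)) feats[[i]]$phase <- NA_integer_
  }
  df <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand, type = df$type,
    phase = as.integer(df$phase),
    ID = df$ID, Parent = ifelse(is.na(df$Parent), NA, df$Parent))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Convert 1-based inclusive intervals to 0-based half-open BED
#'
#' @param df data.frame with `chrom`, `start`, `end` (1-based inclusive).
#' @return data.frame with BED columns `chrom`, `start` (0-based), `end`
#'   (exclusive); extra columns preserved.
#' @export
to_bed <- function(df) {
  out <- df
  out$start <- df$start - 1
  out
}

#' Convert 0-based half-open BED intervals to 1-based inclusive
#'
#' Exact inverse of [to_bed()].
#'
#' @param df data.frame with BED `chrom`, `start`, `end`.
#' @return data.frame with 1-based inclusive `start`, `end`.
#' @export
from_bed <- function(df) {
  out <- df
  out$start <- df$start + 1
  out
}

#' Write window statistics as native TSV and BED
#'
#' Writes `<stem>.tsv` (1-based inclusive) and `<stem>.bed` (0-based
#' half-open), clearly suffixed.
#'
#' @param windows a [window_scan()]/[zfst_transform()] result.
#' @param stem output path stem (without extension).
#' @export
write_windows <- function(windows, stem) {
  utils::write.table(windows, paste0(stem, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(to_bed(windows), paste0(stem, ".bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(stem)
}
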