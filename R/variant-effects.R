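#' Length of a 1-based inclusive interval
#'
#' All native coordinates in this package are 1-based and inclusive, so a
#' span covers `end - start + 1` bases (a single base has span 1).
#'
#' @param start,end 1-based inclusive coordinates, `start <= end`, both >= 1.
#' @return Span in bp.
#' @export
inclusive_span <- function(start, end) {
  if (any(start < 1) || any(end < 1)) stop("coordinates are 1-based (>= 1)")
  if (any(start > end)) stop("start must not exceed end")
  end - start + 1
}

#' Distance between two point positions
#'
#' Plain absolute difference `|b - a|` — the number of steps between two
#' points, NOT the inclusive span of the interval they bound (two positions
#' 5 bp apart span 6 bases). Both operations exist to keep the two
#' conventions from being silently conflated.
#'
#' @param pos_a,pos_b 1-based positions.
#' @return `|pos_b - pos_a|`.
#' @export
position_distance <- function(pos_a, pos_b) {
  if (any(pos_a < 1) || any(pos_b < 1)) stop("positions are 1-based (>= 1)")
  abs(pos_b - pos_a)
}

revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1]]),
        collapse = "")
}

complement <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

translate_cds <- function(cds) {
  n <- nchar(cds)
  if (n %% 3 != 0) stop("CDS length not divisible by 3")
  codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  aa <- Biostrings::GENETIC_CODE[codons]
  if (anyNA(aa)) stop("CDS contains non-ACGT characters")
  paste(aa, collapse = "")
}

#' Gene model with coding sequence
#'
#' A minimal transcript model: ordered non-overlapping exons, CDS intervals
#' within them, strand, and the reference coding sequence (mRNA
#' orientation, including the stop codon). The reference CDS must
#' translate without internal stops and end in a stop codon.
#'
#' @param id gene id.
#' @param chrom chromosome.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with `start`, `end` (1-based inclusive, sorted,
#'   non-overlapping).
#' @param cds data.frame with `start`, `end` CDS intervals (subset of exon
#'   space).
#' @param cds_seq reference coding sequence 5'->3' in mRNA orientation
#'   (character). Its length must equal the summed CDS interval lengths.
#' @return A `gene_model` object.
#' @export
gene_model <- function(id, chrom, strand = c("+", "-"), exons, cds, cds_seq) {
  strand <- match.arg(strand)
  stopifnot(is.data.frame(exons), is.data.frame(cds),
            all(c("start", "end") %in% names(exons)),
            all(c("start", "end") %in% names(cds)))
  exons <- exons[order(exons$start), , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  if (any(exons$start > exons$end) || any(cds$start > cds$end)) {
    stop("malformed intervals")
  }
  if (nrow(exons) > 1 &&
      any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop("exons overlap")
  }
  cds_len <- sum(cds$end - cds$start + 1)
  cds_seq <- toupper(cds_seq)
  if (nchar(cds_seq) != cds_len) {
    stop("cds_seq length (", nchar(cds_seq), ") does not match CDS intervals (",
         cds_len, ")")
  }
  prot <- translate_cds(cds_seq)
  n_aa <- nchar(prot)
  if (substr(prot, n_aa, n_aa) != "*") stop("CDS must end in a stop codon")
  if (grepl("\\*", substr(prot, 1, n_aa - 1))) {
    stop("reference CDS contains an internal stop")
  }
  structure(list(id = id, chrom = chrom, strand = strand, exons = exons,
                 cds = cds, cds_seq = cds_seq,
                 protein_length = n_aa - 1L),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d (%s), %d exon(s), protein %d aa\n",
              x$id, x$chrom, min(x$exons$start), max(x$exons$end), x$strand,
              nrow(x$exons), x$protein_length))
  invisible(x)
}

# 1-based index into the coding sequence (mRNA orientation) of a genomic
# position, or NA if the position is not in the CDS
cds_offset <- function(gene, pos) {
  cds <- gene$cds
  lens <- cds$end - cds$start + 1
  hit <- which(pos >= cds$start & pos <= cds$end)
  if (!length(hit)) return(NA_integer_)
  if (gene$strand == "+") {
    before <- if (hit > 1) sum(lens[seq_len(hit - 1)]) else 0
    as.integer(before + pos - cds$start[hit] + 1)
  } else {
    after <- if (hit < nrow(cds)) sum(lens[(hit + 1):nrow(cds)]) else 0
    as.integer(after + cds$end[hit] - pos + 1)
  }
}

gene_span <- function(gene) c(min(gene$exons$start), max(gene$exons$end))

#' Annotate a variant's coding consequence on a gene model
#'
#' SNVs in the CDS are classified by translating the affected codon before
#' and after the change (`synonymous`, `nonsynonymous`, `stopgain`,
#' `stoploss`); CDS indels are `frameshift_indel` when the length change is
#' not a multiple of 3, else `nonframeshift_indel`; exonic/intronic
#' non-CDS positions are `noncoding`; positions outside the gene span are
#' `upstream`/`downstream` (strand-aware) with their distance. All
#' annotation is strand-aware: on `-` genes the supplied plus-strand
#' ref/alt bases are complemented into mRNA space.
#'
#' @param gene a [gene_model()].
#' @param chrom,pos,ref,alt the variant (plus-strand alleles; indels as
#'   multi-base ref/alt strings).
#' @return list of class `effect_annotation`: `category`, `protein_change`,
#'   `codon_index`, `truncated_length` (stopgain only), `distance_bp`
#'   (up/downstream only).
#' @export
annotate_variant <- function(gene, chrom, pos, ref, alt) {
  stopifnot(inherits(gene, "gene_model"))
  if (chrom != gene$chrom) {
    stop("variant on ", chrom, " but gene model is on ", gene$chrom)
  }
  ref <- toupper(ref); alt <- toupper(alt)
  ann <- list(category = NA_character_, protein_change = NA_character_,
              codon_index = NA_integer_, truncated_length = NA_integer_,
              distance_bp = NA_real_)
  span <- gene_span(gene)
  if (pos < span[1] || pos > span[2]) {
    before <- pos < span[1]
    ann$category <- if ((before && gene$strand == "+") ||
                        (!before && gene$strand == "-")) "upstream" else "downstream"
    ann$distance_bp <- if (before) span[1] - pos else pos - span[2]
    class(ann) <- "effect_annotation"
    return(ann)
  }
  off <- cds_offset(gene, pos)
  is_indel <- nchar(ref) != nchar(alt)
  if (is.na(off)) {
    ann$category <- "noncoding"
    class(ann) <- "effect_annotation"
    return(ann)
  }
  if (is_indel) {
    shift <- abs(nchar(ref) - nchar(alt)) %% 3
    ann$category <- if (shift != 0) "frameshift_indel" else "nonframeshift_indel"
    ann$codon_index <- as.integer((off - 1) %/% 3 + 1)
    class(ann) <- "effect_annotation"
    return(ann)
  }
  if (nchar(ref) != 1 || nchar(alt) != 1) stop("MNVs are not supported")
  ref_mrna <- if (gene$strand == "+") ref else complement(ref)
  alt_mrna <- if (gene$strand == "+") alt else complement(alt)
  if (substr(gene$cds_seq, off, off) != ref_mrna) {
    stop("reference allele mismatch at ", chrom, ":", pos,
         " (model has ", substr(gene$cds_seq, off, off),
         ", variant ref is ", ref_mrna, " in mRNA space)")
  }
  codon_index <- (off - 1) %/% 3 + 1
  cstart <- (codon_index - 1) * 3 + 1
  codon_ref <- substr(gene$cds_seq, cstart, cstart + 2)
  codon_alt <- codon_ref
  substr(codon_alt, off - cstart + 1, off - cstart + 1) <- alt_mrna
  aa_ref <- unname(Biostrings::GENETIC_CODE[codon_ref])
  aa_alt <- unname(Biostrings::GENETIC_CODE[codon_alt])
  ann$codon_index <- as.integer(codon_index)
  ann$protein_change <- paste0(aa_ref, codon_index, aa_alt)
  ann$category <- if (aa_ref == aa_alt) {
    "synonymous"
  } else if (aa_alt == "*") {
    "stopgain"
  } else if (aa_ref == "*") {
    "stoploss"
  } else {
    "nonsynonymous"
  }
  if (ann$category == "stopgain") {
    ann$truncated_length <- as.integer(codon_index - 1)
  }
  class(ann) <- "effect_annotation"
  ann
}

#' Residues retained by a stopgain variant
#'
#' Number of complete codons 5' of (and excluding) the premature stop: a
#' stopgain at codon `k` leaves `k - 1` residues.
#'
#' @inheritParams annotate_variant
#' @return Integer residue count (strictly less than the reference protein
#'   length).
#' @export
truncated_protein_length <- function(gene, chrom, pos, ref, alt) {
  ann <- annotate_variant(gene, chrom, pos, ref, alt)
  if (!identical(ann$category, "stopgain")) {
    stop("not a stopgain variant (category: ", ann$category, ")")
  }
  if (ann$truncated_length >= gene$protein_length) {
    stop("not a truncation: new stop does not shorten the protein")
  }
  ann$truncated_length
}

#' Severity ranking of effect categories
#'
#' Rank 1 = protein-truncating (stopgain, stoploss, frameshift), rank 2 =
#' other coding changes, rank 3 = everything else. Used by candidate
#' prioritization.
#'
#' @param category character vector of effect categories.
#' @return Integer severity ranks.
#' @export
effect_severity <- function(category) {
  r <- rep(3L, length(category))
  r[category %in% c("stopgain", "stoploss", "frameshift_indel")] <- 1L
  r[category %in% c("nonsynonymous", "nonframeshift_indel")] <- 2L
  r
}
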