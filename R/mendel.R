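#' Single-locus cross hypotheses
#'
#' Two genetic models explain a 3:1 normal:affected F2 from two unaffected
#' parents at a single autosomal locus:
#'
#' * `recessive_causal` — the affected phenotype is caused by a recessive
#'   allele *a*; both parents are *Aa* and affected offspring are *aa*.
#' * `dominant_inhibitor` — the whole population is fixed for the causal
#'   mutation, but a dominant inhibitor allele *B* suppresses the phenotype;
#'   both parents are *Bb* and affected offspring are *bb* (no inhibitor).
#'
#' In both cases the locus tracked in the pooled data is the segregating
#' allele (*a* or *B*): parents are heterozygous and the phenotype pools
#' have sharply different expected frequencies of it.
#'
#' @param name `"recessive_causal"` or `"dominant_inhibitor"`.
#' @return A `cross_hypothesis` object.
#' @export
cross_hypothesis <- function(name = c("recessive_causal", "dominant_inhibitor")) {
  name <- match.arg(name)
  structure(
    list(
      name = name,
      parental_genotype = "het",
      # affected iff alternate dosage satisfies the rule
      affected_rule = if (name == "recessive_causal") {
        function(dosage) dosage == 2L
      } else {
        function(dosage) dosage == 0L
      }
    ),
    class = "cross_hypothesis"
  )
}

as_hypothesis <- function(h) {
  if (inherits(h, "cross_hypothesis")) h else cross_hypothesis(h)
}

#' Expected frequency of the segregating allele in each library role
#'
#' For an F2 from two heterozygous parents (offspring 1/4 : 1/2 : 1/4 hom
#' ref : het : hom alt), the expected frequency of the segregating allele
#' in each phenotype-defined pool:
#'
#' * recessive causal: parent 1/2, affected pool 1 (all *aa*), unaffected
#'   pool 1/3 (*AA*:*Aa* = 1:2).
#' * dominant inhibitor: parent 1/2, affected pool 0 (no *B*), unaffected
#'   pool 2/3 (*BB*:*Bb* = 1:2 among carriers).
#'
#' @param hypothesis a [cross_hypothesis()] or its name.
#' @param library_role one of `"parent"`, `"affected_pool"`,
#'   `"unaffected_pool"`.
#' @return Expected allele frequency in `[0, 1]`.
#' @export
expected_pool_allele_freq <- function(hypothesis, library_role) {
  h <- as_hypothesis(hypothesis)
  role <- match.arg(library_role,
                    c("parent", "affected_pool", "unaffected_pool"))
  if (role == "parent") return(1 / 2)
  if (h$name == "recessive_causal") {
    if (role == "affected_pool") 1 else 1 / 3
  } else {
    if (role == "affected_pool") 0 else 2 / 3
  }
}

#' Theoretical allele-frequency difference (dAF) between phenotype pools
#'
#' Absolute difference of the expected segregating-allele frequency between
#' the affected and unaffected pools; 2/3 under both single-locus
#' hypotheses, which is why a dAF filter separates the causal locus from
#' unlinked background.
#'
#' @inheritParams expected_pool_allele_freq
#' @return The absolute expected dAF (2/3 under both hypotheses).
#' @export
theoretical_daf <- function(hypothesis) {
  abs(expected_pool_allele_freq(hypothesis, "affected_pool") -
        expected_pool_allele_freq(hypothesis, "unaffected_pool"))
}

#' Segregation-ratio goodness-of-fit test
#'
#' Pearson chi-square test (1 df, no continuity correction) of observed
#' affected/unaffected counts against an expected ratio, by default the
#' 1:3 of a fully penetrant recessive in an F2.
#'
#' @param n_affected,n_unaffected observed counts.
#' @param ratio length-2 numeric weights, affected:unaffected.
#' @return A list of class `segregation_test` with `observed`, `expected`,
#'   `ratio`, `chi2`, `df`, `p`.
#' @export
segregation_chi2 <- function(n_affected, n_unaffected, ratio = c(1, 3)) {
  stopifnot(length(ratio) == 2, all(ratio > 0),
            n_affected >= 0, n_unaffected >= 0)
  total <- n_affected + n_unaffected
  if (total == 0) stop("no observations")
  ct <- suppressWarnings(
    stats::chisq.test(c(n_affected, n_unaffected), p = ratio / sum(ratio),
                      correct = FALSE)
  )
  structure(
    list(
      observed = c(affected = n_affected, unaffected = n_unaffected),
      expected = unname(ct$expected),
      ratio = ratio,
      chi2 = unname(ct$statistic),
      df = unname(ct$parameter),
      p = unname(ct$p.value)
    ),
    class = "segregation_test"
  )
}

#' @export
print.segregation_test <- function(x, ...) {
  cat(sprintf(
    "Segregation test %d:%d observed vs %g:%g expected: chi2 = %.4g (df = %d), p = %.4g\n",
    x$observed[1], x$observed[2], x$ratio[1], x$ratio[2], x$chi2, x$df, x$p))
  invisible(x)
}

#' Genotype-phenotype concordance under the recessive model
#'
#' Cross-tabulates diagnostic genotype calls against binary phenotypes and
#' reports whether they are perfectly concordant with a fully penetrant
#' recessive mutation: every affected individual homozygous alternate and
#' no unaffected individual homozygous alternate. `no_call` genotypes are
#' excluded from the verdict but counted.
#'
#' @param genotype_calls character vector in
#'   `c("hom_ref", "het", "hom_alt", "no_call")`.
#' @param phenotypes character vector in `c("affected", "unaffected")`.
#' @return A list of class `concordance_report` with the cross-tabulation
#'   (`table`), `concordant` flag, `discordant` index vector, `n_no_call`,
#'   and `vacuous` flag (TRUE when no informative calls were available).
#' @export
diagnostic_concordance <- function(genotype_calls, phenotypes) {
  if (length(genotype_calls) != length(phenotypes)) {
    stop("genotype_calls and phenotypes must have equal length")
  }
  gt_levels <- c("hom_ref", "het", "hom_alt", "no_call")
  ph_levels <- c("affected", "unaffected")
  if (!all(genotype_calls %in% gt_levels)) stop("unknown genotype class")
  if (!all(phenotypes %in% ph_levels)) stop("unknown phenotype")
  g <- factor(genotype_calls, levels = gt_levels)
  p <- factor(phenotypes, levels = ph_levels)
  tab <- table(genotype = g, phenotype = p)
  informative <- genotype_calls != "no_call"
  bad <- which(informative &
                 ((phenotypes == "affected" & genotype_calls != "hom_alt") |
                    (phenotypes == "unaffected" & genotype_calls == "hom_alt")))
  structure(
    list(
      table = tab,
      concordant = length(bad) == 0,
      discordant = bad,
      n_no_call = sum(!informative),
      vacuous = !any(informative)
    ),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  print(x$table)
  cat("concordant with recessive model:", x$concordant,
      if (x$vacuous) "(vacuous: no informative calls)" else "", "\n")
  if (length(x$discordant)) {
    cat("discordant individuals:", paste(x$discordant, collapse = ", "), "\n")
  }
  invisible(x)
}
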