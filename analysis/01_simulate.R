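#!/usr/bin/env Rscript
# Stage 1 — simulate the mapping experiment.
#
# One seeded synthetic study: two het x het F2 crosses (629 offspring
# each) segregating a recessive causal SNP at chr1:12,500,000, phenotype
# pools (59/64 affected, 80 unaffected) sequenced at 30x, three parents
# at 10x, and fifty 4x individuals from 5 farms (farms 1-2 share the
# causal haplotype). Writes the library manifest, the simulated truth,
# and a small excerpt of the allele-count table; heavy per-site tables
# are regenerated by later stages rather than stored.

library(recmap)

seed <- 2L
dir.create("results", showWarnings = FALSE)
ex <- simulate_experiment(sim_config(seed = seed))

wt <- function(x, f) write.table(x, file.path("results", f), sep = "\t",
                                 quote = FALSE, row.names = FALSE)

wt(ex$table$libraries, "library_manifest.tsv")
wt(cbind(ex$truth$causal, gene = ex$truth$causal_gene), "truth_causal.tsv")
wt(ex$truth$gene_truth, "truth_genes.tsv")

# 60-site excerpt around the causal locus, in sync format
ci <- which(ex$founders$sites$is_causal)
keep <- max(1, ci - 30):min(nrow(ex$founders$sites), ci + 29)
excerpt <- allele_count_table(ex$table$sites[keep, ],
                              ex$table$ref[keep, , drop = FALSE],
                              ex$table$alt[keep, , drop = FALSE],
                              ex$table$libraries)
write_sync(excerpt, "results/causal_region_excerpt.sync")

aff <- vapply(ex$crosses, function(cr) sum(cr$phenotype == "affected"), 0)
tot <- vapply(ex$crosses, function(cr) length(cr$phenotype), 0)
cat(sprintf("seed %d: cross1 %d/%d affected, cross2 %d/%d affected\n",
            seed, aff[1], tot[1], aff[2], tot[2]))
cat(sprintf("causal SNP %s:%d %s>%s in gene %s\n",
            ex$truth$causal$chrom, ex$truth$causal$pos,
            ex$truth$causal$ref, ex$truth$causal$alt,
            ex$truth$causal_gene))
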