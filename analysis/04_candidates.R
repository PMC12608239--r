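#!/usr/bin/env Rscript
# Stage 4 — segregation-pattern candidate mutations.
#
# Within the candidate regions, retain variants with dAF > 0.5 between
# the pools that are heterozygous in both parents and the unaffected
# pool and homozygous (either direction) in the affected pool, then
# intersect the two crosses.

library(recmap)

cfg <- run_config(sim_config(seed = 2L))
ex <- simulate_experiment(cfg$sim)
regions <- read.delim("results/candidate_regions.tsv")

keep <- rep(FALSE, nrow(ex$table$sites))
for (i in seq_len(nrow(regions))) {
  keep <- keep | (ex$table$sites$chrom == regions$chrom[i] &
                    ex$table$sites$pos >= regions$start[i] &
                    ex$table$sites$pos <= regions$end[i])
}
reg_tab <- allele_count_table(ex$table$sites[keep, ],
                              ex$table$ref[keep, , drop = FALSE],
                              ex$table$alt[keep, , drop = FALSE],
                              ex$table$libraries)

cand <- list()
for (cr in 1:2) {
  cand[[cr]] <- candidate_mutation_filter(
    reg_tab,
    cross_libraries(c("NEM", paste0("NEF", cr)),
                    paste0("Pool_CE", cr), paste0("Pool_NE", cr)),
    daf_min = cfg$daf_min)
  cat(sprintf("cross %d: %d candidate mutations in %d region-restricted sites\n",
              cr, nrow(cand[[cr]]), nrow(reg_tab$sites)))
}
shared <- intersect_crosses(cand[[1]], cand[[2]])
cat(sprintf("shared between crosses: %d (causal retained: %s)\n",
            nrow(shared), any(shared$pos == cfg$sim$causal_pos)))
write.table(shared[, c("chrom", "pos", "ref", "alt", "daf", "daf_cross2")],
            "results/candidate_mutations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
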