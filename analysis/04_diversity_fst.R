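#!/usr/bin/env Rscript
# Diversity parameters (gene diversity, mean pairwise differences,
# nucleotide diversity, with standard deviations) for the modern
# populations, and the pairwise FST matrix with 1023-permutation p-values
# and a Bonferroni-adjusted significance level. Requires
# results/haplotypes.tsv.

library(mtcontinuity)

pops <- read_haplotype_table("results/haplotypes.tsv")
moderns <- pops[c("LG", "AL")]

div <- do.call(rbind, lapply(moderns, diversity_summary))
print(div, digits = 4)
write.table(div, "results/diversity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# FST with estimates above the diagonal and permutation p-values below it;
# alpha 0.05 Bonferroni-corrected inside pairwise_fst_matrix
m <- pairwise_fst_matrix(moderns, n_perm = 1023, seed = 4)
print(round(m, 4))
write.table(cbind(population = rownames(m), as.data.frame(m)),
            "results/fst_matrix.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("modern-pair FST = %.4f (p = %.4f, 1023 permutations)",
                m[1, 2], m[2, 1]))
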