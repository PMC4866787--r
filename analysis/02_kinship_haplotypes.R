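#!/usr/bin/env Rscript
# Shared-haplotype / kinship screening of the ancient sample, and the
# ancient-vs-modern haplotype comparison for the J1c2 lineage cluster.
# Requires results/haplotypes.tsv from 01_simulate_dataset.R.

library(mtcontinuity)

pops <- read_haplotype_table("results/haplotypes.tsv")
anc <- pops$LH

groups <- shared_haplotype_groups(anc)
write.table(groups, "results/shared_groups.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
shared <- table(groups$group)
message(sprintf("%d ancient samples fall into %d haplotype groups; %d groups observed more than once (%d of them on partial-evidence ranges)",
                nrow(groups), length(shared), sum(shared > 1),
                length(unique(groups$group[groups$partial_evidence & groups$group %in%
                                           as.integer(names(shared[shared > 1]))]))))

# the classic ancient/modern comparison: an ancient J1c2 haplotype against a
# modern relative carrying two additional HVS-I substitutions
cr <- list(circular_range(16024, 576))
ancient <- parse_motif("16069T, 16126C, 73G, 185A, 188G, 228A, 263G, 295T",
                       cr, "ancient_J1c2")
modern <- parse_motif("16069T, 16126C, 16278T, 16366T, 73G, 185A, 188G, 228A, 263G, 295T",
                      cr, "modern_J1c2")
message(sprintf("ancient J1c2 classifies as %s; distance to the modern J1c2 haplotype over the common range: %d (16278, 16366)",
                classify_haplogroup(ancient)$label,
                haplotype_distance(ancient, modern)))
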