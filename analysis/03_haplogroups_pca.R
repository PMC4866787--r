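#!/usr/bin/env Rscript
# Haplogroup composition of the built-in ancient example population (with
# the kin merge) and of the simulated modern populations; PCA on the basal
# haplogroup frequencies. Requires results/haplotypes.tsv and
# results/coding_calls.json.

library(mtcontinuity)

fx <- ancient_lineage_fixture()
freq <- haplogroup_frequencies(fx$pop, coding = fx$coding,
                               merge_groups = fx$merge_groups)
message("ancient example population (", attr(freq, "n"), " lineages after kin merge):")
print(freq)
write.table(freq, "results/ancient_haplogroups.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

pops <- read_haplotype_table("results/haplotypes.tsv")
coding <- lapply(jsonlite::read_json("results/coding_calls.json"), unlist)
tree <- load_haplogroup_tree()
basal <- lapply(c(LH = "LH", LG = "LG", AL = "AL"), function(nm) {
  haplogroup_frequencies(pops[[nm]], coding = coding, tier = "basal",
                         tree = tree)
})
labels <- sort(unique(unlist(lapply(basal, `[[`, "label"))))
m <- t(vapply(basal, function(f) {
  setNames(ifelse(is.na(match(labels, f$label)), 0,
                  f$frequency[match(labels, f$label)]), labels)
}, numeric(length(labels))))
pca <- haplogroup_pca(m)
message(sprintf("PCA on basal haplogroup frequencies: PC1+PC2 explain %.1f%% of the variance",
                100 * pca$pc12_share))
jsonlite::write_json(list(frequencies = as.data.frame(m),
                          scores = as.data.frame(pca$scores),
                          explained = pca$explained),
                     "results/haplogroup_pca.json", auto_unbox = TRUE,
                     digits = NA)
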