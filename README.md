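# mtcontinuity

Tools for testing **maternal genetic continuity** between an ancient human
population and present-day populations from mitochondrial DNA
control-region data.

Ancient-DNA studies of burial sites routinely ask whether the people
interred there have maternal descendants among today's local inhabitants.
The evidence is mtDNA control-region haplotypes: ancient samples with
partial, heterogeneous sequence coverage (HVS-I/II, sometimes HVS-III),
modern samples with the complete control region (rCRS positions
16024–576). `mtcontinuity` implements the whole analytical chain:

* **Haplotype handling under partial coverage** — rCRS-relative motif
  parsing (`16069T`, `309.1C`, `249del`), circular edition ranges,
  distances restricted to common coverage with the conventional exclusion
  of poly-C length variants (16193, 309, 573), IUPAC heteroplasmy codes
  compared conservatively, shared-haplotype/kinship grouping with a
  partial-evidence flag.
* **Haplogroup classification** — motif matching down a curated reduced
  phylogeny plus minisequencing coding-region diagnostics (G3010A for H1,
  A6776G for H3, …, 7028/11467 as H/U discriminators), `*`-style
  uncertainty labels for partially covered samples (`J1*`, `U5b*`), basal
  collapsing for cross-dataset comparison.
* **Population statistics** — gene diversity H, mean pairwise differences
  π, nucleotide diversity π_n (each with standard deviations), AMOVA-based
  pairwise F\_ST with 1023-permutation p-values and Bonferroni-corrected
  significance, Pearson chi-square tests (no continuity correction), PCA
  on haplogroup frequency tables.
* **ABC model choice** — a serial-sampling (heterochronous) coalescent
  simulator over demographic scenarios with HKY85 sequence evolution
  (pairwise coalescence rate 1/N_e for haploid mtDNA; μ ~ U(10⁻⁸, 10⁻⁶)
  per site per generation), pairwise-F\_ST summary statistics, rejection +
  local logistic-regression posterior probabilities for a *genealogical
  continuity* versus *genealogical independence* scenario, PCA
  pre-evaluation, and type I/II error estimation from pseudo-observed
  datasets.
* **Synthetic data** — a generator that emulates the study structure
  (25 ancient / 51 + 56 modern samples, haplogroup backbone, kin clusters,
  degraded ancient coverage) so every stage is testable without downloads.

## Worked example

```r
library(mtcontinuity)

# An ancient haplotype printed the way control-region studies report them:
cr <- list(circular_range(16024, 576))
ancient <- parse_motif("16069T, 16126C, 73G, 185A, 188G, 228A, 263G, 295T",
                       cr, "LHY099")
classify_haplogroup(ancient)$label
#> [1] "J1c2"

# ...and its closest modern relative, two HVS-I steps away:
modern <- parse_motif(
  "16069T, 16126C, 16278T, 16366T, 73G, 185A, 188G, 228A, 263G, 295T",
  cr, "LG003")
haplotype_distance(ancient, modern)
#> [1] 2

# Haplogroup bookkeeping on the bundled synthetic ancient example
# (25 typed samples, one kin pair counted once):
fx <- ancient_lineage_fixture()
f <- haplogroup_frequencies(fx$pop, coding = fx$coding,
                            merge_groups = fx$merge_groups, tier = "basal")
setNames(f$count, f$label)
#>  H  J  K U5  W
#>  9  8  1  5  1
attr(f, "n")
#> [1] 24

# Did adult and infant burials differ in DNA recovery? (2/8 vs 4/33 above
# the quantification detection limit)
chi_square_2x2(matrix(c(2, 6, 4, 29), 2, byrow = TRUE))$p
#> [1] 0.3551681
```

The numbers mean: the printed ancient haplotype carries the full J1c2
motif; its modern counterpart differs only at 16278 and 16366; the ancient
sample resolves to 24 maternal lineages dominated by H (9) and J (8); and
adult/infant DNA recovery does not differ significantly (p = 0.355).

The `analysis/` directory holds the numbered end-to-end workflow
(`01_simulate_dataset.R` … `05_abc_model_choice.R`): simulate a study-like
dataset, screen for kin, classify and ordinate haplogroups, compute
diversity and F\_ST, and run the ABC scenario choice. Each script prints
what it found and writes its tables under `results/`.

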