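# Built-in example dataset: a synthetic Iron Age-like burial population.

#' Synthetic ancient-population example dataset
#'
#' A constructed example of an ancient mtDNA study sample: 25 typed
#' individuals with partial control-region coverage (HVS-I/HVS-II, some with
#' reduced edition ranges), haplogroup composition H1:6, H3:3, J1:2 (one
#' probable kin pair from a shared burial context, counted as a single
#' lineage), J1c1:2, J1c2:5, K2a5:1, U5a1b1:2, U5b:1, U5b1c1a:2, W:1 —
#' 24 maternal lineages after the kin merge. Motifs are synthetic: founder
#' motifs from the embedded haplogroup tree plus fabricated private
#' variants; R0-derived samples carry full minisequencing call sets. The two
#' J1 samples and one U5b sample have edition ranges that leave a deeper
#' diagnostic position unobserved, so they classify with the `*` uncertainty
#' suffix, as is typical for partially covered ancient samples.
#'
#' @return list with `pop` (a `population_sample`), `coding` (per-sample
#'   coding call sets), `merge_groups` (kin pairs counted once) and
#'   `expected_counts` (named lineage counts after the kin merge)
#' @export
ancient_lineage_fixture <- function() {
  hvs12 <- list(circular_range(16024L, 16383L), circular_range(57L, 372L))
  hvs12_long <- list(circular_range(16024L, 16420L), circular_range(57L, 372L))
  j1_partial <- list(circular_range(16024L, 16383L), circular_range(190L, 372L))
  u5b_partial <- list(circular_range(16200L, 16383L), circular_range(57L, 372L))
  hvs123 <- list(circular_range(16024L, 16383L), circular_range(57L, 372L),
                 circular_range(438L, 576L))

  h_panel <- function(path_calls) {
    calls <- CODING_ANCESTRAL[setdiff(names(CODING_ANCESTRAL), "11467")]
    calls[names(path_calls)] <- path_calls
    calls
  }
  spec <- list(
    # H1: six individuals, distinct private HVS-I variants
    list(id = "LHY101", motif = "16093C, 263G", cov = hvs12,
         calls = h_panel(c(`7028` = "C", `3010` = "A"))),
    list(id = "LHY102", motif = "16129A, 263G", cov = hvs12,
         calls = h_panel(c(`7028` = "C", `3010` = "A"))),
    list(id = "LHY103", motif = "16162G, 263G", cov = hvs12,
         calls = h_panel(c(`7028` = "C", `3010` = "A"))),
    list(id = "LHY104", motif = "16209C, 263G", cov = hvs12,
         calls = h_panel(c(`7028` = "C", `3010` = "A"))),
    list(id = "LHY105", motif = "16356C, 263G", cov = hvs12,
         calls = h_panel(c(`7028` = "C", `3010` = "A"))),
    list(id = "LHY106", motif = "263G, 152C", cov = hvs12,
         calls = h_panel(c(`7028` = "C", `3010` = "A"))),
    # H3: three individuals
    list(id = "LHY111", motif = "263G", cov = hvs12,
         calls = h_panel(c(`7028` = "C", `6776` = "G"))),
    list(id = "LHY112", motif = "16304C, 263G", cov = hvs12,
         calls = h_panel(c(`7028` = "C", `6776` = "G"))),
    list(id = "LHY113", motif = "16245T, 263G", cov = hvs12,
         calls = h_panel(c(`7028` = "C", `6776` = "G"))),
    # J1 kin pair (same burial group, identical haplotype, 185 unobserved)
    list(id = "LHY235", motif = "16069T, 16126C, 228A, 263G, 295T",
         cov = j1_partial, calls = NULL),
    list(id = "LHY236", motif = "16069T, 16126C, 228A, 263G, 295T",
         cov = j1_partial, calls = NULL),
    # J1c1
    list(id = "LHY121", motif = "16069T, 16126C, 16261T, 73G, 185A, 228A, 263G, 295T",
         cov = hvs12, calls = NULL),
    list(id = "LHY122", motif = "16069T, 16126C, 16261T, 16311C, 73G, 185A, 228A, 263G, 295T",
         cov = hvs12, calls = NULL),
    # J1c2 (LHY099/LHY181: identical haplotype, different burials)
    list(id = "LHY099", motif = "16069T, 16126C, 73G, 185A, 188G, 228A, 263G, 295T, 309.1C, 315.1C",
         cov = hvs12, calls = NULL),
    list(id = "LHY181", motif = "16069T, 16126C, 73G, 185A, 188G, 228A, 263G, 295T, 309.1C, 315.1C",
         cov = hvs12, calls = NULL),
    list(id = "LHY131", motif = "16069T, 16126C, 16145A, 73G, 185A, 188G, 228A, 263G, 295T",
         cov = hvs12, calls = NULL),
    list(id = "LHY132", motif = "16069T, 16126C, 16231C, 73G, 185A, 188G, 228A, 263G, 295T",
         cov = hvs12, calls = NULL),
    list(id = "LHY133", motif = "16069T, 16126C, 73G, 146C, 185A, 188G, 228A, 263G, 295T",
         cov = hvs12, calls = NULL),
    # K2a5 (HVS-III also sequenced, excluding K1a's 497 diagnostic)
    list(id = "LHY141", motif = "16148T, 16224C, 16311C, 16352C, 73G, 263G",
         cov = hvs123, calls = c(`11467` = "G")),
    # U5a1b1 (edition range extended past 16383 to cover 16399)
    list(id = "LHY151", motif = "16256C, 16270T, 16399G, 73G, 263G",
         cov = hvs12_long, calls = c(`11467` = "G")),
    list(id = "LHY152", motif = "16114T, 16256C, 16270T, 16399G, 73G, 263G",
         cov = hvs12_long, calls = c(`11467` = "G")),
    # U5b with 16189 unobserved -> U5b*
    list(id = "LHY161", motif = "16270T, 73G, 150T, 263G",
         cov = u5b_partial, calls = c(`11467` = "G")),
    # U5b1c1a
    list(id = "LHY171", motif = "16189C, 16270T, 73G, 150T, 263G",
         cov = hvs12, calls = c(`11467` = "G")),
    list(id = "LHY172", motif = "16189C, 16192T, 16270T, 73G, 150T, 263G",
         cov = hvs12, calls = c(`11467` = "G")),
    # W
    list(id = "LHY191", motif = "16223T, 16292T, 73G, 204C, 263G",
         cov = hvs12, calls = NULL)
  )
  haps <- lapply(spec, function(s) parse_motif(s$motif, s$cov, s$id))
  coding <- stats::setNames(lapply(spec, `[[`, "calls"),
                            vapply(spec, `[[`, character(1), "id"))
  coding <- coding[!vapply(coding, is.null, logical(1))]
  list(pop = population_sample("LH", haps, age_generations = 96),
       coding = coding,
       merge_groups = list(c("LHY235", "LHY236")),
       expected_counts = c(`H1` = 6L, `H3` = 3L, `J1*` = 1L, `J1c1` = 2L,
                           `J1c2` = 5L, `K2a5` = 1L, `U5a1b1` = 2L,
                           `U5b*` = 1L, `U5b1c1a` = 2L, `W` = 1L))
}
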