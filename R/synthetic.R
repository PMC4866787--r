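# Synthetic study-like datasets: haplogroup backbone founders plus private
# control-region mutations, kin clusters of identical haplotypes, and
# partial-coverage degradation mimicking ancient-DNA edition ranges.

# Conventional hypervariable-segment bounds used by the coverage model.
HVS_SEGMENTS <- list(
  HVS1 = c(16024L, 16383L),
  HVS2 = c(57L, 372L),
  HVS3 = c(438L, 576L)
)

#' Template describing a study-like dataset to synthesize
#'
#' The default emulates the structure of an ancient/modern control-region
#' study: one ancient population (25 typed samples at 96 generations before
#' present, partial HVS coverage, one kin cluster of two identical
#' haplotypes) and two modern populations (51 and 56 samples, complete
#' control region). Backbone haplogroup frequencies follow the haplogroup
#' spectrum typical of northern Iberian datasets (H1/H3/J1c/U5-dominated).
#'
#' @param populations data.frame with columns `name`, `n`, `age_generations`
#'   and `coverage` (`"full"` or `"partial"`)
#' @param backbone named haplogroup frequencies (names must be tree nodes)
#' @param private_rate Poisson mean of private control-region substitutions
#'   per lineage
#' @param kin_clusters named list: per population, integer vector of cluster
#'   sizes (each cluster shares one exact haplotype); `NULL` places one pair
#'   in the first partial-coverage population
#' @param coverage_model for `"partial"` populations: list with per-segment
#'   retention probabilities `p_hvs1`, `p_hvs2`, `p_hvs3` and `trunc_width`
#'   (maximal uniform truncation, in sites, at each retained segment end)
#' @param seed integer seed making generation deterministic
#' @return object of class `study_template`
#' @export
study_template <- function(
    populations = data.frame(
      name = c("LH", "LG", "AL"),
      n = c(25L, 51L, 56L),
      age_generations = c(96, 0, 0),
      coverage = c("partial", "full", "full"),
      stringsAsFactors = FALSE),
    backbone = c(H1 = 0.25, H3 = 0.12, HV0 = 0.05, J1c1 = 0.08, J1c2 = 0.18,
                 K2a5 = 0.04, T = 0.06, U5a1b1 = 0.08, U5b1c1a = 0.08,
                 W = 0.03, X2 = 0.03),
    private_rate = 2,
    kin_clusters = NULL,
    coverage_model = list(p_hvs1 = 0.9, p_hvs2 = 0.95, p_hvs3 = 0.25,
                          trunc_width = 60L),
    seed = 1L) {
  stopifnot(all(populations$n > 0L),
            abs(sum(backbone) - 1) < 1e-9,
            private_rate >= 0)
  if (is.null(kin_clusters)) {
    # default: one identical-haplotype pair in the first partial-coverage
    # population (mimics a probable kin burial), none elsewhere
    partial <- populations$name[populations$coverage == "partial"]
    kin_clusters <- if (length(partial)) stats::setNames(list(2L), partial[1])
                    else list()
  }
  for (nm in names(kin_clusters)) {
    stopifnot(nm %in% populations$name,
              sum(kin_clusters[[nm]]) <= populations$n[populations$name == nm])
  }
  structure(list(populations = populations, backbone = backbone,
                 private_rate = private_rate, kin_clusters = kin_clusters,
                 coverage_model = coverage_model, seed = as.integer(seed)),
            class = "study_template")
}

# Accumulated control-region motif from the root down to a node.
node_full_motif <- function(tree, name) {
  rows <- list()
  cur <- name
  while (!is.na(cur)) {
    rows[[length(rows) + 1L]] <- tree$nodes[[cur]]$own_motif
    cur <- tree$nodes[[cur]]$parent
  }
  out <- do.call(rbind, rev(rows))
  if (is.null(out)) empty_variants() else out
}

# Coding calls that type a sample unambiguously: derived bases along the
# path, ancestral bases at off-path panel diagnostics in the same subtree.
CODING_ANCESTRAL <- c(`3010` = "G", `11377` = "C", `4769` = "C", `6776` = "A",
                      `3992` = "C", `456` = "G", `3915` = "C", `4793` = "T",
                      `13101` = "A", `13020` = "T", `14470` = "T",
                      `8448` = "A", `3936` = "C", `4745` = "A", `6253` = "T",
                      `7028` = "T", `11467` = "A")

node_coding_calls <- function(tree, name) {
  path <- character(0); cur <- name
  while (!is.na(cur)) { path <- c(path, cur); cur <- tree$nodes[[cur]]$parent }
  calls <- character(0)
  in_r0 <- any(path %in% c("H", "R0"))
  in_u <- "U" %in% path
  if (!in_r0 && !in_u) return(calls)
  for (nm in names(tree$nodes)) {
    cd <- tree$nodes[[nm]]$own_coding
    if (!nrow(cd)) next
    on_path <- nm %in% path
    relevant <- if (in_r0) TRUE else nm %in% c("U")  # U-subtree: 11467 only
    if (!relevant && !on_path) next
    for (i in seq_len(nrow(cd))) {
      key <- as.character(cd$position[i])
      calls[key] <- if (on_path) cd$base[i] else CODING_ANCESTRAL[[key]]
    }
  }
  calls
}

#' Generate a backbone dataset from a study template
#'
#' Each sample draws a haplogroup from the backbone frequencies, inherits
#' the accumulated control-region founder motif of that haplogroup, and
#' receives a Poisson number of private substitutions at positions that are
#' neither defining positions of any backbone haplogroup nor poly-C anchor
#' sites, so classification stays unambiguous. Kin clusters share one exact
#' haplotype. Partial-coverage populations are degraded through
#' [degrade_coverage()]. Deterministic under the template seed.
#'
#' @param template a [study_template()]
#' @param tree a `haplogroup_tree`
#' @return list with `populations` (named list of `population_sample`),
#'   `coding` (per-sample coding call sets), `truth` (data.frame
#'   `sample_id`, `population`, `haplogroup`, `kin_group`)
#' @export
generate_backbone_dataset <- function(template, tree = load_haplogroup_tree()) {
  stopifnot(all(names(template$backbone) %in% names(tree$nodes)))
  set.seed(template$seed)
  cr <- circular_range(16024L, 576L)
  reserved <- unique(unlist(lapply(names(tree$nodes), function(nm) {
    tree$nodes[[nm]]$own_motif$position
  })))
  anchors <- c(16193L, 309L, 573L, 315L)  # length-variant anchors kept clean
  candidate_sites <- setdiff(range_positions(cr), c(reserved, anchors))

  pops <- list(); coding <- list(); truth <- list()
  for (pi in seq_len(nrow(template$populations))) {
    pop_spec <- template$populations[pi, ]
    n <- pop_spec$n
    clusters <- template$kin_clusters[[pop_spec$name]]
    # lineage plan: one founder draw per independent lineage, clusters reuse it
    hg_lineage <- sample(names(template$backbone),
                         n - sum(clusters %||% 0L) + length(clusters %||% integer(0)),
                         replace = TRUE, prob = template$backbone)
    haps <- vector("list", n)
    kin_group <- rep(NA_integer_, n)
    hg_sample <- character(n)
    slot <- 1L; lineage <- 1L
    make_motif <- function(hg) {
      founder <- node_full_motif(tree, hg)
      k <- stats::rpois(1, template$private_rate)
      if (k > 0L) {
        sites <- sample(setdiff(candidate_sites, founder$position), k)
        priv <- do.call(rbind, lapply(sites, function(p) {
          variant_row(p, 0L, sample(c("A", "C", "G", "T"), 1L))
        }))
        founder <- rbind(founder, priv)
      }
      founder
    }
    if (length(clusters %||% integer(0))) {
      for (ci in seq_along(clusters)) {
        hg <- hg_lineage[lineage]; lineage <- lineage + 1L
        motif <- make_motif(hg)
        for (m in seq_len(clusters[ci])) {
          id <- sprintf("%s%03d", pop_spec$name, slot)
          haps[[slot]] <- control_region_haplotype(id, motif, list(cr))
          kin_group[slot] <- ci
          hg_sample[slot] <- hg
          slot <- slot + 1L
        }
      }
    }
    while (slot <= n) {
      hg <- hg_lineage[lineage]; lineage <- lineage + 1L
      id <- sprintf("%s%03d", pop_spec$name, slot)
      haps[[slot]] <- control_region_haplotype(id, make_motif(hg), list(cr))
      hg_sample[slot] <- hg
      slot <- slot + 1L
    }
    pop <- population_sample(pop_spec$name, haps, pop_spec$age_generations)
    if (identical(pop_spec$coverage, "partial")) {
      pop <- degrade_coverage(pop, template$coverage_model)
    }
    for (h in pop$haplotypes) {
      calls <- node_coding_calls(tree, hg_sample[match(h$sample_id,
        vapply(pop$haplotypes, function(x) x$sample_id, character(1)))])
      if (length(calls)) coding[[h$sample_id]] <- calls
    }
    pops[[pop_spec$name]] <- pop
    truth[[pi]] <- data.frame(sample_id = vapply(pop$haplotypes,
                                                 function(h) h$sample_id,
                                                 character(1)),
                              population = pop_spec$name,
                              haplogroup = hg_sample,
                              kin_group = kin_group,
                              stringsAsFactors = FALSE)
  }
  list(populations = pops, coding = coding, truth = do.call(rbind, truth))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Degrade coverage of a population to partial hypervariable segments
#'
#' For each sample, each hypervariable segment (HVS-I 16024-16383, HVS-II
#' 57-372, HVS-III 438-576) is retained with its model probability and
#' truncated at both ends by independent uniform widths. Variants falling
#' outside the retained ranges are dropped. A sample losing all segments is
#' an error (empty coverage is rejected).
#'
#' @param pop a `population_sample`
#' @param coverage_model list with `p_hvs1`, `p_hvs2`, `p_hvs3`,
#'   `trunc_width`
#' @param seed optional seed (omit to continue the current RNG stream)
#' @return the degraded `population_sample`
#' @export
degrade_coverage <- function(pop, coverage_model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- c(coverage_model$p_hvs1, coverage_model$p_hvs2, coverage_model$p_hvs3)
  tw <- coverage_model$trunc_width %||% 0L
  haps <- lapply(pop$haplotypes, function(h) {
    keep <- stats::runif(3) < p
    if (!any(keep)) {
      stop("coverage model removed every segment for sample '",
           h$sample_id, "' (empty coverage rejected)")
    }
    ranges <- lapply(which(keep), function(i) {
      seg <- HVS_SEGMENTS[[i]]
      a <- seg[1] + if (tw > 0) sample.int(tw + 1L, 1L) - 1L else 0L
      b <- seg[2] - if (tw > 0) sample.int(tw + 1L, 1L) - 1L else 0L
      # positions are linear within each segment (no origin wrap inside)
      if (cr_order(a) > cr_order(b)) { a <- seg[1]; b <- seg[2] }
      circular_range(a, b)
    })
    v <- h$variants
    inside <- if (nrow(v)) Reduce(`|`, lapply(ranges, range_contains, pos = v$position))
              else logical(0)
    control_region_haplotype(h$sample_id, v[inside, , drop = FALSE], ranges)
  })
  population_sample(pop$name, haps, pop$age_generations)
}

#' Simulate a dataset under a demographic scenario as population samples
#'
#' Bridges the coalescent/HKY engine into the haplotype-table world: the
#' simulated sequences are expressed as variants relative to the
#' simulation's root sequence (the dataset is synthetic; no rCRS bases are
#' implied), mapped onto control-region coordinates, and returned as
#' `population_sample`s that round-trip through the TSV dialect.
#'
#' @param scenario an `abc_scenario`
#' @param params named parameter list (see [draw_params()]); must include
#'   `mu`
#' @param model an [hky_model()]
#' @param seed optional seed
#' @return list with `populations` (named list of `population_sample`) and
#'   `root_sequence` (character vector of length `model$L`)
#' @export
generate_scenario_dataset <- function(scenario, params, model = hky_model(),
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- simulate_genealogy(scenario, params)
  sim <- mutate_hky(tree, model, params$mu)
  bases <- c("A", "C", "G", "T")
  pos_map <- sim_site_positions(model$L)
  coverage <- positions_to_ranges(sort(unique(pos_map)))
  labels <- unique(scenario$samples$label)
  ages <- stats::setNames(scenario$samples$age, scenario$samples$label)
  pops <- lapply(labels, function(lb) {
    rows <- which(sim$tip_label == lb)
    haps <- lapply(seq_along(rows), function(k) {
      s <- sim$sequences[rows[k], ]
      d <- which(s != sim$root_sequence)
      v <- if (length(d)) {
        data.frame(position = pos_map[d], ins_index = 0L,
                   observed = bases[s[d]], reference = bases[sim$root_sequence[d]],
                   stringsAsFactors = FALSE)
      } else empty_variants()
      control_region_haplotype(sprintf("%s%03d", lb, k), v, coverage)
    })
    population_sample(lb, haps, ages[[lb]])
  })
  names(pops) <- labels
  list(populations = pops, root_sequence = bases[sim$root_sequence])
}
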