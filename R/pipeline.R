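# End-to-end orchestration: validate -> classify -> diversity/FST/chi-square/
# PCA -> ABC simulate -> model choice -> error rates -> report bundle.

#' Run the full analysis pipeline from a configuration
#'
#' The configuration is a nested list (or the path to a YAML file with the
#' same structure):
#'
#' \preformatted{
#' input: path to a haplotype TSV        # or `synthetic: true` to generate
#' roles:
#'   ancient: LH
#'   modern: [LG, AL]
#' stages: [validate, classify, stats, fst, chisq, pca, abc]
#' seed: 1
#' outdir: results/run1
#' options:
#'   n_perm: 1023
#'   chisq_tables:                        # optional named 2x2 tables
#'     dna_detection: [[2, 6], [4, 29]]
#'   abc:
#'     n_sims: 10000
#'     retain_frac: 0.01
#'     n_pods: 50
#' }
#'
#' Every stage writes its artifacts (TSV/JSON) under `outdir`; a manifest
#' records package version, seeds and parameters. A failing stage halts the
#' run with an error naming the stage.
#'
#' @param config nested list or YAML path
#' @return invisible list of per-stage results; artifacts on disk
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages %||% c("validate", "classify", "stats", "fst")
  outdir <- config$outdir %||% "pipeline_out"
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  opts <- config$options %||% list()
  results <- list()
  coding <- list()

  stage <- function(name, fun, always = FALSE) {
    if (!always && !(name %in% stages)) return(invisible(NULL))
    tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # input loading is part of the validate stage but always runs: every other
  # stage needs the parsed populations
  pops <- NULL
  stage("validate", always = TRUE, fun = function() {
    if (isTRUE(config$synthetic)) {
      tmpl_args <- config$template %||% list()
      # YAML configs give populations as a list of mappings; an unquoted
      # `n:` key parses as the YAML boolean FALSE and is mapped back
      if (!is.null(tmpl_args$populations) && !is.data.frame(tmpl_args$populations)) {
        tmpl_args$populations <- do.call(rbind, lapply(tmpl_args$populations,
                                                       as.data.frame))
        names(tmpl_args$populations)[names(tmpl_args$populations) == "FALSE."] <- "n"
      }
      if (!is.null(tmpl_args$backbone)) {
        tmpl_args$backbone <- unlist(tmpl_args$backbone)
      }
      tmpl <- do.call(study_template, c(tmpl_args, list(seed = seed)))
      ds <- generate_backbone_dataset(tmpl)
      coding <<- ds$coding
      path <- file.path(outdir, "haplotypes.tsv")
      write_haplotype_table(ds$populations, path)
      pops <<- read_haplotype_table(path)
    } else {
      if (is.null(config$input)) stop("no input file and synthetic not requested")
      if (!file.exists(config$input)) stop("input file not found: ", config$input)
      pops <<- read_haplotype_table(config$input)
    }
    results$validate <<- data.frame(
      population = vapply(pops, `[[`, character(1), "name"),
      n = vapply(pops, function(p) length(p$haplotypes), integer(1)),
      age_generations = vapply(pops, `[[`, numeric(1), "age_generations"))
    if ("validate" %in% stages) {
      utils::write.table(results$validate, file.path(outdir, "validation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  })

  tree <- load_haplogroup_tree()
  stage("classify", function() {
    rows <- do.call(rbind, lapply(pops, function(pop) {
      do.call(rbind, lapply(pop$haplotypes, function(h) {
        cls <- classify_haplogroup(h, coding[[h$sample_id]], tree)
        data.frame(sample_id = h$sample_id, population = pop$name,
                   haplogroup = cls$label,
                   basal = collapse_to_basal(cls$label, tree),
                   uncertain = cls$uncertain, stringsAsFactors = FALSE)
      }))
    }))
    results$classify <<- rows
    utils::write.table(rows, file.path(outdir, "classifications.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  stage("stats", function() {
    div <- do.call(rbind, lapply(pops, diversity_summary))
    results$stats <<- div
    utils::write.table(div, file.path(outdir, "diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  stage("fst", function() {
    n_perm <- as.integer(opts$n_perm %||% 1023L)
    m <- pairwise_fst_matrix(pops, n_perm = n_perm, seed = seed)
    results$fst <<- m
    utils::write.table(cbind(population = rownames(m), as.data.frame(m)),
                       file.path(outdir, "fst_matrix.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  stage("chisq", function() {
    tabs <- opts$chisq_tables
    if (is.null(tabs)) stop("no chisq_tables configured")
    out <- lapply(tabs, function(t) {
      chi_square_2x2(do.call(rbind, t))
    })
    results$chisq <<- out
    jsonlite::write_json(out, file.path(outdir, "chisq.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  stage("pca", function() {
    freqs <- lapply(pops, haplogroup_frequencies, coding = coding,
                    tier = "basal", tree = tree)
    labels <- sort(unique(unlist(lapply(freqs, `[[`, "label"))))
    m <- t(vapply(freqs, function(f) {
      stats::setNames(f$frequency[match(labels, f$label)], labels)
    }, numeric(length(labels))))
    m[is.na(m)] <- 0
    pca <- haplogroup_pca(m)
    results$pca <<- pca
    jsonlite::write_json(list(explained = pca$explained,
                              pc12_share = pca$pc12_share,
                              scores = as.data.frame(pca$scores)),
                         file.path(outdir, "pca.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  stage("abc", function() {
    abc_opts <- opts$abc %||% list()
    roles <- config$roles %||% list(ancient = names(pops)[1],
                                    modern = names(pops)[-1])
    ordered <- c(roles$ancient, roles$modern)
    stopifnot(all(ordered %in% names(pops)), length(ordered) == 3L)
    obs_pops <- pops[ordered]
    ancient <- obs_pops[[1]]
    scenarios <- default_scenarios(
      n_ancient = length(ancient$haplotypes),
      n_modern1 = length(obs_pops[[2]]$haplotypes),
      n_modern2 = length(obs_pops[[3]]$haplotypes),
      t_s = ancient$age_generations, labels = ordered)
    priors <- default_priors(scenarios)
    n_sims <- as.integer(abc_opts$n_sims %||% 1e4)
    retain_frac <- abc_opts$retain_frac %||% 0.01
    observed <- summarize_fst(unname(obs_pops))
    table <- build_reference_table(scenarios, priors, n_sims, seed = seed)
    write_reference_table(table, file.path(outdir, "reference_table.tsv"))
    pre <- pca_preevaluation(table, observed)
    mc <- model_choice(observed, table, retain_frac)
    err <- NULL
    n_pods <- as.integer(abc_opts$n_pods %||% 0L)
    if (n_pods > 0L) {
      err <- confusion_errors(scenarios, priors, table, n_pods = n_pods,
                              seed = seed + 1L, best = mc$selected,
                              retain_frac = retain_frac)
    }
    results$abc <<- list(observed = observed, model_choice = mc,
                         pre_evaluation = pre, errors = err)
    jsonlite::write_json(
      list(observed = as.list(observed),
           direct = as.list(mc$direct),
           regression = if (!is.null(mc$regression)) as.list(mc$regression),
           selected = mc$selected,
           out_of_envelope = pre$out_of_envelope,
           type1 = if (!is.null(err)) err$type1,
           type2 = if (!is.null(err)) err$type2),
      file.path(outdir, "abc_model_choice.json"), auto_unbox = TRUE,
      digits = NA)
  })

  manifest <- list(
    package = "mtcontinuity",
    version = as.character(utils::packageVersion("mtcontinuity")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, stages = stages, options = opts)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}
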