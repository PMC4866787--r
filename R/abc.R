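# ABC model choice between demographic scenarios: FST summary statistics,
# rejection on scaled Euclidean distance, and local logistic regression.

# FST (frequency mode) from a haplotype x population count matrix, two
# populations. Equivalent to the AMOVA partition with 0/1 identity distance.
fst_from_counts <- function(counts) {
  stopifnot(ncol(counts) == 2L)
  n <- colSums(counts)
  N <- sum(n)
  ctot <- rowSums(counts)
  diff_total <- (N^2 - sum(ctot^2)) / 2
  ssd_total <- diff_total / N
  ssd_within <- sum((n^2 - colSums(counts^2)) / 2 / n)
  ssd_among <- ssd_total - ssd_within
  sigma_w <- ssd_within / (N - 2)
  n_prime <- N - sum(n^2) / N
  sigma_a <- (ssd_among - sigma_w) / n_prime
  denom <- sigma_a + sigma_w
  if (denom <= 0) return(0)
  sigma_a / denom
}

#' Pairwise FST summary statistics of a three-population dataset
#'
#' Computes the three pairwise FST point estimates (frequency mode, no
#' permutations) in label order: (pop1, pop2), (pop1, pop3), (pop2, pop3).
#' Accepts either the output of [mutate_hky()] (simulated sequences) or a
#' list of three `population_sample`s (the observed-data path).
#'
#' @param dataset `mutate_hky()` result or list of 3 `population_sample`
#' @param labels population label order; defaults to order of appearance
#' @param range optional comparison range for the observed-data path, for
#'   datasets whose joint coverage intersection is empty (e.g. ancient
#'   samples with disjoint edition ranges); every sample must cover it
#' @return named numeric vector of 3 FST values
#' @export
summarize_fst <- function(dataset, labels = NULL, range = NULL) {
  if (is.list(dataset) && !is.null(dataset$sequences)) {
    tl <- dataset$tip_label
    if (is.null(labels)) labels <- unique(tl)
    stopifnot(length(labels) == 3L)
    seqs <- dataset$sequences
    cand <- dataset$mutated_sites
    seg <- if (is.null(cand)) which(matrixStats_colAnyDiff(seqs))
           else cand[matrixStats_colAnyDiff(seqs[, cand, drop = FALSE])]
    key <- if (length(seg)) {
      do.call(paste0, lapply(seg, function(s) seqs[, s]))
    } else rep("0", nrow(seqs))
    f <- match(key, unique(key))
    nh <- max(f)
    pop_counts <- lapply(labels, function(lb) tabulate(f[tl == lb], nh))
    out <- numeric(3)
    names(out) <- pair_names(labels)
    idx <- 1L
    for (i in 1:2) for (j in seq.int(i + 1L, 3L)) {
      out[idx] <- fst_from_counts(cbind(pop_counts[[i]], pop_counts[[j]]))
      idx <- idx + 1L
    }
    return(out)
  }
  stopifnot(length(dataset) == 3L,
            all(vapply(dataset, inherits, logical(1), "population_sample")))
  if (is.null(labels)) labels <- vapply(dataset, `[[`, character(1), "name")
  out <- numeric(3)
  names(out) <- pair_names(labels)
  idx <- 1L
  for (i in 1:2) for (j in seq.int(i + 1L, 3L)) {
    r <- pairwise_fst(dataset[[i]], dataset[[j]], mode = "frequency",
                      n_perm = 0L, range = range)
    out[idx] <- r$fst
    idx <- idx + 1L
  }
  out
}

pair_names <- function(labels) {
  c(paste0("fst_", labels[1], "_", labels[2]),
    paste0("fst_", labels[1], "_", labels[3]),
    paste0("fst_", labels[2], "_", labels[3]))
}

# columns with more than one state
matrixStats_colAnyDiff <- function(m) {
  if (nrow(m) == 1L) return(rep(FALSE, ncol(m)))
  colSums(m != rep(m[1L, ], each = nrow(m))) > 0L
}

# One simulated dataset under a scenario: parameter draw (unless supplied),
# genealogy, HKY mutation, summary statistics.
simulate_dataset_stats <- function(scenario, priors, model, params = NULL) {
  if (is.null(params)) params <- draw_params(scenario, priors)
  tree <- simulate_genealogy(scenario, params)
  ds <- mutate_hky(tree, model, params$mu)
  list(stats = summarize_fst(ds, labels = unique(scenario$samples$label)),
       params = params)
}

#' Build an ABC reference table
#'
#' Draws scenarios with equal prior probability, draws parameters from their
#' priors, simulates each dataset under the serial coalescent with HKY
#' mutation, and records the 3-vector of pairwise FST summary statistics.
#' Reproducible under a fixed seed.
#'
#' @param scenarios list of `abc_scenario` (typically [default_scenarios()])
#' @param priors an `abc_priors` (typically [default_priors()])
#' @param n_sims number of simulated datasets
#' @param seed integer seed (optional)
#' @param model an [hky_model()]
#' @param verbose log progress every 10%
#' @return object of class `abc_reference_table`: list with `stats`
#'   (n_sims x 3), `scenario` (integer vector), `params` (data.frame),
#'   `scenarios`, `priors`, `seed`, `n_sims`
#' @export
build_reference_table <- function(scenarios, priors, n_sims, seed = NULL,
                                  model = hky_model(), verbose = FALSE) {
  stopifnot(n_sims >= 1L)
  if (!is.null(seed)) set.seed(seed)
  labels <- unique(scenarios[[1]]$samples$label)
  for (sc in scenarios) stopifnot(identical(unique(sc$samples$label), labels))
  all_params <- unique(c(unlist(lapply(scenarios, `[[`, "param_names")), "mu"))
  stats <- matrix(NA_real_, n_sims, 3L, dimnames = list(NULL, pair_names(labels)))
  scen_idx <- sample.int(length(scenarios), n_sims, replace = TRUE)
  pmat <- matrix(NA_real_, n_sims, length(all_params),
                 dimnames = list(NULL, all_params))
  tick <- max(1L, n_sims %/% 10L)
  for (i in seq_len(n_sims)) {
    s <- scen_idx[i]
    r <- simulate_dataset_stats(scenarios[[s]], priors, model)
    stats[i, ] <- r$stats
    pmat[i, names(r$params)] <- unlist(r$params)
    if (verbose && i %% tick == 0L) {
      message(sprintf("reference table: %d / %d simulations", i, n_sims))
    }
  }
  structure(list(stats = stats, scenario = scen_idx,
                 params = as.data.frame(pmat), scenarios = scenarios,
                 priors = priors, seed = seed, n_sims = as.integer(n_sims),
                 model = model),
            class = "abc_reference_table")
}

#' @export
print.abc_reference_table <- function(x, ...) {
  cat(sprintf("<abc_reference_table: %d simulations, %d scenarios>\n",
              x$n_sims, length(x$scenarios)))
  print(table(scenario = x$scenario))
  invisible(x)
}

#' Write / read a reference table as TSV plus a JSON header
#'
#' The columnar TSV holds scenario index, parameter draws and summary
#' statistics; the JSON sidecar records scenario and prior definitions, the
#' seed and the simulation count, so runs are auditable and resumable.
#'
#' @param table an `abc_reference_table`
#' @param path TSV path (`<path>.json` is written alongside)
#' @export
write_reference_table <- function(table, path) {
  df <- data.frame(scenario = table$scenario, table$params, table$stats,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  header <- list(
    n_sims = table$n_sims, seed = table$seed,
    scenario_names = vapply(table$scenarios, `[[`, character(1), "name"),
    priors = lapply(unclass(table$priors), as.numeric),
    model = list(kappa = table$model$kappa,
                 base_frequencies = as.list(table$model$base_frequencies),
                 L = table$model$L))
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' ABC model choice by rejection and local logistic regression
#'
#' Summary statistics are scaled by their median absolute deviation across
#' the reference table; the `retain_frac` simulations closest to the
#' observed vector (Euclidean distance) are retained. The direct estimate is
#' the scenario proportion among retained simulations; the regression
#' estimate fits a local (Epanechnikov-weighted) logistic regression of the
#' scenario indicator on the centred statistics and evaluates it at the
#' observed point.
#'
#' @param observed numeric 3-vector of observed summary statistics
#' @param table an `abc_reference_table`
#' @param retain_frac fraction of simulations retained (default 0.01)
#' @return list with `direct` and `regression` posterior probabilities per
#'   scenario (each summing to 1), `retained` (count), `distances` of
#'   retained simulations, and `selected` (index of the scenario with the
#'   highest regression posterior, falling back to the direct one)
#' @export
model_choice <- function(observed, table, retain_frac = 0.01) {
  stopifnot(retain_frac > 0, retain_frac <= 1)
  stats <- table$stats
  observed <- as.numeric(observed)
  stopifnot(length(observed) == ncol(stats))
  scales <- apply(stats, 2, stats::mad)
  scales[scales < .Machine$double.eps] <- 1
  z <- sweep(stats, 2, scales, `/`)
  zobs <- observed / scales
  d <- sqrt(rowSums(sweep(z, 2, zobs, `-`)^2))
  n_ret <- max(2L, as.integer(ceiling(retain_frac * nrow(stats))))
  keep <- order(d)[seq_len(n_ret)]
  scen <- table$scenario[keep]
  n_scen <- length(table$scenarios)
  direct <- as.numeric(table(factor(scen, levels = seq_len(n_scen)))) / n_ret
  names(direct) <- vapply(table$scenarios, `[[`, character(1), "name")

  regression <- NULL
  if (length(unique(scen)) < 2L) {
    message("all retained simulations come from one scenario; ",
            "regression step skipped, direct estimate returned")
  } else {
    X <- sweep(z[keep, , drop = FALSE], 2, zobs, `-`)
    dk <- d[keep]
    dmax <- max(dk)
    w <- if (dmax > 0) 1 - (dk / dmax)^2 else rep(1, n_ret)
    w[w < 1e-12] <- 1e-12
    df <- data.frame(y = as.integer(scen == n_scen), X)
    names(df) <- c("y", paste0("s", seq_len(ncol(X))))
    fit <- suppressWarnings(
      stats::glm(y ~ ., family = stats::quasibinomial(), data = df, weights = w))
    nd <- as.data.frame(as.list(stats::setNames(rep(0, ncol(X)),
                                                paste0("s", seq_len(ncol(X))))))
    p_last <- suppressWarnings(
      as.numeric(stats::predict(fit, newdata = nd, type = "response")))
    regression <- stats::setNames(c(1 - p_last, p_last), names(direct))
  }
  post <- if (is.null(regression)) direct else regression
  list(direct = direct, regression = regression, retained = n_ret,
       distances = sort(d)[seq_len(n_ret)],
       selected = unname(which.max(post)))
}

#' PCA pre-evaluation of scenarios against the observed statistics
#'
#' Projects the observed summary-statistic vector into the principal
#' component space of the simulated vectors and flags it when it falls
#' outside the convex hull of the simulations on PC1-PC2 — a sign that
#' neither scenario can reproduce the data.
#'
#' @param table an `abc_reference_table`
#' @param observed numeric summary-statistic vector
#' @param max_points subsample size for the hull (evenly spaced rows)
#' @return list with `scores` (subsampled simulations), `observed_scores`,
#'   `explained` variance fractions, and `out_of_envelope` flag
#' @export
pca_preevaluation <- function(table, observed, max_points = 5000L) {
  stats <- table$stats
  if (nrow(stats) > max_points) {
    stats <- stats[round(seq(1L, nrow(stats), length.out = max_points)), ,
                   drop = FALSE]
  }
  p <- stats::prcomp(stats, center = TRUE, scale. = FALSE)
  expl <- p$sdev^2 / sum(p$sdev^2)
  obs <- stats::predict(p, newdata = matrix(as.numeric(observed), nrow = 1,
                                            dimnames = list(NULL, colnames(stats))))
  hull <- grDevices::chull(p$x[, 1], p$x[, 2])
  inside <- point_in_polygon(obs[1], obs[2], p$x[hull, 1], p$x[hull, 2])
  list(scores = p$x, observed_scores = obs[1, ], explained = expl,
       out_of_envelope = !inside)
}

# even-odd ray casting; points on an edge count as inside
point_in_polygon <- function(px, py, hx, hy) {
  n <- length(hx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if (((hy[i] > py) != (hy[j] > py)) &&
        (px < (hx[j] - hx[i]) * (py - hy[i]) / (hy[j] - hy[i]) + hx[i])) {
      inside <- !inside
    }
    j <- i
  }
  if (!inside) {
    # boundary tolerance
    d <- sqrt((hx - px)^2 + (hy - py)^2)
    if (min(d) < 1e-12) inside <- TRUE
  }
  inside
}

#' Type I / type II error of ABC model choice from pseudo-observed datasets
#'
#' Simulates `n_pods` datasets per scenario from the priors, runs
#' [model_choice()] on each against the reference table, and reports the
#' type I error (pods from the best-supported scenario where it is not
#' selected) and type II error (pods from the alternative scenario where the
#' best-supported scenario is incorrectly selected).
#'
#' @param scenarios,priors,model as in [build_reference_table()]
#' @param table an `abc_reference_table`
#' @param n_pods pseudo-observed datasets per scenario (default 100)
#' @param seed integer seed (optional)
#' @param best index of the best-supported scenario (default 2)
#' @param retain_frac passed to [model_choice()]
#' @return list with `type1`, `type2`, `selections` (matrix scenarios x
#'   pods), `n_pods`
#' @export
confusion_errors <- function(scenarios, priors, table, n_pods = 100L,
                             seed = NULL, best = 2L, retain_frac = 0.01,
                             model = hky_model()) {
  stopifnot(n_pods >= 1L, best %in% seq_along(scenarios))
  if (!is.null(seed)) set.seed(seed)
  sel <- matrix(NA_integer_, length(scenarios), n_pods)
  for (s in seq_along(scenarios)) {
    for (k in seq_len(n_pods)) {
      pod <- simulate_dataset_stats(scenarios[[s]], priors, model)
      mc <- suppressMessages(model_choice(pod$stats, table, retain_frac))
      sel[s, k] <- mc$selected
    }
  }
  others <- setdiff(seq_along(scenarios), best)
  list(type1 = mean(sel[best, ] != best),
       type2 = mean(sel[others, , drop = FALSE] == best),
       selections = sel, n_pods = as.integer(n_pods))
}
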