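# Diversity parameters, AMOVA-based pairwise FST with permutation
# significance, 2x2 chi-square tests, and PCA on haplogroup frequencies.

# Shared comparison range of a set of haplotypes: intersection of all
# coverages (optionally intersected with a user-supplied range).
shared_range <- function(haps, range = NULL) {
  common <- Reduce(common_range, lapply(haps, function(h) h$coverage))
  if (!is.null(range)) common <- common_range(common, as_coverage(range))
  common
}

# Assign haplotypes to distinct-sequence classes: connected components of
# the zero-distance relation over a fixed range (ambiguity codes make the
# relation non-transitive, so components give the conservative grouping).
haplotype_classes <- function(haps, range, ignore_indel_sites) {
  n <- length(haps)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      if (haplotype_distance(haps[[i]], haps[[j]], range, ignore_indel_sites) == 0L) {
        parent[find(j)] <- find(i)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Gene (haplotype) diversity with its standard deviation
#'
#' Computes Nei's unbiased gene diversity
#' \eqn{\hat H = n(1 - \sum p_i^2)/(n-1)} over distinct-haplotype
#' frequencies, with the standard deviation from Nei's variance estimator
#' (as implemented in Arlequin).
#'
#' @param pop a `population_sample` (n >= 2)
#' @param range optional comparison range (default: shared coverage)
#' @param ignore_indel_sites poly-C anchors excluded from comparisons
#' @return list with `H`, `sd`, `k` (number of distinct haplotypes), `n`
#' @export
gene_diversity <- function(pop, range = NULL,
                           ignore_indel_sites = c(16193L, 309L, 573L)) {
  haps <- pop$haplotypes
  n <- length(haps)
  if (n < 2L) stop("gene diversity requires n >= 2")
  rng <- shared_range(haps, range)
  cls <- haplotype_classes(haps, rng, ignore_indel_sites)
  p <- as.numeric(table(cls)) / n
  s2 <- sum(p^2); s3 <- sum(p^3)
  H <- n * (1 - s2) / (n - 1)
  v <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(H = H, sd = sqrt(max(v, 0)), k = length(unique(cls)), n = n)
}

#' Mean number of pairwise differences (and nucleotide diversity)
#'
#' \eqn{\pi = \binom{n}{2}^{-1} \sum_{i<j} d_{ij}} with `d` from
#' [haplotype_distance()]. Two standard-deviation estimators are reported:
#' `sd` from Tajima's total variance under no recombination,
#' \eqn{(3n(n+1)\pi + 2(n^2+n+3)\pi^2) / (11(n^2-7n+6))}, and `sd_alt` from
#' the sampling+stochastic form \eqn{(n+1)\pi/(3(n-1)) +
#' 2(n^2+n+3)\pi^2/(9n(n-1))}.
#'
#' @inheritParams gene_diversity
#' @return list with `pi`, `sd`, `sd_alt`, `n`, `L` (compared sites: range
#'   length minus ignored anchor sites inside the range)
#' @export
mean_pairwise_differences <- function(pop, range = NULL,
                                      ignore_indel_sites = c(16193L, 309L, 573L)) {
  haps <- pop$haplotypes
  n <- length(haps)
  if (n < 2L) stop("mean pairwise differences require n >= 2")
  rng <- shared_range(haps, range)
  if (length(rng) == 0L) stop("empty common range")
  total <- 0
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    total <- total + haplotype_distance(haps[[i]], haps[[j]], rng, ignore_indel_sites)
  }
  pi <- 2 * total / (n * (n - 1))
  v_norec <- (3 * n * (n + 1) * pi + 2 * (n^2 + n + 3) * pi^2) /
    (11 * (n^2 - 7 * n + 6))
  v_alt <- (n + 1) * pi / (3 * (n - 1)) +
    2 * (n^2 + n + 3) * pi^2 / (9 * n * (n - 1))
  L <- compared_sites(rng, ignore_indel_sites)
  list(pi = pi, sd = sqrt(max(v_norec, 0)), sd_alt = sqrt(max(v_alt, 0)),
       n = n, L = L)
}

compared_sites <- function(rng, ignore_indel_sites) {
  in_rng <- vapply(ignore_indel_sites, function(p) {
    any(vapply(rng, function(r) range_contains(r, p), logical(1)))
  }, logical(1))
  sum(vapply(rng, range_length, integer(1))) - sum(in_rng)
}

#' Nucleotide diversity with its standard deviation
#'
#' \eqn{\pi_n = \pi / L}. The standard deviation uses
#' \eqn{V(\pi_n) = \frac{n+1}{3L(n-1)}\pi_n +
#' \frac{2(n^2+n+3)}{9n(n-1)}\pi_n^2} (Nei 1987, as in Arlequin).
#'
#' @inheritParams gene_diversity
#' @return list with `pi_n`, `sd`, `n`, `L`
#' @export
nucleotide_diversity <- function(pop, range = NULL,
                                 ignore_indel_sites = c(16193L, 309L, 573L)) {
  mpd <- mean_pairwise_differences(pop, range, ignore_indel_sites)
  pn <- mpd$pi / mpd$L
  list(pi_n = pn, sd = sqrt(nucleotide_diversity_variance(pn, mpd$n, mpd$L)),
       n = mpd$n, L = mpd$L)
}

#' Variance of nucleotide diversity at given pi_n, n, L
#' @noRd
nucleotide_diversity_variance <- function(pi_n, n, L) {
  (n + 1) / (3 * L * (n - 1)) * pi_n +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi_n^2
}

#' Summary of diversity parameters for one population
#'
#' @inheritParams gene_diversity
#' @return data.frame with one row: `n`, `k`, `H`, `H_sd`, `pi`, `pi_sd`,
#'   `pi_sd_alt`, `pi_n`, `pi_n_sd`, `L`
#' @export
diversity_summary <- function(pop, range = NULL,
                              ignore_indel_sites = c(16193L, 309L, 573L)) {
  gd <- gene_diversity(pop, range, ignore_indel_sites)
  mpd <- mean_pairwise_differences(pop, range, ignore_indel_sites)
  nd <- nucleotide_diversity(pop, range, ignore_indel_sites)
  data.frame(population = pop$name, n = gd$n, k = gd$k,
             H = gd$H, H_sd = gd$sd,
             pi = mpd$pi, pi_sd = mpd$sd, pi_sd_alt = mpd$sd_alt,
             pi_n = nd$pi_n, pi_n_sd = nd$sd, L = mpd$L,
             stringsAsFactors = FALSE)
}

# Two-group AMOVA variance partition from a pairwise distance matrix.
# `labels` is a logical/integer vector of group membership. Returns FST.
fst_from_distances <- function(D, labels) {
  groups <- unique(labels)
  stopifnot(length(groups) == 2L)
  N <- nrow(D)
  idx <- lower.tri(D)
  ssd_total <- sum(D[idx]) / N
  ssd_within <- 0
  for (g in groups) {
    sel <- labels == g
    ng <- sum(sel)
    ssd_within <- ssd_within + sum(D[sel, sel][lower.tri(D[sel, sel])]) / ng
  }
  ssd_among <- ssd_total - ssd_within
  n_sizes <- vapply(groups, function(g) sum(labels == g), numeric(1))
  df_among <- 1
  df_within <- N - 2
  sigma_w <- ssd_within / df_within
  n_prime <- (N - sum(n_sizes^2) / N) / df_among
  sigma_a <- (ssd_among / df_among - sigma_w) / n_prime
  denom <- sigma_a + sigma_w
  if (denom <= 0) return(0)
  sigma_a / denom
}

#' Pairwise FST between two populations with permutation significance
#'
#' AMOVA-style variance partition among/within populations (Excoffier,
#' Smouse & Quattro 1992). `mode = "frequency"` treats haplotypes as
#' unordered alleles (0/1 identity distance, FST proper); `mode = "distance"`
#' weights by pairwise difference counts (PhiST-like). The p-value permutes
#' individuals across populations and uses the +1/+1 estimator
#' \eqn{(\#\{F_{perm} \ge F_{obs}\}+1)/(n_{perm}+1)}, so it is never zero.
#' Negative estimates are reported as computed, not clamped.
#'
#' @param a,b `population_sample`s (each n >= 2)
#' @param mode `"frequency"` (default) or `"distance"`
#' @param n_perm number of permutations (default 1023)
#' @param seed integer seed for the permutation stream
#' @param alpha significance level before correction (default 0.05)
#' @param n_comparisons Bonferroni divisor supplied by the caller (e.g. 10
#'   pairwise comparisons give an adjusted level of 0.005)
#' @param range,ignore_indel_sites comparison range handling as elsewhere
#' @return list with `fst`, `p_value`, `n_permutations`,
#'   `significant_after_bonferroni`
#' @export
pairwise_fst <- function(a, b, mode = c("frequency", "distance"),
                         n_perm = 1023L, seed = NULL, alpha = 0.05,
                         n_comparisons = 1L, range = NULL,
                         ignore_indel_sites = c(16193L, 309L, 573L)) {
  mode <- match.arg(mode)
  stopifnot(length(a$haplotypes) >= 2L, length(b$haplotypes) >= 2L)
  haps <- c(a$haplotypes, b$haplotypes)
  labels <- rep(c(1L, 2L), c(length(a$haplotypes), length(b$haplotypes)))
  rng <- shared_range(haps, range)
  if (length(rng) == 0L) stop("populations share no common range")
  n <- length(haps)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    d <- haplotype_distance(haps[[i]], haps[[j]], rng, ignore_indel_sites)
    D[i, j] <- D[j, i] <- d
  }
  if (mode == "frequency") D <- (D > 0) + 0
  if (all(D == 0)) {
    return(list(fst = 0, p_value = 1, n_permutations = as.integer(n_perm),
                significant_after_bonferroni = FALSE))
  }
  fst <- fst_from_distances(D, labels)
  if (!is.null(seed)) set.seed(seed)
  ge <- 0L
  for (r in seq_len(n_perm)) {
    perm <- sample.int(n)
    if (fst_from_distances(D, labels[perm]) >= fst) ge <- ge + 1L
  }
  p <- (ge + 1) / (n_perm + 1)
  list(fst = fst, p_value = p, n_permutations = as.integer(n_perm),
       significant_after_bonferroni = p < alpha / n_comparisons)
}

#' Pairwise FST matrix across several populations
#'
#' Returns a square matrix with FST estimates above the diagonal and
#' permutation p-values below it (the conventional distance-matrix report
#' layout). The Bonferroni divisor defaults to the number of pairs.
#'
#' @param pops list of `population_sample`
#' @inheritParams pairwise_fst
#' @export
pairwise_fst_matrix <- function(pops, mode = c("frequency", "distance"),
                                n_perm = 1023L, seed = NULL, alpha = 0.05,
                                range = NULL,
                                ignore_indel_sites = c(16193L, 309L, 573L)) {
  mode <- match.arg(mode)
  k <- length(pops)
  stopifnot(k >= 2L)
  n_comp <- k * (k - 1) / 2
  m <- matrix(NA_real_, k, k,
              dimnames = list(vapply(pops, `[[`, character(1), "name"),
                              vapply(pops, `[[`, character(1), "name")))
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    r <- pairwise_fst(pops[[i]], pops[[j]], mode, n_perm,
                      seed = if (is.null(seed)) NULL else seed + 1000L * i + j,
                      alpha = alpha, n_comparisons = n_comp, range = range,
                      ignore_indel_sites = ignore_indel_sites)
    m[i, j] <- r$fst
    m[j, i] <- r$p_value
  }
  diag(m) <- 0
  m
}

#' Pearson chi-square test on a 2x2 table
#'
#' No continuity correction, df = 1, upper-tail p-value — the convention
#' used for small archaeological count comparisons (a Yates-corrected test
#' would roughly double the p-value on tables this small).
#'
#' @param tab 2x2 matrix of non-negative integer counts with positive margins
#' @return list with `chi2`, `p`
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)))
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-square test undefined for a table with a zero margin")
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(res$statistic), p = unname(res$p.value))
}

#' PCA on a populations x haplogroups frequency matrix
#'
#' Column-centred covariance PCA on raw frequencies (no scaling, no
#' log-ratio transform), the convention for haplogroup-frequency ordinations
#' of ancient-population datasets. Zero-variance columns are dropped with a
#' message.
#'
#' @param freq matrix (rows = populations, columns = basal haplogroups)
#' @return list with `scores` (populations x components), `explained`
#'   (variance fractions, non-increasing), `pc12_share` (PC1+PC2 combined),
#'   `loadings`, `center`, `dropped` (names of zero-variance columns)
#' @export
haplogroup_pca <- function(freq) {
  freq <- as.matrix(freq)
  if (nrow(freq) < 3L) stop("PCA requires at least 3 populations")
  v <- apply(freq, 2, stats::var)
  dropped <- colnames(freq)[v < .Machine$double.eps]
  if (length(dropped)) {
    message("dropping zero-variance column(s): ", paste(dropped, collapse = ", "))
    freq <- freq[, v >= .Machine$double.eps, drop = FALSE]
  }
  p <- stats::prcomp(freq, center = TRUE, scale. = FALSE)
  expl <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x, explained = expl,
       pc12_share = sum(expl[seq_len(min(2L, length(expl)))]),
       loadings = p$rotation, center = p$center, dropped = dropped)
}
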