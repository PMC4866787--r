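test_that("gene diversity matches closed-form values and the enumeration oracle", {
  expect_equal(gene_diversity(mkpop(c("73G", "73G", "73G")))$H, 0)
  expect_equal(gene_diversity(mkpop(c("73G", "263G")))$H, 1)
  h <- gene_diversity(mkpop(c("73G", "73G", "146C", "263G")))
  expect_equal(h$H, (4 / 3) * (1 - (1 / 4 + 1 / 16 + 1 / 16)))
  expect_equal(h$k, 3L)
  expect_error(gene_diversity(mkpop("73G")), "n >= 2")

  set.seed(3)
  sites <- setdiff(16024:16383, 16193)
  for (rep in 1:5) {
    n <- sample(4:12, 1)
    motifs <- vapply(seq_len(n), function(i) {
      if (stats::runif(1) < 0.3) "73G" else random_motif(sites, sample(1:4, 1))
    }, character(1))
    pop <- mkpop(motifs)
    expect_equal(gene_diversity(pop)$H, oracle_gene_diversity(motifs),
                 tolerance = 1e-12)
    expect_equal(mean_pairwise_differences(pop)$pi, oracle_pi(motifs),
                 tolerance = 1e-12)
  }
})

test_that("mean pairwise differences and nucleotide diversity follow their definitions", {
  expect_equal(mean_pairwise_differences(mkpop(c("", "73G, 146C, 263G")))$pi, 3)
  expect_equal(mean_pairwise_differences(mkpop(c("73G", "73G")))$pi, 0)
  # pairwise distances {1, 2, 3} -> pi = 2
  p <- mkpop(c("", "73G", "73G, 146C, 152C"))
  expect_equal(mean_pairwise_differences(p)$pi, 2)
  nd <- nucleotide_diversity(p)
  expect_equal(nd$L, 1119L)  # 1122 sites minus the three poly-C anchors
  expect_equal(nd$pi_n, 2 / 1119)

  ds <- diversity_summary(p)
  expect_equal(ds$pi_n, ds$pi / ds$L)
  expect_true(ds$H >= 0 && ds$H <= 1)
})

test_that("the nucleotide-diversity variance estimator reproduces published-scale sds", {
  # At pi = 8.2235 (n = 51) and pi = 6.2487 (n = 56) over the 1122-site
  # control region the estimator gives sd(pi_n) of 0.0038 and 0.0030 to the
  # reported precision of such tables.
  v1 <- mtcontinuity:::nucleotide_diversity_variance(8.2235 / 1122, 51, 1122)
  v2 <- mtcontinuity:::nucleotide_diversity_variance(6.2487 / 1122, 56, 1122)
  expect_equal(round(sqrt(v1), 4), 0.0038)
  expect_equal(round(sqrt(v2), 4), 0.0030)
})

test_that("pairwise FST separates fixed populations and vanishes under panmixia", {
  pa <- mkpop(rep("73G", 8), "A")
  pb <- mkpop(rep("263G", 8), "B")
  r <- pairwise_fst(pa, pb, n_perm = 199, seed = 1)
  expect_equal(r$fst, 1)
  expect_lt(r$p_value, 0.05)
  expect_equal(r$n_permutations, 199L)

  # same composition, moderate n: estimate near zero
  m <- c(rep("73G", 5), rep("263G", 5), rep("146C", 5))
  r0 <- pairwise_fst(mkpop(m, "A"), mkpop(m, "B"), n_perm = 99, seed = 1)
  expect_lt(abs(r0$fst), 0.1)
  expect_gt(r0$p_value, 0.1)

  # degenerate: everything identical
  rz <- pairwise_fst(mkpop(rep("73G", 4), "A"), mkpop(rep("73G", 4), "B"))
  expect_equal(rz$fst, 0)
  expect_equal(rz$p_value, 1)
})

test_that("permutation p-values are reproducible, label-symmetric and +1/+1 bounded", {
  set.seed(5)
  pool <- vapply(1:20, function(i) random_motif(16024:16383, sample(0:3, 1)),
                 character(1))
  a <- mkpop(pool[1:10], "A"); b <- mkpop(pool[11:20], "B")
  r1 <- pairwise_fst(a, b, n_perm = 199, seed = 42)
  r2 <- pairwise_fst(a, b, n_perm = 199, seed = 42)
  expect_identical(r1, r2)
  r3 <- pairwise_fst(b, a, n_perm = 199, seed = 42)
  expect_equal(r1$fst, r3$fst)
  expect_gte(r1$p_value, 1 / 200)
  expect_lte(r1$p_value, 1)
})

test_that("null FST on random splits of one pool centres near zero", {
  set.seed(9)
  pool <- vapply(1:20, function(i) random_motif(16024:16383, sample(0:3, 1)),
                 character(1))
  fsts <- ps <- numeric(10)
  for (k in 1:10) {
    idx <- sample(20, 10)
    r <- pairwise_fst(mkpop(pool[idx], "A"), mkpop(pool[-idx], "B"),
                      n_perm = 99, seed = k)
    fsts[k] <- r$fst; ps[k] <- r$p_value
  }
  expect_lt(abs(mean(fsts)), 0.05)
  expect_gt(mean(ps), 0.2)  # p roughly uniform under the null
})

test_that("distance mode weights differentiation by divergence", {
  # two populations fixed for haplotypes 4 substitutions apart vs 1 apart:
  # frequency mode is identical, distance mode is not informative about that
  # here (both fixed -> 1), but mixed compositions differ
  a <- mkpop(c("73G", "73G", "73G, 146C, 152C, 186T, 195C"), "A")
  b <- mkpop(c("263G", "263G", "263G, 310C"), "B")
  rf <- pairwise_fst(a, b, mode = "frequency", n_perm = 0)
  rd <- pairwise_fst(a, b, mode = "distance", n_perm = 0)
  expect_false(isTRUE(all.equal(rf$fst, rd$fst)))
})

test_that("the FST matrix carries estimates above and p-values below the diagonal", {
  pops <- list(mkpop(rep(c("73G", "146C"), 3), "A"),
               mkpop(rep(c("73G", "263G"), 3), "B"),
               mkpop(rep(c("152C", "263G"), 3), "C"))
  m <- pairwise_fst_matrix(pops, n_perm = 49, seed = 1)
  expect_equal(dim(m), c(3L, 3L))
  expect_equal(diag(m), c(A = 0, B = 0, C = 0))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_true(m[j, i] > 0 && m[j, i] <= 1)  # p-value below diagonal
  }
})

test_that("Pearson chi-square matches the closed form, errors on zero margins", {
  r <- chi_square_2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
  # property: agreement with the closed-form statistic on random tables
  set.seed(13)
  for (i in 1:20) {
    t <- matrix(rpois(4, 10) + 1, 2)
    r <- chi_square_2x2(t)
    n <- sum(t)
    expected <- outer(rowSums(t), colSums(t)) / n
    chi2 <- sum((t - expected)^2 / expected)
    expect_equal(r$chi2, chi2, tolerance = 1e-12)
    expect_equal(r$p, stats::pchisq(chi2, 1, lower.tail = FALSE))
  }
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2)), "zero margin")
  expect_error(chi_square_2x2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("haplogroup PCA matches an eigendecomposition oracle", {
  set.seed(17)
  f <- matrix(stats::runif(5 * 6), 5, 6)
  f <- f / rowSums(f)
  colnames(f) <- paste0("hg", 1:6)
  p <- haplogroup_pca(f)
  # oracle: eigenvalues of the covariance of centred columns
  ev <- eigen(stats::cov(scale(f, scale = FALSE)), symmetric = TRUE)$values
  ev <- ev[ev > 1e-12]
  expect_equal(p$explained[seq_along(ev)], ev / sum(ev), tolerance = 1e-9)
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_equal(sum(p$explained), 1, tolerance = 1e-9)

  # 3 populations in general position: rank <= 2 after centring
  p3 <- haplogroup_pca(f[1:3, ])
  expect_equal(p3$pc12_share, 1, tolerance = 1e-9)

  # duplicated rows score identically
  fdup <- rbind(f, f[1, ])
  pd <- haplogroup_pca(fdup)
  expect_equal(pd$scores[1, ], pd$scores[6, ], tolerance = 1e-9)

  # zero-variance columns dropped with a message
  fz <- cbind(f, const = 0.1)
  expect_message(pz <- haplogroup_pca(fz), "zero-variance")
  expect_equal(pz$dropped, "const")
  expect_error(haplogroup_pca(f[1:2, ]), "at least 3 populations")
})
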