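# Scaled-down reference tables keep these unit tests fast; the full-scale
# calibration and recovery experiments live in the acceptance suite.

small_scenarios <- function() {
  default_scenarios(n_ancient = 8L, n_modern1 = 10L, n_modern2 = 10L)
}

test_that("reference tables are reproducible, balanced and bounded", {
  scs <- small_scenarios()
  pri <- default_priors(scs)
  t1 <- build_reference_table(scs, pri, n_sims = 10, seed = 7)
  t2 <- build_reference_table(scs, pri, n_sims = 10, seed = 7)
  expect_identical(t1$stats, t2$stats)
  expect_identical(t1$scenario, t2$scenario)

  t3 <- build_reference_table(scs, pri, n_sims = 400, seed = 8)
  # scenario draws within the binomial 99.9% interval around n/2
  expect_lt(abs(sum(t3$scenario == 1) - 200), 3.3 * sqrt(400 * 0.25))
  expect_true(all(is.finite(t3$stats)))
  expect_true(all(t3$stats <= 1 & t3$stats >= -1))
  expect_equal(colnames(t3$stats), c("fst_LH_LG", "fst_LH_AL", "fst_LG_AL"))
})

test_that("reference tables persist as columnar TSV with a JSON header", {
  scs <- small_scenarios()
  pri <- default_priors(scs)
  tab <- build_reference_table(scs, pri, n_sims = 20, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_reference_table(tab, path)
  df <- utils::read.delim(path)
  expect_equal(nrow(df), 20L)
  expect_true(all(c("scenario", "mu", "fst_LH_LG") %in% names(df)))
  hdr <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(hdr$n_sims, 20L)
  expect_equal(unlist(hdr$scenario_names), c("continuity", "independence"))
})

test_that("summary statistics: identical populations give near-zero FST, interface accepts observed data", {
  # the unbiased estimator has an O(1/n) negative offset for exactly
  # duplicated compositions (here -1/(n-1)); it vanishes with n
  motifs <- rep(c("73G", "146C", "263G", "73G, 152C"), 3)
  mkp <- function(nm, age) population_sample(nm, lapply(seq_along(motifs),
    function(i) parse_motif(motifs[i], CR, paste0(nm, i))), age)
  s <- summarize_fst(list(mkp("LH", 96), mkp("LG", 0), mkp("AL", 0)))
  expect_named(s, c("fst_LH_LG", "fst_LH_AL", "fst_LG_AL"))
  expect_true(all(abs(s) < 0.1))
  expect_true(all(s <= 0))
})

test_that("deep splits produce strong differentiation in the summaries", {
  set.seed(21)
  scs <- small_scenarios()
  pri <- default_priors(scs)
  high <- 0
  for (i in 1:10) {
    p <- list(N_LH = 300, N_LG = 300, N_AL = 300, t_split = 150, t_anc = 30000,
              mu = 8e-7)
    s <- mtcontinuity:::simulate_dataset_stats(scs$independence, pri,
                                               hky_model(), params = p)$stats
    if (s[["fst_LH_LG"]] > 0.3 && s[["fst_LH_AL"]] > 0.3) high <- high + 1
  }
  # the ancient population split ~100 Ne generations ago: strong
  # differentiation from both modern populations in most replicates
  expect_gte(high, 8)
})

test_that("model choice: retain_frac = 1 returns the prior proportions and relabeling is symmetric", {
  scs <- small_scenarios()
  pri <- default_priors(scs)
  tab <- build_reference_table(scs, pri, n_sims = 300, seed = 5)
  obs <- c(0.02, 0.03, 0.01)
  mc_all <- suppressMessages(model_choice(obs, tab, retain_frac = 1))
  expect_equal(unname(mc_all$direct),
               as.numeric(table(tab$scenario)) / 300, tolerance = 1e-12)

  # swapping the scenario labels swaps the posteriors
  tab_swapped <- tab
  tab_swapped$scenario <- 3L - tab$scenario
  tab_swapped$scenarios <- rev(tab$scenarios)
  mc1 <- suppressMessages(model_choice(obs, tab, retain_frac = 0.2))
  mc2 <- suppressMessages(model_choice(obs, tab_swapped, retain_frac = 0.2))
  expect_equal(unname(mc1$direct), unname(rev(mc2$direct)), tolerance = 1e-12)
  if (!is.null(mc1$regression) && !is.null(mc2$regression)) {
    expect_equal(unname(mc1$regression), unname(rev(mc2$regression)),
                 tolerance = 1e-6)
  }
})

test_that("model choice posteriors sum to one and direct/regression agree when retention is broad", {
  set.seed(31)
  scs <- small_scenarios()
  pri <- default_priors(scs)
  tab <- build_reference_table(scs, pri, n_sims = 600, seed = 11)
  obs <- apply(tab$stats, 2, stats::median)
  mc <- suppressMessages(model_choice(obs, tab, retain_frac = 0.5))
  expect_equal(sum(mc$direct), 1, tolerance = 1e-9)
  if (!is.null(mc$regression)) {
    expect_equal(sum(mc$regression), 1, tolerance = 1e-9)
    expect_lt(max(abs(mc$regression - mc$direct)), 0.1)
  }
  expect_equal(mc$retained, 300L)
  expect_true(all(diff(mc$distances) >= 0))
})

test_that("a one-scenario retained set skips regression with a notice", {
  scs <- small_scenarios()
  pri <- default_priors(scs)
  tab <- build_reference_table(scs, pri, n_sims = 50, seed = 13)
  tab$scenario <- rep(1L, 50)  # degenerate: all retained are scenario 1
  expect_message(mc <- model_choice(c(0, 0, 0), tab, retain_frac = 0.2),
                 "regression step skipped")
  expect_null(mc$regression)
  expect_equal(unname(mc$direct), c(1, 0))
})

test_that("PCA pre-evaluation projects the simulation mean to the origin and flags outliers", {
  scs <- small_scenarios()
  pri <- default_priors(scs)
  tab <- build_reference_table(scs, pri, n_sims = 200, seed = 17)
  centre <- colMeans(tab$stats)
  pre <- pca_preevaluation(tab, centre)
  expect_true(all(abs(pre$observed_scores) < 1e-9))
  expect_false(pre$out_of_envelope)
  far <- centre + 50 * apply(tab$stats, 2, stats::sd) + 1
  pre2 <- pca_preevaluation(tab, far)
  expect_true(pre2$out_of_envelope)
  # explained fractions agree with a direct eigendecomposition
  ev <- eigen(stats::cov(scale(tab$stats, scale = FALSE)), symmetric = TRUE)$values
  expect_equal(pre$explained, ev / sum(ev), tolerance = 1e-9)
})

test_that("confusion errors are reproducible, bounded, and near one half for identical scenarios", {
  scs <- small_scenarios()
  twin <- list(a = scs$continuity, b = scs$continuity)
  twin$b$name <- "continuity_copy"
  pri <- default_priors(twin)
  tab <- build_reference_table(twin, pri, n_sims = 400, seed = 19)
  e1 <- confusion_errors(twin, pri, tab, n_pods = 12, seed = 23, best = 2,
                         retain_frac = 0.05)
  e2 <- confusion_errors(twin, pri, tab, n_pods = 12, seed = 23, best = 2,
                         retain_frac = 0.05)
  expect_identical(e1$selections, e2$selections)
  expect_true(e1$type1 >= 0 && e1$type1 <= 1)
  expect_true(e1$type2 >= 0 && e1$type2 <= 1)
  # identical scenarios: both error rates hover around 0.5
  expect_gt(e1$type1, 0.1); expect_lt(e1$type1, 0.9)
  expect_gt(e1$type2, 0.1); expect_lt(e1$type2, 0.9)
})
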