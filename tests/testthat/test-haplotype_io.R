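test_that("motif parsing handles substitutions, insertions, ambiguities and the identity case", {
  h <- parse_motif(
    "16069T, 16126C, 73G, 185A, 188G, 228A, 263G, 295T, 309.1C, 315.1C",
    CR, "LHY099")
  expect_equal(nrow(h$variants), 10L)
  expect_equal(sum(h$variants$ins_index > 0L), 2L)
  # variants come back in control-region order: HVS-I before HVS-II
  expect_equal(h$variants$position[1:2], c(16069L, 16126L))
  expect_equal(h$variants$position[nrow(h$variants)], 315L)

  empty <- parse_motif("", CR, "rCRS")
  expect_equal(nrow(empty$variants), 0L)

  amb <- parse_motif("16291Y", CR, "VG110")
  expect_equal(amb$variants$observed, "Y")

  expect_equal(format_motif(h),
               "16069T, 16126C, 73G, 185A, 188G, 228A, 263G, 295T, 309.1C, 315.1C")
})

test_that("malformed tokens and out-of-coverage positions are rejected with context", {
  expect_error(parse_motif("16069X9", CR), "malformed motif token.*16069X9")
  expect_error(parse_motif("abc", CR), "malformed motif token")
  expect_error(parse_motif("20000A", CR), "outside 1\\.\\.16569")
  expect_error(parse_motif("700G", CR), "outside coverage")
  expect_error(parse_motif("309.0C", CR), "malformed|index")
})

test_that("circular ranges wrap the origin and report correct lengths", {
  cr <- circular_range(16024, 576)
  expect_equal(range_length(cr), 1122L)
  expect_true(all(range_contains(cr, c(16024, 16569, 1, 576))))
  expect_false(any(range_contains(cr, c(16023, 577, 8000))))
  expect_equal(range_length(circular_range(100, 100)), 1L)
})

test_that("common_range intersects on the circle, is commutative and idempotent", {
  a <- list(circular_range(16024, 576))
  expect_equal(format(common_range(a, a)[[1]]), "16024-576")
  b <- common_range(list(circular_range(16000, 300)), list(circular_range(100, 576)))
  expect_equal(format(b[[1]]), "100-300")
  expect_length(common_range(list(circular_range(16024, 16400)),
                             list(circular_range(30, 576))), 0L)
  # property: commutativity and idempotence on random range pairs
  set.seed(7)
  for (i in 1:20) {
    r1 <- list(circular_range(sample(16569, 1), sample(16569, 1)))
    r2 <- list(circular_range(sample(16569, 1), sample(16569, 1)))
    ab <- common_range(r1, r2); ba <- common_range(r2, r1)
    expect_identical(lapply(ab, format), lapply(ba, format))
    expect_identical(lapply(common_range(ab, ab), format), lapply(ab, format))
  }
})

test_that("haplotype distance reproduces the published two-position difference", {
  a <- mk("16069T, 16126C, 73G, 185A, 188G, 228A, 263G, 295T", "LHY099")
  b <- mk("16069T, 16126C, 16278T, 16366T, 73G, 185A, 188G, 228A, 263G, 295T",
          "LG003")
  expect_equal(haplotype_distance(a, b), 2L)
  expect_equal(haplotype_distance(a, a), 0L)
  # the poly-C insertions at 309/315.1 are carried by the full haplotype;
  # only the 309 anchor is conventionally disregarded
  a_full <- mk("16069T, 16126C, 73G, 185A, 188G, 228A, 263G, 295T, 309.1C, 315.1C")
  expect_equal(haplotype_distance(a_full, a), 1L)
  expect_equal(haplotype_distance(a_full, a, ignore_indel_sites = c(16193, 309, 315, 573)),
               0L)
})

test_that("ambiguity codes compare as no difference against compatible states", {
  y <- mk("16291Y", "het")
  t_ <- mk("16291T", "plain")
  r <- mk("", "ref")
  expect_equal(haplotype_distance(y, t_), 0L)
  expect_equal(haplotype_distance(y, r), 0L)   # Y may include the reference base
  expect_equal(haplotype_distance(t_, r), 1L)
  d <- mk("16291del", "del")
  expect_equal(haplotype_distance(d, t_), 1L)
  expect_equal(haplotype_distance(d, r), 1L)
})

test_that("distance errors when the requested range leaves the common coverage", {
  a <- mk("73G", cov = list(circular_range(57, 372)))
  b <- mk("73G", cov = list(circular_range(57, 372)))
  expect_error(haplotype_distance(a, b, list(circular_range(16024, 576))),
               "outside the common coverage")
})

test_that("distance is a pseudometric on a fixed range (random fixtures)", {
  set.seed(11)
  sites <- setdiff(c(16024:16383, 57:372), c(16193, 309))
  haps <- lapply(1:8, function(i) mk(random_motif(sites, sample(0:6, 1)),
                                     paste0("r", i), HVS12))
  n <- length(haps)
  D <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    D[i, j] <- haplotype_distance(haps[[i]], haps[[j]], HVS12)
  }
  expect_true(all(diag(D) == 0))
  expect_identical(D, t(D))
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_lte(D[i, j], D[i, k] + D[k, j])
  }
  # agreement with the independent token-set oracle
  for (i in 1:n) for (j in 1:n) {
    expect_equal(D[i, j], oracle_distance(format_motif(haps[[i]]),
                                          format_motif(haps[[j]])))
  }
})

test_that("shared haplotype groups merge zero-distance samples and flag partial evidence", {
  full_a <- mk("16069T, 73G", "a", HVS12)
  full_b <- mk("16069T, 73G", "b", HVS12)
  other <- mk("16224C", "c", HVS12)
  pop <- population_sample("P", list(full_a, full_b, other))
  g <- shared_haplotype_groups(pop, full_range = HVS12)
  expect_equal(g$group[g$sample_id == "a"], g$group[g$sample_id == "b"])
  expect_false(any(g$partial_evidence[g$sample_id %in% c("a", "b")]))

  # identical only over a small HVS-II window -> grouped but partial
  small <- list(circular_range(100, 300))
  p2 <- population_sample("Q", list(mk("263G", "x", HVS12), mk("263G", "y", small)))
  g2 <- shared_haplotype_groups(p2, full_range = HVS12)
  expect_equal(g2$group[1], g2$group[2])
  expect_true(all(g2$partial_evidence))

  # all distinct -> singletons
  p3 <- mkpop(c("73G", "146C", "263G"))
  expect_equal(sort(shared_haplotype_groups(p3)$group), 1:3)
})

test_that("haplotype tables round-trip through the TSV dialect", {
  pops <- list(
    mkpop(c("16069T, 16126C, 73G, 295T", "", "16291Y, 309.1C"), "ANC",
          HVS12, age = 96),
    mkpop(c("73G, 16224C", "263G"), "MOD", CR, age = 0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_haplotype_table(pops, path)
  back <- read_haplotype_table(path)
  expect_named(back, c("ANC", "MOD"))
  expect_equal(back$ANC$age_generations, 96)
  for (p in c("ANC", "MOD")) {
    orig <- if (p == "ANC") pops[[1]] else pops[[2]]
    for (i in seq_along(orig$haplotypes)) {
      expect_equal(format_motif(back[[p]]$haplotypes[[i]]),
                   format_motif(orig$haplotypes[[i]]))
      cov_str <- function(h) paste(vapply(h$coverage, format, character(1)),
                                   collapse = ";")
      expect_equal(cov_str(back[[p]]$haplotypes[[i]]),
                   cov_str(orig$haplotypes[[i]]))
    }
  }
})

test_that("table reading rejects duplicate ids, missing columns and bad positions", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tpopulation\tage_generations\tcoverage\tmotif",
               "s1\tP\t0\t16024-576\t73G",
               "s1\tP\t0\t16024-576\t263G"), path)
  expect_error(read_haplotype_table(path), "duplicate sample id")
  writeLines(c("sample_id\tpopulation\tmotif", "s1\tP\t73G"), path)
  expect_error(read_haplotype_table(path), "missing column")
  writeLines(c("sample_id\tpopulation\tage_generations\tcoverage\tmotif",
               "s1\tP\t0\t16024-576\t16570A"), path)
  expect_error(read_haplotype_table(path), "outside")
})

test_that("FASTA export realizes sequences over coverage", {
  ref <- rep("A", 16569)
  pop <- mkpop(c("60C", "60G, 62del"), "P", list(circular_range(57, 64)))
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(pop, path, ref)
  lines <- readLines(path)
  expect_equal(lines[1], ">P1")
  expect_equal(lines[2], "AAACAAAA")
  expect_equal(lines[4], "AAAGA-AA")
})
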