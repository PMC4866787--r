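# rCRS-relative control-region haplotypes with partial (circular) coverage.

MT_LENGTH <- 16569L

#' IUPAC nucleotide codes and the bases they denote
#' @noRd
.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Circular coordinate range on the mitochondrial genome
#'
#' Closed interval of 1-based rCRS coordinates. When `start > end` the range
#' wraps the replication origin, e.g. the control region 16024-576.
#'
#' @param start,end rCRS coordinates in 1..16569.
#' @return An object of class `circular_range`.
#' @examples
#' cr <- circular_range(16024, 576)
#' range_length(cr)  # 1122 sites
#' @export
circular_range <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start > MT_LENGTH ||
      end < 1L || end > MT_LENGTH) {
    stop("circular_range coordinates must lie in 1..", MT_LENGTH)
  }
  structure(list(start = start, end = end), class = "circular_range")
}

#' @export
print.circular_range <- function(x, ...) {
  cat(sprintf("<circular_range %d-%d (%d sites)>\n", x$start, x$end,
              range_length(x)))
  invisible(x)
}

#' @export
format.circular_range <- function(x, ...) sprintf("%d-%d", x$start, x$end)

#' Test whether positions fall inside a circular range
#' @param range a `circular_range`
#' @param pos integer vector of rCRS positions
#' @return logical vector
#' @export
range_contains <- function(range, pos) {
  if (range$start <= range$end) {
    pos >= range$start & pos <= range$end
  } else {
    pos >= range$start | pos <= range$end
  }
}

#' Number of sites in a circular range
#' @param range a `circular_range`
#' @export
range_length <- function(range) {
  if (range$start <= range$end) range$end - range$start + 1L
  else (MT_LENGTH - range$start + 1L) + range$end
}

#' All positions of a circular range, in circular order from its start
#' @noRd
range_positions <- function(range) {
  if (range$start <= range$end) seq.int(range$start, range$end)
  else c(seq.int(range$start, MT_LENGTH), seq.int(1L, range$end))
}

# Circular order index relative to the control-region start (16024 -> 0).
cr_order <- function(pos) (as.integer(pos) - 16024L) %% MT_LENGTH

#' Intersect two coverage lists on the circle
#'
#' Coverage is a list of `circular_range`s. The intersection is returned as a
#' (possibly empty) list of maximal ranges, ordered by control-region
#' position of their start. Commutative and idempotent.
#'
#' @param a,b lists of `circular_range` (a bare `circular_range` is accepted)
#' @return list of `circular_range`
#' @examples
#' common_range(list(circular_range(16000, 300)), list(circular_range(100, 576)))
#' @export
common_range <- function(a, b) {
  a <- as_coverage(a); b <- as_coverage(b)
  in_a <- rep(FALSE, MT_LENGTH); in_b <- rep(FALSE, MT_LENGTH)
  for (r in a) in_a[range_positions(r)] <- TRUE
  for (r in b) in_b[range_positions(r)] <- TRUE
  positions_to_ranges(which(in_a & in_b))
}

# Coerce a single range or list of ranges to a coverage list.
as_coverage <- function(x) {
  if (inherits(x, "circular_range")) return(list(x))
  if (is.list(x) && all(vapply(x, inherits, logical(1), "circular_range"))) {
    return(x)
  }
  stop("coverage must be a circular_range or a list of circular_range")
}

# Collapse a sorted set of positions into maximal circular runs.
positions_to_ranges <- function(pos) {
  if (length(pos) == 0L) return(list())
  if (length(pos) == MT_LENGTH) return(list(circular_range(1L, MT_LENGTH)))
  keep <- logical(MT_LENGTH); keep[pos] <- TRUE
  prev <- function(p) if (p == 1L) MT_LENGTH else p - 1L
  starts <- pos[!keep[vapply(pos, prev, integer(1))]]
  runs <- lapply(starts, function(s) {
    e <- s
    nxt <- if (e == MT_LENGTH) 1L else e + 1L
    while (keep[nxt]) {
      e <- nxt
      nxt <- if (e == MT_LENGTH) 1L else e + 1L
    }
    circular_range(s, e)
  })
  runs[order(vapply(runs, function(r) cr_order(r$start), numeric(1)))]
}

#' Parse an rCRS-relative haplotype motif string
#'
#' Motifs are comma-separated tokens: substitutions `<pos><base>` (IUPAC
#' ambiguity codes such as `16291Y` are preserved), insertions
#' `<pos>.<k><base>` (e.g. `309.1C`), deletions `<pos>del`. An empty motif
#' denotes identity with the rCRS over the covered range.
#'
#' @param text motif string (may be empty or NA for the rCRS itself)
#' @param coverage list of `circular_range` giving the sequenced (edition)
#'   range(s); every variant must fall inside it
#' @param sample_id identifier attached to the haplotype
#' @return A `control_region_haplotype`: list with `sample_id`, `variants`
#'   (data.frame `position`, `ins_index`, `observed`, `reference`) and
#'   `coverage`. Variants are sorted in control-region order (16024..16569,
#'   then 1..576).
#' @examples
#' h <- parse_motif("16069T, 16126C, 73G, 263G, 295T, 309.1C",
#'                  list(circular_range(16024, 576)), "EX1")
#' nrow(h$variants)
#' @export
parse_motif <- function(text, coverage, sample_id = "sample") {
  coverage <- as_coverage(coverage)
  if (length(coverage) == 0L) stop("coverage must be non-empty")
  if (is.null(text) || is.na(text)) text <- ""
  tokens <- trimws(strsplit(text, ",", fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) {
    return(control_region_haplotype(sample_id, empty_variants(), coverage))
  }
  rows <- lapply(tokens, parse_variant_token)
  v <- do.call(rbind, rows)
  control_region_haplotype(sample_id, v, coverage)
}

empty_variants <- function() {
  data.frame(position = integer(0), ins_index = integer(0),
             observed = character(0), reference = character(0),
             stringsAsFactors = FALSE)
}

parse_variant_token <- function(tok) {
  iupac <- paste(names(.IUPAC), collapse = "")
  m <- regmatches(tok, regexec(sprintf("^([0-9]+)\\.([0-9]+)([%s])$", iupac), tok))[[1]]
  if (length(m)) {
    pos <- as.integer(m[2]); k <- as.integer(m[3])
    if (k < 1L) stop("malformed motif token (insertion index < 1): ", tok)
    return(variant_row(pos, k, m[4]))
  }
  m <- regmatches(tok, regexec("^([0-9]+)(del|DEL|-)$", tok))[[1]]
  if (length(m)) return(variant_row(as.integer(m[2]), 0L, "del"))
  m <- regmatches(tok, regexec(sprintf("^([0-9]+)([%s])$", iupac), tok))[[1]]
  if (length(m)) return(variant_row(as.integer(m[2]), 0L, m[3]))
  stop("malformed motif token: '", tok, "'")
}

variant_row <- function(pos, k, obs, ref = NA_character_) {
  if (pos < 1L || pos > MT_LENGTH) {
    stop("variant position ", pos, " outside 1..", MT_LENGTH)
  }
  obs <- if (tolower(obs) %in% c("del", "-")) "del" else toupper(obs)
  data.frame(position = as.integer(pos), ins_index = as.integer(k),
             observed = obs, reference = ref,
             stringsAsFactors = FALSE)
}

#' Construct a control-region haplotype
#'
#' @param sample_id identifier
#' @param variants data.frame with columns `position`, `ins_index`,
#'   `observed`, `reference` (reference may be NA when the rCRS base is not
#'   tracked)
#' @param coverage list of `circular_range`
#' @export
control_region_haplotype <- function(sample_id, variants, coverage) {
  coverage <- as_coverage(coverage)
  stopifnot(is.data.frame(variants))
  if (nrow(variants)) {
    covered <- Reduce(`|`, lapply(coverage, range_contains, pos = variants$position))
    if (!all(covered)) {
      bad <- variants$position[!covered]
      stop("variant position(s) outside coverage for sample '", sample_id,
           "': ", paste(bad, collapse = ", "))
    }
    known_ref <- !is.na(variants$reference)
    subst <- variants$ins_index == 0L & variants$observed != "del"
    if (any(known_ref & subst & variants$observed == variants$reference)) {
      stop("substitution equal to the reference base in sample '", sample_id, "'")
    }
    ord <- order(cr_order(variants$position), variants$ins_index)
    variants <- variants[ord, , drop = FALSE]
    rownames(variants) <- NULL
    key <- paste(variants$position, variants$ins_index)
    if (anyDuplicated(key)) {
      stop("duplicate variant position in sample '", sample_id, "'")
    }
  }
  structure(list(sample_id = sample_id, variants = variants,
                 coverage = coverage),
            class = "control_region_haplotype")
}

#' @export
print.control_region_haplotype <- function(x, ...) {
  cat(sprintf("<haplotype %s: %d variant(s) over %s>\n", x$sample_id,
              nrow(x$variants),
              paste(vapply(x$coverage, format, character(1)), collapse = ";")))
  invisible(x)
}

#' Format a haplotype back to its canonical motif string
#'
#' Inverse of [parse_motif()] on canonical input: `format_motif(parse_motif(x))`
#' equals `x` up to whitespace.
#' @param h a `control_region_haplotype`
#' @export
format_motif <- function(h) {
  v <- h$variants
  if (!nrow(v)) return("")
  tok <- ifelse(v$observed == "del", paste0(v$position, "del"),
         ifelse(v$ins_index > 0L,
                paste0(v$position, ".", v$ins_index, v$observed),
                paste0(v$position, v$observed)))
  paste(tok, collapse = ", ")
}

# State lookup at a position: observed base, "del", or "ref".
hap_state <- function(h, pos) {
  v <- h$variants
  i <- which(v$position == pos & v$ins_index == 0L)
  if (length(i)) v$observed[i[1]] else "ref"
}

# TRUE when two site states cannot be distinguished: IUPAC codes sharing a
# base are compatible, and an ambiguity code against the (possibly unknown)
# reference is treated as compatible -- conservative for kinship matching.
states_compatible <- function(a, b) {
  if (a == b) return(TRUE)
  if (a == "del" || b == "del") return(FALSE)
  if (a == "ref" || b == "ref") {
    other <- if (a == "ref") b else a
    return(length(.IUPAC[[other]]) > 1L)  # ambiguous code may include the ref base
  }
  length(intersect(.IUPAC[[a]], .IUPAC[[b]])) > 0L
}

#' Count differences between two haplotypes over a range
#'
#' Compares variant states at every position of `range`, which must lie
#' within the common coverage of both haplotypes. Insertions anchored at the
#' poly-C length-heteroplasmy sites (`ignore_indel_sites`, default 16193,
#' 309, 573) are disregarded, as is conventional for control-region
#' comparisons. An IUPAC ambiguity code compatible with the other state
#' counts as no difference; deletions are a distinct state.
#'
#' @param a,b `control_region_haplotype`s
#' @param range list of `circular_range` (default: the common coverage)
#' @param ignore_indel_sites anchor positions whose insertions are ignored
#' @return integer number of differences
#' @examples
#' cov <- list(circular_range(16024, 576))
#' x <- parse_motif("16069T, 73G", cov, "a")
#' y <- parse_motif("16069T, 73G, 16278T", cov, "b")
#' haplotype_distance(x, y)  # 1
#' @export
haplotype_distance <- function(a, b, range = NULL,
                               ignore_indel_sites = c(16193L, 309L, 573L)) {
  common <- common_range(a$coverage, b$coverage)
  if (is.null(range)) {
    range <- common
  } else {
    range <- as_coverage(range)
    inside <- common_range(range, common)
    if (sum(vapply(inside, range_length, integer(1))) !=
        sum(vapply(range, range_length, integer(1)))) {
      stop("comparison range extends outside the common coverage")
    }
  }
  if (length(range) == 0L) return(0L)
  in_range <- function(pos) {
    Reduce(`|`, lapply(range, range_contains, pos = pos), init = rep(FALSE, length(pos)))
  }
  # substitution / deletion sites
  pa <- a$variants[a$variants$ins_index == 0L, , drop = FALSE]
  pb <- b$variants[b$variants$ins_index == 0L, , drop = FALSE]
  sites <- union(pa$position, pb$position)
  sites <- sites[in_range(sites)]
  n <- 0L
  for (p in sites) {
    if (!states_compatible(hap_state(a, p), hap_state(b, p))) n <- n + 1L
  }
  # insertions (excluding the ignored length-heteroplasmy anchors)
  ins_keys <- function(h) {
    v <- h$variants[h$variants$ins_index > 0L, , drop = FALSE]
    v <- v[!(v$position %in% ignore_indel_sites) & in_range(v$position), ,
           drop = FALSE]
    if (!nrow(v)) character(0) else paste0(v$position, ".", v$ins_index, v$observed)
  }
  ka <- ins_keys(a); kb <- ins_keys(b)
  n + length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}

#' A named collection of haplotypes with a sampling age
#'
#' @param name population label
#' @param haplotypes list of `control_region_haplotype`
#' @param age_generations sampling age in generations before present
#'   (0 for modern populations)
#' @export
population_sample <- function(name, haplotypes, age_generations = 0) {
  stopifnot(length(haplotypes) >= 1L, age_generations >= 0)
  ids <- vapply(haplotypes, function(h) h$sample_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate sample id(s) in population '", name, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(list(name = name, haplotypes = haplotypes,
                 age_generations = age_generations),
            class = "population_sample")
}

#' @export
print.population_sample <- function(x, ...) {
  cat(sprintf("<population %s: n = %d, age = %g generations>\n", x$name,
              length(x$haplotypes), x$age_generations))
  invisible(x)
}

#' Group samples sharing a haplotype over their common range
#'
#' Two samples join the same group when their distance is zero over their
#' pairwise common coverage (groups are connected components of that
#' relation, which need not be transitive under partial coverage). A group is
#' flagged `partial_evidence` when the joint common range of its members is a
#' strict subset of `full_range`, i.e. identity could only be checked on part
#' of the region.
#'
#' @param pop a `population_sample`
#' @param full_range reference range for the partial-evidence flag; defaults
#'   to the union of the population's coverage
#' @param ignore_indel_sites passed to [haplotype_distance()]
#' @return data.frame with columns `sample_id`, `group`, `partial_evidence`
#' @export
shared_haplotype_groups <- function(pop, full_range = NULL,
                                    ignore_indel_sites = c(16193L, 309L, 573L)) {
  haps <- pop$haplotypes
  n <- length(haps)
  if (is.null(full_range)) {
    covered <- rep(FALSE, MT_LENGTH)
    for (h in haps) for (r in h$coverage) covered[range_positions(r)] <- TRUE
    full_range <- positions_to_ranges(which(covered))
  } else {
    full_range <- as_coverage(full_range)
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      cr <- common_range(haps[[i]]$coverage, haps[[j]]$coverage)
      if (length(cr) == 0L) next
      if (haplotype_distance(haps[[i]], haps[[j]], cr, ignore_indel_sites) == 0L) {
        parent[find(j)] <- find(i)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  group <- match(roots, unique(roots))
  full_len <- sum(vapply(full_range, range_length, integer(1)))
  partial <- vapply(seq_along(unique(roots)), function(g) {
    members <- haps[group == g]
    cr <- Reduce(common_range, lapply(members, function(h) h$coverage))
    sum(vapply(cr, range_length, integer(1))) < full_len
  }, logical(1))
  data.frame(sample_id = vapply(haps, function(h) h$sample_id, character(1)),
             group = group, partial_evidence = partial[group],
             stringsAsFactors = FALSE)
}

coverage_to_string <- function(coverage) {
  paste(vapply(coverage, format, character(1)), collapse = ";")
}

coverage_from_string <- function(s) {
  parts <- strsplit(trimws(s), ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  if (!length(parts)) stop("empty coverage field")
  lapply(parts, function(p) {
    m <- regmatches(p, regexec("^([0-9]+)-([0-9]+)$", trimws(p)))[[1]]
    if (!length(m)) stop("malformed coverage range: '", p, "'")
    circular_range(as.integer(m[2]), as.integer(m[3]))
  })
}

#' Read population samples from a haplotype TSV table
#'
#' The canonical exchange format has a header row and columns `sample_id`,
#' `population`, `age_generations`, `coverage` (semicolon-separated
#' `start-end` pairs) and `motif` (comma-separated rCRS-relative variants).
#'
#' @param path file path
#' @return named list of `population_sample` in order of first appearance
#' @export
read_haplotype_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  required <- c("sample_id", "population", "age_generations", "coverage", "motif")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("haplotype table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  pops <- unique(df$population)
  out <- lapply(pops, function(p) {
    rows <- df[df$population == p, , drop = FALSE]
    age <- unique(as.numeric(rows$age_generations))
    if (length(age) != 1L) {
      stop("population '", p, "' has inconsistent age_generations")
    }
    haps <- lapply(seq_len(nrow(rows)), function(i) {
      parse_motif(rows$motif[i], coverage_from_string(rows$coverage[i]),
                  rows$sample_id[i])
    })
    population_sample(p, haps, age)
  })
  names(out) <- pops
  out
}

#' Write population samples to the canonical haplotype TSV
#'
#' @param samples a `population_sample` or list of them
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_haplotype_table <- function(samples, path) {
  if (inherits(samples, "population_sample")) samples <- list(samples)
  rows <- do.call(rbind, lapply(samples, function(pop) {
    data.frame(
      sample_id = vapply(pop$haplotypes, function(h) h$sample_id, character(1)),
      population = pop$name,
      age_generations = pop$age_generations,
      coverage = vapply(pop$haplotypes, function(h) coverage_to_string(h$coverage),
                        character(1)),
      motif = vapply(pop$haplotypes, format_motif, character(1)),
      stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write realized sequences over coverage as FASTA
#'
#' Reconstructs each sample's sequence over its covered range by applying its
#' variants to a reference sequence, and writes one FASTA record per sample
#' (record id = sample id). A reference must be supplied because the package
#' does not bundle the rCRS; simulated datasets carry their own root
#' reference.
#'
#' @param pop a `population_sample`
#' @param path output path
#' @param reference character vector of length 16569 (one base per rCRS
#'   position)
#' @export
write_fasta <- function(pop, path, reference) {
  stopifnot(length(reference) == MT_LENGTH)
  con <- file(path, "w"); on.exit(close(con))
  for (h in pop$haplotypes) {
    pos <- unlist(lapply(h$coverage, range_positions))
    seq <- reference[pos]
    v <- h$variants
    for (i in seq_len(nrow(v))) {
      j <- match(v$position[i], pos)
      if (v$ins_index[i] > 0L) next  # insertions appended after the anchor below
      seq[j] <- if (v$observed[i] == "del") "-" else v$observed[i]
    }
    ins <- v[v$ins_index > 0L, , drop = FALSE]
    if (nrow(ins)) {
      for (i in rev(seq_len(nrow(ins)))) {
        j <- match(ins$position[i], pos)
        seq <- append(seq, ins$observed[i], after = j)
        pos <- append(pos, NA_integer_, after = j)
      }
    }
    writeLines(sprintf(">%s", h$sample_id), con)
    writeLines(paste(seq, collapse = ""), con)
  }
  invisible(path)
}
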