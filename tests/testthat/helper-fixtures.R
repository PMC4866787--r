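# Shared fixtures and independent oracles.

CR <- list(circular_range(16024L, 576L))
HVS12 <- list(circular_range(16024L, 16383L), circular_range(57L, 372L))

mk <- function(motif, id = "s", cov = CR) parse_motif(motif, cov, id)

mkpop <- function(motifs, name = "P", cov = CR, age = 0) {
  population_sample(name, lapply(seq_along(motifs), function(i) {
    parse_motif(motifs[i], cov, paste0(name, i))
  }), age)
}

# Independent distance oracle: token-set arithmetic on motif strings over a
# fully shared range, no ambiguity codes, insertions at the poly-C anchors
# dropped. Used only on fixtures that satisfy those assumptions.
oracle_distance <- function(m1, m2, anchors = c("16193", "309", "573")) {
  toks <- function(m) {
    t <- trimws(strsplit(m, ",")[[1]])
    t <- t[nzchar(t)]
    ins <- grepl("\\.", t)
    drop <- ins & sub("\\..*$", "", t) %in% anchors
    t[!drop]
  }
  a <- toks(m1); b <- toks(m2)
  # insertions compare as whole tokens; substitutions by position
  pos <- function(t) sub("^([0-9]+).*$", "\\1", t)
  ia <- a[grepl("\\.", a)]; ib <- b[grepl("\\.", b)]
  sa <- a[!grepl("\\.", a)]; sb <- b[!grepl("\\.", b)]
  n_ins <- length(setdiff(ia, ib)) + length(setdiff(ib, ia))
  all_pos <- union(pos(sa), pos(sb))
  state <- function(s, p) {
    i <- match(p, pos(s))
    if (is.na(i)) "ref" else sub("^[0-9]+", "", s[i])
  }
  n_sub <- sum(vapply(all_pos, function(p) state(sa, p) != state(sb, p), logical(1)))
  n_ins + n_sub
}

oracle_pi <- function(motifs) {
  n <- length(motifs)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    tot <- tot + oracle_distance(motifs[i], motifs[j])
  }
  2 * tot / (n * (n - 1))
}

oracle_gene_diversity <- function(motifs) {
  n <- length(motifs)
  counts <- table(vapply(motifs, function(m) {
    paste(sort(trimws(strsplit(m, ",")[[1]])), collapse = "|")
  }, character(1)))
  p <- as.numeric(counts) / n
  n * (1 - sum(p^2)) / (n - 1)
}

# random motif over a site pool (substitutions only, no ambiguity)
random_motif <- function(sites, k) {
  if (k == 0) return("")
  pos <- sample(sites, k)
  paste(paste0(pos, sample(c("A", "C", "G", "T"), k, replace = TRUE)),
        collapse = ", ")
}
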