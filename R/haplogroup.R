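# Haplogroup assignment from control-region motifs and minisequenced
# coding-region diagnostics, over a reduced hand-curated phylogeny.

#' Minisequencing panel positions accepted in a coding call set
#'
#' Single-base-extension panel for subtyping R0/H lineages (H1, H1bh, H2a,
#' H3, H4, H5'36, H6a, H7, H8, H9, H10, H11, H12, H13a1, H15) plus the 7028
#' and 11467 fallback discriminators for H and U.
#' @export
CODING_PANEL <- c(3010L, 11377L, 4769L, 6776L, 3992L, 456L, 3915L, 4793L,
                  13101L, 13020L, 14470L, 8448L, 3936L, 4745L, 6253L,
                  7028L, 11467L)

#' Load a haplogroup tree fixture
#'
#' The fixture is a tab-separated table with columns `name`, `parent`,
#' `cr_motif` (comma-separated rCRS-relative control-region variants required
#' at the node, incremental over the parent) and `coding_diagnostics`
#' (semicolon/comma-separated `position:base` pairs from the minisequencing
#' panel). The shipped tree is a reduced, hand-curated phylogeny restricted
#' to lineages relevant to Iberian ancient/modern control-region studies; it
#' can be replaced by the user.
#'
#' @param path fixture path; defaults to the tree shipped with the package
#' @return a `haplogroup_tree`: named list of nodes with accumulated
#'   requirements
#' @export
load_haplogroup_tree <- function(path = system.file("extdata", "haplogroup_tree.tsv",
                                                    package = "mtcontinuity")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  stopifnot(all(c("name", "parent", "cr_motif", "coding_diagnostics") %in% names(df)))
  nodes <- list()
  for (i in seq_len(nrow(df))) {
    nm <- df$name[i]
    parent <- df$parent[i]
    if (!nzchar(parent)) parent <- NA_character_
    motif <- trimws(strsplit(df$cr_motif[i], ",", fixed = TRUE)[[1]])
    motif <- motif[nzchar(motif)]
    own_motif <- if (length(motif)) do.call(rbind, lapply(motif, parse_variant_token))
                 else empty_variants()
    coding <- parse_coding_spec(df$coding_diagnostics[i])
    nodes[[nm]] <- list(name = nm, parent = parent, own_motif = own_motif,
                        own_coding = coding, children = character(0))
  }
  roots <- names(nodes)[vapply(nodes, function(n) is.na(n$parent), logical(1))]
  if (length(roots) != 1L) stop("tree must have exactly one root, found: ",
                                paste(roots, collapse = ", "))
  for (nm in names(nodes)) {
    p <- nodes[[nm]]$parent
    if (!is.na(p)) {
      if (is.null(nodes[[p]])) stop("unknown parent '", p, "' of node '", nm, "'")
      nodes[[p]]$children <- c(nodes[[p]]$children, nm)
    }
  }
  # depth + cycle check
  for (nm in names(nodes)) {
    seen <- character(0); cur <- nm
    while (!is.na(nodes[[cur]]$parent)) {
      if (cur %in% seen) stop("cycle in haplogroup tree at '", cur, "'")
      seen <- c(seen, cur); cur <- nodes[[cur]]$parent
    }
    nodes[[nm]]$depth <- length(seen)
  }
  structure(list(nodes = nodes, root = roots), class = "haplogroup_tree")
}

parse_coding_spec <- function(s) {
  parts <- trimws(strsplit(s, "[;,]")[[1]])
  parts <- parts[nzchar(parts)]
  if (!length(parts)) {
    return(data.frame(position = integer(0), base = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(parts, function(p) {
    m <- regmatches(p, regexec("^([0-9]+):([ACGT])$", p))[[1]]
    if (!length(m)) stop("malformed coding diagnostic: '", p, "'")
    data.frame(position = as.integer(m[2]), base = m[3], stringsAsFactors = FALSE)
  }))
  out
}

#' Validate a minisequencing coding call set
#'
#' @param calls named vector/list: names are coding positions (restricted to
#'   [CODING_PANEL]), values observed bases
#' @return named character vector of calls
#' @export
coding_call_set <- function(calls) {
  if (is.null(calls) || length(calls) == 0L) return(character(0))
  pos <- as.integer(names(calls))
  if (anyNA(pos) || !all(pos %in% CODING_PANEL)) {
    stop("coding call positions restricted to the minisequencing panel: ",
         paste(CODING_PANEL, collapse = ", "))
  }
  out <- toupper(unlist(calls, use.names = FALSE))
  stopifnot(all(out %in% c("A", "C", "G", "T")))
  names(out) <- pos
  out
}

# Evaluate one node's own requirements against a haplotype + coding calls.
# Returns list(status, n_positive, n_unobserved, coding_positive).
# status: "blocked" (an observed requirement contradicts), "supported"
# (>=1 positively observed, none contradicted, or empty requirement set),
# "unobserved" (non-empty requirements, none observable).
node_status <- function(node, hap, calls) {
  n_pos <- 0L; n_unobs <- 0L; coding_pos <- FALSE
  m <- node$own_motif
  for (i in seq_len(nrow(m))) {
    p <- m$position[i]
    covered <- any(vapply(hap$coverage, function(r) range_contains(r, p), logical(1)))
    if (!covered) { n_unobs <- n_unobs + 1L; next }
    if (m$ins_index[i] > 0L) {
      v <- hap$variants
      hit <- any(v$position == p & v$ins_index == m$ins_index[i] &
                 v$observed == m$observed[i])
      if (hit) n_pos <- n_pos + 1L else return(list(status = "blocked"))
    } else {
      st <- hap_state(hap, p)
      if (st == "ref") return(list(status = "blocked"))
      if (states_compatible(st, m$observed[i])) n_pos <- n_pos + 1L
      else return(list(status = "blocked"))
    }
  }
  cd <- node$own_coding
  for (i in seq_len(nrow(cd))) {
    key <- as.character(cd$position[i])
    if (is.null(calls) || !(key %in% names(calls))) { n_unobs <- n_unobs + 1L; next }
    if (calls[[key]] == cd$base[i]) { n_pos <- n_pos + 1L; coding_pos <- TRUE }
    else return(list(status = "blocked"))
  }
  n_req <- nrow(m) + nrow(cd)
  status <- if (n_req == 0L) "supported"
            else if (n_pos > 0L) "supported"
            else "unobserved"
  list(status = status, n_positive = n_pos, n_unobserved = n_unobs,
       coding_positive = coding_pos)
}

#' Classify a haplotype into a haplogroup
#'
#' Walks the tree from the root, descending into the child whose (incremental)
#' defining requirements are satisfied within the haplotype's coverage.
#' Requirement positions outside coverage (or coding positions without a
#' call) are treated as unobserved: they neither support nor block a node.
#' A node is entered only when at least one of its defining requirements is
#' positively observed and none is contradicted. Descent stops at the deepest
#' such node; the label carries a `*` uncertainty suffix when a defining
#' position along the path, or of a child that could refine the label, was
#' unobserved.
#'
#' Ties between sibling clades (possible with back-mutations) are broken in
#' favour of the sibling with more positively observed defining positions;
#' if both are supported by mutually exclusive minisequencing calls a
#' classification error is raised, otherwise the parent is returned with the
#' uncertainty flag.
#'
#' @param hap a `control_region_haplotype`
#' @param coding optional coding call set (see [coding_call_set()])
#' @param tree a `haplogroup_tree`
#' @return list with `label` (string, `*`-suffixed when uncertain), `node`
#'   (tree node name), `uncertain` (logical) and `trace` (data.frame of
#'   evaluated nodes and statuses)
#' @export
classify_haplogroup <- function(hap, coding = NULL,
                                tree = load_haplogroup_tree()) {
  calls <- coding_call_set(coding)
  nodes <- tree$nodes
  cur <- tree$root
  uncertain <- FALSE
  trace <- list()
  repeat {
    kids <- nodes[[cur]]$children
    if (!length(kids)) break
    st <- lapply(kids, function(k) node_status(nodes[[k]], hap, calls))
    names(st) <- kids
    for (k in kids) {
      trace[[length(trace) + 1L]] <- data.frame(node = k, status = st[[k]]$status,
                                                stringsAsFactors = FALSE)
    }
    supported <- kids[vapply(st, function(s) s$status == "supported", logical(1))]
    unobserved <- kids[vapply(st, function(s) s$status == "unobserved", logical(1))]
    if (length(unobserved)) uncertain <- TRUE
    if (!length(supported)) break
    if (length(supported) > 1L) {
      npos <- vapply(supported, function(k) st[[k]]$n_positive, integer(1))
      best <- supported[npos == max(npos)]
      if (length(best) > 1L) {
        via_coding <- vapply(best, function(k) st[[k]]$coding_positive, logical(1))
        if (sum(via_coding) >= 2L) {
          stop("conflicting coding calls: mutually exclusive clades ",
               paste(best[via_coding], collapse = " and "),
               " are both supported")
        }
        uncertain <- TRUE
        break
      }
      supported <- best
    }
    if (st[[supported]]$n_unobserved > 0L) uncertain <- TRUE
    cur <- supported
  }
  label <- if (uncertain) paste0(cur, "*") else cur
  list(label = label, node = cur, uncertain = uncertain,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(node = character(0), status = character(0)))
}

#' Default basal tier used to pool subhaplogroups
#'
#' Subhaplogroups are grouped into their basal haplogroup for frequency-based
#' comparisons (PCA), since datasets rarely share the same resolution.
#' @export
BASAL_TIER <- c("R0", "HV0", "H", "J", "T", "K", "U5", "U6a", "W", "X2", "L1b")

#' Collapse a haplogroup label to its basal haplogroup
#'
#' @param label haplogroup label (a `*` uncertainty suffix is ignored)
#' @param tree a `haplogroup_tree`
#' @param basal node names forming the basal tier
#' @return basal label (the node itself if already at or above the tier)
#' @export
collapse_to_basal <- function(label, tree = load_haplogroup_tree(),
                              basal = BASAL_TIER) {
  nm <- sub("\\*$", "", label)
  if (is.null(tree$nodes[[nm]])) stop("unknown haplogroup label: '", label, "'")
  cur <- nm
  while (!(cur %in% basal)) {
    p <- tree$nodes[[cur]]$parent
    if (is.na(p)) return(nm)  # above the basal tier
    cur <- p
  }
  cur
}

#' Haplogroup frequencies of a population
#'
#' Classifies every sample and tabulates label counts and frequencies.
#' Samples listed together in `merge_groups` (e.g. probable maternal kin
#' recovered from one burial group) are counted as a single lineage.
#'
#' @param pop a `population_sample`
#' @param coding named list: per-sample coding call sets (names = sample ids)
#' @param tier `"full"` for the assigned labels, `"basal"` to pool into
#'   [BASAL_TIER]
#' @param merge_groups list of character vectors of sample ids, each counted
#'   once
#' @param tree a `haplogroup_tree`
#' @return data.frame `label`, `count`, `frequency` (frequencies sum to 1);
#'   attribute `n` holds the number of counted lineages
#' @export
haplogroup_frequencies <- function(pop, coding = list(), tier = c("full", "basal"),
                                   merge_groups = NULL,
                                   tree = load_haplogroup_tree()) {
  tier <- match.arg(tier)
  ids <- vapply(pop$haplotypes, function(h) h$sample_id, character(1))
  keep <- rep(TRUE, length(ids))
  if (!is.null(merge_groups)) {
    for (g in merge_groups) {
      idx <- match(g, ids)
      if (anyNA(idx)) stop("merge group names unknown sample(s): ",
                           paste(g[is.na(idx)], collapse = ", "))
      keep[idx[-1]] <- FALSE
    }
  }
  labels <- vapply(which(keep), function(i) {
    h <- pop$haplotypes[[i]]
    cls <- classify_haplogroup(h, coding[[h$sample_id]], tree)
    if (tier == "basal") collapse_to_basal(cls$label, tree) else cls$label
  }, character(1))
  tab <- table(labels)
  out <- data.frame(label = names(tab), count = as.integer(tab),
                    frequency = as.numeric(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(out$label), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n") <- sum(keep)
  out
}
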