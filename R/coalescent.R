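# Serial-sampling (heterochronous) coalescent over structured populations,
# with HKY85 sequence evolution along the genealogy. mtDNA is treated as
# haploid and maternally inherited: within a deme of effective female size
# N_e the pairwise coalescence rate is 1/N_e per generation.

#' Demographic scenario for the serial coalescent
#'
#' A scenario is a deme topology: sampled populations (each with a sample
#' size and a sampling age in generations before present), and an ordered
#' set of merge events moving lineages from a derived deme into its ancestral
#' deme backward in time. Effective sizes and event times are symbolic
#' parameter names, filled in from a prior draw at simulation time.
#'
#' @param name scenario label
#' @param samples data.frame with columns `label` (population label carried
#'   by the output), `deme` (deme the lineages are sampled from), `n`
#'   (sample size), `age` (sampling age, generations)
#' @param events data.frame with columns `param` (name of the time
#'   parameter), `from`, `to` (demes: at the drawn time, lineages in `from`
#'   move to `to`)
#' @param ne_params named character vector mapping each deme to the name of
#'   its effective-size parameter
#' @param constraints list of `c(later, earlier)` parameter-name pairs
#'   enforcing `later > earlier` by rejection at draw time
#' @return object of class `abc_scenario`
#' @export
abc_scenario <- function(name, samples, events, ne_params, constraints = list()) {
  stopifnot(all(c("label", "deme", "n", "age") %in% names(samples)))
  stopifnot(all(c("param", "from", "to") %in% names(events)) || nrow(events) == 0L)
  stopifnot(all(samples$deme %in% names(ne_params)))
  params <- unique(c(unname(ne_params), if (nrow(events)) events$param))
  structure(list(name = name, samples = samples, events = events,
                 ne_params = ne_params, constraints = constraints,
                 param_names = params),
            class = "abc_scenario")
}

#' The two competing demographic scenarios for an ancient/modern triad
#'
#' Builds the "genealogical continuity" and "genealogical independence"
#' scenarios for one ancient population (default label `LH`, sampled at
#' `t_s` generations before present) and two modern populations (`LG`,
#' `AL`). Under continuity the ancient sample is drawn from the direct
#' ancestor deme of the first modern population, and the second modern
#' population splits from that lineage at `t_split`. Under independence the
#' ancient lineage splits from the ancestor of both modern populations at
#' `t_anc`, constrained to predate their own split, and contributes no
#' ancestry to either.
#'
#' @param n_ancient,n_modern1,n_modern2 sample sizes (defaults 24, 51, 56)
#' @param t_s ancient sampling age in generations (default 96: a 5th-century
#'   BC horizon at 25 years/generation)
#' @param labels population labels in the order ancient, modern1, modern2
#' @return list of two `abc_scenario` objects
#' @export
default_scenarios <- function(n_ancient = 24L, n_modern1 = 51L, n_modern2 = 56L,
                              t_s = 96, labels = c("LH", "LG", "AL")) {
  a <- labels[1]; m1 <- labels[2]; m2 <- labels[3]
  continuity <- abc_scenario(
    name = "continuity",
    samples = data.frame(label = c(a, m1, m2),
                         deme = c(m1, m1, m2),
                         n = c(n_ancient, n_modern1, n_modern2),
                         age = c(t_s, 0, 0),
                         stringsAsFactors = FALSE),
    events = data.frame(param = "t_split", from = m2, to = m1,
                        stringsAsFactors = FALSE),
    ne_params = stats::setNames(c(paste0("N_", m1), paste0("N_", m2)), c(m1, m2)))
  independence <- abc_scenario(
    name = "independence",
    samples = data.frame(label = c(a, m1, m2),
                         deme = c(a, m1, m2),
                         n = c(n_ancient, n_modern1, n_modern2),
                         age = c(t_s, 0, 0),
                         stringsAsFactors = FALSE),
    events = data.frame(param = c("t_split", "t_anc"),
                        from = c(m2, a), to = c(m1, m1),
                        stringsAsFactors = FALSE),
    ne_params = stats::setNames(c(paste0("N_", a), paste0("N_", m1), paste0("N_", m2)),
                                c(a, m1, m2)),
    constraints = list(c("t_anc", "t_split")))
  list(continuity = continuity, independence = independence)
}

#' Uniform prior specification
#'
#' Named list of `c(lower, upper)` bounds, one entry per scenario parameter
#' plus `mu`, the per-site per-generation mutation rate (default bounds
#' 1e-8 to 1e-6).
#'
#' @param scenarios list of `abc_scenario` (bounds are created for every
#'   parameter used by any of them)
#' @param ne_bounds bounds for every effective-size parameter
#' @param time_bounds bounds for every event-time parameter
#' @param mu_bounds bounds for the mutation rate
#' @return named list of bounds, class `abc_priors`
#' @export
default_priors <- function(scenarios, ne_bounds = c(100, 50000),
                           time_bounds = c(97, 4000),
                           mu_bounds = c(1e-8, 1e-6)) {
  params <- unique(unlist(lapply(scenarios, `[[`, "param_names")))
  pri <- lapply(params, function(p) {
    if (startsWith(p, "N_")) ne_bounds else time_bounds
  })
  names(pri) <- params
  pri$mu <- mu_bounds
  for (b in pri) stopifnot(b[1] < b[2])
  structure(pri, class = "abc_priors")
}

#' Draw scenario parameters from uniform priors
#'
#' Ordering constraints are enforced by rejection.
#' @param scenario an `abc_scenario`
#' @param priors an `abc_priors`
#' @return named list of parameter values including `mu`
#' @export
draw_params <- function(scenario, priors) {
  repeat {
    p <- lapply(priors[scenario$param_names], function(b) stats::runif(1, b[1], b[2]))
    names(p) <- scenario$param_names
    ok <- all(vapply(scenario$constraints, function(cn) {
      p[[cn[1]]] > p[[cn[2]]]
    }, logical(1)))
    if (ok) break
  }
  p$mu <- stats::runif(1, priors$mu[1], priors$mu[2])
  p
}

#' Simulate a genealogy under the serial coalescent
#'
#' Lineages enter their deme at their sampling age; within a deme holding
#' `k` lineages of effective size `N`, coalescences occur at rate
#' `k(k-1)/(2N)` per generation. At each merge event all lineages of the
#' derived deme move to the ancestral deme (which keeps its own size).
#' Returns a binary tree over all sampled lineages.
#'
#' @param scenario an `abc_scenario`
#' @param params named list of parameter values (see [draw_params()])
#' @return list with `n_tips`, `parent` (parent index per node, 0 at root),
#'   `time` (node times in generations), `tip_label` (population label per
#'   tip), `tmrca`
#' @export
simulate_genealogy <- function(scenario, params) {
  smp <- scenario$samples
  n_tips <- sum(smp$n)
  n_nodes <- 2L * n_tips - 1L
  parent <- integer(n_nodes)
  node_time <- numeric(n_nodes)
  tip_label <- rep(smp$label, smp$n)
  tip_deme <- rep(smp$deme, smp$n)
  tip_age <- rep(smp$age, smp$n)
  node_time[seq_len(n_tips)] <- tip_age

  ev <- scenario$events
  ev_times <- if (nrow(ev)) vapply(ev$param, function(p) params[[p]], numeric(1))
              else numeric(0)
  if (nrow(ev)) {
    o <- order(ev_times)
    ev <- ev[o, , drop = FALSE]; ev_times <- ev_times[o]
    if (any(diff(ev_times) <= 0)) stop("event times must be strictly increasing")
    for (i in seq_len(nrow(smp))) {
      affecting <- ev_times[ev$from == smp$deme[i]]
      if (length(affecting) && smp$age[i] >= min(affecting)) {
        stop("ancient sampling age must predate the first event affecting its deme")
      }
    }
  }
  ne <- vapply(scenario$ne_params, function(p) params[[p]], numeric(1))
  if (any(ne <= 0)) stop("effective sizes must be positive")

  # demes as integer ids; schedule of sample entries and merges as vectors
  deme_names <- names(ne)
  n_demes <- length(deme_names)
  smp_deme_id <- match(smp$deme, deme_names)
  sched_time <- c(smp$age, ev_times)
  sched_enter <- c(rep(TRUE, nrow(smp)), rep(FALSE, length(ev_times)))
  sched_idx <- c(seq_len(nrow(smp)), seq_along(ev_times))
  o <- order(sched_time, !sched_enter)
  sched_time <- sched_time[o]; sched_enter <- sched_enter[o]
  sched_idx <- sched_idx[o]
  ev_from <- match(ev$from, deme_names); ev_to <- match(ev$to, deme_names)

  active <- vector("list", n_demes)   # lineage ids per deme
  for (d in seq_len(n_demes)) active[[d]] <- integer(0)
  k <- integer(n_demes)               # lineage counts per deme
  t <- 0
  next_internal <- n_tips
  si <- 1L
  n_sched <- length(sched_time)
  repeat {
    rates <- k * (k - 1L) / (2 * ne)
    total <- sum(rates)
    t_next_sched <- if (si <= n_sched) sched_time[si] else Inf
    dt <- if (total > 0) stats::rexp(1L, total) else Inf
    if (t + dt < t_next_sched) {
      t <- t + dt
      d <- if (n_demes == 1L) 1L else
        sample.int(n_demes, 1L, prob = rates / total)
      lin <- active[[d]]
      pair <- if (length(lin) == 2L) 1:2 else sample.int(length(lin), 2L)
      next_internal <- next_internal + 1L
      parent[lin[pair]] <- next_internal
      node_time[next_internal] <- t
      lin[pair[1L]] <- next_internal
      active[[d]] <- lin[-pair[2L]]
      k[d] <- k[d] - 1L
      if (sum(k) == 1L && si > n_sched) break
    } else {
      if (is.infinite(t_next_sched)) break
      t <- t_next_sched
      if (sched_enter[si]) {
        i <- sched_idx[si]
        d <- smp_deme_id[i]
        new_ids <- which(tip_deme == smp$deme[i] & tip_age == smp$age[i] &
                         tip_label == smp$label[i])
        active[[d]] <- c(active[[d]], new_ids)
        k[d] <- k[d] + length(new_ids)
      } else {
        e <- sched_idx[si]
        active[[ev_to[e]]] <- c(active[[ev_to[e]]], active[[ev_from[e]]])
        k[ev_to[e]] <- k[ev_to[e]] + k[ev_from[e]]
        active[[ev_from[e]]] <- integer(0)
        k[ev_from[e]] <- 0L
      }
      si <- si + 1L
    }
  }
  root <- next_internal
  list(n_tips = n_tips, parent = parent, time = node_time,
       tip_label = tip_label, tmrca = node_time[root], root = root)
}

#' HKY85 mutation model
#'
#' @param kappa transition/transversion rate ratio (> 0)
#' @param base_frequencies named frequencies for A, C, G, T (sum to 1);
#'   defaults approximate the base composition of the human mtDNA control
#'   region
#' @param L sequence length in sites (default 1122, the control region
#'   16024-576)
#' @export
hky_model <- function(kappa = 20,
                      base_frequencies = c(A = 0.31, C = 0.31, G = 0.13, T = 0.25),
                      L = 1122L) {
  stopifnot(kappa > 0, abs(sum(base_frequencies) - 1) < 1e-9,
            identical(names(base_frequencies), c("A", "C", "G", "T")), L >= 1L)
  structure(list(kappa = kappa, base_frequencies = base_frequencies,
                 L = as.integer(L)),
            class = "hky_model")
}

# Row-normalized replacement probabilities of the HKY rate matrix
# (diagonal excluded). Bases coded 1=A, 2=C, 3=G, 4=T; transitions A<->G,
# C<->T carry the kappa factor.
hky_replacement_matrix <- function(model) {
  pi <- unname(model$base_frequencies)
  k <- model$kappa
  ts_partner <- c(3L, 4L, 1L, 2L)
  P <- matrix(0, 4, 4)
  for (b in 1:4) for (c in 1:4) {
    if (b == c) next
    P[b, c] <- pi[c] * if (c == ts_partner[b]) k else 1
  }
  P / rowSums(P)
}

#' Evolve sequences along a genealogy under HKY
#'
#' The root sequence is drawn from the model's base frequencies; mutations
#' are placed as a Poisson process at rate `mu * L` per generation along each
#' branch. Each mutation hits a uniformly chosen site and replaces its base
#' by a draw from the HKY rate-matrix row of the current base (diagonal
#' excluded).
#'
#' @param tree a genealogy from [simulate_genealogy()]
#' @param model an [hky_model()]
#' @param mu per-site per-generation mutation rate
#' @return list with `sequences` (n_tips x L integer matrix, bases coded
#'   1=A..4=T), `root_sequence`, `tip_label`, `n_mutations`
#' @export
mutate_hky <- function(tree, model, mu) {
  stopifnot(mu >= 0)
  L <- model$L
  P <- hky_replacement_matrix(model)
  CP <- t(apply(P, 1, cumsum))  # row-wise cumulative replacement probabilities
  root_seq <- sample.int(4L, L, replace = TRUE,
                         prob = unname(model$base_frequencies))
  n_nodes <- length(tree$parent)
  seqs <- matrix(0L, tree$n_tips, L)
  n_mut_total <- 0L
  mutated <- integer(0)
  # children lists for a root-to-tips traversal
  kids <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) {
    p <- tree$parent[i]
    if (p > 0L) kids[[p]] <- c(kids[[p]], i)
  }
  stack <- list(list(node = tree$root, seq = root_seq))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (ch in kids[[top$node]]) {
      s <- top$seq
      brlen <- tree$time[top$node] - tree$time[ch]
      nm <- stats::rpois(1L, mu * L * brlen)
      if (nm > 0L) {
        n_mut_total <- n_mut_total + nm
        sites <- sample.int(L, nm, replace = TRUE)
        u <- stats::runif(nm)
        for (m in seq_len(nm)) {
          cp <- CP[s[sites[m]], ]
          s[sites[m]] <- 1L + (u[m] > cp[1L]) + (u[m] > cp[2L]) + (u[m] > cp[3L])
        }
        mutated <- c(mutated, sites)
      }
      if (ch <= tree$n_tips) seqs[ch, ] <- s
      else stack[[length(stack) + 1L]] <- list(node = ch, seq = s)
    }
  }
  list(sequences = seqs, root_sequence = root_seq,
       tip_label = tree$tip_label, n_mutations = n_mut_total,
       mutated_sites = unique(mutated))
}

# Map simulated site indices 1..L to rCRS control-region coordinates
# (16024..16569 then 1..576 when L = 1122).
sim_site_positions <- function(L) {
  cr <- c(seq.int(16024L, 16569L), seq.int(1L, 576L))
  if (L <= length(cr)) cr[seq_len(L)] else seq_len(L)
}
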