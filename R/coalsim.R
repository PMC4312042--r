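# Serial (heterochronous) coalescent simulation.
#
# This file holds the reference R implementation: an explicit genealogy
# builder and a finite-sites mutation layer.  The batch engine used for
# reference tables and pseudo-observed datasets lives in src/ and is
# cross-checked distributionally against this path in the test suite.
#
# Time runs backward in generations: modern lineages enter at t = 0,
# ancient lineages at t = ancient_age (55 by default).  With k lineages
# in a deme of haploid size N(t), the pairwise coalescence rate is
# k(k-1)/2 per N(t) generations; exponential-growth epochs are handled
# by closed-form inversion of the rescaled-time integral.

# piecewise description of a deme's size within an epoch:
# N(t) = scale * N0 * exp(-r * t)  (r = 0 for constant pieces)
main_branch_piece <- function(model, t) {
  r <- log(model$N0 / model$N_anc) / model$T_growth
  if (t >= model$T_growth) return(list(C = model$N_anc, r = 0))
  scale <- if (model$plague && t >= model$T_plague) 1 / model$f_plague else 1
  list(C = scale * model$N0, r = r)
}

# waiting time from s to next coalescence among k lineages, capped at
# `end`, for size N(t) = C exp(-r t); E is a fresh Exp(1) deviate
piece_wait <- function(E, k, s, end, C, r) {
  rate <- k * (k - 1) / 2
  if (rate == 0) return(Inf)
  if (r == 0) {
    tau <- E * C / rate
    if (s + tau > end) Inf else s + tau
  } else {
    # integral of rate/N(t) from s to x equals E  =>  solve for x
    val <- exp(r * s) + E * C * r / rate
    if (val <= 0) return(Inf)   # r < 0: hazard integral bounded below E
    x <- log(val) / r
    if (x > end) Inf else x
  }
}

#' Simulate a serial-coalescent genealogy
#'
#' Builds a binary rooted genealogy whose tips are `n_modern` lineages
#' entering at time 0 and `n_ancient` lineages entering at
#' `ancient_age` generations before present.  Under discontinuity
#' topologies the ancient lineages evolve in a separate branch (of
#' constant size `N_anc`) and can only coalesce with modern-side
#' lineages above `T_div`.
#'
#' @param model A [demographic_model()].
#' @param n_ancient,n_modern Tip counts (`n_modern >= 1`).
#' @param ancient_age Entry time of the ancient tips (default 55).
#' @param seed Optional integer seed.
#' @return An object of class `"genealogy"`: a list with `parent` and
#'   `time` vectors over `2 n_tips - 1` nodes (tips first: modern
#'   `1..n_modern`, then ancient), plus tip bookkeeping.
#' @export
simulate_genealogy <- function(model, n_ancient, n_modern,
                               ancient_age = 55, seed = NULL) {
  stopifnot(inherits(model, "demographic_model"),
            n_modern >= 1L, n_ancient >= 0L)
  if (n_ancient + n_modern < 2L)
    stop("need at least two tips in total", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  n_tips <- n_ancient + n_modern
  n_nodes <- 2L * n_tips - 1L
  parent <- integer(n_nodes)           # 0 = root
  node_time <- numeric(n_nodes)
  node_time[seq_len(n_modern)] <- 0
  if (n_ancient > 0L)
    node_time[n_modern + seq_len(n_ancient)] <- ancient_age

  # deme 1: main/modern branch; deme 2: ancient branch (discontinuity)
  anc_deme <- if (model$discontinuity) 2L else 1L
  active <- list(seq_len(n_modern), integer())
  next_node <- n_tips + 1L
  t_cur <- 0

  boundaries <- ancient_age
  if (model$plague) boundaries <- c(boundaries, model$T_plague)
  boundaries <- c(boundaries, model$T_growth)
  if (model$discontinuity) boundaries <- c(boundaries, model$T_div)
  boundaries <- sort(unique(boundaries[boundaries > 0]))
  entered <- n_ancient == 0L
  merged <- !model$discontinuity

  repeat {
    k1 <- length(active[[1L]]); k2 <- length(active[[2L]])
    if (entered && merged && (k1 + k2) <= 1L) break
    seg_end <- if (length(boundaries)) boundaries[1L] else Inf

    # candidate next coalescence per deme within the current segment
    p1 <- main_branch_piece(model, t_cur)
    t1 <- piece_wait(stats::rexp(1), k1, t_cur, seg_end, p1$C, p1$r)
    t2 <- if (k2 >= 2L)
      piece_wait(stats::rexp(1), k2, t_cur, seg_end, model$N_anc, 0)
    else Inf

    if (min(t1, t2) < seg_end) {
      d <- if (t1 <= t2) 1L else 2L
      t_cur <- min(t1, t2)
      pick <- sample(length(active[[d]]), 2L)
      pair <- active[[d]][pick]
      parent[pair] <- next_node
      node_time[next_node] <- t_cur
      active[[d]] <- c(active[[d]][-pick], next_node)
      next_node <- next_node + 1L
    } else {
      if (!is.finite(seg_end)) stop("coalescent failed to terminate")
      t_cur <- seg_end
      boundaries <- boundaries[-1L]
      if (t_cur == ancient_age && n_ancient > 0L) {
        active[[anc_deme]] <- c(active[[anc_deme]],
                                n_modern + seq_len(n_ancient))
        entered <- TRUE
      }
      if (model$discontinuity && t_cur == model$T_div) {
        active[[1L]] <- c(active[[1L]], active[[2L]])
        active[[2L]] <- integer()
        merged <- TRUE
      }
    }
  }

  structure(list(parent = parent, time = node_time, n_tips = n_tips,
                 n_modern = n_modern, n_ancient = n_ancient,
                 ancient_age = ancient_age,
                 tmrca = node_time[n_nodes],
                 total_length = sum(node_time[parent[parent > 0L]] -
                                    node_time[parent > 0L])),
            class = "genealogy")
}

#' @export
print.genealogy <- function(x, ...) {
  cat(sprintf(
    "<genealogy> %d modern + %d ancient tips, TMRCA = %.1f generations\n",
    x$n_modern, x$n_ancient, x$tmrca))
  invisible(x)
}

transition_partner <- c(A = "G", G = "A", C = "T", T = "C")

#' Drop finite-sites mutations on a genealogy
#'
#' Mutations fall on each branch as a Poisson process of rate `u * L`
#' per generation, hit sites chosen uniformly among the `L` window
#' positions, and change the current base: a transition with probability
#' `kappa / (kappa + 2)`, otherwise one of the two transversions at
#' random.  Tip variant sets are expressed relative to the root state
#' (the reference window).
#'
#' @param genealogy A [simulate_genealogy()] result.
#' @param u Mutation rate per site per generation.
#' @param L Number of sites (default 361).
#' @param kappa Transition:transversion bias (default 10).
#' @param reference Reference bases (length `L`); defaults to the
#'   packaged window.
#' @param seed Optional integer seed.
#' @return A list with elements `ancient` and `modern`, both
#'   [population_sample()] objects (ancient empty slot dropped when
#'   `n_ancient = 0`).
#' @export
mutate_genealogy <- function(genealogy, u, L = 361L, kappa = 10,
                             reference = NULL, seed = NULL) {
  stopifnot(inherits(genealogy, "genealogy"), u >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(reference)) {
    reference <- if (L == HVR1_LEN) unname(hvr1_reference())
                 else rep(c("A", "C", "G", "T"), length.out = L)
  }
  stopifnot(length(reference) == L)

  parent <- genealogy$parent
  n_nodes <- length(parent)
  n_tips <- genealogy$n_tips
  blen <- numeric(n_nodes)
  nz <- parent > 0L
  blen[nz] <- genealogy$time[parent[nz]] - genealogy$time[nz]
  n_mut <- stats::rpois(n_nodes, blen * u * L)
  mut_site <- lapply(n_mut, function(m) sample.int(L, m, replace = TRUE))

  children <- split(seq_len(n_nodes)[parent > 0L], parent[parent > 0L])
  tip_state <- vector("list", n_tips)
  p_transition <- kappa / (kappa + 2)

  # pre-order walk from the root, mutating a running state vector;
  # R's copy-on-modify keeps sibling states independent
  walk <- function(node, state) {
    sites <- mut_site[[node]]
    for (s in sites) {
      cur <- state[s]
      state[s] <- if (stats::runif(1) < p_transition)
        transition_partner[[cur]]
      else sample(setdiff(setdiff(c("A", "C", "G", "T"), cur),
                          transition_partner[[cur]]), 1L)
    }
    if (node <= n_tips) {
      tip_state[[node]] <<- state
    } else {
      for (ch in children[[as.character(node)]]) walk(ch, state)
    }
  }
  root <- which(parent == 0L)
  walk(root, reference)

  make_hap <- function(state) {
    idx <- which(state != reference)
    haplotype(HVR1_START + idx - 1L, state[idx])
  }
  mod_ids <- paste0("mod", seq_len(genealogy$n_modern))
  modern <- population_sample(
    "modern_sim", 0L, mod_ids,
    lapply(tip_state[seq_len(genealogy$n_modern)], make_hap))
  ancient <- NULL
  if (genealogy$n_ancient > 0L) {
    anc_ids <- paste0("anc", seq_len(genealogy$n_ancient))
    ancient <- population_sample(
      "ancient_sim", as.integer(round(genealogy$ancient_age)), anc_ids,
      lapply(tip_state[genealogy$n_modern + seq_len(genealogy$n_ancient)],
             make_hap))
  }
  list(ancient = ancient, modern = modern)
}

#' Simulate one reference-table record (reference R path)
#'
#' Draws one parameter vector from the priors, simulates the genealogy
#' and mutations, and computes the ten-statistic summary vector with the
#' same code path used for observed data.
#'
#' @param topology Model topology name.
#' @param priors A [prior_set()] for that topology.
#' @param config A [sampling_config()].
#' @param seed Integer seed (mandatory: records are addressed by seed).
#' @return A list with `topology`, `params`, `stats` (named length-10
#'   vector), and the simulated `samples`.
#' @export
simulate_record <- function(topology, priors, config, seed) {
  set.seed(seed)
  par <- draw_parameters(priors, 1L)
  model <- do.call(demographic_model, c(list(topology = topology),
                                        as.list(par)))
  gen <- simulate_genealogy(model, config$n_ancient, config$n_modern,
                            config$ancient_age)
  samp <- mutate_genealogy(gen, model$u, L = config$L, kappa = config$kappa)
  stats <- summary_vector(samp$ancient, samp$modern)
  list(topology = topology, params = par, stats = stats, samples = samp,
       genealogy = gen, seed = seed)
}

# root-state note: mutate_genealogy mutates relative to the reference
# window, so the root haplotype IS the reference; all statistics depend
# only on pairwise differences and are unaffected by that choice.
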