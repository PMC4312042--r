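# Demographic models and parameter priors.
#
# Four model topologies relate the medieval sample (55 generations ago)
# to a modern sample:
#   continuity            the medieval population is a direct ancestor of
#                         the modern one; exponential growth from an
#                         ancestral size N_anc starting T_growth
#                         generations ago (> 55) up to N0 at present
#   discontinuity         medieval and modern samples sit on two branches
#                         that only join T_div generations ago; the
#                         medieval branch does not contribute to the
#                         modern gene pool
#   *_plague              either topology plus an instantaneous reduction
#                         of the modern-branch size by a factor f_plague
#                         at T_plague (13th-century plague: ~27
#                         generations ago, survivors = 2/3 by default)
#
# Sizes are haploid (matrilineal female) effective sizes throughout.

MODEL_TOPOLOGIES <- c("continuity", "discontinuity",
                      "continuity_plague", "discontinuity_plague")

#' Construct a demographic model
#'
#' @param topology One of `"continuity"`, `"discontinuity"`,
#'   `"continuity_plague"`, `"discontinuity_plague"`.
#' @param N0 Modern (haploid, matrilineal) effective size.
#' @param N_anc Ancestral size before growth onset.
#' @param T_growth Growth onset, generations before present (> 55).
#' @param T_div Divergence time of the two branches (discontinuity
#'   topologies; > 55).
#' @param T_plague Bottleneck time in generations (plague topologies;
#'   default 27, i.e. the 13th century at 25 years per generation).
#' @param f_plague Survival fraction of the bottleneck in (0, 1];
#'   default 2/3 (a reduction by one-third).
#' @param u Mutation rate per site per generation.
#' @return An object of class `"demographic_model"`.
#' @export
demographic_model <- function(topology, N0, N_anc, T_growth, T_div = NA,
                              T_plague = 27, f_plague = 2 / 3, u = 2e-6) {
  topology <- match.arg(topology, MODEL_TOPOLOGIES)
  disc <- grepl("^discontinuity", topology)
  plague <- grepl("plague$", topology)
  if (N0 < 2 || N_anc < 2) stop("population sizes must be >= 2", call. = FALSE)
  if (T_growth <= 55) stop("T_growth must exceed 55 generations", call. = FALSE)
  if (disc) {
    if (is.na(T_div) || T_div <= 55)
      stop("discontinuity topologies need T_div > 55", call. = FALSE)
  } else T_div <- NA_real_
  if (plague) {
    if (!(f_plague > 0 && f_plague <= 1))
      stop("f_plague must lie in (0, 1]", call. = FALSE)
    if (T_plague <= 0 || T_plague >= 55)
      stop("T_plague must lie in (0, 55)", call. = FALSE)
  } else { T_plague <- NA_real_; f_plague <- NA_real_ }
  if (u < 0) stop("mutation rate must be non-negative", call. = FALSE)
  structure(list(topology = topology, N0 = N0, N_anc = N_anc,
                 T_growth = T_growth, T_div = T_div, T_plague = T_plague,
                 f_plague = f_plague, u = u,
                 discontinuity = disc, plague = plague),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat(sprintf("<demographic_model> %s: N0=%.4g N_anc=%.4g T_growth=%.4g",
              x$topology, x$N0, x$N_anc, x$T_growth))
  if (x$discontinuity) cat(sprintf(" T_div=%.4g", x$T_div))
  if (x$plague) cat(sprintf(" T_plague=%.4g f_plague=%.3f",
                            x$T_plague, x$f_plague))
  cat(sprintf(" u=%.3g\n", x$u))
  invisible(x)
}

#' Effective size at time t on the main (modern) branch
#'
#' Backward-time size trajectory: `N(t) = N0 exp(-r t)` for
#' `t <= T_growth` with `r = log(N0/N_anc)/T_growth`, and `N_anc` for
#' `t > T_growth`.  Plague topologies model an instantaneous reduction
#' by the factor `f_plague` at `T_plague` moving forward in time, so on
#' the ancestral side of `T_plague` (up to growth onset) the pre-plague
#' sizes are the growth curve divided by `f_plague`.
#'
#' @param model A [demographic_model()].
#' @param t Generations before present (vectorized, `t >= 0`).
#' @return Numeric vector of haploid effective sizes.
#' @export
size_trajectory <- function(model, t) {
  stopifnot(inherits(model, "demographic_model"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  r <- log(model$N0 / model$N_anc) / model$T_growth
  n <- ifelse(t <= model$T_growth, model$N0 * exp(-r * t), model$N_anc)
  if (model$plague) {
    pre <- t >= model$T_plague & t < model$T_growth
    n[pre] <- n[pre] / model$f_plague
  }
  n
}

#' Default priors for a model topology
#'
#' Each parameter gets a distribution kind and bounds: effective sizes
#' are log-uniform, times and the mutation rate uniform, and the plague
#' parameters fixed by default.  `N_anc <= N0` (growth) and
#' `T_growth > 55`, `T_div > 55` are enforced at draw time by rejection.
#'
#' Defaults: `N0`, `N_anc` log-uniform on `[1e2, 1e6]`; `T_growth`
#' uniform on `[56, 1200]` generations; `T_div` uniform on `[56, 2000]`;
#' `u` uniform on `[5e-7, 5e-6]` per site per generation;
#' `T_plague = 27`; `f_plague = 2/3`.
#'
#' @param topology One of the four model topologies.
#' @return An object of class `"prior_set"`: a named list of
#'   `list(dist, min, max)` or `list(dist = "fixed", value)` entries.
#' @export
default_priors <- function(topology = MODEL_TOPOLOGIES) {
  topology <- match.arg(topology)
  pr <- list(
    N0       = list(dist = "loguniform", min = 1e2, max = 1e6),
    N_anc    = list(dist = "loguniform", min = 1e2, max = 1e6),
    T_growth = list(dist = "uniform", min = 56, max = 1200),
    u        = list(dist = "uniform", min = 5e-7, max = 5e-6)
  )
  if (grepl("^discontinuity", topology))
    pr$T_div <- list(dist = "uniform", min = 56, max = 2000)
  if (grepl("plague$", topology)) {
    pr$T_plague <- list(dist = "fixed", value = 27)
    pr$f_plague <- list(dist = "fixed", value = 2 / 3)
  }
  prior_set(pr)
}

#' Validate and construct a prior set
#'
#' @param priors Named list of `list(dist, min, max)` /
#'   `list(dist = "fixed", value)` entries; `dist` is `"uniform"`,
#'   `"loguniform"` or `"fixed"`.
#' @return The validated list with class `"prior_set"`.
#' @export
prior_set <- function(priors) {
  stopifnot(is.list(priors), !is.null(names(priors)))
  for (nm in names(priors)) {
    p <- priors[[nm]]
    if (!p$dist %in% c("uniform", "loguniform", "fixed"))
      stop("unknown prior distribution for ", nm, ": ", p$dist, call. = FALSE)
    if (p$dist == "fixed") {
      if (is.null(p$value) || !is.finite(p$value))
        stop("fixed prior for ", nm, " needs a finite value", call. = FALSE)
    } else {
      if (!is.finite(p$min) || !is.finite(p$max) || p$min > p$max)
        stop("prior bounds for ", nm, " must be finite with min <= max",
             call. = FALSE)
      if (p$dist == "loguniform" && p$min <= 0)
        stop("log-uniform prior for ", nm, " needs min > 0", call. = FALSE)
    }
  }
  structure(priors, class = "prior_set")
}

draw_one_prior <- function(p, n) {
  switch(p$dist,
    uniform = stats::runif(n, p$min, p$max),
    loguniform = exp(stats::runif(n, log(p$min), log(p$max))),
    fixed = rep(p$value, n))
}

#' Draw parameter vectors from a prior set
#'
#' Draws each parameter independently from its prior, then enforces the
#' topology constraints `N_anc <= N0` (when both are present),
#' `T_growth > 55` and `T_div > 55` by rejection.
#'
#' @param priors A [prior_set()].
#' @param n Number of draws.
#' @param seed Optional integer seed (set locally).
#' @return A data frame with one column per parameter and `n` rows.
#' @export
draw_parameters <- function(priors, n = 1L, seed = NULL) {
  stopifnot(inherits(priors, "prior_set"))
  if (!is.null(seed)) set.seed(seed)
  draw_block <- function(m) {
    as.data.frame(lapply(priors, draw_one_prior, n = m))
  }
  ok_rows <- function(df) {
    ok <- rep(TRUE, nrow(df))
    if (all(c("N0", "N_anc") %in% names(df))) ok <- ok & df$N_anc <= df$N0
    if ("T_growth" %in% names(df)) ok <- ok & df$T_growth > 55
    if ("T_div" %in% names(df)) ok <- ok & df$T_div > 55
    ok
  }
  out <- draw_block(n)
  keep <- ok_rows(out)
  guard <- 0L
  while (!all(keep)) {
    m <- sum(!keep)
    guard <- guard + 1L
    if (guard > 10000L)
      stop("prior constraints unsatisfiable (rejection did not terminate)",
           call. = FALSE)
    repl <- draw_block(m)
    rok <- ok_rows(repl)
    idx <- which(!keep)[rok]
    out[idx, ] <- repl[rok, , drop = FALSE]
    keep[idx] <- TRUE
  }
  out
}

#' Bundle the sampling configuration of a study
#'
#' @param n_ancient Number of ancient sequences (default 28).
#' @param n_modern Number of modern sequences.
#' @param ancient_age Age of the ancient sample in generations
#'   (default 55).
#' @param L Sequence length in sites (default 361).
#' @param kappa Transition:transversion bias of the mutation model
#'   (default 10, control-region-like).
#' @return A list with class `"sampling_config"`.
#' @export
sampling_config <- function(n_ancient = 28L, n_modern = 75L,
                            ancient_age = 55, L = 361L, kappa = 10) {
  stopifnot(n_ancient >= 0L, n_modern >= 1L, ancient_age > 0, L >= 1L,
            kappa > 0)
  structure(list(n_ancient = as.integer(n_ancient),
                 n_modern = as.integer(n_modern),
                 ancient_age = ancient_age, L = as.integer(L),
                 kappa = kappa),
            class = "sampling_config")
}
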