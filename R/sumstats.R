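# Intra- and inter-population summary statistics for HVR-I samples.
#
# These six statistics (ten numbers: four per-population statistics for
# the ancient and the modern sample, plus two cross-population ones)
# summarize each observed or simulated dataset for the ABC comparison:
#   K     number of distinct haplotypes per population
#   P     number of private polymorphic sites per population
#   MPWD  mean number of pairwise sequence differences per population
#   H     gene diversity (haplotype heterozygosity) per population
#   FST   Hudson's FST between the two populations
#   AS    allele sharing: fraction of the ancient sample's distinct
#         haplotypes also present in the modern sample

# distinct haplotypes with multiplicities; returns list(haps, counts, keys)
distinct_haplotypes <- function(p) {
  keys <- vapply(p$haplotypes, haplotype_key, character(1))
  tab <- table(keys)
  first <- !duplicated(keys)
  list(haps = p$haplotypes[first],
       keys = keys[first],
       counts = as.integer(tab[keys[first]]))
}

#' Number of distinct haplotypes in a population sample
#'
#' @param p A [population_sample()].
#' @return Integer count of distinct variant sets.
#' @export
haplotype_count <- function(p) {
  stopifnot(inherits(p, "population_sample"), length(p) >= 1L)
  length(unique(vapply(p$haplotypes, haplotype_key, character(1))))
}

# per-site state table: for each position occurring in any member,
# the multiset of states (variant base, or "" for the reference state)
site_states <- function(p) {
  n <- length(p)
  pos_all <- unlist(lapply(p$haplotypes, names), use.names = FALSE)
  base_all <- unlist(lapply(p$haplotypes, unname), use.names = FALSE)
  if (!length(pos_all)) return(list())
  states <- split(base_all, pos_all)
  # members without a variant at the site carry the reference state
  lapply(seq_along(states), function(i) {
    s <- states[[i]]
    c(s, rep("", n - length(s)))
  }) |> stats::setNames(names(states))
}

#' Number of segregating sites in a population sample
#'
#' A site segregates when at least two states (the reference state
#' included) are observed among the members.
#'
#' @param p A [population_sample()].
#' @return Integer count of segregating positions.
#' @export
segregating_sites <- function(p) {
  stopifnot(inherits(p, "population_sample"), length(p) >= 1L)
  st <- site_states(p)
  if (!length(st)) return(0L)
  sum(vapply(st, function(s) length(unique(s)) >= 2L, logical(1)))
}

#' Gene diversity (haplotype heterozygosity)
#'
#' The unbiased estimator `H = n (1 - sum p_i^2) / (n - 1)` where `p_i`
#' are the sample frequencies of the distinct haplotypes.
#'
#' @param p A [population_sample()] with at least two members.
#' @return A number in `[0, 1]`.
#' @export
gene_diversity <- function(p) {
  stopifnot(inherits(p, "population_sample"))
  n <- length(p)
  if (n < 2L)
    stop("gene diversity undefined for n < 2", call. = FALSE)
  counts <- distinct_haplotypes(p)$counts
  n * (1 - sum((counts / n)^2)) / (n - 1)
}

# pairwise difference matrix between two lists of haplotypes
hap_dist_matrix <- function(ha, hb) {
  outer(seq_along(ha), seq_along(hb),
        Vectorize(function(i, j) pairwise_difference(ha[[i]], hb[[j]])))
}

#' Mean number of pairwise differences (MPWD)
#'
#' Average of [pairwise_difference()] over all `n(n-1)/2` unordered
#' member pairs.
#'
#' @param p A [population_sample()] with at least two members.
#' @return A non-negative number.
#' @export
mean_pairwise_differences <- function(p) {
  stopifnot(inherits(p, "population_sample"))
  n <- length(p)
  if (n < 2L) stop("MPWD undefined for n < 2", call. = FALSE)
  d <- distinct_haplotypes(p)
  k <- length(d$haps)
  if (k == 1L) return(0)
  dm <- hap_dist_matrix(d$haps, d$haps)
  w <- outer(d$counts, d$counts)
  diag(w) <- 0
  sum(dm * w) / 2 / (n * (n - 1) / 2)
}

#' Private polymorphic sites of two population samples
#'
#' For each population: the number of sites segregating within it whose
#' non-reference state(s) observed there are all absent from the other
#' population (Arlequin-style convention).
#'
#' @param a,b [population_sample()] objects over the same window.
#' @return Integer vector `c(private_a, private_b)`.
#' @export
private_polymorphic_sites <- function(a, b) {
  stopifnot(inherits(a, "population_sample"), inherits(b, "population_sample"))
  count_private <- function(x, other) {
    stx <- site_states(x)
    sto <- site_states(other)
    n_other <- length(other)
    if (!length(stx)) return(0L)
    seg <- vapply(stx, function(s) length(unique(s)) >= 2L, logical(1))
    priv <- vapply(names(stx)[seg], function(pos) {
      vx <- setdiff(unique(stx[[pos]]), "")
      so <- sto[[pos]]
      states_other <- if (is.null(so)) {
        if (n_other > 0L) "" else character()
      } else unique(so)
      !any(vx %in% states_other)
    }, logical(1))
    sum(priv)
  }
  c(count_private(a, b), count_private(b, a))
}

# mean pairwise difference across all between-population pairs
between_mpwd <- function(a, b) {
  da <- distinct_haplotypes(a)
  db <- distinct_haplotypes(b)
  dm <- hap_dist_matrix(da$haps, db$haps)
  w <- outer(da$counts, db$counts)
  sum(dm * w) / (length(a) * length(b))
}

#' Hudson's FST between two population samples
#'
#' `FST = 1 - Hw / Hb` where `Hw` is the unweighted mean of the two
#' within-population MPWDs and `Hb` the mean pairwise difference over
#' all between-population pairs (Hudson, Slatkin and Maddison form).
#' Negative estimates are reported as computed; when `Hb = 0` (jointly
#' monomorphic samples) the value is defined as 0.
#'
#' @param a,b [population_sample()] objects, each with `n >= 2`.
#' @return A number `<= 1`.
#' @export
hudson_fst <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  hb <- between_mpwd(a, b)
  if (hb == 0) return(0)
  hw <- (mean_pairwise_differences(a) + mean_pairwise_differences(b)) / 2
  1 - hw / hb
}

#' Allele sharing between a modern and an ancient sample
#'
#' The number of distinct haplotypes of the modern sample also present
#' in the ancient sample, scaled by the total number of distinct
#' haplotypes in the ancient sample.
#'
#' @param modern,ancient [population_sample()] objects.
#' @return A number in `[0, 1]`.
#' @export
allele_sharing <- function(modern, ancient) {
  stopifnot(length(modern) >= 1L, length(ancient) >= 1L)
  km <- unique(vapply(modern$haplotypes, haplotype_key, character(1)))
  ka <- unique(vapply(ancient$haplotypes, haplotype_key, character(1)))
  length(intersect(km, ka)) / length(ka)
}

#' Names of the ten summary-statistic slots, in fixed order
#' @return Character vector of length 10.
#' @export
summary_stat_names <- function() {
  c("K_anc", "K_mod", "P_anc", "P_mod", "MPWD_anc", "MPWD_mod",
    "H_anc", "H_mod", "FST", "AS")
}

#' The ten-number ABC summary vector for an ancient/modern pair
#'
#' Computes, in fixed order: haplotype counts, private polymorphic
#' sites, MPWDs and gene diversities of the ancient and modern samples,
#' then Hudson's FST and allele sharing.  The identical code path is
#' used for observed and simulated data.
#'
#' @param ancient,modern [population_sample()] objects;
#'   `ancient$age_generations` must exceed `modern$age_generations`.
#' @return Named numeric vector of length 10 (see [summary_stat_names()]).
#' @export
summary_vector <- function(ancient, modern) {
  if (ancient$age_generations <= modern$age_generations)
    stop("ancient sample must be older than modern sample", call. = FALSE)
  pp <- private_polymorphic_sites(ancient, modern)
  stats::setNames(c(
    haplotype_count(ancient), haplotype_count(modern),
    pp[1L], pp[2L],
    mean_pairwise_differences(ancient), mean_pairwise_differences(modern),
    gene_diversity(ancient), gene_diversity(modern),
    hudson_fst(ancient, modern), allele_sharing(modern, ancient)
  ), summary_stat_names())
}
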