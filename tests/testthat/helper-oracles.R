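# Independent brute-force oracles: statistics recomputed from fully
# expanded 361-base sequence matrices with naive O(n^2) loops, kept
# deliberately separate from the package's variant-set code paths.

REF_BASES <- unname(hvr1_reference())

# expand a population to an n x 361 character matrix of full sequences
pop_matrix <- function(p, ref = REF_BASES) {
  t(vapply(p$haplotypes, function(h) {
    s <- ref
    if (length(h)) s[as.integer(names(h)) - 16023L] <- unname(h)
    s
  }, character(361)))
}

oracle_K <- function(m) length(unique(apply(m, 1L, paste0, collapse = "")))

oracle_S <- function(m) sum(apply(m, 2L, function(col)
  length(unique(col)) >= 2L))

oracle_H <- function(m) {
  n <- nrow(m)
  cnt <- table(apply(m, 1L, paste0, collapse = ""))
  n * (1 - sum((cnt / n)^2)) / (n - 1)
}

oracle_MPWD <- function(m) {
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    tot <- tot + sum(m[i, ] != m[j, ])
  tot / (n * (n - 1) / 2)
}

oracle_between_mpwd <- function(ma, mb) {
  tot <- 0
  for (i in seq_len(nrow(ma))) for (j in seq_len(nrow(mb)))
    tot <- tot + sum(ma[i, ] != mb[j, ])
  tot / (nrow(ma) * nrow(mb))
}

oracle_fst <- function(ma, mb) {
  hb <- oracle_between_mpwd(ma, mb)
  if (hb == 0) return(0)
  1 - (oracle_MPWD(ma) + oracle_MPWD(mb)) / 2 / hb
}

# site-by-site private polymorphic site tally
oracle_private <- function(ma, mb, ref = REF_BASES) {
  count <- function(mx, mo) {
    tot <- 0L
    for (s in seq_len(ncol(mx))) {
      if (length(unique(mx[, s])) < 2L) next          # not segregating
      vx <- setdiff(unique(mx[, s]), ref[s])
      if (!any(vx %in% unique(mo[, s]))) tot <- tot + 1L
    }
    tot
  }
  c(count(ma, mb), count(mb, ma))
}

oracle_AS <- function(m_modern, m_ancient) {
  km <- unique(apply(m_modern, 1L, paste0, collapse = ""))
  ka <- unique(apply(m_ancient, 1L, paste0, collapse = ""))
  length(intersect(km, ka)) / length(ka)
}

# random population whose variants always differ from the reference
random_population <- function(n, label = "rnd", age = 0L, max_var = 5L) {
  haps <- lapply(seq_len(n), function(i) {
    nv <- sample(0:max_var, 1L)
    if (nv == 0L) return(haplotype())
    pos <- sample(16024:16384, nv)
    base <- vapply(pos, function(p)
      sample(setdiff(c("A", "C", "G", "T"), REF_BASES[p - 16023L]), 1L),
      character(1))
    haplotype(pos, base)
  })
  population_sample(label, age, sprintf("%s%03d", label, seq_len(n)), haps)
}

# exhaustive pair-counting AUC (Mann-Whitney with half ties)
oracle_auc <- function(p_true, p_false) {
  tot <- 0
  for (a in p_true) for (b in p_false)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(p_true) * length(p_false))
}
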