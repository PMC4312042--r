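# Summary statistics against published values, hand examples and the
# brute-force full-sequence oracles.

med <- medieval_fixture()

test_that("pairwise_difference counts symmetric differences per site", {
  expect_equal(pairwise_difference(haplotype(), parse_motif("311C")), 1L)
  # published pair one mutation apart
  expect_equal(pairwise_difference(parse_motif("069T 126C"),
                                   parse_motif("069T 126C 153A")), 1L)
  # same site, different base: one difference, not two
  expect_equal(pairwise_difference(haplotype(16129, "A"),
                                   haplotype(16129, "C")), 1L)
  expect_equal(pairwise_difference(haplotype(), haplotype()), 0L)
})

test_that("medieval sample reproduces the published panel", {
  expect_equal(haplotype_count(med), 18L)
  expect_equal(segregating_sites(med), 23L)
  expect_equal(round(gene_diversity(med), 3), 0.942)
  expect_equal(round(mean_pairwise_differences(med), 3), 3.484)
})

test_that("within-population statistics match the brute-force oracle", {
  set.seed(101)
  for (rep in 1:100) {
    p <- random_population(sample(2:30, 1L))
    m <- pop_matrix(p)
    expect_equal(haplotype_count(p), oracle_K(m))
    expect_equal(segregating_sites(p), oracle_S(m))
    expect_equal(gene_diversity(p), oracle_H(m))
    expect_equal(mean_pairwise_differences(p), oracle_MPWD(m))
  }
})

test_that("degenerate populations are handled", {
  mono <- population_sample("m", 0L, c("a", "b", "c"),
                            rep(list(parse_motif("311C")), 3))
  expect_equal(haplotype_count(mono), 1L)
  expect_equal(segregating_sites(mono), 0L)
  expect_equal(gene_diversity(mono), 0)
  expect_equal(mean_pairwise_differences(mono), 0)
  single <- population_sample("s", 0L, "a", list(haplotype()))
  expect_error(gene_diversity(single), "n < 2")
  expect_error(mean_pairwise_differences(single), "n < 2")
})

test_that("gene diversity matches the closed form on known counts", {
  # counts {2,1,1} of n = 4: H = n(1 - sum p^2)/(n-1) = 5/6
  p <- population_sample("t", 0L, paste0("s", 1:4),
                         list(parse_motif("311C"), parse_motif("311C"),
                              haplotype(), parse_motif("069T")))
  expect_equal(gene_diversity(p), 5 / 6)
})

test_that("private polymorphic sites follow the one-sided convention", {
  a <- population_sample("a", 0L, c("a1", "a2"),
                         list(haplotype(), parse_motif("311C")))
  b <- population_sample("b", 0L, c("b1", "b2"),
                         list(haplotype(), haplotype()))
  expect_equal(private_polymorphic_sites(a, b), c(1L, 0L))
  expect_equal(private_polymorphic_sites(a, a), c(0L, 0L))
  set.seed(77)
  for (rep in 1:40) {
    pa <- random_population(5, "a")
    pb <- random_population(5, "b")
    expect_equal(private_polymorphic_sites(pa, pb),
                 oracle_private(pop_matrix(pa), pop_matrix(pb)))
  }
})

test_that("Hudson's FST behaves at its limits and matches the oracle", {
  fix <- function(m, n) population_sample("f", 0L, paste0(m, 1:n),
    rep(list(parse_motif(m)), n))
  # two monomorphic populations k > 0 sites apart: Hw = 0 so FST = 1
  expect_equal(hudson_fst(fix("311C", 4), fix("069T 126C", 5)), 1)
  # jointly monomorphic: defined as 0
  expect_equal(hudson_fst(fix("311C", 4), fix("311C", 5)), 0)
  set.seed(5)
  for (rep in 1:25) {
    pa <- random_population(sample(2:12, 1), "a")
    pb <- random_population(sample(2:12, 1), "b")
    expect_equal(hudson_fst(pa, pb),
                 oracle_fst(pop_matrix(pa), pop_matrix(pb)))
  }
})

test_that("samples drawn from one pool give near-zero FST", {
  set.seed(11)
  pool <- random_population(200, "pool")$haplotypes
  draw <- function(lbl) population_sample(lbl, 0L,
    sprintf("%s%02d", lbl, 1:50), sample(pool, 50, replace = TRUE))
  f <- replicate(10, hudson_fst(draw("a"), draw("b")))
  expect_true(all(abs(f) < 0.05))
})

test_that("self-comparison FST equals the estimator's -1/(n-1) artifact", {
  # Hb over all n^2 cross pairs includes the n identical pairs, so a
  # literal self-comparison of a polymorphic sample gives -1/(n-1),
  # not 0; this pins the implemented convention
  n <- length(med)
  expect_equal(hudson_fst(med, med), -1 / (n - 1), tolerance = 1e-12)
})

test_that("allele sharing follows its definition and invariances", {
  h1 <- haplotype(); h2 <- parse_motif("311C")
  h3 <- parse_motif("069T"); h4 <- parse_motif("126C 294T")
  pop <- function(lbl, haps) population_sample(lbl, 0L,
    sprintf("%s%d", lbl, seq_along(haps)), haps)
  modern <- pop("m", list(h1, h2, h3))
  ancient <- pop("a", list(h1, h4))
  expect_equal(allele_sharing(modern, ancient), 1 / 2)
  expect_equal(allele_sharing(pop("m", list(h2, h3)),
                              pop("a", list(h4))), 0)
  expect_equal(allele_sharing(modern, pop("a", list(h1, h2))), 1)
  # invariant to member order and duplication
  modern2 <- pop("m", list(h3, h2, h1, h1, h2))
  expect_equal(allele_sharing(modern2, ancient),
               allele_sharing(modern, ancient))
  set.seed(8)
  pa <- random_population(8, "a"); pm <- random_population(8, "m")
  expect_equal(allele_sharing(pm, pa),
               oracle_AS(pop_matrix(pm), pop_matrix(pa)))
})

test_that("duplicating a member never increases the haplotype count", {
  set.seed(9)
  for (rep in 1:10) {
    p <- random_population(sample(2:15, 1))
    i <- sample(length(p), 1L)
    p2 <- population_sample(p$label, p$age_generations,
                            c(p$sample_id, "dup"),
                            c(p$haplotypes, p$haplotypes[i]))
    expect_equal(haplotype_count(p2), haplotype_count(p))
  }
})

test_that("summary_vector composes the ten statistics in fixed order", {
  modcopy <- med
  modcopy$age_generations <- 0L
  modcopy$label <- "copy"
  sv <- summary_vector(med, modcopy)
  expect_length(sv, 10L)
  expect_named(sv, summary_stat_names())
  expect_equal(unname(sv["K_anc"]), 18)
  expect_equal(unname(sv["AS"]), 1)
  expect_equal(unname(sv["P_anc"]), 0)
  # components equal individually computed statistics
  set.seed(21)
  anc <- random_population(10, "anc", age = 55L)
  mod <- random_population(12, "mod")
  sv2 <- summary_vector(anc, mod)
  expect_equal(unname(sv2["K_mod"]), haplotype_count(mod))
  expect_equal(unname(sv2["MPWD_anc"]), mean_pairwise_differences(anc))
  expect_equal(unname(sv2["FST"]), hudson_fst(anc, mod))
  expect_equal(unname(sv2["AS"]), allele_sharing(mod, anc))
  expect_equal(unname(sv2[c("P_anc", "P_mod")]),
               as.numeric(private_polymorphic_sites(anc, mod)))
  # age ordering enforced
  expect_error(summary_vector(mod, anc), "older")
})
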