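# Prior draws, size trajectory, the serial-coalescent genealogy and
# mutation layers, engine agreement, and reference-table plumbing.

const_model <- function(N, u = 0, topology = "continuity", ...)
  demographic_model(topology, N0 = N, N_anc = N, T_growth = 100, u = u, ...)

test_that("draw_parameters respects priors and constraints", {
  pr <- prior_set(list(N0 = list(dist = "uniform", min = 7, max = 7)))
  expect_true(all(draw_parameters(pr, 50, seed = 1)$N0 == 7))

  pr2 <- default_priors("discontinuity")
  d <- draw_parameters(pr2, 10000, seed = 2)
  expect_true(all(d$T_growth > 55))
  expect_true(all(d$T_div > 55))
  expect_true(all(d$N_anc <= d$N0))
  expect_true(all(d$u >= 5e-7 & d$u <= 5e-6))
  # log10 of a log-uniform size prior is uniform (KS, alpha = 0.01);
  # N0 draws are constrained (N_anc <= N0), so test the unconstrained
  # marginal from a sizes-only prior set
  pr3 <- prior_set(list(N0 = list(dist = "loguniform", min = 1e2,
                                  max = 1e6)))
  x <- log10(draw_parameters(pr3, 10000, seed = 3)$N0)
  ks <- suppressWarnings(ks.test(x, "punif", 2, 6))
  expect_gt(ks$p.value, 0.01)
})

test_that("size_trajectory follows the closed form", {
  m <- demographic_model("continuity", N0 = 1e4, N_anc = 1e3,
                         T_growth = 500, u = 1e-6)
  expect_equal(size_trajectory(m, 0), 1e4)
  expect_equal(size_trajectory(m, 600), 1e3)     # beyond growth onset
  r <- log(1e4 / 1e3) / 500
  expect_equal(size_trajectory(m, 250), 1e4 * exp(-r * 250))
  expect_error(size_trajectory(m, -1), "non-negative")
  # constant-size degenerate case
  expect_equal(size_trajectory(const_model(500), 100), 500)
  # plague: pre-plague (ancestral-side) sizes are the curve / f_plague
  mp <- demographic_model("continuity_plague", N0 = 1e4, N_anc = 1e3,
                          T_growth = 500, T_plague = 27, f_plague = 2/3,
                          u = 1e-6)
  expect_equal(size_trajectory(mp, 10), size_trajectory(m, 10))
  expect_equal(size_trajectory(mp, 40), size_trajectory(m, 40) / (2/3))
  expect_equal(size_trajectory(mp, 600), 1e3)
  # f_plague = 1 reduces to the no-plague trajectory everywhere
  mp1 <- demographic_model("continuity_plague", N0 = 1e4, N_anc = 1e3,
                           T_growth = 500, f_plague = 1, u = 1e-6)
  tt <- c(0, 5, 26, 27, 100, 499, 700)
  expect_equal(size_trajectory(mp1, tt), size_trajectory(m, tt))
})

tip_descendants <- function(gen, node) {
  kids <- which(gen$parent == node)
  if (!length(kids)) return(node)
  unlist(lapply(kids, tip_descendants, gen = gen))
}

test_that("genealogies are well-formed binary serial trees", {
  set.seed(31)
  gen <- simulate_genealogy(const_model(200), n_ancient = 6, n_modern = 10)
  n_tips <- 16L
  expect_equal(gen$n_tips, n_tips)
  expect_length(gen$parent, 2L * n_tips - 1L)
  expect_equal(sum(gen$parent == 0L), 1L)          # single root
  expect_equal(gen$time[seq_len(10L)], rep(0, 10))
  expect_equal(gen$time[10L + seq_len(6L)], rep(55, 6))
  nonroot <- which(gen$parent > 0L)
  expect_true(all(gen$time[gen$parent[nonroot]] > gen$time[nonroot]))
  expect_equal(sort(tip_descendants(gen, which(gen$parent == 0L))),
               seq_len(n_tips))
})

test_that("discontinuity forbids ancient-modern coalescence below T_div", {
  m <- demographic_model("discontinuity", N0 = 100, N_anc = 100,
                         T_growth = 100, T_div = 1e6, u = 0)
  set.seed(32)
  for (rep in 1:5) {
    gen <- simulate_genealogy(m, n_ancient = 5, n_modern = 8)
    internal <- which(seq_along(gen$parent) > gen$n_tips)
    below <- internal[gen$time[internal] < 1e6]
    for (nd in below) {
      tips <- tip_descendants(gen, nd)
      expect_true(all(tips <= 8L) || all(tips > 8L))  # never mixed
    }
    expect_gte(gen$tmrca, 1e6)
  }
})

test_that("coalescence times match serial-coalescent expectations", {
  # E[T2] = N for a modern pair under constant haploid size N
  N <- 400
  set.seed(33)
  t2 <- replicate(3000, simulate_genealogy(const_model(N), 0, 2)$tmrca)
  se <- sd(t2) / sqrt(length(t2))
  expect_lt(abs(mean(t2) - N), 3 * se)
  # one ancient + one modern lineage: E[TMRCA] = 55 + N
  t2s <- replicate(3000, simulate_genealogy(const_model(N), 1, 1)$tmrca)
  se_s <- sd(t2s) / sqrt(length(t2s))
  expect_lt(abs(mean(t2s) - (55 + N)), 3 * se_s)
  expect_true(all(t2s >= 55))
})

test_that("constant-size TMRCA distribution matches ape::rcoal", {
  skip_if_not_installed("ape")
  # rcoal works in coalescent units of N (E[T2] = 1): compare TMRCA/N
  N <- 1000; n <- 10
  set.seed(34)
  mine <- replicate(1500,
    simulate_genealogy(const_model(N), 0, n)$tmrca) / N
  theirs <- replicate(1500, max(ape::branching.times(ape::rcoal(n))))
  ks <- suppressWarnings(ks.test(mine, theirs))
  expect_gt(ks$p.value, 0.01)
})

test_that("mutation layer: u = 0 and Poisson mutation counts", {
  set.seed(35)
  gen <- simulate_genealogy(const_model(300), 4, 8)
  samp <- mutate_genealogy(gen, u = 0)
  expect_equal(haplotype_count(samp$modern), 1L)
  expect_equal(mean_pairwise_differences(samp$modern), 0)
  expect_length(samp$modern$haplotypes[[1L]], 0L)
  # mutation count on a fixed tree is Poisson(total_length * u * L)
  u <- 5e-6; L <- 361
  par <- data.frame(N0 = 300, N_anc = 300, T_growth = 100, u = u)
  st <- sim_batch("continuity", par[rep(1, 3000), ],
                  sampling_config(n_ancient = 4, n_modern = 8),
                  seeds = 1:3000)
  # n_mut | tree ~ Poisson(total_length * u * L): the ratio of summed
  # counts to summed expectations is 1 within Monte-Carlo error
  expect_equal(sum(st[, "n_mut"]) / (sum(st[, "total_length"]) * u * L),
               1, tolerance = 0.05)
  # and Poisson dispersion: Var(n_mut - lambda_i) ~ mean(lambda_i)
  lam <- st[, "total_length"] * u * L
  expect_equal(var(st[, "n_mut"] - lam) / mean(lam), 1, tolerance = 0.15)
})

test_that("modern-pair MPWD matches the theta expectation 2NuL", {
  N <- 500; u <- 2e-6; L <- 361
  par <- data.frame(N0 = N, N_anc = N, T_growth = 100, u = u)
  st <- sim_batch("continuity", par[rep(1, 10000), ],
                  sampling_config(n_ancient = 0, n_modern = 2),
                  seeds = 20000 + 1:10000)
  mp <- st[, "MPWD_mod"]
  se <- sd(mp) / sqrt(length(mp))
  expect_lt(abs(mean(mp) - 2 * N * u * L), 3 * se)
})

test_that("simulate_record is deterministic and self-consistent", {
  cfg <- sampling_config(n_ancient = 5, n_modern = 10)
  pr <- default_priors("continuity")
  r1 <- simulate_record("continuity", pr, cfg, seed = 99)
  r2 <- simulate_record("continuity", pr, cfg, seed = 99)
  expect_equal(r1$params, r2$params)
  expect_equal(r1$stats, r2$stats)
  # summary vector equals sumstats recomputed on the emitted samples
  expect_equal(r1$stats,
               summary_vector(r1$samples$ancient, r1$samples$modern))
})

test_that("compiled and R engines agree distributionally", {
  par <- data.frame(N0 = 800, N_anc = 200, T_growth = 300, u = 3e-6)
  cfg <- sampling_config(n_ancient = 6, n_modern = 12)
  n <- 600
  a <- sim_batch("continuity", par[rep(1, n), ], cfg, seeds = 1:n,
                 engine = "cpp")
  b <- sim_batch("continuity", par[rep(1, n), ], cfg, seeds = 1:n,
                 engine = "R")
  for (stat in c("MPWD_mod", "H_mod", "K_anc", "tmrca")) {
    ks <- suppressWarnings(ks.test(a[, stat], b[, stat]))
    expect_gt(ks$p.value, 0.001)
  }
  # discontinuity topology too
  par2 <- cbind(par, T_div = 400)
  a2 <- sim_batch("discontinuity", par2[rep(1, n), ], cfg, seeds = 1:n)
  b2 <- sim_batch("discontinuity", par2[rep(1, n), ], cfg, seeds = 1:n,
                  engine = "R")
  ks2 <- suppressWarnings(ks.test(a2[, "MPWD_anc"], b2[, "MPWD_anc"]))
  expect_gt(ks2$p.value, 0.001)
  # divergence pushes ancient-modern coalescence above T_div
  expect_true(all(a2[, "tmrca"] >= 400))
})

test_that("reference tables are reproducible and resumable", {
  cfg <- sampling_config(n_ancient = 4, n_modern = 8)
  tops <- c("continuity", "discontinuity")
  rt1 <- build_reference_table(tops, NULL, 100, cfg, seed = 7)
  expect_equal(nrow(rt1), 200L)
  expect_equal(as.integer(table(rt1$model)), c(100L, 100L))
  expect_named(rt1, c("model", serialabc:::PARAM_COLS,
                      summary_stat_names()), ignore.order = TRUE)
  rt2 <- build_reference_table(tops, NULL, 100, cfg, seed = 7)
  expect_equal(as.data.frame(rt1), as.data.frame(rt2))
  # resume from a truncated checkpoint reproduces the one-pass table
  ck <- withr::local_tempfile(fileext = ".tsv")
  rt3 <- build_reference_table(tops, NULL, 100, cfg, seed = 7,
                               checkpoint_path = ck,
                               checkpoint_every = 50L)
  lines <- readLines(ck)
  writeLines(lines[seq_len(1 + 100)], ck)          # keep 2 of 4 chunks
  rt4 <- build_reference_table(tops, NULL, 100, cfg, seed = 7,
                               checkpoint_path = ck,
                               checkpoint_every = 50L)
  expect_equal(as.data.frame(rt4), as.data.frame(rt3),
               tolerance = 1e-12)
  # round-trip through the on-disk format
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_reference_table(rt1, tmp)
  back <- read_reference_table(tmp)
  expect_equal(as.data.frame(back), as.data.frame(rt1),
               tolerance = 1e-12)
  expect_equal(attr(back, "n_per_model"), 100L)
})

test_that("sim_batch is partition-independent record by record", {
  cfg <- sampling_config(n_ancient = 3, n_modern = 6)
  pr <- default_priors("continuity")
  par <- draw_parameters(pr, 40, seed = 4)
  full <- sim_batch("continuity", par, cfg, seeds = 1:40)
  half <- rbind(
    sim_batch("continuity", par[1:20, ], cfg, seeds = 1:20),
    sim_batch("continuity", par[21:40, ], cfg, seeds = 21:40))
  expect_equal(full, half)
})
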