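# Standardization, distances, AR/LR model choice, stability, the
# log-tangent transform, parameter estimation and the PCA diagnostic.

# toy reference table: two models with Gaussian statistic clouds
toy_table <- function(n1, n2, mu1, mu2, sd = 1, seed = 1) {
  set.seed(seed)
  mk <- function(n, mu, model) {
    m <- matrix(rnorm(n * 10, mu, sd), n, 10,
                dimnames = list(NULL, summary_stat_names()))
    data.frame(model = model, m, check.names = FALSE)
  }
  rbind(mk(n1, mu1, "continuity"), mk(n2, mu2, "discontinuity"))
}

obs_vec <- function(v) setNames(rep(v, 10), summary_stat_names())

test_that("standardize centers, scales and drops flat statistics", {
  tab <- toy_table(200, 200, 0, 3)
  z <- standardize(tab, obs_vec(0))
  expect_equal(unname(apply(z$scaled, 2, sd)), rep(1, 10))
  expect_equal(unname(colMeans(z$scaled)), rep(0, 10), tolerance = 1e-12)
  # zero-variance statistic dropped and flagged
  tab$AS <- 1
  expect_warning(z2 <- standardize(tab, obs_vec(0)), "AS")
  expect_equal(z2$dropped, "AS")
  expect_equal(ncol(z2$scaled), 9L)
})

test_that("euclidean distances match hand computation", {
  tab <- toy_table(50, 50, 0, 0)
  obs <- colMeans(as.matrix(tab[, summary_stat_names()]))
  z <- standardize(tab, obs)
  d <- euclidean_distances(z$scaled, z$observed)
  # record equal to observed has distance 0
  tab2 <- rbind(tab, c(model = "continuity", as.list(obs)))
  for (cn in summary_stat_names()) tab2[[cn]] <- as.numeric(tab2[[cn]])
  z2 <- standardize(tab2, obs)
  d2 <- euclidean_distances(z2$scaled, z2$observed)
  expect_equal(d2[101L], 0, tolerance = 1e-10)
  # one record one (table) SD away in one statistic -> distance 1
  z3 <- standardize(tab2, obs)
  rec <- obs; rec["FST"] <- obs["FST"] + z3$scale["FST"]
  scaled_rec <- (rec[z3$kept] - z3$center) / z3$scale
  expect_equal(unname(sqrt(sum((scaled_rec - z3$observed)^2))), 1,
               tolerance = 1e-10)
  # brute-force distance recomputation agrees for every record
  brute <- apply(z$scaled, 1L, function(r) sqrt(sum((r - z$observed)^2)))
  expect_equal(d, brute)
})

test_that("AR probabilities are exact retained-count ratios", {
  # 70 near records from model 1, 30 slightly farther from model 2,
  # the rest far away: retention of 100 gives exactly 0.70 / 0.30
  set.seed(2)
  base <- obs_vec(0)
  mk <- function(n, dist, model) {
    m <- matrix(0, n, 10, dimnames = list(NULL, summary_stat_names()))
    m[, 1] <- dist + seq_len(n) * 1e-6
    data.frame(model = model, m, check.names = FALSE)
  }
  tab <- rbind(mk(70, 1, "continuity"), mk(30, 2, "discontinuity"),
               mk(500, 50, "continuity"), mk(500, 60, "discontinuity"))
  # only one statistic varies by construction, so the zero-variance
  # drop warning is expected here
  post <- suppressWarnings(ar_model_choice(tab, base, 100L))
  expect_equal(unname(post$probabilities["continuity"]), 0.70)
  expect_equal(unname(post$probabilities["discontinuity"]), 0.30)
  expect_equal(sum(post$probabilities), 1)
  # all retained from one model
  post2 <- suppressWarnings(ar_model_choice(tab, base, 70L))
  expect_equal(unname(post2$probabilities["continuity"]), 1)
  expect_error(suppressWarnings(ar_model_choice(tab, base, 10000L)),
               "table size")
})

test_that("AR is invariant to consistent rescaling of a statistic", {
  tab <- toy_table(300, 300, 0, 1.5, seed = 3)
  obs <- obs_vec(0.4)
  p0 <- ar_model_choice(tab, obs, 100L)$probabilities
  tab2 <- tab
  tab2$MPWD_mod <- tab2$MPWD_mod * 1000
  obs2 <- obs; obs2["MPWD_mod"] <- obs2["MPWD_mod"] * 1000
  expect_equal(ar_model_choice(tab2, obs2, 100L)$probabilities, p0)
})

test_that("AR converges to table-wide proportions as n_retain grows", {
  tab <- toy_table(300, 100, 0, 0.2, seed = 4)
  obs <- obs_vec(0.1)
  p_full <- ar_model_choice(tab, obs, 400L)$probabilities
  expect_equal(unname(p_full), c(0.75, 0.25))
  # nested retention: probabilities approach the table proportions
  devs <- vapply(c(50L, 100L, 200L, 400L), function(nr)
    abs(ar_model_choice(tab, obs, nr)$probabilities["continuity"] - 0.75),
    numeric(1))
  expect_equal(devs[4L], 0, tolerance = 1e-12)
})

test_that("LR gives 0.5 on symmetric toys and > 0.99 on separable ones", {
  # identical simulated statistic distributions -> P ~ 0.5 each
  probs <- vapply(1:5, function(s) {
    tab <- toy_table(2000, 2000, 0, 0, seed = s)
    lr_model_choice(tab, obs_vec(0), 2000L)$probabilities["continuity"]
  }, numeric(1))
  expect_true(all(abs(probs - 0.5) < 0.05))
  # model 1 clustered at the observed vector, model 2 far away but
  # overlapping enough to avoid complete separation
  tab <- toy_table(1000, 1000, 0, 2.5, sd = 1.2, seed = 6)
  lr <- suppressWarnings(lr_model_choice(tab, obs_vec(0), 1500L))
  expect_false(lr$fallback)
  expect_gt(lr$probabilities["continuity"], 0.99)
  expect_equal(sum(lr$probabilities), 1, tolerance = 1e-9)
  expect_true(all(lr$band["lower", ] <= lr$probabilities + 1e-12))
  expect_true(all(lr$band["upper", ] >= lr$probabilities - 1e-12))
  # AR and LR agree on well-separated toys (AR retained entirely from
  # the near model)
  ar <- ar_model_choice(tab, obs_vec(0), 300L)
  expect_lt(abs(ar$probabilities["continuity"] -
                lr$probabilities["continuity"]), 0.1)
})

test_that("complete separation yields the saturated-fit limit", {
  tab <- toy_table(500, 500, 0, 100, seed = 7)    # perfectly divided
  expect_warning(lr <- lr_model_choice(tab, obs_vec(0), 800L),
                 "separat")
  expect_true(lr$separation)
  expect_false(lr$fallback)
  expect_gt(lr$probabilities["continuity"], 0.99)
  # a single-model retained set falls back to AR proportions
  tab1 <- tab[tab$model == "continuity", ]
  lr1 <- lr_model_choice(tab1, obs_vec(0), 200L)
  expect_true(lr1$fallback)
  expect_equal(unname(lr1$probabilities["continuity"]), 1)
})

test_that("stability profile flags constant probabilities as stable", {
  tab <- toy_table(600, 600, 0, 4, seed = 8)
  obs <- obs_vec(0)
  sp <- stability_profile(tab, obs, "AR",
                          thresholds = c(100L, 200L, 300L))
  expect_equal(nrow(sp), 3L)
  expect_true(attr(sp, "stable"))
  expect_true(all(sp$continuity > 0.95))
  # default AR threshold set is 100..500
  sp2 <- stability_profile(tab, obs, "AR")
  expect_equal(sp2$n_retain, seq(100L, 500L, by = 100L))
})

test_that("logtan and its inverse are mutually inverse", {
  a <- 10; b <- 2000
  x <- seq(a + 1e-6, b - 1e-6, length.out = 200)
  expect_equal(inv_logtan(logtan(x, a, b), a, b), x, tolerance = 1e-10)
  y <- seq(-20, 20, length.out = 101)
  expect_equal(logtan(inv_logtan(y, a, b), a, b), y, tolerance = 1e-8)
  # transformed values cover the real line monotonically
  expect_true(all(diff(logtan(x, a, b)) > 0))
})

test_that("parameter estimation adjusts toward the observed vector", {
  # table under one model; records whose statistics equal the observed
  # vector exactly are returned unadjusted (identity adjustment)
  set.seed(9)
  n <- 1500
  m <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, summary_stat_names()))
  par_true <- runif(n, 100, 1000)
  tab <- data.frame(model = "continuity", N0 = par_true, m,
                    check.names = FALSE)
  pr <- prior_set(list(N0 = list(dist = "uniform", min = 100,
                                 max = 1000)))
  obs <- obs_vec(0)
  # degenerate case: all retained records identical to observed
  tab0 <- tab
  for (cn in summary_stat_names()) tab0[[cn]] <- obs[[cn]]
  # (all statistics flat -> standardize warns about dropping them)
  ep0 <- suppressWarnings(
    estimate_parameters(tab0, obs, "continuity",
                        n_best = 1000L, priors = pr))
  expect_true(ep0$N0$degenerate)
  expect_equal(sort(ep0$N0$sample), sort(par_true[1:1000]),
               tolerance = 1e-9)
  # regression case: parameter linearly tied to a statistic
  tab$N0 <- 550 + 300 * tanh(tab$K_anc)   # stays inside prior bounds
  ep <- estimate_parameters(tab, obs, "continuity", n_best = 1000L,
                            priors = pr)
  expect_true(ep$N0$adjusted)
  # adjusted posterior concentrates near the value implied at K_anc = 0
  expect_lt(abs(ep$N0$median - 550), 30)
  expect_true(all(ep$N0$sample >= 100 & ep$N0$sample <= 1000))
  expect_lt(ep$N0$ci90[1L], ep$N0$median)
  expect_gt(ep$N0$ci90[2L], ep$N0$median)
})

test_that("PCA diagnostic projects the centroid to the origin", {
  tab <- toy_table(400, 400, 0, 1, seed = 10)
  z <- standardize(tab, obs_vec(0.5))
  # use the pooled centroid of the retained records as observed
  pc <- pca_diagnostic(tab, obs_vec(0.5), n_best_per_model = 400L)
  centroid_scaled <- colMeans(z$scaled)
  centroid_raw <- centroid_scaled * z$scale + z$center
  pc2 <- pca_diagnostic(tab, centroid_raw, n_best_per_model = 400L)
  expect_equal(unname(pc2$observed), rep(0, 10), tolerance = 1e-10)
  # component variances are non-increasing
  expect_true(all(diff(pc$sdev) <= 1e-12))
  expect_equal(nrow(pc$scores), 800L)
})
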