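# Pseudo-observed-dataset (POD) validation: Type I error, power across
# decision thresholds, and the ROC construction over ranked posterior
# probabilities.

#' Generate pseudo-observed datasets under one model
#'
#' Simulates `n_pods` independent datasets with parameters drawn from
#' the priors, keeping the truth labels (generating model and parameter
#' values) alongside each summary vector.
#'
#' @param topology Generating model topology.
#' @param priors A [prior_set()] (default: [default_priors()]).
#' @param n_pods Number of PODs (the study used 1000 per model).
#' @param config A [sampling_config()].
#' @param seed Integer seed.
#' @param engine `"cpp"` or `"R"`.
#' @return A `"pod_set"`: list with `topology`, `stats` (matrix
#'   `n_pods` x 10), `params`, `seed`.
#' @export
generate_pods <- function(topology, priors = NULL, n_pods, config, seed,
                          engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  topology <- match.arg(topology, MODEL_TOPOLOGIES)
  if (is.null(priors)) priors <- default_priors(topology)
  params <- draw_parameters(priors, n_pods, seed = derive_seed(seed, 1L))
  set.seed(derive_seed(seed, 2L))
  seeds <- sample.int(2147483646L, n_pods, replace = TRUE)
  stats <- sim_batch(topology, params, config, seeds, engine = engine)
  structure(list(topology = topology,
                 stats = stats[, summary_stat_names(), drop = FALSE],
                 params = params, seed = seed),
            class = "pod_set")
}

#' @export
print.pod_set <- function(x, ...) {
  cat(sprintf("<pod_set> %d PODs under %s\n", nrow(x$stats), x$topology))
  invisible(x)
}

# posterior probabilities for a batch of summary vectors against one
# standardized table; shares the standardization across all rows
posterior_matrix <- function(table, stats_mat, method, n_retain) {
  df <- as.data.frame(table)
  scols <- summary_stat_names()
  m <- as.matrix(df[, scols, drop = FALSE])
  center <- colMeans(m)
  scl <- apply(m, 2L, stats::sd)
  keep <- scl > 0 & is.finite(scl)
  Tm <- sweep(sweep(m[, keep, drop = FALSE], 2L, center[keep]),
              2L, scl[keep], "/")
  Om <- sweep(sweep(stats_mat[, scols, drop = FALSE][, keep, drop = FALSE],
                    2L, center[keep]), 2L, scl[keep], "/")
  model <- factor(df$model)
  K <- nlevels(model)
  tt <- rowSums(Tm * Tm)
  oo <- rowSums(Om * Om)
  n_pods <- nrow(Om)
  out <- matrix(NA_real_, n_pods, K, dimnames = list(NULL, levels(model)))
  for (j in seq_len(n_pods)) {
    d2 <- pmax(tt - 2 * drop(Tm %*% Om[j, ]) + oo[j], 0)
    idx <- order(d2, seq_along(d2))[seq_len(n_retain)]
    if (method == "AR") {
      tabj <- table(model[idx])
      out[j, ] <- as.numeric(tabj[levels(model)]) / n_retain
    } else {
      y <- droplevels(model[idx])
      if (nlevels(y) < 2L) {
        tabj <- table(model[idx])
        out[j, ] <- as.numeric(tabj[levels(model)]) / n_retain
        next
      }
      dj <- sqrt(d2[idx])
      delta <- max(dj)
      w <- if (delta > 0) 1 - (dj / delta)^2 else rep(1, n_retain)
      w[w <= 0] <- min(w[w > 0], 1e-8)
      X <- sweep(Tm[idx, , drop = FALSE], 2L, Om[j, ])
      fit <- fit_multinom(y, X, w)
      if (fit$singular) {
        tabj <- table(model[idx])
        out[j, ] <- as.numeric(tabj[levels(model)]) / n_retain
      } else {
        pj <- stats::setNames(softmax0(fit$coef[1L, ]), fit$levels)
        row <- stats::setNames(numeric(K), levels(model))
        row[names(pj)] <- pj
        out[j, ] <- row
      }
    }
  }
  out
}

#' Classify PODs against a reference table
#'
#' Computes each POD's model posterior probabilities (AR or LR), then,
#' for every decision threshold, assigns support to a model when its
#' probability exceeds the threshold and aggregates:
#' `power` (true model supported), `type1` (a wrong model supported),
#' `undecided` (no probability above threshold), and
#' `error_inclusive = type1 + undecided` (the conservative reading in
#' which failing to decide also counts against the method).
#'
#' @param pods A `"pod_set"` or list of pod sets.
#' @param table A `"reference_table"` containing the candidate models.
#' @param method `"AR"` or `"LR"`.
#' @param n_retain Retained simulations per POD (study defaults: 100
#'   for AR, 50,000 for LR).
#' @param thresholds Decision probability thresholds
#'   (default `c(0.5, 0.6, 0.7, 0.8, 0.9)`).
#' @return A `"validation_report"`: list with `report` (data frame,
#'   one row per true-model x threshold) and `posteriors` (named list
#'   of per-POD posterior matrices by true model).
#' @export
classify_pods <- function(pods, table, method = c("AR", "LR"),
                          n_retain = NULL,
                          thresholds = c(0.5, 0.6, 0.7, 0.8, 0.9)) {
  method <- match.arg(method)
  if (inherits(pods, "pod_set")) pods <- list(pods)
  if (is.null(n_retain)) n_retain <- if (method == "AR") 100L else 50000L
  if (n_retain > nrow(table))
    stop("n_retain exceeds table size", call. = FALSE)
  stopifnot(all(thresholds > 0 & thresholds <= 1))
  posteriors <- list()
  rows <- list()
  for (ps in pods) {
    P <- posterior_matrix(table, ps$stats, method, n_retain)
    posteriors[[ps$topology]] <- P
    truth <- ps$topology
    for (th in thresholds) {
      sup <- P > th                          # at most one TRUE per row
      correct <- mean(sup[, truth])
      wrong <- mean(rowSums(sup[, colnames(P) != truth, drop = FALSE]) > 0)
      rows[[length(rows) + 1L]] <- data.frame(
        true_model = truth, method = method, n_retain = n_retain,
        threshold = th, power = correct, type1 = wrong,
        undecided = max(0, 1 - correct - wrong),
        error_inclusive = 1 - correct, n_pods = nrow(P))
    }
  }
  structure(list(report = do.call(rbind, rows), posteriors = posteriors,
                 method = method, n_retain = n_retain),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' ROC curve from two sets of POD posterior probabilities
#'
#' Implements the ranked-list construction: the pooled posterior
#' probabilities (of the focal model) from PODs generated under the
#' focal model and under the alternative are ranked from highest to
#' lowest; walking down the list, each threshold yields a point
#' (proportion of alternative-model PODs incorrectly classified,
#' proportion of focal-model PODs correctly classified), with tied
#' values processed in a single step.  The curve starts at (0,0) and
#' ends at (1,1); the AUC accumulates trapezoids over the points and
#' equals the Mann-Whitney statistic `P(p1 > p2) + 0.5 P(p1 = p2)`.
#'
#' @param posteriors_true Posterior probabilities of the focal model
#'   for PODs truly generated under it.
#' @param posteriors_false The same probabilities for PODs generated
#'   under the alternative model.
#' @return A `"roc_result"`: list with `points` (data frame `fpr`,
#'   `tpr`, `threshold`) and `auc`.
#' @export
roc_from_posteriors <- function(posteriors_true, posteriors_false) {
  stopifnot(length(posteriors_true) >= 1L, length(posteriors_false) >= 1L)
  thr <- sort(unique(c(posteriors_true, posteriors_false)),
              decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(posteriors_true >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(posteriors_false >= t), numeric(1))
  pts <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                    threshold = c(Inf, thr))
  if (pts$fpr[nrow(pts)] < 1 || pts$tpr[nrow(pts)] < 1)
    pts <- rbind(pts, data.frame(fpr = 1, tpr = 1, threshold = -Inf))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                              diff(pts$tpr) / 2))
  structure(list(points = pts, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %d points, AUC = %.4f\n",
              nrow(x$points), x$auc))
  invisible(x)
}
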