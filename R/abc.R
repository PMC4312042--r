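# ABC model choice and parameter estimation.
#
# Model choice compares an observed ten-statistic summary vector with a
# reference table of simulated vectors:
#   AR  acceptance-rejection: retain the n closest records (Euclidean
#       distance on SD-standardized statistics) and report per-model
#       retention proportions
#   LR  weighted multinomial logistic regression local to the observed
#       vector (Epanechnikov weights on distance, bandwidth = largest
#       retained distance), evaluated at the observed point
# Parameter estimation is Beaumont-style local-linear regression
# adjustment after a log-tangent transform that confines adjusted
# values to the prior support.

#' Standardize a reference table and an observed vector
#'
#' Centers and scales each of the ten statistics by its mean and
#' standard deviation across the table.  Statistics with zero variance
#' across the table carry no distance information and are dropped with
#' a warning (recorded in the output).
#'
#' @param table A `"reference_table"` (or data frame with the summary
#'   statistic columns).
#' @param observed Named summary vector as from [summary_vector()].
#' @return List with `scaled` (matrix), `observed` (scaled vector),
#'   `model` (factor of record topologies), `kept`, `dropped`,
#'   `center`, `scale`.
#' @export
standardize <- function(table, observed) {
  stats_cols <- intersect(summary_stat_names(), colnames(table))
  if (nrow(table) == 0L) stop("empty reference table", call. = FALSE)
  m <- as.matrix(as.data.frame(table)[, stats_cols, drop = FALSE])
  center <- colMeans(m)
  scale <- apply(m, 2L, stats::sd)
  dropped <- stats_cols[scale == 0 | !is.finite(scale)]
  if (length(dropped))
    warning("dropping zero-variance statistics: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  kept <- setdiff(stats_cols, dropped)
  scaled <- sweep(sweep(m[, kept, drop = FALSE], 2L, center[kept]),
                  2L, scale[kept], "/")
  obs <- (observed[kept] - center[kept]) / scale[kept]
  model <- if ("model" %in% colnames(table))
    factor(as.data.frame(table)$model) else NULL
  list(scaled = scaled, observed = obs, model = model,
       kept = kept, dropped = dropped,
       center = center[kept], scale = scale[kept])
}

#' Euclidean distances from each table record to the observed vector
#'
#' @param scaled Standardized statistics matrix.
#' @param observed Standardized observed vector.
#' @return Numeric vector of distances, one per record.
#' @export
euclidean_distances <- function(scaled, observed) {
  sweep(scaled, 2L, observed) |> (\(d) sqrt(rowSums(d * d)))()
}

# retention: n smallest distances, ties broken by record index
retain_indices <- function(d, n_retain) {
  if (n_retain > length(d))
    stop("n_retain exceeds table size", call. = FALSE)
  order(d, seq_along(d))[seq_len(n_retain)]
}

new_model_posterior <- function(method, retained, probabilities, ...) {
  structure(c(list(method = method, retained = retained,
                   probabilities = probabilities), list(...)),
            class = "model_posterior")
}

#' @export
print.model_posterior <- function(x, ...) {
  cat(sprintf("<model_posterior> %s, %d retained\n", x$method, x$retained))
  print(round(x$probabilities, 4))
  if (isTRUE(x$fallback))
    cat("  (fell back to AR: logistic regression unstable)\n")
  invisible(x)
}

#' ABC model choice by acceptance-rejection
#'
#' Retains the `n_retain` records closest to the observed vector and
#' estimates each model's posterior probability as its share of the
#' retained set.
#'
#' @param table A `"reference_table"` with records from >= 1 models.
#' @param observed Named observed summary vector.
#' @param n_retain Number of retained simulations (the study used
#'   100--500 for AR).
#' @return A `"model_posterior"`.
#' @export
ar_model_choice <- function(table, observed, n_retain = 100L) {
  z <- standardize(table, observed)
  d <- euclidean_distances(z$scaled, z$observed)
  idx <- retain_indices(d, n_retain)
  tab <- table(z$model[idx])
  probs <- as.numeric(tab) / n_retain
  names(probs) <- names(tab)
  new_model_posterior("AR", as.integer(n_retain), probs,
                      retained_index = idx, distances = d[idx])
}

# weighted multinomial logistic regression by Newton-Raphson.
# y: factor (K levels), X: n x p design (no intercept column), w: weights.
# Returns coefficients (K-1) x (p+1), their SEs, fitted probabilities at
# x = 0, and a convergence/separation flag.
fit_multinom <- function(y, X, w, max_iter = 100L, tol = 1e-8) {
  K <- nlevels(y)
  n <- nrow(X); p <- ncol(X)
  Xd <- cbind(`(Intercept)` = 1, X)
  pc <- p + 1L
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), as.integer(y))] <- 1
  B <- matrix(0, pc, K - 1L)  # class 1 is the reference
  sep <- FALSE; singular <- FALSE
  H <- NULL
  for (iter in seq_len(max_iter)) {
    eta <- Xd %*% B                       # n x (K-1)
    em <- cbind(0, eta)
    rowmax <- em[, 1L]
    for (k in seq_len(K - 1L)) rowmax <- pmax(rowmax, em[, k + 1L])
    em <- em - rowmax
    P <- exp(em); P <- P / rowSums(P)     # n x K
    G <- crossprod(Xd, w * (Y[, -1L, drop = FALSE] -
                            P[, -1L, drop = FALSE]))
    H <- matrix(0, pc * (K - 1L), pc * (K - 1L))
    for (a in seq_len(K - 1L)) for (b in a:(K - 1L)) {
      wab <- w * (P[, a + 1L] * ((a == b) - P[, b + 1L]))
      blk <- crossprod(Xd, wab * Xd)
      ia <- (a - 1L) * pc + seq_len(pc); ib <- (b - 1L) * pc + seq_len(pc)
      H[ia, ib] <- blk
      if (a != b) H[ib, ia] <- blk
    }
    step <- tryCatch(solve(H + diag(1e-10, nrow(H)), as.vector(G)),
                     error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) { singular <- TRUE; break }
    B <- B + matrix(step, pc, K - 1L)
    if (max(abs(B)) > 30) { sep <- TRUE; break }   # (near-)separation:
    if (max(abs(step)) < tol) break                # stop at capped fit
  }
  if (iter == max_iter) sep <- TRUE
  se <- tryCatch({
    hi <- solve(H)
    matrix(sqrt(pmax(diag(hi), 0)), pc, K - 1L)
  }, error = function(e) matrix(NA_real_, pc, K - 1L))
  rownames(B) <- rownames(se) <- colnames(Xd)
  list(coef = B, se = se, separation = sep, singular = singular,
       levels = levels(y))
}

softmax0 <- function(a) {       # probabilities from (K-1) linear scores
  e <- c(0, a); e <- exp(e - max(e)); e / sum(e)
}

#' ABC model choice by local weighted multinomial logistic regression
#'
#' Fits a multinomial logistic regression of model identity on the
#' standardized statistics of the `n_retain` closest records, weighted
#' by an Epanechnikov kernel on distance (bandwidth = largest retained
#' distance), with predictors centered at the observed vector so the
#' fitted intercepts give the posterior probabilities at the observed
#' point.  Coefficient standard errors come from the inverse observed
#' information; the reported `band` recomputes the probabilities with
#' all coefficients shifted by +/- 2 SE.  When the retained models are
#' completely separated the maximum-likelihood estimate diverges; the
#' fit is then stopped at a coefficient cap and the saturated-fit
#' probabilities (essentially 1 for the nearest model) are returned
#' with a `separation` flag and a warning.  A singular fit or a
#' retained set containing a single model falls back to the AR result
#' with a `fallback` flag.
#'
#' @param table A `"reference_table"` with records from >= 2 models.
#' @param observed Named observed summary vector.
#' @param n_retain Number of retained simulations (the study used
#'   25,000--150,000 for LR).
#' @return A `"model_posterior"` with elements `beta`, `beta_se`,
#'   `band` and `fallback`.
#' @export
lr_model_choice <- function(table, observed, n_retain = 50000L) {
  z <- standardize(table, observed)
  d <- euclidean_distances(z$scaled, z$observed)
  idx <- retain_indices(d, n_retain)
  y <- droplevels(z$model[idx])
  ar <- function(flag) {
    out <- ar_model_choice(table, observed, n_retain)
    out$method <- "LR"
    out$fallback <- TRUE
    out$fallback_reason <- flag
    # report on the full model set
    full <- stats::setNames(numeric(nlevels(z$model)), levels(z$model))
    full[names(out$probabilities)] <- out$probabilities
    out$probabilities <- full
    out
  }
  if (nlevels(y) < 2L) return(ar("single model retained"))
  delta <- max(d[idx])
  w <- if (delta > 0) 1 - (d[idx] / delta)^2 else rep(1, length(idx))
  w[w <= 0] <- min(w[w > 0], 1e-8)     # boundary record keeps tiny weight
  X <- sweep(z$scaled[idx, , drop = FALSE], 2L, z$observed)
  fit <- fit_multinom(y, X, w)
  if (fit$singular) {
    out <- ar("singular information matrix")
    warning("logistic regression failed (singular fit); AR fallback",
            call. = FALSE)
    return(out)
  }
  if (fit$separation)
    warning("retained models are (near-)completely separated; ",
            "probabilities are the saturated-fit limit", call. = FALSE)
  a <- fit$coef[1L, ]                  # intercepts = scores at observed
  a_se <- fit$se[1L, ]
  probs <- stats::setNames(softmax0(a), fit$levels)
  band <- rbind(lower = pmin(softmax0(a - 2 * a_se),
                             softmax0(a + 2 * a_se), probs),
                upper = pmax(softmax0(a - 2 * a_se),
                             softmax0(a + 2 * a_se), probs))
  colnames(band) <- fit$levels
  full <- stats::setNames(numeric(nlevels(z$model)), levels(z$model))
  full[names(probs)] <- probs
  new_model_posterior("LR", as.integer(n_retain), full,
                      beta = fit$coef, beta_se = fit$se, band = band,
                      fallback = FALSE, separation = fit$separation,
                      bandwidth = delta)
}

#' Posterior-probability stability across retention thresholds
#'
#' Recomputes the model posterior at each retention threshold and
#' reports the per-threshold probabilities together with a stability
#' flag: stable when every model's probability varies by less than 0.05
#' across thresholds.
#'
#' @param table A `"reference_table"`.
#' @param observed Named observed summary vector.
#' @param method `"AR"` or `"LR"`.
#' @param thresholds Retention counts; defaults to the study's sets:
#'   100..500 for AR, 25,000..150,000 for LR (capped at the table size).
#' @return Data frame of probabilities (one row per threshold) with
#'   attributes `stable` and `range`.
#' @export
stability_profile <- function(table, observed, method = c("AR", "LR"),
                              thresholds = NULL) {
  method <- match.arg(method)
  if (is.null(thresholds)) {
    thresholds <- if (method == "AR") seq(100L, 500L, by = 100L)
                  else seq(25000L, 150000L, by = 25000L)
    thresholds <- thresholds[thresholds <= nrow(table)]
    if (!length(thresholds))
      stop("table too small for the default threshold set", call. = FALSE)
  }
  fun <- if (method == "AR") ar_model_choice else lr_model_choice
  models <- sort(unique(as.data.frame(table)$model))
  rows <- lapply(thresholds, function(nr) {
    p <- fun(table, observed, nr)$probabilities
    full <- stats::setNames(numeric(length(models)), models)
    full[names(p)] <- p
    full
  })
  out <- data.frame(n_retain = thresholds, do.call(rbind, rows),
                    check.names = FALSE)
  rng <- apply(out[, models, drop = FALSE], 2L,
               function(x) max(x) - min(x))
  attr(out, "range") <- rng
  attr(out, "stable") <- all(rng < 0.05)
  out
}

#' Log-tangent transform to the real line
#'
#' Maps `x` in the open interval `(a, b)` to the real line via
#' `log(tan(pi (x - a) / (2 (b - a))))`; [inv_logtan()] is its inverse.
#' Used so regression-adjusted parameter values stay inside the prior
#' bounds.
#'
#' @param x Numeric vector in `[a, b]` (boundary values are nudged in
#'   by a relative 1e-12).
#' @param a,b Prior bounds.
#' @return Numeric vector.
#' @export
logtan <- function(x, a, b) {
  u <- (x - a) / (b - a)
  eps <- 1e-12
  u <- pmin(pmax(u, eps), 1 - eps)
  log(tan(pi * u / 2))
}

#' @rdname logtan
#' @param y Numeric vector on the real line.
#' @export
inv_logtan <- function(y, a, b) {
  a + (b - a) * (2 / pi) * atan(exp(y))
}

#' ABC parameter estimation by local-linear regression adjustment
#'
#' Restricts the table to one model, retains the `n_best` closest
#' records, maps each parameter to the real line by [logtan()] over its
#' prior bounds (log10 scale first for log-uniform priors), performs an
#' Epanechnikov-weighted linear regression of the transformed parameter
#' on the standardized statistics centered at the observed vector, and
#' forms the adjusted posterior sample from intercept plus residuals,
#' back-transformed.  When the regression is degenerate (zero weight
#' spread or a singular design) the unadjusted retained values are
#' returned with a flag.
#'
#' @param table A `"reference_table"`.
#' @param observed Named observed summary vector.
#' @param topology Model whose parameters to estimate.
#' @param n_best Retained simulations (default 1000).
#' @param priors The [prior_set()] used to build the table (defaults to
#'   the set stored on the table, else [default_priors()]).
#' @return Named list of `"parameter_posterior"` objects: each holds
#'   the adjusted sample and median / 50 / 90 / 95 % interval summaries.
#' @export
estimate_parameters <- function(table, observed, topology,
                                n_best = 1000L, priors = NULL) {
  df <- as.data.frame(table)
  sub <- df[df$model == topology, , drop = FALSE]
  if (nrow(sub) < n_best)
    stop("table has fewer than n_best records of model ", topology,
         call. = FALSE)
  if (is.null(priors)) {
    priors <- attr(table, "priors")[[topology]]
    if (is.null(priors)) priors <- default_priors(topology)
  }
  z <- standardize(sub, observed)
  d <- euclidean_distances(z$scaled, z$observed)
  idx <- retain_indices(d, n_best)
  delta <- max(d[idx])
  degenerate <- delta == 0
  w <- if (degenerate) rep(1, n_best) else 1 - (d[idx] / delta)^2
  w[w <= 0] <- min(w[w > 0], 1e-8)
  X <- cbind(1, sweep(z$scaled[idx, , drop = FALSE], 2L, z$observed))

  free <- names(priors)[vapply(priors, function(p) p$dist != "fixed",
                               logical(1))]
  out <- list()
  for (nm in free) {
    p <- priors[[nm]]
    vals <- sub[[nm]][idx]
    loga <- p$dist == "loguniform"
    lo <- if (loga) log10(p$min) else p$min
    hi <- if (loga) log10(p$max) else p$max
    yv <- logtan(if (loga) log10(vals) else vals, lo, hi)
    adj_flag <- FALSE
    if (!degenerate) {
      fit <- stats::lm.wfit(X, yv, w)
      if (any(is.na(fit$coefficients))) adj_flag <- TRUE
      else yv <- fit$coefficients[1L] + fit$residuals
    } else adj_flag <- TRUE
    back <- inv_logtan(yv, lo, hi)
    if (loga) back <- 10^back
    qs <- stats::quantile(back, c(0.025, 0.05, 0.25, 0.5, 0.75,
                                  0.95, 0.975), names = FALSE)
    out[[nm]] <- structure(list(
      parameter = nm, sample = back, median = qs[4L],
      ci50 = c(qs[3L], qs[5L]), ci90 = c(qs[2L], qs[6L]),
      ci95 = c(qs[1L], qs[7L]),
      adjusted = !adj_flag && !degenerate,
      degenerate = degenerate || adj_flag),
      class = "parameter_posterior")
  }
  out
}

#' @export
print.parameter_posterior <- function(x, ...) {
  cat(sprintf("<parameter_posterior> %s: median %.4g, 90%% CI [%.4g, %.4g]%s\n",
              x$parameter, x$median, x$ci90[1L], x$ci90[2L],
              if (x$degenerate) " (unadjusted)" else ""))
  invisible(x)
}

#' PCA diagnostic of the best simulations per model
#'
#' Pools the `n_best_per_model` records closest to the observed vector
#' from each model, runs a principal component analysis of their
#' standardized statistics, and projects both records and the observed
#' vector for overlap inspection (the study plotted the first 10,000
#' best simulations from each model).
#'
#' @param table A `"reference_table"`.
#' @param observed Named observed summary vector.
#' @param n_best_per_model Records retained per model (default 10000,
#'   capped at each model's record count).
#' @return List with `scores` (data frame: model + PC coordinates),
#'   `observed` (PC coordinates of the observed vector), `sdev`,
#'   `rotation`.
#' @export
pca_diagnostic <- function(table, observed, n_best_per_model = 10000L) {
  z <- standardize(table, observed)
  d <- euclidean_distances(z$scaled, z$observed)
  models <- levels(z$model)
  idx <- unlist(lapply(models, function(m) {
    im <- which(z$model == m)
    im[order(d[im], im)][seq_len(min(n_best_per_model, length(im)))]
  }))
  pooled <- z$scaled[idx, , drop = FALSE]
  pc <- stats::prcomp(pooled, center = TRUE, scale. = FALSE)
  obs <- (z$observed - pc$center) %*% pc$rotation
  list(scores = data.frame(model = as.character(z$model[idx]),
                           pc$x, check.names = FALSE),
       observed = drop(obs), sdev = pc$sdev, rotation = pc$rotation)
}
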