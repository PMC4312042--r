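# Reference tables: simulated parameter vectors paired with the
# ten-statistic summary panel, one row per simulated dataset.

PARAM_COLS <- c("N0", "N_anc", "T_growth", "T_div", "T_plague",
                "f_plague", "u")

# parameter data frame (topology-specific columns) -> fixed 7-col matrix
params_to_matrix <- function(par) {
  m <- matrix(0, nrow(par), length(PARAM_COLS),
              dimnames = list(NULL, PARAM_COLS))
  for (cn in intersect(names(par), PARAM_COLS)) m[, cn] <- par[[cn]]
  m
}

reference_codes <- function(reference) {
  match(toupper(reference), c("A", "C", "G", "T")) - 1L
}

# deterministic sub-seed derivation (kept below 2^31)
derive_seed <- function(seed, idx) {
  (as.numeric(seed) * 69069 + idx * 104729) %% 2147483647 + 1
}

#' Simulate a batch of summary vectors under one model (fast engine)
#'
#' Low-level access to the compiled serial-coalescent engine: one row of
#' `params` per simulated dataset, each run on its own deterministic
#' seed.  Returns the ten summary statistics plus `tmrca`,
#' `total_length` and `n_mut` diagnostics per record.
#'
#' @param topology Model topology name.
#' @param params Data frame of parameter draws (see [draw_parameters()]).
#' @param config A [sampling_config()].
#' @param seeds Integer vector of per-record seeds (length `nrow(params)`).
#' @param engine `"cpp"` (compiled, default) or `"R"` (reference
#'   implementation; slow, used for cross-checks).
#' @return Numeric matrix with 13 named columns.
#' @export
sim_batch <- function(topology, params, config, seeds,
                      engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  topology <- match.arg(topology, MODEL_TOPOLOGIES)
  stopifnot(inherits(config, "sampling_config"),
            length(seeds) == nrow(params))
  if (engine == "cpp") {
    ref <- if (config$L == HVR1_LEN) unname(hvr1_reference())
           else rep(c("A", "C", "G", "T"), length.out = config$L)
    .sim_batch_cpp(match(topology, MODEL_TOPOLOGIES),
                   params_to_matrix(params),
                   config$n_ancient, config$n_modern, config$ancient_age,
                   config$L, config$kappa, reference_codes(ref),
                   as.numeric(seeds))
  } else {
    out <- matrix(NA_real_, nrow(params), 13,
                  dimnames = list(NULL, c(summary_stat_names(),
                                          "tmrca", "total_length", "n_mut")))
    for (i in seq_len(nrow(params))) {
      set.seed(seeds[i])
      model <- do.call(demographic_model,
                       c(list(topology = topology),
                         as.list(params[i, , drop = FALSE])))
      gen <- simulate_genealogy(model, config$n_ancient, config$n_modern,
                                config$ancient_age)
      samp <- mutate_genealogy(gen, model$u, L = config$L,
                               kappa = config$kappa)
      out[i, 1:10] <- summary_vector(samp$ancient, samp$modern)
      out[i, 11:13] <- c(gen$tmrca, gen$total_length, NA)
    }
    out
  }
}

#' Build an ABC reference table
#'
#' Simulates `n_sims_per_model` datasets under each model: parameters
#' drawn from the priors, genealogy and mutations simulated, summary
#' statistics computed.  Per-record seeds are derived deterministically
#' from the master seed, so the table is reproducible regardless of how
#' the work is partitioned, and an interrupted run can resume from its
#' checkpoint file to a table identical to a single pass.
#'
#' @param topologies Character vector of model topology names.
#' @param priors `NULL` (defaults per topology), a single [prior_set()]
#'   applied to every topology, or a named list of prior sets.
#' @param n_sims_per_model Simulations per model.
#' @param config A [sampling_config()].
#' @param seed Master integer seed.
#' @param engine `"cpp"` or `"R"`.
#' @param checkpoint_path Optional TSV path: rows are appended every
#'   `checkpoint_every` records and the build resumes from it.
#' @param checkpoint_every Chunk size for checkpointing (default 10000).
#' @return A `"reference_table"`: a data frame with columns `model`
#'   (topology), the seven parameter slots and the ten statistics, with
#'   the build configuration attached as attributes.
#' @export
build_reference_table <- function(topologies, priors = NULL,
                                  n_sims_per_model, config, seed,
                                  engine = c("cpp", "R"),
                                  checkpoint_path = NULL,
                                  checkpoint_every = 10000L) {
  engine <- match.arg(engine)
  topologies <- vapply(topologies, match.arg, "", MODEL_TOPOLOGIES)
  prior_list <- resolve_priors(topologies, priors)
  n <- as.integer(n_sims_per_model)
  stopifnot(n >= 1L)

  done <- NULL
  n_done <- 0L
  if (!is.null(checkpoint_path) && file.exists(checkpoint_path)) {
    done <- data.table::fread(checkpoint_path, sep = "\t",
                              data.table = FALSE)
    n_done <- nrow(done)
  }

  chunks <- list()
  global <- 0L
  for (j in seq_along(topologies)) {
    top <- topologies[j]
    params <- draw_parameters(prior_list[[top]], n,
                              seed = derive_seed(seed, j))
    set.seed(derive_seed(seed, 1000L + j))
    seeds <- sample.int(2147483646L, n, replace = TRUE)
    starts <- seq.int(1L, n, by = checkpoint_every)
    for (s in starts) {
      e <- min(s + checkpoint_every - 1L, n)
      idx <- s:e
      if (global + length(idx) <= n_done) {        # chunk already done
        global <- global + length(idx)
        next
      }
      stats <- sim_batch(top, params[idx, , drop = FALSE], config,
                         seeds[idx], engine = engine)
      chunk <- data.frame(model = top,
                          params_to_matrix(params[idx, , drop = FALSE]),
                          stats[, summary_stat_names(), drop = FALSE],
                          row.names = NULL)
      if (!is.null(checkpoint_path))
        data.table::fwrite(chunk, checkpoint_path, sep = "\t",
                           append = file.exists(checkpoint_path))
      chunks[[length(chunks) + 1L]] <- chunk
      global <- global + length(idx)
    }
  }

  tab <- if (!is.null(checkpoint_path))
    data.table::fread(checkpoint_path, sep = "\t", data.table = FALSE)
  else do.call(rbind, chunks)
  rownames(tab) <- NULL
  structure(tab,
            class = c("reference_table", "data.frame"),
            topologies = topologies, n_per_model = n, seed = seed,
            config = config, priors = prior_list, engine = engine)
}

resolve_priors <- function(topologies, priors) {
  if (is.null(priors))
    return(stats::setNames(lapply(topologies, default_priors), topologies))
  if (inherits(priors, "prior_set"))
    return(stats::setNames(rep(list(priors), length(topologies)),
                           topologies))
  stopifnot(is.list(priors), all(topologies %in% names(priors)))
  priors[topologies]
}

#' @export
as.data.frame.reference_table <- function(x, ...) {
  data.frame(unclass(x), check.names = FALSE, stringsAsFactors = FALSE)
}

#' @export
print.reference_table <- function(x, ...) {
  cat(sprintf("<reference_table> %d records, models: %s\n", nrow(x),
              paste(attr(x, "topologies"), collapse = ", ")))
  invisible(x)
}

#' Write a reference table and its metadata sidecar
#'
#' The table goes to `path` as TSV; the build metadata (seed, priors,
#' sampling configuration, model list) to `<path>.meta.json`.
#'
#' @param rt A `"reference_table"`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_reference_table <- function(rt, path) {
  data.table::fwrite(as.data.frame(rt), path, sep = "\t")
  meta <- list(topologies = attr(rt, "topologies"),
               n_per_model = attr(rt, "n_per_model"),
               seed = attr(rt, "seed"),
               engine = attr(rt, "engine"),
               config = unclass(attr(rt, "config")),
               priors = lapply(attr(rt, "priors"), unclass))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a reference table written by [write_reference_table()]
#'
#' @param path TSV path.
#' @return A `"reference_table"`.
#' @export
read_reference_table <- function(path) {
  tab <- data.table::fread(path, sep = "\t", data.table = FALSE)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)
          else NULL
  structure(tab, class = c("reference_table", "data.frame"),
            topologies = unlist(meta$topologies),
            n_per_model = meta$n_per_model, seed = meta$seed,
            engine = meta$engine, config = meta$config,
            priors = meta$priors)
}
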