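# End-to-end orchestration: observed statistics, reference tables, ABC
# model choice, parameter estimation and POD validation, driven by a
# JSON run configuration with a mandatory master seed.

#' Read and validate a run configuration
#'
#' The configuration is a single JSON file.  Recognized fields (with
#' defaults): `models` (the four topologies), `n_sims_per_model`
#' (10000), `ar_retain` (100..500), `lr_retain` (25000..150000),
#' `thresholds` (0.5..0.9), `n_pods` (1000), `seed` (mandatory),
#' `n_ancient` (28), `ancient_age` (55), `n_modern` (named list or
#' single number), `kappa` (10), `output_dir`, and optional `priors`
#' overrides (per topology, per parameter:
#' `{"dist": ..., "min": ..., "max": ...}`).
#'
#' @param path JSON file path.
#' @return A validated `"run_config"` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- list(
    models = MODEL_TOPOLOGIES,
    n_sims_per_model = 10000L,
    ar_retain = seq(100L, 500L, by = 100L),
    lr_retain = seq(25000L, 150000L, by = 25000L),
    ar_default_retain = 100L, lr_default_retain = 50000L,
    thresholds = c(0.5, 0.6, 0.7, 0.8, 0.9),
    n_pods = 1000L, n_ancient = 28L, ancient_age = 55,
    n_modern = 75L, kappa = 10, output_dir = "serialabc_run")
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (is.null(cfg$seed))
    stop("run config must set a seed (reproducibility is mandatory)",
         call. = FALSE)
  cfg$models <- vapply(cfg$models, match.arg, "", MODEL_TOPOLOGIES)
  if (!is.null(cfg$priors))
    cfg$priors <- lapply(cfg$priors, function(pr) {
      base <- list()
      for (nm in names(pr)) base[[nm]] <- as.list(pr[[nm]])
      prior_set(base)
    })
  structure(cfg, class = "run_config")
}

config_priors <- function(cfg, topology) {
  if (!is.null(cfg$priors) && !is.null(cfg$priors[[topology]]))
    cfg$priors[[topology]]
  else default_priors(topology)
}

config_sampling <- function(cfg, n_modern) {
  sampling_config(n_ancient = cfg$n_ancient, n_modern = n_modern,
                  ancient_age = cfg$ancient_age, kappa = cfg$kappa)
}

write_manifest <- function(cfg, out_dir, stage, extra = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- c(list(
    stage = stage,
    package_version = as.character(utils::packageVersion("serialabc")),
    seed = cfg$seed,
    config = unclass(cfg),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), extra)
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Summary-statistics report for observed data
#'
#' Computes the within-population panel (n, K, S, H, MPWD) for an
#' ancient and/or modern motif file, plus the cross-population
#' statistics (private sites, Hudson's FST, allele sharing) when both
#' are given.  With no `ancient` argument the packaged medieval sample
#' is used.
#'
#' @param ancient Path to the ancient motif table (`NULL` = packaged
#'   medieval sample).
#' @param modern Optional path to a modern motif table.
#' @param modern_label,ancient_label Labels for the report.
#' @return List with `panel` (data frame) and, when both samples are
#'   present, `pair` (named vector) and `summary` (the ten-statistic
#'   vector); printed as a report.
#' @export
cmd_stats <- function(ancient = NULL, modern = NULL,
                      ancient_label = "ancient", modern_label = "modern") {
  anc <- if (is.null(ancient)) medieval_fixture()
         else load_population(ancient, ancient_label, 55L)
  pops <- list(anc)
  mod <- NULL
  if (!is.null(modern)) {
    mod <- load_population(modern, modern_label, 0L)
    pops <- c(pops, list(mod))
  }
  panel <- do.call(rbind, lapply(pops, function(p) data.frame(
    population = p$label, n = length(p), K = haplotype_count(p),
    S = segregating_sites(p),
    H = round(gene_diversity(p), 3),
    MPWD = round(mean_pairwise_differences(p), 3))))
  out <- list(panel = panel)
  if (!is.null(mod)) {
    out$summary <- summary_vector(anc, mod)
    pp <- private_polymorphic_sites(anc, mod)
    out$pair <- c(FST = round(hudson_fst(anc, mod), 4),
                  AS = round(allele_sharing(mod, anc), 4),
                  private_ancient = pp[1L], private_modern = pp[2L])
  }
  class(out) <- "stats_report"
  out
}

#' @export
print.stats_report <- function(x, ...) {
  print(x$panel, row.names = FALSE)
  if (!is.null(x$pair)) {
    cat("pairwise:\n")
    print(x$pair)
  }
  invisible(x)
}

#' Build and persist reference tables for a run
#'
#' One reference table per modern population (the models in
#' `cfg$models`, `cfg$n_sims_per_model` records each), written as TSV +
#' metadata sidecar under `output_dir`, with checkpointed streaming
#' writes and a run manifest.
#'
#' @param cfg A `"run_config"`.
#' @param output_dir Output directory (default from config).
#' @param engine `"cpp"` or `"R"`.
#' @return Named list of reference-table paths.
#' @export
cmd_simulate <- function(cfg, output_dir = cfg$output_dir,
                         engine = "cpp") {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  n_modern <- cfg$n_modern
  if (is.null(names(n_modern)))
    n_modern <- stats::setNames(as.list(n_modern),
                                paste0("modern", seq_along(n_modern)))
  priors <- stats::setNames(lapply(cfg$models, config_priors, cfg = cfg),
                            cfg$models)
  paths <- list()
  for (i in seq_along(n_modern)) {
    popname <- names(n_modern)[i]
    scfg <- config_sampling(cfg, n_modern[[i]])
    path <- file.path(output_dir, paste0("reftable_", popname, ".tsv"))
    rt <- build_reference_table(
      cfg$models, priors, cfg$n_sims_per_model, scfg,
      seed = derive_seed(cfg$seed, 100L + i), engine = engine,
      checkpoint_path = file.path(output_dir,
                                  paste0("reftable_", popname,
                                         ".checkpoint.tsv")))
    write_reference_table(rt, path)
    paths[[popname]] <- path
    message(sprintf("[simulate] %s: %d records -> %s", popname,
                    nrow(rt), path))
  }
  write_manifest(cfg, output_dir, "simulate",
                 list(tables = unlist(paths)))
  paths
}

#' ABC model choice and parameter estimation for observed data
#'
#' For each modern population: computes the observed summary vector
#' against the ancient sample, runs AR and LR stability profiles over
#' the configured retention sets, estimates parameters of the
#' best-supported model, and writes the PCA diagnostic coordinates.
#'
#' @param cfg A `"run_config"`.
#' @param tables Named list of reference-table paths (as returned by
#'   [cmd_simulate()]).
#' @param moderns Named list of modern [population_sample()] objects or
#'   motif-table paths; names must match `tables`.
#' @param ancient Ancient [population_sample()] (default: packaged
#'   medieval sample).
#' @param output_dir Output directory.
#' @return Named list of per-population result lists (`ar_profile`,
#'   `lr_profile`, `best_model`, `posterior`, `parameters`, `pca`).
#' @export
cmd_abc <- function(cfg, tables, moderns, ancient = medieval_fixture(),
                    output_dir = cfg$output_dir) {
  stopifnot(inherits(cfg, "run_config"),
            all(names(moderns) %in% names(tables)))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  for (popname in names(moderns)) {
    mod <- moderns[[popname]]
    if (is.character(mod)) mod <- load_population(mod, popname, 0L)
    obs <- summary_vector(ancient, mod)
    rt <- read_reference_table(tables[[popname]])
    ar <- stability_profile(rt, obs, "AR",
                            cfg$ar_retain[cfg$ar_retain <= nrow(rt)])
    lr <- stability_profile(rt, obs, "LR",
                            cfg$lr_retain[cfg$lr_retain <= nrow(rt)])
    post <- lr_model_choice(rt, obs,
                            min(cfg$lr_default_retain, nrow(rt)))
    best <- names(which.max(post$probabilities))
    pars <- tryCatch(
      estimate_parameters(rt, obs, best,
                          n_best = min(1000L, sum(rt$model == best))),
      error = function(e) NULL)
    pca <- pca_diagnostic(rt, obs,
                          min(10000L, cfg$n_sims_per_model))
    res <- list(observed = obs, ar_profile = ar, lr_profile = lr,
                posterior = post, best_model = best, parameters = pars,
                pca = pca)
    results[[popname]] <- res
    prof <- rbind(cbind(method = "AR", ar), cbind(method = "LR", lr))
    utils::write.table(prof,
                       file.path(output_dir,
                                 paste0("abc_", popname, "_profile.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    message(sprintf("[abc] %s: best model %s (P = %.3f)", popname, best,
                    max(post$probabilities)))
  }
  write_manifest(cfg, output_dir, "abc")
  results
}

#' POD validation: Type I error, power and ROC
#'
#' Generates `cfg$n_pods` PODs under each configured model, classifies
#' them against the supplied reference table with both AR and LR at
#' their default retention counts, tabulates power / Type I error /
#' undecided proportions across the decision thresholds, and builds the
#' ROC curve for the first two configured models.
#'
#' @param cfg A `"run_config"`.
#' @param table A `"reference_table"` or path to one.
#' @param output_dir Output directory.
#' @param methods Methods to run (default both).
#' @return List with `reports` (combined data frame), `roc` (per
#'   method), and the per-method `"validation_report"` objects.
#' @export
cmd_validate <- function(cfg, table, output_dir = cfg$output_dir,
                         methods = c("AR", "LR")) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.character(table)) table <- read_reference_table(table)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  scfg <- config_sampling(cfg, if (is.null(names(cfg$n_modern)))
    cfg$n_modern[[1L]] else cfg$n_modern[[1L]])
  pods <- lapply(seq_along(cfg$models), function(j)
    generate_pods(cfg$models[j], config_priors(cfg, cfg$models[j]),
                  cfg$n_pods, scfg,
                  seed = derive_seed(cfg$seed, 200L + j)))
  out <- list()
  reports <- list()
  rocs <- list()
  for (method in methods) {
    n_retain <- if (method == "AR") min(cfg$ar_default_retain, nrow(table))
                else min(cfg$lr_default_retain, nrow(table))
    vr <- classify_pods(pods, table, method, n_retain, cfg$thresholds)
    reports[[method]] <- vr$report
    out[[method]] <- vr
    if (length(cfg$models) >= 2L) {
      m1 <- cfg$models[1L]; m2 <- cfg$models[2L]
      rocs[[method]] <- roc_from_posteriors(
        vr$posteriors[[m1]][, m1], vr$posteriors[[m2]][, m1])
    }
  }
  report <- do.call(rbind, reports)
  utils::write.table(report, file.path(output_dir, "validation_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (method in names(rocs))
    utils::write.table(rocs[[method]]$points,
                       file.path(output_dir,
                                 paste0("roc_", method, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(cfg, output_dir, "validate",
                 list(auc = lapply(rocs, `[[`, "auc")))
  list(reports = report, roc = rocs, validation = out)
}

#' Materialize the synthetic study scenario to a directory
#'
#' Writes the medieval sample and the four synthetic modern samples as
#' motif tables under `output_dir`.
#'
#' @param seed Integer seed.
#' @param output_dir Output directory.
#' @return Named vector of file paths.
#' @export
cmd_synth <- function(seed, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- study_scenario(seed)
  paths <- vapply(names(bundle), function(nm) {
    p <- file.path(output_dir, paste0(nm, ".tsv"))
    write_population(bundle[[nm]], p)
    p
  }, character(1))
  paths
}

#' Command-line entry point
#'
#' Dispatches the subcommands `stats`, `simulate`, `abc`, `validate`
#' and `synth`; run `serialabc <subcommand> --help` for flags.  Thread
#' count never changes results: all parallelism is over records with
#' deterministically derived per-record seeds.
#'
#' @param args Character vector of command-line arguments (default:
#'   the process arguments).
#' @return Exit status, invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: serialabc <stats|simulate|abc|validate|synth> [options]"
  if (!length(args)) { message(usage); return(invisible(1L)) }
  sub <- args[1L]; rest <- args[-1L]
  opt_list <- list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--out", type = "character", default = NULL),
    optparse::make_option("--ancient", type = "character", default = NULL),
    optparse::make_option("--modern", type = "character", default = NULL),
    optparse::make_option("--table", type = "character", default = NULL))
  opts <- optparse::parse_args(
    optparse::OptionParser(option_list = opt_list), args = rest)
  get_cfg <- function() {
    if (is.null(opts$config)) stop("--config is required", call. = FALSE)
    cfg <- read_run_config(opts$config)
    if (!is.null(opts$seed)) cfg$seed <- opts$seed
    if (!is.null(opts$out)) cfg$output_dir <- opts$out
    cfg
  }
  switch(sub,
    stats = print(cmd_stats(opts$ancient, opts$modern)),
    simulate = cmd_simulate(get_cfg()),
    validate = {
      cfg <- get_cfg()
      if (is.null(opts$table)) stop("--table is required", call. = FALSE)
      cmd_validate(cfg, opts$table)
    },
    abc = {
      cfg <- get_cfg()
      if (is.null(opts$table) || is.null(opts$modern))
        stop("--table and --modern are required", call. = FALSE)
      cmd_abc(cfg, stats::setNames(list(opts$table), "modern"),
              stats::setNames(list(opts$modern), "modern"))
    },
    synth = {
      if (is.null(opts$seed) || is.null(opts$out))
        stop("--seed and --out are required", call. = FALSE)
      cmd_synth(opts$seed, opts$out)
    },
    stop(usage, call. = FALSE))
  invisible(0L)
}
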