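#' @title End-to-end pipeline orchestration
#' @description Runs the five-stage workflow — curation, featurization,
#'   splitting, model generation (tuning + training + champion selection),
#'   validation — and optionally profiles probe compounds with the resulting
#'   champion registry. Configuration is a nested list (round-trippable
#'   through YAML) whose defaults are the published protocol values: 80/20
#'   stratified split, 5-fold CV, 90/10 bootstrap, Tc > 0.7 applicability
#'   domain, concern cutoff 6.5, EF levels 1/5/10% with 2% active labelling.
#' @name cli_config
NULL

#' Default pipeline configuration
#'
#' @param preset `"desk"` (default: 20 validation iterations, 5-minute
#'   tuning budget, small LHS) or `"full"` (100 iterations, 100-minute
#'   budget).
#' @return nested configuration list.
#' @export
default_config <- function(preset = c("desk", "full")) {
  preset <- match.arg(preset)
  full <- preset == "full"
  list(
    curation = list(species = c("homo sapiens", "human"),
                    activity_types = c("IC50", "EC50", "Ki", "Kd"),
                    drop_censored = TRUE),
    split = list(strategy = "stratified", train_fraction = 0.8, seed = 17),
    tuning = list(enabled = TRUE, n_init = if (full) 20 else 6,
                  max_generations = if (full) 30 else 3,
                  stagnation = 5,
                  time_budget = if (full) 6000 else 300),
    validation = list(iterations = if (full) 100 else 20,
                      protocols = c("external", "cv", "bootstrap",
                                    "y_scrambling")),
    profiling = list(ad_threshold = 0.7, concern_cutoff = 6.5,
                     variable_cutoff = FALSE),
    enrichment = list(chi = c(0.01, 0.05, 0.10), active_fraction = 0.02),
    seed = 1)
}

#' Validate a pipeline configuration
#'
#' @param config nested configuration list.
#' @return the config, invisibly, or an error describing the first violation.
#' @export
validate_config <- function(config) {
  tf <- config$split$train_fraction
  if (is.null(tf) || tf <= 0 || tf >= 1)
    stop("train_fraction must be in (0, 1): an external test set is required")
  if (!config$split$strategy %in% c("stratified", "random", "diversity",
                                    "scaffold"))
    stop("unknown split strategy: ", config$split$strategy)
  if (config$validation$iterations < 1) stop("iterations must be >= 1")
  if (config$profiling$ad_threshold < 0 || config$profiling$ad_threshold > 1)
    stop("ad_threshold must be in [0, 1]")
  invisible(config)
}

#' Read / write a configuration file (YAML)
#' @param path YAML file path.
#' @return configuration list.
#' @export
read_config <- function(path) {
  cfg <- utils::modifyList(default_config(), yaml::read_yaml(path))
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @param config configuration list to serialize.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full pipeline on a raw activity table
#'
#' Stages run in order per target: curate, featurize, split, (optionally)
#' tune, fit MLR/RF/GB, validate, select the champion by external Pearson R.
#' All artifacts are written under `out_dir`; numeric outputs are
#' reproducible from the config seeds.
#'
#' @param raw raw activity record data.frame with a `target` column (or a
#'   CSV path).
#' @param config configuration list (see [default_config()]).
#' @param out_dir artifact directory (created if missing); `NULL` skips
#'   writing.
#' @param algos algorithms to fit (default all three).
#' @return list keyed by target: `dataset`, `split`, `models`,
#'   `validation`, `champion`, `enrichment`; plus `registry` (champion
#'   models) at the top level.
#' @export
run_pipeline <- function(raw, config = default_config(), out_dir = NULL,
                         algos = c("MLR", "RF", "GB")) {
  validate_config(config)
  # champion selection needs the external row regardless of configuration
  config$validation$protocols <- union("external",
                                       config$validation$protocols)
  if (is.character(raw)) raw <- read_activity_records(raw)
  if (is.null(raw$target)) raw$target <- "target"
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  results <- list()
  registry <- list()
  for (tg in unique(raw$target)) {
    rtg <- raw[raw$target == tg, , drop = FALSE]
    ds <- curate_dataset(rtg, target_id = tg, rules = config$curation)
    fm <- build_feature_matrix(ds)
    sim <- attr(fm, "similarity")
    sp <- split_dataset(ds, strategy = config$split$strategy,
                        train_fraction = config$split$train_fraction,
                        seed = config$split$seed, similarity = sim)
    y <- ds$compounds$pACTIVITY
    xt <- fm[sp$train, , drop = FALSE]; yt <- y[sp$train]

    models <- list(); reports <- list()
    for (algo in algos) {
      cfg <- list()
      if (algo %in% c("RF", "GB") && isTRUE(config$tuning$enabled)) {
        tn <- tune(xt, yt, algo,
                   n_init = config$tuning$n_init,
                   max_generations = config$tuning$max_generations,
                   stagnation = config$tuning$stagnation,
                   time_budget = config$tuning$time_budget,
                   seed = config$seed)
        cfg <- tn$best_config
      }
      m <- fit_model(xt, yt, algo, cfg, seed = config$seed,
                     similarity = sim[sp$train, , drop = FALSE])
      models[[algo]] <- m
      reports[[algo]] <- validation_report(
        fm, y, algo, cfg, sp$train, sp$test,
        iterations = config$validation$iterations, seed = config$seed,
        model = m, protocols = config$validation$protocols)
    }
    cand <- lapply(setdiff(algos, "MLR"), function(a)
      list(model = models[[a]], R = reports[[a]]$external$mean["R"],
           algo = a))
    champ <- if (length(cand) > 0) select_champion(cand) else
      list(model = models[[1]], R = reports[[1]]$external$mean["R"])
    ef <- if (length(sp$test) >= 1 / config$enrichment$active_fraction) {
      enrichment_factor(
        y[sp$test], predict(champ$model, fm[sp$test, , drop = FALSE]),
        chi = config$enrichment$chi,
        active_fraction = config$enrichment$active_fraction,
        ids = ds$compounds$standardized_smiles[sp$test])
    } else NULL  # test partition too small for the active-labelling fraction

    registry[[tg]] <- champ$model
    results[[tg]] <- list(dataset = ds, split = sp, models = models,
                          validation = reports, champion = champ,
                          enrichment = ef)
    if (!is.null(out_dir)) {
      write_curated(ds, file.path(out_dir, paste0(tg, "_curated.csv")))
      summ <- lapply(reports, function(r) lapply(
        r[intersect(names(r), c("external", "cv", "bootstrap",
                                "y_scrambling"))],
        function(p) list(mean = as.list(p$mean), sd = as.list(p$sd))))
      jsonlite::write_json(
        list(target = tg, validation = summ,
             champion = champ$model$algorithm,
             enrichment = ef, auc = attr(ef, "auc"),
             provenance = as.list(ds$provenance),
             seeds = list(pipeline = config$seed,
                          split = config$split$seed)),
        file.path(out_dir, paste0(tg, "_report.json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  structure(list(targets = results, registry = registry, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result:", length(x$targets), "target(s)\n")
  for (tg in names(x$targets)) {
    r <- x$targets[[tg]]
    cat(sprintf("  %s: n=%d champion=%s external R=%.3f\n", tg,
                nrow(r$dataset$compounds), r$champion$model$algorithm,
                r$champion$R))
  }
  invisible(x)
}
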