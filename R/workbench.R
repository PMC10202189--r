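#' Default end-to-end experiment configuration
#'
#' Returns the nested configuration list for [run_experiment()]: the
#' four-cultivation synthetic study, feature settings, augmentation,
#' architecture, training and evaluation blocks, and one global seed from
#' which every stage derives its own stream. Serializable to/from YAML.
#'
#' @param seed Global seed.
#' @return Nested named list.
#' @export
default_experiment_config <- function(seed = 20L) {
  list(
    seed = as.integer(seed),
    scenarios = "default",
    train_ids = c("y1_spring", "y1_autumn"),
    test_id = "y2_spring",
    features = list(t_base = 10),
    observation = list(n_dates = 5L, cv = 0.08, n_plants = 6L),
    augment = list(n_draws = 3L, start_rule = 0.5),
    model = list(memory_length = 7L, d_model = 64L, n_heads = 4L,
                 n_encoder_blocks = 2L, n_decoder_blocks = 2L,
                 kernels = c(1L, 3L, 5L, 7L), ff_width = 128L, dropout = 0),
    training = list(epochs = 16L, batch_size = 32L, lr = 1e-3, split = 0.8,
                    patience = Inf),
    simulation = list(guidance = TRUE, sanitize = FALSE),
    evaluation = list(factors = c("plant_height", "max_nodes", "leaf_area",
                                  "leaf_fw", "leaf_dw", "stem_fw", "stem_dw",
                                  "petiole_fw", "petiole_dw", "harvest_fw",
                                  "harvest_dw")))
}

#' Read and validate an experiment configuration
#'
#' Loads a YAML file, overlays it on [default_experiment_config()] and
#' checks required keys; a missing or unknown key is a schema error naming
#' the key.
#'
#' @param path YAML file path, or a list already in memory.
#' @return Validated configuration list.
#' @export
read_experiment_config <- function(path) {
  user <- if (is.character(path)) yaml::read_yaml(path) else path
  base <- default_experiment_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  merge2 <- function(b, u) {
    if (!is.list(b) || !is.list(u)) return(u)
    bad <- setdiff(names(u), names(b))
    if (length(bad))
      stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
    for (nm in names(u)) b[[nm]] <- merge2(b[[nm]], u[[nm]])
    b
  }
  cfg <- merge2(base, user)
  for (key in c("seed", "train_ids", "test_id"))
    if (is.null(cfg[[key]]) || length(cfg[[key]]) == 0)
      stop("missing configuration key: ", key)
  cfg
}

experiment_scenarios <- function(cfg) {
  if (identical(cfg$scenarios, "default")) return(default_scenarios(cfg$seed))
  lapply(cfg$scenarios, function(s) do.call(cultivation_scenario, s))
}

#' Run a full experiment from one configuration
#'
#' Executes the complete workflow -- synthesize data, derive features,
#' interpolate and augment labels, build windows, train, simulate the
#' held-out cultivation from initial state and environment only, evaluate --
#' and writes every artifact (dataset CSVs, loss trace, checkpoint,
#' trajectory, metrics) plus a manifest recording seeds, package version and
#' file hashes. Any stage failure aborts with the stage name; artifacts
#' written before the failure are preserved.
#'
#' @param config Path to a YAML configuration or a configuration list.
#' @param out_dir Output directory.
#' @param verbose Print stage progress.
#' @return Invisibly, a list with `model`, `run`, `metrics` and `paths`.
#' @export
run_experiment <- function(config, out_dir, verbose = FALSE) {
  cfg <- read_experiment_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  paths <- list()

  data <- stage("synth", {
    scen <- experiment_scenarios(cfg)
    generate_dataset(scen, file.path(out_dir, "data"),
                     n_dates = cfg$observation$n_dates,
                     cv = cfg$observation$cv,
                     n_plants = cfg$observation$n_plants)
  })
  paths$data <- file.path(out_dir, "data")

  ids <- names(data)
  missing <- setdiff(c(cfg$train_ids, cfg$test_id), ids)
  if (length(missing))
    stop("stage 'synth' failed: configured cultivation id(s) not generated: ",
         paste(missing, collapse = ", "), call. = FALSE)

  windows <- stage("windows", {
    cult <- lapply(cfg$train_ids, function(id) {
      d <- data[[id]]
      lab <- interpolate_growth_daily(d$obs,
                                      start_rule = cfg$augment$start_rule)
      draws <- augment_labels(lab, n_draws = cfg$augment$n_draws,
                              seed = cfg$seed + 100L + match(id, ids))
      list(env = d$env, labels = lab, draws = draws, id = id)
    })
    make_training_windows(cult, cfg$model$memory_length,
                          split = cfg$training$split, seed = cfg$seed + 7L,
                          t_base = cfg$features$t_base)
  })

  model <- stage("train", {
    mcfg <- do.call(attncrop_config, c(cfg$model, list(seed = cfg$seed)))
    attncrop(windows, mcfg, epochs = cfg$training$epochs,
             batch_size = cfg$training$batch_size, lr = cfg$training$lr,
             patience = cfg$training$patience, verbose = verbose)
  })
  paths$trace <- file.path(out_dir, "trace.csv")
  utils::write.csv(model$trace, paths$trace, row.names = FALSE, quote = FALSE)
  paths$checkpoint <- file.path(out_dir, "checkpoint.rds")
  save_checkpoint(model, paths$checkpoint)

  run <- stage("simulate", {
    d <- data[[cfg$test_id]]
    lab <- interpolate_growth_daily(d$obs, start_rule = cfg$augment$start_rule)
    init <- lab$mean[1, ]
    names(init) <- colnames(lab$mean)
    daily <- compute_daily_features(d$env, t_base = cfg$features$t_base)
    run_simulation(model, d$env, init,
                   n_days = max(daily$day) - cfg$model$memory_length,
                   guidance = cfg$simulation$guidance,
                   sanitize = cfg$simulation$sanitize)
  })
  paths$trajectory <- file.path(out_dir, "trajectory.csv")
  write_trajectory_csv(run, paths$trajectory)

  metrics <- stage("evaluate", {
    d <- data[[cfg$test_id]]
    train_mat <- do.call(rbind, lapply(cfg$train_ids, function(id)
      as.matrix(data[[id]]$truth[, crop_factors()$name])))
    suppressWarnings(
      evaluate_simulation(run, d$truth, factors = cfg$evaluation$factors,
                          baseline = train_mat))
  })
  paths$metrics <- file.path(out_dir, "metrics.csv")
  utils::write.csv(as.data.frame(metrics), paths$metrics, row.names = FALSE,
                   quote = FALSE)

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  manifest <- list(
    seed = cfg$seed,
    derived_seeds = list(windows = cfg$seed + 7L,
                         augment = cfg$seed + 100L + seq_along(ids)),
    package_version = as.character(utils::packageVersion("attncrop")),
    config = cfg,
    files = as.list(tools::md5sum(files)))
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(model = model, run = run, metrics = metrics, paths = paths))
}
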