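# Pipeline orchestration: configuration, stage execution, manifest.

pipeline_stages <- c("simulate", "preprocess", "ggm", "boot", "dag",
                     "effects", "report")

#' Build a validated pipeline configuration
#'
#' Returns the full configuration with profile defaults filled in.  The
#' `test` profile is sized for continuous testing (200 bootstrap
#' replicates, 2e5 MCMC iterations); the `full` profile mirrors the
#' emulated study's scale (5000 bootstraps, 1e7 iterations retaining
#' 50,000 DAGs).  Every stage seed is derived deterministically from the
#' master seed and the stage name.
#'
#' @param config named list (or path to a YAML file) of overrides.
#' @param profile `"test"` or `"full"`.
#' @param seed master seed (overrides the config entry).
#' @param output_dir output directory (overrides the config entry).
#' @return a validated configuration list of class `run_config`.
#' @export
run_config <- function(config = list(), profile = NULL, seed = NULL,
                       output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  profile <- profile %||% config$profile %||% "test"
  if (!profile %in% c("test", "full"))
    stop("profile must be 'test' or 'full'")
  full <- profile == "full"
  defaults <- list(
    seed = 1L,
    output_dir = "psynet_out",
    profile = profile,
    simulate = list(enabled = TRUE, p = 12L, n = if (full) 6161L else 2000L,
                    edge_prob = 0.25, weight_range = c(0.15, 0.5),
                    reliability = 0.8, missing_rate = 0.02,
                    age_mean = 45.6, age_sd = 14.7),
    input = list(csv = NULL, config = NULL),
    preprocess = list(m = if (full) 5L else 2L, iterations = 3L,
                      max_missing_frac = 0.20, age_sd_mult = 2.0,
                      min_age = 18L),
    ggm = list(gamma = 0.5, nlambda = 100L, lambda_min_ratio = 0.01),
    boot = list(enabled = TRUE, B = if (full) 5000L else 200L,
                cs_enabled = FALSE, cs_B = if (full) 100L else 20L),
    dag = list(sampler = "partition", iterations = if (full) 1e7 else 2e5,
               burn_in = NULL, thinning = NULL, am = 1, aw = NULL,
               edge_logprior = 0),
    effects = list(focal = NULL, edge_threshold = 0.50,
                   direction_threshold = 0.90))
  cfg <- modify_defaults(defaults, config)
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  cfg$profile <- profile
  validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

modify_defaults <- function(defaults, overrides) {
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]]) &&
        !is.null(names(defaults[[nm]])))
      defaults[[nm]] <- modify_defaults(defaults[[nm]], overrides[[nm]])
    else defaults[[nm]] <- overrides[[nm]]
  }
  defaults
}

validate_run_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1)
  eff <- cfg$effects
  if (eff$edge_threshold <= 0 || eff$edge_threshold > 1 ||
      eff$direction_threshold <= 0 || eff$direction_threshold > 1)
    stop("config error [effects]: thresholds must lie in (0, 1]")
  if (eff$direction_threshold < eff$edge_threshold)
    stop("config error [effects]: direction_threshold must not be below edge_threshold")
  if (!cfg$dag$sampler %in% c("partition", "edge_mh"))
    stop("config error [dag]: sampler must be 'partition' or 'edge_mh'")
  if (cfg$dag$iterations < 1000)
    stop("config error [dag]: iterations too small to retain a sample")
  if (!isTRUE(cfg$simulate$enabled) &&
      (is.null(cfg$input$csv) || is.null(cfg$input$config)))
    stop("config error [input]: supply input csv + config or enable simulate")
  invisible(cfg)
}

plog <- function(level, stage, ...) {
  message(sprintf("[%s] [%s] %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(...)))
}

artifact <- function(cfg, ...) file.path(cfg$output_dir, ...)

require_artifact <- function(cfg, file, producer) {
  path <- artifact(cfg, file)
  if (!file.exists(path))
    stop(sprintf("missing upstream artifact '%s': run the '%s' stage first",
                 path, producer), call. = FALSE)
  path
}

stage_simulate <- function(cfg) {
  sim <- cfg$simulate
  p <- sim$p
  specs <- if (p == 12L) default_scale_specs()
           else as_scale_spec_list(lapply(seq_len(p), function(i)
             scale_spec(paste0("s", i), 8L, 0L, 4L)))
  study <- simulate_study(n = sim$n, specs = specs,
                          edge_prob = sim$edge_prob,
                          weight_range = sim$weight_range,
                          reliability = sim$reliability,
                          missing_rate = sim$missing_rate,
                          age_mean = sim$age_mean, age_sd = sim$age_sd,
                          seed = stage_seed(cfg$seed, "simulate"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  write_likert_dataset(study$data, artifact(cfg, "data.csv"),
                       artifact(cfg, "data_config.yaml"),
                       ages = study$ages, dag = study$dag)
  plog("info", "simulate", "wrote %d x %d item table", nrow(study$data$items),
       ncol(study$data$items))
  c(artifact(cfg, "data.csv"), artifact(cfg, "data_config.yaml"))
}

stage_preprocess <- function(cfg) {
  if (isTRUE(cfg$simulate$enabled)) {
    csv <- require_artifact(cfg, "data.csv", "simulate")
    ycf <- require_artifact(cfg, "data_config.yaml", "simulate")
  } else {
    csv <- cfg$input$csv; ycf <- cfg$input$config
    if (!file.exists(csv) || !file.exists(ycf))
      stop("config error [input]: input files not found")
  }
  ds <- read_likert_dataset(csv, ycf)
  if (is.null(ds$ages)) ds$ages <- rep(30, nrow(ds$data$items))
  pp <- cfg$preprocess
  clean <- preprocess(ds$data, ds$ages, m = pp$m, iterations = pp$iterations,
                      seed = stage_seed(cfg$seed, "preprocess"),
                      max_missing_frac = pp$max_missing_frac,
                      age_sd_mult = pp$age_sd_mult, min_age = pp$min_age)
  paths <- artifact(cfg, c("totals.csv", "z.csv", "pooled_correlation.csv",
                           "exclusions.csv", "alphas.csv"))
  write.csv(data.frame(participant_id = clean$kept_ids, clean$totals,
                       check.names = FALSE), paths[1], row.names = FALSE)
  write.csv(data.frame(participant_id = clean$kept_ids, clean$z,
                       check.names = FALSE), paths[2], row.names = FALSE)
  write.csv(data.frame(node = colnames(clean$S), clean$S,
                       check.names = FALSE), paths[3], row.names = FALSE)
  write.csv(clean$exclusions, paths[4], row.names = FALSE)
  write.csv(data.frame(scale = names(clean$alphas),
                       alpha = unname(clean$alphas)),
            paths[5], row.names = FALSE)
  plog("info", "preprocess", "kept %d participants (%d excluded)", clean$n,
       nrow(clean$exclusions))
  paths
}

read_z_artifact <- function(cfg, producer = "preprocess") {
  path <- require_artifact(cfg, "z.csv", producer)
  df <- read.csv(path, check.names = FALSE)
  as.matrix(df[, setdiff(names(df), "participant_id"), drop = FALSE])
}

stage_ggm <- function(cfg) {
  spath <- require_artifact(cfg, "pooled_correlation.csv", "preprocess")
  sdf <- read.csv(spath, check.names = FALSE)
  S <- as.matrix(sdf[, -1, drop = FALSE])
  rownames(S) <- sdf$node
  z <- read_z_artifact(cfg)
  net <- ggm_model_select(S, n = nrow(z), gamma = cfg$ggm$gamma,
                          nlambda = cfg$ggm$nlambda,
                          lambda_min_ratio = cfg$ggm$lambda_min_ratio,
                          labels = colnames(S))
  paths <- write_network(net, cfg$output_dir)
  cent <- centrality(net)
  cpath <- artifact(cfg, "centrality.csv")
  write.csv(cent, cpath, row.names = FALSE)
  plog("info", "ggm", "selected %d edges (EBIC %.1f)", nrow(net$edges),
       net$ebic)
  c(paths, cpath)
}

stage_boot <- function(cfg) {
  if (!isTRUE(cfg$boot$enabled)) return(character(0))
  z <- read_z_artifact(cfg)
  res <- nonparametric_boot(z, B = cfg$boot$B,
                            seed = stage_seed(cfg$seed, "boot"),
                            gamma = cfg$ggm$gamma,
                            nlambda = cfg$ggm$nlambda,
                            lambda_min_ratio = cfg$ggm$lambda_min_ratio)
  cs <- NULL
  if (isTRUE(cfg$boot$cs_enabled))
    cs <- case_drop_boot(z, B = cfg$boot$cs_B,
                         seed = stage_seed(cfg$seed, "boot_cs"),
                         gamma = cfg$ggm$gamma,
                         nlambda = cfg$ggm$nlambda,
                         lambda_min_ratio = cfg$ggm$lambda_min_ratio)
  plog("info", "boot", "%d bootstrap replicates done", res$B)
  write_boot_summary(res, cfg$output_dir, cs)
}

stage_dag <- function(cfg) {
  z <- read_z_artifact(cfg)
  dg <- cfg$dag
  sc <- score_config(am = dg$am, aw = dg$aw,
                     edge_logprior = dg$edge_logprior)
  set <- sample_dags(z, iterations = dg$iterations, burn_in = dg$burn_in,
                     thinning = dg$thinning, config = sc,
                     seed = stage_seed(cfg$seed, "dag"),
                     sampler = dg$sampler)
  p1 <- artifact(cfg, "dag_samples.txt")
  write_dag_samples(set, p1)
  diag <- list(retained = nrow(set$parent_masks),
               acceptance_rate = set$acceptance_rate,
               score_range = range(set$score_trace),
               sampler = set$sampler)
  p2 <- artifact(cfg, "dag_diagnostics.json")
  jsonlite::write_json(diag, p2, auto_unbox = TRUE, digits = NA)
  plog("info", "dag", "retained %d DAGs (acceptance %.3f)", diag$retained,
       diag$acceptance_rate)
  c(p1, p2)
}

stage_effects <- function(cfg) {
  z <- read_z_artifact(cfg)
  spath <- require_artifact(cfg, "dag_samples.txt", "dag")
  set <- read_dag_samples(spath)
  focal <- cfg$effects$focal %||% set$labels[1]
  if (!focal %in% set$labels)
    stop(sprintf("config error [effects]: unknown focal construct '%s'", focal))
  eff <- effects_table(set, z, focal)
  mg <- mixed_graph(set, cfg$effects$edge_threshold,
                    cfg$effects$direction_threshold)
  plog("info", "effects", "%d directed + %d undirected mixed-graph edges",
       nrow(mg$directed_edges), nrow(mg$undirected_edges))
  write_effects(eff, mg, cfg$output_dir)
}

#' Run the full pipeline
#'
#' Executes simulate (optional), preprocess, network estimation and
#' bootstrap, DAG sampling, and effect averaging, writing every artifact
#' under the configured output directory plus a JSON manifest recording
#' the settings, stage seeds, and the MD5 checksum of every artifact.
#' Re-running with the same configuration and master seed reproduces
#' byte-identical numeric outputs.
#'
#' @param config a [run_config] (or a named list / YAML path coerced
#'   through [run_config]).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  t0 <- Sys.time()
  arts <- character(0)
  stages <- c(if (isTRUE(config$simulate$enabled)) "simulate",
              "preprocess", "ggm", "boot", "dag", "effects")
  for (st in stages) {
    fn <- get(paste0("stage_", st), mode = "function")
    arts <- c(arts, tryCatch(fn(config), error = function(e)
      stop(sprintf("stage '%s' failed: %s", st, conditionMessage(e)),
           call. = FALSE)))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("psynet")),
    created = format(t0, "%Y-%m-%dT%H:%M:%S"),
    seed = config$seed,
    stage_seeds = stats::setNames(
      lapply(pipeline_stages, function(s) stage_seed(config$seed, s)),
      pipeline_stages),
    profile = config$profile,
    settings = unclass(config),
    artifacts = lapply(arts, function(a)
      list(path = a, md5 = unname(tools::md5sum(a)))))
  mpath <- artifact(config, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  plog("info", "report", "manifest lists %d artifacts", length(arts))
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `preprocess`, `ggm`, `boot`, `dag`,
#' `effects`, `report`, `all`.  Flags: `--config PATH`, `--seed INT`,
#' `--profile test|full`, `--out DIR`.  Each subcommand consumes the
#' artifacts of its upstream stages by path and emits its own; a missing
#' upstream artifact raises an error naming the producing subcommand.
#'
#' @param args character vector of command-line arguments (defaults to
#'   the live command line).
#' @return integer exit status (0 on success), invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: psynet <simulate|preprocess|ggm|boot|dag|effects|report|all>",
    "              [--config PATH] [--seed INT] [--profile test|full] [--out DIR]",
    sep = "\n")
  if (length(args) == 0 || !(args[1] %in% c(pipeline_stages, "all"))) {
    message(usage)
    return(invisible(2L))
  }
  sub <- args[1]
  flags <- list()
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% c("config", "seed", "profile", "out", "log-level") ||
        i == length(args)) {
      message("unknown or incomplete flag: ", args[i]); message(usage)
      return(invisible(2L))
    }
    flags[[key]] <- args[i + 1]
    i <- i + 2
  }
  status <- tryCatch({
    cfg <- run_config(config = flags$config %||% list(),
                      profile = flags$profile,
                      seed = if (!is.null(flags$seed))
                        as.integer(flags$seed),
                      output_dir = flags$out)
    if (sub == "all") {
      run_pipeline(cfg)
    } else if (sub == "report") {
      run_pipeline_manifest_only(cfg)
    } else {
      fn <- get(paste0("stage_", sub), mode = "function")
      fn(cfg)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

run_pipeline_manifest_only <- function(cfg) {
  files <- list.files(cfg$output_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(seed = cfg$seed, profile = cfg$profile,
                   settings = unclass(cfg),
                   artifacts = lapply(files, function(a)
                     list(path = a, md5 = unname(tools::md5sum(a)))))
  jsonlite::write_json(manifest, artifact(cfg, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
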