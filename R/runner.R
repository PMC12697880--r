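#' Read a run configuration from a YAML or JSON file
#'
#' Flat key-value configuration; recognized keys mirror the arguments of
#' [nca_architecture()], [nca_config()], [aging_schedules()] (schedules in
#' the compact `kind:from:to` string form) and [intervention_policy()].
#' Unknown keys raise an error.
#'
#' @param path config file (`.yaml`/`.yml` or `.json`), or a named list
#'   already in memory.
#' @param overrides named list of keys overriding the file's values.
#' @return a named list of raw configuration values.
#' @export
read_run_config <- function(path, overrides = list()) {
  cfg <- if (is.list(path)) {
    path
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg[names(overrides)] <- overrides
  known <- c("width", "height", "n_types", "n_hidden", "sensor_dim",
             "hidden_dim", "t_D", "t_A", "xi_c", "r_T", "r_S", "population",
             "generations", "repetitions", "sigma0", "noise", "competency",
             "gap_junction", "mutation_sigma", "threshold", "mode",
             "include_boundary", "payload", "refractory", "start", "target",
             "genome", "seed", "k", "window", "stride", "record_states")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")))
  cfg
}

build_config <- function(cfg, target = NULL) {
  arch_args <- cfg[intersect(names(cfg), c("width", "height", "n_types",
                                           "n_hidden", "sensor_dim", "hidden_dim"))]
  if (!is.null(target)) {
    arch_args$width <- target$width
    arch_args$height <- target$height
    arch_args$n_types <- target$n_types
  }
  arch <- do.call(nca_architecture, arch_args)
  cfg_args <- cfg[intersect(names(cfg), c("t_D", "t_A", "xi_c", "r_T", "r_S",
                                          "population", "generations",
                                          "repetitions", "sigma0"))]
  do.call(nca_config, c(list(arch = arch), cfg_args))
}

build_schedules <- function(cfg) {
  parse_one <- function(x) {
    if (is.null(x)) return(NULL)
    if (inherits(x, "nca_schedule")) return(x)
    parse_schedule(x)
  }
  aging_schedules(noise = parse_one(cfg$noise),
                  competency = parse_one(cfg$competency),
                  gap_junction = parse_one(cfg$gap_junction),
                  mutation_sigma = if (is.null(cfg$mutation_sigma)) 0 else
                    cfg$mutation_sigma)
}

write_trajectory_csv <- function(trajectory, target, config, path) {
  ts <- 0:trajectory$steps
  tv <- as.vector(target$types)
  n_G <- apply(trajectory$types, 1L, function(row) sum(row == tv))
  df <- data.frame(t = ts, n_G = n_G,
                   pattern_term = 2L * n_G - length(tv),
                   se = apply(trajectory$types, 1L, spatial_entropy))
  if (!is.null(trajectory$scores)) {
    df <- cbind(df, as.data.frame(trajectory$scores))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Execute a named command into a run directory
#'
#' Top-level orchestration for the five platform commands:
#' * `evolve` — evolve a genome for the configured target; writes
#'   `genome.json` and `generations.csv`.
#' * `simulate` — deploy a genome under baseline conditions; writes
#'   `trajectory.csv` (t, correct cells, pattern term, spatial entropy).
#' * `age` — deploy under the configured perturbation schedules.
#' * `analyze` — sliding-window information dynamics of a fresh deployment;
#'   writes `info.csv` and per-epoch AIS/TE maps.
#' * `rejuvenate` — deploy with organ monitoring and the configured policy;
#'   writes `trajectory.csv` and `events.csv`.
#'
#' Every run directory receives a `config.json` snapshot and `seed.txt`
#' ledger so the run can be replayed from the directory alone; identical
#' command, config and seed produce byte-identical logs.
#'
#' @param name command name.
#' @param config path to a YAML/JSON config file or a named list (see
#'   [read_run_config()]); must name a `target` pattern file for all commands
#'   and a `genome` file for the deployment commands.
#' @param out_dir run directory to create.
#' @param seed master seed (overrides the config's).
#' @param overrides named list of config overrides.
#' @return the run directory path, invisibly; a `summary.json` with the
#'   command's headline numbers is always written.
#' @export
run_command <- function(name, config, out_dir,
                        seed = NULL, overrides = list()) {
  name <- match.arg(name, c("evolve", "simulate", "age", "analyze", "rejuvenate"))
  cfg <- read_run_config(config, overrides)
  if (!is.null(seed)) cfg$seed <- seed
  if (is.null(cfg$seed)) stop("a seed is required (config key 'seed' or argument)")
  if (is.null(cfg$target)) stop("config must name a 'target' pattern file")
  target <- if (inherits(cfg$target, "nca_pattern")) cfg$target else
    read_pattern(cfg$target)
  run_cfg <- build_config(cfg, target)
  schedules <- build_schedules(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  snap <- cfg
  snap$target <- if (is.character(cfg$target)) cfg$target else "<in-memory pattern>"
  snap$genome <- if (is.character(cfg$genome)) cfg$genome else
    if (!is.null(cfg$genome)) "<in-memory genome>" else NULL
  jsonlite::write_json(snap[!vapply(snap, is.null, NA)],
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  writeLines(as.character(cfg$seed), file.path(out_dir, "seed.txt"))

  need_genome <- function() {
    if (is.null(cfg$genome)) stop(sprintf("command '%s' requires a 'genome'", name))
    if (inherits(cfg$genome, "nca_genome")) cfg$genome else read_genome(cfg$genome)
  }
  summary <- list(command = name, seed = cfg$seed)

  if (name == "evolve") {
    res <- evolve_nca(target, run_cfg, seed = cfg$seed)
    write_genome(res$genome, file.path(out_dir, "genome.json"), seed = cfg$seed)
    utils::write.csv(res$history, file.path(out_dir, "generations.csv"),
                     row.names = FALSE)
    summary$solved <- res$solved
    summary$best_r <- res$best_r
  } else if (name %in% c("simulate", "age")) {
    genome <- need_genome()
    sch <- if (name == "age") schedules else NULL
    traj <- simulate_nca(genome, run_cfg, schedules = sch, seed = cfg$seed)
    df <- write_trajectory_csv(traj, target, run_cfg,
                               file.path(out_dir, "trajectory.csv"))
    summary$final_pattern_term <- df$pattern_term[nrow(df)]
    summary$t_D_pattern_term <- df$pattern_term[run_cfg$t_D + 1L]
  } else if (name == "analyze") {
    genome <- need_genome()
    traj <- simulate_nca(genome, run_cfg, schedules = schedules, seed = cfg$seed)
    k <- if (is.null(cfg$k)) 2L else as.integer(cfg$k)
    window <- if (is.null(cfg$window)) 100L else as.integer(cfg$window)
    stride <- if (is.null(cfg$stride)) 10L else as.integer(cfg$stride)
    info <- info_series(traj, k = k, window = window, stride = stride)
    utils::write.csv(info, file.path(out_dir, "info.csv"), row.names = FALSE)
    maps <- info_maps(traj, k = k)
    utils::write.table(maps$ais, file.path(out_dir, "ais_map.csv"), sep = ",",
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(maps$te, file.path(out_dir, "te_map.csv"), sep = ",",
                       row.names = FALSE, col.names = FALSE)
    summary$mean_ais <- mean(maps$ais)
    summary$mean_te <- mean(maps$te, na.rm = TRUE)
  } else if (name == "rejuvenate") {
    genome <- need_genome()
    if (is.null(target$organs)) stop("rejuvenate requires a target with organ masks")
    pol_args <- cfg[intersect(names(cfg), c("threshold", "mode",
                                            "include_boundary", "payload",
                                            "refractory", "start"))]
    policy <- do.call(intervention_policy, pol_args)
    traj <- run_with_rejuvenation(genome, run_cfg, policy, target$organs,
                                  target, schedules = schedules, seed = cfg$seed)
    write_trajectory_csv(traj, target, run_cfg,
                         file.path(out_dir, "trajectory.csv"))
    utils::write.csv(traj$events, file.path(out_dir, "events.csv"),
                     row.names = FALSE)
    summary$n_events <- nrow(traj$events)
    summary$final_pattern_term <- pattern_term(traj, target, traj$steps)
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
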