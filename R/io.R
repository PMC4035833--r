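#' Load a run configuration from YAML or JSON
#'
#' The file may contain any subset of the blocks `task`, `network`,
#' `plasticity` and `experiment`; missing keys take the package defaults
#' (N = 250, tau_e = 2.5, the printed learning and adaptation rates, 2e4
#' trials per block, five repeats).  Unknown keys and invariant violations
#' are rejected with the offending key named.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [run_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  .config_from_list(raw)
}

.check_keys <- function(block, allowed, where) {
  bad <- setdiff(names(block), allowed)
  if (length(bad))
    stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "))
  block
}

.config_from_list <- function(raw) {
  .check_keys(raw, c("task", "network", "plasticity", "experiment"), "config")
  task <- .check_keys(raw$task %||% list(),
                      c("family", "K", "delay_mode", "schedule"), "task")
  netb <- .check_keys(raw$network %||% list(),
                      setdiff(names(formals(network_params)), "n_decision"),
                      "network")
  plab <- .check_keys(raw$plasticity %||% list(),
                      names(formals(plasticity_params)), "plasticity")
  expb <- .check_keys(raw$experiment %||% list(),
                      c("trials_per_block", "n_repeats", "recurrent_mode",
                        "seed", "record_trials", "engine"), "experiment")

  family <- task$family %||% "delayed_response"
  template <- task_spec(family, K = task$K, T_max = 1L)
  net_defaults <- list(
    n_decision = template$M,
    x0_recurrent = if (family == "multitask_overlap") 0.05 else 0.03)
  network <- do.call(network_params, modifyList(net_defaults, netb))
  plasticity <- do.call(plasticity_params, plab)

  args <- list(family = family, K = task$K,
               delay_mode = task$delay_mode %||% "variable",
               schedule = task$schedule,
               network = network, plasticity = plasticity)
  args <- c(args, expb)
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Persist a run to disk
#'
#' Writes the trial log and the 100-trial performance curve as CSV, the
#' weight matrices and thresholds as CSV arrays, and a JSON manifest holding
#' the full configuration (including the task's category maps), the seed,
#' the package version and the output inventory — enough to re-run the
#' experiment bit-identically.  Each call creates a fresh subdirectory, so
#' repeated runs never overwrite one another.
#'
#' @param run A `wm_run`.
#' @param dir Target directory (created if needed).
#' @return The manifest, invisibly; its `dir` element names the run
#'   subdirectory.
#' @export
persist_run <- function(run, dir) {
  stopifnot(inherits(run, "wm_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, 2L) != 0L) stop("directory not writable: ", dir)
  base <- sprintf("run-seed%d", run$config$seed)
  sub <- file.path(dir, base)
  k <- 1L
  while (dir.exists(sub)) { k <- k + 1L; sub <- file.path(dir, sprintf("%s-%d", base, k)) }
  dir.create(sub)

  files <- c(trial_log = "trial_log.csv", performance = "performance.csv",
             w_rec = "weights_recurrent.csv", w_dec = "weights_decision.csv",
             thresholds = "thresholds.csv")
  write.csv(run$trial_log, file.path(sub, files["trial_log"]), row.names = FALSE)
  write.csv(performance_curve(run), file.path(sub, files["performance"]),
            row.names = FALSE)
  write.csv(run$network$w_rec, file.path(sub, files["w_rec"]), row.names = FALSE)
  write.csv(run$network$w_dec, file.path(sub, files["w_dec"]), row.names = FALSE)
  th <- data.frame(unit = c(seq_len(run$network$n_exc),
                            seq_len(run$network$n_inh),
                            seq_len(run$config$network$n_decision)),
                   population = rep(c("exc", "inh", "dec"),
                                    c(run$network$n_exc, run$network$n_inh,
                                      run$config$network$n_decision)),
                   theta = c(run$network$theta_exc, run$network$theta_inh,
                             run$network$theta_dec))
  write.csv(th, file.path(sub, files["thresholds"]), row.names = FALSE)

  manifest <- list(
    package = "wmcircuit",
    version = as.character(packageVersion("wmcircuit")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = run$config$seed,
    config = .config_snapshot(run$config),
    task_maps = run$task$maps,
    files = as.list(files))
  jsonlite::write_json(manifest, file.path(sub, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest$dir <- sub
  invisible(manifest)
}

.config_snapshot <- function(cfg) {
  list(task = list(family = cfg$family, K = cfg$K,
                   delay_mode = cfg$delay_mode, schedule = cfg$schedule),
       network = unclass(cfg$network),
       plasticity = unclass(cfg$plasticity),
       experiment = list(trials_per_block = cfg$trials_per_block,
                         n_repeats = cfg$n_repeats,
                         recurrent_mode = cfg$recurrent_mode,
                         seed = cfg$seed, record_trials = cfg$record_trials,
                         engine = cfg$engine))
}

#' Load a persisted run directory
#'
#' @param dir A run subdirectory created by [persist_run()].
#' @return List with the `manifest`, `trial_log`, `performance` curve and the
#'   weight/threshold tables.
#' @export
load_run <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  out <- list(manifest = manifest)
  for (nm in names(manifest$files))
    out[[nm]] <- read.csv(file.path(dir, manifest$files[[nm]]))
  out
}

#' Rebuild a run configuration from a manifest
#'
#' @param manifest Manifest list (or the output of [load_run()]).
#' @return A [run_config()] equivalent to the persisted one; running it
#'   reproduces the original trial log.
#' @export
config_from_manifest <- function(manifest) {
  if (!is.null(manifest$manifest)) manifest <- manifest$manifest
  cfg <- manifest$config
  run_config(family = cfg$task$family, K = cfg$task$K,
             delay_mode = cfg$task$delay_mode,
             schedule = unlist(cfg$task$schedule),
             trials_per_block = cfg$experiment$trials_per_block,
             n_repeats = cfg$experiment$n_repeats,
             recurrent_mode = cfg$experiment$recurrent_mode,
             seed = cfg$experiment$seed,
             network = do.call(network_params, cfg$network),
             plasticity = do.call(plasticity_params, cfg$plasticity),
             record_trials = cfg$experiment$record_trials,
             engine = cfg$experiment$engine)
}
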