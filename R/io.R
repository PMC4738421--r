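#' Read and write simulation configurations
#'
#' Configurations are stored as human-readable YAML mirroring the
#' [simulation_config()] fields. Each process time law is a mapping with
#' keys `rho0`, `tau`, `direction`; the proteinaceous fusion/fission pair
#' is stored once under `ffp` (`rho0`, `tau`) since the two laws share
#' their parameters. The round trip `read_config(write_config(cfg))`
#' reproduces the configuration exactly: numbers are serialised at full
#' double precision.
#'
#' @param config A [simulation_config()].
#' @param path File path of the YAML document.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a [simulation_config()].
#' @examples
#' path <- tempfile(fileext = ".yaml")
#' write_config(simulation_config(n_steps = 100), path)
#' read_config(path)
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  p <- config$params
  law_to_list <- function(law) {
    list(rho0 = law$rho0, tau = law$tau, direction = law$direction)
  }
  doc <- list(
    Q = config$Q,
    dt = config$dt,
    n_steps = config$n_steps,
    initial = if (is.character(config$initial)) config$initial else as.list(config$initial),
    enabled = as.list(config$enabled),
    seed = config$seed,
    record_every = config$record_every,
    record_snapshots = config$record_snapshots,
    params = list(
      gamma = p$gamma, ff1 = p$ff1, ff2 = p$ff2, f_rd = p$f_rd,
      ffm = law_to_list(p$law_ffm),
      ffp = list(rho0 = p$law_ffp_fusion$rho0, tau = p$law_ffp_fusion$tau),
      mb = law_to_list(p$law_mb),
      rep = law_to_list(p$law_rep),
      ec = law_to_list(p$law_ec),
      ed = law_to_list(p$law_ed)
    )
  )
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop("malformed config file '", path, "': ",
                             conditionMessage(e))
  )
  need <- c("Q", "n_steps", "params")
  missing <- setdiff(need, names(doc))
  if (length(missing)) {
    stop("malformed config file '", path, "': missing field(s) ",
         paste(missing, collapse = ", "))
  }
  pp <- doc$params
  law_from <- function(x, what) {
    if (is.null(x) || is.null(x$rho0) || is.null(x$tau)) {
      stop("malformed config file '", path, "': process '", what,
           "' needs rho0 and tau")
    }
    process_law(x$rho0, x$tau, x$direction)
  }
  params <- model_parameters(
    gamma = pp$gamma %||% 1,
    ff1 = pp$ff1 %||% 2,
    ff2 = pp$ff2 %||% 3,
    f_rd = pp$f_rd %||% 0.03,
    law_ffm = law_from(pp$ffm, "ffm"),
    rho0_ffp = pp$ffp$rho0,
    tau_ffp = pp$ffp$tau,
    law_mb = law_from(pp$mb, "mb"),
    law_rep = law_from(pp$rep, "rep"),
    law_ec = law_from(pp$ec, "ec"),
    law_ed = law_from(pp$ed, "ed")
  )
  initial <- doc$initial %||% "uniform"
  if (is.list(initial)) initial <- unlist(initial)
  simulation_config(
    Q = doc$Q,
    dt = doc$dt %||% 1,
    n_steps = doc$n_steps,
    initial = initial,
    enabled = unlist(doc$enabled %||% as.list(process_names())),
    params = params,
    seed = doc$seed %||% 1L,
    record_every = doc$record_every %||% 100L,
    record_snapshots = isTRUE(doc$record_snapshots)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write and read trajectory tables
#'
#' Trajectories are written as plain CSV in tidy layout: `metrics.csv`
#' with columns `t, qbar, sigma_q, p0, nprob` (one row per recorded time)
#' and, when snapshots were recorded, `snapshots.csv` with columns
#' `t, q, P` (`Q + 1` rows per recorded time). All numbers carry 17
#' significant digits so the 12-decimal conservation criterion can be
#' audited from the files.
#'
#' @param traj A `trajectory` from [run_simulation()].
#' @param dir Output directory (created if missing).
#' @return `write_trajectory()` invisibly returns the paths written;
#'   `read_trajectory()` returns a list with elements `metrics` and
#'   (possibly `NULL`) `snapshots`.
#' @export
write_trajectory <- function(traj, dir) {
  stopifnot(inherits(traj, "trajectory"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, "metrics.csv")
  write_full_csv(traj$metrics, paths[1L])
  if (!is.null(traj$snapshots)) {
    paths <- c(paths, file.path(dir, "snapshots.csv"))
    write_full_csv(traj$snapshots, paths[2L])
  }
  invisible(paths)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(dir) {
  mpath <- file.path(dir, "metrics.csv")
  if (!file.exists(mpath)) stop("no metrics.csv under ", dir)
  spath <- file.path(dir, "snapshots.csv")
  list(
    metrics = utils::read.csv(mpath),
    snapshots = if (file.exists(spath)) utils::read.csv(spath)
  )
}

write_full_csv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Run manifest
#'
#' A YAML record of everything needed to reproduce a run bit-identically:
#' the scenario name (if any), the fully resolved configuration (including
#' the seed), the package version and timestamps. `manifest + seed`
#' suffices: [rerun_manifest()] re-executes the recorded configuration.
#'
#' @param traj A `trajectory`.
#' @param path Output YAML path.
#' @param scenario Optional scenario name to record.
#' @return `write_manifest()` invisibly returns `path`;
#'   `rerun_manifest()` returns a fresh `trajectory`.
#' @export
write_manifest <- function(traj, path, scenario = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  cfg_path <- tempfile(fileext = ".yaml")
  write_config(traj$config, cfg_path)
  doc <- list(
    scenario = scenario %||% "custom",
    software = paste0("mitoquality ", as.character(utils::packageVersion("mitoquality"))),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = traj$config$seed,
    config = yaml::read_yaml(cfg_path)
  )
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

#' @rdname write_manifest
#' @export
rerun_manifest <- function(path) {
  doc <- yaml::read_yaml(path)
  cfg_path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(doc$config, cfg_path, precision = 17)
  run_simulation(read_config(cfg_path))
}
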