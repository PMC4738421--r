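#' Named scenario presets
#'
#' Every simulation experiment of the model is available as a named,
#' reproducible preset built from the reference parameter set
#' ([model_parameters()]) with documented overrides. `list_scenarios()`
#' returns the registry with one-line descriptions; [build_scenario()]
#' materialises a preset into a full [simulation_config()].
#'
#' The families are:
#' \describe{
#'   \item{`single_*`}{one process enabled at reference values, 30000
#'     steps: `single_ff` (both networking terms), `single_mb`,
#'     `single_repair`, `single_ec`, `single_ed`.}
#'   \item{`ff_metabolic_only`, `ff_protein_only`}{the two networking
#'     halves separately, 30000 steps.}
#'   \item{`interplay`}{networking plus recycling
#'     (`ff_metabolic`, `ff_protein`, `mb`), 30000 steps; repair and the
#'     damage processes are absent entirely.}
#'   \item{`aging`}{all five processes at reference values, 100000 steps:
#'     the cell-aging experiment.}
#'   \item{`non_aging`}{aging with every process lifetime set to
#'     `5e8` tu, i.e. time-independent processes.}
#'   \item{`stable_repair`}{aging with only the repair lifetime set to
#'     `5e8` tu.}
#'   \item{`stressed`}{high external ROS and metabolic activity:
#'     `rho0_ec = 0.05`, `rho0_ed = 0.1`, `f_rd = 0.3`; variants
#'     `stressed_stable_ec`, `stressed_stable_ed`,
#'     `stressed_stable_both` freeze the corresponding lifetimes at
#'     `5e8` tu.}
#'   \item{`hec`}{high-energy-demand cell: `rho0_ec = 0.05`. Variants
#'     modify networking (`hec_net_rho`: `rho0_ffm = rho0_ffp = 0.5`;
#'     `hec_net_tau`: networking lifetimes `5e8`; `hec_net_rho_tau`:
#'     both), recycling (`hec_rec_rho`: `rho0_mb = 0.05`;
#'     `hec_rec_tau`; `hec_rec_rho_tau`), both processes
#'     (`hec_net_rec_rho`, `hec_net_rec_rho_tau`), and the best
#'     combined strategy `hec_best` (networking raised and stabilised,
#'     recycling raised but not stabilised).}
#'   \item{`robust_*`}{robustness checks with doubled parameters:
#'     `robust_interplay_net` (`rho0_ffm = rho0_ffp = 0.1`, networking
#'     lifetimes 100000 tu), `robust_interplay_rec` (`rho0_mb = 0.02`,
#'     `tau_mb = 100000`), `robust_stable_repair` (stable repair with
#'     `rho0_rep = 0.02`).}
#' }
#'
#' @param name Scenario identifier, one of `list_scenarios()$name`.
#' @param overrides Optional named list applied on top of the preset.
#'   Recognised names: the [simulation_config()] fields (`Q`, `dt`,
#'   `n_steps`, `seed`, `record_every`, `record_snapshots`, `initial`,
#'   `enabled`) and the parameter shortcuts `gamma`, `ff1`, `ff2`, `f_rd`,
#'   `rho0_ffm`, `tau_ffm`, `rho0_ffp`, `tau_ffp`, `rho0_mb`, `tau_mb`,
#'   `rho0_rep`, `tau_rep`, `rho0_ec`, `tau_ec`, `rho0_ed`, `tau_ed`.
#' @return An object of class `scenario_spec` with fields `name`,
#'   `description` and `config`.
#' @examples
#' build_scenario("interplay")
#' build_scenario("aging", list(Q = 4, n_steps = 1000))
#' @export
build_scenario <- function(name, overrides = NULL) {
  reg <- scenario_registry()
  if (!name %in% names(reg)) {
    stop(
      "unknown scenario '", name, "'; available: ",
      paste(names(reg), collapse = ", ")
    )
  }
  preset <- reg[[name]]
  args <- preset$args
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides), !is.null(names(overrides)))
    args[names(overrides)] <- overrides
  }
  structure(
    list(
      name = name,
      description = preset$description,
      config = do.call(scenario_config, args)
    ),
    class = "scenario_spec"
  )
}

#' @rdname build_scenario
#' @export
list_scenarios <- function() {
  reg <- scenario_registry()
  data.frame(
    name = names(reg),
    description = vapply(reg, `[[`, "", "description"),
    row.names = NULL
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> %s: %s\n", x$name, x$description))
  print(x$config)
  invisible(x)
}

#' Run a scenario preset
#'
#' Convenience wrapper: [build_scenario()] followed by
#' [run_simulation()].
#'
#' @inheritParams build_scenario
#' @return A `trajectory` (see [run_simulation()]).
#' @export
run_scenario <- function(name, overrides = NULL) {
  run_simulation(build_scenario(name, overrides)$config)
}

## Turn a flat argument list (config fields + parameter shortcuts) into a
## simulation_config. Shortcut names modify the corresponding law or scalar
## of model_parameters().
scenario_config <- function(...) {
  args <- list(...)
  par_scalars <- intersect(names(args), c("gamma", "ff1", "ff2", "f_rd"))
  law_names <- c(ffm = "law_ffm", mb = "law_mb", rep = "law_rep",
                 ec = "law_ec", ed = "law_ed")
  par_args <- args[par_scalars]
  # laws: start from the reference set, apply rho0_*/tau_* shortcuts
  defaults <- model_parameters()
  for (proc in names(law_names)) {
    law <- defaults[[law_names[[proc]]]]
    rho_key <- paste0("rho0_", proc)
    tau_key <- paste0("tau_", proc)
    if (rho_key %in% names(args) || tau_key %in% names(args)) {
      rho0 <- if (rho_key %in% names(args)) args[[rho_key]] else law$rho0
      tau <- if (tau_key %in% names(args)) args[[tau_key]] else law$tau
      par_args[[law_names[[proc]]]] <- process_law(rho0, tau, law$direction)
    }
  }
  if ("rho0_ffp" %in% names(args)) par_args$rho0_ffp <- args$rho0_ffp
  if ("tau_ffp" %in% names(args)) par_args$tau_ffp <- args$tau_ffp
  params <- do.call(model_parameters, par_args)
  cfg_names <- intersect(
    names(args),
    c("Q", "dt", "n_steps", "initial", "enabled", "seed",
      "record_every", "record_snapshots")
  )
  do.call(simulation_config, c(args[cfg_names], list(params = params)))
}

scenario_registry <- function() {
  stable_all <- list(
    tau_ffm = tau_stable, tau_ffp = tau_stable, tau_mb = tau_stable,
    tau_rep = tau_stable, tau_ec = tau_stable, tau_ed = tau_stable
  )
  hec <- list(rho0_ec = 0.05)
  reg <- list(
    single_ff = list(
      description = "fission/fusion only (metabolic + proteinaceous), 30000 tu",
      args = list(enabled = c("ff_metabolic", "ff_protein"), n_steps = 30000)
    ),
    single_mb = list(
      description = "mitophagy/biogenesis recycling only, 30000 tu",
      args = list(enabled = "mb", n_steps = 30000)
    ),
    single_repair = list(
      description = "binomial repair only, 30000 tu",
      args = list(enabled = "repair", n_steps = 30000)
    ),
    single_ec = list(
      description = "energy-consumption damage only, 30000 tu",
      args = list(enabled = "ec", n_steps = 30000)
    ),
    single_ed = list(
      description = "stochastic external damage only, 30000 tu",
      args = list(enabled = "ed", n_steps = 30000)
    ),
    ff_metabolic_only = list(
      description = "metabolic (kiss-and-run) fission/fusion only, 30000 tu",
      args = list(enabled = "ff_metabolic", n_steps = 30000)
    ),
    ff_protein_only = list(
      description = "proteinaceous fission/fusion only, 30000 tu",
      args = list(enabled = "ff_protein", n_steps = 30000)
    ),
    interplay = list(
      description = "networking + recycling interplay, 30000 tu",
      args = list(enabled = c("ff_metabolic", "ff_protein", "mb"),
                  n_steps = 30000)
    ),
    aging = list(
      description = "all five processes, reference values, 100000 tu",
      args = list(n_steps = 100000)
    ),
    non_aging = list(
      description = "all processes with lifetimes 5e8 tu (time-independent)",
      args = c(list(n_steps = 100000), stable_all)
    ),
    stable_repair = list(
      description = "aging with the repair lifetime frozen at 5e8 tu",
      args = list(n_steps = 100000, tau_rep = tau_stable)
    ),
    stressed = list(
      description = "stressed cell: rho0_ec 0.05, rho0_ed 0.1, f_rd 0.3",
      args = list(n_steps = 100000, rho0_ec = 0.05, rho0_ed = 0.1, f_rd = 0.3)
    ),
    stressed_stable_ec = list(
      description = "stressed cell with energy consumption stabilised",
      args = list(n_steps = 100000, rho0_ec = 0.05, rho0_ed = 0.1,
                  f_rd = 0.3, tau_ec = tau_stable)
    ),
    stressed_stable_ed = list(
      description = "stressed cell with external damage stabilised",
      args = list(n_steps = 100000, rho0_ec = 0.05, rho0_ed = 0.1,
                  f_rd = 0.3, tau_ed = tau_stable)
    ),
    stressed_stable_both = list(
      description = "stressed cell with both damage processes stabilised",
      args = list(n_steps = 100000, rho0_ec = 0.05, rho0_ed = 0.1,
                  f_rd = 0.3, tau_ec = tau_stable, tau_ed = tau_stable)
    ),
    hec = list(
      description = "high-energy-demand cell: rho0_ec raised to 0.05",
      args = c(list(n_steps = 100000), hec)
    ),
    hec_net_rho = list(
      description = "hec with networking probabilities raised to 0.5",
      args = c(list(n_steps = 100000, rho0_ffm = 0.5, rho0_ffp = 0.5), hec)
    ),
    hec_net_tau = list(
      description = "hec with networking stabilised (tau 5e8 tu)",
      args = c(list(n_steps = 100000, tau_ffm = tau_stable,
                    tau_ffp = tau_stable), hec)
    ),
    hec_net_rho_tau = list(
      description = "hec with networking raised and stabilised",
      args = c(list(n_steps = 100000, rho0_ffm = 0.5, rho0_ffp = 0.5,
                    tau_ffm = tau_stable, tau_ffp = tau_stable), hec)
    ),
    hec_rec_rho = list(
      description = "hec with recycling probability raised to 0.05",
      args = c(list(n_steps = 100000, rho0_mb = 0.05), hec)
    ),
    hec_rec_tau = list(
      description = "hec with recycling stabilised (tau 5e8 tu)",
      args = c(list(n_steps = 100000, tau_mb = tau_stable), hec)
    ),
    hec_rec_rho_tau = list(
      description = "hec with recycling raised and stabilised",
      args = c(list(n_steps = 100000, rho0_mb = 0.05,
                    tau_mb = tau_stable), hec)
    ),
    hec_net_rec_rho = list(
      description = "hec with networking and recycling probabilities raised",
      args = c(list(n_steps = 100000, rho0_ffm = 0.5, rho0_ffp = 0.5,
                    rho0_mb = 0.05), hec)
    ),
    hec_net_rec_rho_tau = list(
      description = "hec with both processes raised and stabilised",
      args = c(list(n_steps = 100000, rho0_ffm = 0.5, rho0_ffp = 0.5,
                    rho0_mb = 0.05, tau_ffm = tau_stable,
                    tau_ffp = tau_stable, tau_mb = tau_stable), hec)
    ),
    hec_best = list(
      description = "hec best strategy: networking raised + stabilised, recycling raised",
      args = c(list(n_steps = 100000, rho0_ffm = 0.5, rho0_ffp = 0.5,
                    rho0_mb = 0.05, tau_ffm = tau_stable,
                    tau_ffp = tau_stable), hec)
    ),
    robust_interplay_net = list(
      description = "interplay robustness: networking parameters doubled",
      args = list(enabled = c("ff_metabolic", "ff_protein", "mb"),
                  n_steps = 30000, rho0_ffm = 0.1, rho0_ffp = 0.1,
                  tau_ffm = 100000, tau_ffp = 100000)
    ),
    robust_interplay_rec = list(
      description = "interplay robustness: recycling parameters doubled",
      args = list(enabled = c("ff_metabolic", "ff_protein", "mb"),
                  n_steps = 30000, rho0_mb = 0.02, tau_mb = 100000)
    ),
    robust_stable_repair = list(
      description = "stable repair robustness: rho0_rep doubled to 0.02",
      args = list(n_steps = 100000, rho0_rep = 0.02, tau_rep = tau_stable)
    )
  )
  reg
}
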