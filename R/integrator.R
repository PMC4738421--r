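#' Simulation configuration
#'
#' Bundles everything needed to reproduce a run: the state space, the step
#' size and horizon, the initial distribution, which processes are enabled,
#' the model parameters, the RNG seed and the output cadence.
#'
#' @param Q Maximal quality state. The model is calibrated for 5 to 15
#'   states, i.e. `Q` between 4 and 14; a larger state space upsets the
#'   balance between the processes.
#' @param dt Euler step size in tu (> 0). The reference step is 1 tu.
#' @param n_steps Number of Euler steps (>= 1).
#' @param initial Either the string `"uniform"` or a probability vector of
#'   length `Q + 1`.
#' @param enabled Character subset of
#'   `c("ff_metabolic", "ff_protein", "mb", "repair", "ec", "ed")` naming
#'   the processes to simulate.
#' @param params A [model_parameters()] object.
#' @param seed Integer RNG seed; only consumed when external damage (`ed`)
#'   is enabled, but always recorded so a run is reproducible.
#' @param record_every Output cadence in steps: metrics are recorded at
#'   `t = 0` and after every `record_every`-th step; the final step is
#'   always recorded.
#' @param record_snapshots If `TRUE`, the full distribution is stored at
#'   every recorded time.
#' @return An object of class `simulation_config`.
#' @examples
#' simulation_config(enabled = c("ff_metabolic", "ff_protein"), n_steps = 100)
#' @export
simulation_config <- function(Q = 10,
                              dt = 1,
                              n_steps = 100000,
                              initial = "uniform",
                              enabled = process_names(),
                              params = model_parameters(),
                              seed = 1L,
                              record_every = 100L,
                              record_snapshots = FALSE) {
  stopifnot(
    is.numeric(Q), length(Q) == 1L, Q == round(Q),
    is.numeric(dt), dt > 0,
    is.numeric(n_steps), n_steps >= 1, n_steps == round(n_steps),
    is.numeric(record_every), record_every >= 1,
    inherits(params, "model_parameters"),
    is.logical(record_snapshots)
  )
  if (Q < 4 || Q > 14) {
    stop("'Q' must lie between 4 and 14 (5 to 15 quality states); got ", Q)
  }
  enabled <- match.arg(enabled, process_names(), several.ok = TRUE)
  if (is.character(initial)) {
    initial <- match.arg(initial, "uniform")
  } else {
    stopifnot(is.numeric(initial), length(initial) == Q + 1)
    validate_probs(initial, where = "initial distribution")
  }
  structure(
    list(
      Q = as.integer(Q), dt = dt, n_steps = as.integer(n_steps),
      initial = initial, enabled = enabled, params = params,
      seed = as.integer(seed), record_every = as.integer(record_every),
      record_snapshots = record_snapshots
    ),
    class = "simulation_config"
  )
}

#' Names of the five model processes
#'
#' @return Character vector of the process identifiers accepted by
#'   `simulation_config(enabled = ...)`.
#' @export
process_names <- function() {
  c("ff_metabolic", "ff_protein", "mb", "repair", "ec", "ed")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> Q = %d, dt = %g tu, %d steps, seed %d\n",
    x$Q, x$dt, x$n_steps, x$seed
  ))
  cat("  enabled:", paste(x$enabled, collapse = ", "), "\n")
  init <- if (is.character(x$initial)) x$initial else "custom vector"
  cat("  initial:", init, " record_every:", x$record_every, "\n")
  invisible(x)
}

initial_distribution <- function(config) {
  if (is.character(config$initial)) {
    uniform_distribution(config$Q)
  } else {
    quality_distribution(config$initial)
  }
}

#' One explicit Euler step of the master equation
#'
#' Advances the distribution by `dt`: the enabled deterministic operators
#' are evaluated at the step's start time (left-point rule), summed --
#' with the proteinaceous networking term weighted by `gamma` -- and added
#' as `P + dt * dP`; if external damage is enabled its stochastic map is
#' then applied to the updated probabilities. The result must pass the
#' integrity guard (no entry below `-1e-12`, total mass 1 to the 12th
#' decimal); a violation aborts with a diagnostic naming the offending
#' state and time rather than silently renormalising.
#'
#' @param P A [quality_distribution()] or probability vector over `0..Q`.
#' @param t Start time of the step in tu.
#' @param config A [simulation_config()] (its `Q` must match `P`).
#' @return The updated probability vector.
#' @export
euler_step <- function(P, t, config) {
  p <- as.numeric(P)
  stopifnot(length(p) == config$Q + 1L)
  ctx <- step_context(config)
  step_ctx(p, t, law_values(ctx, t), ctx)
}

## Evaluate all seven time laws at time(s) t; rows in the fixed order
## consumed by step_ctx.
law_values <- function(ctx, t) {
  vapply(ctx$laws, rho_of_t, numeric(length(t)), t = t)
}

## Precompute every (Q, params)-dependent quantity once per run.
step_context <- function(config) {
  params <- config$params
  Q <- config$Q
  en <- config$enabled
  list(
    Q = Q, dt = config$dt, gamma = params$gamma, f_rd = params$f_rd,
    laws = params[c("law_ffm", "law_ffp_fusion", "law_ffp_fission",
                    "law_mb", "law_rep", "law_ec", "law_ed")],
    do_ffm = "ff_metabolic" %in% en,
    do_ffp = "ff_protein" %in% en,
    do_mb = "mb" %in% en,
    do_rep = "repair" %in% en,
    do_ec = "ec" %in% en,
    do_ed = "ed" %in% en,
    ffm = ffm_context(Q, params),
    ffp = ffp_context(Q, params),
    binom = binom_context(Q),
    ed = ed_context(Q)
  )
}

## One Euler step given the pre-evaluated law values at the step's start
## time: rhos is the vector (ffm, ffp_fusion, ffp_fission, mb, rep, ec, ed).
step_ctx <- function(p, t, rhos, ctx) {
  dp <- 0
  if (ctx$do_ffm) {
    dp <- dp + dp_ffm_ctx(p, rhos[[1L]], ctx$ffm)
  }
  if (ctx$do_ffp) {
    dp <- dp + ctx$gamma * dp_ffp_ctx(p, rhos[[2L]], rhos[[3L]], ctx$ffp)
  }
  if (ctx$do_mb) {
    flux <- rhos[[4L]] * p[1L]
    v <- numeric(ctx$Q + 1L)
    v[1L] <- -flux
    v[ctx$Q + 1L] <- flux
    dp <- dp + v
  }
  if (ctx$do_rep) {
    K <- kernel_from_ctx(
      rhos[[5L]],
      ctx$binom$rep_choose, ctx$binom$rep_k, ctx$binom$rep_nk
    )
    dp <- dp + as.numeric(p %*% K) - p
  }
  if (ctx$do_ec) {
    K <- kernel_from_ctx(
      rhos[[6L]],
      ctx$binom$ec_choose, ctx$binom$ec_k, ctx$binom$ec_nk
    )
    dp <- dp + as.numeric(p %*% K) - p
  }
  p <- p + ctx$dt * dp
  if (ctx$do_ed) {
    p <- apply_ed_ctx(p, rhos[[7L]], ctx$f_rd, ctx$ed)
  }
  guard_step(p, t)
  p
}

guard_step <- function(p, t) {
  bad <- which(p < -1e-12)
  if (length(bad)) {
    stop(
      "integrity guard: probability of state q = ", bad[1L] - 1L,
      " fell to ", format(p[bad[1L]], digits = 15),
      " during the step starting at t = ", t, " tu"
    )
  }
  total <- sum(p)
  if (abs(total - 1) > 1e-12) {
    stop(
      "integrity guard: total probability mass ", format(total, digits = 17),
      " violates conservation to the 12th decimal at the step starting at t = ",
      t, " tu"
    )
  }
  invisible(p)
}

#' Run a simulation
#'
#' Integrates the master equation with explicit Euler steps from the
#' configured initial distribution, evaluating each process time law at
#' the start of every step and applying the stochastic external-damage
#' map after the deterministic update. The global RNG is seeded from
#' `config$seed` at the start, so identical configurations give
#' bit-identical trajectories.
#'
#' Metrics (average quality, deviation of quality, inactive fraction and
#' the conservation norm) are recorded at `t = 0`, after every
#' `record_every`-th step and at the final step.
#'
#' @param config A [simulation_config()].
#' @return An object of class `trajectory`: a list with
#'   \describe{
#'     \item{`metrics`}{`data.frame` with columns `t`, `qbar`, `sigma_q`,
#'       `p0`, `nprob`, one row per recorded time.}
#'     \item{`snapshots`}{long `data.frame` with columns `t`, `q`, `P`
#'       (or `NULL` when snapshots were not requested).}
#'     \item{`final`}{the final [quality_distribution()].}
#'     \item{`config`}{the configuration that produced the run.}
#'   }
#' @examples
#' traj <- run_simulation(simulation_config(
#'   enabled = "mb", n_steps = 1000, record_every = 100
#' ))
#' tail(traj$metrics)
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  ctx <- step_context(config)
  p <- as.numeric(initial_distribution(config))
  set.seed(config$seed)

  n <- config$n_steps
  rec <- config$record_every
  cadence <- if (rec <= n) seq.int(rec, n, by = rec) else integer(0)
  rec_steps <- unique(c(0L, cadence, n))
  nrec <- length(rec_steps)
  m <- matrix(NA_real_, nrec, 5L,
              dimnames = list(NULL, c("t", "qbar", "sigma_q", "p0", "nprob")))
  snaps <- if (config$record_snapshots) matrix(NA_real_, nrec, config$Q + 1L)
  q <- 0:config$Q

  record <- function(row, step, p) {
    tt <- step * config$dt
    qbar <- sum(q * p)
    m[row, ] <<- c(tt, qbar, sum(abs(q - qbar) * p), p[1L], sum(p))
    if (!is.null(snaps)) snaps[row, ] <<- p
  }

  # all seven law values for every step start time, evaluated in one go
  rho_tab <- law_values(ctx, (seq_len(n) - 1L) * config$dt)
  if (!is.matrix(rho_tab)) rho_tab <- matrix(rho_tab, nrow = 1L)

  row <- 1L
  record(row, 0L, p)
  for (step in seq_len(n)) {
    p <- step_ctx(p, (step - 1L) * config$dt, rho_tab[step, ], ctx)
    if (step %% rec == 0L || step == n) {
      row <- row + 1L
      record(row, step, p)
    }
  }

  snapshots <- NULL
  if (!is.null(snaps)) {
    snapshots <- data.frame(
      t = rep(m[, "t"], each = config$Q + 1L),
      q = rep(q, nrec),
      P = as.vector(t(snaps))
    )
  }
  structure(
    list(
      metrics = as.data.frame(m),
      snapshots = snapshots,
      final = quality_distribution(p),
      config = config
    ),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  n <- nrow(x$metrics)
  last <- x$metrics[n, ]
  cat(sprintf(
    "<trajectory> %d recorded points over %g tu (%s)\n",
    n, last$t, paste(x$config$enabled, collapse = ", ")
  ))
  cat(sprintf(
    "  final: qbar = %.4f, sigma_q = %.4f, P(0) = %.4f, N_prob = %.12f\n",
    last$qbar, last$sigma_q, last$p0, last$nprob
  ))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) x$metrics
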