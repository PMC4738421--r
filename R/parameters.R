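#' Free parameters of the mitochondrial quality model
#'
#' Collects every free parameter of the model: the balance constant between
#' metabolic and proteinaceous fission/fusion, the two Hill coefficients of
#' the networking rates, the probability fraction exchanged by an external
#' damage event, and one exponential time law per process. The defaults are
#' the reference parameter set used by all scenario presets; they were
#' estimated relative to each other (networking is about five times more
#' frequent than the slower turnover processes, and all other processes share
#' a common starting probability by indifference), so the model is suited to
#' qualitative comparison rather than absolute quantification.
#'
#' The proteinaceous fusion and fission laws share one starting probability
#' `rho0_ffp` and one lifetime `tau_ffp`: fusion decays
#' (\eqn{\rho_{0} e^{-t/\tau}}) while fission grows
#' (\eqn{\rho_{0} e^{+t/\tau}}), reflecting the age-related shift of the
#' networking balance towards fragmentation.
#'
#' @param gamma Balance constant weighting the proteinaceous relative to the
#'   metabolic fission/fusion term (dimensionless, >= 0).
#' @param ff1,ff2 Hill coefficients of the networking rates (> 0): `ff1` is
#'   the Hill exponent, `ff2` the half-saturation quality difference.
#' @param f_rd Fraction of probability mass moved by one external-damage
#'   event, in `[0, 1]`.
#' @param law_ffm Time law (decay) of metabolic "kiss-and-run"
#'   fission/fusion.
#' @param rho0_ffp,tau_ffp Starting probability and lifetime shared by the
#'   proteinaceous fusion (decay) and fission (growth) laws.
#' @param law_mb Time law (growth) of the coupled mitophagy/biogenesis
#'   recycling cycle.
#' @param law_rep Time law (decay) of the per-quality-unit repair
#'   probability.
#' @param law_ec Time law (growth) of the per-quality-unit loss probability
#'   from activity-dependent internal oxidative stress.
#' @param law_ed Time law (growth) of the external-damage event probability.
#' @return An object of class `model_parameters`. The proteinaceous pair is
#'   exposed as `law_ffp_fusion` and `law_ffp_fission`.
#' @examples
#' p <- model_parameters()                      # reference values
#' p$law_ffm
#' model_parameters(f_rd = 0.3, law_ec = process_law(0.05, 50000, "growth"))
#' @export
model_parameters <- function(gamma = 1,
                             ff1 = 2,
                             ff2 = 3,
                             f_rd = 0.03,
                             law_ffm = process_law(0.05, 50000, "decay"),
                             rho0_ffp = 0.05,
                             tau_ffp = 50000,
                             law_mb = process_law(0.01, 50000, "growth"),
                             law_rep = process_law(0.01, 50000, "decay"),
                             law_ec = process_law(0.01, 50000, "growth"),
                             law_ed = process_law(0.01, 50000, "growth")) {
  stopifnot(
    is.numeric(gamma), length(gamma) == 1L, gamma >= 0,
    is.numeric(ff1), ff1 > 0, is.numeric(ff2), ff2 > 0,
    is.numeric(f_rd), f_rd >= 0, f_rd <= 1
  )
  for (nm in c("law_ffm", "law_mb", "law_rep", "law_ec", "law_ed")) {
    if (!inherits(get(nm), "process_law")) {
      stop("'", nm, "' must be a process_law object")
    }
  }
  stopifnot(rho0_ffp >= 0, rho0_ffp <= 1, tau_ffp > 0)
  structure(
    list(
      gamma = gamma, ff1 = ff1, ff2 = ff2, f_rd = f_rd,
      law_ffm = law_ffm,
      law_ffp_fusion = process_law(rho0_ffp, tau_ffp, "decay"),
      law_ffp_fission = process_law(rho0_ffp, tau_ffp, "growth"),
      law_mb = law_mb, law_rep = law_rep, law_ec = law_ec, law_ed = law_ed
    ),
    class = "model_parameters"
  )
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("<model_parameters>\n")
  cat(sprintf("  gamma = %g, FF1 = %g, FF2 = %g, f_rd = %g\n",
              x$gamma, x$ff1, x$ff2, x$f_rd))
  for (nm in c("law_ffm", "law_ffp_fusion", "law_ffp_fission",
               "law_mb", "law_rep", "law_ec", "law_ed")) {
    cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}

#' Hill rate of a networking process
#'
#' Rate of a fission/fusion transition as a function of a quality
#' difference, modelled with Hill's equation for ligand binding:
#' \deqn{R(\Delta) = \frac{\Delta^{FF_1}}{FF_2^{FF_1} + \Delta^{FF_1}}.}
#' For metabolic and proteinaceous fusion the argument is the quality gap
#' \eqn{|q_1 - q_2|} between the partners (a larger gap makes the exchange
#' more valuable); for proteinaceous fission it is the distance \eqn{Q - q}
#' from the maximal quality (lower-quality mitochondria divide more readily).
#'
#' @param delta Non-negative quality difference(s).
#' @param ff1 Hill exponent.
#' @param ff2 Half-saturation constant: `hill_rate(ff2, ff1, ff2)` is 0.5.
#' @return Rate(s) in `[0, 1)`, monotone increasing in `delta`.
#' @examples
#' hill_rate(0:10, ff1 = 2, ff2 = 3)
#' @export
hill_rate <- function(delta, ff1 = 2, ff2 = 3) {
  stopifnot(is.numeric(delta), all(delta >= 0), ff1 > 0, ff2 > 0)
  dn <- delta^ff1
  dn / (ff2^ff1 + dn)
}
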