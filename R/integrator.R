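#' Integrator configuration
#'
#' @param dt forward-Euler step size.  The underlying rates are O(1), and a
#'   halving-dt convergence check is part of the test suite; 0.1 is the
#'   default working step.
#' @param t_end integration horizon of one ecological equilibration phase
#'   (default 1000 time units, long enough for allele frequencies to settle
#'   between evolutionary events).
#' @param clamp_threshold density below which a compartment is set to exactly
#'   zero at the *end* of an equilibration phase.  Deterministic ODEs never
#'   reach zero; clamping once per phase makes reported losses and exclusions
#'   complete without letting a decaying lineage be rescued later.
#' @param record_every sample the trajectory every this many time units
#'   (NULL = no trajectory).
#' @return an object of class `integrator_config`.
#' @export
integrator_config <- function(dt = 0.1, t_end = 1000,
                              clamp_threshold = 1e-9, record_every = NULL) {
  stopifnot(dt > 0, t_end >= dt, clamp_threshold >= 0)
  structure(list(dt = dt, t_end = t_end, clamp_threshold = clamp_threshold,
                 record_every = record_every), class = "integrator_config")
}

#' Single forward-Euler step (reference implementation)
#'
#' Pure-R reference path: `state + dt * derivatives(state)`, with any entry
#' driven below zero projected back to zero.  The production equilibration
#' loop runs the same scheme in compiled code; the two are tested against
#' each other step-for-step.
#'
#' @inheritParams derivatives
#' @param dt step size.
#' @return the advanced [system_state()].
#' @export
euler_step <- function(state, params, grid, dt) {
  stopifnot(dt > 0)
  d <- derivatives(state, params, grid)
  system_state(S = pmax(state$S + dt * d$S, 0),
               R = pmax(state$R + dt * d$R, 0),
               I_e = max(state$I_e + dt * d$I_e, 0),
               I_f = max(state$I_f + dt * d$I_f, 0),
               grid = grid)
}

#' Integrate to ecological equilibrium
#'
#' Runs `t_end / dt` forward-Euler steps in compiled code, then zeroes every
#' compartment below `clamp_threshold`.  If `config$record_every` is set, a
#' trajectory of compartment totals is attached as attribute `"trajectory"`
#' (columns: time, S_total, R_total, I_e, I_f).
#'
#' @inheritParams derivatives
#' @param config an [integrator_config()].
#' @return the equilibrated [system_state()].
#' @export
equilibrate <- function(state, params, grid, config = integrator_config()) {
  nsteps <- as.integer(round(config$t_end / config$dt))
  rec <- if (is.null(config$record_every)) 0L
         else as.integer(max(1, round(config$record_every / config$dt)))
  out <- clonal_euler_cpp(state$S, state$R, state$I_e, state$I_f,
                          grid$values,
                          cost_of_general_resistance(grid$values, params$theta),
                          params$b, params$mu, params$gamma,
                          params$beta_e, params$beta_f, params$r, params$c_r,
                          params$transmission_mode == "frequency",
                          config$dt, nsteps, rec)
  thr <- config$clamp_threshold
  res <- system_state(S = ifelse(out$S < thr, 0, out$S),
                      R = ifelse(out$R < thr, 0, out$R),
                      I_e = if (out$I_e < thr) 0 else out$I_e,
                      I_f = if (out$I_f < thr) 0 else out$I_f,
                      grid = grid)
  if (rec > 0L) {
    traj <- out$trajectory
    colnames(traj) <- c("time", "S_total", "R_total", "I_e", "I_f")
    attr(res, "trajectory") <- traj
  }
  res
}
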