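#' Grid of general-resistance strengths
#'
#' General resistance q is modelled as a continuous trait discretised on a
#' uniform grid over \[0, 1\] (default step 0.01, i.e. 101 bins).  Every
#' uninfected compartment vector in the model is indexed by this grid.
#'
#' @param step grid spacing; must divide 1 exactly (up to floating error).
#' @return an object of class `q_grid` with fields `values` (strictly
#'   increasing, from 0 to 1) and `n` (number of bins).
#' @examples
#' g <- q_grid()
#' g$n            # 101
#' g$values[42]   # 0.41
#' @export
q_grid <- function(step = 0.01) {
  stopifnot(is.numeric(step), length(step) == 1, step > 0, step <= 1)
  n <- round(1 / step) + 1L
  if (abs((n - 1L) * step - 1) > 1e-9)
    stop("grid step must divide the interval [0, 1] exactly")
  structure(list(values = seq(0, 1, length.out = n), n = n), class = "q_grid")
}

#' Model parameters
#'
#' Bundles the demographic, transmission and resistance parameters of the SI
#' model.  Defaults are the standing parameter set used throughout the
#' analyses: b = 1.5, mu = 0.2, gamma = 0.01, beta_e = 1, theta = 0.5, with
#' no specific resistance and no foreign pathogen.
#'
#' @param b per-capita birth rate of uninfected hosts.
#' @param mu per-capita mortality rate (all hosts, infected or not).
#' @param gamma coefficient of density-dependent population regulation.
#' @param beta_e transmission rate of the endemic pathogen.
#' @param beta_f transmission rate of the foreign pathogen.
#' @param r strength of specific resistance in \[0, 1\]; the R allele
#'   multiplies endemic transmission by (1 - r) and has no effect on the
#'   foreign pathogen.
#' @param c_r fecundity cost of carrying the R allele, in \[0, 1\].
#' @param theta curvature of the general-resistance cost function
#'   c(q) = 1 - (1 - q)^theta; theta < 1 gives accelerating costs.
#' @param transmission_mode `"frequency"` (infection pressure scales with
#'   I/N, the pollinator-borne case) or `"density"` (scales with I).
#' @return an object of class `model_params`.
#' @details The standing biological assumption is beta_e >= beta_f (a newly
#'   host-shifted pathogen is maladapted); violating it only raises a
#'   warning so that threshold-finding sweeps can cross the boundary.
#' @export
model_params <- function(b = 1.5, mu = 0.2, gamma = 0.01,
                         beta_e = 1, beta_f = 0,
                         r = 0, c_r = 0, theta = 0.5,
                         transmission_mode = c("frequency", "density")) {
  transmission_mode <- match.arg(transmission_mode)
  for (nm in c("b", "mu", "gamma", "beta_e", "beta_f", "r", "c_r", "theta")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
  }
  if (min(b, mu, gamma, beta_e, beta_f) < 0)
    stop("rates must be non-negative")
  if (r < 0 || r > 1) stop("'r' must lie in [0, 1]")
  if (c_r < 0 || c_r > 1) stop("'c_r' must lie in [0, 1]")
  if (theta <= 0) stop("'theta' must be positive")
  if (beta_f > beta_e)
    warning("beta_f > beta_e: foreign pathogen more transmissible than endemic")
  structure(list(b = b, mu = mu, gamma = gamma, beta_e = beta_e,
                 beta_f = beta_f, r = r, c_r = c_r, theta = theta,
                 transmission_mode = transmission_mode),
            class = "model_params")
}

#' System state of the clonal model
#'
#' Densities of uninfected hosts without (`S`) and with (`R`) the specific
#' resistance allele, indexed by the general-resistance grid, plus the two
#' infected pools.
#'
#' @param S,R numeric vectors of length `grid$n` (scalars are recycled into
#'   a vector with all mass at q = 0 when `at` is not given).
#' @param I_e,I_f densities infected by the endemic / foreign pathogen.
#' @param grid a [q_grid()].
#' @return an object of class `system_state`.
#' @export
system_state <- function(S = 0, R = 0, I_e = 0, I_f = 0, grid = q_grid()) {
  expand <- function(v) {
    if (length(v) == 1) v <- c(v, rep(0, grid$n - 1L))
    if (length(v) != grid$n) stop("host vector length must equal grid$n")
    v
  }
  S <- expand(S); R <- expand(R)
  if (any(S < 0) || any(R < 0) || I_e < 0 || I_f < 0)
    stop("state densities must be non-negative")
  structure(list(S = S, R = R, I_e = I_e, I_f = I_f), class = "system_state")
}

#' Fecundity cost of general resistance
#'
#' The cost of expressing general resistance at strength q is
#' c(q) = 1 - (1 - q)^theta.  theta < 1 makes costs accelerating (steep near
#' q = 0), theta > 1 decelerating.
#'
#' @param q resistance strength(s) in \[0, 1\]; vectorised.
#' @param theta positive cost-curve exponent.
#' @return cost(s) in \[0, 1\], monotone non-decreasing in q.
#' @examples
#' cost_of_general_resistance(0.41, theta = 0.5)  # ~0.2319
#' @export
cost_of_general_resistance <- function(q, theta) {
  if (!is.numeric(q) || any(q < 0 | q > 1)) stop("'q' must lie in [0, 1]")
  if (!is.numeric(theta) || length(theta) != 1 || theta <= 0)
    stop("'theta' must be a single positive number")
  1 - (1 - q)^theta
}

#' Total population density
#'
#' N = sum(S) + sum(R) + I_e + I_f.  Infected hosts count towards N: they
#' die at rate mu and occupy density-regulated space even though they are
#' sterile.
#'
#' @param state a [system_state()].
#' @return total density (scalar).
#' @export
total_population <- function(state) {
  sum(state$S) + sum(state$R) + state$I_e + state$I_f
}

#' Right-hand side of the ecological ODE system
#'
#' Evaluates the time derivative of every compartment:
#' \deqn{dS_i/dt = S_i (b - c(q_i) - \mu - \gamma N - (1-q_i)(\beta_e I_e + \beta_f I_f)/N)}
#' \deqn{dR_i/dt = R_i (b - c(q_i) - c_r - \mu - \gamma N - (1-q_i)((1-r)\beta_e I_e + \beta_f I_f)/N)}
#' \deqn{dI_e/dt = I_e (\sum_i \beta_e (1-q_i)(S_i + (1-r)R_i)/N - \mu)}
#' \deqn{dI_f/dt = I_f (\sum_i \beta_f (1-q_i)(S_i + R_i)/N - \mu)}
#' In density-dependent mode the 1/N inside every transmission term is
#' dropped.  Infected hosts are sterile (no birth term) and costs act on the
#' uninfected growth term only.  General and specific resistance combine
#' multiplicatively on transmission, their costs additively.
#'
#' @param state a [system_state()].
#' @param params a [model_params()].
#' @param grid the [q_grid()] indexing the host vectors.
#' @return an object of class `state_derivative` with the same shape as the
#'   state.  An identically-zero state returns a zero derivative.
#' @export
derivatives <- function(state, params, grid) {
  N <- total_population(state)
  if (N <= 0) {
    return(structure(list(S = numeric(grid$n), R = numeric(grid$n),
                          I_e = 0, I_f = 0), class = "state_derivative"))
  }
  Nd <- if (params$transmission_mode == "frequency") N else 1
  q <- grid$values
  cq <- cost_of_general_resistance(q, params$theta)
  oq <- 1 - q

  press_S <- (params$beta_e * state$I_e + params$beta_f * state$I_f) / Nd
  press_R <- ((1 - params$r) * params$beta_e * state$I_e +
                params$beta_f * state$I_f) / Nd

  dS <- state$S * (params$b - cq - params$mu - params$gamma * N - oq * press_S)
  dR <- state$R * (params$b - cq - params$c_r - params$mu - params$gamma * N -
                     oq * press_R)
  dIe <- state$I_e *
    (sum(params$beta_e * oq * (state$S + (1 - params$r) * state$R)) / Nd -
       params$mu)
  dIf <- state$I_f *
    (sum(params$beta_f * oq * (state$S + state$R)) / Nd - params$mu)

  d <- list(S = dS, R = dR, I_e = dIe, I_f = dIf)
  if (!all(vapply(d, function(x) all(is.finite(x)), logical(1))))
    stop("non-finite derivative encountered")
  structure(d, class = "state_derivative")
}

#' Monomorphic disease-free equilibrium density
#'
#' For a single uninfected genotype at resistance q the host equation has
#' the stable equilibrium N* = (b - c(q) - mu) / gamma.
#'
#' @param params a [model_params()].
#' @param q resistance strength of the monomorphic host.
#' @return equilibrium density.  Errors (class `coresist_nonviable`) if the
#'   net growth rate b - c(q) - mu is not positive.
#' @export
disease_free_equilibrium <- function(params, q = 0) {
  growth <- params$b - cost_of_general_resistance(q, params$theta) - params$mu
  if (growth <= 0) {
    stop(structure(class = c("coresist_nonviable", "error", "condition"),
                   list(message = sprintf(
                     "host not viable at q=%g: b - c(q) - mu = %g <= 0",
                     q, growth), call = sys.call(-1))))
  }
  growth / params$gamma
}
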