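#' Basic reproduction number
#'
#' For a sterilizing pathogen with frequency-dependent transmission, no
#' recovery and no added mortality, R0 = beta / mu; the pathogen spreads in
#' a wholly susceptible population iff R0 > 1.
#'
#' @param beta effective transmission rate.
#' @param mu host mortality rate (> 0).
#' @return R0.
#' @export
basic_reproduction_number <- function(beta, mu) {
  if (!is.numeric(mu) || any(mu <= 0)) stop("'mu' must be positive")
  if (any(beta < 0)) stop("'beta' must be non-negative")
  beta / mu
}

#' Minimum foreign transmission rate permitting invasion
#'
#' General resistance reduces the foreign pathogen's effective transmission
#' to beta_f (1 - q), so invasion requires beta_f (1 - q) > mu; the
#' threshold is mu / (1 - q).  At q = 0 and mu = 0.2 this is 0.2; at the
#' evolved general resistance q = 0.41 it rises to ~0.339.
#'
#' @param q general-resistance strength of the resident hosts, in \[0, 1).
#' @param mu host mortality rate (> 0).
#' @return threshold value of beta_f.  Errors (class
#'   `coresist_no_threshold`) at q = 1, where no finite transmission rate
#'   allows invasion.
#' @export
foreign_invasion_threshold <- function(q, mu) {
  if (!is.numeric(mu) || any(mu <= 0)) stop("'mu' must be positive")
  if (!is.numeric(q) || any(q < 0 | q > 1)) stop("'q' must lie in [0, 1]")
  if (any(q == 1)) {
    stop(structure(class = c("coresist_no_threshold", "error", "condition"),
                   list(message = "q = 1: no finite invasion threshold",
                        call = sys.call(-1))))
  }
  mu / (1 - q)
}

#' Minimum specific-resistance strength permitting foreign persistence
#'
#' Specific resistance shields R hosts from the endemic pathogen only, so
#' the foreign pathogen can persist alongside a more transmissible endemic
#' competitor only if beta_f > (1 - r) beta_e, i.e. r > 1 - beta_f/beta_e.
#'
#' @param beta_e endemic transmission rate (> 0).
#' @param beta_f foreign transmission rate (> 0).
#' @return the critical r; 0 when beta_f >= beta_e (condition holds for all
#'   r).
#' @export
foreign_persistence_min_r <- function(beta_e, beta_f) {
  if (!is.numeric(beta_e) || any(beta_e <= 0)) stop("'beta_e' must be positive")
  if (!is.numeric(beta_f) || any(beta_f <= 0)) stop("'beta_f' must be positive")
  pmax(0, 1 - beta_f / beta_e)
}

#' Closed-form endemic equilibrium prevalence
#'
#' For a monomorphic host at resistance q with only the endemic pathogen,
#' dI_e/dt = 0 gives an uninfected fraction mu / (beta (1 - q)), i.e. an
#' equilibrium prevalence 1 - mu / (beta (1 - q)) whenever the pathogen is
#' above threshold (0 otherwise).
#'
#' @param q host general-resistance strength.
#' @param beta pathogen transmission rate.
#' @param mu host mortality.
#' @return equilibrium infected fraction I / N.
#' @export
endemic_prevalence <- function(q, beta, mu) {
  pmax(0, 1 - mu / (beta * (1 - q)))
}

#' Selection gradient on general resistance (closed form)
#'
#' Invasion fitness of a rare mutant at q_m in a monomorphic resident
#' population at q (endemic pathogen only, frequency-dependent) is
#' s(q_m) = b - c(q_m) - mu - gamma N* - (1 - q_m) beta_e I*/N*, where the
#' resident equilibrium prevalence I*/N* = 1 - mu/(beta_e (1 - q)) follows
#' from dI_e/dt = 0.  Differentiating at q_m = q gives the local gradient
#' g(q) = -c'(q) + beta_e (1 - mu / (beta_e (1 - q))).
#'
#' This is algebra only — it never touches the grid simulation or the
#' integrator — and serves as the independent oracle for the evolved
#' singular strategy.
#'
#' @param q resident resistance strength.
#' @param params a [model_params()] (uses beta_e, mu, theta).
#' @return the selection gradient (positive = selection for more
#'   resistance).
#' @export
selection_gradient <- function(q, params) {
  prev <- endemic_prevalence(q, params$beta_e, params$mu)
  -params$theta * (1 - q)^(params$theta - 1) + params$beta_e * prev
}

#' Singular strategy of general resistance (bisection oracle)
#'
#' Finds the root of [selection_gradient()] by bisection.  With
#' accelerating costs (theta < 1) the gradient is decreasing through the
#' root, making the singular point a convergence-stable attractor.
#'
#' @param params a [model_params()].
#' @param lower,upper bracketing interval.
#' @param tol bisection tolerance on q.
#' @return the singular resistance strength q*; 0 if the gradient is
#'   negative everywhere (resistance never pays).
#' @export
singular_strategy <- function(params, lower = 0, upper = 1 - 1e-6,
                              tol = 1e-6) {
  g_lo <- selection_gradient(lower, params)
  if (g_lo <= 0) return(lower)
  g_hi <- selection_gradient(upper, params)
  if (g_hi >= 0) return(upper)
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (selection_gradient(mid, params) > 0) lower <- mid else upper <- mid
  }
  (lower + upper) / 2
}

#' Invasion analytics bundle
#'
#' Convenience wrapper returning the basic reproduction number of the
#' foreign pathogen against fully susceptible hosts, the invasion threshold
#' at the given q, and the minimum r permitting persistence against the
#' endemic pathogen.
#'
#' @param params a [model_params()].
#' @param q resident general-resistance strength.
#' @return a list of class `invasion_report` with fields `R0`,
#'   `beta_f_threshold`, `r_min`.
#' @export
invasion_report <- function(params, q = 0) {
  structure(list(
    R0 = basic_reproduction_number(params$beta_f * (1 - q), params$mu),
    beta_f_threshold = foreign_invasion_threshold(q, params$mu),
    r_min = if (params$beta_f > 0)
      foreign_persistence_min_r(params$beta_e, params$beta_f) else NA_real_),
    class = "invasion_report")
}
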