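GENOTYPES <- c("QpS", "QpR", "QmS", "QmR")

#' Parameters of the two-locus recombination model
#'
#' The continuous general-resistance trait is collapsed to two alleles:
#' Q+ at strength `q_plus` (the strength evolved in the S background) and
#' Q- at strength `q_minus` (typically 0, the strength evolved in the R
#' background), giving four haploid genotypes Q+S, Q+R, Q-S, Q-R.
#' Recombination between the Q and R loci occurs at rate `p`.
#'
#' @param p recombination rate in \[0, 1\].
#' @param q_plus,q_minus general-resistance strengths of the two Q alleles,
#'   with 0 <= q_minus <= q_plus <= 1.  `q_plus` may take any value in
#'   \[0, 1\], not just grid values.
#' @param params a [model_params()] supplying the demographic, transmission
#'   and specific-resistance parameters.
#' @return an object of class `recomb_params`.
#' @export
recomb_params <- function(p, q_plus, q_minus = 0, params = model_params()) {
  stopifnot(is.numeric(p), length(p) == 1, p >= 0, p <= 1)
  if (!(q_minus >= 0 && q_minus <= q_plus && q_plus <= 1))
    stop("need 0 <= q_minus <= q_plus <= 1")
  structure(c(list(p = p, q_plus = q_plus, q_minus = q_minus), params),
            class = "recomb_params")
}

#' Four-genotype state
#'
#' @param QpS,QpR,QmS,QmR uninfected genotype densities.
#' @param I_e,I_f infected pool densities.
#' @return an object of class `four_genotype_state` holding `U` (named
#'   length-4 vector, order Q+S, Q+R, Q-S, Q-R) and the infected pools.
#' @export
four_genotype_state <- function(QpS = 0, QpR = 0, QmS = 0, QmR = 0,
                                I_e = 0, I_f = 0) {
  U <- c(QpS = QpS, QpR = QpR, QmS = QmS, QmR = QmR)
  if (any(U < 0) || I_e < 0 || I_f < 0) stop("densities must be non-negative")
  names(U) <- GENOTYPES
  structure(list(U = U, I_e = I_e, I_f = I_f), class = "four_genotype_state")
}

geno_traits <- function(rp) {
  list(q = c(rp$q_plus, rp$q_plus, rp$q_minus, rp$q_minus),
       isR = c(FALSE, TRUE, FALSE, TRUE))
}

geno_costs <- function(rp) {
  tr <- geno_traits(rp)
  cost_of_general_resistance(tr$q, rp$theta) + rp$c_r * tr$isR
}

#' Build the mating matrix
#'
#' For mother m and father f the offspring is the maternal genotype with
#' probability 1 - p; with probability p it is a recombinant carrying the
#' mother's allele at one locus and the father's at the other, each of the
#' two recombinant phases with probability p/2.  Every row sums to 1, and
#' at p = 0 the offspring is always maternal, which makes the recombination
#' model collapse exactly onto the clonal adaptive-dynamics model.
#'
#' @param p recombination rate in \[0, 1\].
#' @return a 16 x 4 matrix; row `4 (m - 1) + f` is the offspring-genotype
#'   distribution for mother m and father f (genotype order Q+S, Q+R, Q-S,
#'   Q-R).
#' @export
build_mating_matrix <- function(p) {
  stopifnot(p >= 0, p <= 1)
  Qa <- c(1, 1, 0, 0)  # 1 = Q+
  Ra <- c(0, 1, 0, 1)  # 1 = R
  idx <- function(Q, R) (1 - Q) * 2 + R + 1
  M <- matrix(0, 16, 4,
              dimnames = list(
                paste(rep(GENOTYPES, each = 4), rep(GENOTYPES, 4), sep = "x"),
                GENOTYPES))
  for (m in 1:4) {
    for (f in 1:4) {
      row <- 4 * (m - 1) + f
      M[row, m] <- M[row, m] + (1 - p)
      r1 <- idx(Qa[m], Ra[f])  # maternal Q, paternal R locus
      r2 <- idx(Qa[f], Ra[m])  # paternal Q, maternal R locus
      M[row, r1] <- M[row, r1] + p / 2
      M[row, r2] <- M[row, r2] + p / 2
    }
  }
  M
}

#' Right-hand side of the four-genotype model (reference implementation)
#'
#' Births of genotype g sum `(b - cost(mother)) * U_m * (U_f / U_tot)` over
#' all parent pairs weighted by the mating matrix; costs (additive:
#' c(q allele) + c_r for R carriers) act on maternal fecundity, fathers are
#' drawn proportional to uninfected genotype frequencies (infected plants
#' are sterile on both sides), and all loss and infection terms match the
#' clonal model with each genotype's (1 - q, r) profile.
#'
#' @param state a [four_genotype_state()].
#' @param rp a [recomb_params()].
#' @return list with fields `U`, `I_e`, `I_f` holding the derivatives.
#' @export
recomb_derivatives <- function(state, rp) {
  U <- state$U
  Ut <- sum(U)
  N <- Ut + state$I_e + state$I_f
  if (N <= 0)
    return(list(U = U * 0, I_e = 0, I_f = 0))
  if (Ut <= 0)
    stop("no uninfected hosts but population positive: mating undefined")
  Nd <- if (rp$transmission_mode == "frequency") N else 1

  tr <- geno_traits(rp)
  cost <- geno_costs(rp)
  M <- build_mating_matrix(rp$p)

  B <- numeric(4)
  for (m in 1:4) {
    for (f in 1:4) {
      w <- (rp$b - cost[m]) * U[m] * U[f] / Ut
      B <- B + w * M[4 * (m - 1) + f, ]
    }
  }

  oq <- 1 - tr$q
  spec <- ifelse(tr$isR, 1 - rp$r, 1)
  dU <- B - U * (rp$mu + rp$gamma * N) -
    U * oq * (spec * rp$beta_e * state$I_e + rp$beta_f * state$I_f) / Nd
  dIe <- state$I_e * (sum(rp$beta_e * oq * spec * U) / Nd - rp$mu)
  dIf <- state$I_f * (sum(rp$beta_f * oq * U) / Nd - rp$mu)
  list(U = dU, I_e = dIe, I_f = dIf)
}

#' Default initial state for the recombination runs
#'
#' The recombination experiments start from the equilibrium reached by the
#' clonal (no-recombination) dynamics: Q+S and Q-R seeded at density 1
#' together with both pathogens, integrated with p = 0 for one
#' equilibration horizon.  The recombinant genotypes Q+R and Q-S are absent
#' at the start and can only be created by recombination.
#'
#' @param rp a [recomb_params()].
#' @param config an [integrator_config()].
#' @return a [four_genotype_state()].
#' @export
default_recomb_init <- function(rp, config = integrator_config()) {
  st <- four_genotype_state(QpS = 1, QmR = 1, I_e = 1, I_f = 1)
  rp0 <- rp; rp0$p <- 0
  run_recombination(rp0, config = config, t_end = config$t_end,
                    state0 = st, record_every = NULL)$final_state
}

#' Integrate the four-genotype recombination model
#'
#' Forward-Euler integration (compiled core) of the two-locus system,
#' recording the six densities and the linkage disequilibrium
#' D = x(Q+S) x(Q-R) - x(Q+R) x(Q-S) over uninfected frequencies through
#' time, and classifying which genotypes persist above the clamp threshold
#' at the end.
#'
#' @param rp a [recomb_params()].
#' @param config an [integrator_config()] (dt and clamp threshold are taken
#'   from here).
#' @param t_end integration horizon for this run (defaults to 20x the
#'   equilibration horizon — long enough for the slow allele-frequency
#'   dynamics driven by rare recombinants to play out).
#' @param state0 initial [four_genotype_state()]; default
#'   [default_recomb_init()].
#' @param record_every trajectory sampling stride in time units (NULL = no
#'   trajectory, only the final state).
#' @return list of class `recomb_run` with `trajectory` (data frame: time,
#'   four genotype densities, I_e, I_f, D), `final_state`, `persisting`
#'   (character vector of genotype names), and `rp`.
#' @export
run_recombination <- function(rp, config = integrator_config(),
                              t_end = 20 * config$t_end,
                              state0 = NULL, record_every = 1) {
  if (is.null(state0)) state0 <- default_recomb_init(rp, config)
  tr <- geno_traits(rp)
  nsteps <- as.integer(round(t_end / config$dt))
  rec <- if (is.null(record_every)) 0L
         else as.integer(max(1, round(record_every / config$dt)))
  out <- recomb_euler_cpp(unname(state0$U), state0$I_e, state0$I_f,
                          tr$q, tr$isR, geno_costs(rp),
                          build_mating_matrix(rp$p),
                          rp$b, rp$mu, rp$gamma, rp$beta_e, rp$beta_f, rp$r,
                          rp$transmission_mode == "frequency",
                          config$dt, nsteps, rec)
  thr <- config$clamp_threshold
  U <- ifelse(out$U < thr, 0, out$U)
  names(U) <- GENOTYPES
  final <- four_genotype_state(U[1], U[2], U[3], U[4],
                               if (out$I_e < thr) 0 else out$I_e,
                               if (out$I_f < thr) 0 else out$I_f)

  traj <- NULL
  if (rec > 0L) {
    m <- out$trajectory
    colnames(m) <- c("time", GENOTYPES, "I_e", "I_f")
    traj <- as.data.frame(m)
    Ut <- traj$QpS + traj$QpR + traj$QmS + traj$QmR
    traj$D <- ifelse(Ut > 0,
                     (traj$QpS * traj$QmR - traj$QpR * traj$QmS) / Ut^2,
                     NA_real_)
  }
  structure(list(trajectory = traj, final_state = final,
                 persisting = GENOTYPES[U > 0], rp = rp),
            class = "recomb_run")
}
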