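#' Schedule of evolutionary events
#'
#' Controls when the specific-resistance allele R and the foreign pathogen
#' are seeded into the adaptive-dynamics run, and how many mutation
#' iterations are executed in total.
#'
#' Introduction indices count *completed* mutation iterations: the default
#' two-pathogen protocol seeds R after 50 iterations (once general
#' resistance has settled in the S background) and the foreign pathogen
#' after 100, then runs to 150.  Use `"start"` (= 0) to seed before the
#' first iteration and `"never"` to omit an introduction.
#'
#' @param introduce_R_at iterations completed before R is seeded at density
#'   1 (`"start"`, `"never"`, or an integer in \[0, total_iterations\]).
#' @param introduce_If_at iterations completed before the foreign pathogen
#'   is seeded at density 1.
#' @param total_iterations number of mutation iterations (<= 150 in the
#'   standard protocol).
#' @param freeze_general_until iteration index before which mutation of q is
#'   suppressed; supports the "specific resistance evolves first" variant
#'   (ecology still runs, the q distribution just cannot move).
#' @param R_intro_q resistance strength at which the R allele is seeded.
#'   By default R arrives without general resistance (q = 0): it is a new
#'   allele at low frequency, not a recombinant of the evolved S background.
#' @param intro_density density at which R / I_f are seeded (default 1).
#' @return an object of class `event_schedule`.
#' @export
event_schedule <- function(introduce_R_at = "never", introduce_If_at = "never",
                           total_iterations = 100, freeze_general_until = 0,
                           R_intro_q = 0, intro_density = 1) {
  norm <- function(x, nm) {
    if (identical(x, "never")) return(Inf)
    if (identical(x, "start")) return(0)
    if (!is.numeric(x) || length(x) != 1 || x < 0 ||
        (is.finite(x) && x > total_iterations))
      stop("'", nm, "' must be 'never', 'start', or an index in [0, ",
           total_iterations, "]")
    x
  }
  stopifnot(total_iterations >= 1, freeze_general_until >= 0,
            R_intro_q >= 0, R_intro_q <= 1, intro_density > 0)
  structure(list(introduce_R_at = norm(introduce_R_at, "introduce_R_at"),
                 introduce_If_at = norm(introduce_If_at, "introduce_If_at"),
                 total_iterations = as.integer(total_iterations),
                 freeze_general_until = freeze_general_until,
                 R_intro_q = R_intro_q, intro_density = intro_density),
            class = "event_schedule")
}

#' Mutation step of the adaptive-dynamics loop
#'
#' Transfers a fraction (default 5%) of the density in every occupied q bin
#' to the adjacent bins, independently in the S and R backgrounds.  Interior
#' bins split the moved mass equally between their two neighbours; the
#' boundary bins (q = 0 and q = 1) send all of it to their single
#' neighbour.  Total density per background is conserved exactly.
#'
#' @param state a [system_state()].
#' @param grid the [q_grid()].
#' @param fraction mutated fraction per bin, in \[0, 1\].
#' @return the mutated [system_state()] (infected pools untouched).
#' @export
mutate_state <- function(state, grid, fraction = 0.05) {
  stopifnot(fraction >= 0, fraction <= 1)
  n <- grid$n
  spread <- function(v) {
    moved <- fraction * v
    out <- v - moved
    if (n == 1) return(v)
    # boundary bins: everything to the single neighbour
    out[2] <- out[2] + moved[1]
    out[n - 1] <- out[n - 1] + moved[n]
    if (n > 2) {
      mid <- moved[2:(n - 1)] / 2
      out[1:(n - 2)] <- out[1:(n - 2)] + mid
      out[3:n] <- out[3:n] + mid
    }
    out
  }
  system_state(S = spread(state$S), R = spread(state$R),
               I_e = state$I_e, I_f = state$I_f, grid = grid)
}

q_summary <- function(v, grid) {
  tot <- sum(v)
  if (tot <= 0) return(c(mean = NA_real_, mode = NA_real_))
  c(mean = sum(v * grid$values) / tot,
    mode = grid$values[which.max(v)])
}

#' Run the adaptive-dynamics evolutionary loop
#'
#' Starts from a single S host at q = 0 plus one endemic-infected individual
#' and iterates: equilibrate the ecology to `t_end`, record the equilibrium,
#' mutate 5% of each occupied q bin to adjacent bins.  The R allele and the
#' foreign pathogen are seeded according to `schedule`.  The run terminates
#' early with an extinction flag if all uninfected hosts fall below the
#' clamp threshold.
#'
#' @param params a [model_params()].
#' @param grid a [q_grid()].
#' @param schedule an [event_schedule()].
#' @param config an [integrator_config()].
#' @param mutation_fraction fraction moved per bin and iteration.
#' @param init optional initial [system_state()] overriding the standard
#'   single-S, single-I_e start.
#' @return an object of class `evolution_trace`: `$summary` is a per-
#'   iteration data frame of compartment totals and q summaries, `$S_dist` /
#'   `$R_dist` hold the full post-equilibration q distributions (one row per
#'   iteration), `$final_state` the last equilibrium, `$hosts_extinct` the
#'   extinction flag.
#' @export
run_evolution <- function(params, grid = q_grid(),
                          schedule = event_schedule(),
                          config = integrator_config(),
                          mutation_fraction = 0.05,
                          init = NULL) {
  state <- if (is.null(init)) {
    system_state(S = 1, I_e = 1, grid = grid)
  } else init

  n_it <- schedule$total_iterations
  S_dist <- matrix(0, n_it, grid$n)
  R_dist <- matrix(0, n_it, grid$n)
  summ <- data.frame(iteration = seq_len(n_it), S_total = NA_real_,
                     R_total = NA_real_, I_e = NA_real_, I_f = NA_real_,
                     q_S_mean = NA_real_, q_S_mode = NA_real_,
                     q_R_mean = NA_real_, q_R_mode = NA_real_)
  extinct <- FALSE
  done <- 0L

  for (i in seq_len(n_it)) {
    if (schedule$introduce_R_at == i - 1) {
      Rv <- state$R
      bin <- which.min(abs(grid$values - schedule$R_intro_q))
      Rv[bin] <- Rv[bin] + schedule$intro_density
      state <- system_state(S = state$S, R = Rv, I_e = state$I_e,
                            I_f = state$I_f, grid = grid)
    }
    if (schedule$introduce_If_at == i - 1) {
      state <- system_state(S = state$S, R = state$R, I_e = state$I_e,
                            I_f = state$I_f + schedule$intro_density,
                            grid = grid)
    }

    state <- equilibrate(state, params, grid, config)

    S_dist[i, ] <- state$S
    R_dist[i, ] <- state$R
    qs <- q_summary(state$S, grid); qr <- q_summary(state$R, grid)
    summ[i, 2:9] <- c(sum(state$S), sum(state$R), state$I_e, state$I_f,
                      qs["mean"], qs["mode"], qr["mean"], qr["mode"])
    done <- i

    if (sum(state$S) + sum(state$R) < config$clamp_threshold) {
      extinct <- TRUE
      break
    }
    if (i > schedule$freeze_general_until && mutation_fraction > 0) {
      state <- mutate_state(state, grid, mutation_fraction)
    }
  }

  structure(list(summary = summ[seq_len(done), , drop = FALSE],
                 S_dist = S_dist[seq_len(done), , drop = FALSE],
                 R_dist = R_dist[seq_len(done), , drop = FALSE],
                 final_state = state, hosts_extinct = extinct,
                 params = params, grid = grid, schedule = schedule,
                 config = config),
            class = "evolution_trace")
}

#' Classify the end state of a run as stable or cyclic
#'
#' Looks at the last ten mutation iterations; if the variation (max - min)
#' of each of the four compartment totals (sum S, sum R, I_e, I_f) is below
#' 0.001, the end state is stable, otherwise cyclic.
#'
#' @param trace an [run_evolution()] trace with at least 10 iterations.
#' @param tol variation threshold (default 0.001).
#' @return `"stable"` or `"cyclic"`.
#' @export
classify_stability <- function(trace, tol = 0.001) {
  s <- trace$summary
  if (nrow(s) < 10) stop("stability test needs at least 10 iterations")
  tail10 <- s[(nrow(s) - 9):nrow(s), c("S_total", "R_total", "I_e", "I_f")]
  variation <- vapply(tail10, function(x) diff(range(x)), numeric(1))
  if (all(variation < tol)) "stable" else "cyclic"
}

#' Summarise the outcome of an evolutionary run
#'
#' Classifies the fate of the specific-resistance allele from its final
#' frequency among uninfected hosts (below `eps` = lost/S fixed, above
#' 1 - eps = R fixed, otherwise polymorphism), reports the evolved general
#' resistance per background (density-weighted mean and modal bin), pathogen
#' persistence, and stability.
#'
#' @param trace an [run_evolution()] trace.
#' @param eps fixation/loss tolerance on the R frequency (default 0.01 —
#'   well above the clamp threshold, well below any reported polymorphism).
#' @return an object of class `outcome_record`.
#' @export
summarize_outcome <- function(trace, eps = 0.01) {
  st <- trace$final_state
  uninf <- sum(st$S) + sum(st$R)
  if (trace$hosts_extinct || uninf <= 0) {
    fate <- "hosts_extinct"
    fR <- NA_real_
  } else {
    fR <- sum(st$R) / uninf
    fate <- if (fR < eps) "S_fixed" else if (fR > 1 - eps) "R_fixed"
            else "polymorphism"
  }
  qs <- q_summary(st$S, trace$grid); qr <- q_summary(st$R, trace$grid)
  stab <- if (nrow(trace$summary) >= 10) classify_stability(trace)
          else NA_character_
  structure(list(specific_fate = fate, R_freq = fR,
                 q_S_mean = qs[["mean"]], q_S_mode = qs[["mode"]],
                 q_R_mean = qr[["mean"]], q_R_mode = qr[["mode"]],
                 endemic_persists = st$I_e > 0,
                 foreign_persists = st$I_f > 0,
                 stability = stab),
            class = "outcome_record")
}
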