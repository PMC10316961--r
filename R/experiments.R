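#' Two-axis parameter sweep specification
#'
#' @param axis1_name,axis2_name names of [model_params()] arguments to vary
#'   (e.g. `"r"`, `"c_r"`, `"beta_f"`); axis1 is the outer loop.
#' @param axis1_values,axis2_values non-empty numeric vectors of axis
#'   values.
#' @param schedule the [event_schedule()] applied in every cell.
#' @return an object of class `sweep_spec`.
#' @export
sweep_spec <- function(axis1_name, axis1_values, axis2_name, axis2_values,
                       schedule = event_schedule()) {
  ok_names <- setdiff(names(formals(model_params)), "transmission_mode")
  for (nm in c(axis1_name, axis2_name)) {
    if (!nm %in% ok_names)
      stop("unknown sweep axis '", nm, "'; must be one of: ",
           paste(ok_names, collapse = ", "))
  }
  if (length(axis1_values) < 1 || length(axis2_values) < 1)
    stop("sweep axes must be non-empty")
  structure(list(axis1_name = axis1_name, axis1_values = axis1_values,
                 axis2_name = axis2_name, axis2_values = axis2_values,
                 schedule = schedule), class = "sweep_spec")
}

outcome_row <- function(oc) {
  data.frame(specific_fate = oc$specific_fate, R_freq = oc$R_freq,
             q_S_mode = oc$q_S_mode, q_S_mean = oc$q_S_mean,
             q_R_mode = oc$q_R_mode, q_R_mean = oc$q_R_mean,
             endemic_persists = oc$endemic_persists,
             foreign_persists = oc$foreign_persists,
             stability = oc$stability, error = NA_character_,
             stringsAsFactors = FALSE)
}

#' Run a two-axis parameter sweep
#'
#' Executes one independent [run_evolution()] per grid cell (axis1 outer,
#' axis2 inner, so results do not depend on execution order) and collects
#' one [summarize_outcome()] record per cell.  A failure in one cell is
#' recorded in its `error` column and does not abort the sweep.
#'
#' @param spec a [sweep_spec()].
#' @param base_params a [model_params()] providing all non-swept values.
#' @param grid a [q_grid()].
#' @param config an [integrator_config()].
#' @param progress print one line per cell.
#' @return a data frame of class `outcome_map`: axis columns followed by
#'   the outcome fields.
#' @export
run_sweep <- function(spec, base_params = model_params(), grid = q_grid(),
                      config = integrator_config(), progress = FALSE) {
  cells <- expand.grid(a2 = spec$axis2_values, a1 = spec$axis1_values)
  # expand.grid varies its first factor fastest; reorder to axis1-outer
  cells <- cells[, c("a1", "a2")]
  rows <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    pl <- unclass(base_params)
    pl[[spec$axis1_name]] <- cells$a1[k]
    pl[[spec$axis2_name]] <- cells$a2[k]
    rows[[k]] <- tryCatch({
      params <- suppressWarnings(do.call(model_params, pl))
      tr <- run_evolution(params, grid, spec$schedule, config)
      outcome_row(summarize_outcome(tr))
    }, error = function(e) {
      out <- outcome_row(structure(list(
        specific_fate = NA_character_, R_freq = NA_real_,
        q_S_mode = NA_real_, q_S_mean = NA_real_, q_R_mode = NA_real_,
        q_R_mean = NA_real_, endemic_persists = NA, foreign_persists = NA,
        stability = NA_character_), class = "outcome_record"))
      out$error <- conditionMessage(e)
      out
    })
    if (progress)
      message(sprintf("[%d/%d] %s=%g %s=%g -> %s", k, nrow(cells),
                      spec$axis1_name, cells$a1[k], spec$axis2_name,
                      cells$a2[k], rows[[k]]$specific_fate))
  }
  res <- cbind(stats::setNames(cells, c(spec$axis1_name, spec$axis2_name)),
               do.call(rbind, rows))
  class(res) <- c("outcome_map", "data.frame")
  res
}

#' Write an outcome map to CSV
#'
#' Deterministic: the same map always produces a byte-identical file
#' (fixed header, axis1-outer row order inherited from [run_sweep()]).
#'
#' @param map an `outcome_map`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_outcomes <- function(map, path) {
  write.csv(as.data.frame(map), path, row.names = FALSE, quote = FALSE,
            eol = "\n")
  invisible(path)
}

#' Scenario presets
#'
#' Returns the fully resolved configuration of one named computational
#' experiment.  Shared parameters across presets: b = 1.5, mu = 0.2,
#' gamma = 0.01, beta_e = 1, theta = 0.5.
#'
#' \describe{
#'   \item{fig1a}{specific resistance only (q frozen at 0): r x c_r sweep,
#'     single endemic pathogen.}
#'   \item{fig1b}{general resistance only: single 50-iteration run, no R,
#'     no foreign pathogen; the evolved modal q is the singular strategy.}
#'   \item{fig1c / fig1d}{joint evolution, single pathogen: r x c_r sweep
#'     with R introduced after 50 iterations, 100 in total.}
#'   \item{fig1_specific_first}{order-of-introduction variant: R present
#'     from the start, q mutation frozen for the first 50 iterations.}
#'   \item{fig2}{two pathogens: beta_f = 0.6, R at 50, foreign pathogen at
#'     100, 150 iterations; r x c_r sweep.}
#'   \item{fig3}{single run at the polymorphism point r = 0.85,
#'     c_r = 0.325, beta_f = 0.6.}
#'   \item{fig4}{two pathogens at r = 0.8: beta_f x c_r sweep.}
#'   \item{fig5_p0, fig5_p005, fig5_p05}{four-genotype recombination runs
#'     at p = 0, 0.005, 0.05 (mu = 0.2, gamma = 0.001, r = 0.2, c_r = 0.1,
#'     q_plus = 0.091, beta_f = 0.7).}
#'   \item{ld_demo_p0, ld_demo_p005, ld_demo_p05}{recombination runs at a
#'     self-consistent polymorphic source state (r = 0.8, c_r = 0.2,
#'     beta_f = 0.7, q_plus = 0.17) demonstrating how recombination erodes
#'     the evolved linkage disequilibrium; see the methods vignette.}
#' }
#'
#' @param name preset name (see above).
#' @param tier `"full"` (26 x 26 sweep grids) or `"smoke"` (6 x 6), per
#'   sweep presets only.  Region topology, not resolution, is the tested
#'   object.
#' @return a list with `type` (`"evolution"`, `"sweep"` or `"recomb"`) and
#'   the matching configuration objects.
#' @export
scenario_preset <- function(name, tier = c("full", "smoke")) {
  tier <- match.arg(tier)
  k <- if (tier == "full") 26L else 6L
  r_ax <- seq(0, 1, length.out = k)
  cr_ax <- seq(0, 0.5, length.out = k)
  bf_ax <- seq(0, 1, length.out = k)
  base <- model_params(b = 1.5, mu = 0.2, gamma = 0.01, beta_e = 1,
                       theta = 0.5)
  two_path <- function(beta_f) {
    p <- base; p$beta_f <- beta_f; class(p) <- "model_params"; p
  }
  sched_single <- event_schedule(introduce_R_at = 50, total_iterations = 150)
  sched_two <- event_schedule(introduce_R_at = 50, introduce_If_at = 100,
                              total_iterations = 150)

  switch(name,
    fig1a = list(type = "sweep", params = base, grid = q_grid(),
                 config = integrator_config(),
                 spec = sweep_spec("r", r_ax, "c_r", cr_ax,
                                   event_schedule(introduce_R_at = 50,
                                                  total_iterations = 100,
                                                  freeze_general_until = Inf))),
    fig1b = list(type = "evolution", params = base, grid = q_grid(),
                 config = integrator_config(),
                 schedule = event_schedule(total_iterations = 150)),
    fig1c = ,
    fig1d = list(type = "sweep", params = base, grid = q_grid(),
                 config = integrator_config(),
                 spec = sweep_spec("r", r_ax, "c_r", cr_ax, sched_single)),
    fig1_specific_first = list(
      type = "sweep", params = base, grid = q_grid(),
      config = integrator_config(),
      spec = sweep_spec("r", r_ax, "c_r", cr_ax,
                        event_schedule(introduce_R_at = "start",
                                       total_iterations = 100,
                                       freeze_general_until = 50))),
    fig2 = list(type = "sweep", params = two_path(0.6), grid = q_grid(),
                config = integrator_config(),
                spec = sweep_spec("r", r_ax, "c_r", cr_ax, sched_two)),
    fig3 = {
      p <- two_path(0.6); p$r <- 0.85; p$c_r <- 0.325
      list(type = "evolution", params = p, grid = q_grid(),
           config = integrator_config(), schedule = sched_two)
    },
    fig4 = {
      p <- base; p$r <- 0.8; class(p) <- "model_params"
      list(type = "sweep", params = p, grid = q_grid(),
           config = integrator_config(),
           spec = sweep_spec("beta_f", bf_ax, "c_r", cr_ax, sched_two))
    },
    fig5_p0 = ,
    fig5_p005 = ,
    fig5_p05 = {
      p <- switch(name, fig5_p0 = 0, fig5_p005 = 0.005, fig5_p05 = 0.05)
      mp <- suppressWarnings(model_params(
        b = 1.5, mu = 0.2, gamma = 0.001, beta_e = 1, beta_f = 0.7,
        r = 0.2, c_r = 0.1, theta = 0.5))
      list(type = "recomb",
           rp = recomb_params(p, q_plus = 0.091, q_minus = 0, params = mp),
           config = integrator_config(), t_end = 20000)
    },
    ld_demo_p0 = ,
    ld_demo_p005 = ,
    ld_demo_p05 = {
      # self-consistent linkage-disequilibrium demonstration: a Fig-4-family
      # cell (r = 0.8, c_r = 0.2, beta_f = 0.7) where the package's own
      # adaptive dynamics yields a two-pathogen S/R polymorphism with
      # q_S ~ 0.17 and q_R = 0, unlike the printed fig5 parameter set whose
      # clonal dynamics exclude Q+S for any recombination rate (see the
      # methods vignette)
      p <- switch(name, ld_demo_p0 = 0, ld_demo_p005 = 0.005,
                  ld_demo_p05 = 0.05)
      mp <- suppressWarnings(model_params(
        b = 1.5, mu = 0.2, gamma = 0.001, beta_e = 1, beta_f = 0.7,
        r = 0.8, c_r = 0.2, theta = 0.5))
      list(type = "recomb",
           rp = recomb_params(p, q_plus = 0.17, q_minus = 0, params = mp),
           config = integrator_config(), t_end = 20000)
    },
    stop("unknown scenario '", name, "'; known scenarios: ",
         paste(scenario_names(), collapse = ", "))
  )
}

#' Names of the registered scenario presets
#' @return character vector of valid [scenario_preset()] names.
#' @export
scenario_names <- function() {
  c("fig1a", "fig1b", "fig1c", "fig1d", "fig1_specific_first", "fig2",
    "fig3", "fig4", "fig5_p0", "fig5_p005", "fig5_p05",
    "ld_demo_p0", "ld_demo_p005", "ld_demo_p05")
}
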