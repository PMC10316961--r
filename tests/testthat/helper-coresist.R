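# shared fixtures: everything is generated in code, no stored data

default_params <- function(...) {
  args <- utils::modifyList(list(b = 1.5, mu = 0.2, gamma = 0.01,
                                 beta_e = 1, theta = 0.5), list(...))
  suppressWarnings(do.call(model_params, args))
}

# deterministic pseudo-random state for property-style loops
random_state <- function(seed, grid = q_grid(), scale = 10) {
  set.seed(seed)
  system_state(S = runif(grid$n) * scale, R = runif(grid$n) * scale,
               I_e = runif(1) * scale, I_f = runif(1) * scale, grid = grid)
}

# hand-built evolution_trace for classifier unit tests
fake_trace <- function(S_tot, R_tot = 0, Ie = 0, If = 0, grid = q_grid()) {
  n <- length(S_tot)
  R_tot <- rep_len(R_tot, n); Ie <- rep_len(Ie, n); If <- rep_len(If, n)
  structure(list(
    summary = data.frame(iteration = seq_len(n), S_total = S_tot,
                         R_total = R_tot, I_e = Ie, I_f = If,
                         q_S_mean = 0, q_S_mode = 0,
                         q_R_mean = 0, q_R_mode = 0),
    S_dist = matrix(0, n, grid$n), R_dist = matrix(0, n, grid$n),
    final_state = system_state(grid = grid), hosts_extinct = FALSE,
    grid = grid), class = "evolution_trace")
}
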