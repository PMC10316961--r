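test_that("mutation moves 5% to adjacent bins with the boundary rule", {
  g <- q_grid()
  # boundary: all moved mass goes to the single neighbour
  st <- system_state(S = 100, grid = g)  # mass at q = 0
  m <- mutate_state(st, g, 0.05)
  expect_equal(m$S[1], 95)
  expect_equal(m$S[2], 5)
  expect_equal(sum(m$S), 100)

  # interior: equal split
  v <- numeric(g$n); v[51] <- 100  # q = 0.50
  m2 <- mutate_state(system_state(S = v, grid = g), g, 0.05)
  expect_equal(m2$S[51], 95)
  expect_equal(m2$S[50], 2.5)
  expect_equal(m2$S[52], 2.5)

  # fraction 0 is the identity
  st3 <- random_state(7, g)
  m3 <- mutate_state(st3, g, 0)
  expect_identical(m3$S, st3$S)
  expect_identical(m3$R, st3$R)
})

test_that("mutation conserves density per background to machine precision", {
  g <- q_grid()
  for (seed in 1:10) {
    st <- random_state(seed, g)
    m <- mutate_state(st, g, 0.05)
    expect_equal(sum(m$S), sum(st$S), tolerance = 1e-13)
    expect_equal(sum(m$R), sum(st$R), tolerance = 1e-13)
    expect_identical(m$I_e, st$I_e)
    expect_true(all(m$S >= 0) && all(m$R >= 0))
  }
})

test_that("event_schedule validates indices", {
  s <- event_schedule(introduce_R_at = "start", introduce_If_at = "never",
                      total_iterations = 20)
  expect_equal(s$introduce_R_at, 0)
  expect_equal(s$introduce_If_at, Inf)
  expect_error(event_schedule(introduce_R_at = 30, total_iterations = 20),
               "introduce_R_at")
  expect_error(event_schedule(introduce_R_at = -1, total_iterations = 20),
               "introduce_R_at")
})

test_that("classify_stability applies the range-below-0.001 rule", {
  expect_equal(classify_stability(fake_trace(rep(10, 12))), "stable")
  expect_equal(classify_stability(fake_trace(rep(c(10, 10.1), 6))), "cyclic")
  # variation just below threshold in every series
  expect_equal(classify_stability(
    fake_trace(10 + seq(0, 0.0009, length.out = 10))), "stable")
  expect_error(classify_stability(fake_trace(rep(10, 9))), "at least 10")
})

test_that("no pathogen means no benefit: q stays at zero", {
  g <- q_grid()
  p <- default_params(beta_e = 0)
  tr <- run_evolution(p, g, event_schedule(total_iterations = 15),
                      integrator_config())
  oc <- summarize_outcome(tr)
  expect_equal(oc$q_S_mode, 0)
  # the mutation kernel parks a small tail above 0; the mean stays tiny
  expect_lt(oc$q_S_mean, 0.02)
})

test_that("neutral R allele leaves merged dynamics identical to a no-R run", {
  g <- q_grid()
  p <- default_params(r = 0, c_r = 0)
  cfg <- integrator_config()
  n_it <- 12
  a <- run_evolution(p, g, event_schedule(total_iterations = n_it), cfg,
                     init = system_state(S = 2, I_e = 1, grid = g))
  b <- run_evolution(p, g, event_schedule(total_iterations = n_it), cfg,
                     init = system_state(S = 1, R = 1, I_e = 1, grid = g))
  expect_equal(b$summary$S_total + b$summary$R_total, a$summary$S_total,
               tolerance = 1e-8)
  expect_equal(b$summary$I_e, a$summary$I_e, tolerance = 1e-8)
  expect_equal(b$S_dist + b$R_dist, a$S_dist, tolerance = 1e-8)
})

test_that("scheduled introductions seed R and the foreign pathogen", {
  g <- q_grid()
  p <- default_params(r = 0.9, c_r = 0.05, beta_f = 0.6)
  tr <- run_evolution(p, g,
                      event_schedule(introduce_R_at = 3, introduce_If_at = 6,
                                     total_iterations = 10),
                      integrator_config())
  s <- tr$summary
  expect_true(all(s$R_total[1:3] == 0))
  expect_gt(s$R_total[4], 0)
  expect_true(all(s$I_f[1:6] == 0))
  expect_gt(s$I_f[7], 0)
})

test_that("summarize_outcome classifies fates from the final state", {
  g <- q_grid()
  tr <- fake_trace(rep(10, 12))
  tr$final_state <- system_state(S = 100, I_e = 10, grid = g)
  expect_equal(summarize_outcome(tr)$specific_fate, "S_fixed")
  tr$final_state <- system_state(S = 50, R = 50, grid = g)
  oc <- summarize_outcome(tr)
  expect_equal(oc$specific_fate, "polymorphism")
  expect_equal(oc$R_freq, 0.5)
  tr$final_state <- system_state(R = 80, I_e = 5, grid = g)
  oc2 <- summarize_outcome(tr)
  expect_equal(oc2$specific_fate, "R_fixed")
  expect_true(oc2$endemic_persists)
  expect_false(oc2$foreign_persists)
  expect_true(is.na(oc2$q_S_mode))
})

test_that("specific-first introduction excludes general resistance at least as often", {
  # coarse 3x3 (r, c_r) grid: cells where the general-first schedule ends
  # with general resistance excluded are a subset of the cells where the
  # specific-first schedule does
  excluded <- function(oc) {
    qs <- ifelse(is.na(oc$q_S_mode), 0, oc$q_S_mode)
    qr <- ifelse(is.na(oc$q_R_mode), 0, oc$q_R_mode)
    qs <= 0.01 && qr <= 0.01
  }
  gen_first <- event_schedule(introduce_R_at = 50, total_iterations = 150)
  spec_first <- event_schedule(introduce_R_at = "start",
                               total_iterations = 150,
                               freeze_general_until = 50)
  for (rr in c(0.2, 0.6, 1.0)) for (cc in c(0.1, 0.3, 0.5)) {
    p <- default_params(r = rr, c_r = cc)
    a <- excluded(summarize_outcome(run_evolution(p, schedule = gen_first)))
    b <- excluded(summarize_outcome(run_evolution(p, schedule = spec_first)))
    expect_true(!a || b, label = sprintf("r=%g c_r=%g: %s implies %s", rr,
                                         cc, a, b))
  }
})

test_that("host extinction terminates the trace with a flag", {
  g <- q_grid()
  # birth rate below mortality: hosts die out deterministically
  p <- default_params(b = 0.1)
  tr <- run_evolution(p, g, event_schedule(total_iterations = 5),
                      integrator_config())
  expect_true(tr$hosts_extinct)
  expect_lt(nrow(tr$summary), 5)
  expect_equal(summarize_outcome(tr)$specific_fate, "hosts_extinct")
})
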