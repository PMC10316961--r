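test_that("mating matrix rows are distributions with the right limits", {
  for (p in c(0, 0.005, 0.05, 0.5, 1)) {
    M <- build_mating_matrix(p)
    expect_equal(unname(rowSums(M)), rep(1, 16))
    expect_true(all(M >= 0))
    # selfing (mother = father) is always maternal: recombination between
    # identical haplotypes is silent
    for (m in 1:4) expect_equal(unname(M[4 * (m - 1) + m, m]), 1)
  }
  # p = 0: offspring always maternal
  M0 <- build_mating_matrix(0)
  for (m in 1:4) for (f in 1:4)
    expect_equal(unname(M0[4 * (m - 1) + f, m]), 1)
  # p = 1, QpS mother x QmR father: the two recombinant phases, half each
  M1 <- build_mating_matrix(1)
  expect_equal(unname(M1[4 * 0 + 4, ]), c(0, 0.5, 0.5, 0),
               ignore_attr = TRUE) # -> QpR and QmS
})

test_that("p = 0 derivatives collapse onto the clonal model", {
  g <- q_grid()
  mp <- default_params(r = 0.6, c_r = 0.12, beta_f = 0.5)
  rp <- recomb_params(0, q_plus = 0.5, q_minus = 0, params = mp)
  fg <- four_genotype_state(QpS = 3, QpR = 2, QmS = 5, QmR = 7,
                            I_e = 4, I_f = 1.5)
  d4 <- recomb_derivatives(fg, rp)

  Sv <- numeric(g$n); Rv <- numeric(g$n)
  Sv[51] <- 3; Sv[1] <- 5   # q = 0.5 and q = 0 in the S background
  Rv[51] <- 2; Rv[1] <- 7
  dc <- derivatives(system_state(S = Sv, R = Rv, I_e = 4, I_f = 1.5,
                                 grid = g), mp, g)
  expect_equal(unname(d4$U), c(dc$S[51], dc$R[51], dc$S[1], dc$R[1]),
               tolerance = 1e-12)
  expect_equal(d4$I_e, dc$I_e, tolerance = 1e-12)
  expect_equal(d4$I_f, dc$I_f, tolerance = 1e-12)
})

test_that("recombination is silent in a monomorphic population", {
  mp <- default_params(r = 0.3, c_r = 0.1)
  st <- four_genotype_state(QpS = 10, I_e = 2)
  d0 <- recomb_derivatives(st, recomb_params(0, 0.4, 0, mp))
  d7 <- recomb_derivatives(st, recomb_params(0.7, 0.4, 0, mp))
  expect_equal(d0, d7, tolerance = 1e-12)
})

test_that("offspring bookkeeping: total births are independent of p", {
  mp <- default_params(r = 0.5, c_r = 0.2)
  st <- four_genotype_state(QpS = 3, QpR = 1, QmS = 2, QmR = 6, I_e = 2,
                            I_f = 1)
  dU0 <- recomb_derivatives(st, recomb_params(0, 0.3, 0, mp))$U
  dU5 <- recomb_derivatives(st, recomb_params(0.5, 0.3, 0, mp))$U
  expect_equal(sum(dU0), sum(dU5), tolerance = 1e-12)
})

test_that("degenerate states are handled", {
  mp <- default_params()
  rp <- recomb_params(0.1, 0.5, 0, mp)
  d <- recomb_derivatives(four_genotype_state(), rp)
  expect_true(all(unlist(d) == 0))
  expect_error(recomb_derivatives(four_genotype_state(I_e = 5), rp),
               "uninfected")
  expect_error(recomb_params(0.5, q_plus = 0.3, q_minus = 0.6), "q_minus")
})

test_that("p = 0 trajectories match the clonal integrator (equivalence oracle)", {
  g <- q_grid()
  mp <- default_params(r = 0.6, c_r = 0.12, beta_f = 0.5)
  rp <- recomb_params(0, q_plus = 0.5, q_minus = 0, params = mp)
  cfg <- integrator_config()

  res <- run_recombination(rp, cfg, t_end = 1000,
                           state0 = four_genotype_state(QpS = 1, QmR = 1,
                                                        I_e = 1, I_f = 1),
                           record_every = NULL)
  Sv <- numeric(g$n); Rv <- numeric(g$n)
  Sv[51] <- 1; Rv[1] <- 1
  eq <- equilibrate(system_state(S = Sv, R = Rv, I_e = 1, I_f = 1, grid = g),
                    mp, g, cfg)
  expect_equal(res$final_state$U[["QpS"]], eq$S[51], tolerance = 1e-6)
  expect_equal(res$final_state$U[["QmR"]], eq$R[1], tolerance = 1e-6)
  expect_equal(res$final_state$I_e, eq$I_e, tolerance = 1e-6)
  expect_equal(res$final_state$I_f, eq$I_f, tolerance = 1e-6)
})

test_that("trajectories carry linkage disequilibrium and persistence calls", {
  pre <- scenario_preset("ld_demo_p005")
  res <- run_recombination(pre$rp, pre$config, t_end = 2000,
                           record_every = 10)
  tr <- res$trajectory
  expect_true(all(c("time", "QpS", "QpR", "QmS", "QmR", "I_e", "I_f", "D")
                  %in% names(tr)))
  # D = x(QpS) x(QmR) - x(QpR) x(QmS) over uninfected frequencies
  i <- nrow(tr)
  Ut <- sum(tr[i, c("QpS", "QpR", "QmS", "QmR")])
  expect_equal(tr$D[i],
               (tr$QpS[i] * tr$QmR[i] - tr$QpR[i] * tr$QmS[i]) / Ut^2,
               tolerance = 1e-12)
  expect_true(all(res$persisting %in% c("QpS", "QpR", "QmS", "QmR")))
})

test_that("recombination erodes the evolved linkage disequilibrium", {
  # the package's own self-consistent polymorphic source state: without
  # recombination only the coupled genotypes Q+S and Q-R exist (maximal D);
  # with recombination the double susceptible Q-S floods the population and
  # D collapses
  r0 <- run_recombination(scenario_preset("ld_demo_p0")$rp,
                          t_end = 20000, record_every = 100)
  r5 <- run_recombination(scenario_preset("ld_demo_p05")$rp,
                          t_end = 20000, record_every = 100)
  expect_setequal(r0$persisting, c("QpS", "QmR"))
  expect_equal(r0$final_state$U[["QmS"]], 0)
  expect_gt(r5$final_state$U[["QmS"]], r5$final_state$U[["QpS"]])
  D0 <- tail(r0$trajectory$D, 1)
  D5 <- tail(r5$trajectory$D, 1)
  expect_gt(D0, 0.1)
  expect_lt(D5, D0 / 5)
})
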