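# Hamiltonian and Metropolis dynamics of the lattice core.

test_that("total energy of an isolated square cell is adhesion plus elastic", {
  p <- quiet_params()
  lab <- matrix(0L, 12, 12)
  lab[5:8, 5:8] <- 1L
  s <- fixture_state(lab, type = 1L, params = p)

  # A = A_T: elastic term vanishes; Moore adhesion of a 4x4 square against
  # free space: 4 corner pixels see 5 outside neighbours, the 8 other edge
  # pixels see 3
  J_cs <- p$energy$J_cell_substrate
  n_pairs <- 4 * 5 + 8 * 3
  expect_equal(total_energy(s), J_cs * n_pairs)

  # displace the target area by delta: energy rises by exactly lambda delta^2
  delta <- 7.5
  s$AT[1] <- 16 + delta
  lam <- p$energy$lambda[["winner"]]
  expect_equal(total_energy(s), J_cs * n_pairs + lam * delta^2)
})

test_that("total energy matches the brute-force pair-enumeration oracle", {
  for (seed in 1:4) {
    lab <- random_fixture(20, 20, 3, seed = seed)
    set.seed(seed + 100)
    s <- fixture_state(lab, type = c(1L, 2L, 1L),
                       AT = tabulate(lab[lab > 0], 3) + round(runif(3, -9, 9)),
                       params = quiet_params())
    expect_equal(total_energy(s), oracle_energy_of_state(s), tolerance = 1e-12)
  }
  # and under periodic boundaries / von Neumann adhesion
  p <- sim_params(energy = energy_params(lambda_m = c(winner = 0, loser = 0),
                                         boundary = "periodic",
                                         neighbor_order = 1))
  lab <- random_fixture(18, 22, 3, seed = 9)
  s <- fixture_state(lab, type = c(2L, 1L, 2L), params = p)
  expect_equal(total_energy(s), oracle_energy_of_state(s), tolerance = 1e-12)
})

test_that("total_energy rejects inconsistent lattice/cell bookkeeping", {
  lab <- matrix(0L, 6, 6); lab[2:3, 2:3] <- 1L
  s <- fixture_state(lab, type = 1L)
  s$A[1] <- 7L
  expect_error(total_energy(s), "inconsistent")
})

test_that("delta_energy is an exact increment of the total energy", {
  lab <- random_fixture(15, 15, 3, seed = 3)
  s <- fixture_state(lab, type = c(1L, 2L, 2L),
                     AT = tabulate(lab[lab > 0], 3) + c(-5, 3, 0),
                     params = quiet_params())
  set.seed(42)
  n_checked <- 0
  while (n_checked < 50) {
    r <- sample(nrow(s$labels), 1); c <- sample(ncol(s$labels), 1)
    dr <- sample(-1:1, 1); dc <- sample(-1:1, 1)
    rr <- r + dr; cc <- c + dc
    if (rr < 1 || rr > nrow(s$labels) || cc < 1 || cc > ncol(s$labels)) next
    cand <- s$labels[rr, cc]
    if (cand == s$labels[r, c]) {
      expect_identical(delta_energy(s, c(r, c), cand), 0)  # identity flip
      next
    }
    e_before <- oracle_energy_of_state(s)
    dh <- delta_energy(s, c(r, c), cand)
    old <- s$labels[r, c]
    epicompete:::cpp_apply_flip(s$labels, s$A, r - 1L, c - 1L, cand)
    expect_equal(dh, oracle_energy_of_state(s) - e_before, tolerance = 1e-9)
    # the exact reverse flip cancels (lambda_m = 0)
    dh_rev <- delta_energy(s, c(r, c), old)
    expect_equal(dh + dh_rev, 0, tolerance = 1e-9)
    n_checked <- n_checked + 1
  }
})

test_that("Metropolis acceptance follows the Boltzmann factor", {
  # two abutting cells; pushing cell 1 into cell 2 when both are at target
  # area costs a known dH > 0
  p <- quiet_params()
  lab <- matrix(0L, 10, 11)
  lab[4:7, 3:6] <- 1L
  lab[4:7, 7:10] <- 2L
  s0 <- fixture_state(lab, type = c(1L, 1L), params = p)
  dh <- delta_energy(s0, c(5, 7), 1L)
  expect_gt(dh, 0)
  p_theory <- exp(-dh / p$energy$temperature)

  set.seed(7)
  n <- 20000
  acc <- 0L
  for (i in seq_len(n)) {
    s <- fixture_state(lab, type = c(1L, 1L), params = p)
    if (attempt_flip(s, source = c(5, 6), target = c(5, 7))) acc <- acc + 1L
  }
  se <- sqrt(p_theory * (1 - p_theory) / n)
  expect_lt(abs(acc / n - p_theory), 3 * se)

  # dH < 0 is always accepted; T -> 0+ rejects any dH > 0
  s <- fixture_state(lab, type = c(1L, 1L), params = p)
  s$AT[1] <- 26  # cell 1 far below target: growing is downhill
  expect_true(delta_energy(s, c(5, 7), 1L) < 0)
  expect_true(attempt_flip(s, source = c(5, 6), target = c(5, 7)))
  p_cold <- sim_params(energy = energy_params(temperature = 1e-9,
                                              lambda_m = c(winner = 0, loser = 0)))
  set.seed(8)
  for (i in 1:20) {
    s <- fixture_state(lab, type = c(1L, 1L), params = p_cold)
    expect_false(attempt_flip(s, source = c(5, 6), target = c(5, 7)))
  }
})

test_that("one MCS gives every lattice site one attempt, conserving pixels", {
  p <- quiet_params()
  lab <- random_fixture(25, 30, 4, seed = 5)
  s <- fixture_state(lab, type = c(1L, 2L, 1L, 2L), params = p)
  set.seed(1)
  monte_carlo_step(s, 1)
  expect_identical(s$attempts, 25 * 30)
  monte_carlo_step(s, 99)
  expect_identical(s$attempts, 100 * 25 * 30)
  # pixel conservation and area bookkeeping
  expect_identical(sum(s$A[epicompete:::present_ids(s)]) + sum(s$labels == 0L),
                   25L * 30L)
  expect_true(epicompete:::check_state_integrity(s))
  # an all-free-space lattice never changes
  s0 <- new_state(12, 9, params = p)
  monte_carlo_step(s0, 25)
  expect_true(all(s0$labels == 0L))
})

test_that("accepted energy changes sum to the total energy difference", {
  p <- quiet_params()
  lab <- random_fixture(24, 24, 3, seed = 6)
  s <- fixture_state(lab, type = c(1L, 2L, 1L),
                     AT = tabulate(lab[lab > 0], 3) + c(4, -6, 2), params = p)
  e0 <- total_energy(s)
  set.seed(3)
  monte_carlo_step(s, 1000)
  expect_equal(s$dh_sum, total_energy(s) - e0,
               tolerance = 1e-6 * max(1, abs(s$dh_sum)))
})

test_that("cell areas fluctuate around the target area at moderate T", {
  p <- quiet_params()
  lab <- matrix(0L, 40, 40)
  lab[13:28, 13:28] <- 1L  # 256-pixel cell, A = A_T
  s <- fixture_state(lab, type = 1L, params = p)
  set.seed(4)
  a_sum <- 0
  for (i in 1:120) { monte_carlo_step(s, 5); a_sum <- a_sum + s$A[1] }
  expect_lt(abs(a_sum / 120 - 256) / 256, 0.05)
})

test_that("polarity diffusion preserves norm and decorrelates as exp(-D t)", {
  dr <- 0.15
  p <- sim_params(energy = energy_params(rot_diffusion = dr))
  s <- new_state(10, 10, params = p)
  n <- 4000
  for (i in seq_len(n))
    epicompete:::add_cell_record(s, 1L, A = 1L, AT = 1, added = 0, dA_div = 1e9)
  s$A[] <- 0L; s$A[seq_len(n)] <- 1L  # records only; no lattice needed
  theta0 <- s$pol[seq_len(n)]
  set.seed(9)
  for (t in 1:10) update_polarity(s)
  corr <- mean(cos(s$pol[seq_len(n)] - theta0))
  expect_lt(abs(corr - exp(-dr * 10)), 4 / sqrt(n))
  expect_equal(sqrt(cos(s$pol[1:5])^2 + sin(s$pol[1:5])^2), rep(1, 5))

  # zero rotational diffusion leaves polarity untouched
  p0 <- sim_params(energy = energy_params(rot_diffusion = 0))
  s0 <- new_state(5, 5, params = p0)
  epicompete:::add_cell_record(s0, 1L, A = 1L, AT = 1, added = 0, dA_div = 1e9)
  th <- s0$pol[1]
  update_polarity(s0)
  expect_identical(s0$pol[1], th)
})
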