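# Cell-automaton rules: growth, adder division, apoptosis laws, extrusion.

test_that("growth increment follows the contact-inhibition law", {
  expect_equal(growth_increment(G = 5, k = 0.3, A = 100, AT = 100), 5)
  expect_equal(growth_increment(G = 5, k = 0, A = 50, AT = 500), 5)
  expect_equal(growth_increment(G = 2, k = 0.01, A = 110, AT = 100),
               2 * exp(-1))
  # direction of the deviation does not matter, only its magnitude
  expect_equal(growth_increment(3, 1e-4, 90, 100),
               growth_increment(3, 1e-4, 110, 100))
})

test_that("adder criterion is inclusive and independent of birth size", {
  expect_true(should_divide(added = 300, threshold = 300))
  expect_false(should_divide(added = 0, threshold = 300))
  expect_false(should_divide(added = 299.99, threshold = 300))
  expect_identical(should_divide(added = c(250, 250), threshold = c(200, 300)),
                   c(TRUE, FALSE))
})

test_that("mechanical apoptosis probability is the stated sigmoid", {
  p_max <- 0.004; alpha <- 300; rho_half <- 0.02
  expect_equal(mech_apoptosis_prob(rho_half, p_max, alpha, rho_half), p_max / 2)
  expect_equal(mech_apoptosis_prob(1e6, p_max, alpha, rho_half), p_max)
  expect_equal(mech_apoptosis_prob(0.019, p_max, 1e9, rho_half), 0)
  expect_equal(mech_apoptosis_prob(0.021, p_max, 1e9, rho_half), p_max)
  rho <- seq(0, 0.1, by = 0.001)
  p <- mech_apoptosis_prob(rho, p_max, alpha, rho_half)
  expect_true(all(diff(p) >= 0))         # nondecreasing
  expect_true(all(p <= p_max + 1e-15))   # bounded
})

test_that("biochemical apoptosis probability is the stated Hill function", {
  p_max <- 0.004; S <- 0.3
  expect_equal(biochem_apoptosis_prob(0, p_max, S), 0)
  expect_equal(biochem_apoptosis_prob(S, p_max, S, n = 3), p_max / 2)
  expect_equal(biochem_apoptosis_prob(2 * S, p_max, S, n = 3), p_max * 8 / 9)
  p <- biochem_apoptosis_prob(seq(0, 1, by = 0.01), p_max, S)
  expect_true(all(diff(p) >= 0) && all(p <= p_max))
  expect_error(biochem_apoptosis_prob(1.2, p_max, S), "\\[0, 1\\]")
})

test_that("starting apoptosis zeroes the target area and sets lambda to 2", {
  lab <- matrix(0L, 10, 10); lab[3:6, 3:6] <- 1L
  s <- fixture_state(lab, type = 1L)
  start_apoptosis(s, 1L)
  expect_identical(s$fate[1], 1L)
  expect_identical(s$AT[1], 0)
  expect_identical(s$lam[1], 2)
  lam_before <- s$lam[1]
  start_apoptosis(s, 1L)  # no-op on an already apoptosing cell
  expect_identical(s$lam[1], lam_before)
})

test_that("an apoptosing cell shrinks to extinction through the dynamics", {
  lab <- matrix(0L, 24, 24); lab[7:18, 7:18] <- 1L
  s <- fixture_state(lab, type = 1L, params = quiet_params())
  start_apoptosis(s, 1L)
  set.seed(11)
  areas <- integer(0)
  for (i in 1:60) { monte_carlo_step(s, 5); areas <- c(areas, s$A[1]) }
  expect_identical(tail(areas, 1), 0L)
  # monotone in expectation: smoothed trace never rises appreciably
  sm <- stats::filter(areas, rep(1 / 5, 5), sides = 1)
  expect_true(all(diff(sm[!is.na(sm)]) <= 2))
})

test_that("extrusion threshold is inclusive at half the mean area", {
  expect_true(check_extrusion(A = 50, mean_area = 100))
  expect_false(check_extrusion(A = 100, mean_area = 100))
  expect_false(check_extrusion(A = 50.5, mean_area = 100))
})

test_that("division splits a rectangle across its major axis", {
  lab <- matrix(0L, 12, 14)
  lab[5:8, 4:11] <- 1L  # 4 rows x 8 cols
  s <- fixture_state(lab, type = 1L)
  set.seed(2)
  ids <- divide_cell(s, 1L)
  expect_identical(sort(s$A[ids]), c(16L, 16L))
  d1 <- s$labels == ids[1]; d2 <- s$labels == ids[2]
  expect_identical(sum(d1 & d2), 0L)                    # disjoint
  expect_identical(which(d1 | d2), which(lab == 1L))    # exact partition
  # each daughter is one of the two 4x4 halves
  expect_true(all(which(d2, arr.ind = TRUE)[, "col"] >= 8))
  # daughters restart their cycle
  expect_identical(s$added[ids], c(0, 0))
  expect_identical(s$parent[ids[2]], 1L)
})

test_that("degenerate (isotropic) cells split along a seeded random axis", {
  lab <- matrix(0L, 11, 11)
  lab[4:7, 4:7] <- 1L  # square: moment tensor is isotropic
  s1 <- fixture_state(lab, type = 1L)
  set.seed(5); r1 <- divide_cell(s1, 1L); l1 <- s1$labels
  s2 <- fixture_state(lab, type = 1L)
  set.seed(5); r2 <- divide_cell(s2, 1L); l2 <- s2$labels
  expect_identical(l1, l2)  # same seed, same tie-break
  expect_identical(sum(s1$A[r1]), 16L)
  expect_true(all(s1$A[r1] > 0L))
})

test_that("decision pass is quiet when all rules are disabled", {
  p <- sim_params(
    energy = energy_params(lambda_m = c(winner = 0, loser = 0)),
    growth = growth_params(G = c(winner = 1e-9, loser = 1e-9)),
    apoptosis = apoptosis_params(mech_p_max = c(winner = 0, loser = 0)))
  lab <- matrix(0L, 20, 20)
  lab[3:8, 3:8] <- 1L; lab[12:17, 3:8] <- 2L
  lab[3:8, 12:17] <- 3L; lab[12:17, 12:17] <- 4L
  s <- fixture_state(lab, type = c(1L, 2L, 1L, 2L), params = p)
  set.seed(1)
  ev <- decision_pass(s)
  expect_identical(nrow(ev), 0L)
  expect_identical(sort(epicompete:::present_ids(s)), 1:4)
})

test_that("certain death: p_apo = 1 for losers kills every loser at once", {
  p <- sim_params(apoptosis = apoptosis_params(
    mech_p_max = c(winner = 0, loser = 1),
    mech_rho_half = c(winner = 0.03, loser = -1),  # sigmoid fully open
    mech_alpha = c(winner = 300, loser = 1e9)))
  lab <- random_fixture(30, 30, 4, seed = 8)
  s <- fixture_state(lab, type = c(1L, 2L, 1L, 2L), params = p)
  set.seed(1)
  ev <- decision_pass(s)
  expect_setequal(ev$cell_id[ev$event == "apoptosis_start"], c(2L, 4L))
  expect_true(all(s$fate[c(2, 4)] == 1L))
  # apoptosing cells take no further part in growth or division
  at_before <- s$AT[c(2, 4)]
  set.seed(2)
  decision_pass(s)
  expect_identical(s$AT[c(2, 4)], at_before)
})

test_that("identical seeds give identical event logs", {
  p <- tiny_cell_params()
  run_once <- function() {
    set.seed(33)
    s <- seed_lattice(seeding_spec("mixed", loser_fraction = 0.5,
                                   total_density = 0.5),
                      80, 80, 0.33, p)
    evs <- list()
    for (f in 1:6) {
      monte_carlo_step(s, 10)
      s$frame <- f
      evs[[f]] <- decision_pass(s)
    }
    list(ev = dplyr::bind_rows(evs), labels = s$labels)
  }
  a <- run_once(); b <- run_once()
  expect_identical(a$ev, b$ev)
  expect_identical(a$labels, b$labels)
})
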