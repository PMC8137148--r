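# Measurement layer: neighbour graph, density, contact, entropy, MSD.

two_rectangles <- function() {
  # two cells sharing a 4-pixel vertical interface
  lab <- matrix(0L, 10, 12)
  lab[4:7, 3:6] <- 1L
  lab[4:7, 7:10] <- 2L
  lab
}

test_that("neighbour graph counts shared boundaries in pixel-pair units", {
  g <- build_neighbor_graph(two_rectangles(), adjacency = 4)
  expect_identical(nrow(g$edges), 1L)
  expect_identical(g$edges$shared_boundary, 4L)
  # perimeter of each 4x4 cell: 16 boundary pixel pairs (4-adjacency)
  expect_equal(g$nodes$perimeter, c(16, 16))
})

test_that("graph edges equal a brute-force all-pairs pixel scan", {
  for (seed in c(2, 7, 13)) {
    lab <- random_fixture(28, 26, 6, seed = seed)
    g <- build_neighbor_graph(lab, adjacency = 4)
    got <- as.data.frame(g$edges[order(g$edges$a, g$edges$b), ])
    want <- oracle_edges(lab)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got$a, want$a)
    expect_identical(got$b, want$b)
    expect_identical(got$shared_boundary, want$shared_boundary)
    # symmetry / no self-loops by construction
    expect_true(all(g$edges$a != g$edges$b))
  }
})

test_that("local density is the sum of inverse areas of cell + neighbours", {
  px2 <- 0.33^2
  # isolated cell
  lab <- matrix(0L, 10, 10); lab[3:6, 3:6] <- 1L
  s <- fixture_state(lab, type = 1L)
  d <- local_density(build_neighbor_graph(s))
  expect_equal(d$rho, 1 / (16 * px2))

  # two abutting equal cells: rho = 2/A each
  s2 <- fixture_state(two_rectangles(), type = c(1L, 2L))
  d2 <- local_density(build_neighbor_graph(s2))
  expect_equal(d2$rho, rep(2 / (16 * px2), 2))

  # random confluent fixture vs direct recomputation from the label grid
  lab <- random_fixture(30, 30, 6, p_free = 0, seed = 4)
  areas <- tabulate(lab, nbins = 6) * px2
  g <- build_neighbor_graph(lab, adjacency = 4)
  d3 <- local_density(g)
  want <- vapply(1:6, function(id) {
    nb <- unique(c(g$edges$b[g$edges$a == id], g$edges$a[g$edges$b == id]))
    1 / areas[id] + sum(1 / areas[nb])
  }, 1.0)
  expect_equal(d3$rho[order(d3$cell_id)], want)

  # the alternative reading: inverse of the total area
  d4 <- local_density(g, definition = "inverse_total")
  want4 <- vapply(1:6, function(id) {
    nb <- unique(c(g$edges$b[g$edges$a == id], g$edges$a[g$edges$b == id]))
    1 / (areas[id] + sum(areas[nb]))
  }, 1.0)
  expect_equal(d4$rho[order(d4$cell_id)], want4)
})

test_that("heterotypic fraction counts boundary with the other type", {
  # all neighbours of the same type -> 0
  s <- fixture_state(two_rectangles(), type = c(1L, 1L))
  expect_equal(heterotypic_fraction(build_neighbor_graph(s))$het_frac, c(0, 0))

  # loser fully wrapped by a winner: p = 1 with the cell-cell denominator
  lab <- matrix(0L, 12, 12)
  lab[3:10, 3:10] <- 2L
  lab[6:7, 6:7] <- 1L
  s2 <- fixture_state(lab, type = c(1L, 2L))
  hf <- heterotypic_fraction(build_neighbor_graph(s2))
  expect_equal(hf$het_frac[hf$cell_id == 1], 1)

  # constructed fixture: exactly half the cell-cell boundary heterotypic
  lab3 <- matrix(0L, 12, 12)
  lab3[4:7, 1:4] <- 1L   # focal winner
  lab3[4:5, 5:8] <- 2L   # loser touching rows 4:5 -> 2 pixel pairs
  lab3[6:7, 5:8] <- 3L   # winner touching rows 6:7 -> 2 pixel pairs
  s3 <- fixture_state(lab3, type = c(1L, 2L, 1L))
  hf3 <- heterotypic_fraction(build_neighbor_graph(s3))
  expect_equal(hf3$het_frac[hf3$cell_id == 1], 0.5)
  # including free space in the denominator dilutes p
  hf3p <- heterotypic_fraction(build_neighbor_graph(s3),
                               denominator = "perimeter")
  p1 <- hf3p$het_frac[hf3p$cell_id == 1]
  expect_lt(p1, 0.5)
  expect_equal(p1, 2 / 16)  # 4+4+4+4 boundary pairs, 2 heterotypic
})

test_that("sidedness of a 3x3 block grid is the enumerated histogram", {
  lab <- matrix(0L, 9, 9)
  for (i in 0:2) for (j in 0:2)
    lab[(3 * i + 1):(3 * i + 3), (3 * j + 1):(3 * j + 3)] <- i * 3 + j + 1L
  g <- build_neighbor_graph(lab, adjacency = 4)
  sd <- sidedness_distribution(g)
  expect_equal(sd$fraction[sd$neighbors == 2], 4 / 9)
  expect_equal(sd$fraction[sd$neighbors == 3], 4 / 9)
  expect_equal(sd$fraction[sd$neighbors == 4], 1 / 9)
  expect_equal(sum(sd$fraction), 1)
  # single isolated cell: all mass at zero neighbours
  lab1 <- matrix(0L, 6, 6); lab1[2:4, 2:4] <- 1L
  sd1 <- sidedness_distribution(build_neighbor_graph(lab1))
  expect_identical(sd1$neighbors, 0L)
  expect_equal(sd1$fraction, 1)
  # empty lattice: empty distribution
  expect_identical(nrow(sidedness_distribution(
    build_neighbor_graph(matrix(0L, 4, 4)))), 0L)
})

test_that("mixing entropy is bounded, label-symmetric, and 0 when sorted", {
  # 2x2 block grid, columns sorted by type: every neighbour mix is pure or
  # half/half depending on geometry; use stripes for the extremes
  stripe <- function(widths, types) {
    lab <- matrix(0L, 8, 4 * length(widths))
    for (i in seq_along(widths))
      lab[, (4 * i - 3):(4 * i)] <- i
    fixture_state(lab, type = types)
  }
  # alternating single stripes: every neighbourhood is homogeneous (all of
  # the other type), so the neighbour-composition entropy is 0
  s_alt <- stripe(rep(1, 6), rep(c(1L, 2L), 3))
  expect_equal(mixing_entropy(build_neighbor_graph(s_alt)), 0)
  # two sorted blocks: only the two interface cells have mixed neighbours
  s_sorted <- stripe(rep(1, 6), c(1L, 1L, 1L, 2L, 2L, 2L))
  g_sorted <- build_neighbor_graph(s_sorted)
  per <- mixing_entropy(g_sorted, per_cell = TRUE)
  # brute-force tally: stripe i neighbours are i-1, i+1
  types <- c(1L, 1L, 1L, 2L, 2L, 2L)
  want <- vapply(1:6, function(i) {
    nb <- types[setdiff(c(i - 1, i + 1), c(0, 7))]
    p1 <- mean(nb == 1L)
    s <- 0
    for (p in c(p1, 1 - p1)) if (p > 0) s <- s - p * log(p)
    s
  }, 1.0)
  expect_equal(per$s, want)
  expect_equal(mixing_entropy(g_sorted), mean(want))
  # swapping the labels leaves S invariant
  s_swap <- stripe(rep(1, 6), c(2L, 2L, 2L, 1L, 1L, 1L))
  expect_equal(mixing_entropy(build_neighbor_graph(s_swap)),
               mixing_entropy(g_sorted))
  # half/half neighbourhoods attain the ln 2 bound: paired stripes give
  # every interior cell one neighbour of each type
  s_mix <- stripe(rep(1, 8), c(1L, 1L, 2L, 2L, 1L, 1L, 2L, 2L))
  per_mix <- mixing_entropy(build_neighbor_graph(s_mix), per_cell = TRUE)
  expect_equal(max(per_mix$s), log(2))
  # ... and the sorted two-block arrangement sits strictly below it
  expect_lt(mixing_entropy(g_sorted),
            mixing_entropy(build_neighbor_graph(s_mix)))
})

test_that("event probability and its binomial precision", {
  e <- event_probability(292, 1.6e5)
  expect_equal(e$p, 292 / 1.6e5)
  expect_equal(e$p, 1.825e-3)
  expect_equal(e$cv, sqrt((1 - e$p) / (e$p * 1.6e5)))
  expect_equal(event_probability(10, 10)$p, 1)
  expect_equal(event_probability(10, 10)$cv, 0)
  z <- event_probability(0, 100)
  expect_equal(z$p, 0)
  expect_true(is.na(z$cv))
  expect_error(event_probability(5, 0), "N > 0")
  expect_error(event_probability(11, 10), "N > 0")
})

test_that("MSD: stationary, ballistic and diffusive closed forms", {
  still <- tibble::tibble(cell_id = 1L, frame = 0:20, x = 3, y = -2)
  expect_true(all(msd(still)$msd == 0))

  v <- 0.7
  ball <- tibble::tibble(cell_id = 1L, frame = 0:40,
                         x = v * (0:40) * 0.6, y = v * (0:40) * 0.8)
  m <- msd(ball)
  expect_equal(m$msd, v^2 * m$lag^2)

  set.seed(10)
  sigma <- 0.5
  rw <- dplyr::bind_rows(lapply(1:300, function(id)
    tibble::tibble(cell_id = id, frame = 0:30,
                   x = cumsum(c(0, rnorm(30, 0, sigma))),
                   y = cumsum(c(0, rnorm(30, 0, sigma))))))
  m2 <- msd(rw, lags = c(1L, 4L, 8L))
  expect_equal(m2$msd, 2 * sigma^2 * m2$lag, tolerance = 0.05)
})

test_that("entropy and density skip degenerate inputs gracefully", {
  g0 <- build_neighbor_graph(matrix(0L, 5, 5))
  expect_true(is.na(mixing_entropy(g0)))
  lab <- matrix(0L, 8, 8); lab[2:5, 2:5] <- 1L
  s <- fixture_state(lab, type = 1L)
  s$A[1] <- 0L  # simulate a zero-area record
  g <- build_neighbor_graph(s)
  g$nodes$area[1] <- 0L
  expect_warning(d <- local_density(g), "zero-area")
  expect_identical(nrow(d), 0L)
})
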