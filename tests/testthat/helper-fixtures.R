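# Hand-built lattice states and brute-force oracles used across the suite.

# Build a cc_state from an explicit label matrix. Labels must be
# consecutive ids 1..n; `type` maps id -> 1 (winner) / 2 (loser).
# Target areas default to the actual pixel counts (zero elastic energy).
fixture_state <- function(labels, type, AT = NULL, params = default_params()) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  s <- new_state(ncol(labels), nrow(labels), pixel_size = 0.33, params = params)
  s$labels <- labels
  n <- max(labels, 0L)
  A <- tabulate(labels[labels > 0L], nbins = max(n, 1L))
  for (id in seq_len(n)) {
    epicompete:::add_cell_record(s, type[id], A = A[id],
                                 AT = if (is.null(AT)) A[id] else AT[id],
                                 added = 0, dA_div = 1e9)
    s$A[id] <- A[id]
  }
  s
}

# random labelled fixture: k seed points grown by nearest-seed assignment,
# with some free space left around the border
random_fixture <- function(H, W, k, p_free = 0.2, seed = 1) {
  set.seed(seed)
  sr <- runif(k, 1, H); sc <- runif(k, 1, W)
  lab <- matrix(0L, H, W)
  for (r in 1:H) for (c in 1:W) {
    d <- (r - sr)^2 + (c - sc)^2
    if (min(d) < (1 - p_free) * (H * W) / k) lab[r, c] <- which.min(d)
  }
  # drop empty ids and relabel consecutively
  ids <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], ids)
  lab
}

# Brute-force Hamiltonian: enumerates every neighbour pair and every cell
# term directly from the label matrix. Written independently of the
# lattice kernel; wall contacts (fixed frame) count once, in-lattice pairs
# are halved because both orientations are visited.
oracle_total_energy <- function(labels, type, AT, lam, J3,
                                neighbor_order = 2, periodic = FALSE) {
  H <- nrow(labels); W <- ncol(labels)
  offs <- if (neighbor_order >= 2)
    cbind(dr = rep(-1:1, 3), dc = rep(-1:1, each = 3))[-5, , drop = FALSE]
  else cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  tof <- function(l) if (l == 0L) 0L else type[l]
  E <- 0
  for (r in seq_len(H)) for (c in seq_len(W)) {
    l0 <- labels[r, c]
    for (k in seq_len(nrow(offs))) {
      rr <- r + offs[k, 1]; cc <- c + offs[k, 2]
      if (periodic) {
        rr <- ((rr - 1) %% H) + 1; cc <- ((cc - 1) %% W) + 1
        l1 <- labels[rr, cc]; w <- 0.5
      } else if (rr < 1 || rr > H || cc < 1 || cc > W) {
        l1 <- 0L; w <- 1
      } else {
        l1 <- labels[rr, cc]; w <- 0.5
      }
      if (l1 != l0) E <- E + w * J3[tof(l0) + 1, tof(l1) + 1]
    }
  }
  A <- tabulate(labels[labels > 0L], nbins = length(AT))
  for (id in seq_along(AT))
    if (!is.na(type[id]) && type[id] > 0)
      E <- E + lam[id] * (A[id] - AT[id])^2
  E
}

oracle_energy_of_state <- function(s) {
  oracle_total_energy(s$labels, s$typ[seq_len(max(s$labels, 1))],
                      s$AT, s$lam, s$J,
                      neighbor_order = s$params$energy$neighbor_order,
                      periodic = s$params$energy$boundary == "periodic")
}

# Brute-force neighbour relation: all-pairs pixel scan under 4-adjacency.
oracle_edges <- function(labels) {
  H <- nrow(labels); W <- ncol(labels)
  out <- list()
  for (r in seq_len(H)) for (c in seq_len(W)) {
    l0 <- labels[r, c]
    if (l0 == 0L) next
    for (k in 1:2) {
      rr <- r + c(1, 0)[k]; cc <- c + c(0, 1)[k]
      if (rr > H || cc > W) next
      l1 <- labels[rr, cc]
      if (l1 > 0L && l1 != l0) {
        key <- paste(min(l0, l1), max(l0, l1))
        out[[key]] <- (out[[key]] %||% 0L) + 1L
      }
    }
  }
  if (!length(out)) return(data.frame(a = integer(), b = integer(),
                                      shared_boundary = integer()))
  ab <- do.call(rbind, strsplit(names(out), " "))
  d <- data.frame(a = as.integer(ab[, 1]), b = as.integer(ab[, 2]),
                  shared_boundary = unlist(out))
  d[order(d$a, d$b), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# params with quiet lattice dynamics (no motility) for energy tests
quiet_params <- function(...) {
  sim_params(energy = energy_params(lambda_m = c(winner = 0, loser = 0), ...))
}

# small cells (~300 px^2) so that populated scenarios fit on the tiny
# lattices the io/scenario tests use
tiny_cell_params <- function(profile = "mechanical") {
  p <- default_params(profile)
  p$growth <- growth_params(G = c(winner = 2.5, loser = 2.2),
                            dA_tot = c(winner = 220, loser = 250),
                            AT0 = c(winner = 300, loser = 340),
                            k = c(winner = 1e-4, loser = 1e-4))
  p
}
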