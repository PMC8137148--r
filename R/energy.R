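#' Total lattice energy
#'
#' Evaluates the Hamiltonian of the current configuration: the adhesion
#' term summed over unlike-label neighbour pixel pairs (using the
#' homotypic, heterotypic or cell-substrate surface energy for each pair)
#' plus the elastic term `lambda * (A - A_T)^2` for every cell (free space
#' carries no target area and is exempt). The motility term is defined
#' only for a concrete copy attempt (it needs a displacement direction),
#' so it contributes to [delta_energy()] but not to the global energy.
#'
#' @param state a `cc_state`.
#' @param check verify lattice/cell bookkeeping first (integrity error on
#'   mismatch).
#' @return scalar energy.
#' @export
total_energy <- function(state, check = TRUE) {
  if (check) check_state_integrity(state)
  cpp_total_energy(state$labels, state$A, state$AT, state$lam, state$typ,
                   state$J, state$params$energy$boundary == "periodic",
                   state$params$energy$neighbor_order)
}

#' Energy change of a single copy attempt
#'
#' Incremental form of the Hamiltonian used by the Metropolis dynamics:
#' the energy difference of overwriting the label at `site` with
#' `candidate`, including the elastic change for both the shrinking and
#' the growing cell and, when `source` is given, the motility bias
#' `-lambda_m * (m . s_hat)` along the copy direction.
#'
#' @param state a `cc_state`.
#' @param site integer `c(row, col)` of the target pixel (1-based).
#' @param candidate label to copy onto the site (0 = free space).
#' @param source optional `c(row, col)` of the neighbour supplying the
#'   candidate label; needed only for the motility term.
#' @return scalar energy difference; exactly 0 when `candidate` already
#'   labels the site.
#' @export
delta_energy <- function(state, site, candidate, source = NULL) {
  if (is.null(source)) source <- c(0L, 0L)
  cpp_delta_energy(state$labels, state$A, state$AT, state$lam, state$typ,
                   state$J, state$params$energy$boundary == "periodic",
                   state$params$energy$neighbor_order,
                   site[1] - 1L, site[2] - 1L, as.integer(candidate),
                   source[1] - 1L, source[2] - 1L,
                   cos(state$pol), sin(state$pol),
                   state$params$energy$lambda_m[pmax(state$typ, 1L)] *
                     (state$typ > 0L))
}

#' Attempt one Metropolis copy
#'
#' Proposes copying the label at `source` onto the neighbouring `target`
#' pixel and accepts with probability 1 if the energy change is
#' non-positive, otherwise `exp(-dH / T)`. On acceptance the label grid
#' and both cells' areas are updated.
#'
#' @param state a `cc_state`.
#' @param source,target integer `c(row, col)` pixel coordinates; must be
#'   lattice neighbours with different labels.
#' @return logical, whether the copy was accepted.
#' @export
attempt_flip <- function(state, source, target) {
  cand <- state$labels[source[1], source[2]]
  old <- state$labels[target[1], target[2]]
  if (cand == old) return(FALSE)
  dh <- delta_energy(state, target, cand, source = source)
  acc <- dh <= 0 || runif(1) < exp(-dh / state$params$energy$temperature)
  state$attempts <- state$attempts + 1
  if (acc) {
    cpp_apply_flip(state$labels, state$A, target[1] - 1L, target[2] - 1L,
                   as.integer(cand))
    state$accepts <- state$accepts + 1
    state$dh_sum <- state$dh_sum + dh
  }
  acc
}

#' Run Monte Carlo steps
#'
#' One Monte Carlo step (MCS) gives each lattice site, on average, one
#' chance of changing identity: `width * height` copy attempts, each
#' picking a random site and a random neighbour (random-sequential order,
#' avoiding sweep artefacts). Attempt/acceptance counters and the running
#' sum of accepted energy changes accumulate on the state.
#'
#' @param state a `cc_state`.
#' @param n number of MCS.
#' @return the state, invisibly.
#' @export
monte_carlo_step <- function(state, n = 1) {
  en <- state$params$energy
  lamm <- en$lambda_m[pmax(state$typ, 1L)] * (state$typ > 0L)
  lamm[state$fate == 1L] <- 0   # apoptosing cells lose active motility
  res <- cpp_run_mcs(state$labels, as.integer(n), state$A, state$AT,
                     state$lam, state$typ, cos(state$pol), sin(state$pol),
                     lamm, state$J, en$temperature,
                     en$boundary == "periodic", en$neighbor_order)
  state$attempts <- state$attempts + res$attempts
  state$accepts <- state$accepts + res$accepts
  state$dh_sum <- state$dh_sum + res$dh_sum
  invisible(state)
}

#' Rotational diffusion of polarity vectors
#'
#' Adds a mean-zero Gaussian increment of variance `2 * rot_diffusion * dt`
#' to every cell's polarity angle, so the ensemble directional
#' autocorrelation decays as `exp(-rot_diffusion * t)`. Norms are
#' preserved exactly (the polarity is stored as an angle).
#'
#' @param state a `cc_state`.
#' @param dt time step in frames.
#' @return the state, invisibly.
#' @export
update_polarity <- function(state, dt = 1) {
  dr <- state$params$energy$rot_diffusion
  if (dr > 0) {
    ids <- present_ids(state)
    state$pol[ids] <- (state$pol[ids] +
                       rnorm(length(ids), 0, sqrt(2 * dr * dt))) %% (2 * pi)
  }
  invisible(state)
}
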