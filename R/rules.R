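#' Target-area growth increment under contact inhibition
#'
#' The effective growth rate is `G * exp(-k * (A - A_T)^2)`: growth slows
#' exponentially as the actual area falls behind the target area, the
#' model's rendering of contact inhibition of proliferation. Re-evaluated
#' every frame, so growth resumes immediately when free space appears.
#'
#' @param G growth rate in the absence of crowding (pixel^2 / frame).
#' @param k contact-inhibition sensitivity (pixel^-4).
#' @param A,AT actual and target areas (pixel^2).
#' @param dt time step in frames.
#' @return the target-area increment, `G * exp(-k (A - AT)^2) * dt`.
#' @export
growth_increment <- function(G, k, A, AT, dt = 1) {
  G * exp(-k * (A - AT)^2) * dt
}

#' Adder division criterion
#'
#' A cell divides once it has added a threshold area since birth,
#' independent of its birth size (inclusive at the boundary).
#'
#' @param added target area added since birth (pixel^2).
#' @param threshold the cell's division threshold drawn at birth.
#' @return logical.
#' @export
should_divide <- function(added, threshold) {
  added >= threshold
}

#' Density-dependent (mechanical) apoptosis probability
#'
#' Sigmoid of local density: `p_max / (1 + exp(-alpha * (rho - rho_half)))`.
#' Winner and loser cells share the saturation probability; the winner
#' curve is shifted towards higher densities via `rho_half`.
#'
#' @param rho local cell density (1/um^2), non-negative.
#' @param p_max saturation probability per frame.
#' @param alpha steepness (um^2).
#' @param rho_half density at half-maximum (1/um^2).
#' @return probability per frame, in `[0, p_max]`.
#' @export
mech_apoptosis_prob <- function(rho, p_max, alpha, rho_half) {
  stopifnot(all(rho >= 0))
  p_max / (1 + exp(-alpha * (rho - rho_half)))
}

#' Contact-dependent (biochemical) apoptosis probability
#'
#' Hill function of the heterotypic perimeter fraction:
#' `p_max * p^n / (S^n + p^n)`.
#'
#' @param p fraction of the cell perimeter in heterotypic contact, in
#'   `[0, 1]`.
#' @param p_max amplitude, probability per frame.
#' @param S half-maximum heterotypic fraction.
#' @param n Hill coefficient.
#' @return probability per frame.
#' @export
biochem_apoptosis_prob <- function(p, p_max, S, n = 3) {
  if (any(p < 0 | p > 1)) abort("heterotypic fraction `p` must lie in [0, 1]")
  p_max * p^n / (S^n + p^n)
}

#' Start apoptosis execution
#'
#' Sets the cell's target area to 0 and its area-expansion modulus to the
#' configured apoptotic value (default 2), after which the cell shrinks
#' through normal lattice dynamics -- a quick but not instantaneous loss of
#' area. The record is removed (and logged as completed) when the area
#' reaches 0. Apoptosing cells are never selected for growth, division or
#' further death draws. No-op for cells already apoptosing.
#'
#' @param state a `cc_state`.
#' @param ids cell ids entering apoptosis.
#' @return the state, invisibly.
#' @export
start_apoptosis <- function(state, ids) {
  ids <- ids[state$typ[ids] > 0L & state$fate[ids] == 0L]
  state$fate[ids] <- 1L
  state$AT[ids] <- 0
  state$lam[ids] <- state$params$apoptosis_lambda
  invisible(state)
}

#' Live-extrusion criterion
#'
#' A cell is extruded -- removed from the lattice instantaneously, unlike
#' apoptosis -- when its area has dropped to half the current population
#' mean or below (inclusive threshold).
#'
#' @param A cell area(s), pixel^2.
#' @param mean_area average area of all (live) cells at the current frame.
#' @return logical.
#' @export
check_extrusion <- function(A, mean_area) {
  A <= mean_area / 2
}

#' Divide a cell along its major axis
#'
#' Splits the cell's pixel set by the line through its centroid
#' perpendicular to the principal axis of its pixel second-moment tensor.
#' The two daughters partition the parent's pixels exactly; each gets a
#' fresh birth target area and adder threshold drawn from the birth
#' distributions, adder progress 0, a fresh polarity, and `parent_id` set.
#' One daughter keeps the parent's lattice label. Circularly symmetric
#' (degenerate-moment) cells split along a random axis. Single-pixel cells
#' defer division by one frame.
#'
#' @param state a `cc_state`.
#' @param id the dividing cell.
#' @return integer ids `c(daughter_keeping_label, new_daughter)`, or
#'   `NULL` if division was deferred.
#' @export
divide_cell <- function(state, id) {
  res <- divide_cells(state, id)
  if (nrow(res) == 0) NULL else c(res$id1[1], res$id2[1])
}

# vectorised division used by decision_pass(); returns a tibble of
# completed divisions
divide_cells <- function(state, ids) {
  ids <- ids[state$A[ids] >= 2L]
  if (!length(ids))
    return(tibble(parent = integer(), id1 = integer(), id2 = integer()))
  g <- state$params$growth
  new_ids <- integer(length(ids))
  # register daughter records first so the relabeling can update areas
  for (j in seq_along(ids)) {
    ty <- state$typ[ids[j]]
    new_ids[j] <- add_cell_record(
      state, ty, A = 0L,
      AT = rtrunc_norm(1, g$AT0[[ty]], g$AT0_cv, lower = 25),
      added = 0, dA_div = rtrunc_norm(1, g$dA_tot[[ty]], g$dA_tot_cv, lower = 25),
      parent = ids[j])
  }
  fb <- runif(length(ids), 0, pi)
  res <- cpp_divide_cells(state$labels, state$A, as.integer(ids),
                          as.integer(new_ids), fb)
  done <- which(res$ok)
  failed <- which(!res$ok)
  drop_cell_record(state, new_ids[failed]) # deferred: revert daughter record
  for (j in done) {
    id <- ids[j]; ty <- state$typ[id]
    # the label-keeping daughter is a fresh cell: reset its adder state
    state$AT[id] <- rtrunc_norm(1, g$AT0[[ty]], g$AT0_cv, lower = 25)
    state$added[id] <- 0
    state$dA_div[id] <- rtrunc_norm(1, g$dA_tot[[ty]], g$dA_tot_cv, lower = 25)
    state$birth[id] <- state$frame
    state$parent[id] <- id
    state$pol[id] <- runif(1, 0, 2 * pi)
  }
  tibble(parent = ids[done], id1 = ids[done], id2 = new_ids[done])
}

#' One automaton decision pass
#'
#' Executes the per-frame probabilistic rules for every live cell, in a
#' fixed order so that a cell cannot divide and die in the same frame:
#' (1) minor-fragment cleanup and metrics (local density rho and/or
#' heterotypic perimeter fraction p from the neighbour graph), (2)
#' apoptosis draws for the active mode, (3) live extrusion against the
#' mean live-cell area, (4) target-area growth under contact inhibition,
#' (5) adder-triggered divisions, then polarity diffusion and removal of
#' apoptosing cells that have reached zero area. Identical seeds give
#' identical event sequences.
#'
#' @param state a `cc_state`.
#' @return tibble of events for this frame (`cell_id`, `type`, `event`),
#'   with the per-cell metrics attached as attribute `"metrics"`.
#' @export
decision_pass <- function(state) {
  prm <- state$params
  frag <- cpp_fragment_cleanup(state$labels, state$A, prm$fragment_min_px,
                               prm$energy$boundary == "periodic")

  graph <- build_neighbor_graph(state)
  live <- live_ids(state)
  events <- list()
  ev <- function(ids, what) if (length(ids))
    tibble::new_tibble(list(cell_id = as.integer(ids),
                            type = type_label(state$typ[ids]),
                            event = rep.int(what, length(ids))),
                       nrow = length(ids))

  rho <- het <- setNames(rep(NA_real_, length(live)), live)
  mode <- prm$apoptosis$mode
  need_rho <- mode %in% c("mechanical", "both")
  need_het <- mode %in% c("biochemical", "both")
  if (length(live)) {
    dens <- local_density(graph, definition = prm$density_definition)
    rho[match(dens$cell_id, live)] <- dens$rho
    hf <- heterotypic_fraction(graph, denominator = prm$het_denominator)
    het[match(hf$cell_id, live)] <- hf$het_frac
  }

  # (2) apoptosis draws, cell-id order for a reproducible stream
  if (length(live)) {
    ty <- state$typ[live]
    p_death <- rep(0, length(live))
    if (need_rho) {
      ap <- prm$apoptosis
      p_mech <- mech_apoptosis_prob(ifelse(is.na(rho), 0, rho),
                                    ap$mech_p_max[ty], ap$mech_alpha[ty],
                                    ap$mech_rho_half[ty])
      p_death <- 1 - (1 - p_death) * (1 - p_mech)
    }
    if (need_het) {
      ap <- prm$apoptosis
      p_bio <- biochem_apoptosis_prob(ifelse(is.na(het), 0, het),
                                      ap$bio_p_max[ty], ap$bio_S[ty],
                                      ap$bio_n[ty])
      p_death <- 1 - (1 - p_death) * (1 - p_bio)
    }
    dying <- live[runif(length(live)) < p_death]
    start_apoptosis(state, dying)
    events$apo <- ev(dying, "apoptosis_start")
    live <- setdiff(live, dying)
  }

  # (3) live extrusion: instantaneous removal within the same frame
  if (length(live)) {
    pool <- if (prm$extrusion_include_apoptosing) present_ids(state) else live
    mean_area <- mean(state$A[pool])
    extruded <- live[check_extrusion(state$A[live], mean_area)]
    if (length(extruded)) {
      events$ext <- ev(extruded, "extrusion")
      cpp_erase_cells(state$labels, state$A, as.integer(extruded))
      drop_cell_record(state, extruded)
      live <- setdiff(live, extruded)
    }
  }

  # (4) growth: per-cell stochastic increment, contact-inhibited
  if (length(live)) {
    g <- prm$growth
    ty <- state$typ[live]
    Gi <- rtrunc_norm(length(live), g$G[ty], g$G_cv)
    inc <- growth_increment(Gi, g$k[ty], state$A[live], state$AT[live])
    state$AT[live] <- state$AT[live] + inc
    state$added[live] <- state$added[live] + inc
  }

  # (5) adder divisions
  if (length(live)) {
    dividing <- live[should_divide(state$added[live], state$dA_div[live])]
    div <- divide_cells(state, dividing)
    if (nrow(div)) events$div <- tibble(cell_id = div$id2,
                                        type = type_label(state$typ[div$id2]),
                                        event = "division")
  }

  update_polarity(state)

  # apoptosis completion / fluctuation collapse
  gone <- which(state$typ > 0L & state$A == 0L)
  if (length(gone)) {
    events$done <- ev(gone[state$fate[gone] == 1L], "apoptosis_complete")
    events$coll <- ev(gone[state$fate[gone] == 0L], "extrusion")
    drop_cell_record(state, gone)
  }

  out <- dplyr::bind_rows(events)
  if (!nrow(out))
    out <- tibble(cell_id = integer(), type = type_label(integer()),
                  event = character())
  attr(out, "metrics") <- tibble::new_tibble(
    list(cell_id = as.integer(names(rho)), rho = unname(rho),
         het_frac = unname(het)), nrow = length(rho))
  out
}
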