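#' Scenario configuration
#'
#' Bundles everything a run needs: lattice geometry, model parameters,
#' seeding, duration and the RNG seed. Defaults mirror the reference
#' experimental field of view: a 1600 x 1200 px lattice of 0.33 um pixels
#' (528 x 396 um), 10 Monte Carlo steps per 4-minute frame.
#'
#' @param width,height lattice size in pixels.
#' @param pixel_size um per pixel side.
#' @param params a [sim_params()] object.
#' @param seeding a [seeding_spec()].
#' @param duration_frames run length in frames (4 min each by default);
#'   alternatively give `duration_hours`.
#' @param duration_hours convenience alternative to `duration_frames`.
#' @param mcs_per_frame Monte Carlo steps per frame.
#' @param frame_minutes physical duration of one frame.
#' @param seed RNG seed; every source of randomness in the run derives
#'   from it, and it is recorded in the trajectory header.
#' @param record_snapshots `NULL`, or an integer n to keep a copy of the
#'   label grid every n frames.
#' @return list of class `cc_config`.
#' @export
scenario_config <- function(width = 1600, height = 1200, pixel_size = 0.33,
                            params = default_params(),
                            seeding = seeding_spec(),
                            duration_frames = NULL, duration_hours = NULL,
                            mcs_per_frame = 10, frame_minutes = 4,
                            seed = 1, record_snapshots = NULL) {
  if (is.null(duration_frames)) {
    if (is.null(duration_hours)) duration_hours <- 80
    duration_frames <- as.integer(round(duration_hours * 60 / frame_minutes))
  }
  stopifnot(duration_frames >= 0, mcs_per_frame >= 1, frame_minutes > 0,
            inherits(params, "cc_params"), inherits(seeding, "cc_seeding"))
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_size = pixel_size, params = params, seeding = seeding,
                 duration_frames = as.integer(duration_frames),
                 mcs_per_frame = as.integer(mcs_per_frame),
                 frame_minutes = frame_minutes, seed = as.integer(seed),
                 record_snapshots = record_snapshots),
            class = "cc_config")
}

#' Convert frames to hours
#' @param frames frame indices.
#' @param frame_minutes minutes per frame.
#' @return hours.
#' @export
frames_to_hours <- function(frames, frame_minutes = 4) frames * frame_minutes / 60

new_trajectory <- function(header, cells, snapshots = list()) {
  structure(list(header = header, cells = cells, snapshots = snapshots),
            class = "cc_trajectory")
}

#' @export
print.cc_trajectory <- function(x, ...) {
  nf <- length(unique(x$cells$frame))
  cat(sprintf("<cc_trajectory> %d frames (%.1f h), %d cell-frame rows, seed %s\n",
              nf, frames_to_hours(max(x$cells$frame, 0), x$header$frame_minutes),
              nrow(x$cells), x$header$seed))
  invisible(x)
}

# one logged row per cell present this frame, plus terminal rows for cells
# removed during the frame's decision pass
log_frame <- function(state, events, metrics) {
  ids <- present_ids(state)
  cent <- cpp_centroids(state$labels, length(state$A))
  x <- (cent$sum_x / pmax(cent$n, 1L)) * state$pixel_size
  y <- (cent$sum_y / pmax(cent$n, 1L)) * state$pixel_size
  n <- length(ids)
  rows <- tibble::new_tibble(list(
    frame = rep.int(state$frame, n),
    cell_id = ids,
    type = type_label(state$typ[ids]),
    x = x[ids], y = y[ids],
    area = state$A[ids],
    target_area = state$AT[ids],
    rho = rep.int(NA_real_, n), het_frac = rep.int(NA_real_, n),
    fate = ifelse(state$fate[ids] == 1L, "apoptosing", "alive"),
    event = rep.int("none", n),
    parent_id = state$parent[ids],
    birth_frame = state$birth[ids]), nrow = n)
  if (!is.null(metrics) && nrow(metrics)) {
    m <- match(metrics$cell_id, rows$cell_id)
    ok <- !is.na(m)
    rows$rho[m[ok]] <- metrics$rho[ok]
    rows$het_frac[m[ok]] <- metrics$het_frac[ok]
  }
  if (!is.null(events) && nrow(events)) {
    m <- match(events$cell_id, rows$cell_id)
    ok <- !is.na(m)
    rows$event[m[ok]] <- events$event[ok]
    # terminal rows: cells no longer on the lattice
    term <- events[is.na(m), ]
    if (nrow(term)) {
      rows <- dplyr::bind_rows(rows, tibble(
        frame = state$frame, cell_id = term$cell_id, type = term$type,
        x = NA_real_, y = NA_real_, area = 0L, target_area = 0,
        rho = NA_real_, het_frac = NA_real_,
        fate = ifelse(term$event == "apoptosis_complete", "apoptosing", "alive"),
        event = term$event, parent_id = NA_integer_,
        birth_frame = NA_integer_))
    }
  }
  rows
}

#' Run a simulation
#'
#' Alternates `mcs_per_frame` Monte Carlo steps of the lattice model with
#' one automaton [decision_pass()] per frame, recording per-frame per-cell
#' state and the event log. Identical configurations and seeds give
#' identical trajectories.
#'
#' @param config a [scenario_config()].
#' @param state optionally, a pre-built `cc_state` to continue from
#'   (seeding is then skipped; the RNG seed is still applied).
#' @param quiet suppress the per-run progress message.
#' @param until optional early-stop predicate, a function of the state
#'   evaluated after each frame (e.g. loser extinction); the trajectory
#'   then ends at the stopping frame.
#' @return a `cc_trajectory`.
#' @export
run_simulation <- function(config, state = NULL, quiet = TRUE, until = NULL) {
  stopifnot(inherits(config, "cc_config"))
  set.seed(config$seed)
  if (is.null(state))
    state <- seed_lattice(config$seeding, config$width, config$height,
                          config$pixel_size, config$params)
  header <- list(
    format = "epicompete/trajectory", version = 1L,
    package = as.character(packageVersion("epicompete")),
    seed = config$seed, width = state$width, height = state$height,
    pixel_size = state$pixel_size, mcs_per_frame = config$mcs_per_frame,
    frame_minutes = config$frame_minutes,
    seeding = unclass(config$seeding),
    params = serialize_params(state$params))
  snaps <- list()
  keep_snap <- function() {
    if (!is.null(config$record_snapshots) &&
        state$frame %% config$record_snapshots == 0L)
      snaps[[as.character(state$frame)]] <<- state$labels + 0L
  }
  # frame 0: seeded state with its metrics
  graph0 <- build_neighbor_graph(state)
  m0 <- if (nrow(graph0$nodes)) {
    d <- local_density(graph0, definition = state$params$density_definition)
    h <- heterotypic_fraction(graph0, denominator = state$params$het_denominator)
    dplyr::left_join(d[c("cell_id", "rho")], h, by = "cell_id")
  } else NULL
  rows <- vector("list", config$duration_frames + 1L)
  rows[[1]] <- log_frame(state, NULL, m0)
  keep_snap()
  for (f in seq_len(config$duration_frames)) {
    monte_carlo_step(state, config$mcs_per_frame)
    state$frame <- f
    events <- decision_pass(state)
    rows[[f + 1L]] <- log_frame(state, events, attr(events, "metrics"))
    keep_snap()
    if (!quiet && f %% 75L == 0L)
      message(sprintf("frame %d/%d (%.1f h): %d cells", f,
                      config$duration_frames, frames_to_hours(f, config$frame_minutes),
                      length(present_ids(state))))
    if (!is.null(until) && isTRUE(until(state))) break
  }
  traj <- new_trajectory(header, dplyr::bind_rows(rows), snaps)
  attr(traj, "final_state") <- state
  traj
}

serialize_params <- function(p) {
  if (is.list(p)) lapply(unclass(p), serialize_params)
  else if (!is.null(names(p))) as.list(p)   # keep type names in JSON
  else p
}
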