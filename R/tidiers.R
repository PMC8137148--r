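#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trajectory into its per-frame per-cell table
#'
#' @param x a `cc_trajectory`.
#' @param ... unused.
#' @return tibble with one row per cell per frame (`frame`, `time_h`,
#'   `cell_id`, `type`, centroid `x`/`y` in um, `area`, `target_area`,
#'   `rho`, `het_frac`, `fate`, `event`, `parent_id`).
#' @export
tidy.cc_trajectory <- function(x, ...) {
  out <- x$cells
  out$time_h <- frames_to_hours(out$frame, x$header$frame_minutes)
  dplyr::relocate(out, "frame", "time_h")
}

#' One-row summary of a trajectory
#'
#' @param x a `cc_trajectory`.
#' @param ... unused.
#' @return tibble with run length, initial/final counts per type,
#'   cumulative event totals and final normalised counts.
#' @export
glance.cc_trajectory <- function(x, ...) {
  ps <- population_summary(x)
  last <- ps[ps$frame == max(ps$frame), ]
  first <- ps[ps$frame == 0, ]
  tibble(
    frames = max(ps$frame),
    hours = max(ps$time_h),
    n_initial_winner = first$n_cells[first$type == "winner"],
    n_initial_loser = first$n_cells[first$type == "loser"],
    n_final_winner = last$n_cells[last$type == "winner"],
    n_final_loser = last$n_cells[last$type == "loser"],
    norm_count_winner = last$norm_count[last$type == "winner"],
    norm_count_loser = last$norm_count[last$type == "loser"],
    divisions = sum(last$cum_divisions),
    apoptoses = sum(last$cum_apoptoses),
    extrusions = sum(last$cum_extrusions),
    seed = x$header$seed)
}

#' Birth-to-division intervals of a trajectory
#'
#' One row per completed cell cycle: for every division event, the
#' interval between the dividing cell's recorded birth and the division.
#' Cells already present at seeding start with an unknown (uniform) cycle
#' phase, so their first division is excluded unless `include_seeded`.
#'
#' @param trajectory a `cc_trajectory`.
#' @param include_seeded keep cycles of the seeded founder cells.
#' @return tibble (`frame`, `time_h`, `parent_id`, `interval_frames`,
#'   `interval_h`, `type`).
#' @export
division_intervals <- function(trajectory, include_seeded = FALSE) {
  d <- trajectory$cells
  divs <- d[d$event == "division" & !is.na(d$parent_id), ]
  prev <- d[d$event != "division", c("frame", "cell_id", "birth_frame")]
  m <- match(paste(divs$parent_id, divs$frame - 1L),
             paste(prev$cell_id, prev$frame))
  out <- tibble(frame = divs$frame,
                time_h = frames_to_hours(divs$frame,
                                         trajectory$header$frame_minutes),
                parent_id = divs$parent_id,
                birth_frame = prev$birth_frame[m],
                interval_frames = divs$frame - prev$birth_frame[m],
                type = divs$type)
  out$interval_h <- frames_to_hours(out$interval_frames,
                                    trajectory$header$frame_minutes)
  out <- out[!is.na(out$interval_frames), ]
  if (!include_seeded) out <- out[out$birth_frame > 0L, ]
  out
}

#' Centroid tracks of a trajectory
#'
#' Convenience accessor for [msd()]: the (`cell_id`, `frame`, `x`, `y`)
#' columns of live-cell rows.
#'
#' @param trajectory a `cc_trajectory`.
#' @return tibble.
#' @export
cell_tracks <- function(trajectory) {
  d <- trajectory$cells
  d <- d[d$fate == "alive" & !is.na(d$x), c("cell_id", "frame", "x", "y")]
  as_tibble(d)
}
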