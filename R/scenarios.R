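#' Stretch-release homeostasis protocol
#'
#' Reproduces the classic stretch-release experiment in silico: a pure
#' winner population grows to its homeostatic density plateau; at t = 0
#' the cell density is instantaneously increased by `crowding_increase` by
#' remapping the confluent configuration onto a lattice shrunk by
#' `1 / (1 + crowding_increase)` along one axis (cell identities and
#' neighbour topology preserved, subsampled rows dropped); the relaxation
#' phase then records the return to the pre-perturbation plateau through
#' extrusions and density-mediated apoptoses.
#'
#' The plateau is detected on the cell count: the trailing
#' `plateau_window` frames of phase 1 must vary by less than
#' `plateau_tol` (relative range); otherwise the protocol errors.
#'
#' @param config a [scenario_config()]; its duration is the phase-1
#'   (growth) duration.
#' @param crowding_increase fractional density step (0.30 reproduces the
#'   reference perturbation).
#' @param relax_hours duration of the recorded relaxation phase.
#' @param plateau_window frames used to check for a plateau.
#' @param plateau_tol maximum relative range of the count over the window.
#' @return list of class `cc_stretch_release`: `growth` and `relax`
#'   trajectories, `plateau_density` (cells/um^2, pre-perturbation),
#'   `density` (tibble of cell density vs time across the step), and
#'   `recovery_h` (first time after the step at which density re-enters
#'   the `recovery_band` around the plateau).
#' @param recovery_band relative band around the plateau density that
#'   counts as recovered.
#' @export
stretch_release_protocol <- function(config, crowding_increase = 0.30,
                                     relax_hours = 20,
                                     plateau_window = 120,
                                     plateau_tol = 0.15,
                                     recovery_band = 0.05) {
  stopifnot(crowding_increase >= 0)
  growth <- run_simulation(config)
  state <- attr(growth, "final_state")
  ps <- population_summary(growth)
  ps <- ps[ps$type == "winner", ]
  wnd <- tail(ps$n_cells, plateau_window)
  if (length(wnd) < plateau_window ||
      (max(wnd) - min(wnd)) / max(mean(wnd), 1) > plateau_tol)
    abort("phase 1 did not reach a density plateau; extend the growth duration")
  area_um2 <- state$width * state$height * state$pixel_size^2
  # estimate from the most recent stretch: a long window would lag any
  # residual upward drift and bias the recovery band low
  plateau_density <- stats::median(tail(wnd, 75)) / area_um2

  # instantaneous density step: remap onto a lattice shrunk in y
  new_h <- as.integer(round(state$height / (1 + crowding_increase)))
  keep_rows <- unique(pmin(state$height,
                           as.integer(round((seq_len(new_h) - 0.5) *
                                            state$height / new_h + 0.5))))
  new_labels <- state$labels[keep_rows, , drop = FALSE]
  state2 <- new_state(ncol(new_labels), nrow(new_labels), state$pixel_size,
                      state$params)
  state2$labels <- new_labels
  for (f in c("typ", "A", "AT", "lam", "added", "dA_div", "birth", "fate",
              "parent", "pol"))
    state2[[f]] <- state[[f]]
  state2$next_id <- state$next_id
  tab <- tabulate(new_labels[new_labels > 0L], nbins = length(state2$A))
  lost <- present_ids(state2)[tab[present_ids(state2)] == 0L]
  state2$A <- as.integer(tab)
  if (length(lost)) drop_cell_record(state2, lost)
  state2$frame <- 0L

  relax_cfg <- scenario_config(
    width = state2$width, height = state2$height,
    pixel_size = state$pixel_size, params = state$params,
    seeding = config$seeding,
    duration_hours = relax_hours, mcs_per_frame = config$mcs_per_frame,
    frame_minutes = config$frame_minutes, seed = config$seed + 1L)
  relax <- run_simulation(relax_cfg, state = state2)

  area2 <- state2$width * state2$height * state2$pixel_size^2
  pr <- population_summary(relax)
  pr <- pr[pr$type == "winner", ]
  dens <- dplyr::bind_rows(
    tibble(time_h = ps$time_h - max(ps$time_h), density = ps$n_cells / area_um2,
           phase = "growth"),
    tibble(time_h = pr$time_h, density = pr$n_cells / area2, phase = "relax"))
  in_band <- abs(pr$n_cells / area2 - plateau_density) <=
    recovery_band * plateau_density
  recovery_h <- if (any(in_band)) min(pr$time_h[in_band]) else NA_real_
  structure(list(growth = growth, relax = relax,
                 plateau_density = plateau_density,
                 crowding_increase = crowding_increase,
                 density = dens, recovery_h = recovery_h),
            class = "cc_stretch_release")
}

#' @export
print.cc_stretch_release <- function(x, ...) {
  cat(sprintf("<cc_stretch_release> +%.0f%% step; plateau %.4g cells/um^2; recovery %.2f h\n",
              100 * x$crowding_increase, x$plateau_density, x$recovery_h))
  invisible(x)
}

# first time at which the loser count reaches 0 / falls to half its peak
elimination_times <- function(summary_tbl, cap_h = Inf) {
  los <- summary_tbl[summary_tbl$type == "loser", ]
  t_elim <- if (any(los$n_cells == 0)) min(los$time_h[los$n_cells == 0]) else NA_real_
  if (is.na(t_elim) && is.finite(cap_h)) t_elim <- cap_h
  peak <- max(los$n_cells)
  half <- los$time_h[los$n_cells <= peak / 2 & los$time_h >= los$time_h[which.max(los$n_cells)]]
  t_half <- if (length(half)) min(half) else NA_real_
  tibble(time_to_elimination_h = t_elim,
         time_to_half_h = t_half, peak_losers = peak)
}

#' Parameter sweep over competition outcomes
#'
#' Runs replicate competition simulations across values of one model
#' parameter and tabulates the outcome measures used to characterise
#' mechanical competition: loser survival fraction at a reference time
#' (default 80 h), time to 50% loser elimination (first time at or below
#' half the peak loser count -- the peak, not the initial count, because
#' loser counts rise before falling), time to elimination, and final
#' normalised counts.
#'
#' @param config base [scenario_config()].
#' @param parameter one of `"k_winner"` (contact-inhibition sensitivity of
#'   winners), `"Lambda"` (stiffness ratio loser/winner, winner fixed),
#'   `"S_loser"` (biochemical steepness), `"J_heterotypic"`, `"G_loser"`.
#' @param values parameter values to sweep.
#' @param replicates replicate runs per value.
#' @param survival_at_h reference time for the survival fraction.
#' @return tibble of class `cc_sweep`, one row per (value, replicate).
#' @export
parameter_sweep <- function(config, parameter = c("k_winner", "Lambda",
                                                  "S_loser", "J_heterotypic",
                                                  "G_loser"),
                            values, replicates = 3, survival_at_h = 80) {
  parameter <- match.arg(parameter)
  stopifnot(all(is.finite(values)), replicates >= 1)
  out <- list()
  for (i in seq_along(values)) {
    cfg <- apply_sweep_value(config, parameter, values[i])
    for (r in seq_len(replicates)) {
      cfg$seed <- config$seed + 1000L * (i - 1L) + r
      traj <- run_simulation(cfg)
      ps <- population_summary(traj)
      los <- ps[ps$type == "loser", ]
      ref <- los[which.min(abs(los$time_h - survival_at_h)), ]
      el <- elimination_times(ps)
      out[[length(out) + 1L]] <- tibble(
        parameter = parameter, value = values[i], replicate = r,
        seed = cfg$seed,
        survival_fraction = ref$n_cells / max(los$n_cells[los$frame == 0], 1),
        norm_count_final = tail(los$norm_count, 1),
        time_to_half_h = el$time_to_half_h,
        time_to_elimination_h = el$time_to_elimination_h,
        peak_losers = el$peak_losers)
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("cc_sweep", class(res))
  res
}

apply_sweep_value <- function(config, parameter, value) {
  p <- config$params
  en <- p$energy; gr <- p$growth; ap <- p$apoptosis
  if (parameter == "k_winner") gr$k[["winner"]] <- value
  if (parameter == "Lambda") en$lambda[["loser"]] <- value * en$lambda[["winner"]]
  if (parameter == "S_loser") ap$bio_S[["loser"]] <- value
  if (parameter == "J_heterotypic") en$J_heterotypic <- value
  if (parameter == "G_loser") gr$G[["loser"]] <- value
  p$energy <- en; p$growth <- gr; p$apoptosis <- ap
  config$params <- p
  config
}

#' Colony-size dependence of biochemical elimination
#'
#' Embeds one loser colony of each requested size in a winner population
#' (single-colony seeding) under a biochemical-competition parameter set
#' and records the time to elimination (first frame with zero losers;
#' capped at the run duration). Optionally fits the decreasing trend of
#' elimination time vs colony size... the canonical summary is the raw
#' table; an exponential fit `A * exp(-t / tau)` of colony size vs time is
#' returned when `fit = TRUE` and the fit converges.
#'
#' @param config base [scenario_config()] with biochemical apoptosis
#'   configured.
#' @param colony_sizes integer loser colony sizes (0 = winners-only
#'   control, which records no elimination).
#' @param fit attempt the exponential fit.
#' @return tibble (`colony_size`, `seed`, `time_to_elimination_h`,
#'   `eliminated`), with the fit (if any) as attribute `"fit"`.
#' @export
colony_size_experiment <- function(config, colony_sizes, fit = FALSE) {
  stopifnot(config$params$apoptosis$mode %in% c("biochemical", "both"))
  out <- list()
  for (i in seq_along(colony_sizes)) {
    cs <- colony_sizes[i]
    n_total <- seed_cell_count(config$seeding$total_density, config$width,
                               config$height, config$pixel_size)
    if (cs > n_total)
      abort("colony larger than the field supports at this density")
    cfg <- config
    cfg$seeding <- seeding_spec(mode = "single_colony",
                                total_density = config$seeding$total_density,
                                colony_size = cs,
                                gap_px = config$seeding$gap_px)
    cfg$seed <- config$seed + i
    traj <- run_simulation(cfg)
    ps <- population_summary(traj)
    los <- ps[ps$type == "loser", ]
    t_e <- if (cs == 0) NA_real_
           else if (any(los$n_cells == 0)) min(los$time_h[los$n_cells == 0])
           else max(los$time_h)
    out[[i]] <- tibble(colony_size = cs, seed = cfg$seed,
                       time_to_elimination_h = t_e,
                       eliminated = isTRUE(cs > 0 && any(los$n_cells == 0)))
  }
  res <- dplyr::bind_rows(out)
  if (fit && sum(res$eliminated) >= 3) {
    d <- res[res$eliminated, ]
    f <- tryCatch(nls(colony_size ~ A * exp(-time_to_elimination_h / tau),
                      data = d,
                      start = list(A = max(d$colony_size) * 2, tau = 60)),
                  error = function(e) NULL)
    attr(res, "fit") <- f
  }
  res
}
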