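#' Lattice simulation state
#'
#' A `cc_state` is a mutable environment wrapping the integer label grid
#' (0 = free space, otherwise a cell id) together with per-cell record
#' vectors indexed by id: cell type, actual area `A` (always equal to the
#' cell's pixel count), target area `A_T`, area-expansion modulus, adder
#' progress, polarity angle, fate and lineage. It is created by
#' [seed_lattice()] (or [new_state()] for hand-built fixtures) and advanced
#' by [monte_carlo_step()] and [decision_pass()].
#'
#' Coordinates: the grid is a matrix with `height` rows and `width`
#' columns; x runs rightward along columns, y downward along rows, pixel
#' centres at half-integers, and centroids are reported in micrometres from
#' the top-left corner.
#'
#' @param width,height lattice size in pixels.
#' @param pixel_size physical size of a pixel side in micrometres.
#' @param params a [sim_params()] object.
#' @return an environment of class `cc_state`.
#' @export
new_state <- function(width, height, pixel_size = 0.33,
                      params = default_params()) {
  stopifnot(width >= 1, height >= 1, pixel_size > 0,
            inherits(params, "cc_params"))
  s <- new.env(parent = emptyenv())
  s$labels <- matrix(0L, nrow = height, ncol = width)
  s$width <- as.integer(width)
  s$height <- as.integer(height)
  s$pixel_size <- pixel_size
  s$params <- params
  s$J <- j_matrix(params$energy)
  s$frame <- 0L
  n0 <- 64L
  s$typ <- integer(n0)        # 0 = unused slot
  s$A <- integer(n0)
  s$AT <- numeric(n0)
  s$lam <- numeric(n0)
  s$added <- numeric(n0)
  s$dA_div <- numeric(n0)
  s$birth <- integer(n0)
  s$fate <- integer(n0)       # 0 live, 1 apoptosing
  s$parent <- integer(n0)
  s$pol <- numeric(n0)
  s$next_id <- 1L
  s$attempts <- 0
  s$accepts <- 0
  s$dh_sum <- 0
  class(s) <- "cc_state"
  s
}

#' @export
print.cc_state <- function(x, ...) {
  n <- sum(x$typ > 0L)
  cat(sprintf("<cc_state> %d x %d px (%.0f x %.0f um), frame %d, %d cells (%d winner, %d loser, %d apoptosing)\n",
              x$width, x$height, x$width * x$pixel_size,
              x$height * x$pixel_size, x$frame, n,
              sum(x$typ == 1L & x$fate == 0L),
              sum(x$typ == 2L & x$fate == 0L),
              sum(x$typ > 0L & x$fate == 1L)))
  invisible(x)
}

ensure_capacity <- function(s, n) {
  cap <- length(s$typ)
  if (n <= cap) return(invisible(s))
  new_cap <- max(n, 2L * cap)
  grow <- function(v) { length(v) <- new_cap; v[is.na(v)] <- 0; v }
  for (f in c("A", "typ", "birth", "fate", "parent"))
    s[[f]] <- { v <- s[[f]]; length(v) <- new_cap; v[is.na(v)] <- 0L; v }
  for (f in c("AT", "lam", "added", "dA_div", "pol")) s[[f]] <- grow(s[[f]])
  invisible(s)
}

# Register a cell record; pixels must already be (or be about to be)
# painted by the caller, which is responsible for keeping A consistent.
add_cell_record <- function(s, type, A, AT, added, dA_div, parent = 0L,
                            pol = runif(1, 0, 2 * pi)) {
  id <- s$next_id
  ensure_capacity(s, id)
  s$next_id <- id + 1L
  s$typ[id] <- as.integer(type)
  s$A[id] <- as.integer(A)
  s$AT[id] <- AT
  s$lam[id] <- s$params$energy$lambda[[type]]
  s$added[id] <- added
  s$dA_div[id] <- dA_div
  s$birth[id] <- s$frame
  s$fate[id] <- 0L
  s$parent[id] <- as.integer(parent)
  s$pol[id] <- pol
  id
}

drop_cell_record <- function(s, ids) {
  s$typ[ids] <- 0L
  s$fate[ids] <- 0L
  s$A[ids] <- 0L
  invisible(s)
}

live_ids <- function(s) which(s$typ > 0L & s$fate == 0L)
present_ids <- function(s) which(s$typ > 0L)

#' Snapshot of the per-cell records as a tibble
#'
#' @param state a `cc_state`.
#' @return tibble with one row per live or apoptosing cell.
#' @export
cell_table <- function(state) {
  ids <- present_ids(state)
  tibble(
    cell_id = ids,
    type = type_label(state$typ[ids]),
    area = state$A[ids],
    target_area = state$AT[ids],
    lambda = state$lam[ids],
    added = state$added[ids],
    div_threshold = state$dA_div[ids],
    birth_frame = state$birth[ids],
    fate = factor(ifelse(state$fate[ids] == 1L, "apoptosing", "alive"),
                  levels = c("alive", "apoptosing")),
    parent_id = state$parent[ids],
    pol_angle = state$pol[ids])
}

# verify the area bookkeeping invariant (A equals the pixel count of every
# label); used by total_energy() and the test-suite
check_state_integrity <- function(s) {
  tab <- tabulate(s$labels[s$labels > 0L], nbins = length(s$A))
  ids <- present_ids(s)
  bad <- ids[tab[ids] != s$A[ids]]
  stray <- setdiff(which(tab > 0L), ids)
  if (length(bad) || length(stray))
    abort(sprintf(
      "lattice/cell bookkeeping is inconsistent (cells: %s; stray labels: %s)",
      paste(head(bad, 5), collapse = ","),
      paste(head(stray, 5), collapse = ",")))
  invisible(TRUE)
}

#' Seeding specification
#'
#' Describes the initial condition of a simulated field of view. Cells are
#' placed as non-overlapping squares separated by free space, with cell
#' cycle phase initialised uniformly: each seed draws a birth target area
#' and an adder threshold, plus a uniform adder progress, mimicking a
#' uniform probability of being at any cycle stage.
#'
#' @param mode seeding geometry: `"pure"` (single type), `"mixed"` (types
#'   interspersed at random positions), `"partially_sorted"` (losers
#'   grouped into circular colonies on a jittered grid), `"fully_sorted"`
#'   (losers on the left of the field, winners on the right),
#'   `"single_colony"` (one loser colony of `colony_size` cells embedded
#'   in winners).
#' @param loser_fraction fraction of seeded cells of the loser type
#'   (ignored for `"single_colony"`, where `colony_size` is absolute).
#' @param total_density seeded cells per 100 um^2 (the experimental
#'   seeding density is 0.07).
#' @param colony_count number of loser colonies for `"partially_sorted"`.
#' @param colony_size loser-colony cell count for `"single_colony"`.
#' @param gap_px minimum free-space gap between seeded cells, pixels.
#' @return list of class `cc_seeding`.
#' @export
seeding_spec <- function(mode = c("pure", "mixed", "partially_sorted",
                                  "fully_sorted", "single_colony"),
                         loser_fraction = 0,
                         total_density = 0.07,
                         colony_count = 3,
                         colony_size = 10,
                         gap_px = 2) {
  mode <- match.arg(mode)
  stopifnot(loser_fraction >= 0, loser_fraction <= 1, total_density > 0,
            colony_count >= 1, colony_size >= 0, gap_px >= 0)
  structure(list(mode = mode, loser_fraction = loser_fraction,
                 total_density = total_density, colony_count = colony_count,
                 colony_size = colony_size, gap_px = gap_px),
            class = "cc_seeding")
}

#' Number of cells implied by a seeding density
#'
#' @param total_density cells per 100 um^2.
#' @param width,height lattice size, pixels.
#' @param pixel_size um per pixel side.
#' @return integer cell count (`round(density * area)`).
#' @export
seed_cell_count <- function(total_density, width, height, pixel_size = 0.33) {
  area_um2 <- width * height * pixel_size^2
  as.integer(round(total_density / 100 * area_um2))
}

#' Seed a lattice
#'
#' Places `seed_cell_count()` cells according to the seeding specification
#' and returns a ready-to-run [new_state()]. Cells are initially separated
#' by free space. Loser counts in mixed mode use `round(loser_fraction *
#' n)`.
#'
#' @param spec a [seeding_spec()].
#' @param width,height lattice size in pixels.
#' @param pixel_size um per pixel side.
#' @param params a [sim_params()] object.
#' @return a `cc_state`.
#' @export
seed_lattice <- function(spec, width, height, pixel_size = 0.33,
                         params = default_params()) {
  stopifnot(inherits(spec, "cc_seeding"))
  s <- new_state(width, height, pixel_size, params)
  n <- seed_cell_count(spec$total_density, width, height, pixel_size)
  if (spec$mode == "single_colony") {
    n_losers <- as.integer(spec$colony_size)
    n_winners <- max(0L, n - n_losers)
  } else if (spec$mode == "pure") {
    n_losers <- if (spec$loser_fraction >= 0.5) n else 0L
    n_winners <- n - n_losers
  } else {
    n_losers <- as.integer(round(spec$loser_fraction * n))
    n_winners <- n - n_losers
  }
  if (n_winners + n_losers == 0L) return(s)

  types <- c(rep(1L, n_winners), rep(2L, n_losers))
  if (spec$mode == "mixed") types <- sample(types)
  g <- params$growth
  AT0 <- rtrunc_norm(length(types), g$AT0[types], g$AT0_cv, lower = 25)
  dA <- rtrunc_norm(length(types), g$dA_tot[types], g$dA_tot_cv, lower = 25)
  phase <- runif(length(types))
  AT_seed <- AT0 + phase * dA
  side <- pmax(2L, as.integer(round(sqrt(AT_seed))))

  pos <- switch(spec$mode,
    pure = ,
    mixed = place_random(s, side, spec$gap_px),
    fully_sorted = place_sorted(s, side, types, spec$gap_px),
    partially_sorted = place_colonies(s, side, types, spec$colony_count,
                                      spec$gap_px),
    single_colony = place_colonies(s, side, types, 1L, spec$gap_px))

  for (i in seq_along(types)) {
    id <- add_cell_record(s, types[i], A = 0L, AT = AT_seed[i],
                          added = phase[i] * dA[i], dA_div = dA[i])
    paint_square(s, id, pos$row[i], pos$col[i], side[i])
  }
  # colony modes may paint adjacent squares over one another at clamped
  # borders; recount pixel areas and cull any fully overwritten record
  tab <- tabulate(s$labels[s$labels > 0L], nbins = length(s$A))
  ids <- present_ids(s)
  s$A[ids] <- tab[ids]
  drop_cell_record(s, ids[tab[ids] == 0L])
  check_state_integrity(s)
  s
}

paint_square <- function(s, id, r0, c0, side) {
  rows <- r0:min(s$height, r0 + side - 1L)
  cols <- c0:min(s$width, c0 + side - 1L)
  s$labels[rows, cols] <- id
  s$A[id] <- length(rows) * length(cols)
  invisible(s)
}

# rejection-sample non-overlapping axis-aligned squares with a gap; at
# packing fractions where rejection stalls, fall back to a jittered grid
place_random <- function(s, side, gap, region = NULL) {
  n <- length(side)
  rows <- integer(n); cols <- integer(n)
  r_lo <- 1L; r_hi <- s$height; c_lo <- 1L; c_hi <- s$width
  if (!is.null(region)) { c_lo <- region[1]; c_hi <- region[2] }
  placed <- matrix(0, 0, 4) # r0, c0, r1, c1
  for (i in order(side, decreasing = TRUE)) {
    ok <- FALSE
    for (try in seq_len(2000)) {
      r0 <- sample.int(max(1L, r_hi - side[i]), 1L) + r_lo - 1L
      c0 <- sample.int(max(1L, c_hi - c_lo + 1L - side[i]), 1L) + c_lo - 1L
      r1 <- r0 + side[i] - 1L; c1 <- c0 + side[i] - 1L
      if (nrow(placed) == 0 ||
          all(r0 > placed[, 3] + gap | r1 < placed[, 1] - gap |
              c0 > placed[, 4] + gap | c1 < placed[, 2] - gap)) {
        ok <- TRUE; break
      }
    }
    if (!ok) return(place_grid(s, side, gap, region))
    placed <- rbind(placed, c(r0, c0, r1, c1))
    rows[i] <- r0; cols[i] <- c0
  }
  list(row = rows, col = cols)
}

# shelf-packing fallback for dense seedings: cells sorted by size fill
# rows left to right, keeping the configured gap; positions stay tied to
# the caller's cell order so type assignment is unaffected
place_grid <- function(s, side, gap, region = NULL) {
  n <- length(side)
  c_lo <- 1L; c_hi <- s$width
  if (!is.null(region)) { c_lo <- region[1]; c_hi <- region[2] }
  rows <- integer(n); cols <- integer(n)
  r_cur <- 1L; c_cur <- c_lo; shelf_h <- 0L
  for (i in order(side, decreasing = TRUE)) {
    if (c_cur + side[i] - 1L > c_hi) {      # next shelf
      r_cur <- r_cur + shelf_h + gap + 1L
      c_cur <- c_lo
      shelf_h <- 0L
    }
    if (r_cur + side[i] - 1L > s$height)
      abort("infeasible packing: could not place all seed cells")
    rows[i] <- r_cur; cols[i] <- c_cur
    c_cur <- c_cur + side[i] + gap + 1L
    shelf_h <- max(shelf_h, side[i])
  }
  list(row = rows, col = cols)
}

# losers on the left of the field, winners on the right, split
# proportionally to the loser cell fraction
place_sorted <- function(s, side, types, gap) {
  frac <- mean(types == 2L)
  split_col <- as.integer(round(s$width * frac))
  rows <- integer(length(side)); cols <- integer(length(side))
  il <- which(types == 2L); iw <- which(types == 1L)
  if (length(il)) {
    p <- place_random(s, side[il], gap, region = c(1L, max(split_col, max(side[il]) + 1L)))
    rows[il] <- p$row; cols[il] <- p$col
  }
  if (length(iw)) {
    p <- place_random(s, side[iw], gap, region = c(split_col + 1L, s$width))
    rows[iw] <- p$row; cols[iw] <- p$col
  }
  list(row = rows, col = cols)
}

# circular loser colonies on a jittered grid; winners random elsewhere.
# within a colony the cells sit on a compact local grid (gap 1 px).
place_colonies <- function(s, side, types, n_colonies, gap) {
  il <- which(types == 2L); iw <- which(types == 1L)
  rows <- integer(length(side)); cols <- integer(length(side))
  occupied <- matrix(0, 0, 4)
  if (length(il)) {
    per <- split(il, rep(seq_len(n_colonies), length.out = length(il)))
    gx <- ceiling(sqrt(n_colonies)); gy <- ceiling(n_colonies / gx)
    centers_c <- (seq_len(gx) - 0.5) / gx * s$width
    centers_r <- (seq_len(gy) - 0.5) / gy * s$height
    grid <- expand.grid(r = centers_r, c = centers_c)[seq_len(n_colonies), ]
    jit_r <- runif(n_colonies, -0.08, 0.08) * s$height
    jit_c <- runif(n_colonies, -0.08, 0.08) * s$width
    for (k in seq_len(n_colonies)) {
      members <- per[[k]]
      m <- length(members)
      ncol_local <- ceiling(sqrt(m))
      pitch <- max(side[members]) + 1L
      span <- ncol_local * pitch
      r_base <- as.integer(round(grid$r[k] + jit_r[k] - span / 2))
      c_base <- as.integer(round(grid$c[k] + jit_c[k] - span / 2))
      for (j in seq_along(members)) {
        i <- members[j]
        rr <- r_base + ((j - 1L) %/% ncol_local) * pitch
        cc <- c_base + ((j - 1L) %% ncol_local) * pitch
        rr <- min(max(1L, rr), s$height - side[i])
        cc <- min(max(1L, cc), s$width - side[i])
        rows[i] <- rr; cols[i] <- cc
        occupied <- rbind(occupied, c(rr, cc, rr + side[i] - 1L, cc + side[i] - 1L))
      }
    }
  }
  for (i in iw) {
    ok <- FALSE
    for (try in seq_len(4000)) {
      r0 <- sample.int(max(1L, s$height - side[i]), 1L)
      c0 <- sample.int(max(1L, s$width - side[i]), 1L)
      r1 <- r0 + side[i] - 1L; c1 <- c0 + side[i] - 1L
      if (nrow(occupied) == 0 ||
          all(r0 > occupied[, 3] + gap | r1 < occupied[, 1] - gap |
              c0 > occupied[, 4] + gap | c1 < occupied[, 2] - gap)) {
        ok <- TRUE; break
      }
    }
    if (!ok) abort("infeasible packing: could not place all seed cells")
    occupied <- rbind(occupied, c(r0, c0, r1, c1))
    rows[i] <- r0; cols[i] <- c0
  }
  list(row = rows, col = cols)
}
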