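#' Build the cell-adjacency graph of a labelled lattice
#'
#' Two cells are neighbours iff they share at least one adjacent pixel
#' pair under the configured adjacency; edges carry the shared boundary
#' length and nodes their total perimeter, both in pixel-pair units (the
#' perimeter includes the boundary against free space and, in fixed-frame
#' mode, the field-of-view walls). The default 4-adjacency counts each
#' boundary step once, which is what perimeter fractions need.
#'
#' @param x a `cc_state`, or a plain integer label matrix (0 = free
#'   space).
#' @param adjacency 4 or 8.
#' @param include_apoptosing keep apoptosing cells as nodes (default
#'   drops them: shrinking corpses have divergent inverse areas).
#' @param cells optional tibble with `cell_id` and `type` columns for
#'   matrix input.
#' @param pixel_size um per pixel for matrix input.
#' @param periodic treat the lattice as periodic for matrix input.
#' @return list of class `cc_graph` with tibbles `nodes` (`cell_id`,
#'   `type`, `area`, `perimeter`) and `edges` (`a`, `b`,
#'   `shared_boundary`).
#' @export
build_neighbor_graph <- function(x, adjacency = NULL,
                                 include_apoptosing = FALSE, cells = NULL,
                                 pixel_size = 0.33, periodic = FALSE) {
  if (inherits(x, "cc_state")) {
    adjacency <- adjacency %||% x$params$graph_adjacency
    labels <- x$labels
    periodic <- x$params$energy$boundary == "periodic"
    pixel_size <- x$pixel_size
    ids <- if (include_apoptosing) present_ids(x) else live_ids(x)
    cells <- tibble(cell_id = ids, type = type_label(x$typ[ids]),
                    area = x$A[ids])
    if (!include_apoptosing && any(x$fate == 1L)) {
      # hide apoptosing labels from the scan so their contacts count as
      # free space
      labels <- labels
      apo <- which(x$fate == 1L & x$typ > 0L)
      labels[labels %in% apo] <- 0L
    }
  } else {
    adjacency <- adjacency %||% 4
    labels <- x
    if (is.null(cells)) {
      ids <- sort(unique(labels[labels > 0L]))
      cells <- tibble(cell_id = as.integer(ids),
                      type = type_label(rep(NA_integer_, length(ids))),
                      area = as.integer(tabulate(labels, nbins = max(ids, 0))[ids]))
    }
  }
  stopifnot(adjacency %in% c(4, 8))
  g <- cpp_neighbor_graph(labels, as.integer(adjacency), periodic)
  keep <- g$edge_a %in% cells$cell_id & g$edge_b %in% cells$cell_id
  edges <- tibble::new_tibble(list(a = g$edge_a[keep], b = g$edge_b[keep],
                                   shared_boundary = g$shared_boundary[keep]),
                              nrow = sum(keep))
  nodes <- cells
  nodes$perimeter <- g$perimeter[nodes$cell_id]
  structure(list(nodes = nodes, edges = edges, adjacency = adjacency,
                 pixel_size = pixel_size),
            class = "cc_graph")
}

#' @export
print.cc_graph <- function(x, ...) {
  cat(sprintf("<cc_graph> %d cells, %d contacts (%d-adjacency)\n",
              nrow(x$nodes), nrow(x$edges), x$adjacency))
  invisible(x)
}

# long view of the edge list: one row per (cell, neighbour)
graph_incidences <- function(graph) {
  e <- graph$edges
  tibble::new_tibble(
    list(cell_id = c(e$a, e$b), neighbor = c(e$b, e$a),
         shared_boundary = c(e$shared_boundary, e$shared_boundary)),
    nrow = 2L * nrow(e))
}

# accumulate `w` over integer groups 1..n (fast rowsum wrapper)
acc_by <- function(w, group, n) {
  out <- numeric(n)
  if (length(group)) {
    ag <- rowsum(w, group)
    out[as.integer(rownames(ag))] <- ag[, 1]
  }
  out
}

#' Local cell density
#'
#' The density around a cell is the sum of the inverse areas of the cell
#' itself and its first neighbours, `rho = 1/A_k + sum_i 1/A_i`, in
#' 1/um^2. The alternative reading `definition = "inverse_total"` (the
#' inverse of the summed area of the cell and its neighbours) is also
#' available. Zero-area cells are excluded with a warning.
#'
#' @param graph a [build_neighbor_graph()] result.
#' @param definition `"sum_inverse"` (default) or `"inverse_total"`.
#' @return tibble (`cell_id`, `n_neighbors`, `rho`).
#' @export
local_density <- function(graph, definition = c("sum_inverse", "inverse_total")) {
  definition <- match.arg(definition)
  nodes <- graph$nodes
  if (any(nodes$area == 0)) {
    warn("zero-area cells excluded from local density")
    nodes <- nodes[nodes$area > 0, ]
  }
  ids <- nodes$cell_id
  n <- length(ids)
  area_um2 <- nodes$area * graph$pixel_size^2
  e <- graph$edges
  ia <- match(e$a, ids); ib <- match(e$b, ids)
  ok <- !is.na(ia) & !is.na(ib)
  ia <- ia[ok]; ib <- ib[ok]
  grp <- c(ia, ib); nb <- c(ib, ia)
  n_nb <- tabulate(grp, nbins = n)
  rho <- if (definition == "sum_inverse")
    1 / area_um2 + acc_by(1 / area_um2[nb], grp, n)
  else
    1 / (area_um2 + acc_by(area_um2[nb], grp, n))
  ord <- order(ids)
  tibble::new_tibble(list(cell_id = ids[ord], n_neighbors = n_nb[ord],
                          rho = rho[ord]), nrow = n)
}

#' Heterotypic perimeter fraction
#'
#' Fraction of a cell's boundary in contact with cells of the other type.
#' By default the denominator is the cell-cell boundary only (free-space
#' boundary excluded), so a sub-confluent loser surrounded by winners
#' still reads p = 1; `denominator = "perimeter"` includes the free-space
#' boundary. Cells with no cell-cell contact get p = 0.
#'
#' @param graph a [build_neighbor_graph()] result (node types required).
#' @param denominator `"cell_cell"` or `"perimeter"`.
#' @return tibble (`cell_id`, `het_frac`).
#' @export
heterotypic_fraction <- function(graph, denominator = c("cell_cell", "perimeter")) {
  denominator <- match.arg(denominator)
  nodes <- graph$nodes
  ids <- nodes$cell_id
  n <- length(ids)
  ty <- as.integer(nodes$type)
  e <- graph$edges
  ia <- match(e$a, ids); ib <- match(e$b, ids)
  ok <- !is.na(ia) & !is.na(ib)
  ia <- ia[ok]; ib <- ib[ok]; w <- e$shared_boundary[ok]
  grp <- c(ia, ib); nb <- c(ib, ia); ww <- c(w, w)
  hetero <- ty[grp] != ty[nb]
  het <- acc_by(ww[hetero], grp[hetero], n)
  den <- if (denominator == "cell_cell") acc_by(ww, grp, n) else nodes$perimeter
  frac <- ifelse(den > 0, het / den, 0)
  tibble::new_tibble(list(cell_id = ids, het_frac = frac), nrow = n)
}

#' Sidedness distribution
#'
#' Normalised histogram of the number of neighbours per cell in the
#' adjacency graph.
#'
#' @param graph a [build_neighbor_graph()] result.
#' @return tibble (`neighbors`, `n_cells`, `fraction`); empty for an
#'   empty graph.
#' @export
sidedness_distribution <- function(graph) {
  if (!nrow(graph$nodes))
    return(tibble(neighbors = integer(), n_cells = integer(),
                  fraction = numeric()))
  inc <- graph_incidences(graph)
  deg <- table(factor(inc$cell_id, levels = graph$nodes$cell_id))
  h <- table(as.integer(deg))
  tibble(neighbors = as.integer(names(h)), n_cells = as.integer(h),
         fraction = as.integer(h) / sum(h))
}

#' Entropy of cell mixing
#'
#' Per cell, the two-state Shannon entropy of the type composition of its
#' neighbourhood, `s = -P1 log P1 - P2 log P2` with P1/P2 the winner and
#' loser fractions among the cell's neighbours (0 log 0 = 0). The tissue
#' value is the mean of s over cells with at least one neighbour, bounded
#' by `[0, log 2]` and invariant under swapping the type labels: 0 for a
#' fully sorted tissue, log 2 for a perfectly mixed one.
#'
#' @param graph a [build_neighbor_graph()] result (node types required).
#' @param per_cell return the per-cell table instead of the mean.
#' @return scalar entropy in nats, or a tibble (`cell_id`, `s`).
#' @export
mixing_entropy <- function(graph, per_cell = FALSE) {
  nodes <- graph$nodes
  ty <- setNames(as.integer(nodes$type), nodes$cell_id)
  inc <- graph_incidences(graph)
  if (!nrow(inc)) {
    if (per_cell) return(tibble(cell_id = integer(), s = numeric()))
    return(NA_real_)
  }
  inc$nb_type <- ty[as.character(inc$neighbor)]
  per <- dplyr::summarise(
    dplyr::group_by(inc, .data$cell_id),
    p1 = mean(.data$nb_type == 1L),
    .groups = "drop")
  xlx <- function(p) ifelse(p > 0, p * log(p), 0)
  per$s <- -(xlx(per$p1) + xlx(1 - per$p1))
  if (per_cell) return(tibble(cell_id = per$cell_id, s = per$s))
  mean(per$s)
}

#' Event probability with binomial precision
#'
#' Estimates the per-observation probability of a rare event (apoptosis
#' or division) as `p = n / N` and reports the relative precision of the
#' estimator, `cv = sqrt((1 - p) / (p * N))` (undefined and flagged `NA`
#' when no events were observed).
#'
#' @param n event count.
#' @param N observation count (cell-frames), positive, `n <= N`.
#' @return tibble (`n`, `N`, `p`, `cv`).
#' @export
event_probability <- function(n, N) {
  if (any(N <= 0) || any(n < 0) || any(n > N))
    abort("need 0 <= n <= N and N > 0")
  p <- n / N
  cv <- ifelse(n > 0, sqrt((1 - p) / (p * N)), NA_real_)
  tibble(n = n, N = N, p = p, cv = cv)
}

#' Mean squared displacement of cell tracks
#'
#' Ensemble- and time-averaged MSD per lag over a set of centroid tracks,
#' used to calibrate the conversion between Monte Carlo steps and
#' experimental time.
#'
#' @param tracks tibble with `cell_id`, `frame`, `x`, `y` (positions in
#'   um); each track needs at least 2 frames.
#' @param lags integer lags (frames) to evaluate; defaults to all lags up
#'   to half the longest track.
#' @return tibble (`lag`, `msd`, `n_obs`).
#' @export
msd <- function(tracks, lags = NULL) {
  stopifnot(all(c("cell_id", "frame", "x", "y") %in% names(tracks)))
  split_tr <- split(tracks[c("frame", "x", "y")], tracks$cell_id)
  split_tr <- Filter(function(d) nrow(d) >= 2, split_tr)
  if (!length(split_tr)) abort("need at least one track with >= 2 frames")
  max_len <- max(vapply(split_tr, nrow, 1L))
  if (is.null(lags)) lags <- seq_len(max(1L, max_len %/% 2L))
  acc <- matrix(0, length(lags), 2) # sum, count
  for (d in split_tr) {
    d <- d[order(d$frame), ]
    f <- d$frame
    for (i in seq_along(lags)) {
      j <- match(f + lags[i], f)
      ok <- !is.na(j)
      if (any(ok)) {
        dx <- d$x[j[ok]] - d$x[ok]
        dy <- d$y[j[ok]] - d$y[ok]
        acc[i, 1] <- acc[i, 1] + sum(dx^2 + dy^2)
        acc[i, 2] <- acc[i, 2] + sum(ok)
      }
    }
  }
  tibble(lag = lags, msd = ifelse(acc[, 2] > 0, acc[, 1] / acc[, 2], NA_real_),
         n_obs = as.integer(acc[, 2]))
}

#' Winner division probability by heterotypic contact
#'
#' Compares the per-frame division probability of winner cells in contact
#' with at least one loser against winners contacting only winners, the
#' readout in which upregulated winner division near losers emerges from
#' purely mechanical rules. Observations are winner cell-frames, split by
#' whether the logged heterotypic contact fraction is positive; each
#' division is attributed to the dividing cell's contact state in the
#' frame before the event. Precision comes from [event_probability()].
#'
#' @param trajectory a `cc_trajectory` (or a list of them, pooled).
#' @return tibble with rows `heterotypic` and `homotypic` (`contact`,
#'   `n`, `N`, `p`, `cv`).
#' @export
division_bias <- function(trajectory) {
  trajs <- if (inherits(trajectory, "cc_trajectory")) list(trajectory)
           else trajectory
  n_het <- n_hom <- N_het <- N_hom <- 0
  for (tr in trajs) {
    d <- tr$cells
    w <- d[d$type == "winner" & d$fate == "alive" & !is.na(d$het_frac), ]
    het <- w$het_frac > 0
    N_het <- N_het + sum(het)
    N_hom <- N_hom + sum(!het)
    divs <- d[d$event == "division" & d$type == "winner" &
                !is.na(d$parent_id), ]
    m <- match(paste(divs$parent_id, divs$frame - 1L),
               paste(w$cell_id, w$frame))
    ph <- w$het_frac[m[!is.na(m)]] > 0
    n_het <- n_het + sum(ph)
    n_hom <- n_hom + sum(!ph)
  }
  out <- dplyr::bind_rows(event_probability(n_het, max(N_het, 1)),
                          event_probability(n_hom, max(N_hom, 1)))
  out$contact <- c("heterotypic", "homotypic")
  dplyr::relocate(out, "contact")
}

#' Per-frame population summary of a trajectory
#'
#' Tabulates, per frame and cell type: cell count (live plus apoptosing),
#' count normalised to the first frame, mean local density, and cumulative
#' divisions, completed apoptoses and extrusions. The counts obey
#' `count(t) = count(0) + divisions(<=t) - apoptoses(<=t) - extrusions(<=t)`.
#'
#' @param trajectory a `cc_trajectory`.
#' @return tibble keyed by (`frame`, `type`).
#' @export
population_summary <- function(trajectory) {
  cells <- trajectory$cells
  fm <- trajectory$header$frame_minutes
  terminal <- c("apoptosis_complete", "extrusion")
  grid <- tidyr::expand_grid(frame = sort(unique(cells$frame)),
                             type = factor(CELL_TYPES, levels = CELL_TYPES))
  present <- dplyr::summarise(
    dplyr::group_by(cells[!cells$event %in% terminal, ], .data$frame, .data$type),
    n_cells = dplyr::n(), mean_rho = mean(.data$rho, na.rm = TRUE),
    .groups = "drop")
  evc <- function(what) {
    d <- cells[cells$event %in% what, ]
    dplyr::summarise(dplyr::group_by(d, .data$frame, .data$type),
                     k = dplyr::n(), .groups = "drop")
  }
  out <- dplyr::left_join(grid, present, by = c("frame", "type"))
  out$n_cells[is.na(out$n_cells)] <- 0L
  for (nm in c("division", "apoptosis_complete", "extrusion")) {
    e <- evc(nm)
    names(e)[3] <- "k"
    out <- dplyr::left_join(out, e, by = c("frame", "type"))
    out$k[is.na(out$k)] <- 0L
    out <- dplyr::group_by(out, .data$type)
    out <- dplyr::mutate(out, !!paste0("cum_", nm) := cumsum(.data$k))
    out <- dplyr::ungroup(out)
    out$k <- NULL
  }
  out <- dplyr::group_by(out, .data$type)
  out <- dplyr::mutate(out, norm_count = .data$n_cells /
                         ifelse(dplyr::first(.data$n_cells) > 0,
                                dplyr::first(.data$n_cells), NA_real_))
  out <- dplyr::ungroup(out)
  out$time_h <- out$frame * fm / 60
  names(out)[names(out) == "cum_division"] <- "cum_divisions"
  names(out)[names(out) == "cum_apoptosis_complete"] <- "cum_apoptoses"
  names(out)[names(out) == "cum_extrusion"] <- "cum_extrusions"
  dplyr::select(out, "frame", "time_h", "type", "n_cells", "norm_count",
                "mean_rho", "cum_divisions", "cum_apoptoses",
                "cum_extrusions")
}
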