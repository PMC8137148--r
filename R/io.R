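#' Write / read a trajectory
#'
#' Trajectories are stored as a delimited (CSV) table of per-frame per-cell
#' rows with the resolved run header (config, seed, lattice spec, frame
#' duration) embedded as a JSON comment line, so a run is reproducible
#' from the file alone. The round trip is lossless field-for-field for the
#' tabular payload and header. Label-image snapshots are not part of the
#' delimited file; export them with [write_snapshot()].
#'
#' @param trajectory a `cc_trajectory`.
#' @param path file path.
#' @return `write_trajectory()` the path, invisibly; `read_trajectory()` a
#'   `cc_trajectory`.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "cc_trajectory"))
  hdr <- jsonlite::toJSON(trajectory$header, auto_unbox = TRUE, digits = NA)
  writeLines(c("# epicompete trajectory v1", paste0("# header ", hdr)), path)
  cells <- trajectory$cells
  cells$type <- as.character(cells$type)
  readr::write_csv(cells, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path, n = 2L)
  if (length(lines) < 2L || !startsWith(lines[1], "# epicompete trajectory"))
    abort(sprintf("not an epicompete trajectory file: %s (first line: %s)",
                  path, if (length(lines)) lines[1] else "<empty>"))
  if (!startsWith(lines[2], "# header "))
    abort(sprintf("malformed trajectory %s: missing header record on line 2", path))
  header <- jsonlite::fromJSON(sub("^# header ", "", lines[2]),
                               simplifyVector = TRUE)
  cells <- readr::read_csv(
    path, comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      frame = readr::col_integer(), cell_id = readr::col_integer(),
      type = readr::col_character(), x = readr::col_double(),
      y = readr::col_double(), area = readr::col_integer(),
      target_area = readr::col_double(), rho = readr::col_double(),
      het_frac = readr::col_double(), fate = readr::col_character(),
      event = readr::col_character(), parent_id = readr::col_integer(),
      birth_frame = readr::col_integer()))
  missing_cols <- setdiff(c("frame", "cell_id", "type", "event"), names(cells))
  if (length(missing_cols))
    abort(sprintf("malformed trajectory %s: missing column(s) %s", path,
                  paste(missing_cols, collapse = ", ")))
  cells$type <- factor(cells$type, levels = CELL_TYPES)
  new_trajectory(header, as_tibble(cells))
}

#' Export a lattice snapshot image
#'
#' `colormode = "labels"` writes a lossless 16-bit label TIFF (cell ids as
#' pixel values; re-reading reproduces the label grid exactly);
#' `colormode = "types"` writes a display PNG with winners green, losers
#' red and free space black. Image dimensions equal the lattice
#' dimensions.
#'
#' @param x a `cc_state` or an integer label matrix.
#' @param path output path (`.tif` for labels, `.png` for types).
#' @param colormode `"labels"` or `"types"`.
#' @param types for matrix input with `colormode = "types"`: integer
#'   vector mapping cell id to type (1 winner, 2 loser).
#' @return the path, invisibly.
#' @export
write_snapshot <- function(x, path, colormode = c("labels", "types"),
                           types = NULL) {
  colormode <- match.arg(colormode)
  labels <- if (inherits(x, "cc_state")) x$labels else x
  if (colormode == "labels") {
    if (max(labels) > 65535L) abort("more than 65535 labels; cannot write 16-bit TIFF")
    tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L,
                    compression = "none")
  } else {
    if (is.null(types) && inherits(x, "cc_state")) types <- x$typ
    if (is.null(types)) abort("`types` needed to colour a plain label matrix")
    ty <- matrix(0L, nrow(labels), ncol(labels))
    ty[labels > 0L] <- types[labels[labels > 0L]]
    img <- array(0, dim = c(nrow(labels), ncol(labels), 3))
    img[, , 1] <- (ty == 2L)
    img[, , 2] <- (ty == 1L) * 0.8
    png::writePNG(img, path)
  }
  invisible(path)
}

#' Read back a label TIFF written by [write_snapshot()]
#' @param path file path.
#' @return integer label matrix.
#' @export
read_snapshot <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Read / write a scenario configuration file
#'
#' Scenario configurations are stored as human-readable YAML mirroring the
#' [scenario_config()] arguments; unknown keys are rejected with an error
#' naming the offending key, and every run writes back its fully resolved
#' configuration (including the seed) for provenance.
#'
#' @param path YAML file.
#' @return `read_scenario_config()` a `cc_config`;
#'   `write_scenario_config()` the path, invisibly.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  known_top <- c("width", "height", "pixel_size", "duration_frames",
                 "duration_hours", "mcs_per_frame", "frame_minutes", "seed",
                 "record_snapshots", "profile", "seeding", "energy",
                 "growth", "apoptosis", "options")
  bad <- setdiff(names(y), known_top)
  if (length(bad))
    abort(sprintf("unknown config key: %s", paste(bad, collapse = ", ")))
  profile <- y$profile %||% "mechanical"
  params <- default_params(profile)
  params$energy <- merge_component(params$energy, y$energy, energy_params, "energy")
  params$growth <- merge_component(params$growth, y$growth, growth_params, "growth")
  params$apoptosis <- merge_component(params$apoptosis, y$apoptosis,
                                      apoptosis_params, "apoptosis")
  if (!is.null(y$options)) {
    opt_ok <- c("apoptosis_lambda", "fragment_min_px",
                "extrusion_include_apoptosing", "graph_adjacency",
                "density_definition", "het_denominator")
    bad <- setdiff(names(y$options), opt_ok)
    if (length(bad))
      abort(sprintf("unknown config key: options.%s", paste(bad, collapse = ", ")))
    for (nm in names(y$options)) params[[nm]] <- y$options[[nm]]
  }
  seeding_args <- y$seeding %||% list()
  bad <- setdiff(names(seeding_args), names(formals(seeding_spec)))
  if (length(bad))
    abort(sprintf("unknown config key: seeding.%s", paste(bad, collapse = ", ")))
  seeding <- do.call(seeding_spec, seeding_args)
  scenario_config(
    width = y$width %||% 1600, height = y$height %||% 1200,
    pixel_size = y$pixel_size %||% 0.33, params = params, seeding = seeding,
    duration_frames = y$duration_frames,
    duration_hours = y$duration_hours,
    mcs_per_frame = y$mcs_per_frame %||% 10,
    frame_minutes = y$frame_minutes %||% 4,
    seed = y$seed %||% 1,
    record_snapshots = y$record_snapshots)
}

merge_component <- function(base, overrides, constructor, what) {
  if (is.null(overrides)) return(base)
  ok <- names(formals(constructor))
  bad <- setdiff(names(overrides), ok)
  if (length(bad))
    abort(sprintf("unknown config key: %s.%s", what, paste(bad, collapse = ", ")))
  args <- unclass(base)
  for (nm in names(overrides)) {
    v <- overrides[[nm]]
    if (is.list(v)) v <- unlist(v)
    if (!is.null(names(args[[nm]])) && is.null(names(v)) &&
        length(v) == length(args[[nm]]))
      names(v) <- names(args[[nm]])
    args[[nm]] <- v
  }
  do.call(constructor, args[intersect(names(args), ok)])
}

#' @rdname read_scenario_config
#' @param config a `cc_config`.
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "cc_config"))
  y <- list(
    width = config$width, height = config$height,
    pixel_size = config$pixel_size,
    duration_frames = config$duration_frames,
    mcs_per_frame = config$mcs_per_frame,
    frame_minutes = config$frame_minutes, seed = config$seed,
    seeding = unclass(config$seeding),
    energy = lapply(unclass(config$params$energy), as.list),
    growth = lapply(unclass(config$params$growth), as.list),
    apoptosis = lapply(unclass(config$params$apoptosis), as.list),
    options = config$params[c("apoptosis_lambda", "fragment_min_px",
                              "extrusion_include_apoptosing",
                              "graph_adjacency", "density_definition",
                              "het_denominator")])
  yaml::write_yaml(y, path)
  invisible(path)
}
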