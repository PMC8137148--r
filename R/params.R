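#' Energy parameters of the cellular Potts model
#'
#' Houses every coefficient of the lattice Hamiltonian
#' \deqn{H = \sum_{<ij,i'j'>} J(\tau,\tau') (1-\delta_{\sigma\sigma'})
#'       + \sum_\sigma \lambda (A-A_T)^2 \Theta(\tau)
#'       + \lambda_m \sum_\sigma \hat m \cdot \hat s,}
#' where the adhesion sum runs over unlike-label neighbour pixel pairs, the
#' elastic term penalises deviation of a cell's actual area from its target
#' area (free space is exempt), and the motility term biases copy attempts
#' along each cell's polarity vector.
#'
#' Surface energies `J` follow the usual CPM convention: they are the
#' difference between surface tension and adhesion, so *higher* J means
#' *lower* effective adhesion.
#'
#' @param temperature Metropolis fluctuation scale (energy units, > 0).
#' @param J_homotypic named length-2 numeric, surface energy between two
#'   cells of the same type (`winner`, `loser`).
#' @param J_heterotypic surface energy of a winner-loser interface.
#' @param J_cell_substrate surface energy of a cell's boundary with free
#'   space (the substrate/medium), shared by both types.
#' @param lambda named length-2 numeric, area-expansion modulus per type
#'   (energy / pixel^4).
#' @param lambda_m named length-2 numeric, motility amplitude per type
#'   (energy). Motion along the polarity vector lowers the flip energy.
#' @param rot_diffusion rotational diffusion coefficient of the polarity
#'   vector (rad^2 / frame); the angular increment per frame has variance
#'   `2 * rot_diffusion`, so the directional autocorrelation decays as
#'   `exp(-rot_diffusion * t)`.
#' @param neighbor_order 1 (von Neumann, 4 neighbours) or 2 (Moore, 8
#'   neighbours); used both for the adhesion sum and for copy-attempt
#'   candidates.
#' @param boundary `"fixed"` (field-of-view walls behave as free space that
#'   cannot be invaded) or `"periodic"`.
#'
#' @return A named list of class `cc_energy_params`.
#' @export
energy_params <- function(temperature = 20,
                          J_homotypic = c(winner = 8, loser = 8),
                          J_heterotypic = 8,
                          J_cell_substrate = 12,
                          lambda = c(winner = 1.0, loser = 0.5),
                          lambda_m = c(winner = 2, loser = 2),
                          rot_diffusion = 0.1,
                          neighbor_order = 2,
                          boundary = c("fixed", "periodic")) {
  boundary <- match.arg(boundary)
  J_homotypic <- per_type(J_homotypic, "J_homotypic")
  lambda <- per_type(lambda, "lambda")
  lambda_m <- per_type(lambda_m, "lambda_m")
  stopifnot(temperature > 0, J_heterotypic >= 0, J_cell_substrate >= 0,
            all(J_homotypic >= 0), neighbor_order %in% 1:2,
            rot_diffusion >= 0)
  structure(list(temperature = temperature, J_homotypic = J_homotypic,
                 J_heterotypic = J_heterotypic,
                 J_cell_substrate = J_cell_substrate, lambda = lambda,
                 lambda_m = lambda_m, rot_diffusion = rot_diffusion,
                 neighbor_order = neighbor_order, boundary = boundary),
            class = "cc_energy_params")
}

#' Growth, adder-division and contact-inhibition parameters
#'
#' Cells grow by increasing their target area at rate
#' `G * exp(-k (A - A_T)^2)` per frame (contact inhibition of
#' proliferation) and divide along their major axis once the target area
#' added since birth reaches a per-cell threshold drawn at birth
#' (the adder rule, independent of birth size).
#'
#' All areas are in pixel^2, rates in pixel^2 / frame.
#'
#' @param G named length-2 numeric, mean growth rate per type in the
#'   absence of crowding.
#' @param G_cv coefficient of variation of the per-cell per-frame growth
#'   increment (truncated-normal, left-truncated at 0).
#' @param dA_tot named length-2 numeric, mean added-area threshold for
#'   division.
#' @param dA_tot_cv coefficient of variation of the per-cell threshold
#'   drawn at birth.
#' @param AT0 named length-2 numeric, mean target area at birth.
#' @param AT0_cv coefficient of variation of the birth target area.
#' @param k named length-2 numeric, contact-inhibition sensitivity
#'   (pixel^-4). Larger k stalls growth at smaller deviations of actual
#'   from target area.
#'
#' @return A named list of class `cc_growth_params`.
#' @export
growth_params <- function(G = c(winner = 1400 / 270, loser = 1600 / 324),
                          G_cv = 0.3,
                          dA_tot = c(winner = 1400, loser = 1600),
                          dA_tot_cv = 0.1,
                          AT0 = c(winner = 2800, loser = 3200),
                          AT0_cv = 0.1,
                          k = c(winner = 1.5e-6, loser = 1.5e-6)) {
  G <- per_type(G, "G"); dA_tot <- per_type(dA_tot, "dA_tot")
  AT0 <- per_type(AT0, "AT0"); k <- per_type(k, "k")
  stopifnot(all(G > 0), all(dA_tot > 0), all(AT0 > 0), all(k >= 0),
            G_cv >= 0, dA_tot_cv >= 0, AT0_cv >= 0)
  structure(list(G = G, G_cv = G_cv, dA_tot = dA_tot,
                 dA_tot_cv = dA_tot_cv, AT0 = AT0, AT0_cv = AT0_cv, k = k),
            class = "cc_growth_params")
}

#' Apoptosis rules for mechanical and biochemical competition
#'
#' Mechanical (density-dependent) apoptosis: per frame, a cell dies with
#' probability `p_max / (1 + exp(-alpha * (rho - rho_half)))`, a sigmoid of
#' its local density rho (1/um^2). Biochemical (contact-dependent)
#' apoptosis: a Hill function `p_max * p^n / (S^n + p^n)` of the fraction p
#' of the cell's perimeter in heterotypic contact.
#'
#' @param mode which rule(s) are active: `"mechanical"`, `"biochemical"`,
#'   or `"both"` (the two per-frame probabilities are combined as
#'   `1 - (1-p_mech)(1-p_bio)`).
#' @param mech_p_max,mech_alpha,mech_rho_half named length-2 numerics per
#'   type: saturation probability per frame, sigmoid steepness (um^2), and
#'   density at half-maximum (1/um^2).
#' @param bio_p_max,bio_S,bio_n named length-2 numerics per type: Hill
#'   amplitude per frame, half-maximum heterotypic fraction in (0, 1], and
#'   Hill coefficient (>= 1).
#'
#' @return A named list of class `cc_apoptosis_params`.
#' @export
apoptosis_params <- function(mode = c("mechanical", "biochemical", "both"),
                             mech_p_max = c(winner = 0.008, loser = 0.003),
                             mech_alpha = c(winner = 2000, loser = 2000),
                             mech_rho_half = c(winner = 0.026, loser = 0.004),
                             bio_p_max = c(winner = 8e-4, loser = 8e-3),
                             bio_S = c(winner = 0.5, loser = 0.3),
                             bio_n = c(winner = 3, loser = 3)) {
  mode <- match.arg(mode)
  mech_p_max <- per_type(mech_p_max, "mech_p_max")
  mech_alpha <- per_type(mech_alpha, "mech_alpha")
  mech_rho_half <- per_type(mech_rho_half, "mech_rho_half")
  bio_p_max <- per_type(bio_p_max, "bio_p_max")
  bio_S <- per_type(bio_S, "bio_S")
  bio_n <- per_type(bio_n, "bio_n")
  stopifnot(all(mech_p_max >= 0), all(mech_p_max <= 1),
            all(bio_p_max >= 0), all(bio_p_max <= 1),
            all(bio_S > 0), all(bio_S <= 1), all(bio_n >= 1))
  structure(list(mode = mode, mech_p_max = mech_p_max,
                 mech_alpha = mech_alpha, mech_rho_half = mech_rho_half,
                 bio_p_max = bio_p_max, bio_S = bio_S, bio_n = bio_n),
            class = "cc_apoptosis_params")
}

#' Assemble a full model parameter set
#'
#' @param energy a [energy_params()] object.
#' @param growth a [growth_params()] object.
#' @param apoptosis an [apoptosis_params()] object.
#' @param apoptosis_lambda area-expansion modulus assigned to apoptosing
#'   cells; apoptosis execution sets the target area to 0 and lambda to
#'   this value so the cell shrinks through normal lattice dynamics.
#' @param fragment_min_px disconnected fragments of a cell smaller than
#'   this (pixels, 4-connected) are released back to free space at frame
#'   boundaries; the largest fragment always survives.
#' @param extrusion_include_apoptosing whether apoptosing cells count
#'   towards the population mean area in the live-extrusion rule
#'   `A <= <A>/2` (default excludes the shrinking corpses).
#' @param graph_adjacency pixel adjacency (4 or 8) used for the neighbour
#'   graph and boundary counting in the metrics layer.
#' @param density_definition `"sum_inverse"` (local density is the sum of
#'   inverse areas of the cell and its first neighbours) or
#'   `"inverse_total"` (inverse of their summed area).
#' @param het_denominator denominator of the heterotypic perimeter
#'   fraction: `"cell_cell"` (cell-cell boundary only, default) or
#'   `"perimeter"` (includes the free-space boundary).
#'
#' @return list of class `cc_params`.
#' @export
sim_params <- function(energy = energy_params(),
                       growth = growth_params(),
                       apoptosis = apoptosis_params(),
                       apoptosis_lambda = 2,
                       fragment_min_px = 8,
                       extrusion_include_apoptosing = FALSE,
                       graph_adjacency = 4,
                       density_definition = c("sum_inverse", "inverse_total"),
                       het_denominator = c("cell_cell", "perimeter")) {
  stopifnot(inherits(energy, "cc_energy_params"),
            inherits(growth, "cc_growth_params"),
            inherits(apoptosis, "cc_apoptosis_params"),
            graph_adjacency %in% c(4, 8), apoptosis_lambda >= 0)
  structure(list(energy = energy, growth = growth, apoptosis = apoptosis,
                 apoptosis_lambda = apoptosis_lambda,
                 fragment_min_px = fragment_min_px,
                 extrusion_include_apoptosing = extrusion_include_apoptosing,
                 graph_adjacency = graph_adjacency,
                 density_definition = match.arg(density_definition),
                 het_denominator = match.arg(het_denominator)),
            class = "cc_params")
}

#' Default parameter profiles
#'
#' Named profiles mirroring the roles of the study's scenario parameter
#' tables: `"mechanical"` (pure populations and density-mediated
#' competition; winners are stiffer and tolerate higher densities than
#' losers) and `"biochemical"` (contact-dependent killing; both types share
#' stiffness, contact inhibition and a high, equal homeostatic density so
#' that density-mediated death does not confound the contact rule).
#'
#' Every numeric value in these profiles is a calibration choice of this
#' package (see the methods vignette), reproducing the published
#' observables: pre-confluence cycle times of ~18 h (winner) and ~21.6 h
#' (loser), a pure-winner plateau at ~5.5x the seeded count, recovery from
#' a 30% density step in ~6 h, and loser elimination in mixed populations.
#'
#' @param profile profile name.
#' @return list of class `cc_params`.
#' @export
default_params <- function(profile = c("mechanical", "biochemical")) {
  profile <- match.arg(profile)
  switch(profile,
    mechanical = sim_params(),
    biochemical = sim_params(
      energy = energy_params(lambda = c(winner = 1.0, loser = 1.0)),
      apoptosis = apoptosis_params(
        mode = "both",
        mech_rho_half = c(winner = 0.045, loser = 0.045),
        bio_p_max = c(winner = 8e-4, loser = 8e-3),
        bio_S = c(winner = 0.5, loser = 0.3))))
}

# J lookup matrix indexed by type + 1 (free space, winner, loser)
j_matrix <- function(energy) {
  J <- matrix(0, 3, 3)
  J[1, 2] <- J[2, 1] <- energy$J_cell_substrate
  J[1, 3] <- J[3, 1] <- energy$J_cell_substrate
  J[2, 2] <- energy$J_homotypic[["winner"]]
  J[3, 3] <- energy$J_homotypic[["loser"]]
  J[2, 3] <- J[3, 2] <- energy$J_heterotypic
  J
}

per_type <- function(x, what) {
  if (length(x) == 1L) x <- c(winner = unname(x), loser = unname(x))
  if (is.null(names(x))) names(x) <- CELL_TYPES
  if (!all(CELL_TYPES %in% names(x)))
    abort(sprintf("`%s` must be named with 'winner' and 'loser'", what))
  x[CELL_TYPES]
}

# truncated-normal draw, left-truncated at `lower` (redraw would bias the
# mean for large cv; a simple clamp keeps the increment interpretation)
rtrunc_norm <- function(n, mean, cv, lower = 0) {
  pmax(lower, rnorm(n, mean, cv * mean))
}
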