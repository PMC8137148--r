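width: 300
height: 400
pixel_size: 0.33
duration_frames: 60
mcs_per_frame: 10
frame_minutes: 4.0
seed: 43
seeding:
  mode: partially_sorted
  loser_fraction: 0.5
  total_density: 0.07
  colony_count: 3.0
  colony_size: 10.0
  gap_px: 2.0
energy:
  temperature:
  - 20.0
  J_homotypic:
    winner: 8.0
    loser: 8.0
  J_heterotypic:
  - 8.0
  J_cell_substrate:
  - 12.0
  lambda:
    winner: 1.0
    loser: 1.0
  lambda_m:
    winner: 2.0
    loser: 2.0
  rot_diffusion:
  - 0.1
  neighbor_order:
  - 2.0
  boundary:
  - fixed
growth:
  G:
    winner: 7.4074074
    loser: 7.0555556
  G_cv:
  - 0.3
  dA_tot:
    winner: 2000.0
    loser: 2286.0
  dA_tot_cv:
  - 0.1
  AT0:
    winner: 2800.0
    loser: 3200.0
  AT0_cv:
  - 0.1
  k:
    winner: 1.5e-06
    loser: 1.5e-06
apoptosis:
  mode:
  - both
  mech_p_max:
    winner: 0.008
    loser: 0.008
  mech_alpha:
    winner: 2000.0
    loser: 200.0
  mech_rho_half:
    winner: 0.045
    loser: 0.045
  bio_p_max:
    winner: 0.0008
    loser: 0.008
  bio_S:
    winner: 0.5
    loser: 0.3
  bio_n:
    winner: 3.0
    loser: 3.0
options:
  apoptosis_lambda: 2.0
  fragment_min_px: 8.0
  extrusion_include_apoptosing: no
  graph_adjacency: 4.0
  density_definition: sum_inverse
  het_denominator: cell_cell
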