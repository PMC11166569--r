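## Shared fixtures, kept small so the default run stays fast.

ctrl_gen <- function(seed = 42, n = 44) {
  activation_gen_config(forces = c(2, 6, 12.5, 18, 25), n_per_force = n,
                        intercept_a0 = 190, slope_beta = -4.7, width_b = 12,
                        seed = seed)
}

## logistic(a, b) draws snapped UP to a step grid -- oracle expectation of
## the snapped value by direct summation over the grid
snapped_mean_oracle <- function(a, b, step) {
  g <- seq(step, a + 25 * b, by = step)
  pr <- stats::plogis(g, a, b) - stats::plogis(g - step, a, b)
  pr[1L] <- stats::plogis(g[1L], a, b)  # clamped first protocol step
  sum(g * pr) / sum(pr)
}

small_flim_scene <- function(seed = 7, delta = 0.3, photons = 2000,
                             n_steps = 1) {
  generate_flim_scene(flim_scene_config(
    ny = 18, nx = 18, pixel_size_um = 0.15, tau_base = 5,
    tau_site_delta = delta, site_radius_um = 0.9, site_width_um = 0.3,
    photons_per_pixel = photons, n_bins = 128, n_steps = n_steps,
    seed = seed))
}

coarse_membrane <- function(anchor_spacing = 0.4, anchor_k = 20, seed = 2,
                            radius = 2.5, edge = 0.2, pre_strain = 0.01) {
  build_membrane_system(membrane_config(
    patch_radius_um = radius, edge_len_um = edge, spring_k = 2,
    pre_strain = pre_strain, anchor_spacing_um = anchor_spacing,
    anchor_k = anchor_k, seed = seed))
}
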