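# small fixture builders shared across test files

# digital ball of radius r voxels centered in a cube of side d voxels
digital_ball <- function(r, d = 2 * r + 11) {
  g <- seq_len(d) - (d + 1) / 2
  outer(outer(g^2, g^2, `+`), g^2, `+`) <= r^2
}

# closed-form diffusive-slab transmission used as the MC oracle
diffusion_T_absfree <- function(L, l_t, z_e) {
  (l_t + z_e * l_t) / (L + 2 * z_e * l_t)
}

# angular scan pooled over several independent MC runs of one geometry
pooled_angular_scan <- function(geom, seeds, n_photons = 1e5) {
  W <- numeric(180); cnt <- integer(180); res <- NULL
  for (s in seeds) {
    res <- mc_simulate(geom, n_photons = n_photons, seed = s)
    W <- W + res$transmitted_angles$weight
    cnt <- cnt + res$transmitted_angles$count
  }
  res$transmitted_angles$weight <- W
  res$transmitted_angles$count <- cnt
  res$n_transmitted <- sum(cnt)
  angular_transmittance(res)
}
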