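# coraloptics

Photon transport and optical characterization of photosynthetic
biomaterials — the analysis chain behind 3D-printed "bionic coral"
constructs that grow dense microalgal cultures by managing light the way
coral skeletons do.

The package is for experimentalists and modellers working on scattering
photosynthetic materials (printed hydrogel tissues, skeletal mimics,
dense algal cultures) who need to:

* **simulate** light in layered or voxelized scattering–absorbing media
  — time-resolved Monte Carlo with Henyey–Greenstein scattering,
  weight-based absorption, Fresnel/Snell interfaces (`mc_simulate()`,
  `fluence_depth_profile()`, `tpsf_snapshot()`,
  `angular_transmittance()`);
* **invert** optical measurements — transport mean free path $l_t$ and
  absorption length $l_a$ from integrating-sphere transmission versus
  thickness via the diffusive-slab law
  $T = \sinh(l_t(1+z_e)/L_\alpha)\,/\,\sinh((L+2z_e l_t)/L_\alpha)$ with
  $L_\alpha = \sqrt{l_a l_t/3}$, the extrapolation length $z_e$ from the
  angular law $P(\mu) = \mu(z_e+\mu)/(z_e/2+1/3)$, Beer–Lambert
  extinction in the weakly scattering regime, and refractive index from
  the Brewster angle $n = \tan\theta_B$ (`fit_diffusion()`,
  `fit_extrapolation_length()`, `fit_beer_lambert()`,
  `find_brewster()`, `brewster_index()`);
* **convert** tomographic image stacks into printable geometry — 3D
  median denoising, per-slice multilevel Otsu segmentation, watertight
  isosurface extraction, STL export, hole filling, and even–odd slicing
  into printer masks (`denoise_median3d()`, `segment_surface()`,
  `extract_surface()`, `write_stl()`, `fill_holes()`, `slice_masks()`)
  — plus confocal aggregate segmentation with volume, surface area and
  sphericity $\pi^{1/3}(6V)^{2/3}/A$ (`segment_particles()`);
* **quantify** photosynthetic performance — diffusive O$_2$ flux by
  Fick's first law from microsensor profiles, light–dark-shift gross
  photosynthesis, Webb-type photosynthesis–irradiance fits
  $P = P_{max}(1-e^{-E/E_k})$, and logistic growth fits with confidence
  and prediction bands (`diffusive_flux()`, `gross_photosynthesis()`,
  `fit_pi_curve()`, `fit_growth()`).

Every estimator has a matching synthetic-data generator with known
ground truth and configurable noise (`make_corallite_volume()`,
`make_transmission_series()`, `make_angular_scan()`,
`make_brewster_scan()`, `make_o2_profile()`, `make_pi_data()`,
`make_growth_series()`, `make_aggregate_stack()`), so the whole pipeline
runs and is tested without instrument data.

## Worked example

Simulate the two-layer construct — absorbing, forward-scattering tissue
at culture density over the diffusely backscattering skeleton — and
compare light availability at depth against a flat absorbing slab:

```r
library(coraloptics)

slab <- layered_slab(list(material_preset("tissue_culture"),
                          material_preset("skeleton")),
                     thickness = c(1, 1))        # mm
res <- mc_simulate(slab, n_photons = 5e4, seed = 42, nz = 100)
res
#> <sim_result> 50000 photons: T = 0.1875, R = 0.1109, A = 0.7016 (closure se 1.7e-07)

prof <- fluence_depth_profile(res)
fluence_at_depth(prof, 750)                      # % of incident irradiance
#> 114.5

flat <- layered_slab(material(0.5, 0, 0, 1.40), thickness = 2)
pf <- fluence_depth_profile(mc_simulate(flat, n_photons = 5e4, seed = 43,
                                        nz = 100))
fluence_fold_change(prof, pf, 750)
#> 1.7
```

18.8 % of the light leaves through the bottom, 11.1 % returns upward,
70.2 % is absorbed (the three fractions close to 1 within Monte Carlo
error). At 750 µm depth the scalar irradiance inside the scattering
construct is 114.5 % of the incident level — scattering plus internal
reflection traps light — a 1.7-fold enhancement over the non-scattering
slab with the same absorber density.

Inverse optics on synthetic integrating-sphere and goniometer data with
2 % noise, and the supporting point estimates:

```r
ser <- make_transmission_series(l_a = 100, l_t = 3, z_e = 1.32,
                                config = phantom_config(seed = 7, noise_rel = 0.02))
sc  <- make_angular_scan(z_e = 1.32,
                         config = phantom_config(seed = 8, noise_rel = 0.02))
fit_diffusion(ser, sc)
#> <diffusion_fit> l_a = 94.9 mm, l_t = 3.14 mm, z_e = 1.37 (converged, 2 iter)

brewster_index(54.0)$n                     # refractive index at theta_B = 54 deg
#> 1.376

pr <- make_o2_profile(J = 0.25, config = phantom_config(seed = 3, noise_rel = 0.01))
fx <- diffusive_flux(pr)
sprintf("J = %.3f +/- %.3f nmol O2 cm^-2 s^-1", fx$J, fx$J_se)
#> "J = 0.249 +/- 0.001 nmol O2 cm^-2 s^-1"
```

The diffusion fit recovers the ground truth ($l_a = 100$ mm,
$l_t = 3$ mm) within 5 %, and the Fick-law flux recovers the generated
0.25 nmol O$_2$ cm$^{-2}$ s$^{-1}$ production rate within its standard
error, with the linear window auto-selected exactly on the 300 µm
diffusive boundary layer.

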