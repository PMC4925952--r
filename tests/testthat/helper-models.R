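## fixtures built in code; memoized so expensive models build once per run

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

## a bare voxel model from explicit arrays (for oracle-sized FE cases)
manual_model <- function(frac, voxel = 35, struts = NULL) {
  frac <- as.array(frac)
  g <- dim(frac)
  if (is.null(struts)) {
    struts <- data.frame(id = 1L, axis = "z", orientation = "vertical",
                         x0 = 0, x1 = g[1] * voxel, y0 = 0, y1 = g[2] * voxel,
                         z0 = 0, z1 = g[3] * voxel,
                         thickness = min(g[1:2]) * voxel, shrink = "xy",
                         boundary = TRUE, removed = FALSE,
                         stringsAsFactors = FALSE)
  }
  structure(list(grid = as.integer(g), voxel = voxel, extent = g * voxel,
                 frac = frac, strut_id = array(1L, g) * (frac > 0),
                 struts = struts,
                 lattice = list(type = "manual", thickness = NA_real_,
                                spacing = g[1] * voxel, cells = c(1L, 1L, 1L),
                                requested_voxel = voxel)),
            class = "voxel_model")
}

solid_block <- function(nx = 1, ny = 1, nz = 1, voxel = 35)
  manual_model(array(1, c(nx, ny, nz)), voxel)

single_voxel <- function(voxel = 35) solid_block(1, 1, 1, voxel)

trab <- function() material_preset("trabecular")

rod_small <- function() fixture("rod_small",
  function() build_normal_model("rod", c(2L, 2L, 2L), 70))

rod_test <- function() fixture("rod_test",
  function() build_normal_model("rod", c(3L, 3L, 3L), 70))

## brute-force BV/TV oracle: plain loop over the voxel array
bvtv_oracle <- function(model) {
  tot <- 0
  f <- model$frac
  for (i in seq_along(f)) tot <- tot + f[i]
  tot / length(f)
}

## displacement-controlled uniaxial ramp on one fully solid element,
## inviscid law, no sub-stepping (fixed strain grid)
uniaxial_ramp <- function(direction, to, by = 5e-5, material = trab(),
                          voxel = 35) {
  ld <- loading_spec(strain_targets = seq(by, to, by = by),
                     viscous_stabilization = 0,
                     substep_fraction = 2,
                     stop_fraction_of_peak = 1e-9)
  run_compression(single_voxel(voxel), material, ld, direction = direction)
}

## one-element-wide failing band: 1x1xN column whose middle element has half
## solid fraction, so the column stress peaks far below the neighbours' yield
## stress and damage localizes strictly in that element; pulled in tension
## until the band fully fails. The material uses nu = 0 so the band is free
## of Poisson confinement by its elastic neighbours and the measured energy
## isolates the uniaxial crack-band law. Returns dissipated energy, the band
## cross-section (mm^2) and the band element's solid fraction (the band's
## effective fracture energy scales with the solid it contains).
band_dissipation <- function(voxel_um, n_elem = 4, weak = 0.5,
                             material = material_preset("trabecular",
                                                        nu = 0)) {
  frac <- array(1, c(1, 1, n_elem))
  frac[1, 1, ceiling(n_elem / 2)] <- weak
  m <- manual_model(frac, voxel_um)
  h_mm <- voxel_um / 1000
  span <- dissipate_Gf(material, h_mm, mode = "tension")
  eps_end <- (material$eps_crack_t * n_elem + 1.05 * span) / n_elem
  ld <- loading_spec(strain_targets = seq(eps_end / 250, eps_end,
                                          length.out = 250),
                     viscous_stabilization = 0,
                     substep_fraction = 2,
                     stop_fraction_of_peak = 1e-12,
                     max_damage_iterations = 80L,
                     scale_tol = 1e-8)
  res <- run_compression(m, material, ld, direction = "tension")
  s <- res$steps[nrow(res$steps), ]
  list(dissipated = s$external_work - s$stored_energy,
       area = h_mm^2, weak = weak, result = res)
}
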