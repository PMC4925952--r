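## The normal/aged simulation battery backing the ordering and magnitude
## checks. Scaled for a desk run: rod family 3x3x3 cells at ~70 um voxels
## (two elements across a strut), plate family 2x2x3 cells at ~137 um voxels
## (one element across a wall), 50/40 strain increments to 4% apparent
## strain, replicate seeds for the stochastic (random-removal) models.
## Plate runs cost several minutes each, so the plate family's stochastic
## models run a single seed. Built lazily once per test session.

battery_loading <- function(family)
  loading_spec(max_apparent_strain = 0.04,
               n_steps = if (family == "rod") 50L else 40L)

battery_models <- function(family) {
  mat <- trab()
  if (family == "rod") {
    normal <- build_normal_model("rod", c(3L, 3L, 3L), 70)
    two_step <- 0.15
  } else {
    normal <- build_normal_model("plate", c(2L, 2L, 3L), 140)
    two_step <- 0.25
  }
  seeds <- if (family == "rod") 1:3 else 1L
  tol <- 0.02   # strut granularity at reduced cell counts
  out <- list(list(family = family, model = "A", seed = 1, vm = normal))
  for (s in seeds)
    out <- c(out, list(list(family = family, model = "B", seed = s,
                            vm = apply_aging(normal,
                              degeneration_spec("random", "two_step", two_step,
                                                seed = s, tolerance = tol)))))
  out <- c(out, list(list(family = family, model = "C", seed = 1,
                          vm = apply_aging(normal,
                            degeneration_spec("low_strain", "two_step",
                                              two_step, seed = 1,
                                              tolerance = tol), mat))))
  out <- c(out, list(list(family = family, model = "D", seed = 1,
                          vm = apply_aging(normal,
                            degeneration_spec("random", "thinning_only", 0.08,
                                              seed = 1, tolerance = tol)))))
  for (s in seeds) for (mo in c("E", "F"))
    out <- c(out, list(list(family = family, model = mo, seed = s,
                            vm = apply_aging(normal,
                              degeneration_spec("random",
                                if (mo == "E") "vertical_loss" else
                                  "horizontal_loss",
                                0.08, seed = s, tolerance = tol)))))
  out
}

run_battery <- function() {
  mat <- trab()
  rows <- list(); runs <- list()
  for (family in c("rod", "plate")) {
    ld <- battery_loading(family)
    for (entry in battery_models(family)) {
      res <- run_compression(entry$vm, mat, ld)
      met <- extract_metrics(res)
      key <- sprintf("%s_%s_%d", entry$family, entry$model, entry$seed)
      runs[[key]] <- list(metrics = met, termination = res$termination,
                          model = entry$vm,
                          proximity = if (entry$model %in% c("E", "F"))
                            fracture_site_proximity(res, failed = "cracked")
                          else NULL)
      rows[[key]] <- data.frame(
        family = entry$family, model = entry$model, seed = entry$seed,
        ultimate_stress = met$ultimate_stress,
        fracture_strain = met$fracture_strain,
        strain_at_ultimate = met$strain_at_ultimate,
        apparent_modulus = met$apparent_modulus,
        termination = res$termination)
    }
  }
  list(metrics = do.call(rbind, rows), runs = runs)
}

battery <- function() fixture("battery", run_battery)
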