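#' @title Incremental compression-to-failure driver
#' @name simulation
#' @description Displacement-controlled loading with event-driven damage
#'   iteration per step (assemble-solve-update secant iteration until no state
#'   change), apparent stress-strain history and complete-failure detection.
NULL

#' Loading specification
#'
#' @param max_apparent_strain Final apparent strain (default 0.05, the imposed
#'   5% compression).
#' @param n_steps Number of equal strain increments (default 100).
#' @param max_damage_iterations Secant iterations allowed per step.
#' @param viscous_stabilization Relaxation pseudo-time (in apparent-strain
#'   units) of the damage evolution: within a strain increment `de` each
#'   element closes only the fraction `de / (de + viscous_stabilization)` of
#'   the gap between its current and target secant scale, damping softening
#'   oscillations and abrupt failure cascades (default `1e-4`; `0` recovers
#'   the inviscid law).
#' @param stop_fraction_of_peak Terminate once apparent stress falls below
#'   this fraction of the running peak (default 0.10).
#' @param substep_fraction If more than this fraction of elements changes
#'   state in one increment the increment is bisected (up to `max_substep_depth`
#'   times) for robustness.
#' @param max_substep_depth Maximum recursive bisections per increment.
#' @param strain_targets Optional explicit vector of increasing apparent
#'   strains overriding `max_apparent_strain` / `n_steps`.
#' @param scale_tol Secant-iteration convergence tolerance on the per-element
#'   modulus scale (default `1e-5`).
#' @return A `loading_spec` object.
#' @export
loading_spec <- function(max_apparent_strain = 0.05, n_steps = 100L,
                         max_damage_iterations = 40L,
                         viscous_stabilization = 1e-4,
                         stop_fraction_of_peak = 0.10,
                         substep_fraction = 0.05,
                         max_substep_depth = 4L,
                         strain_targets = NULL,
                         scale_tol = 1e-5) {
  if (max_apparent_strain <= 0 || max_apparent_strain > 1)
    stop("max_apparent_strain must lie in (0, 1]")
  if (is.null(strain_targets) && n_steps < 2)
    stop("n_steps must be at least 2")
  if (!is.null(strain_targets)) {
    if (any(diff(strain_targets) <= 0) || any(strain_targets <= 0))
      stop("strain_targets must be strictly increasing and positive")
    max_apparent_strain <- max(strain_targets)
  }
  structure(list(max_apparent_strain = max_apparent_strain,
                 n_steps = as.integer(n_steps),
                 max_damage_iterations = as.integer(max_damage_iterations),
                 viscous_stabilization = viscous_stabilization,
                 stop_fraction_of_peak = stop_fraction_of_peak,
                 substep_fraction = substep_fraction,
                 max_substep_depth = as.integer(max_substep_depth),
                 strain_targets = strain_targets,
                 scale_tol = scale_tol),
            class = "loading_spec")
}

## load-path connectivity among intact (not fully failed) elements
intact_path_ok <- function(system, state) {
  grid <- system$grid
  mask <- logical(prod(grid))
  mask[system$elements[state$d < 1 - 1e-12]] <- TRUE
  if (!any(mask)) return(FALSE)
  reach <- flood_reach(mask, face_layer_indices(grid, "bottom"), grid)
  any(reach[face_layer_indices(grid, "top")])
}

#' Run an incremental compression (or tension) simulation to failure
#'
#' For each strain increment the system is reassembled with the current
#' element secant scales, solved, and element damage states updated from the
#' principal-strain demands; the assemble-solve-update loop repeats within the
#' step until no element changes state (secant iteration, guaranteed monotone
#' because damage never heals). The run terminates at the maximum strain, at
#' load-path disconnection of the intact elements (complete fracture), or when
#' the apparent stress drops below `stop_fraction_of_peak` times the running
#' peak.
#'
#' @param model A `voxel_model` that passes [check_load_path()].
#' @param material A `material_params`.
#' @param loading A [loading_spec()].
#' @param direction `"compression"` (default) or `"tension"`.
#' @param damage If `FALSE`, runs a purely linear elastic ramp (no state
#'   updates); useful as a reference.
#' @param solver Passed to [assemble()].
#' @param verbose Print per-step progress.
#' @return A `simulation_result`: `steps` data frame (apparent strain, stress
#'   in MPa, newly yielded / cracked / failed element counts, external work,
#'   stored energy, dissipated energy in mJ, damage iterations), `termination`
#'   reason, final `damage_state`, the `fe_system`, and curve metadata.
#' @export
run_compression <- function(model, material, loading = loading_spec(),
                            direction = c("compression", "tension"),
                            damage = TRUE,
                            solver = c("auto", "direct", "cg"),
                            verbose = FALSE) {
  direction <- match.arg(direction)
  solver <- match.arg(solver)
  stopifnot(inherits(loading, "loading_spec"))
  lp <- check_load_path(model)
  if (!lp$connected)
    stop("model has no load path between the top and bottom faces")
  system <- assemble(model, material, solver = solver)
  state <- damage_state(system$n_e)
  h_mm <- system$h_mm
  tau <- loading$viscous_stabilization
  floor_scale <- 1e-5
  targets <- if (is.null(loading$strain_targets))
    seq(loading$max_apparent_strain / loading$n_steps,
        loading$max_apparent_strain, length.out = loading$n_steps)
  else loading$strain_targets
  steps <- vector("list", 2L * length(targets))
  nrec <- 0L
  termination <- "max_strain"
  peak <- 0
  W <- 0; F_prev <- 0; d_prev <- 0
  queue <- as.list(targets)
  depth <- integer(length(queue))
  prev_strain <- 0
  crack_dirs <- list()
  while (length(queue)) {
    eps <- queue[[1]]; dq <- depth[1]
    queue <- queue[-1]; depth <- depth[-1]
    snapshot <- state
    it <- 0L
    n_flag_prev <- c(sum(state$yielded_t), sum(state$yielded_c),
                     sum(state$cracked), sum(state$d >= 1 - 1e-12))
    de <- eps - prev_strain
    relax <- if (tau > 0) de / (de + tau) else 1
    s_start <- state$scale
    d_start <- state$d
    repeat {
      it <- it + 1L
      sol <- solve_compression(system, eps, direction)
      dem <- list(
        tension = pmax(0, sol$principal[, 1]),
        compression = pmax(0, -sol$principal[, 3]))
      if (!damage) break
      new_state <- update_state(state, dem, material, h_mm, floor_scale)
      ## viscous relaxation: damage closes only part of the gap per increment
      s_appl <- pmax(new_state$scale,
                     s_start - relax * (s_start - new_state$scale))
      d_appl <- pmin(new_state$d, d_start + relax * (new_state$d - d_start))
      ## snap essentially complete damage so erosion bookkeeping is crisp
      done <- d_appl >= 0.999
      d_appl[done] <- 1
      s_appl[done] <- floor_scale
      dscale <- max(abs(s_appl - state$scale))
      new_state$scale <- pmin(state$scale, s_appl)
      new_state$d <- pmax(state$d, d_appl)
      state <- new_state
      if (dscale > 1e-9) set_system_scales(system, state$scale)
      if (dscale <= loading$scale_tol || it >= loading$max_damage_iterations) break
    }
    n_flag <- c(sum(state$yielded_t), sum(state$yielded_c),
                sum(state$cracked), sum(state$d >= 1 - 1e-12))
    n_events <- sum(n_flag - n_flag_prev)
    stalled <- FALSE
    if (damage && it >= loading$max_damage_iterations) {
      sol_chk <- solve_compression(system, eps, direction)
      stalled <- abs(sol_chk$apparent_stress - sol$apparent_stress) >
        1e-3 * max(peak, sol$apparent_stress, 1e-12)
      sol <- sol_chk
    }
    if (damage &&
        (n_events > loading$substep_fraction * system$n_e || stalled) &&
        dq < loading$max_substep_depth && eps - prev_strain > 1e-8) {
      ## too much happened at once: rollback and bisect the increment
      state <- snapshot
      set_system_scales(system, state$scale)
      mid <- 0.5 * (prev_strain + eps)
      queue <- c(list(mid, eps), queue)
      depth <- c(dq + 1L, dq + 1L, depth)
      next
    }
    ## record crack normals for elements cracking in this step
    if (damage) {
      newly <- which(state$cracked & is.na(state$crack_normal[, 1]))
      if (length(newly)) {
        pr <- principal_strains(system, sol, directions_for = newly)
        state$crack_normal[newly, ] <- pr$directions
      }
    }
    delta_now <- eps * system$H_mm
    F_now <- abs(sol$reaction_force)
    W <- W + 0.5 * (F_prev + F_now) * (delta_now - d_prev)
    F_prev <- F_now; d_prev <- delta_now
    nrec <- nrec + 1L
    steps[[nrec]] <- data.frame(
      strain = eps, stress = sol$apparent_stress,
      n_yielded_t = n_flag[1], n_yielded_c = n_flag[2],
      n_cracked = n_flag[3], n_failed = n_flag[4],
      new_events = n_events, iterations = it,
      external_work = W, stored_energy = sol$stored_energy,
      dissipated = W - sol$stored_energy)
    if (verbose)
      message(sprintf("strain %.4f%%: stress %.4f MPa, %d events, %d its",
                      100 * eps, sol$apparent_stress, n_events, it))
    peak <- max(peak, sol$apparent_stress)
    prev_strain <- eps
    if (damage && !intact_path_ok(system, state)) {
      termination <- "complete_fracture"
      break
    }
    if (damage && peak > 0 && sol$apparent_stress <
        loading$stop_fraction_of_peak * peak &&
        sol$apparent_stress < peak) {
      termination <- "load_drop"
      break
    }
    if (stalled) {
      ## secant loop still moving after the iteration and bisection budgets
      termination <- "non_convergence"
      break
    }
  }
  steps <- do.call(rbind, steps[seq_len(nrec)])
  structure(list(steps = steps, termination = termination,
                 state = state, system = system, model = model,
                 material = material, loading = loading,
                 direction = direction,
                 fracture_strain = steps$strain[nrec],
                 ultimate_stress = max(steps$stress),
                 strain_at_ultimate = steps$strain[which.max(steps$stress)]),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("simulation_result: %d steps, termination: %s\n",
              nrow(x$steps), x$termination))
  cat(sprintf("  ultimate stress %.3f MPa at %.3f%% strain; fracture strain %.3f%%\n",
              x$ultimate_stress, 100 * x$strain_at_ultimate,
              100 * x$fracture_strain))
  invisible(x)
}

#' Linear elastic probe solve
#'
#' One stateless linear solve at a small apparent strain; feeds the low-strain
#' strut ranking and apparent-modulus reporting.
#'
#' @param model A `voxel_model` with a load path.
#' @param material A `material_params`.
#' @param strain Apparent strain (default 0.001).
#' @param solver Passed to [assemble()].
#' @return A `field_solution` with an extra `apparent_modulus` field (MPa).
#' @export
elastic_probe <- function(model, material, strain = 0.001,
                          solver = c("auto", "direct", "cg")) {
  solver <- match.arg(solver)
  if (strain < 0) stop("strain must be non-negative")
  system <- assemble(model, material, solver = solver)
  sol <- solve_compression(system, strain)
  sol$apparent_modulus <- if (strain > 0) sol$apparent_stress / strain else NA_real_
  sol$system <- system
  sol
}
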