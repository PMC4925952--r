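#' @title Age-related bone loss transforms
#' @name degeneration
#' @description Two-step thinning-then-resorption at random or low-strain
#'   sites, and the three isolated degeneration patterns (uniform thinning,
#'   loss of vertical trabeculae, loss of horizontal trabeculae), each
#'   targeting a prescribed relative BV/TV reduction.
NULL

#' Degeneration specification
#'
#' @param location Where bone is lost: `"random"` sites or `"low_strain"`
#'   locations (struts carrying the least strain energy under a small elastic
#'   compression probe).
#' @param pattern `"two_step"` (thinning of a degenerated region followed by
#'   strut resorption), `"thinning_only"`, `"vertical_loss"` or
#'   `"horizontal_loss"`.
#' @param target_bvtv_reduction Relative BV/TV reduction, e.g. 0.15 for the
#'   aged rod models, 0.25 for the aged plate models, 0.08 for the isolated
#'   pattern models.
#' @param thinned_thickness Thickness (um) the degenerated region is thinned
#'   to in the two-step process (default 126, the aged trabecular thickness).
#' @param low_strain_percentile Fraction of struts forming the degenerated
#'   region (default 0.30); also sets the random-site region size.
#' @param seed RNG seed making stochastic degeneration reproducible.
#' @param tolerance Allowed deviation of the achieved relative reduction
#'   (default 0.005, i.e. half a percentage point).
#' @return A `degeneration_spec` object.
#' @export
degeneration_spec <- function(location = c("random", "low_strain"),
                              pattern = c("two_step", "thinning_only",
                                          "vertical_loss", "horizontal_loss"),
                              target_bvtv_reduction,
                              thinned_thickness = 126,
                              low_strain_percentile = 0.30,
                              seed = 1L,
                              tolerance = 0.005) {
  location <- match.arg(location)
  pattern <- match.arg(pattern)
  if (target_bvtv_reduction < 0 || target_bvtv_reduction >= 1)
    stop("target_bvtv_reduction must lie in [0, 1)")
  if (thinned_thickness <= 0) stop("thinned_thickness must be positive")
  if (low_strain_percentile <= 0 || low_strain_percentile > 1)
    stop("low_strain_percentile must lie in (0, 1]")
  structure(list(location = location, pattern = pattern,
                 target_bvtv_reduction = target_bvtv_reduction,
                 thinned_thickness = thinned_thickness,
                 low_strain_percentile = low_strain_percentile,
                 seed = as.integer(seed), tolerance = tolerance),
            class = "degeneration_spec")
}

active_struts <- function(model) model$struts[!model$struts$removed, , drop = FALSE]

#' Uniformly sample struts eligible for resorption
#'
#' Samples without replacement from the active struts that do not touch the
#' loading platens (boundary struts are never resorbed, to avoid
#' load-introduction artifacts). Reproducible under a fixed seed; the caller's
#' RNG state is untouched.
#'
#' @param model A `voxel_model`.
#' @param n Number of struts to draw.
#' @param seed RNG seed.
#' @return Strut ids in sample order.
#' @export
select_random_struts <- function(model, n, seed = 1L) {
  el <- active_struts(model)
  el <- el$id[!el$boundary]
  if (n > length(el))
    stop(sprintf("requested %d struts but only %d are eligible", n, length(el)))
  if (n == 0) return(integer(0))
  with_local_seed(seed, el[sample.int(length(el), n)])
}

## full ascending ranking of active struts by mean element strain energy
## density under a small elastic compression probe; ties broken by id
strut_strain_ranking <- function(model, material, probe_strain = 0.001) {
  sol <- elastic_probe(model, material, probe_strain)
  owner <- model$strut_id[sol$system$elements]
  keep <- owner > 0L
  sed_mean <- tapply(sol$sed[keep], owner[keep], mean)
  ids <- as.integer(names(sed_mean))
  ord <- order(as.numeric(sed_mean), ids)
  list(ids = ids[ord], sed = as.numeric(sed_mean)[ord])
}

#' Identify low-strain struts
#'
#' Runs one linear elastic compression solve at a small apparent strain, ranks
#' struts by the mean strain-energy density of their member elements, and
#' returns the struts in the lowest `percentile` fraction (strict: with `n`
#' ranked struts, the `floor(percentile * n)` lowest; ties broken by ascending
#' strut id).
#'
#' @param model A `voxel_model` connected between the loading faces.
#' @param material A `material_params`.
#' @param percentile Fraction in (0, 1].
#' @param probe_strain Apparent strain of the elastic probe (default 0.001).
#' @return Strut ids, ascending strain-energy order.
#' @export
identify_low_strain_struts <- function(model, material, percentile = 0.30,
                                       probe_strain = 0.001) {
  if (percentile <= 0 || percentile > 1)
    stop("percentile must lie in (0, 1]")
  rk <- strut_strain_ranking(model, material, probe_strain)
  k <- floor(percentile * length(rk$ids))
  rk$ids[seq_len(k)]
}

## shrink the box of one strut row to a new thickness about its center
shrink_strut_row <- function(struts, row, new_thickness) {
  ax <- strsplit(struts$shrink[row], "")[[1]]
  for (d in ax) {
    lo <- paste0(d, "0"); hi <- paste0(d, "1")
    ctr <- (struts[[lo]][row] + struts[[hi]][row]) / 2
    struts[[lo]][row] <- ctr - new_thickness / 2
    struts[[hi]][row] <- ctr + new_thickness / 2
  }
  struts$thickness[row] <- new_thickness
  struts
}

#' Thin selected struts to a new thickness
#'
#' Rebuilds the listed struts with a reduced cross-section (transverse axes
#' for rods, the normal axis for plates) via partial-occupancy voxels. Voxels
#' outside the listed struts' original extents are unchanged.
#'
#' @param model A `voxel_model`.
#' @param ids Strut ids to thin.
#' @param new_thickness New thickness (um); must not exceed the current
#'   thickness of any listed strut.
#' @return The modified `voxel_model`.
#' @export
thin_struts <- function(model, ids, new_thickness) {
  if (new_thickness <= 0) stop("new_thickness must be positive")
  if (!length(ids)) return(model)
  rows <- match(ids, model$struts$id)
  if (anyNA(rows)) stop("unknown strut id(s)")
  if (any(model$struts$removed[rows])) stop("cannot thin a removed strut")
  if (any(model$struts$thickness[rows] < new_thickness - 1e-9))
    stop("new_thickness exceeds the current thickness of a listed strut")
  changed <- FALSE
  for (r in rows) {
    if (abs(model$struts$thickness[r] - new_thickness) < 1e-12) next
    model$struts <- shrink_strut_row(model$struts, r, new_thickness)
    changed <- TRUE
  }
  if (changed) model <- revoxelize(model)
  model
}

#' Remove (resorb) selected struts
#'
#' Marks the listed struts as removed and rebuilds the voxel arrays; the
#' struts stay in the table for provenance (fracture-site analysis).
#'
#' @param model A `voxel_model`.
#' @param ids Strut ids to remove.
#' @return The modified `voxel_model`.
#' @export
remove_struts <- function(model, ids) {
  if (!length(ids)) return(model)
  rows <- match(ids, model$struts$id)
  if (anyNA(rows)) stop("unknown strut id(s)")
  if (any(model$struts$removed[rows])) stop("strut already removed")
  model$struts$removed[rows] <- TRUE
  revoxelize(model)
}

#' Check the vertical load path of a model
#'
#' @param model A `voxel_model`.
#' @param components Also count 6-connected components of the solid phase.
#' @return A list: `connected` (TRUE iff a 6-connected path of solid voxels
#'   joins the bottom and top faces) and optionally `n_components`.
#' @export
check_load_path <- function(model, components = FALSE) {
  grid <- model$grid
  mask <- model$frac > 0
  reach <- flood_reach(mask, face_layer_indices(grid, "bottom"), grid)
  out <- list(connected = any(reach[face_layer_indices(grid, "top")]))
  if (components) out$n_components <- count_components(mask)
  out
}

## relative BV/TV reduction of a working strut table vs a reference volume
rel_reduction <- function(struts, v0) {
  (v0 - continuous_solid_volume(struts)) / v0
}

## bisection on a multiplicative thickness factor for `rows` of the working
## table so the relative reduction hits `target` (continuous volumes exact);
## returns the thinned table or NULL when even maximal thinning falls short
solve_thinning_factor <- function(struts, rows, m_lo, target, v0) {
  apply_m <- function(m) {
    w <- struts
    for (r in rows) w <- shrink_strut_row(w, r, m * struts$thickness[r])
    w
  }
  f <- function(m) rel_reduction(apply_m(m), v0) - target
  if (f(m_lo) < 0) return(NULL)
  lo <- m_lo; hi <- 1
  for (i in seq_len(60)) {
    mid <- 0.5 * (lo + hi)
    if (f(mid) >= 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) break
  }
  apply_m(lo)
}

#' Apply an age-related degeneration transform
#'
#' The two-step pattern mirrors the age-related bone loss sequence: the
#' degenerated region (random sites or low-strain locations) first becomes
#' thinner, after which part of the thinned struts are resorbed whole. Struts
#' are removed (random order, or ascending strain-energy order for low-strain
#' degeneration) while the next whole strut still fits under the target; the
#' residual gap, smaller than one strut volume, is closed by solving a
#' slightly smaller thickness for the remaining region struts, so the achieved
#' relative BV/TV reduction matches the target essentially exactly. The
#' single-mechanism patterns (`thinning_only`, `vertical_loss`,
#' `horizontal_loss`) target the same reduction through one mechanism alone;
#' pure-loss patterns land within one strut volume of the target.
#'
#' @param model A `voxel_model` (a normal lattice).
#' @param spec A [degeneration_spec()].
#' @param material A `material_params`; required for `location = "low_strain"`.
#' @return The degenerated `voxel_model`, with attributes
#'   `achieved_reduction`, `thinned_ids`, `removed_ids` and `final_thickness`.
#' @export
apply_aging <- function(model, spec, material = NULL) {
  stopifnot(inherits(model, "voxel_model"), inherits(spec, "degeneration_spec"))
  target <- spec$target_bvtv_reduction
  if (target == 0) return(model)
  v0 <- continuous_solid_volume(model$struts)
  act <- active_struts(model)
  eligible <- act$id[!act$boundary]
  work <- model$struts
  thinned_ids <- integer(0); removed_order <- integer(0)
  final_thickness <- NA_real_

  remove_in_order <- function(work, candidates, target, extra = integer(0)) {
    ## greedy whole-strut removal staying below the target
    seq_ids <- c(candidates, extra)
    taken <- integer(0)
    for (id in seq_ids) {
      r <- match(id, work$id)
      if (work$removed[r]) next
      trial <- work
      trial$removed[r] <- TRUE
      if (rel_reduction(trial, v0) > target + 1e-12) next_red <- NULL
      else next_red <- trial
      if (is.null(next_red)) break
      work <- trial
      taken <- c(taken, id)
    }
    list(work = work, taken = taken)
  }

  if (spec$pattern == "two_step") {
    if (spec$location == "low_strain") {
      if (is.null(material))
        stop("material is required for low-strain degeneration")
      rk <- strut_strain_ranking(model, material)
      k <- max(1L, floor(spec$low_strain_percentile * length(rk$ids)))
      region <- rk$ids[seq_len(k)]
      cand <- region[!region %in% act$id[act$boundary]]
      extra <- setdiff(rk$ids[rk$ids %in% eligible], cand)
    } else {
      n_region <- max(1L, round(spec$low_strain_percentile * length(eligible)))
      region <- select_random_struts(model, n_region, spec$seed)
      cand <- region
      extra <- with_local_seed(spec$seed + 1L, {
        rest <- setdiff(eligible, region)
        if (length(rest) > 1) sample(rest) else rest
      })
    }
    ## step 1: thin the degenerated region to the aged thickness
    rows <- match(region, work$id)
    rows <- rows[work$thickness[rows] > spec$thinned_thickness]
    for (r in rows) work <- shrink_strut_row(work, r, spec$thinned_thickness)
    thinned_ids <- work$id[rows]
    r_thin <- rel_reduction(work, v0)
    if (r_thin >= target) {
      ## thinning alone overshoots: solve a milder uniform region thinning
      work <- model$struts
      rows <- match(region, work$id)
      m_lo <- spec$thinned_thickness / max(work$thickness[rows])
      work <- solve_thinning_factor(work, rows, m_lo, target, v0)
      final_thickness <- min(work$thickness[rows])
    } else {
      ## step 2: resorb thinned struts whole until the target is near
      res <- remove_in_order(work, cand, target, extra)
      work <- res$work; removed_order <- res$taken
      ## close the residual gap with a slightly smaller region thickness
      if (rel_reduction(work, v0) < target - 1e-12) {
        gap_rows <- match(setdiff(region, removed_order), work$id)
        gap_rows <- gap_rows[!work$removed[gap_rows]]
        thinned <- if (length(gap_rows))
          solve_thinning_factor(work, gap_rows, 0.3, target, v0) else NULL
        if (is.null(thinned)) {
          ## resorption consumed the whole region: close the gap by slight
          ## uniform thinning of every remaining strut
          gap_rows <- which(!work$removed)
          thinned <- solve_thinning_factor(work, gap_rows, 0.3, target, v0)
        }
        if (is.null(thinned))
          stop(sprintf("degeneration target unreachable (achieved %.4f)",
                       rel_reduction(work, v0)))
        work <- thinned
        final_thickness <- min(work$thickness[gap_rows])
      }
    }
  } else if (spec$pattern == "thinning_only") {
    rows <- seq_len(nrow(work))[!work$removed]
    work <- solve_thinning_factor(work, rows, 0.2, target, v0)
    if (is.null(work)) stop("thinning target unreachable")
    thinned_ids <- work$id[rows]
    final_thickness <- min(work$thickness[rows])
  } else {
    want <- if (spec$pattern == "vertical_loss") "vertical" else "horizontal"
    pool <- act$id[act$orientation == want & !act$boundary]
    if (!length(pool)) stop("no eligible struts of the requested orientation")
    cand <- with_local_seed(spec$seed,
                            if (length(pool) > 1) sample(pool) else pool)
    res <- remove_in_order(work, cand, target)
    work <- res$work; removed_order <- res$taken
    ## nearest landing: one more strut if it lands closer to the target
    left <- cand[!cand %in% removed_order]
    if (length(left)) {
      r <- match(left[1], work$id)
      trial <- work; trial$removed[r] <- TRUE
      if (abs(rel_reduction(trial, v0) - target) <
          abs(rel_reduction(work, v0) - target)) {
        work <- trial
        removed_order <- c(removed_order, left[1])
      }
    }
  }

  achieved <- rel_reduction(work, v0)
  if (abs(achieved - target) > spec$tolerance)
    stop(sprintf("achieved reduction %.4f misses target %.4f (tolerance %.4f)",
                 achieved, target, spec$tolerance))
  model$struts <- work
  model <- revoxelize(model)
  if (!check_load_path(model)$connected)
    stop(sprintf("degeneration disconnected all load paths (achieved %.4f)",
                 achieved))
  attr(model, "achieved_reduction") <- achieved
  attr(model, "thinned_ids") <- thinned_ids
  attr(model, "removed_ids") <- removed_order
  attr(model, "final_thickness") <- final_thickness
  model
}
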