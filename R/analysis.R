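#' @title Curve metrics and normal-vs-aged comparisons
#' @name analysis
#' @description Extraction of apparent-curve metrics (apparent modulus,
#'   ultimate stress, fracture strain), percent differences against the
#'   normal model, ordering verdicts across degeneration locations and
#'   patterns, and fracture-site proximity to resorbed struts.
NULL

#' Extract curve metrics from a simulation result
#'
#' @param result A `simulation_result`, or any object with a `steps` data
#'   frame holding `strain` and `stress` columns.
#' @return A `curve_metrics` list: `apparent_modulus` (MPa, least squares
#'   through the origin on the first three steps), `ultimate_stress` (MPa),
#'   `strain_at_ultimate`, `fracture_strain` (the termination strain),
#'   `yield_stress` / `yield_strain` (0.2%-offset equivalent, `NA` if the
#'   curve never crosses the offset line) and the `termination` reason.
#' @export
extract_metrics <- function(result) {
  s <- result$steps
  if (is.null(s) || nrow(s) < 2) stop("need at least 2 recorded steps")
  if (all(s$stress == 0)) stop("all-zero stress curve")
  k <- seq_len(min(3L, nrow(s)))
  Em <- sum(s$stress[k] * s$strain[k]) / sum(s$strain[k]^2)
  iu <- which.max(s$stress)
  ## 0.2%-offset yield point
  off <- s$stress - Em * (s$strain - 0.002)
  yield_stress <- yield_strain <- NA_real_
  cross <- which(off[-1] <= 0 & off[-nrow(s)] > 0)
  if (length(cross)) {
    i <- cross[1]
    w <- off[i] / (off[i] - off[i + 1])
    yield_strain <- s$strain[i] + w * (s$strain[i + 1] - s$strain[i])
    yield_stress <- s$stress[i] + w * (s$stress[i + 1] - s$stress[i])
  }
  structure(list(apparent_modulus = Em,
                 ultimate_stress = max(s$stress),
                 strain_at_ultimate = s$strain[iu],
                 fracture_strain = s$strain[nrow(s)],
                 yield_stress = yield_stress, yield_strain = yield_strain,
                 termination = if (!is.null(result$termination))
                   result$termination else NA_character_),
            class = "curve_metrics")
}

#' @export
print.curve_metrics <- function(x, ...) {
  cat(sprintf("apparent modulus %.1f MPa; ultimate %.3f MPa at %.3f%%; fracture strain %.3f%%\n",
              x$apparent_modulus, x$ultimate_stress,
              100 * x$strain_at_ultimate, 100 * x$fracture_strain))
  invisible(x)
}

#' Percent difference of curve metrics relative to a reference model
#'
#' `100 * (reference - other) / reference` for fracture strain and ultimate
#' stress; positive values mean the other model is weaker.
#'
#' @param reference,other `curve_metrics` objects.
#' @return Named numeric vector with `fracture_strain` and `ultimate_stress`
#'   percent differences.
#' @export
percent_difference <- function(reference, other) {
  if (reference$fracture_strain == 0 || reference$ultimate_stress == 0)
    stop("reference metrics must be nonzero")
  c(fracture_strain = 100 * (reference$fracture_strain - other$fracture_strain) /
      reference$fracture_strain,
    ultimate_stress = 100 * (reference$ultimate_stress - other$ultimate_stress) /
      reference$ultimate_stress)
}

#' Ordering verdicts across degeneration locations and patterns
#'
#' Aggregates replicate metrics by per-model medians and evaluates the
#' orderings of interest: normal > random-site aged > low-strain aged (A > B
#' > C) within each family, residual strength thinning > horizontal loss >
#' vertical loss (D > F > E), and plate family > rod family, for ultimate
#' stress and fracture strain separately.
#'
#' @param metrics A data frame with columns `family` ("rod"/"plate"), `model`
#'   (e.g. "A", "B", "C", "D", "E", "F"), `seed`, `ultimate_stress`,
#'   `fracture_strain`.
#' @return A data frame of `check`, `metric`, `verdict` rows; attribute
#'   `medians` carries the per-model medians used.
#' @export
ordering_checks <- function(metrics) {
  need <- c("family", "model", "ultimate_stress", "fracture_strain")
  if (!all(need %in% names(metrics))) stop("metrics lacks required columns")
  med <- stats::aggregate(metrics[c("ultimate_stress", "fracture_strain")],
                          by = metrics[c("family", "model")], FUN = stats::median)
  g <- function(fam, mod, what) {
    v <- med[[what]][med$family == fam & med$model == mod]
    if (length(v) != 1) NA_real_ else v
  }
  rows <- list()
  for (what in c("ultimate_stress", "fracture_strain")) {
    for (fam in unique(med$family)) {
      rows[[length(rows) + 1]] <- data.frame(
        check = sprintf("%s: A > B > C", fam), metric = what,
        verdict = g(fam, "A", what) > g(fam, "B", what) &
          g(fam, "B", what) > g(fam, "C", what))
      rows[[length(rows) + 1]] <- data.frame(
        check = sprintf("%s: thinning > horizontal loss > vertical loss", fam),
        metric = what,
        verdict = g(fam, "D", what) > g(fam, "F", what) &
          g(fam, "F", what) > g(fam, "E", what))
    }
    if (all(c("rod", "plate") %in% med$family)) {
      common <- intersect(med$model[med$family == "rod"],
                          med$model[med$family == "plate"])
      rows[[length(rows) + 1]] <- data.frame(
        check = "plate family > rod family", metric = what,
        verdict = all(vapply(common, function(mo)
          g("plate", mo, what) > g("rod", mo, what), TRUE)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "medians") <- med
  out
}

#' Proximity of fracture sites to resorbed struts
#'
#' Distances from failed-element centroids to the nearest removed strut's
#' medial line (rods) or medial plane patch (plates).
#'
#' @param result A `simulation_result` run on a degenerated model.
#' @param model The degenerated `voxel_model` (defaults to the model stored in
#'   the result); its strut table must contain removed struts.
#' @param failed `"failed"` to use fully failed elements (d = 1), `"cracked"`
#'   to use all cracked elements.
#' @return A list: `n_failed`, `mean_distance` (um, `NA` when no elements
#'   failed), `fraction_within_spacing` (fraction of failed elements within
#'   one cell spacing of a removed strut) and the per-element `distances`.
#' @export
fracture_site_proximity <- function(result, model = result$model,
                                    failed = c("failed", "cracked")) {
  failed <- match.arg(failed)
  rem <- model$struts[model$struts$removed, , drop = FALSE]
  if (!nrow(rem)) stop("model has no removed struts; proximity undefined")
  sel <- if (failed == "failed") result$state$d >= 1 - 1e-12 else
    result$state$cracked
  idx <- result$system$elements[sel]
  spacing <- model$lattice$spacing
  if (!length(idx))
    return(list(n_failed = 0L, mean_distance = NA_real_,
                fraction_within_spacing = 0, distances = numeric(0)))
  grid <- model$grid; h <- model$voxel
  i <- (idx - 1L) %% grid[1]; j <- ((idx - 1L) %/% grid[1]) %% grid[2]
  k <- (idx - 1L) %/% (grid[1] * grid[2])
  pt <- cbind((i + 0.5) * h, (j + 0.5) * h, (k + 0.5) * h)
  dmin <- rep(Inf, nrow(pt))
  for (r in seq_len(nrow(rem))) {
    ## medial set: collapse the shrink axes of the box to its center
    lo <- c(rem$x0[r], rem$y0[r], rem$z0[r])
    hi <- c(rem$x1[r], rem$y1[r], rem$z1[r])
    shrink <- strsplit(rem$shrink[r], "")[[1]]
    ax <- match(shrink, c("x", "y", "z"))
    ctr <- (lo + hi) / 2
    lo[ax] <- ctr[ax]; hi[ax] <- ctr[ax]
    dx <- pmax(lo[1] - pt[, 1], 0, pt[, 1] - hi[1])
    dy <- pmax(lo[2] - pt[, 2], 0, pt[, 2] - hi[2])
    dz <- pmax(lo[3] - pt[, 3], 0, pt[, 3] - hi[3])
    dmin <- pmin(dmin, sqrt(dx^2 + dy^2 + dz^2))
  }
  list(n_failed = length(idx), mean_distance = mean(dmin),
       fraction_within_spacing = mean(dmin <= spacing),
       distances = dmin)
}

#' Overlay apparent stress-strain curves
#'
#' @param results Named list of `simulation_result` objects (or data frames
#'   with `strain`/`stress`).
#' @param file Optional path: when given, a PNG is written there.
#' @return Invisibly, the combined long-format data frame.
#' @export
plot_stress_strain <- function(results, file = NULL) {
  dat <- do.call(rbind, lapply(names(results), function(nm) {
    s <- if (!is.null(results[[nm]]$steps)) results[[nm]]$steps else results[[nm]]
    data.frame(model = nm, strain = s$strain, stress = s$stress)
  }))
  draw <- function() {
    if (requireNamespace("ggplot2", quietly = TRUE)) {
      p <- ggplot2::ggplot(dat, ggplot2::aes(x = 100 * strain, y = stress,
                                             colour = model)) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "apparent strain (%)", y = "apparent stress (MPa)")
      print(p)
    } else {
      models <- unique(dat$model)
      plot(NA, xlim = range(100 * dat$strain), ylim = range(dat$stress),
           xlab = "apparent strain (%)", ylab = "apparent stress (MPa)")
      for (q in seq_along(models)) {
        d <- dat[dat$model == models[q], ]
        graphics::lines(100 * d$strain, d$stress, col = q)
      }
      graphics::legend("topright", legend = models, col = seq_along(models),
                       lty = 1)
    }
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600)
    on.exit(grDevices::dev.off())
    draw()
  } else draw()
  invisible(dat)
}
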