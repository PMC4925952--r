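#' @title Idealized trabecular lattice generators
#' @name geometry
#' @description Parametric rod-like (cubic open-cell) and plate-like (walls +
#'   shelves) trabecular lattices, voxelized on a regular grid with exact
#'   partial-occupancy surface voxels. The loading axis is z by convention.
NULL

#' Lattice specification
#'
#' Describes an idealized trabecular lattice before voxelization. All lengths
#' are in micrometres.
#'
#' @param lattice_type `"rod"` (cubic open cell of square-cross-section struts)
#'   or `"plate"` (orthogonal vertical walls plus horizontal shelves).
#' @param strut_thickness Strut side length / plate thickness (um).
#' @param cell_spacing Center-to-center cell spacing (um), isotropic.
#' @param cells_per_axis Integer triple, number of unit cells per axis.
#' @param voxel_size Requested voxel edge (um); snapped to the nearest value
#'   that divides `cell_spacing` evenly so the grid tiles the domain exactly.
#' @param scale_factor Geometric scale applied to all lengths at build time
#'   (e.g. 10 for rapid-prototype replicas); BV/TV is scale invariant.
#' @return An object of class `lattice_spec`.
#' @export
lattice_spec <- function(lattice_type = c("rod", "plate"),
                         strut_thickness = 140,
                         cell_spacing = NULL,
                         cells_per_axis = c(5L, 5L, 5L),
                         voxel_size = 35,
                         scale_factor = 1) {
  lattice_type <- match.arg(lattice_type)
  if (!is.numeric(strut_thickness) || strut_thickness <= 0)
    stop("strut_thickness must be positive")
  if (is.null(cell_spacing))
    stop("cell_spacing must be given (use solve_spacing_for_bvtv() to derive it)")
  if (cell_spacing < strut_thickness)
    stop("cell_spacing must be >= strut_thickness")
  cells_per_axis <- as.integer(rep_len(cells_per_axis, 3L))
  if (any(cells_per_axis < 1L)) stop("cells_per_axis must be >= 1")
  if (voxel_size <= 0 || voxel_size > strut_thickness)
    stop("voxel_size must be in (0, strut_thickness]")
  if (scale_factor < 1) stop("scale_factor must be >= 1")
  structure(list(lattice_type = lattice_type,
                 strut_thickness = strut_thickness,
                 cell_spacing = cell_spacing,
                 cells_per_axis = cells_per_axis,
                 voxel_size = voxel_size,
                 scale_factor = scale_factor),
            class = "lattice_spec")
}

#' Continuous-geometry bone volume fraction of a lattice
#'
#' Closed-form volume fraction of the periodic unit cell as a function of the
#' thickness-to-spacing ratio `x`: `3x^2 - 2x^3` for the cubic open-cell rod
#' lattice (three orthogonal strut families, inclusion-exclusion of the
#' junction cubes), `1 - (1 - x)^3` for the plate lattice (three orthogonal
#' wall families).
#'
#' @param lattice_type `"rod"` or `"plate"`.
#' @param x thickness / spacing ratio in (0, 1].
#' @return Volume fraction in (0, 1].
#' @export
continuous_bvtv <- function(lattice_type, x) {
  switch(lattice_type,
         rod = 3 * x^2 - 2 * x^3,
         plate = 1 - (1 - x)^3,
         stop("unknown lattice_type"))
}

#' Solve the cell spacing that yields a target BV/TV
#'
#' Inverts the closed-form spacing -> BV/TV map by bisection on the monotone
#' thickness/spacing ratio, then rounds the spacing to the nearest 0.1 um.
#'
#' @param lattice_type `"rod"` or `"plate"`.
#' @param strut_thickness Strut/plate thickness (um).
#' @param target_bvtv Target bone volume fraction in (0, 1).
#' @param tol Absolute tolerance on BV/TV (default 1e-3, checked after
#'   rounding).
#' @return Cell spacing in um.
#' @examples
#' solve_spacing_for_bvtv("rod", 140, 0.1029)  # ~705 um
#' @export
solve_spacing_for_bvtv <- function(lattice_type, strut_thickness, target_bvtv,
                                   tol = 1e-3) {
  if (!is.numeric(target_bvtv) || target_bvtv <= 0 || target_bvtv >= 1)
    stop("target_bvtv must lie strictly between 0 and 1")
  if (strut_thickness <= 0) stop("strut_thickness must be positive")
  f <- function(x) continuous_bvtv(lattice_type, x) - target_bvtv
  lo <- 1e-9; hi <- 1
  if (f(hi) < 0) stop("target_bvtv unreachable for this lattice type")
  for (i in seq_len(200)) {          # plain bisection; map is monotone in x
    mid <- 0.5 * (lo + hi)
    if (f(mid) >= 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-14) break
  }
  spacing <- round(strut_thickness / hi, 1)
  achieved <- continuous_bvtv(lattice_type, strut_thickness / spacing)
  if (abs(achieved - target_bvtv) > tol)
    stop(sprintf("spacing inversion missed target (achieved %.5f, target %.5f)",
                 achieved, target_bvtv))
  spacing
}

## ---- strut/panel box tables -------------------------------------------------
## Each strut (rod segment or plate panel) is an axis-aligned box. `shrink`
## names the axes reduced by thinning (transverse axes for rods, the normal
## axis for plates). `removed` struts stay in the table for provenance but are
## excluded from voxelization.

empty_strut_table <- function() {
  data.frame(id = integer(), axis = character(), orientation = character(),
             x0 = numeric(), x1 = numeric(), y0 = numeric(), y1 = numeric(),
             z0 = numeric(), z1 = numeric(), thickness = numeric(),
             shrink = character(), boundary = logical(), removed = logical(),
             stringsAsFactors = FALSE)
}

rod_strut_table <- function(a, t, n) {
  h2 <- t / 2
  rows <- list()
  ## vertical struts (along z), one segment per cell level
  g <- expand.grid(k = seq_len(n[3]), j = seq_len(n[2]), i = seq_len(n[1]))
  cx <- (g$i - 0.5) * a; cy <- (g$j - 0.5) * a
  rows$v <- data.frame(axis = "z", orientation = "vertical",
                       x0 = cx - h2, x1 = cx + h2, y0 = cy - h2, y1 = cy + h2,
                       z0 = (g$k - 1) * a, z1 = g$k * a,
                       thickness = t, shrink = "xy",
                       boundary = g$k == 1L | g$k == n[3],
                       stringsAsFactors = FALSE)
  ## horizontal struts along x
  g <- expand.grid(i = seq_len(n[1]), k = seq_len(n[3]), j = seq_len(n[2]))
  cy <- (g$j - 0.5) * a; cz <- (g$k - 0.5) * a
  rows$x <- data.frame(axis = "x", orientation = "horizontal",
                       x0 = (g$i - 1) * a, x1 = g$i * a,
                       y0 = cy - h2, y1 = cy + h2, z0 = cz - h2, z1 = cz + h2,
                       thickness = t, shrink = "yz", boundary = FALSE,
                       stringsAsFactors = FALSE)
  ## horizontal struts along y
  g <- expand.grid(j = seq_len(n[2]), k = seq_len(n[3]), i = seq_len(n[1]))
  cx <- (g$i - 0.5) * a; cz <- (g$k - 0.5) * a
  rows$y <- data.frame(axis = "y", orientation = "horizontal",
                       x0 = cx - h2, x1 = cx + h2,
                       y0 = (g$j - 1) * a, y1 = g$j * a,
                       z0 = cz - h2, z1 = cz + h2,
                       thickness = t, shrink = "xz", boundary = FALSE,
                       stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  out$id <- seq_len(nrow(out))
  out$removed <- FALSE
  rownames(out) <- NULL
  out[, names(empty_strut_table())]
}

plate_strut_table <- function(a, t, n) {
  h2 <- t / 2
  rows <- list()
  ## walls normal to x (vertical), one panel per (j,k) cell
  g <- expand.grid(k = seq_len(n[3]), j = seq_len(n[2]), i = seq_len(n[1]))
  cx <- (g$i - 0.5) * a
  rows$x <- data.frame(axis = "x", orientation = "vertical",
                       x0 = cx - h2, x1 = cx + h2,
                       y0 = (g$j - 1) * a, y1 = g$j * a,
                       z0 = (g$k - 1) * a, z1 = g$k * a,
                       thickness = t, shrink = "x",
                       boundary = g$k == 1L | g$k == n[3],
                       stringsAsFactors = FALSE)
  ## walls normal to y (vertical)
  g <- expand.grid(k = seq_len(n[3]), i = seq_len(n[1]), j = seq_len(n[2]))
  cy <- (g$j - 0.5) * a
  rows$y <- data.frame(axis = "y", orientation = "vertical",
                       x0 = (g$i - 1) * a, x1 = g$i * a,
                       y0 = cy - h2, y1 = cy + h2,
                       z0 = (g$k - 1) * a, z1 = g$k * a,
                       thickness = t, shrink = "y",
                       boundary = g$k == 1L | g$k == n[3],
                       stringsAsFactors = FALSE)
  ## horizontal shelves normal to z
  g <- expand.grid(j = seq_len(n[2]), i = seq_len(n[1]), k = seq_len(n[3]))
  cz <- (g$k - 0.5) * a
  rows$z <- data.frame(axis = "z", orientation = "horizontal",
                       x0 = (g$i - 1) * a, x1 = g$i * a,
                       y0 = (g$j - 1) * a, y1 = g$j * a,
                       z0 = cz - h2, z1 = cz + h2,
                       thickness = t, shrink = "z", boundary = FALSE,
                       stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  out$id <- seq_len(nrow(out))
  out$removed <- FALSE
  rownames(out) <- NULL
  out[, names(empty_strut_table())]
}

## ---- voxelization -----------------------------------------------------------

## fractional coverage of voxels [ (i-1)h, ih ] by interval [lo, hi]
axis_cover <- function(lo, hi, n, h) {
  if (hi <= lo) return(NULL)
  i0 <- max(1L, as.integer(floor(lo / h + 1e-12)) + 1L)
  i1 <- min(n, as.integer(ceiling(hi / h - 1e-12)))
  if (i1 < i0) return(NULL)
  idx <- i0:i1
  w <- (pmin(hi, idx * h) - pmax(lo, (idx - 1) * h)) / h
  list(idx = idx, w = pmax(w, 0))
}

## pairwise and triple intersections among active boxes (positive volume only).
## Within a family boxes never overlap with positive volume, so depth 3 is exact.
box_overlaps <- function(b) {
  S <- nrow(b)
  out <- list(pairs = NULL, triples = NULL)
  if (S < 2) return(out)
  ia <- rep(seq_len(S), times = S); ib <- rep(seq_len(S), each = S)
  keep <- ia < ib
  ia <- ia[keep]; ib <- ib[keep]
  x0 <- pmax(b$x0[ia], b$x0[ib]); x1 <- pmin(b$x1[ia], b$x1[ib])
  y0 <- pmax(b$y0[ia], b$y0[ib]); y1 <- pmin(b$y1[ia], b$y1[ib])
  z0 <- pmax(b$z0[ia], b$z0[ib]); z1 <- pmin(b$z1[ia], b$z1[ib])
  pos <- (x1 - x0 > 1e-9) & (y1 - y0 > 1e-9) & (z1 - z0 > 1e-9)
  if (!any(pos)) return(out)
  pr <- data.frame(a = ia[pos], b = ib[pos],
                   x0 = x0[pos], x1 = x1[pos], y0 = y0[pos], y1 = y1[pos],
                   z0 = z0[pos], z1 = z1[pos])
  out$pairs <- pr
  ## unique triples: extend each pair with c > b
  tr <- vector("list", nrow(pr))
  for (p in seq_len(nrow(pr))) {
    cs <- which(seq_len(S) > pr$b[p])
    if (!length(cs)) next
    x0 <- pmax(pr$x0[p], b$x0[cs]); x1 <- pmin(pr$x1[p], b$x1[cs])
    y0 <- pmax(pr$y0[p], b$y0[cs]); y1 <- pmin(pr$y1[p], b$y1[cs])
    z0 <- pmax(pr$z0[p], b$z0[cs]); z1 <- pmin(pr$z1[p], b$z1[cs])
    pos <- (x1 - x0 > 1e-9) & (y1 - y0 > 1e-9) & (z1 - z0 > 1e-9)
    if (any(pos))
      tr[[p]] <- data.frame(x0 = x0[pos], x1 = x1[pos], y0 = y0[pos],
                            y1 = y1[pos], z0 = z0[pos], z1 = z1[pos])
  }
  tr <- tr[!vapply(tr, is.null, TRUE)]
  if (length(tr)) out$triples <- do.call(rbind, tr)
  out
}

## exact continuous solid volume of the union of the active boxes
continuous_solid_volume <- function(struts) {
  b <- struts[!struts$removed, , drop = FALSE]
  if (!nrow(b)) return(0)
  vol <- function(d) sum((d$x1 - d$x0) * (d$y1 - d$y0) * (d$z1 - d$z0))
  ov <- box_overlaps(b)
  v <- vol(b)
  if (!is.null(ov$pairs)) v <- v - vol(ov$pairs)
  if (!is.null(ov$triples)) v <- v + vol(ov$triples)
  v
}

## Rasterize active boxes onto the grid. Returns exact per-voxel solid
## fractions (inclusion-exclusion over box overlaps) and per-voxel owning strut
## (largest contribution; ties go to the strut processed first: vertical
## families, then ascending id).
voxelize_struts <- function(struts, grid, h) {
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  frac <- array(0, dim = grid)
  best <- array(0, dim = grid)
  owner <- array(0L, dim = grid)
  act <- struts[!struts$removed, , drop = FALSE]
  if (nrow(act)) {
    ord <- order(act$orientation != "vertical", act$id)
    act <- act[ord, , drop = FALSE]
    for (s in seq_len(nrow(act))) {
      ox <- axis_cover(act$x0[s], act$x1[s], nx, h)
      oy <- axis_cover(act$y0[s], act$y1[s], ny, h)
      oz <- axis_cover(act$z0[s], act$z1[s], nz, h)
      if (is.null(ox) || is.null(oy) || is.null(oz)) next
      contrib <- (ox$w %o% oy$w) %o% oz$w
      frac[ox$idx, oy$idx, oz$idx] <-
        frac[ox$idx, oy$idx, oz$idx, drop = FALSE] + contrib
      cur <- best[ox$idx, oy$idx, oz$idx, drop = FALSE]
      repl <- contrib > cur + 1e-12
      if (any(repl)) {
        cur[repl] <- contrib[repl]
        best[ox$idx, oy$idx, oz$idx] <- cur
        ow <- owner[ox$idx, oy$idx, oz$idx, drop = FALSE]
        ow[repl] <- act$id[s]
        owner[ox$idx, oy$idx, oz$idx] <- ow
      }
    }
    ov <- box_overlaps(act)
    rast <- function(d, w) {
      for (s in seq_len(nrow(d))) {
        ox <- axis_cover(d$x0[s], d$x1[s], nx, h)
        oy <- axis_cover(d$y0[s], d$y1[s], ny, h)
        oz <- axis_cover(d$z0[s], d$z1[s], nz, h)
        if (is.null(ox) || is.null(oy) || is.null(oz)) next
        frac[ox$idx, oy$idx, oz$idx] <<-
          frac[ox$idx, oy$idx, oz$idx, drop = FALSE] +
          w * ((ox$w %o% oy$w) %o% oz$w)
      }
    }
    if (!is.null(ov$pairs)) rast(ov$pairs, -1)
    if (!is.null(ov$triples)) rast(ov$triples, +1)
  }
  frac[frac < 1e-12] <- 0
  frac[frac > 1] <- 1
  owner[frac == 0] <- 0L
  list(frac = frac, strut_id = owner)
}

new_voxel_model <- function(struts, grid, voxel, lattice) {
  vox <- voxelize_struts(struts, grid, voxel)
  structure(list(grid = as.integer(grid), voxel = voxel,
                 extent = grid * voxel,
                 frac = vox$frac, strut_id = vox$strut_id,
                 struts = struts, lattice = lattice),
            class = "voxel_model")
}

## rebuild voxel arrays after a change to the strut table
revoxelize <- function(model) {
  vox <- voxelize_struts(model$struts, model$grid, model$voxel)
  model$frac <- vox$frac
  model$strut_id <- vox$strut_id
  model
}

build_lattice <- function(spec) {
  sf <- spec$scale_factor
  t <- spec$strut_thickness * sf
  a <- spec$cell_spacing * sf
  h0 <- spec$voxel_size * sf
  k <- max(1L, as.integer(round(a / h0)))
  if (a / k > t + 1e-9) k <- as.integer(ceiling(a / h0))
  h <- a / k
  n <- spec$cells_per_axis
  grid <- n * k
  struts <- switch(spec$lattice_type,
                   rod = rod_strut_table(a, t, n),
                   plate = plate_strut_table(a, t, n))
  lattice <- list(type = spec$lattice_type, thickness = t, spacing = a,
                  cells = n, requested_voxel = h0, spec = spec)
  new_voxel_model(struts, grid, h, lattice)
}

#' Build a rod-like (cubic open-cell) trabecular lattice
#'
#' Three orthogonal families of square-cross-section struts meeting at cell
#' centers; vertical struts run along z (the loading axis), horizontal struts
#' along x and y. Surface voxels carry exact partial solid fractions, so the
#' voxelized BV/TV matches the continuous closed form `3x^2 - 2x^3`
#' (x = thickness/spacing) to machine precision.
#'
#' @param spec A [lattice_spec()] with `lattice_type = "rod"`.
#' @return A `voxel_model`: voxel grid (`frac`, `strut_id` arrays), strut table
#'   and lattice metadata.
#' @export
build_rod_lattice <- function(spec) {
  if (spec$lattice_type != "rod") stop("spec is not a rod lattice")
  build_lattice(spec)
}

#' Build a plate-like trabecular lattice
#'
#' Two orthogonal families of vertical walls (a square honeycomb providing
#' continuous vertical load paths) plus horizontal shelf plates at each cell
#' level. Plate thickness equals `strut_thickness`. Voxelized BV/TV matches
#' `1 - (1 - x)^3` exactly.
#'
#' @param spec A [lattice_spec()] with `lattice_type = "plate"`.
#' @return A `voxel_model`.
#' @export
build_plate_lattice <- function(spec) {
  if (spec$lattice_type != "plate") stop("spec is not a plate lattice")
  build_lattice(spec)
}

#' Morphometric summary of a voxel model
#'
#' @param model A `voxel_model`.
#' @param components If `TRUE`, also count 6-connected components of the solid
#'   phase (can be slow on very large grids).
#' @return A list with `bvtv` (sum of per-voxel solid fractions over voxel
#'   count), `n_vertical_struts`, `n_horizontal_struts` and, when requested,
#'   `n_connected_components`.
#' @export
compute_morphometrics <- function(model, components = TRUE) {
  stopifnot(inherits(model, "voxel_model"))
  act <- model$struts[!model$struts$removed, , drop = FALSE]
  out <- list(bvtv = sum(model$frac) / prod(model$grid),
              n_vertical_struts = sum(act$orientation == "vertical"),
              n_horizontal_struts = sum(act$orientation == "horizontal"))
  if (components)
    out$n_connected_components <- count_components(model$frac > 0)
  class(out) <- "trab_morphometrics"
  out
}

#' @export
print.trab_morphometrics <- function(x, ...) {
  cat(sprintf("BV/TV: %.4f%%\n", 100 * x$bvtv))
  cat(sprintf("struts: %d vertical, %d horizontal\n",
              x$n_vertical_struts, x$n_horizontal_struts))
  if (!is.null(x$n_connected_components))
    cat(sprintf("connected components: %d\n", x$n_connected_components))
  invisible(x)
}

#' Geometrically scale a voxel model
#'
#' Multiplies every length (voxel size, extents, strut boxes) by `factor`;
#' the voxel arrays and hence BV/TV are unchanged. Used for the x10
#' rapid-prototype replica configuration.
#'
#' @param model A `voxel_model`.
#' @param factor Scale factor, must be positive (>= 1 for replica use).
#' @return The scaled `voxel_model`.
#' @export
scale_model <- function(model, factor) {
  stopifnot(inherits(model, "voxel_model"))
  if (!is.numeric(factor) || factor <= 0) stop("factor must be positive")
  model$voxel <- model$voxel * factor
  model$extent <- model$extent * factor
  cols <- c("x0", "x1", "y0", "y1", "z0", "z1", "thickness")
  model$struts[cols] <- model$struts[cols] * factor
  model$lattice$thickness <- model$lattice$thickness * factor
  model$lattice$spacing <- model$lattice$spacing * factor
  model
}

#' @export
print.voxel_model <- function(x, ...) {
  cat(sprintf("voxel_model: %s lattice, grid %s, voxel %.3f um\n",
              x$lattice$type, paste(x$grid, collapse = "x"), x$voxel))
  cat(sprintf("  extent %s um, %d struts (%d removed)\n",
              paste(round(x$extent, 1), collapse = " x "),
              nrow(x$struts), sum(x$struts$removed)))
  cat(sprintf("  BV/TV %.4f%%\n", 100 * sum(x$frac) / prod(x$grid)))
  invisible(x)
}

#' Convenience builder for the study's normal models
#'
#' Builds the normal rod-like model (strut thickness 140 um, BV/TV 10.29%) or
#' the normal plate-like model (plate thickness 140 um, BV/TV 27.69%), with the
#' cell spacing recovered by [solve_spacing_for_bvtv()].
#'
#' @param type `"rod"` or `"plate"`.
#' @param cells_per_axis Cells per axis (default `c(5, 5, 5)`).
#' @param voxel_size Requested voxel edge in um (default 35).
#' @param target_bvtv Override the default BV/TV target.
#' @param strut_thickness Strut/plate thickness in um (default 140).
#' @return A `voxel_model`.
#' @export
build_normal_model <- function(type = c("rod", "plate"),
                               cells_per_axis = c(5L, 5L, 5L),
                               voxel_size = 35,
                               target_bvtv = NULL,
                               strut_thickness = 140) {
  type <- match.arg(type)
  if (is.null(target_bvtv))
    target_bvtv <- if (type == "rod") 0.1029 else 0.2769
  spacing <- solve_spacing_for_bvtv(type, strut_thickness, target_bvtv)
  spec <- lattice_spec(type, strut_thickness, spacing, cells_per_axis,
                       voxel_size)
  build_lattice(spec)
}
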