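#' @title Voxel hexahedral finite element machinery
#' @name microfe
#' @description Linear elastic trilinear hexahedral (8-node) voxel FE:
#'   stiffness assembly over solid voxels with per-element modulus scaling,
#'   displacement-controlled uniaxial loading along z between frictionless
#'   platens, sparse direct (CHOLMOD) or conjugate-gradient solution, and
#'   centroid strain recovery.
NULL

## local node order (VTK hexahedron), natural coordinates of the 8 corners
HEX_SIGNS <- matrix(c(-1, -1, -1,  1, -1, -1,  1, 1, -1,  -1, 1, -1,
                      -1, -1,  1,  1, -1,  1,  1, 1,  1,  -1, 1,  1),
                    ncol = 3, byrow = TRUE)

## isotropic elasticity matrix, engineering shear convention
elasticity_matrix <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
  D[1:3, 1:3] <- D[1:3, 1:3] + lam
  D
}

## strain-displacement matrix (6 x 24) at natural point (xi, eta, zeta) for a
## cube element of edge h; strain order (xx, yy, zz, gxy, gyz, gzx)
hex8_bmat <- function(xi, eta, zeta, h) {
  s <- HEX_SIGNS
  dN <- cbind(s[, 1] * (1 + s[, 2] * eta) * (1 + s[, 3] * zeta),
              s[, 2] * (1 + s[, 1] * xi) * (1 + s[, 3] * zeta),
              s[, 3] * (1 + s[, 1] * xi) * (1 + s[, 2] * eta)) / 8 * (2 / h)
  B <- matrix(0, 6, 24)
  ix <- 3 * (1:8) - 2
  B[1, ix] <- dN[, 1]
  B[2, ix + 1] <- dN[, 2]
  B[3, ix + 2] <- dN[, 3]
  B[4, ix] <- dN[, 2]; B[4, ix + 1] <- dN[, 1]
  B[5, ix + 1] <- dN[, 3]; B[5, ix + 2] <- dN[, 2]
  B[6, ix] <- dN[, 3]; B[6, ix + 2] <- dN[, 1]
  B
}

#' Stiffness matrix of a cubic 8-node hexahedral element
#'
#' Full 2x2x2 Gauss integration (exact for the trilinear cube element).
#'
#' @param E Elastic modulus (MPa).
#' @param nu Poisson's ratio.
#' @param h Element edge length (mm).
#' @param n_gauss Gauss points per direction (default 2).
#' @return A 24 x 24 stiffness matrix (N/mm), dof order (ux, uy, uz) per node.
#' @export
hex8_stiffness <- function(E, nu, h, n_gauss = 2) {
  D <- elasticity_matrix(E, nu)
  gp <- statmod_gauss(n_gauss)
  ke <- matrix(0, 24, 24)
  for (a in seq_len(n_gauss)) for (b in seq_len(n_gauss)) for (c in seq_len(n_gauss)) {
    B <- hex8_bmat(gp$x[a], gp$x[b], gp$x[c], h)
    w <- gp$w[a] * gp$w[b] * gp$w[c] * (h / 2)^3
    ke <- ke + w * crossprod(B, D %*% B)
  }
  (ke + t(ke)) / 2
}

## Gauss-Legendre points on [-1, 1]
statmod_gauss <- function(n) {
  if (n == 1) return(list(x = 0, w = 2))
  if (n == 2) return(list(x = c(-1, 1) / sqrt(3), w = c(1, 1)))
  if (n == 3) return(list(x = c(-sqrt(3 / 5), 0, sqrt(3 / 5)),
                          w = c(5, 8, 5) / 9))
  ## Golub-Welsch for larger n
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  ev <- eigen(
    matrix(0, n, n) + diag(0, n) +
      `[<-`(`[<-`(matrix(0, n, n), cbind(i, i + 1), b), cbind(i + 1, i), b),
    symmetric = TRUE)
  list(x = rev(ev$values), w = rev(2 * ev$vectors[1, ]^2))
}

## principal strains (sorted descending) from n x 6 engineering strain rows
principal_from_tensor <- function(eps) {
  exx <- eps[, 1]; eyy <- eps[, 2]; ezz <- eps[, 3]
  exy <- eps[, 4] / 2; eyz <- eps[, 5] / 2; ezx <- eps[, 6] / 2
  m <- (exx + eyy + ezz) / 3
  a11 <- exx - m; a22 <- eyy - m; a33 <- ezz - m
  p1 <- exy^2 + eyz^2 + ezx^2
  p2 <- a11^2 + a22^2 + a33^2 + 2 * p1
  p <- sqrt(p2 / 6)
  lam <- cbind(m, m, m)
  nz <- which(p > 1e-30)
  if (length(nz)) {
    ip <- 1 / p[nz]
    b11 <- a11[nz] * ip; b22 <- a22[nz] * ip; b33 <- a33[nz] * ip
    b12 <- exy[nz] * ip; b23 <- eyz[nz] * ip; b31 <- ezx[nz] * ip
    detB <- b11 * b22 * b33 + 2 * b12 * b23 * b31 -
      b11 * b23^2 - b22 * b31^2 - b33 * b12^2
    r <- pmin(1, pmax(-1, detB / 2))
    phi <- acos(r) / 3
    l1 <- m[nz] + 2 * p[nz] * cos(phi)
    l3 <- m[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)
    lam[nz, ] <- cbind(l1, 3 * m[nz] - l1 - l3, l3)
  }
  colnames(lam) <- c("e1", "e2", "e3")
  lam
}

## column-sorted sparse template plus the element-to-slot projection matrix P,
## so that K@x <- P %*% scales reassembles in O(nnz)
make_template <- function(ri, ci, vals, elems, n_elem, dims, symmetric) {
  ord <- order(ci, ri)
  ri <- ri[ord]; ci <- ci[ord]; vals <- vals[ord]; elems <- elems[ord]
  n <- length(ri)
  newp <- if (n) c(TRUE, ri[-1] != ri[-n] | ci[-1] != ci[-n]) else logical(0)
  slot <- cumsum(newp)
  P <- Matrix::sparseMatrix(i = slot, j = elems, x = vals,
                            dims = c(max(slot, 0L), n_elem))
  K <- Matrix::sparseMatrix(i = ri[newp], j = ci[newp],
                            x = numeric(sum(newp)), dims = dims,
                            symmetric = symmetric)
  list(K = K, P = P)
}

#' Assemble a voxel finite element system
#'
#' Builds the trilinear hexahedral stiffness structure over all voxels with
#' positive effective solid fraction. Element modulus is
#' `E * solid_fraction * modulus_scale` (partial surface occupancy and damage
#' both enter as modulus scaling). Solid components not connected to both
#' loading faces are dropped (their count is recorded in `n_dropped`).
#' Boundary conditions model frictionless platens: bottom-face nodes fixed in
#' z, top-face nodes with prescribed z displacement, lateral motion free, plus
#' minimal in-plane pins to remove rigid-body modes.
#'
#' @param model A `voxel_model`.
#' @param material A `material_params`.
#' @param modulus_scale Optional per-element scale (in element order; see
#'   `$elements` of the result), default 1.
#' @param min_fraction Voxels with solid fraction at or below this are ignored.
#' @param solver `"auto"`, `"direct"` (sparse Cholesky) or `"cg"`.
#' @param direct_max_dof DOF threshold above which `"auto"` switches to
#'   conjugate gradients.
#' @return An `fe_system` object.
#' @export
assemble <- function(model, material, modulus_scale = NULL,
                     min_fraction = 1e-3, solver = c("auto", "direct", "cg"),
                     direct_max_dof = 300000L) {
  stopifnot(inherits(model, "voxel_model"), inherits(material, "material_params"))
  solver <- match.arg(solver)
  grid <- model$grid
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  mask <- model$frac > min_fraction
  if (!any(mask)) stop("model has no effective elements")
  rb <- flood_reach(mask, face_layer_indices(grid, "bottom"), grid)
  rt <- flood_reach(mask, face_layer_indices(grid, "top"), grid)
  keep <- rb & rt
  n_dropped <- sum(mask) - sum(keep)
  if (!any(keep))
    stop("no solid component connects the top and bottom loading faces")
  elems <- which(keep)
  n_e <- length(elems)
  base <- model$frac[elems]
  i0 <- (elems - 1L) %% nx
  j0 <- ((elems - 1L) %/% nx) %% ny
  k0 <- (elems - 1L) %/% (nx * ny)
  nnx <- nx + 1L; nny <- ny + 1L
  conn <- matrix(0L, n_e, 8)
  for (a in 1:8) {
    di <- (HEX_SIGNS[a, 1] + 1L) %/% 2L
    dj <- (HEX_SIGNS[a, 2] + 1L) %/% 2L
    dk <- (HEX_SIGNS[a, 3] + 1L) %/% 2L
    conn[, a] <- 1L + (i0 + di) + nnx * ((j0 + dj) + nny * (k0 + dk))
  }
  nodes <- sort(unique(as.vector(conn)))
  nmap <- integer(nnx * nny * (nz + 1L))
  nmap[nodes] <- seq_along(nodes)
  nn <- length(nodes)
  h_mm <- model$voxel / 1000
  gi <- (nodes - 1L) %% nnx
  gj <- ((nodes - 1L) %/% nnx) %% nny
  gk <- (nodes - 1L) %/% (nnx * nny)
  xyz <- cbind(gi, gj, gk) * h_mm
  H_mm <- nz * h_mm
  A_mm2 <- (nx * h_mm) * (ny * h_mm)
  dofmat <- matrix(0L, n_e, 24)
  for (a in 1:8) {
    pn <- nmap[conn[, a]]
    dofmat[, 3 * a - 2] <- 3L * pn - 2L
    dofmat[, 3 * a - 1] <- 3L * pn - 1L
    dofmat[, 3 * a] <- 3L * pn
  }
  ndof <- 3L * nn
  ## constraints: frictionless platens + in-plane pins
  ztol <- 1e-6 * h_mm
  bottom <- which(abs(xyz[, 3]) < ztol)
  top <- which(abs(xyz[, 3] - H_mm) < ztol)
  A_node <- bottom[order(xyz[bottom, 2], xyz[bottom, 1])][1]
  sameY <- bottom[abs(xyz[bottom, 2] - xyz[A_node, 2]) < ztol &
                    bottom != A_node]
  pins <- cbind(node = A_node, dir = 1)  # ux of A
  pins <- rbind(pins, c(A_node, 2))      # uy of A
  if (length(sameY)) {
    B_node <- sameY[which.max(xyz[sameY, 1])]
    pins <- rbind(pins, c(B_node, 2))    # uy of B kills rotation about z
  } else {
    sameX <- bottom[abs(xyz[bottom, 1] - xyz[A_node, 1]) < ztol &
                      bottom != A_node]
    if (length(sameX)) {
      B_node <- sameX[which.max(xyz[sameX, 2])]
      pins <- rbind(pins, c(B_node, 1))
    }
  }
  cons <- c(3L * bottom, 3L * top,
            3L * (pins[, 1] - 1L) + pins[, 2])
  cons_unit <- c(numeric(length(bottom)), rep(1, length(top)),
                 numeric(nrow(pins)))
  dup <- !duplicated(cons)
  cons <- cons[dup]; cons_unit <- cons_unit[dup]
  cidx <- integer(ndof); cidx[cons] <- seq_along(cons)
  free <- which(cidx == 0L)
  fidx <- integer(ndof); fidx[free] <- seq_along(free)
  ## element stiffness and triplets
  ke0 <- hex8_stiffness(material$E, material$nu, h_mm)
  Arow <- rep(1:24, times = 24)
  Bcol <- rep(1:24, each = 24)
  kv0 <- ke0[cbind(Arow, Bcol)]
  I <- dofmat[, Arow]; J <- dofmat[, Bcol]
  kv <- rep(kv0, each = n_e)
  ev <- rep.int(seq_len(n_e), 576L)
  fI <- fidx[I]; fJ <- fidx[J]; cJ <- cidx[J]
  sel <- fI > 0L & fJ > 0L & fI <= fJ
  tff <- make_template(fI[sel], fJ[sel], kv[sel], ev[sel], n_e,
                       c(length(free), length(free)), symmetric = TRUE)
  sel <- fI > 0L & cJ > 0L
  tfc <- make_template(fI[sel], cJ[sel], kv[sel], ev[sel], n_e,
                       c(length(free), length(cons)), symmetric = FALSE)
  rm(I, J, kv, ev, fI, fJ, cJ, sel)
  grp <- as.vector(dofmat)
  grp_levels <- sort(unique(grp))
  sys <- structure(list(
    grid = grid, h_mm = h_mm, H_mm = H_mm, A_mm2 = A_mm2,
    elements = elems, n_e = n_e, base = base, dofmat = dofmat,
    xyz = xyz, ndof = ndof, free = free, cons = cons, cons_unit = cons_unit,
    top_z_dofs_cons = which(cons_unit == 1),
    Kff = tff$K, Pff = tff$P, Kfc = tfc$K, Pfc = tfc$P,
    ke0 = ke0, D = elasticity_matrix(material$E, material$nu),
    Bc = hex8_bmat(0, 0, 0, h_mm),
    material = material, n_dropped = n_dropped,
    grp = grp, grp_levels = grp_levels,
    solver = solver, direct_max_dof = direct_max_dof,
    cache = new.env(parent = emptyenv())), class = "fe_system")
  set_system_scales(sys, if (is.null(modulus_scale)) rep(1, n_e) else modulus_scale)
  sys
}

#' @export
print.fe_system <- function(x, ...) {
  cat(sprintf("fe_system: %d elements, %d free dofs (%d dropped voxels)\n",
              x$n_e, length(x$free), x$n_dropped))
  invisible(x)
}

#' Update per-element modulus scales of an assembled system
#'
#' Refills the stiffness values in place (the sparsity structure and the
#' symbolic factorization are reused), marking the numeric factor stale.
#'
#' @param system An `fe_system`.
#' @param modulus_scale Per-element damage/occupancy scale (length `n_e`),
#'   multiplied with the element solid fractions.
#' @return The system, invisibly (scales live in the system's cache
#'   environment, so the update is visible through existing references).
#' @export
set_system_scales <- function(system, modulus_scale) {
  eff <- system$base * modulus_scale
  if (all(eff <= 0)) stop("all elements have zero effective stiffness")
  system$Kff@x <- as.numeric(system$Pff %*% eff)
  system$Kfc@x <- as.numeric(system$Pfc %*% eff)
  system$cache$eff <- eff
  system$cache$Kff <- system$Kff
  system$cache$Kfc <- system$Kfc
  system$cache$factor_stale <- TRUE
  invisible(system)
}

## preconditioned conjugate gradients; `prec` maps residual -> z
pcg_solve <- function(K, b, prec, tol = 1e-8, maxit = 20000L, x0 = NULL,
                      error_on_fail = TRUE) {
  x <- if (is.null(x0)) numeric(length(b)) else x0
  b2 <- sqrt(sum(b^2))
  if (b2 == 0) return(list(x = numeric(length(b)), iters = 0L, relres = 0,
                           converged = TRUE))
  r <- b - as.numeric(K %*% x)
  z <- prec(r)
  p <- z
  rz <- sum(r * z)
  relres <- sqrt(sum(r^2)) / b2
  for (it in seq_len(maxit)) {
    Kp <- as.numeric(K %*% p)
    alpha <- rz / sum(p * Kp)
    x <- x + alpha * p
    r <- r - alpha * Kp
    relres <- sqrt(sum(r^2)) / b2
    if (relres <= tol) return(list(x = x, iters = it, relres = relres,
                                   converged = TRUE))
    z <- prec(r)
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  if (error_on_fail)
    stop(sprintf("conjugate gradients failed to converge (relative residual %.3e after %d iterations)",
                 relres, maxit))
  list(x = x, iters = maxit, relres = relres, converged = FALSE)
}

## direct solve against the current stiffness; after modulus-scale updates the
## stale factor serves as a PCG preconditioner, and a full numeric refactor
## happens only when that stalls
system_solve <- function(system, rhs) {
  cache <- system$cache
  if (is.null(cache$chol)) {
    cache$chol <- Matrix::Cholesky(cache$Kff, LDL = FALSE, super = NA)
    cache$factor_stale <- FALSE
    return(as.numeric(Matrix::solve(cache$chol, rhs)))
  }
  if (!isTRUE(cache$factor_stale))
    return(as.numeric(Matrix::solve(cache$chol, rhs)))
  prec <- function(r) as.numeric(Matrix::solve(cache$chol, r))
  out <- pcg_solve(cache$Kff, rhs, prec, tol = 1e-8, maxit = 60L,
                   x0 = cache$last_uf, error_on_fail = FALSE)
  if (out$converged) return(out$x)
  cache$chol <- Matrix::update(cache$chol, cache$Kff)
  cache$factor_stale <- FALSE
  as.numeric(Matrix::solve(cache$chol, rhs))
}

#' Solve a displacement-controlled uniaxial load case
#'
#' Prescribes a uniform z displacement `-apparent_strain * height` on the top
#' face (compression positive; use `direction = "tension"` for the opposite
#' sense), solves the constrained linear system, and recovers element centroid
#' strains, principal strains, strain energy densities and the platen
#' reaction.
#'
#' @param system An `fe_system` from [assemble()].
#' @param apparent_strain Apparent strain magnitude (fraction of height).
#' @param direction `"compression"` or `"tension"`.
#' @return A `field_solution`: nodal displacements `u` (mm, packed dof order),
#'   element strains (n x 6, engineering), sorted principal strains (n x 3),
#'   strain energy density (mJ/mm^3), reaction force (N, signed z force on the
#'   top platen), apparent stress (MPa, positive), external work and stored
#'   energy (mJ).
#' @export
solve_compression <- function(system, apparent_strain,
                              direction = c("compression", "tension")) {
  direction <- match.arg(direction)
  sgn <- if (direction == "compression") -1 else 1
  delta <- sgn * apparent_strain * system$H_mm
  vc <- system$cons_unit * delta
  cache <- system$cache
  rhs <- -as.numeric(cache$Kfc %*% vc)
  nf <- length(system$free)
  use_direct <- system$solver == "direct" ||
    (system$solver == "auto" && nf <= system$direct_max_dof)
  uf <- if (nf == 0) numeric(0)
  else if (use_direct) system_solve(system, rhs)
  else {
    M <- Matrix::diag(cache$Kff)
    M[M <= 0] <- 1
    pcg_solve(cache$Kff, rhs, function(r) r / M, x0 = cache$last_uf)$x
  }
  cache$last_uf <- uf
  u <- numeric(system$ndof)
  u[system$free] <- uf
  u[system$cons] <- vc
  Ue <- matrix(u[system$dofmat], system$n_e, 24)
  Fe <- (Ue %*% system$ke0) * cache$eff
  rs <- rowsum(as.vector(Fe), system$grp, reorder = TRUE)
  f_int <- numeric(system$ndof)
  f_int[system$grp_levels] <- rs
  strains <- Ue %*% t(system$Bc)
  principal <- principal_from_tensor(strains)
  stress <- (strains %*% system$D) * cache$eff
  sed <- 0.5 * rowSums(strains * stress)
  Fz_top <- sum(f_int[system$cons[system$top_z_dofs_cons]])
  structure(list(u = u, strains = strains, principal = principal,
                 sed = sed, stress = stress,
                 reaction_force = Fz_top,
                 apparent_stress = abs(Fz_top) / system$A_mm2,
                 apparent_strain = apparent_strain,
                 direction = direction,
                 external_work = 0.5 * sum(u[system$cons] * f_int[system$cons]),
                 stored_energy = 0.5 * sum(u * f_int),
                 f_int = f_int), class = "field_solution")
}

#' Element principal strains and dominant directions
#'
#' Returns the sorted principal strain triple per element and, for the
#' requested elements, the unit direction of the dominant (largest magnitude)
#' principal strain - the recorded normal of any newly initiated crack.
#'
#' @param system An `fe_system`.
#' @param solution A `field_solution` from [solve_compression()].
#' @param directions_for Integer element indices for which to compute the
#'   dominant principal direction (eigen decomposition per element).
#' @return A list with `principal` (n x 3, descending) and `directions`
#'   (length(directions_for) x 3 matrix).
#' @export
principal_strains <- function(system, solution, directions_for = integer(0)) {
  dirs <- NULL
  if (length(directions_for)) {
    dirs <- matrix(NA_real_, length(directions_for), 3)
    for (q in seq_along(directions_for)) {
      e <- solution$strains[directions_for[q], ]
      Tm <- matrix(c(e[1], e[4] / 2, e[6] / 2,
                     e[4] / 2, e[2], e[5] / 2,
                     e[6] / 2, e[5] / 2, e[3]), 3, 3)
      ev <- eigen(Tm, symmetric = TRUE)
      dom <- which.max(abs(ev$values))
      dirs[q, ] <- ev$vectors[, dom]
    }
  }
  list(principal = solution$principal, directions = dirs)
}
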