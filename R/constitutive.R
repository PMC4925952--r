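#' @title Asymmetric strain-based tissue damage law
#' @name constitutive
#' @description Bilinear elastic/post-yield response with asymmetric tension
#'   and compression thresholds, principal-strain crack initiation, and linear
#'   energy-regularized (crack-band) softening. Damage enters the finite
#'   element model as a scalar secant modulus scale per element.
NULL

#' Material parameter set
#'
#' @param E Tissue elastic modulus (MPa).
#' @param nu Poisson's ratio.
#' @param eps_yield_t,eps_crack_t Tensile yield and crack-initiation principal
#'   strains (dimensionless).
#' @param eps_yield_c,eps_crack_c Compressive yield and crack-initiation
#'   principal strains (positive magnitudes).
#' @param postyield_ratio Post-yield tangent modulus as a fraction of `E`.
#' @param G_f Energy release rate (N/mm): energy dissipated per unit area of
#'   created crack surface, used to regularize element softening.
#' @return An object of class `material_params`.
#' @export
material_params <- function(E, nu, eps_yield_t, eps_crack_t,
                            eps_yield_c, eps_crack_c,
                            postyield_ratio = 0.05, G_f = 0.33) {
  if (E <= 0) stop("E must be positive")
  if (nu <= -1 || nu >= 0.5) stop("nu must lie in (-1, 0.5)")
  if (!(0 < eps_yield_t && eps_yield_t < eps_crack_t))
    stop("need 0 < eps_yield_t < eps_crack_t")
  if (!(0 < eps_yield_c && eps_yield_c < eps_crack_c))
    stop("need 0 < eps_yield_c < eps_crack_c")
  if (!(0 < postyield_ratio && postyield_ratio < 1))
    stop("postyield_ratio must lie in (0, 1)")
  if (G_f <= 0) stop("G_f must be positive")
  structure(list(E = E, nu = nu,
                 eps_yield_t = eps_yield_t, eps_crack_t = eps_crack_t,
                 eps_yield_c = eps_yield_c, eps_crack_c = eps_crack_c,
                 postyield_ratio = postyield_ratio, G_f = G_f),
            class = "material_params")
}

#' Built-in material presets
#'
#' `"trabecular"`: trabecular bone tissue, E = 12 GPa, nu = 0.3, tensile
#' yield/crack strains 0.33%/0.61%, compressive 0.81%/1.02%, post-yield
#' modulus 5% of E, energy release rate 0.33 N/mm. `"polyamide12"`: laser
#' sintered polyamide-12 for scaled rapid-prototype replicas, E = 1300 MPa,
#' nu = 0.3, symmetric yield/crack strains 1.5%/10%.
#'
#' @param name Preset name.
#' @param ... Field overrides passed to [material_params()].
#' @return A `material_params` object.
#' @export
material_preset <- function(name = c("trabecular", "polyamide12"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    trabecular = list(E = 12000, nu = 0.3,
                      eps_yield_t = 0.0033, eps_crack_t = 0.0061,
                      eps_yield_c = 0.0081, eps_crack_c = 0.0102,
                      postyield_ratio = 0.05, G_f = 0.33),
    polyamide12 = list(E = 1300, nu = 0.3,
                       eps_yield_t = 0.015, eps_crack_t = 0.10,
                       eps_yield_c = 0.015, eps_crack_c = 0.10,
                       postyield_ratio = 0.05, G_f = 0.33))
  over <- list(...)
  base[names(over)] <- over
  do.call(material_params, base)
}

#' @export
print.material_params <- function(x, ...) {
  cat(sprintf("material: E %.0f MPa, nu %.2f\n", x$E, x$nu))
  cat(sprintf("  tension  yield %.2f%%, crack %.2f%%\n",
              100 * x$eps_yield_t, 100 * x$eps_crack_t))
  cat(sprintf("  compress yield %.2f%%, crack %.2f%%\n",
              100 * x$eps_yield_c, 100 * x$eps_crack_c))
  cat(sprintf("  post-yield ratio %.2f, G_f %.2f N/mm\n",
              x$postyield_ratio, x$G_f))
  invisible(x)
}

#' Tensile and compressive strain demands from principal strains
#'
#' The tension demand is the positive part of the largest principal strain,
#' the compression demand the positive part of the negated smallest principal
#' strain.
#'
#' @param principal A length-3 numeric vector or an n x 3 matrix of principal
#'   strains (any order).
#' @return A list with numeric `tension` and `compression` components.
#' @export
demand <- function(principal) {
  p <- if (is.matrix(principal)) principal else matrix(principal, nrow = 1)
  mx <- do.call(pmax, c(as.data.frame(p), list(0)))
  mn <- do.call(pmin, c(as.data.frame(p), list(0)))
  list(tension = as.numeric(mx), compression = as.numeric(-mn))
}

## uniaxial stress at crack initiation on the bilinear curve (MPa)
initiation_stress <- function(material, mode = c("tension", "compression")) {
  mode <- match.arg(mode)
  ey <- if (mode == "tension") material$eps_yield_t else material$eps_yield_c
  ec <- if (mode == "tension") material$eps_crack_t else material$eps_crack_c
  material$E * (ey + material$postyield_ratio * (ec - ey))
}

#' Crack-band softening strain span
#'
#' Linear softening over a strain span `2 G_f / (sigma0 h)` so that the energy
#' dissipated by a one-element-wide crack band equals `G_f` per unit crack
#' area, independent of the element size (crack-band regularization).
#'
#' @param material A `material_params` object.
#' @param element_size Element characteristic length h, in mm.
#' @param init_stress Uniaxial stress at crack initiation (MPa). Defaults to
#'   the value implied by the material's bilinear curve in the given `mode`.
#' @param mode `"tension"` or `"compression"` (used only for the default
#'   `init_stress`).
#' @return Softening strain span (dimensionless).
#' @export
dissipate_Gf <- function(material, element_size, init_stress = NULL,
                         mode = c("tension", "compression")) {
  mode <- match.arg(mode)
  if (element_size <= 0) stop("element_size must be positive")
  if (is.null(init_stress)) init_stress <- initiation_stress(material, mode)
  if (init_stress <= 0) stop("initiation stress must be positive")
  2 * material$G_f / (init_stress * element_size)
}

## secant modulus scale (sigma / (E eps)) of the uniaxial curve at history-peak
## demand `p` for one mode; vectorized over p
uniaxial_secant_scale <- function(p, ey, ec, r, deps) {
  s <- rep(1, length(p))
  yld <- p > ey
  s[yld] <- (ey + r * (p[yld] - ey)) / p[yld]
  crk <- p > ec
  if (any(crk)) {
    ## stress falls linearly from the initiation stress to zero over `deps`
    sigma0 <- ey + r * (ec - ey)            # initiation stress / E
    sig <- pmax(0, sigma0 * (1 - (p[crk] - ec) / deps))
    s[crk] <- sig / p[crk]
  }
  s
}

## damage variable on the softening branch; vectorized
uniaxial_damage <- function(p, ec, deps) {
  pmin(1, pmax(0, (p - ec) / deps))
}

#' Initialize a per-element damage state
#'
#' @param n_elements Number of elements.
#' @return A `damage_state`: history-peak tensile/compressive demands, yield
#'   and crack flags per mode, scalar damage `d`, secant modulus scale, and
#'   recorded crack-plane normals.
#' @export
damage_state <- function(n_elements) {
  structure(list(n = n_elements,
                 peak_t = numeric(n_elements),
                 peak_c = numeric(n_elements),
                 yielded_t = logical(n_elements),
                 yielded_c = logical(n_elements),
                 cracked = logical(n_elements),
                 d = numeric(n_elements),
                 scale = rep(1, n_elements),
                 crack_normal = matrix(NA_real_, n_elements, 3)),
            class = "damage_state")
}

#' Update element damage states from current strain demands
#'
#' History-peak demands are monotone (no healing). The governing mode is the
#' one with the larger demand-to-yield ratio (ties go to tension, whose
#' thresholds are lower); the secant modulus scale follows the bilinear curve
#' up to crack initiation and a linear crack-band softening branch beyond it.
#' The returned scale is clipped from below at `floor_scale` so fully failed
#' elements retain a vanishing residual stiffness for numerical stability;
#' elements with `d = 1` are treated as eroded by the load-path bookkeeping.
#'
#' @param state A `damage_state`.
#' @param demands List with `tension` and `compression` demand vectors.
#' @param material A `material_params`.
#' @param element_size Element edge length (mm), sets the crack-band span.
#' @param floor_scale Residual modulus scale floor (default `1e-4`).
#' @return The updated `damage_state` (field `scale` holds the new secant
#'   modulus scale per element).
#' @export
update_state <- function(state, demands, material, element_size,
                         floor_scale = 1e-4) {
  if (element_size <= 0) stop("element_size must be positive")
  m <- material
  pt <- pmax(state$peak_t, demands$tension)
  pc <- pmax(state$peak_c, demands$compression)
  deps_t <- dissipate_Gf(m, element_size, mode = "tension")
  deps_c <- dissipate_Gf(m, element_size, mode = "compression")
  rt <- pt / m$eps_yield_t
  rc <- pc / m$eps_yield_c
  gov_t <- rt >= rc
  s_t <- uniaxial_secant_scale(pt, m$eps_yield_t, m$eps_crack_t,
                               m$postyield_ratio, deps_t)
  s_c <- uniaxial_secant_scale(pc, m$eps_yield_c, m$eps_crack_c,
                               m$postyield_ratio, deps_c)
  s <- ifelse(gov_t, s_t, s_c)
  d_t <- uniaxial_damage(pt, m$eps_crack_t, deps_t)
  d_c <- uniaxial_damage(pc, m$eps_crack_c, deps_c)
  d <- ifelse(gov_t, d_t, d_c)
  state$peak_t <- pt
  state$peak_c <- pc
  state$yielded_t <- state$yielded_t | pt >= m$eps_yield_t
  state$yielded_c <- state$yielded_c | pc >= m$eps_yield_c
  state$cracked <- state$cracked | pt > m$eps_crack_t | pc > m$eps_crack_c
  state$d <- pmax(state$d, d)
  state$scale <- pmin(state$scale, pmax(s, floor_scale))
  state
}
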