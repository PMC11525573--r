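#' Material parameters for the bilayer brain section
#'
#' Bundles the neo-Hookean constitutive constants and the cell-density
#' dependent cortical stiffening law.  The subcortical shear modulus is
#' derived from the fully developed cortical modulus and the stiffness ratio,
#' `mu_s = mu_infinity / beta_mu`.
#'
#' @param mu_infinity shear modulus of the fully developed cortex (kPa).
#' @param poisson_nu Poisson's ratio, in `[0, 0.5)`.
#' @param beta_mu cortex/subcortex stiffness ratio, `>= 1`.
#' @param c_mu_min,c_mu_max total cell-density thresholds (mm^-2) between
#'   which the cortical shear modulus ramps linearly from `mu_s` to
#'   `mu_infinity`.
#' @param stiffness_mode `"varying"` (cortical modulus follows the local cell
#'   density) or `"constant"` (cortical modulus pinned at `mu_infinity`).
#' @return an object of class `fold_material`.
#' @export
material_params <- function(mu_infinity = 2.07, poisson_nu = 0.38,
                            beta_mu = 3, c_mu_min = 200, c_mu_max = 700,
                            stiffness_mode = c("varying", "constant")) {
  stiffness_mode <- match.arg(stiffness_mode)
  if (beta_mu < 1) stop_cfg("beta_mu must be >= 1 (got %g)", beta_mu)
  if (poisson_nu < 0 || poisson_nu >= 0.5)
    stop_cfg("poisson_nu must lie in [0, 0.5) (got %g)", poisson_nu)
  if (c_mu_min >= c_mu_max)
    stop_cfg("c_mu_min (%g) must be below c_mu_max (%g)", c_mu_min, c_mu_max)
  if (mu_infinity <= 0) stop_cfg("mu_infinity must be positive")
  structure(list(
    mu_infinity = mu_infinity, poisson_nu = poisson_nu, beta_mu = beta_mu,
    mu_s = mu_infinity / beta_mu, c_mu_min = c_mu_min, c_mu_max = c_mu_max,
    stiffness_mode = stiffness_mode
  ), class = "fold_material")
}

#' Second Lame parameter from shear modulus and Poisson's ratio
#'
#' Inverts `nu = lambda / (2 (lambda + mu))`, giving
#' `lambda = 2 mu nu / (1 - 2 nu)`.
#'
#' @param mu shear modulus (kPa), positive.
#' @param nu Poisson's ratio in `[0, 0.5)`.
#' @return lambda in kPa (vectorized over `mu`).
#' @export
lame_second_parameter <- function(mu, nu) {
  if (any(nu >= 0.5)) stop_cfg("nu >= 0.5: incompressible limit unsupported")
  if (any(nu < 0)) stop_cfg("nu must be non-negative")
  if (any(mu <= 0)) stop_cfg("mu must be positive")
  2 * mu * nu / (1 - 2 * nu)
}

#' Cell-density dependent cortical shear modulus
#'
#' Piecewise-linear stiffening law: `mu_c(c) = min(mu_inf, mu_s + m <c -
#' c_min>)` with slope `m = (mu_inf - mu_s)/(c_max - c_min)` and Macaulay
#' bracket `<.>` (zero below the lower threshold).
#'
#' @param c total cell density (mm^-2), vectorized; negative excursions are
#'   clipped to zero.
#' @param params a [material_params()] object.
#' @return shear modulus in kPa, clamped to `[mu_s, mu_infinity]`.
#' @export
cortical_shear_modulus <- function(c, params) {
  c <- pmax(c, 0)
  m <- (params$mu_infinity - params$mu_s) / (params$c_mu_max - params$c_mu_min)
  pmin(params$mu_infinity, params$mu_s + m * pmax(c - params$c_mu_min, 0))
}

#' Radially blended shear modulus
#'
#' Blends the subcortical modulus `mu_s` into the cortical value across the
#' cortical-plate boundary `r_cp` with a regularized Heaviside of exponent
#' `gamma_r_cp`.  In `"constant"` mode the cortical target is `mu_infinity`;
#' in `"varying"` mode it is [cortical_shear_modulus()] at the local total
#' density.
#'
#' @param r_i reference radius (mm), vectorized.
#' @param c total cell density (mm^-2), recycled against `r_i`.
#' @param params a [material_params()] object.
#' @param r_cp cortical-plate boundary radius (mm).
#' @param gamma_r_cp Heaviside exponent at the cortex interface (1/mm).
#' @return shear modulus in kPa.
#' @export
radial_shear_modulus <- function(r_i, c, params, r_cp, gamma_r_cp = 50) {
  H <- smooth_heaviside(r_i - r_cp, gamma_r_cp)
  target <- if (params$stiffness_mode == "constant") {
    rep_len(params$mu_infinity, length(H))
  } else {
    rep_len(cortical_shear_modulus(c, params), length(H))
  }
  params$mu_s + (target - params$mu_s) * H
}

as_tensor2 <- function(Fe) {
  Fe <- as.matrix(Fe)
  if (!all(dim(Fe) == c(2L, 2L))) stop_cfg("expected a 2x2 tensor")
  Fe
}

#' Neo-Hookean strain energy (plane strain)
#'
#' `psi(Fe) = lambda/2 ln^2(Je) + mu/2 (Fe:Fe - 3 - 2 ln Je)`, with the 2D
#' elastic tensor promoted to 3D by a unit out-of-plane stretch, so `Fe:Fe`
#' gains `+1` and `Je` is the in-plane determinant.
#'
#' @param Fe 2x2 elastic deformation tensor with positive determinant.
#' @param lambda,mu Lame parameters (kPa).
#' @return energy density in kPa.
#' @export
strain_energy <- function(Fe, lambda, mu) {
  Fe <- as_tensor2(Fe)
  Je <- Fe[1, 1] * Fe[2, 2] - Fe[1, 2] * Fe[2, 1]
  if (Je <= 0) stop_cfg("det(Fe) <= 0: inverted elastic state")
  0.5 * lambda * log(Je)^2 + 0.5 * mu * (sum(Fe * Fe) + 1 - 3 - 2 * log(Je))
}

#' Cauchy stress of the neo-Hookean law (plane strain, in-plane block)
#'
#' `sigma = 1/Je [ (lambda ln Je - mu) I + mu be ]` with
#' `be = Fe Fe^T`.
#'
#' @inheritParams strain_energy
#' @return symmetric 2x2 stress tensor (kPa).
#' @export
cauchy_stress <- function(Fe, lambda, mu) {
  Fe <- as_tensor2(Fe)
  Je <- Fe[1, 1] * Fe[2, 2] - Fe[1, 2] * Fe[2, 1]
  if (Je <= 0) stop_cfg("det(Fe) <= 0: inverted elastic state")
  be <- Fe %*% t(Fe)
  ((lambda * log(Je) - mu) * diag(2) + mu * be) / Je
}
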