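#' Growth parameters
#'
#' Constants of the density-driven finite-growth law.  `kappa_s` scales how
#' strongly the local cell density inflates the tissue; `beta_kappa >= 1`
#' splits the cortical growth into a larger circumferential factor
#' `beta_kappa * kappa_s` and a smaller radial factor `kappa_s / beta_kappa`
#' (differential growth), while the subcortex grows isotropically.
#'
#' @param kappa_s subcortical growth factor (mm^2, per unit density).
#' @param alpha growth exponent (dimensionless).
#' @param beta_kappa cortical growth ratio, `>= 1`.
#' @param gamma_r_cp Heaviside exponent of the radial blend at the cortex.
#' @return an object of class `fold_growth`.
#' @export
growth_params <- function(kappa_s = 4.07e-4, alpha = 1.65, beta_kappa = 1.5,
                          gamma_r_cp = 50) {
  if (beta_kappa < 1) stop_cfg("beta_kappa must be >= 1 (got %g)", beta_kappa)
  if (kappa_s < 0) stop_cfg("kappa_s must be non-negative")
  structure(list(kappa_s = kappa_s, alpha = alpha, beta_kappa = beta_kappa,
                 gamma_r_cp = gamma_r_cp), class = "fold_growth")
}

#' Radial distribution of the growth factors
#'
#' Blends the isotropic subcortical factor into the differential cortical
#' pair across `r_cp`:
#' `kappa_perp = kappa_s (1 + (beta-1) H)` and
#' `kappa_par = kappa_s (1 + (1/beta - 1) H)`.
#'
#' @param r_i reference radius (mm), vectorized.
#' @param params a [growth_params()] object.
#' @param r_cp cortical-plate boundary radius (mm).
#' @return list with components `kappa_perp` and `kappa_par` (mm^2).
#' @export
radial_growth_factors <- function(r_i, params, r_cp) {
  H <- smooth_heaviside(r_i - r_cp, params$gamma_r_cp)
  list(
    kappa_perp = params$kappa_s * (1 + (params$beta_kappa - 1) * H),
    kappa_par  = params$kappa_s * (1 + (1 / params$beta_kappa - 1) * H)
  )
}

#' Growth multipliers from the local cell density
#'
#' `theta = (1 + kappa c)^alpha`, evaluated separately for the
#' circumferential and radial factors.  Negative densities (advection
#' undershoot) are clipped to zero inside this law only.
#'
#' @param c total cell density (mm^-2), vectorized.
#' @param kappa_perp,kappa_par growth factors (mm^2).
#' @param alpha growth exponent.
#' @return list with components `theta_perp` and `theta_par`, each `>= 1`.
#' @export
growth_multipliers <- function(c, kappa_perp, kappa_par, alpha) {
  c <- pmax(c, 0)
  list(theta_perp = (1 + kappa_perp * c)^alpha,
       theta_par  = (1 + kappa_par * c)^alpha)
}

#' Assemble the growth tensor
#'
#' `Fg = theta_perp (I - N x N) + theta_par N x N`: stretch `theta_par` along
#' the (referential, radial) unit normal `N` and `theta_perp` transverse to
#' it.
#'
#' @param theta_perp,theta_par growth multipliers.
#' @param N reference normal (2-vector); normalized internally.
#' @return symmetric positive-definite 2x2 matrix with determinant
#'   `theta_perp * theta_par`.
#' @export
growth_tensor <- function(theta_perp, theta_par, N) {
  nrm <- sqrt(sum(N^2))
  if (nrm == 0) stop_cfg("zero reference normal")
  N <- N / nrm
  NN <- tcrossprod(N)
  theta_perp * (diag(2) - NN) + theta_par * NN
}

#' Elastic part of the deformation gradient
#'
#' Inverts the multiplicative split `F = Fe Fg`, i.e. `Fe = F Fg^-1`.
#'
#' @param F total deformation gradient (2x2).
#' @param Fg growth tensor (2x2), non-singular.
#' @return the elastic tensor `Fe`.
#' @export
elastic_decomposition <- function(F, Fg) {
  dg <- Fg[1, 1] * Fg[2, 2] - Fg[1, 2] * Fg[2, 1]
  if (abs(dg) < .Machine$double.eps) stop_cfg("singular growth tensor")
  if (dg <= 0) stop_cfg("det(Fg) <= 0")
  F %*% solve(Fg)
}
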