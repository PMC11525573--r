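#' Regularized Heaviside function
#'
#' Logistic smoothing `H(x; gamma) = exp(gamma x) / (1 + exp(gamma x))`,
#' used throughout for zone blending (in space) and density gating (in
#' density).  Saturates exactly to 0/1 for large `|gamma x|` to avoid
#' overflow.
#'
#' @param x argument, vectorized.
#' @param gamma sharpness exponent.
#' @return values in `(0, 1)`, `H(0) = 1/2`.
#' @export
smooth_heaviside <- function(x, gamma) {
  z <- gamma * x
  out <- numeric(length(z))
  hi <- z > 35
  lo <- z < -35
  mid <- !(hi | lo)
  out[hi] <- 1
  out[lo] <- 0
  out[mid] <- exp(z[mid]) / (1 + exp(z[mid]))
  out
}

#' Gestational-week timeline
#'
#' Affine map between computational days and gestational weeks,
#' `t_GW = 0.3 t + 4`.
#'
#' @param t computational time (days).
#' @param gw gestational week.
#' @return the mapped time.
#' @export
gw_from_time <- function(t) 0.3 * t + 4

#' @rdname gw_from_time
#' @export
time_from_gw <- function(gw) (gw - 4) / 0.3

#' Transport and diffusivity parameters
#'
#' Speeds and diffusivities of the advection-diffusion system together with
#' the Heaviside exponents that shape their radial distributions and the
#' density gate, plus the SUPG stabilization constant and the mitotic somal
#' translocation (MST) rate that moves the outer subventricular boundary.
#'
#' @param v_N,v_ORG,v_IP migration/translocation speeds (mm/day).
#' @param d_c,d_N diffusivities (mm^2/day): `d_c` for progenitors, `d_N`
#'   for neurons in the cortex.
#' @param c0_threshold density gate threshold (mm^-2) of the advection term.
#' @param gamma_c density-gate exponent (mm^2).
#' @param gamma_r,gamma_r_cp spatial Heaviside exponents (1/mm): general, and
#'   at the subcortex-cortex interface (calibrated pair 20/50).
#' @param beta_supg streamline artificial-diffusivity constant.
#' @param m_mst MST boundary speed (mm/day).
#' @return an object of class `fold_transport`.
#' @export
transport_params <- function(v_N = 5, v_ORG = 10, v_IP = 0.025,
                             d_c = 0.1, d_N = 0.11, c0_threshold = 500,
                             gamma_c = 0.008, gamma_r = 20, gamma_r_cp = 50,
                             beta_supg = 0.1, m_mst = 0.02) {
  vals <- c(v_N = v_N, v_ORG = v_ORG, v_IP = v_IP, d_c = d_c, d_N = d_N,
            beta_supg = beta_supg, m_mst = m_mst)
  bad <- names(vals)[vals < 0]
  if (length(bad)) stop_cfg("negative transport parameter(s): %s",
                            paste(bad, collapse = ", "))
  structure(list(v_N = v_N, v_ORG = v_ORG, v_IP = v_IP, d_c = d_c, d_N = d_N,
                 c0_threshold = c0_threshold, gamma_c = gamma_c,
                 gamma_r = gamma_r, gamma_r_cp = gamma_r_cp,
                 beta_supg = beta_supg, m_mst = m_mst),
            class = "fold_transport")
}

# ---------------------------------------------------------------------------
# Lineage ledger

new_phase <- function(name, gw_start, gw_end, G) {
  G <- as.matrix(G)
  if (!all(dim(G) == c(4L, 4L))) stop_cfg("phase %s: G must be 4x4", name)
  if (any(G < 0)) stop_cfg("phase %s: division ratios must be >= 0", name)
  dimnames(G) <- list(produced = CELL_TYPES, parent = CELL_TYPES)
  list(name = name, gw_start = gw_start, gw_end = gw_end, G = G)
}

#' Cell-lineage ledger
#'
#' Ordered division phases, each an interval of gestational weeks
#' `[gw_start, gw_end)` with a 4x4 division-ratio matrix
#' `G[produced, parent]` feeding the source term
#' `f_b = sum_p G[b, p] c_p` (per day).
#'
#' @param phases list of phases as produced by the internal constructor; each
#'   needs `name`, `gw_start`, `gw_end` and `G`.
#' @return an object of class `fold_ledger`.
#' @seealso [default_lineage_ledger()], [source_terms()]
#' @export
lineage_ledger <- function(phases) {
  phases <- lapply(phases, function(p)
    new_phase(p$name, p$gw_start, p$gw_end, p$G))
  starts <- vapply(phases, `[[`, 0, "gw_start")
  ends <- vapply(phases, `[[`, 0, "gw_end")
  if (is.unsorted(starts, strictly = TRUE))
    stop_cfg("phases must be ordered by gw_start")
  if (any(ends <= starts)) stop_cfg("each phase needs gw_end > gw_start")
  if (length(phases) > 1 &&
      any(abs(starts[-1] - ends[-length(ends)]) > 1e-9))
    stop_cfg("phases must be contiguous and non-overlapping")
  structure(list(phases = phases), class = "fold_ledger")
}

#' Default (reconstructed) lineage ledger
#'
#' Net per-day production rates `G[produced, parent]` reconstructed from the
#' lineage narrative: the published record keeps the full ratio table in
#' supplementary material not reproduced in the main text, so these matrices
#' are calibration inputs, not ground truth.  Each entry is an effective net
#' rate (products per division beyond parent replacement, times divisions
#' per day), calibrated so the simulated chronology reproduces the reported
#' milestones (radial-glia density peak near GW 9, outer-radial-glia peak
#' late in the ORG-production window, neuron surge peaking near GW 30,
#' folding onset shortly after GW 24).  Phase content: P1 symmetric RG
#' amplification; P2 gradual switch to asymmetric division (RG feed IPs,
#' IPs transit-amplify, early trickle of neurons); P3 RG source ORGs
#' instead; P4 ORGs become the second IP source and neuron output rises;
#' P5 IPs produce cortical neurons exclusively.  See the methods vignette
#' for the calibration rationale and what these defaults cannot express
#' (no parent consumption, hence no late IP decline).
#'
#' @param gw_end last gestational week covered (default 40).
#' @return a [lineage_ledger()].
#' @export
default_lineage_ledger <- function(gw_end = 40) {
  G0 <- function() matrix(0, 4, 4, dimnames = list(CELL_TYPES, CELL_TYPES))
  g1 <- G0(); g1["RG", "RG"] <- 0.75
  g2 <- G0(); g2["RG", "RG"] <- 0.1; g2["IP", "RG"] <- 0.035
  g2["IP", "IP"] <- 0.32; g2["N", "IP"] <- 0.02
  g3 <- G0(); g3["ORG", "RG"] <- 0.12; g3["N", "IP"] <- 0.02
  g4 <- G0(); g4["IP", "ORG"] <- 0.05; g4["ORG", "ORG"] <- 0.03
  g4["N", "IP"] <- 0.02
  g5 <- G0(); g5["N", "IP"] <- 0.05
  lineage_ledger(list(
    list(name = "P1", gw_start = 5, gw_end = 7, G = g1),
    list(name = "P2", gw_start = 7, gw_end = 11, G = g2),
    list(name = "P3", gw_start = 11, gw_end = 18, G = g3),
    list(name = "P4", gw_start = 18, gw_end = 24, G = g4),
    list(name = "P5", gw_start = 24, gw_end = gw_end, G = g5)
  ))
}

#' Division phase active at a gestational week
#'
#' Phase intervals are half-open `[gw_start, gw_end)`; the final phase also
#' accepts its right endpoint.
#'
#' @param t_gw gestational week (scalar).
#' @param ledger a [lineage_ledger()].
#' @return the phase (list with `name`, bounds and `G`).
#' @export
current_phase <- function(t_gw, ledger) {
  ph <- ledger$phases
  if (t_gw < ph[[1]]$gw_start)
    stop_cfg("t_gw = %g precedes first phase (starts GW %g)",
             t_gw, ph[[1]]$gw_start)
  last <- ph[[length(ph)]]
  if (t_gw > last$gw_end)
    stop_cfg("t_gw = %g beyond ledger coverage (ends GW %g)",
             t_gw, last$gw_end)
  for (p in ph) if (t_gw >= p$gw_start && t_gw < p$gw_end) return(p)
  last
}

#' Lineage source terms
#'
#' Literal evaluation of the division-ratio source
#' `f_b = sum_p G[b, p] c_p` in units of density per day.
#'
#' @param c_prev densities of the four types at the previous converged step:
#'   a length-4 vector or an n x 4 matrix ordered RG, IP, ORG, N.
#' @param phase a phase from [current_phase()] (or any list with a 4x4 `G`).
#' @return same shape as `c_prev`: per-type production rates (mm^-2 day^-1).
#' @export
source_terms <- function(c_prev, phase) {
  G <- phase$G
  if (is.null(G)) stop_cfg("phase '%s' has no ratio matrix",
                           phase$name %||% "?")
  if (is.matrix(c_prev)) {
    out <- c_prev %*% t(G)
    colnames(out) <- CELL_TYPES
    out
  } else {
    drop(G %*% c_prev)
  }
}

# ---------------------------------------------------------------------------
# Radial transport / diffusivity distributions

#' Moving outer subventricular boundary
#'
#' Mitotic somal translocation advances the OSVZ outer boundary linearly in
#' time after the end of phase P2:
#' `r_osvz(t) = min(r_osvz, r_isvz + m_mst <t - t_P2>)`.
#'
#' @param t computational time (days).
#' @param m_mst MST rate (mm/day).
#' @param t_P2 end of the second division phase (days).
#' @param r_isvz,r_osvz inner-SVZ and maximal OSVZ radii (mm).
#' @return the current boundary radius (mm), vectorized over `t`.
#' @export
osvz_radius <- function(t, m_mst, t_P2, r_isvz, r_osvz) {
  pmin(r_osvz, r_isvz + m_mst * pmax(t - t_P2, 0))
}

check_cell_type <- function(cell_type) {
  if (!cell_type %in% CELL_TYPES)
    stop_cfg("unknown cell type '%s' (expected one of %s)", cell_type,
             paste(CELL_TYPES, collapse = ", "))
  cell_type
}

t_P2_of <- function(ledger) {
  for (p in ledger$phases) if (p$name == "P2") return(time_from_gw(p$gw_end))
  time_from_gw(11)
}

#' Radial transport-speed field
#'
#' Type-specific migration speed as a function of the reference radius.
#' Intermediate progenitors and outer radial glia move below the (moving)
#' OSVZ boundary; neurons migrate below the cortical plate; radial glia do
#' not advect.
#'
#' @param cell_type one of `"RG"`, `"IP"`, `"ORG"`, `"N"`.
#' @param r_i reference radius (mm), vectorized.
#' @param t computational time (days).
#' @param params a [transport_params()] object.
#' @param domain a [build_domain()] object.
#' @param t_P2 end time of phase P2 (days), see [osvz_radius()].
#' @return speed in mm/day, `>= 0`.
#' @export
transport_speed_field <- function(cell_type, r_i, t, params, domain,
                                  t_P2 = time_from_gw(11)) {
  check_cell_type(cell_type)
  rosvz <- osvz_radius(t, params$m_mst, t_P2, domain$r_isvz, domain$r_osvz)
  switch(cell_type,
    RG = rep_len(0, length(r_i)),
    IP = params$v_IP * (1 - smooth_heaviside(r_i - rosvz, params$gamma_r)),
    ORG = params$v_ORG * (1 - smooth_heaviside(r_i - rosvz, params$gamma_r)),
    N = params$v_N * (1 - smooth_heaviside(r_i - domain$r_cp,
                                           params$gamma_r_cp))
  )
}

#' Radial diffusivity field
#'
#' Radial glia disperse inside the ventricular zone, intermediate
#' progenitors and outer radial glia below the moving OSVZ boundary, neurons
#' only once inside the cortical plate.
#'
#' @inheritParams transport_speed_field
#' @return diffusivity in mm^2/day, `>= 0`.
#' @export
diffusivity_field <- function(cell_type, r_i, t, params, domain,
                              t_P2 = time_from_gw(11)) {
  check_cell_type(cell_type)
  rosvz <- osvz_radius(t, params$m_mst, t_P2, domain$r_isvz, domain$r_osvz)
  switch(cell_type,
    RG = params$d_c * (1 - smooth_heaviside(r_i - domain$r_vz,
                                            params$gamma_r)),
    IP = params$d_c * (1 - smooth_heaviside(r_i - rosvz, params$gamma_r)),
    ORG = params$d_c * (1 - smooth_heaviside(r_i - rosvz, params$gamma_r)),
    N = params$d_N * smooth_heaviside(r_i - domain$r_cp, params$gamma_r_cp)
  )
}

#' Density-gated advective velocity
#'
#' `v_hat = H(c - c0; gamma_c) v(r_i) n / |n|`: transport along the pushed
#' forward radial direction `n = F N`, switched on smoothly once the
#' type-specific density passes the gate threshold.
#'
#' @inheritParams transport_speed_field
#' @param c_type density of this cell type (mm^-2, scalar).
#' @param n spatial direction vector (2-vector, `F %*% N`), non-zero.
#' @return velocity 2-vector (mm/day).
#' @export
advective_velocity <- function(cell_type, c_type, n, r_i, t, params, domain,
                               t_P2 = time_from_gw(11)) {
  nrm <- sqrt(sum(n^2))
  if (nrm == 0) stop_cfg("zero spatial normal")
  gate <- smooth_heaviside(c_type - params$c0_threshold, params$gamma_c)
  v <- transport_speed_field(cell_type, r_i, t, params, domain, t_P2)
  gate * v * n / nrm
}

#' Streamline (SUPG-type) artificial diffusivity
#'
#' `nu = beta h |v| / 2`, applied isotropically; stabilizes the
#' advection-dominated transport at the subcortex-cortex transition.
#'
#' @param h element size (mm), positive.
#' @param v_magnitude local advective speed (mm/day), `>= 0`.
#' @param beta_supg stabilization constant.
#' @return artificial diffusivity (mm^2/day).
#' @export
artificial_diffusivity <- function(h, v_magnitude, beta_supg) {
  if (any(h <= 0)) stop_cfg("element size must be positive")
  beta_supg * h * v_magnitude / 2
}

#' Cell flux
#'
#' `q = -c v_hat + (d + nu) grad(c)`: advection plus (physical + artificial)
#' isotropic diffusion.
#'
#' @inheritParams advective_velocity
#' @param grad_c spatial density gradient (2-vector, mm^-3).
#' @param h element size for the artificial diffusivity (mm).
#' @return flux 2-vector.
#' @export
flux <- function(cell_type, c_type, grad_c, n, r_i, t, params, domain,
                 h, t_P2 = time_from_gw(11)) {
  vhat <- advective_velocity(cell_type, c_type, n, r_i, t, params, domain,
                             t_P2)
  d <- diffusivity_field(cell_type, r_i, t, params, domain, t_P2)
  nu <- artificial_diffusivity(h, sqrt(sum(vhat^2)), params$beta_supg)
  -c_type * vhat + (d + nu) * grad_c
}
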