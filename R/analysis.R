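#' Deformed outer contour of the sector
#'
#' Returns the deformed positions of the outer-arc nodes ordered by their
#' reference angle (invariant to node numbering).
#'
#' @param mesh a `fold_mesh` with an `outer_arc` boundary tag.
#' @param u nodal displacements (n x 2), defaults to the reference shape.
#' @return matrix (m x 2) of positions, ordered from the first-axis end to
#'   the second-axis end of the arc.
#' @export
extract_outer_contour <- function(mesh, u = NULL) {
  rmax <- max(mesh$r_node)
  # outer ring = all nodes on the outermost radial layer, including the
  # corner nodes whose boundary tag was claimed by the straight edges
  if (!is.null(mesh$n_radial)) {
    nr <- mesh$n_radial + 1L
    ids <- which((seq_len(nrow(mesh$nodes)) - 1L) %% nr == nr - 1L)
  } else {
    ids <- mesh$boundary$outer_arc
  }
  if (!length(ids)) stop_cfg("outer_arc tag missing")
  ang <- atan2(mesh$nodes[ids, 2] - mesh$domain$X0[2],
               mesh$nodes[ids, 1] - mesh$domain$X0[1])
  ids <- ids[order(ang)]
  if (anyDuplicated(round(sort(ang), 12)))
    stop_cfg("outer contour ordering is ambiguous (non-manifold arc)")
  pos <- mesh$nodes[ids, , drop = FALSE]
  if (!is.null(u)) pos <- pos + u[ids, , drop = FALSE]
  unname(pos)
}

poly_perimeter <- function(p, closed = TRUE) {
  q <- if (closed) rbind(p, p[1, ]) else p
  sum(sqrt(rowSums(diff(q)^2)))
}

segments_intersect <- function(p1, p2, p3, p4) {
  d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
  d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
  d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
  d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

poly_simple <- function(p) {
  n <- nrow(p)
  if (n < 4) return(TRUE)
  idx <- rbind(cbind(seq_len(n), c(seq_len(n)[-1], 1L)))
  for (a in seq_len(n - 2)) {
    for (b in (a + 2):n) {
      if (a == 1 && b == n) next
      if (segments_intersect(p[idx[a, 1], ], p[idx[a, 2], ],
                             p[idx[b, 1], ], p[idx[b, 2], ])) return(FALSE)
    }
  }
  TRUE
}

#' Local gyrification index of a closed contour
#'
#' `lGI = perimeter(contour) / perimeter(convex hull)`; 1 for a convex
#' contour, above 1 once folds develop.  Scale- and rigid-motion invariant.
#'
#' @param contour closed polyline as an (n x 2) matrix of vertices (the
#'   closing edge from last to first vertex is implied), `n >= 3`.
#' @param check_simple verify the contour does not self-intersect (error if
#'   it does).
#' @return the gyrification index (`>= 1` up to round-off).
#' @export
gyrification_index <- function(contour, check_simple = TRUE) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 3) stop_cfg("need at least 3 vertices")
  if (check_simple && !poly_simple(contour))
    stop_cfg("contour self-intersects; folding exceeded model validity")
  hull <- contour[chull(contour), , drop = FALSE]
  poly_perimeter(contour) / poly_perimeter(hull)
}

#' Gyrification index of the simulated sector
#'
#' Closes the deformed outer arc through the sector centre (a pie-slice
#' polygon, convex exactly while the outer arc is convex — which makes
#' `lGI = 1` a sharp pre-buckling baseline), then applies
#' [gyrification_index()].
#'
#' @inheritParams extract_outer_contour
#' @return the local gyrification index.
#' @export
sector_gyrification <- function(mesh, u = NULL) {
  arc <- extract_outer_contour(mesh, u)
  poly <- rbind(arc, mesh$domain$X0)
  gyrification_index(poly)
}

#' Dominant fold wavelength of the outer contour
#'
#' Detrends the radius-vs-arclength signal of the deformed outer arc with a
#' quadratic fit and counts its local maxima (crests) above a prominence
#' threshold.  The wavelength is reported in the material (reference) frame
#' — reference outer-arc length divided by the crest count — so it measures
#' the angular spacing of folds and is insensitive to how much the folded
#' surface has grown in absolute terms.
#'
#' @inheritParams extract_outer_contour
#' @param prominence minimum crest height relative to the largest
#'   radial undulation (default 5%).
#' @return wavelength in reference mm, or `NA` if the arc carries no crest.
#' @export
fold_wavelength <- function(mesh, u = NULL, prominence = 0.05) {
  arc <- extract_outer_contour(mesh, u)
  s <- c(0, cumsum(sqrt(rowSums(diff(arc)^2))))
  r <- sqrt((arc[, 1] - mesh$domain$X0[1])^2 +
            (arc[, 2] - mesh$domain$X0[2])^2)
  trend <- stats::fitted(stats::lm(r ~ stats::poly(s, 2)))
  res <- r - trend
  amp <- max(abs(res))
  if (amp < 1e-9) return(NA_real_)
  thr <- prominence * amp
  n <- length(res)
  crest <- which(res[2:(n - 1)] > res[1:(n - 2)] &
                 res[2:(n - 1)] >= res[3:n] &
                 res[2:(n - 1)] > thr)
  if (!length(crest)) return(NA_real_)
  ref_arc <- pi / 2 * max(mesh$r_node)
  ref_arc / length(crest)
}

#' Radial density profile along a mesh ray
#'
#' Samples the four density fields along a radial mesh line (the line whose
#' reference angle is closest to `ray_theta`), against the normalized
#' arclength of the deformed ray from the ventricular surface (0) to the
#' outer surface (1).  With `normalize = TRUE` all densities are scaled by
#' the mean of the total density over the samples, matching the convention
#' used to compare against stained sections.
#'
#' @param mesh a structured `fold_mesh`.
#' @param u nodal displacements (or `NULL` for the reference shape).
#' @param c_nodes nodal densities, n x 4 (columns RG, IP, ORG, N).
#' @param ray_theta reference angle of the ray (radians within `[0, pi/2]`).
#' @param n_samples number of output samples.
#' @param normalize apply the mean-total normalization.
#' @param gw gestational-week stamp carried into the result.
#' @return a `data.frame` (class `fold_profile`) with columns
#'   `normalized_radius`, `ref_radius`, `c_RG`, `c_IP`, `c_ORG`, `c_N`,
#'   `c_total`, `gw`.
#' @export
radial_profile <- function(mesh, u, c_nodes, ray_theta = pi / 4,
                           n_samples = 200, normalize = TRUE, gw = NA_real_) {
  if (is.null(mesh$thetas)) stop_cfg("radial_profile needs a structured mesh")
  if (ray_theta < -1e-9 || ray_theta > pi / 2 + 1e-9)
    stop_cfg("ray angle %.3f outside the sector [0, pi/2]", ray_theta)
  j <- which.min(abs(mesh$thetas - ray_theta))
  nr <- mesh$n_radial + 1L
  ids <- (j - 1L) * nr + seq_len(nr)
  pos <- mesh$nodes[ids, , drop = FALSE]
  if (!is.null(u)) pos <- pos + u[ids, , drop = FALSE]
  s <- c(0, cumsum(sqrt(rowSums(diff(pos)^2))))
  s <- s / max(s)
  xs <- seq(0, 1, length.out = n_samples)
  interp <- function(v) stats::approx(s, v, xout = xs)$y
  out <- data.frame(
    normalized_radius = xs,
    ref_radius = interp(mesh$r_node[ids]),
    c_RG = interp(c_nodes[ids, 1]), c_IP = interp(c_nodes[ids, 2]),
    c_ORG = interp(c_nodes[ids, 3]), c_N = interp(c_nodes[ids, 4]))
  out$c_total <- out$c_RG + out$c_IP + out$c_ORG + out$c_N
  if (normalize) {
    m <- mean(out$c_total)
    if (m > 0) {
      cols <- c("c_RG", "c_IP", "c_ORG", "c_N", "c_total")
      out[cols] <- out[cols] / m
    }
  }
  out$gw <- gw
  class(out) <- c("fold_profile", "data.frame")
  out
}

#' Per-zone cellular deconvolution table
#'
#' Splits a radial profile into the five germinal zones by reference radius
#' and reports the mean density of each cell type plus its fraction of the
#' zone total (fractions sum to one; `NaN` where a zone holds no cells).
#'
#' @param profile a [radial_profile()] result.
#' @param domain the [build_domain()] the profile was sampled on.
#' @return data.frame with one row per zone (VZ, ISVZ, OSVZ, IZ, CP).
#' @export
deconvolution_table <- function(profile, domain) {
  zone <- factor(classify_zone(profile$ref_radius, domain),
                 levels = c("VZ", "ISVZ", "OSVZ", "IZ", "CP"))
  means <- sapply(c("c_RG", "c_IP", "c_ORG", "c_N"), function(col)
    tapply(profile[[col]], zone, mean))
  tot <- rowSums(means)
  fr <- means / tot
  out <- data.frame(zone = rownames(means), means,
                    frac_RG = fr[, 1], frac_IP = fr[, 2],
                    frac_ORG = fr[, 3], frac_N = fr[, 4],
                    row.names = NULL, check.names = FALSE)
  names(out)[2:5] <- c("mean_RG", "mean_IP", "mean_ORG", "mean_N")
  out
}

#' Gestational week of the temporal maximum
#'
#' @param values series of a density statistic (one per recorded step).
#' @param gw matching gestational weeks.
#' @return the gestational week of the global maximum (ties resolve to the
#'   earliest).
#' @export
temporal_peak <- function(values, gw) {
  if (length(values) < 2) stop_cfg("need at least 2 samples")
  if (length(values) != length(gw)) stop_cfg("values/gw length mismatch")
  gw[which.max(values)]
}
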