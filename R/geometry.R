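#' Reference domain of the brain section
#'
#' A quarter annulus centred at `X0` spanning radii `[r, R]`, subdivided into
#' the five concentric germinal zones: ventricular zone (VZ, up to `r_vz`),
#' inner subventricular zone (ISVZ, to `r_isvz`), outer subventricular zone
#' (OSVZ, to `r_osvz`), intermediate zone (IZ, to `r_cp`), and cortical
#' plate (CP, to `R`).
#'
#' @param config named list/vector overriding any of `R`, `r`, `r_vz`,
#'   `r_isvz`, `r_osvz`, `r_cp`, `X0` (defaults: 2, 0.4, 0.5, 0.8, 1.2, 1.9,
#'   origin; all in mm).
#' @return an object of class `fold_domain`.
#' @export
build_domain <- function(config = list()) {
  d <- list(R = 2, r = 0.4, r_vz = 0.5, r_isvz = 0.8, r_osvz = 1.2,
            r_cp = 1.9, X0 = c(0, 0))
  unknown <- setdiff(names(config), names(d))
  if (length(unknown)) stop_cfg("unknown geometry key(s): %s",
                                paste(unknown, collapse = ", "))
  d <- modifyList(d, as.list(config))
  radii <- unlist(d[c("r", "r_vz", "r_isvz", "r_osvz", "r_cp", "R")])
  if (any(!is.finite(radii)) || any(radii <= 0))
    stop_cfg("all radii must be positive and finite")
  inc <- diff(radii) > 0
  if (!all(inc)) {
    i <- which(!inc)[1]
    stop_cfg("zone radii must increase: %s (%g) >= %s (%g)",
             names(radii)[i], radii[i], names(radii)[i + 1], radii[i + 1])
  }
  structure(d, class = "fold_domain")
}

#' Classify reference radii into germinal zones
#'
#' @param r_i reference radius (mm), vectorized.
#' @param domain a [build_domain()] object.
#' @return character vector with values in
#'   `c("VZ", "ISVZ", "OSVZ", "IZ", "CP")`.
#' @export
classify_zone <- function(r_i, domain) {
  breaks <- c(-Inf, domain$r_vz, domain$r_isvz, domain$r_osvz, domain$r_cp,
              Inf)
  zones <- c("VZ", "ISVZ", "OSVZ", "IZ", "CP")
  zones[findInterval(r_i, breaks, left.open = TRUE)]
}

new_mesh <- function(nodes, elems, boundary, domain, extra = list()) {
  r_node <- sqrt((nodes[, 1] - domain$X0[1])^2 +
                 (nodes[, 2] - domain$X0[2])^2)
  structure(c(list(nodes = nodes, elems = elems, boundary = boundary,
                   domain = domain, r_node = r_node), extra),
            class = "fold_mesh")
}

#' Structured quadrilateral mesh of the quarter annulus
#'
#' Polar-structured bilinear quadrilaterals.  The radial subdivision is
#' graded so that the cortical plate (`R - r_cp`) is resolved by at least
#' `cortex_layers` element layers, the remaining layers being uniform over
#' the subcortex; this resolves the thin stiff layer whose buckling the
#' model is about.
#'
#' @param domain a [build_domain()] object.
#' @param n_radial,n_circumferential element counts (each `>= 2`).
#' @param cortex_layers minimum radial layers inside the cortical plate
#'   (default 3, capped at `n_radial - 2`).
#' @return an object of class `fold_mesh` with fields `nodes` (mm),
#'   `elems` (4 columns, counter-clockwise), `boundary` (disjoint tagged
#'   node-id sets `inner_arc`, `edge_x1` where the first coordinate
#'   vanishes, `edge_x2` where the second vanishes, `outer_arc`), and
#'   per-node reference radius `r_node`.
#' @export
generate_mesh <- function(domain, n_radial, n_circumferential,
                          cortex_layers = 3) {
  if (n_radial < 2 || n_circumferential < 2)
    stop_cfg("element counts must be >= 2")
  n_radial <- as.integer(n_radial)
  n_circ <- as.integer(n_circumferential)
  radii <- radial_layout(domain, n_radial, cortex_layers)
  thetas <- seq(0, pi / 2, length.out = n_circ + 1)
  nr <- n_radial + 1L
  grid <- expand.grid(ir = seq_len(nr), it = seq_len(n_circ + 1L))
  nodes <- cbind(domain$X0[1] + radii[grid$ir] * cos(thetas[grid$it]),
                 domain$X0[2] + radii[grid$ir] * sin(thetas[grid$it]))
  # snap the straight edges exactly onto the axes
  nodes[grid$it == 1L, 2] <- domain$X0[2]
  nodes[grid$it == n_circ + 1L, 1] <- domain$X0[1]
  nid <- function(ir, it) (it - 1L) * nr + ir
  e_ir <- rep(seq_len(n_radial), n_circ)
  e_it <- rep(seq_len(n_circ), each = n_radial)
  elems <- cbind(nid(e_ir, e_it), nid(e_ir + 1L, e_it),
                 nid(e_ir + 1L, e_it + 1L), nid(e_ir, e_it + 1L))
  # boundary tags with corner precedence: inner_arc > edges > outer_arc
  inner <- nid(1L, seq_len(n_circ + 1L))
  edge_x2 <- setdiff(nid(seq_len(nr), 1L), inner)           # x2 == 0
  edge_x1 <- setdiff(nid(seq_len(nr), n_circ + 1L), inner)  # x1 == 0
  outer <- setdiff(nid(nr, seq_len(n_circ + 1L)),
                   c(inner, edge_x1, edge_x2))
  new_mesh(nodes, elems,
           boundary = list(inner_arc = inner, edge_x1 = edge_x1,
                           edge_x2 = edge_x2, outer_arc = outer),
           domain = domain,
           extra = list(n_radial = n_radial, n_circ = n_circ,
                        radii = radii, thetas = thetas))
}

# Zone-aware radial node layout: uniform within each germinal zone, with the
# intermediate zone graded geometrically towards the thin cortical plate so
# the advective boundary layer below r_cp and the buckling layer above it are
# both resolved.  Falls back to a uniform split for very coarse meshes.
radial_layout <- function(domain, n_radial, cortex_layers = 3) {
  if (n_radial < 8)
    return(seq(domain$r, domain$R, length.out = n_radial + 1))
  n_cp <- max(min(cortex_layers, n_radial - 6L), 2L)
  rest <- n_radial - n_cp
  n_vz <- max(2L, round(0.18 * rest))
  n_isvz <- max(2L, round(0.2 * rest))
  n_osvz <- max(2L, round(0.22 * rest))
  n_iz <- rest - n_vz - n_isvz - n_osvz
  if (n_iz < 2L) { n_iz <- 2L; n_osvz <- rest - n_vz - n_isvz - n_iz }
  h_cp <- (domain$R - domain$r_cp) / n_cp
  # IZ sizes decrease geometrically towards the cortex, last ~1.5 h_cp
  len_iz <- domain$r_cp - domain$r_osvz
  d_out <- 1.5 * h_cp
  d_iz <- if (n_iz * d_out < len_iz * 0.999) {
    g <- stats::uniroot(function(g) d_out * (g^n_iz - 1) / (g - 1) - len_iz,
                        c(1.0001, 10), extendInt = "upX")$root
    d_out * g^((n_iz - 1):0)
  } else {
    rep(len_iz / n_iz, n_iz)
  }
  r_iz <- domain$r_osvz + cumsum(c(0, d_iz))
  r_iz[n_iz + 1] <- domain$r_cp
  c(seq(domain$r, domain$r_vz, length.out = n_vz + 1),
    seq(domain$r_vz, domain$r_isvz, length.out = n_isvz + 1)[-1],
    seq(domain$r_isvz, domain$r_osvz, length.out = n_osvz + 1)[-1],
    r_iz[-1],
    seq(domain$r_cp, domain$R, length.out = n_cp + 1)[-1])
}

# Structured rectangle mesh (internal; transport verification fixtures).
mesh_strip <- function(length_x, length_y, nx, ny) {
  xs <- seq(0, length_x, length.out = nx + 1)
  ys <- seq(0, length_y, length.out = ny + 1)
  grid <- expand.grid(ix = seq_len(nx + 1), iy = seq_len(ny + 1))
  nodes <- cbind(xs[grid$ix], ys[grid$iy])
  nid <- function(ix, iy) (iy - 1L) * (nx + 1L) + ix
  e_ix <- rep(seq_len(nx), ny)
  e_iy <- rep(seq_len(ny), each = nx)
  elems <- cbind(nid(e_ix, e_iy), nid(e_ix + 1L, e_iy),
                 nid(e_ix + 1L, e_iy + 1L), nid(e_ix, e_iy + 1L))
  dom <- build_domain()
  structure(list(nodes = nodes, elems = elems,
                 boundary = list(inner_arc = integer(), edge_x1 = integer(),
                                 edge_x2 = integer(), outer_arc = integer()),
                 domain = dom,
                 r_node = sqrt(rowSums(nodes^2))),
            class = "fold_mesh")
}

#' Total mesh area
#'
#' Sum of element areas (shoelace formula); converges to the analytic
#' quarter-annulus area `pi (R^2 - r^2) / 4` under refinement.
#'
#' @param mesh a `fold_mesh`.
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) {
  x <- matrix(mesh$nodes[mesh$elems, 1], ncol = 4)
  y <- matrix(mesh$nodes[mesh$elems, 2], ncol = 4)
  xn <- x[, c(2, 3, 4, 1)]
  yn <- y[, c(2, 3, 4, 1)]
  sum(abs(rowSums(x * yn - xn * y)) / 2)
}

#' Seeded radial imperfection
#'
#' Displaces nodes with reference radius above the OSVZ boundary (interior
#' and outer arc only; tagged straight edges and the inner arc stay put)
#' radially by uniform white noise in `[-amplitude, amplitude]`.  Needed to
#' break the rotational symmetry so the buckling instability can select a
#' wrinkling mode; identical seeds give identical meshes.
#'
#' @param mesh a `fold_mesh` from [generate_mesh()].
#' @param amplitude bound on the radial displacement (mm), `>= 0`.
#' @param seed integer RNG seed.
#' @return the perturbed mesh (with `r_node` recomputed).
#' @export
apply_imperfection <- function(mesh, amplitude, seed) {
  if (amplitude < 0) stop_cfg("imperfection amplitude must be >= 0")
  if (amplitude == 0) return(mesh)
  fixed <- unique(c(mesh$boundary$inner_arc, mesh$boundary$edge_x1,
                    mesh$boundary$edge_x2))
  idx <- setdiff(which(mesh$r_node > mesh$domain$r_osvz), fixed)
  old_rng <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(as.integer(seed))
  dr <- runif(length(idx), -amplitude, amplitude)
  if (!is.null(old_rng)) assign(".Random.seed", old_rng, globalenv())
  dir <- mesh$nodes[idx, , drop = FALSE] -
    matrix(mesh$domain$X0, length(idx), 2, byrow = TRUE)
  dir <- dir / mesh$r_node[idx]
  mesh$nodes[idx, ] <- mesh$nodes[idx, ] + dr * dir
  mesh$r_node <- sqrt((mesh$nodes[, 1] - mesh$domain$X0[1])^2 +
                      (mesh$nodes[, 2] - mesh$domain$X0[2])^2)
  mesh
}
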