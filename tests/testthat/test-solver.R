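make_setup <- function(n_radial = 6, n_circ = 8, c_init = 50) {
  cfg <- fold_config(geometry = list(n_radial = n_radial,
                                     n_circumferential = n_circ),
                     solver = list(c_init = c_init,
                                   imperfection_amplitude = 0))
  parts <- corticofold:::config_objects(cfg)
  parts$params$bc <- apply_boundary_conditions(parts$mesh)
  parts$params$qp <- corticofold:::qp_static(parts$mesh,
                                             parts$params$growth,
                                             parts$params$materials,
                                             parts$params$transport)
  parts$params$mass_lumping <- FALSE
  parts$state <- corticofold:::init_state(parts$mesh, parts$solver)
  parts
}

test_that("boundary conditions constrain the stated dof sets", {
  m <- tiny_mesh(4, 6)
  bc <- apply_boundary_conditions(m)
  b <- m$boundary
  # inner arc: both components; straight edges: one component each
  expect_true(all(c(2 * (b$inner_arc - 1) + 1,
                    2 * (b$inner_arc - 1) + 2) %in% bc$fixed))
  expect_true(all((2 * (b$edge_x2 - 1) + 2) %in% bc$fixed))
  expect_false(any((2 * (b$edge_x2 - 1) + 1) %in% bc$fixed))
  expect_true(all((2 * (b$edge_x1 - 1) + 1) %in% bc$fixed))
  # outer arc: natural conditions, no constraint rows
  expect_false(any(c(2 * (b$outer_arc - 1) + 1,
                     2 * (b$outer_arc - 1) + 2) %in% bc$fixed))
  expect_equal(sort(c(bc$fixed, bc$free)), seq_len(2 * nrow(m$nodes)))
  # untagged boundary nodes are rejected
  m2 <- m
  m2$boundary$inner_arc <- m2$boundary$inner_arc[-1]
  expect_error(apply_boundary_conditions(m2), "untagged")
})

test_that("the freshly initialized zero-density state is in equilibrium", {
  su <- make_setup(c_init = 0)
  sys <- assemble_system(su$mesh, su$state, su$params, 0.25)
  expect_lt(sqrt(sum(sys$R_phi^2)), 1e-12)
  for (k in 1:4) expect_lt(sqrt(sum(sys$R_c[[k]]^2)), 1e-10)
  # growth stays at identity with zero density: Fg = I, theta = 1
  ex <- sys$explicit
  expect_equal(max(abs(ex$theta_perp - 1)), 0)
  expect_equal(max(abs(ex$theta_par - 1)), 0)
})

test_that("the density-density tangent blocks vanish by construction", {
  # coupling between species rides on the explicit source only: the
  # transport operator of species k must not change when another species'
  # density changes
  su <- make_setup()
  st <- su$state
  sys1 <- corticofold:::density_systems(su$mesh, st, st,
                                        corticofold:::explicit_fields(
                                          su$mesh, st, su$params),
                                        su$params, 0.25)
  st2 <- st
  st2$c[, "IP"] <- st2$c[, "IP"] + 100
  ex2 <- corticofold:::explicit_fields(su$mesh, st, su$params)
  sys2 <- corticofold:::density_systems(su$mesh, st2, st,
                                        ex2, su$params, 0.25)
  # same prev state => identical RG operator despite different current IP
  expect_equal(sys1$RG$A, sys2$RG$A)
})

test_that("mechanics tangent matches finite differences of the residual", {
  su <- make_setup(4, 6)
  mesh <- su$mesh
  nn <- nrow(mesh$nodes)
  ne <- nrow(mesh$elems)
  set.seed(31)
  u <- matrix(rnorm(2 * nn, 0, 0.004), nn, 2)
  thp <- matrix(runif(ne * 4, 1, 1.3), ne, 4)
  thr <- matrix(runif(ne * 4, 0.9, 1.1), ne, 4)
  qp <- su$params$qp
  mu <- matrix(runif(ne * 4, 0.5, 2), ne, 4)
  lam <- matrix(lame_second_parameter(mu, 0.38), ne, 4)
  asm <- corticofold:::cf_mech_assemble(mesh$nodes, mesh$elems, u, thp, thr,
                                        qp$nx, qp$ny, mu, lam)
  K <- Matrix::sparseMatrix(i = asm$i, j = asm$j, x = asm$x,
                            dims = c(2 * nn, 2 * nn))
  h <- 1e-6
  dirv <- rnorm(2 * nn)
  du <- matrix(dirv, nn, 2, byrow = TRUE)
  rp <- corticofold:::cf_mech_assemble(mesh$nodes, mesh$elems, u + h * du,
                                       thp, thr, qp$nx, qp$ny, mu,
                                       lam)$resid
  rm_ <- corticofold:::cf_mech_assemble(mesh$nodes, mesh$elems, u - h * du,
                                        thp, thr, qp$nx, qp$ny, mu,
                                        lam)$resid
  fd <- (rp - rm_) / (2 * h)
  expect_lt(max(abs(fd - as.numeric(K %*% dirv))) / max(abs(fd)), 1e-5)
})

test_that("density tangent is the exact operator of the linear residual", {
  su <- make_setup()
  st <- su$state
  st$t <- st$t + 0.25
  ex <- corticofold:::explicit_fields(su$mesh, su$state, su$params)
  dens <- corticofold:::density_systems(su$mesh, st, su$state, ex,
                                        su$params, 0.25)
  nn <- nrow(su$mesh$nodes)
  set.seed(32)
  c1 <- runif(nn, 0, 100); c2 <- runif(nn, 0, 100)
  r1 <- dens$RG$A %*% c1 - dens$RG$b
  r2 <- dens$RG$A %*% c2 - dens$RG$b
  expect_equal(as.numeric(r2 - r1), as.numeric(dens$RG$A %*% (c2 - c1)),
               tolerance = 1e-12)
})

test_that("Newton converges fast on a small growth increment", {
  su <- make_setup(6, 8, c_init = 50)
  st1 <- advance_time(su$state, su$mesh, su$params, su$solver)
  expect_lte(st1$newton_iters, 5)
  expect_lte(st1$resid, su$solver$newton_tol)
  expect_true(all(st1$J_prev > 0))
  # converged state re-assembled has a residual within tolerance
  sys <- assemble_system(su$mesh, st1, su$params, 0.25, prev = su$state)
  expect_lte(sqrt(sum(sys$R_phi[su$params$bc$free]^2)),
             su$solver$newton_tol * 1.01)
})

test_that("an impossible step fails controlledly, not with a crash", {
  su <- make_setup(4, 6)
  st <- su$state
  st$c[, 1] <- 1e5  # absurd density -> enormous growth increment
  su$solver$max_dt_halvings <- 1
  su$solver$newton_max_iter <- 3
  expect_error(advance_time(st, su$mesh, su$params, su$solver),
               "Newton failed")
})

test_that("material mass is conserved without sources (f = 0, q.n = 0)", {
  led0 <- default_lineage_ledger()
  for (i in seq_along(led0$phases)) led0$phases[[i]]$G[] <- 0
  path <- tempfile(fileext = ".json")
  write_lineage_ledger(led0, path)
  cfg <- fold_config(geometry = list(n_radial = 12,
                                     n_circumferential = 16),
                     solver = list(t_end = time_from_gw(5) + 100 * 0.25,
                                   imperfection_amplitude = 0),
                     lineage = list(path = path))
  sim <- run_simulation(cfg)
  expect_null(sim$summary$failure)
  expect_equal(nrow(sim$series), 101)
  m0 <- sim$series$mass_RG[1]
  drift <- abs(sim$series$mass_RG - m0) / m0
  expect_lt(max(drift), 1e-3)          # < 0.1% over 100 steps
  # the other species stay identically empty
  expect_lt(max(abs(sim$series$mass_N)), 1e-10)
})

test_that("time integration is first-order accurate in dt", {
  # two steps of dt vs one step of 2 dt on the coupled system
  run_dt <- function(dt, n) {
    su <- make_setup(6, 8)
    st <- su$state
    cfg <- su$solver; cfg$dt <- dt
    for (i in seq_len(n)) st <- advance_time(st, su$mesh, su$params, cfg)
    st
  }
  s_big <- run_dt(0.5, 2)
  s_mid <- run_dt(0.25, 4)
  s_fine <- run_dt(0.125, 8)
  e1 <- max(abs(s_big$c - s_fine$c))
  e2 <- max(abs(s_mid$c - s_fine$c))
  expect_lt(e2, e1)            # errors shrink with dt
  expect_gt(e1 / e2, 1.5)      # at a roughly first-order rate
})

test_that("runs are deterministic given config and seed", {
  cfg <- fold_config(geometry = list(n_radial = 8,
                                     n_circumferential = 10),
                     solver = list(t_end = time_from_gw(6.5)))
  s1 <- run_simulation(cfg)
  s2 <- run_simulation(cfg)
  expect_identical(s1$final$u, s2$final$u)
  expect_identical(s1$final$c, s2$final$c)
  expect_equal(s1$summary$peak_gw, s2$summary$peak_gw)
})

test_that("phase flips exactly when the timeline crosses a boundary", {
  led <- default_lineage_ledger()
  t_boundary <- time_from_gw(7)
  expect_identical(current_phase(gw_from_time(t_boundary - 1e-6), led)$name,
                   "P1")
  expect_identical(current_phase(gw_from_time(t_boundary), led)$name, "P2")
})

test_that("1D advected Gaussian matches the closed form under refinement", {
  v <- 0.8; d <- 0.05; t0 <- 2; T <- 1.5; x0 <- 2
  exact <- function(x, t) exp(-(x - x0 - v * t)^2 / (4 * d * (t0 + t))) /
    sqrt(4 * pi * d * (t0 + t))
  l2err <- function(nx, nsteps) {
    m <- corticofold:::mesh_strip(8, 0.4, nx, 2)
    cini <- exact(m$nodes[, 1], 0)
    cnum <- corticofold:::transport_steps_uniform(m, cini, c(v, 0), d,
                                                  T / nsteps, nsteps)
    sqrt(mean((cnum - exact(m$nodes[, 1], T))^2))
  }
  e_coarse <- l2err(40, 15)
  e_fine <- l2err(80, 30)
  e_finest <- l2err(160, 60)
  expect_lt(e_fine, e_coarse)
  expect_lt(e_finest, e_fine)
  expect_lt(e_finest, 0.02)
})
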