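test_that("regularized Heaviside matches frozen values and is monotone", {
  expect_equal(smooth_heaviside(0, 5), 0.5)
  expect_equal(smooth_heaviside(500, 0.008), exp(4) / (1 + exp(4)),
               tolerance = 1e-12)
  expect_equal(smooth_heaviside(500, 0.008), 0.98201, tolerance = 1e-5)
  expect_equal(smooth_heaviside(-0.1, 20), 0.11920, tolerance = 1e-4)
  x <- seq(-2, 2, by = 0.01)
  expect_true(all(diff(smooth_heaviside(x, 7)) > 0))
  expect_equal(smooth_heaviside(c(-1e6, 1e6), 10), c(0, 1))  # no overflow
})

test_that("gestational-week timeline is the stated affine map", {
  expect_equal(gw_from_time(0), 4)
  expect_equal(time_from_gw(24), 20 / 0.3)
  t <- runif(20, 0, 100)
  expect_equal(time_from_gw(gw_from_time(t)), t)
})

test_that("lineage ledger validates and locates phases", {
  led <- default_lineage_ledger()
  expect_identical(current_phase(6, led)$name, "P1")
  expect_identical(current_phase(9, led)$name, "P2")
  expect_identical(current_phase(15, led)$name, "P3")
  expect_identical(current_phase(7, led)$name, "P2")   # half-open bounds
  expect_identical(current_phase(20, led)$name, "P4")
  expect_identical(current_phase(30, led)$name, "P5")
  expect_error(current_phase(4.5, led), "precedes")
  # P1 carries only radial-glia self-amplification
  G1 <- led$phases[[1]]$G
  expect_true(G1["RG", "RG"] > 0)
  expect_equal(sum(G1 != 0), 1)
  # invalid ledgers rejected
  bad <- led$phases
  bad[[2]]$gw_start <- 8
  expect_error(lineage_ledger(bad), "contiguous")
  bad <- led$phases
  bad[[1]]$G[1, 1] <- -1
  expect_error(lineage_ledger(bad), ">= 0")
})

test_that("source terms evaluate the published worked example literally", {
  f <- source_terms(c(RG = 100, IP = 50, ORG = 10, N = 0),
                    p3_example_phase())
  expect_equal(unname(f), c(100, 50, 110, 100))
  expect_equal(unname(source_terms(rep(0, 4), p3_example_phase())),
               rep(0, 4))
  # matrix form agrees with row-wise evaluation
  cm <- rbind(c(100, 50, 10, 0), c(1, 2, 3, 4))
  fm <- source_terms(cm, p3_example_phase())
  expect_equal(unname(fm[1, ]), c(100, 50, 110, 100))
  expect_equal(unname(fm[2, ]),
               unname(source_terms(c(1, 2, 3, 4), p3_example_phase())))
  expect_error(source_terms(rep(1, 4), list(name = "X")), "ratio matrix")
})

test_that("the OSVZ boundary ramps and clamps as specified", {
  t_P2 <- time_from_gw(11)
  expect_equal(osvz_radius(t_P2 - 5, 0.02, t_P2, 0.8, 1.2), 0.8)
  expect_equal(osvz_radius(t_P2 + 10, 0.02, t_P2, 0.8, 1.2), 1.0)
  expect_equal(osvz_radius(t_P2 + 20, 0.02, t_P2, 0.8, 1.2), 1.2)
  expect_equal(gw_from_time(t_P2 + 20), 17, tolerance = 1e-10)
  expect_equal(osvz_radius(t_P2 + 100, 0.02, t_P2, 0.8, 1.2), 1.2)
})

test_that("transport speeds follow the zone gating per cell type", {
  tp <- transport_params(); d <- build_domain()
  t_mid <- time_from_gw(20)
  expect_equal(transport_speed_field("N", 0.6, t_mid, tp, d), 5,
               tolerance = 1e-9)
  expect_lt(transport_speed_field("N", 2.2, t_mid, tp, d), 1e-4)
  expect_equal(transport_speed_field("ORG", 0.6, t_mid, tp, d), 10,
               tolerance = 1e-3)
  expect_equal(transport_speed_field("RG", 0.6, t_mid, tp, d), 0)
  expect_error(transport_speed_field("XX", 0.6, t_mid, tp, d), "unknown")
  # IP/ORG gate follows the moving boundary
  t_early <- time_from_gw(11)
  expect_lt(transport_speed_field("IP", 1.1, t_early, tp, d),
            transport_speed_field("IP", 1.1, time_from_gw(18), tp, d))
})

test_that("diffusivities are confined to the stated zones", {
  tp <- transport_params(); d <- build_domain()
  t_mid <- time_from_gw(20)
  # mid-VZ: the gamma_r = 20 blend is already at work 0.05 mm from the
  # boundary, so the exact value is d_c (1 - H(-0.05; 20)) = 0.0731
  expect_equal(diffusivity_field("RG", 0.45, t_mid, tp, d),
               0.1 * (1 - smooth_heaviside(-0.05, 20)), tolerance = 1e-9)
  expect_equal(diffusivity_field("RG", 0.41, t_mid, tp, d), 0.1,
               tolerance = 0.2)
  expect_lt(diffusivity_field("RG", 0.8, t_mid, tp, d), 1e-2)
  expect_equal(diffusivity_field("N", 2.2, t_mid, tp, d), 0.11,
               tolerance = 1e-4)
  expect_lt(diffusivity_field("N", 1.0, t_mid, tp, d), 1e-6)
  expect_lt(diffusivity_field("ORG", 1.5, t_mid, tp, d), 1e-2)
  # bounded by their Table constants everywhere
  r <- seq(0.4, 2, by = 0.01)
  for (ct in c("RG", "IP", "ORG", "N")) {
    v <- transport_speed_field(ct, r, t_mid, tp, d)
    dd <- diffusivity_field(ct, r, t_mid, tp, d)
    expect_true(all(v >= 0 & dd >= 0))
    expect_lte(max(v), c(RG = 0, IP = 0.025, ORG = 10, N = 5)[[ct]] + 1e-9)
    expect_lte(max(dd), c(RG = 0.1, IP = 0.1, ORG = 0.1, N = 0.11)[[ct]] +
                 1e-9)
  }
})

test_that("density-gated advective velocity has the stated magnitude", {
  tp <- transport_params(); d <- build_domain()
  t_mid <- time_from_gw(20)
  v <- advective_velocity("N", 500, c(1, 0), 0.6, t_mid, tp, d)
  expect_equal(sqrt(sum(v^2)), 0.5 * 5, tolerance = 1e-6)
  v2 <- advective_velocity("N", 1000, c(0.6, 0.8), 0.6, t_mid, tp, d)
  expect_equal(sqrt(sum(v2^2)), 0.98201 * 5, tolerance = 1e-3)
  expect_equal(v2 / sqrt(sum(v2^2)), c(0.6, 0.8), tolerance = 1e-9)
  expect_error(advective_velocity("N", 500, c(0, 0), 0.6, t_mid, tp, d),
               "zero")
})

test_that("artificial diffusivity follows the streamline formula", {
  expect_equal(artificial_diffusivity(0.05, 0, 0.1), 0)
  expect_equal(artificial_diffusivity(0.05, 5, 0.1), 0.0125)
  expect_equal(artificial_diffusivity(0.1, 5, 0.1),
               2 * artificial_diffusivity(0.05, 5, 0.1))
  expect_error(artificial_diffusivity(0, 5, 0.1), "positive")
})

test_that("flux superposes advection and diffusion", {
  tp <- transport_params(); d <- build_domain()
  t_mid <- time_from_gw(20)
  args <- list(cell_type = "N", c_type = 800, grad_c = c(10, -5),
               n = c(1, 0), r_i = 1.95, t = t_mid, params = tp,
               domain = d, h = 0.05)
  q <- do.call(flux, args)
  adv <- do.call(flux, modifyList(args, list(grad_c = c(0, 0))))
  vhat <- advective_velocity("N", 800, c(1, 0), 1.95, t_mid, tp, d)
  dtot <- diffusivity_field("N", 1.95, t_mid, tp, d) +
    artificial_diffusivity(0.05, sqrt(sum(vhat^2)), 0.1)
  expect_equal(adv, -800 * vhat, tolerance = 1e-10)
  expect_equal(q - adv, dtot * c(10, -5), tolerance = 1e-10)
  # pure advection when diffusivity vanishes (deep subcortex for neurons)
  q_deep <- do.call(flux, modifyList(args, list(r_i = 0.8)))
  vhat <- advective_velocity("N", 800, c(1, 0), 0.8, t_mid, tp, d)
  nu <- artificial_diffusivity(0.05, sqrt(sum(vhat^2)), 0.1)
  expect_equal(q_deep, -800 * vhat + nu * c(10, -5), tolerance = 1e-8)
})
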