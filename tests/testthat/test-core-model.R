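# Flux laws, constraint algebra and the membrane-potential equation.

test_that("impermeant-osmolyte valence and water content follow from the constraints", {
  adj <- tbl2_adjusted()
  med <- tbl2_mp()
  expect_equal(signif(impermeant_valence(adj, med), 3), -2.53)
  expect_equal(water_per_impermeant(adj, med) * 1000, 18.61,
               tolerance = 0.001)

  # hand arithmetic: z = (50 - 150) / (300 - 200) = -1
  cell <- list(na = 50, k = 100, l = 0, cl = 50)
  med300 <- list(na0 = 100, k0 = 5, l0 = 0, cl0 = 105, B0 = 90)
  expect_equal(impermeant_valence(cell, med300), -1)
  # internal sum 250 against 300 mOsm: V/A = 1/50, A/V = 50
  expect_equal(water_per_impermeant(list(na = 60, k = 120, l = 0, cl = 70),
                                    med300), 0.02)

  # no charge deficit -> z exactly zero
  cell0 <- list(na = 50, k = 60, l = 5, cl = 115)
  expect_identical(impermeant_valence(cell0, med300), 0)

  # z * (A/V) reproduces the charge deficit
  z <- impermeant_valence(cell, med300)
  av <- 1 / water_per_impermeant(cell, med300)
  expect_equal(z * av, with(cell, cl - na - k - l))

  # internal osmolytes exceeding the medium is not a physical cell
  expect_error(impermeant_valence(list(na = 200, k = 150, l = 0, cl = 60),
                                  med300),
               class = "ionflux_bad_initial_data")
})

test_that("cotransport fluxes are bilinear in the concentration products", {
  d <- datap_u937()
  bal <- tbl3_balanced
  ct <- cotransport_fluxes(list(na = bal$na, k = bal$k, l = bal$l,
                                cl = bal$cl), d, d)
  expect_equal(ct$flux[ct$pathway == "NC"], 0.4248, tolerance = 0.0005)
  expect_equal(ct$flux[ct$pathway == "LN"], 0.0839, tolerance = 0.0005)

  # equilibrium: equal inside/outside products null every transporter
  p_all <- list(alpha = 0, beta = 0, gamma = 1.5, pna = 0, pk = 0, pl = 0,
                pcl = 0, inc = 1e-4, ikc = 1e-4, ilc = 1e-4, inkcc = 1e-9,
                ilkcc = 1e-9, kp = 1e-4)
  med <- list(na0 = 100, k0 = 10, l0 = 5, cl0 = 80, B0 = 50)
  cell_eq <- list(na = 100, k = 10, l = 5, cl = 80)
  ct_eq <- cotransport_fluxes(cell_eq, med, p_all)
  expect_identical(ct_eq$flux, rep(0, 6))
})

test_that("channel fluxes follow the constant-field form with the anion mirrored", {
  d <- datap_u937()
  bal <- tbl3_balanced
  cell <- list(na = bal$na, k = bal$k, l = bal$l, cl = bal$cl)
  u <- bal$U / 26.7
  ch <- channel_net_flux(cell, d, d, u = u)
  expect_equal(ch[["Na"]], 0.9975, tolerance = 0.001)
  expect_equal(ch[["K"]], -0.9989, tolerance = 0.001)
  expect_equal(ch[["Cl"]], -0.4712, tolerance = 0.001)

  # u -> 0 limit: p * (C_o - C_i) for every species, anion included
  med <- list(na0 = 140, k0 = 5, l0 = 2, cl0 = 120, B0 = 40)
  prm <- list(pna = 0.003, pk = 0.02, pl = 0.003, pcl = 0.004,
              alpha = 0, beta = 0, gamma = 1.5, inc = 0, ikc = 0, ilc = 0,
              inkcc = 0, ilkcc = 0, kp = 0)
  cl2 <- list(na = 30, k = 150, l = 1, cl = 60)
  lim <- c(Na = prm$pna * (med$na0 - cl2$na), K = prm$pk * (med$k0 - cl2$k),
           Li = prm$pl * (med$l0 - cl2$l), Cl = prm$pcl * (med$cl0 - cl2$cl))
  for (u_small in c(1e-8, -1e-8)) {
    expect_equal(channel_net_flux(cl2, med, prm, u = u_small), lim,
                 tolerance = 1e-6)
  }

  # exact null at the ion's Nernst potential
  u_nernst <- log(med$na0 / cl2$na)
  expect_equal(channel_net_flux(cl2, med, prm, u = u_nernst)[["Na"]], 0,
               tolerance = 1e-12)
  u_nernst_cl <- -log(med$cl0 / cl2$cl)
  expect_equal(channel_net_flux(cl2, med, prm, u = u_nernst_cl)[["Cl"]], 0,
               tolerance = 1e-12)
})

test_that("pump fluxes scale with the transported ion and the stoichiometry", {
  pf <- pump_fluxes(list(na = 38.6, k = 0, l = 0, cl = 0),
                    list(beta = 0.039, alpha = 0, gamma = 1.5))
  expect_equal(pf$flux[pf$ion == "Na"], -1.5054, tolerance = 1e-4)
  expect_equal(pf$flux[pf$ion == "K"], 1.0036, tolerance = 1e-4)

  pf37 <- pump_fluxes(list(na = 37, k = 0, l = 0, cl = 0),
                      list(beta = 0.039, alpha = 0, gamma = 1.5))
  expect_equal(pf37$flux[pf37$ion == "Na"], -1.443)
  expect_equal(pf37$flux[pf37$ion == "K"], 0.962)

  off <- pump_fluxes(list(na = 38.6, k = 0, l = 5, cl = 0),
                     list(beta = 0, alpha = 0, gamma = 1.5))
  expect_identical(off$flux, rep(0, 3))
})

test_that("membrane potential solves the charge-flux balance uniquely", {
  d <- datap_u937()
  mp0 <- solve_membrane_potential(tbl2_adjusted(), d, d)
  expect_equal(mp0$U, -49.4, tolerance = 0.05)
  expect_lt(abs(mp0$residual), 1e-10)

  bal <- tbl3_balanced
  mp_bal <- solve_membrane_potential(
    list(na = bal$na, k = bal$k, l = bal$l, cl = bal$cl), d, d)
  expect_equal(mp_bal$U, -47.5, tolerance = 0.05)

  # no gradients, no electrogenic pump: the resting potential is zero
  med <- list(na0 = 100, k0 = 10, l0 = 2, cl0 = 80, B0 = 30)
  prm <- list(pna = 0.003, pk = 0.02, pl = 0.003, pcl = 0.004,
              alpha = 0, beta = 0, gamma = 1.5, inc = 0, ikc = 0, ilc = 0,
              inkcc = 0, ilkcc = 0, kp = 0)
  mp_eq <- solve_membrane_potential(
    list(na = 100, k = 10, l = 2, cl = 80), med, prm)
  expect_equal(mp_eq$U, 0, tolerance = 1e-7)

  # an absurdly strong electrogenic pump pushes the root out of range
  prm_bad <- prm
  prm_bad$beta <- 50
  expect_error(
    solve_membrane_potential(list(na = 100, k = 10, l = 2, cl = 80),
                             med, prm_bad),
    class = "ionflux_range_limit")
})

test_that("membrane-potential root is unique over the physiological range", {
  d <- datap_u937()
  states <- list(
    tbl2_adjusted(),
    with(tbl3_balanced, list(na = na, k = k, l = l, cl = cl)),
    list(na = 80, k = 100, l = 10, cl = 90)
  )
  for (s in states) {
    f <- function(u) {
      flux <- content_derivatives(s, d, d, u = u)
      flux[["na"]] + flux[["k"]] + flux[["l"]] - flux[["cl"]]
    }
    us <- seq(-173 / 26.7, 5 / 26.7, length.out = 401)
    fs <- vapply(us, f, numeric(1))
    expect_equal(sum(fs[-1] * fs[-401] < 0), 1)
  }
})

test_that("electrochemical potential differences use the 26.7 mV slope", {
  d <- datap_u937()
  bal <- tbl3_balanced
  mu <- electrochemical_potentials(
    list(na = bal$na, k = bal$k, l = bal$l, cl = bal$cl), d, U = bal$U)
  expect_equal(mu$mun, -81.9, tolerance = 0.1)
  expect_equal(mu$mucl, 33.7, tolerance = 0.1)
  # calculator check of the anion branch
  expect_equal(26.7 * log(72.1 / 121) + 47.5, mu$mucl)

  mu0 <- electrochemical_potentials(
    list(na = 140, k = 5.8, l = 5, cl = 121), d, U = 0)
  expect_equal(mu0$mun, 0)
})

test_that("content derivatives close the charge balance at the solved potential", {
  d <- datap_u937()
  traj <- simulate_system(d, t_end = 2000, stop_when_balanced = FALSE)
  sys <- attr(traj, "system")

  # fully relaxed balanced state: all derivatives essentially zero
  f_bal <- content_derivatives(sys$s, d, d)
  expect_lt(max(abs(f_bal)), 1e-3)

  # pump-only system: dNa/dt = -beta * na exactly, dK/dt = beta * na / gamma
  prm <- list(pna = 0, pk = 0, pl = 0, pcl = 0, alpha = 0, beta = 0.05,
              gamma = 1.5, inc = 0, ikc = 0, ilc = 0, inkcc = 0, ilkcc = 0,
              kp = 0)
  cell <- list(na = 40, k = 120, l = 0, cl = 60)
  f_pump <- content_derivatives(cell, d, prm, u = -1)
  expect_equal(f_pump[["na"]], -0.05 * 40)
  expect_equal(f_pump[["k"]], 0.05 * 40 / 1.5)

  # onset of Li loading: K declines while Li and Cl load; Na stays near its
  # balance (small transient dip before the rise to 38.6)
  f0 <- content_derivatives(tbl2_adjusted(), d, d)
  expect_lt(f0[["k"]], 0)
  expect_gt(f0[["l"]], 0)
  expect_gt(f0[["cl"]], 0)
  expect_lt(abs(f0[["na"]]), 0.1)

  # charge-flux closure on assorted states
  for (s in list(tbl2_adjusted(), cell, sys$s)) {
    f <- content_derivatives(s, d, d)
    expect_lt(abs(f[["na"]] + f[["k"]] + f[["l"]] - f[["cl"]]),
              1e-9 * max(abs(f), 1e-6))
  }
})
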