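# Initialization, Euler stepping and the approach to the balanced state.

test_that("initialization applies the osmotic kv shift and derives z and V/A", {
  st <- initial_state(datap_u937())
  expect_equal(st$na, 37 * 1.032)
  expect_equal(st$k, 158 * 1.032)
  expect_equal(st$cl, 63 * 1.032)
  expect_equal(st$VA1000, 18.61, tolerance = 0.001)
  expect_equal(signif(attr(st, "z"), 3), -2.53)
  expect_equal(st$U, -49.4, tolerance = 0.05)

  # electroneutrality and osmotic balance hold exactly on the adjusted state
  sys <- attr(st, "system")
  expect_equal(st$na + st$k + st$l - st$cl + attr(st, "z") / sys$V,
               0, tolerance = 1e-9)
  expect_equal(st$na + st$k + st$l + st$cl + 1 / sys$V, sys$S_o)

  # kv = 1 leaves the state untouched
  d1 <- datap_u937()
  d1$kv <- 1
  st1 <- initial_state(d1)
  expect_equal(st1$na, 37)
  expect_equal(st1$k, 158)

  # hypertonic shrinkage beyond the medium osmolarity is rejected
  dbad <- datap_u937()
  dbad$kv <- 1.3
  expect_error(initial_state(dbad), "BAD INITIAL DATA",
               class = "ionflux_bad_initial_data")
})

test_that("euler steps agree with an independently coded scalar oracle", {
  d <- datap_u937()
  adj <- tbl2_adjusted()
  mp <- tbl2_mp()
  for (n in c(1, 2, 10)) {
    ref <- oracle_euler(adj$na, adj$k, adj$l, adj$cl, mp, dt = 0.1, n = n)
    traj <- simulate_system(d, dt = 0.1, hp = n, max_outputs = 1,
                            stop_when_balanced = FALSE)
    got <- traj[nrow(traj), ]
    expect_equal(got$na, ref$na, tolerance = 1e-12)
    expect_equal(got$k, ref$k, tolerance = 1e-12)
    expect_equal(got$l, ref$l, tolerance = 1e-12)
    expect_equal(got$cl, ref$cl, tolerance = 1e-12)
    expect_equal(got$VA1000, ref$V * 1000, tolerance = 1e-12)
  }
})

test_that("the reference run reaches the printed balanced state", {
  traj <- simulate_system(datap_u937(), t_end = 500,
                          stop_when_balanced = FALSE)
  last <- traj[nrow(traj), ]
  expect_equal(last$na, 38.6, tolerance = 0.005)
  expect_equal(last$k, 155.2, tolerance = 0.005)
  expect_equal(last$l, 4.375, tolerance = 0.005)
  expect_equal(last$cl, 72.1, tolerance = 0.005)
  expect_equal(last$U, -47.5, tolerance = 0.005)
  expect_equal(last$VA1000, 20.10, tolerance = 0.005)
  expect_true(is_balanced(traj))

  # early stopping on the derivative criterion lands at the same state
  traj2 <- simulate_system(datap_u937())
  expect_true(attr(traj2, "balanced"))
  expect_equal(traj2$na[nrow(traj2)], last$na, tolerance = 0.001)
})

test_that("charge content is conserved and osmotic balance is exact on every row", {
  traj <- simulate_system(datap_u937(), t_end = 500, hp = 10,
                          stop_when_balanced = FALSE)
  z <- attr(traj, "z")
  V <- traj$VA1000 / 1000
  S_o <- attr(traj, "system")$S_o
  charge <- (traj$na + traj$k + traj$l - traj$cl) * V + z
  expect_lt(max(abs(charge - charge[1])), 1e-6 * max(abs(traj$cl * V)))
  osmo <- traj$na + traj$k + traj$l + traj$cl + 1 / V
  expect_equal(osmo, rep(S_o, nrow(traj)), tolerance = 1e-12)
})

test_that("the balanced state is a fixed point and is step-size converged", {
  d <- datap_u937()
  traj <- simulate_system(d, t_end = 4000, stop_when_balanced = FALSE)
  # restart exactly from the fully relaxed balanced state: nothing should move
  d2 <- continue_datap(traj)
  traj2 <- simulate_system(d2, dt = 0.1, hp = 100, t_end = 100,
                           stop_when_balanced = FALSE)
  expect_lt(max(abs(traj2$na - traj2$na[1])), 1e-3)
  expect_lt(max(abs(traj2$k - traj2$k[1])), 1e-3)
  expect_lt(max(abs(traj2$l - traj2$l[1])), 1e-3)
  expect_lt(max(abs(traj2$cl - traj2$cl[1])), 1e-3)

  # halving dt moves the balanced concentrations by < 0.01 mM
  half <- simulate_system(d, dt = 0.05, t_end = 500,
                          stop_when_balanced = FALSE)
  full <- simulate_system(d, dt = 0.1, t_end = 500,
                          stop_when_balanced = FALSE)
  for (col in c("na", "k", "l", "cl")) {
    expect_lt(abs(half[[col]][nrow(half)] - full[[col]][nrow(full)]), 0.01)
  }
})

test_that("distinct initial states with the same z converge to one balanced state", {
  base <- datap_u937()
  # moving concentration between the cations preserves both the osmotic sum
  # and the charge deficit, hence z and A/V
  variants <- list(c(dna = 0, dk = 0), c(dna = 10, dk = -10),
                   c(dna = -10, dk = 10))
  finals <- lapply(variants, function(v) {
    d <- base
    d$na <- d$na + v[["dna"]]
    d$k <- d$k + v[["dk"]]
    traj <- simulate_system(d, t_end = 1500, stop_when_balanced = FALSE)
    traj[nrow(traj), c("na", "k", "l", "cl", "U")]
  })
  zs <- vapply(variants, function(v) {
    d <- base
    d$na <- d$na + v[["dna"]]
    d$k <- d$k + v[["dk"]]
    attr(initial_state(d), "z")
  }, numeric(1))
  expect_equal(zs, rep(zs[1], 3), tolerance = 1e-12)
  for (fin in finals[-1]) {
    for (col in c("na", "k", "l", "cl")) {
      expect_lt(abs(fin[[col]] - finals[[1]][[col]]), 0.1)
    }
    expect_lt(abs(fin$U - finals[[1]]$U), 0.1)
  }
})

test_that("pump block produces monotone Na gain, K loss and swelling", {
  traj <- simulate_system(datap_ouabain(), hp = 50, t_end = 300,
                          stop_when_balanced = FALSE)
  expect_true(all(diff(traj$na) > 0))
  expect_true(all(diff(traj$k) < 0))
  expect_true(all(diff(traj$VA1000) > 0))
  expect_false(attr(traj, "balanced"))
})

test_that("run diagnostics carry the paper's wording and the failure time", {
  # a nearly Na-free medium drains the cell below the 0.1 mM floor
  d <- datap(na0 = 0.01, k0 = 5.8, cl0 = 116, l0 = 0.01, B0 = 188.2,
             kv = 1, na = 2, k = 73, l = 96, cl = 76,
             beta = 0.039, gamma = 1.5, pna = 0.00349, pk = 0.0229,
             pl = 0.00349, pcl = 0.00426, inc = 3e-5)
  expect_error(simulate_system(d, t_end = 2000, stop_when_balanced = FALSE),
               "LOW SODIUM", class = "ionflux_low_sodium")

  dbad <- datap_u937()
  dbad$beta <- 50
  expect_error(simulate_system(dbad, t_end = 10),
               "RANGE LIMIT", class = "ionflux_range_limit")
})

test_that("balance detection matches the instantaneous derivative criterion", {
  d <- datap_u937()
  st0 <- initial_state(d)
  expect_false(is_balanced(st0, d, d, tol = 0.005))
  expect_true(is_balanced(st0, d, d, tol = Inf))
  traj <- simulate_system(d, t_end = 500, stop_when_balanced = FALSE)
  expect_true(is_balanced(traj, tol = 0.005))
})

test_that("a run can be chained into a new medium with the osmotic shift applied", {
  traj <- simulate_system(datap_u937(), t_end = 500,
                          stop_when_balanced = FALSE)
  sys <- attr(traj, "system")
  # same medium: kv is 1 and the state carries over unchanged
  d_same <- continue_datap(traj)
  expect_equal(d_same$kv, 1)
  expect_equal(d_same$na, sys$s$na)
  # Li-free medium: kv reflects the lower osmolarity
  d_new <- continue_datap(traj, l0 = 0, cl0 = 116, beta = 0)
  expect_equal(d_new$kv, 310 / 320)
  expect_equal(d_new$beta, 0)
  st <- initial_state(d_new)
  expect_equal(st$na, sys$s$na * 310 / 320)
})

test_that("all shipped transient fixtures initialize and integrate", {
  fixtures <- list(
    ouabain = datap_ouabain(),
    ouabain_residual = datap_ouabain(residual_beta = 0.001),
    li_medium_base = datap_na_free_li("base"),
    li_medium_pump = datap_na_free_li("li_pump"),
    li_medium_pump_lc = datap_na_free_li("li_pump_lc"),
    return_to_na = datap_return_to_na(),
    preloaded_no_na = datap_li_preloaded("no_na"),
    preloaded_na = datap_li_preloaded("na_no_kp"),
    preloaded_na_kp = datap_li_preloaded("na_kp")
  )
  for (nm in names(fixtures)) {
    st <- initial_state(fixtures[[nm]])
    expect_true(is.finite(st$U), label = paste(nm, "potential"))
    tr <- simulate_system(fixtures[[nm]], hp = 10, t_end = 20,
                          stop_when_balanced = FALSE)
    expect_equal(nrow(tr), 21, label = paste(nm, "rows"))
  }
  # the Li-series media share the 310-mOsm Li-free base
  for (X in c(1, 2, 5, 10)) {
    d <- datap_li_medium(X)
    expect_equal(d$na0 + d$k0 + d$l0 + d$cl0 + d$B0, 310 + 2 * X)
    expect_equal(d$kv, (310 + 2 * X) / 310)
  }
})
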