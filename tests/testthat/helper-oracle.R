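# Independent scalar oracle used to cross-check the integrator.
#
# Deliberately written from the flux formulas alone, sharing no code with
# the package: its own bisection root finder, its own step loop. Numbers are
# plain scalars throughout.

oracle_charge_flux <- function(u, na, k, l, cl, na0, k0, l0, cl0,
                               pna, pk, pl, pcl, beta, alpha, gamma) {
  r <- if (abs(u) < 1e-6) -1 / (1 + u / 2 + u^2 / 6) else u / (1 - exp(u))
  eu <- exp(u)
  r * (eu * (pna * na + pk * k + pl * l + pcl * cl0) -
         (pna * na0 + pk * k0 + pl * l0 + pcl * cl)) -
    (beta * na + alpha * l) * (1 - 1 / gamma)
}

oracle_solve_u <- function(na, k, l, cl, mp) {
  f <- function(u) oracle_charge_flux(u, na, k, l, cl, mp$na0, mp$k0,
                                      mp$l0, mp$cl0, mp$pna, mp$pk, mp$pl,
                                      mp$pcl, mp$beta, mp$alpha, mp$gamma)
  lo <- -173 / 26.7
  hi <- 5 / 26.7
  us <- seq(lo, hi, length.out = 1001)
  fs <- vapply(us, f, numeric(1))
  i <- which(fs[-1] * fs[-1001] <= 0)[1]
  a <- us[i]; b <- us[i + 1]
  for (iter in 1:200) {
    mid <- (a + b) / 2
    if (f(a) * f(mid) <= 0) b <- mid else a <- mid
  }
  (a + b) / 2
}

# n explicit Euler steps; state and medium/params in one flat list
oracle_euler <- function(na, k, l, cl, mp, dt, n) {
  S_o <- mp$na0 + mp$k0 + mp$l0 + mp$cl0 + mp$B0
  V <- 1 / (S_o - (na + k + l + cl))
  cna <- na * V; ck <- k * V; cl_ <- l * V; ccl <- cl * V
  for (i in seq_len(n)) {
    u <- oracle_solve_u(na, k, l, cl, mp)
    r <- if (abs(u) < 1e-6) -1 / (1 + u / 2 + u^2 / 6) else u / (1 - exp(u))
    eu <- exp(u)
    jnc <- mp$inc * (mp$na0 * mp$cl0 - na * cl)
    jkc <- mp$ikc * (mp$k0 * mp$cl0 - k * cl)
    jlc <- mp$ilc * (mp$l0 * mp$cl0 - l * cl)
    jnkcc <- mp$inkcc * (mp$na0 * mp$k0 * mp$cl0^2 - na * k * cl^2)
    jlkcc <- mp$ilkcc * (mp$l0 * mp$k0 * mp$cl0^2 - l * k * cl^2)
    jln <- mp$kp * (mp$na0 * l - na * mp$l0)
    fna <- mp$pna * r * (na * eu - mp$na0) - mp$beta * na + jnc + jnkcc + jln
    fk <- mp$pk * r * (k * eu - mp$k0) +
      (mp$beta * na + mp$alpha * l) / mp$gamma + jkc + jnkcc + jlkcc
    fcl <- mp$pcl * r * (cl - mp$cl0 * eu) + jnc + jkc + 2 * jnkcc + jlc +
      2 * jlkcc
    fl <- mp$pl * r * (l * eu - mp$l0) - mp$alpha * l + jlc + jlkcc - jln
    cna <- cna + dt * V * fna
    ck <- ck + dt * V * fk
    cl_ <- cl_ + dt * V * fl
    ccl <- ccl + dt * V * fcl
    V <- (cna + ck + cl_ + ccl + 1) / S_o
    na <- cna / V; k <- ck / V; l <- cl_ / V; cl <- ccl / V
  }
  list(na = na, k = k, l = l, cl = cl, V = V)
}

# reference U937 set as flat lists: kv-adjusted internal state + medium/params
tbl2_mp <- function() {
  d <- ionflux::datap_u937()
  as.list(d[c("na0", "k0", "l0", "cl0", "B0", "alpha", "beta", "gamma",
              "pna", "pk", "pl", "pcl", "inc", "ikc", "ilc", "inkcc",
              "ilkcc", "kp")])
}

tbl2_adjusted <- function() {
  d <- ionflux::datap_u937()
  list(na = d$na * d$kv, k = d$k * d$kv, l = d$l * d$kv, cl = d$cl * d$kv)
}

# the balanced state printed for the reference run (concentrations mM, U mV)
tbl3_balanced <- list(na = 38.6, k = 155.2, l = 4.375, cl = 72.1, U = -47.5)
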