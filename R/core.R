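# Core flux laws of the pump-leak model.
#
# Sign convention: every flux is positive inward, in umol/min per ml cell
# water (numerically mM/min). Channel fluxes use the Goldman constant-field
# form with dimensionless potential u (U = 26.7 u mV at 37 C) and
# g = 1 - exp(u); the factor u/g is continued analytically through u = 0,
# where it tends to -1.

RTF_MV <- 26.7            # RT/F at 37 C, mV
U_RANGE_MV <- c(-173, 5)  # physiological search range for the potential

# u/(1 - exp(u)) with a series branch near 0: u/(1-e^u) = -1/(1 + u/2 + ...)
u_over_g <- function(u) {
  if (length(u) == 1L) {
    if (abs(u) < 1e-6) {
      -1 / (1 + u / 2 + u^2 / 6 + u^3 / 24)
    } else {
      u / (1 - exp(u))
    }
  } else {
    ifelse(abs(u) < 1e-6,
           -1 / (1 + u / 2 + u^2 / 6 + u^3 / 24),
           u / (1 - exp(u)))
  }
}

so_total <- function(m) m$na0 + m$k0 + m$l0 + m$cl0 + m$B0

as_cell_list <- function(cell) {
  cell <- as.list(cell)[CELL_FIELDS]
  if (anyNA(names(cell)) || any(!lengths(cell))) {
    rlang::abort("cell must provide na, k, l and cl (mM)")
  }
  lapply(cell, function(v) unname(as.numeric(v)))
}

as_medium_list <- function(medium) {
  medium <- as.list(medium)[MEDIUM_FIELDS]
  if (anyNA(names(medium)) || any(!lengths(medium))) {
    rlang::abort("medium must provide na0, k0, l0, cl0 and B0 (mM)")
  }
  lapply(medium, function(v) unname(as.numeric(v)))
}

as_params_list <- function(params) {
  params <- as.list(params)
  for (f in RATE_FIELDS) if (is.null(params[[f]])) {
    params[[f]] <- if (f == "gamma") 1.5 else 0
  }
  lapply(params[RATE_FIELDS], function(v) unname(as.numeric(v)))
}

#' Mean valence of the impermeant intracellular osmolytes
#'
#' From electroneutrality and osmotic balance, the mean valence of the
#' membrane-impermeant intracellular osmolytes A is fixed by the measured
#' concentrations:
#' `z = (cl - na - k - l) / (S_o - na - k - l - cl)`,
#' where `S_o` is the total external osmolarity. The companion quantity
#' `water_per_impermeant()` is the cell water per unit A,
#' `V/A = 1 / (S_o - na - k - l - cl)` (ml/mmol with A in mmol).
#'
#' @param cell Data frame, one-row tibble or list with intracellular `na`,
#'   `k`, `l`, `cl` (mM). A [datap()] set can be passed directly (its
#'   unadjusted internal concentrations are used).
#' @param medium List or data frame with `na0`, `k0`, `l0`, `cl0`, `B0` (mM);
#'   defaults to the columns of `cell` when present.
#' @return A single numeric value.
#' @export
#' @examples
#' impermeant_valence(list(na = 50, k = 100, l = 0, cl = 50),
#'                    list(na0 = 140, k0 = 5, l0 = 0, cl0 = 105, B0 = 50))
impermeant_valence <- function(cell, medium = cell) {
  s <- as_cell_list(cell)
  m <- as_medium_list(medium)
  den <- so_total(m) - (s$na + s$k + s$l + s$cl)
  if (den <= 0) {
    rlang::abort("BAD INITIAL DATA", class = "ionflux_bad_initial_data")
  }
  (s$cl - s$na - s$k - s$l) / den
}

#' @rdname impermeant_valence
#' @export
water_per_impermeant <- function(cell, medium = cell) {
  s <- as_cell_list(cell)
  m <- as_medium_list(medium)
  den <- so_total(m) - (s$na + s$k + s$l + s$cl)
  if (den <= 0) {
    rlang::abort("BAD INITIAL DATA", class = "ionflux_bad_initial_data")
  }
  1 / den
}

# all net pathway fluxes at dimensionless potential u (scalar core)
net_fluxes_core <- function(s, m, p, u) {
  r <- u_over_g(u)
  eu <- exp(u)
  list(
    chan_na = p$pna * r * (s$na * eu - m$na0),
    chan_k  = p$pk  * r * (s$k  * eu - m$k0),
    chan_l  = p$pl  * r * (s$l  * eu - m$l0),
    chan_cl = p$pcl * r * (s$cl - m$cl0 * eu),
    pump_na = -p$beta * s$na,
    pump_l  = -p$alpha * s$l,
    pump_k  = (p$beta * s$na + p$alpha * s$l) / p$gamma,
    NC   = p$inc   * (m$na0 * m$cl0 - s$na * s$cl),
    KC   = p$ikc   * (m$k0  * m$cl0 - s$k  * s$cl),
    LC   = p$ilc   * (m$l0  * m$cl0 - s$l  * s$cl),
    NKCC = p$inkcc * (m$na0 * m$k0 * m$cl0^2 - s$na * s$k * s$cl^2),
    LKCC = p$ilkcc * (m$l0  * m$k0 * m$cl0^2 - s$l  * s$k * s$cl^2),
    LN   = p$kp    * (m$na0 * s$l - s$na * m$l0)
  )
}

# per-ion content derivatives d([X]V)/dt / V, mM/min
derivs_core <- function(f) {
  c(na = f$chan_na + f$pump_na + f$NC + f$NKCC + f$LN,
    k  = f$chan_k  + f$pump_k  + f$KC + f$NKCC + f$LKCC,
    cl = f$chan_cl + f$NC + f$KC + 2 * f$NKCC + f$LC + 2 * f$LKCC,
    l  = f$chan_l  + f$pump_l  + f$LC + f$LKCC - f$LN)
}

# total signed charge flux (Na + K + Li - Cl); its root in u is the membrane
# potential. Cotransporter terms cancel identically, leaving channel and pump
# terms only -- the finite equivalent of the transcendental potential equation.
charge_flux_core <- function(u, s, m, p) {
  eu <- exp(u)
  u_over_g(u) *
    (eu * (p$pna * s$na + p$pk * s$k + p$pl * s$l + p$pcl * m$cl0) -
       (p$pna * m$na0 + p$pk * m$k0 + p$pl * m$l0 + p$pcl * s$cl)) -
    (p$beta * s$na + p$alpha * s$l) * (1 - 1 / p$gamma)
}

# Bracket scan over the physiological range followed by Brent refinement.
# `warm` (previous root) short-circuits the scan during integration.
solve_u_core <- function(s, m, p, warm = NULL, n_scan = 200) {
  bounds <- U_RANGE_MV / RTF_MV
  f <- function(u) charge_flux_core(u, s, m, p)
  if (!is.null(warm) && warm > bounds[1] && warm < bounds[2]) {
    # during integration the root moves very little per step: a secant
    # iteration from the previous root almost always converges in 2-3 steps
    u0 <- warm
    u1 <- warm + 1e-5
    f0 <- f(u0)
    f1 <- f(u1)
    for (iter in 1:12) {
      if (f1 == f0) break
      u2 <- u1 - f1 * (u1 - u0) / (f1 - f0)
      if (!is.finite(u2) || abs(u2 - warm) > 0.5 ||
          u2 < bounds[1] || u2 > bounds[2]) break
      if (abs(u2 - u1) < 1e-13) return(u2)
      u0 <- u1; f0 <- f1
      u1 <- u2; f1 <- f(u2)
    }
    d <- 0.02
    while (d < 8) {
      lo <- max(warm - d, bounds[1])
      hi <- min(warm + d, bounds[2])
      flo <- f(lo)
      fhi <- f(hi)
      if (flo == 0) return(lo)
      if (fhi == 0) return(hi)
      if (flo * fhi < 0) {
        return(stats::uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi,
                              tol = 1e-13)$root)
      }
      d <- d * 4
    }
  }
  us <- seq(bounds[1], bounds[2], length.out = n_scan + 1)
  gs <- vapply(us, f, numeric(1))
  hit <- which(gs == 0)
  if (length(hit)) return(us[hit[1]])
  cross <- which(gs[-1] * gs[-length(gs)] < 0)
  if (!length(cross)) {
    rlang::abort("RANGE LIMIT", class = "ionflux_range_limit")
  }
  i <- cross[1]
  stats::uniroot(f, c(us[i], us[i + 1]), f.lower = gs[i], f.upper = gs[i + 1],
                 tol = 1e-13)$root
}

#' Solve the membrane potential from the charge-flux balance
#'
#' Finds the dimensionless membrane potential `u` at which the total signed
#' charge flux across the membrane (channel fluxes of Na+, K+, Li+ minus Cl-,
#' plus the electrogenic pump term) vanishes. This is the finite, everywhere
#' well-defined equivalent of the transcendental potential equation: the
#' electroneutral cotransporters cancel from the sum, so only channel and
#' pump terms remain. The root is searched in U between -173 and +5 mV by a
#' sign scan followed by Brent refinement; if no sign change exists in that
#' range a "RANGE LIMIT" error (class `ionflux_range_limit`) is raised.
#'
#' @inheritParams impermeant_valence
#' @param params Rate coefficients (see [datap()]); a `datap` set can be
#'   passed for all three arguments at once.
#' @param warm Optional previous root (dimensionless) used to shortcut the
#'   scan.
#' @param n_scan Number of scan intervals across the search range.
#' @return A list with `u` (dimensionless), `U` (mV) and `residual`, the
#'   charge flux remaining at the root.
#' @export
#' @examples
#' d <- datap_u937()
#' solve_membrane_potential(initial_state(d), d, d)$U
solve_membrane_potential <- function(cell, medium = cell, params = cell,
                                     warm = NULL, n_scan = 200) {
  s <- as_cell_list(cell)
  m <- as_medium_list(medium)
  p <- as_params_list(params)
  u <- solve_u_core(s, m, p, warm = warm, n_scan = n_scan)
  list(u = u, U = u * RTF_MV, residual = charge_flux_core(u, s, m, p))
}

#' Net ion flux through electroconductive channels
#'
#' Goldman-type constant-field flux, positive inward. Cations follow
#' `p * u * (C_i * exp(u) - C_o) / g`; the anion Cl- follows
#' `p * u * (Cl_i - Cl_o * exp(u)) / g`, with `g = 1 - exp(u)`. As `u -> 0`
#' both reduce to `p * (C_o - C_i)`.
#'
#' @inheritParams solve_membrane_potential
#' @param ion Ion species, any of `"Na"`, `"K"`, `"Li"`, `"Cl"`.
#' @param u Dimensionless membrane potential.
#' @return Named numeric vector of net fluxes (umol/min per ml cell water).
#' @export
channel_net_flux <- function(cell, medium = cell, params = cell, u,
                             ion = c("Na", "K", "Li", "Cl")) {
  ion <- match.arg(ion, several.ok = TRUE)
  s <- as_cell_list(cell)
  m <- as_medium_list(medium)
  p <- as_params_list(params)
  f <- net_fluxes_core(s, m, p, u)
  out <- c(Na = f$chan_na, K = f$chan_k, Li = f$chan_l, Cl = f$chan_cl)
  out[ion]
}

#' Pump fluxes
#'
#' The Na/K pump expels Na+ at rate `beta * na` and the Li/K pump expels Li+
#' at `alpha * l`; both import K+ with stoichiometry `gamma`, so the K+
#' influx is `(beta * na + alpha * l) / gamma`.
#'
#' @inheritParams solve_membrane_potential
#' @return A tibble with columns `ion` (Na, Li, K) and `flux`
#'   (positive inward).
#' @export
#' @examples
#' pump_fluxes(list(na = 38.6, k = 155, l = 4.4, cl = 72), datap_u937())
pump_fluxes <- function(cell, params = cell) {
  s <- as_cell_list(cell)
  p <- as_params_list(params)
  tibble::tibble(
    ion = c("Na", "Li", "K"),
    flux = c(-p$beta * s$na, -p$alpha * s$l,
             (p$beta * s$na + p$alpha * s$l) / p$gamma)
  )
}

#' Net cotransport and countertransport fluxes
#'
#' Bilinear mass-action fluxes, positive inward, zero when the inside and
#' outside concentration products are equal:
#' `J_NC = inc * (na0 * cl0 - na * cl)` and analogously for KC and LC;
#' `J_NKCC = inkcc * (na0 * k0 * cl0^2 - na * k * cl^2)` and analogously for
#' LKCC; the Li/Na countertransport is `J_LN = kp * (na0 * l - na * l0)`,
#' positive when Na+ moves in and Li+ moves out.
#'
#' @inheritParams solve_membrane_potential
#' @return A tibble with columns `pathway` and `flux`.
#' @export
#' @examples
#' d <- datap_u937()
#' cotransport_fluxes(list(na = 38.6, k = 155.2, l = 4.375, cl = 72.1), d, d)
cotransport_fluxes <- function(cell, medium = cell, params = cell) {
  s <- as_cell_list(cell)
  m <- as_medium_list(medium)
  p <- as_params_list(params)
  f <- net_fluxes_core(s, m, p, 0)
  tibble::tibble(
    pathway = c("NC", "KC", "LC", "NKCC", "LKCC", "LN"),
    flux = c(f$NC, f$KC, f$LC, f$NKCC, f$LKCC, f$LN)
  )
}

#' Transmembrane electrochemical potential differences
#'
#' Per-ion driving forces in mV: `mun = 26.7 * log(na / na0) + U` (likewise
#' `muk`, `mul`) and `mucl = 26.7 * log(cl / cl0) - U` for the anion. They
#' vanish at passive equilibrium of the respective ion.
#'
#' @inheritParams solve_membrane_potential
#' @param U Membrane potential in mV.
#' @return A one-row tibble with `mun`, `muk`, `mul`, `mucl` (mV). Zero
#'   concentrations yield `-Inf`/`NaN` as the logarithm dictates.
#' @export
electrochemical_potentials <- function(cell, medium = cell, U) {
  s <- as_cell_list(cell)
  m <- as_medium_list(medium)
  tibble::tibble(
    mun = RTF_MV * log(s$na / m$na0) + U,
    muk = RTF_MV * log(s$k / m$k0) + U,
    mul = RTF_MV * log(s$l / m$l0) + U,
    mucl = RTF_MV * log(s$cl / m$cl0) - U
  )
}

#' Rates of change of the intracellular ion contents
#'
#' Evaluates the right-hand sides of the flux-balance equations: for each ion
#' the sum of its channel, pump and (co/counter)transport fluxes, i.e.
#' `d([X] V)/dt / V` in mM/min. At the potential returned by
#' [solve_membrane_potential()] the signed sum (Na + K + Li - Cl) vanishes,
#' which is what keeps the cell electroneutral during integration.
#'
#' @inheritParams solve_membrane_potential
#' @param u Dimensionless membrane potential; solved internally when `NULL`.
#' @return Named numeric vector with components `na`, `k`, `cl`, `l`
#'   (mM/min).
#' @export
#' @examples
#' d <- datap_u937()
#' content_derivatives(initial_state(d), d, d)
content_derivatives <- function(cell, medium = cell, params = cell,
                                u = NULL) {
  s <- as_cell_list(cell)
  m <- as_medium_list(medium)
  p <- as_params_list(params)
  if (is.null(u)) u <- solve_u_core(s, m, p)
  derivs_core(net_fluxes_core(s, m, p, u))
}
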