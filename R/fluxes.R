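# Unidirectional decomposition of every transport pathway.
#
# Channel fluxes split into their two additive constant-field terms: for a
# cation, influx = -p*u*C_o/g and efflux = p*u*exp(u)*C_i/g; for Cl- the
# terms mirror (influx = -p*u*exp(u)*Cl_o/g, efflux = p*u*Cl_i/g). Co- and
# countertransporters split into their outward-product and inward-product
# terms. Pump rows carry only efflux (Na, Li) or influx (K).

PATHWAYS <- c("PUMPN", "PUMPL", "Channel", "NC", "LC", "LN",
              "KC", "NKCC", "LKCC")
IONS <- c("Na", "K", "Li", "Cl")

unidir_core <- function(s, m, p, u) {
  r <- u_over_g(u)
  eu <- exp(u)
  cell <- function(influx, efflux) c(influx = influx, efflux = efflux)
  # one list entry per ion x pathway with nonzero traffic
  cells <- list(
    Na = list(
      PUMPN   = cell(0, -p$beta * s$na),
      Channel = cell(-p$pna * r * m$na0, p$pna * r * eu * s$na),
      NC      = cell(p$inc * m$na0 * m$cl0, -p$inc * s$na * s$cl),
      LN      = cell(p$kp * m$na0 * s$l, -p$kp * s$na * m$l0),
      NKCC    = cell(p$inkcc * m$na0 * m$k0 * m$cl0^2,
                     -p$inkcc * s$na * s$k * s$cl^2)
    ),
    K = list(
      PUMPN   = cell(p$beta * s$na / p$gamma, 0),
      PUMPL   = cell(p$alpha * s$l / p$gamma, 0),
      Channel = cell(-p$pk * r * m$k0, p$pk * r * eu * s$k),
      KC      = cell(p$ikc * m$k0 * m$cl0, -p$ikc * s$k * s$cl),
      NKCC    = cell(p$inkcc * m$na0 * m$k0 * m$cl0^2,
                     -p$inkcc * s$na * s$k * s$cl^2),
      LKCC    = cell(p$ilkcc * m$l0 * m$k0 * m$cl0^2,
                     -p$ilkcc * s$l * s$k * s$cl^2)
    ),
    Li = list(
      PUMPL   = cell(0, -p$alpha * s$l),
      Channel = cell(-p$pl * r * m$l0, p$pl * r * eu * s$l),
      LC      = cell(p$ilc * m$l0 * m$cl0, -p$ilc * s$l * s$cl),
      LN      = cell(p$kp * s$na * m$l0, -p$kp * m$na0 * s$l),
      LKCC    = cell(p$ilkcc * m$l0 * m$k0 * m$cl0^2,
                     -p$ilkcc * s$l * s$k * s$cl^2)
    ),
    Cl = list(
      Channel = cell(-p$pcl * r * eu * m$cl0, p$pcl * r * s$cl),
      NC      = cell(p$inc * m$na0 * m$cl0, -p$inc * s$na * s$cl),
      KC      = cell(p$ikc * m$k0 * m$cl0, -p$ikc * s$k * s$cl),
      LC      = cell(p$ilc * m$l0 * m$cl0, -p$ilc * s$l * s$cl),
      NKCC    = cell(2 * p$inkcc * m$na0 * m$k0 * m$cl0^2,
                     -2 * p$inkcc * s$na * s$k * s$cl^2),
      LKCC    = cell(2 * p$ilkcc * m$l0 * m$k0 * m$cl0^2,
                     -2 * p$ilkcc * s$l * s$k * s$cl^2)
    )
  )
  grid <- expand.grid(pathway = PATHWAYS, ion = IONS,
                      stringsAsFactors = FALSE)
  influx <- efflux <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    entry <- cells[[grid$ion[i]]][[grid$pathway[i]]]
    if (!is.null(entry)) {
      influx[i] <- entry[["influx"]]
      efflux[i] <- entry[["efflux"]]
    }
  }
  influx <- influx + 0  # normalize IEEE negative zeros from zeroed pathways
  efflux <- efflux + 0
  tibble::tibble(
    ion = factor(grid$ion, levels = IONS),
    pathway = factor(grid$pathway, levels = PATHWAYS),
    net = influx + efflux,
    influx = influx,
    efflux = efflux
  )
}

#' Net and unidirectional fluxes for every ion and pathway
#'
#' Decomposes each transport pathway into its unidirectional influx and
#' efflux components at a given cell state (by default, the final state of a
#' trajectory). Within every ion-pathway cell, `influx + efflux = net`
#' exactly; influx is non-negative and efflux non-positive. Pump rows carry
#' only Na+/Li+ efflux and K+ influx.
#'
#' @param x An `ion_trajectory`, a [datap()] parameter set (taken at its
#'   kv-adjusted initial state), or a cell state (then supply `medium` and
#'   `params`).
#' @param medium,params As in [solve_membrane_potential()].
#' @param u Dimensionless membrane potential; solved internally when `NULL`.
#' @return A tibble of class `flux_table` with columns `ion`, `pathway`,
#'   `net`, `influx`, `efflux` (umol/min per ml cell water), 36 rows.
#' @seealso [osor()], [turnover_flux()], [self_exchange_flux()]
#' @export
#' @examples
#' traj <- simulate_system(datap_u937(), t_end = 500)
#' flux_table(traj)
flux_table <- function(x, medium = x, params = x, u = NULL) {
  if (inherits(x, "ion_trajectory")) {
    sys <- traj_system(x)
    s <- sys$s; m <- sys$m; p <- sys$p
    if (is.null(u)) u <- sys$u
  } else if (inherits(x, "datap")) {
    sys <- init_core(x)
    s <- sys$s; m <- sys$m; p <- sys$p
  } else {
    s <- as_cell_list(x)
    m <- as_medium_list(medium)
    p <- as_params_list(params)
  }
  if (is.null(u)) u <- solve_u_core(s, m, p)
  out <- unidir_core(s, m, p, u)
  attr(out, "u") <- u
  attr(out, "state") <- s
  attr(out, "medium") <- m
  class(out) <- c("flux_table", class(out))
  out
}

#' Ratio of ouabain-sensitive to ouabain-resistant K+ influx (OSOR)
#'
#' The pump-mediated (ouabain-sensitive) K+ influx divided by the summed K+
#' influxes of all other (ouabain-resistant) pathways.
#'
#' @param x A [flux_table()].
#' @return A single numeric value.
#' @export
osor <- function(x) {
  stopifnot(inherits(x, "flux_table"))
  k <- x[x$ion == "K", ]
  pump_in <- sum(k$influx[k$pathway %in% c("PUMPN", "PUMPL")])
  leak_in <- sum(k$influx[!k$pathway %in% c("PUMPN", "PUMPL")])
  if (leak_in == 0) {
    rlang::abort("no ouabain-resistant K influx: OSOR undefined")
  }
  pump_in / leak_in
}

#' One-for-one coupled self-exchange flux
#'
#' Mass-action product formula `J = kp * C_o * C_i` for a coupled
#' self-exchange such as Na/Na or Cl/Cl. The exchange moves equal amounts in
#' and out, so it adds to the unidirectional turnover of the ion but to no
#' net flux.
#'
#' @param kp Exchange rate coefficient (ml/umol/min).
#' @param conc_out,conc_in External and internal concentrations (mM).
#' @return Flux in umol/min per ml cell water. Vectorized.
#' @export
#' @examples
#' self_exchange_flux(0.0008, 140, 37) # Na/Na exchange in the normal state
self_exchange_flux <- function(kp, conc_out, conc_in) {
  stopifnot(all(kp >= 0), all(conc_out >= 0), all(conc_in >= 0))
  kp * conc_out * conc_in
}

#' Per-ion turnover flux
#'
#' Sums the unidirectional influxes (and effluxes) of each ion over all
#' pathways and adds any coupled self-exchange. The turnover flux is the
#' total traffic of the ion across the membrane; it sets the equilibration
#' rate of an isotope tracer. At a balanced state the influx-side and
#' efflux-side turnovers coincide.
#'
#' @param x A [flux_table()].
#' @param self_exchange Named numeric vector of self-exchange fluxes per ion
#'   (e.g. `c(Na = 4.14)`), as from [self_exchange_flux()].
#' @return A tibble with one row per ion: total influx, total (absolute)
#'   efflux, self-exchange, and the influx- and efflux-side turnover.
#' @export
#' @examples
#' traj <- simulate_system(datap_u937(), t_end = 500)
#' turnover_flux(flux_table(traj), self_exchange = c(Na = 4.14))
turnover_flux <- function(x, self_exchange = NULL) {
  stopifnot(inherits(x, "flux_table"))
  out <- dplyr::summarise(
    dplyr::group_by(x, .data$ion),
    influx_total = sum(.data$influx),
    efflux_total = sum(abs(.data$efflux)),
    .groups = "drop"
  )
  se <- stats::setNames(numeric(length(IONS)), IONS)
  if (!is.null(self_exchange)) {
    stopifnot(!is.null(names(self_exchange)),
              all(names(self_exchange) %in% IONS))
    se[names(self_exchange)] <- self_exchange
  }
  out$self_exchange <- unname(se[as.character(out$ion)])
  out$turnover_in <- out$influx_total + out$self_exchange
  out$turnover_out <- out$efflux_total + out$self_exchange
  out
}

#' Tracer equilibration rate coefficient implied by a turnover flux
#'
#' `k = turnover / conc_in` (1/min): the fraction of the intracellular pool
#' exchanged per minute.
#'
#' @param turnover Turnover flux (umol/min per ml cell water).
#' @param conc_in Intracellular concentration (mM); must be positive.
#' @return Rate coefficient in 1/min. Vectorized.
#' @export
#' @examples
#' equilibration_rate(0.1849, 4.4) # ~0.042/min for Li
equilibration_rate <- function(turnover, conc_in) {
  stopifnot(all(turnover >= 0))
  if (any(conc_in <= 0)) {
    rlang::abort("conc_in must be positive")
  }
  turnover / conc_in
}

#' Li/Na discrimination coefficient
#'
#' `c_d = (Li_i / Na_i) * (Na_o / Li_o)`: how much better the cell excludes
#' Na+ than Li+. As a ratio of concentration ratios it is independent of the
#' cell water content. A trajectory or balanced-state row may be passed
#' directly.
#'
#' @param l_i,na_i Intracellular Li+ and Na+ (mM), or an `ion_trajectory` as
#'   the first argument.
#' @param l_o,na_o External Li+ and Na+ (mM).
#' @return Dimensionless coefficient. Vectorized over numeric inputs.
#' @export
#' @examples
#' discrimination_coefficient(0.883, 37.3, 1, 140)
discrimination_coefficient <- function(l_i, na_i = NULL, l_o = NULL,
                                       na_o = NULL) {
  if (inherits(l_i, "ion_trajectory")) {
    sys <- traj_system(l_i)
    return(discrimination_coefficient(sys$s$l, sys$s$na,
                                      sys$m$l0, sys$m$na0))
  }
  if (any(c(l_i, na_i, l_o, na_o) <= 0)) {
    rlang::abort("all concentrations must be positive")
  }
  (l_i / na_i) * (na_o / l_o)
}

#' @export
print.flux_table <- function(x, ...) {
  cat(sprintf("# flux table at U = %.1f mV (umol/min per ml cell water)\n",
              attr(x, "u") * RTF_MV))
  NextMethod()
}
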