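# Explicit Euler integration of the flux-balance equations with per-step
# algebraic recomputation of cell volume (osmotic balance) and membrane
# potential (charge-flux balance). Ion *contents* (concentration x volume,
# per A = 1 mmol of impermeant osmolyte) are the integrated variables, so
# total intracellular charge is conserved by construction and volume follows
# from the osmotic constraint without any renormalization.

init_core <- function(x) {
  x <- as_datap(x)
  m <- as_medium_list(x)
  p <- as_params_list(x)
  kv <- x$kv
  # instantaneous osmotic water shift: the cell arrives balanced with the old
  # medium (osmolarity S_o / kv); water leaves/enters instantly, scaling all
  # internal concentrations by kv
  s <- list(na = x$na * kv, k = x$k * kv, l = x$l * kv, cl = x$cl * kv)
  S_o <- so_total(m)
  den <- S_o - (s$na + s$k + s$l + s$cl)
  if (!is.finite(den) || den <= 0) {
    rlang::abort("BAD INITIAL DATA", class = "ionflux_bad_initial_data")
  }
  V <- 1 / den                       # A normalized to 1 mmol
  z <- (s$cl - s$na - s$k - s$l) * V # = charge deficit / (A/V)
  list(s = s, m = m, p = p, S_o = S_o, V = V, z = z, A = 1, hp = x$hp)
}

state_row <- function(t, s, m, V, u, pr = c(na = 0, k = 0, l = 0, cl = 0)) {
  mu <- electrochemical_potentials(s, m, U = u * RTF_MV)
  tibble::tibble(
    t = t, U = u * RTF_MV,
    na = s$na, k = s$k, l = s$l, cl = s$cl,
    VA1000 = V * 1000,
    mun = mu$mun, muk = mu$muk, mul = mu$mul, mucl = mu$mucl,
    prna = pr[["na"]], prk = pr[["k"]], prl = pr[["l"]], prcl = pr[["cl"]]
  )
}

#' Initialize a run: osmotic adjustment and derived cell constants
#'
#' Applies the `kv` osmotic water shift to the intracellular concentrations,
#' computes the impermeant-osmolyte valence `z` and the cell water per unit A
#' from the adjusted state, and solves the initial membrane potential. The
#' returned row is the t = 0 state of the simulated transient. Initial data
#' incompatible with electroneutrality and osmotic balance (non-positive
#' osmotic gap) raise a "BAD INITIAL DATA" error of class
#' `ionflux_bad_initial_data`.
#'
#' @param x A [datap()] parameter set.
#' @return A one-row tibble with `t`, `U` (mV), concentrations (mM),
#'   `VA1000` (cell water per mmol A, x1000), the electrochemical potential
#'   differences and zeroed derivative columns, plus attributes `z` and
#'   `system`.
#' @export
#' @examples
#' initial_state(datap_u937())
initial_state <- function(x) {
  sys <- init_core(x)
  u <- solve_u_core(sys$s, sys$m, sys$p)
  out <- state_row(0, sys$s, sys$m, sys$V, u)
  attr(out, "z") <- sys$z
  attr(out, "system") <- sys
  out
}

#' Integrate the pump-leak system toward the balanced state
#'
#' Advances the flux-balance equations by the explicit Euler method. Each
#' step solves the membrane potential, updates the four ion contents, then
#' recomputes cell water from the osmotic constraint
#' `V = (total ion content + A) / S_o` and the concentrations from the
#' contents. A row is emitted every `hp` steps. The run stops when the
#' balanced state is detected (all per-step concentration derivatives below
#' `balance_tol`), when `max_outputs` rows have been emitted, or at `t_end`
#' if given.
#'
#' The derivative columns `prna`, `prk`, `prl`, `prcl` are per-step finite
#' differences of the concentrations at the emitted time point;
#' [content_derivatives()] gives the instantaneous content derivatives
#' instead.
#'
#' If the internal Na+ concentration falls below 0.1 mM the run stops with a
#' "LOW SODIUM" error (class `ionflux_low_sodium`); a potential root leaving
#' the search range raises "RANGE LIMIT" (class `ionflux_range_limit`). Both
#' report the simulation time of the failure.
#'
#' @param x A [datap()] parameter set.
#' @param dt Euler step (min).
#' @param hp Steps between output rows; defaults to the `hp` field of `x`.
#' @param t_end Total simulated time (min); when given it overrides
#'   `max_outputs` and disables early stopping unless `stop_when_balanced`.
#' @param max_outputs Maximum number of output rows after t = 0.
#' @param balance_tol Balanced-state threshold on |d conc/dt| (mM/min).
#' @param stop_when_balanced Stop at the first output row where all
#'   concentration derivatives are below `balance_tol`.
#' @return A tibble of class `ion_trajectory`, one row per output time, with
#'   attributes `balanced`, `z`, `system` (medium, rate coefficients, final
#'   state, final potential) and `config`.
#' @seealso [balanced_state()], [flux_table()], [initial_state()]
#' @export
#' @examples
#' traj <- simulate_system(datap_u937(), t_end = 500)
#' tail(traj, 2)
simulate_system <- function(x, dt = 0.1, hp = NULL, t_end = NULL,
                            max_outputs = 100, balance_tol = 0.005,
                            stop_when_balanced = TRUE) {
  x <- as_datap(x)
  sys <- init_core(x)
  if (is.null(hp)) hp <- sys$hp
  hp <- max(1L, as.integer(round(hp)))
  if (!is.null(t_end)) {
    n_steps <- as.integer(round(t_end / dt))
  } else {
    n_steps <- hp * as.integer(max_outputs)
  }
  s <- sys$s; m <- sys$m; p <- sys$p
  S_o <- sys$S_o; V <- sys$V; A <- sys$A
  cont <- c(s$na, s$k, s$l, s$cl) * V
  u <- solve_u_core(s, m, p)
  # preallocated numeric recording; mu columns are derived vectorized below
  rec <- matrix(NA_real_, nrow = n_steps %/% hp + 1L, ncol = 11,
                dimnames = list(NULL, c("t", "U", "na", "k", "l", "cl",
                                        "VA1000", "prna", "prk", "prl",
                                        "prcl")))
  rec[1, ] <- c(0, u * RTF_MV, s$na, s$k, s$l, s$cl, V * 1000, 0, 0, 0, 0)
  n_rows <- 1L
  balanced <- FALSE
  pr <- c(Inf, Inf, Inf, Inf)
  step <- 0L
  while (step < n_steps) {
    step <- step + 1L
    f <- derivs_core(net_fluxes_core(s, m, p, u))
    cont <- cont + (dt * V) * f[c("na", "k", "l", "cl")]
    V_new <- (sum(cont) + A) / S_o
    s_new <- list(na = cont[[1]] / V_new, k = cont[[2]] / V_new,
                  l = cont[[3]] / V_new, cl = cont[[4]] / V_new)
    pr <- c(s_new$na - s$na, s_new$k - s$k, s_new$l - s$l,
            s_new$cl - s$cl) / dt
    s <- s_new
    V <- V_new
    if (!all(is.finite(c(s$na, s$k, s$l, s$cl, V))) || V <= 0) {
      rlang::abort(
        sprintf("numerical failure (non-finite state) at t = %.4g min; reduce dt",
                step * dt),
        class = "ionflux_numeric")
    }
    if (s$na < 0.1) {
      rlang::abort(sprintf("LOW SODIUM at t = %.4g min", step * dt),
                   class = "ionflux_low_sodium")
    }
    u <- tryCatch(
      solve_u_core(s, m, p, warm = u),
      ionflux_range_limit = function(e) {
        rlang::abort(sprintf("RANGE LIMIT at t = %.4g min", step * dt),
                     class = "ionflux_range_limit")
      }
    )
    if (step %% hp == 0L) {
      n_rows <- n_rows + 1L
      rec[n_rows, ] <- c(step * dt, u * RTF_MV, s$na, s$k, s$l, s$cl,
                         V * 1000, pr)
      if (stop_when_balanced && max(abs(pr)) < balance_tol) {
        balanced <- TRUE
        break
      }
    }
  }
  if (!balanced && max(abs(pr)) < balance_tol) balanced <- TRUE
  rec <- rec[seq_len(n_rows), , drop = FALSE]
  out <- tibble::as_tibble(as.data.frame(rec))
  out <- out[, c("t", "U", "na", "k", "l", "cl", "VA1000")]
  out$mun <- RTF_MV * log(rec[, "na"] / m$na0) + rec[, "U"]
  out$muk <- RTF_MV * log(rec[, "k"] / m$k0) + rec[, "U"]
  out$mul <- RTF_MV * log(rec[, "l"] / m$l0) + rec[, "U"]
  out$mucl <- RTF_MV * log(rec[, "cl"] / m$cl0) - rec[, "U"]
  out$prna <- rec[, "prna"]
  out$prk <- rec[, "prk"]
  out$prl <- rec[, "prl"]
  out$prcl <- rec[, "prcl"]
  sys$s <- s; sys$V <- V; sys$u <- u
  attr(out, "balanced") <- balanced
  attr(out, "z") <- sys$z
  attr(out, "system") <- sys
  attr(out, "config") <- list(dt = dt, hp = hp, balance_tol = balance_tol,
                              max_outputs = max_outputs, t_end = t_end)
  class(out) <- c("ion_trajectory", class(out))
  out
}

traj_system <- function(x) {
  sys <- attr(x, "system")
  if (is.null(sys)) {
    rlang::abort("not an ion_trajectory: missing system attribute")
  }
  sys
}

#' Is the system at its balanced state?
#'
#' TRUE when every instantaneous concentration derivative |d conc/dt| is
#' below `tol` (mM/min). The concentration derivative accounts for the
#' concurrent volume change: `d[X]/dt = f_X - [X] * sum(f) / S_o` with `f`
#' the content derivatives per ml cell water.
#'
#' @param x An `ion_trajectory`, or a cell state (with `medium`/`params`).
#' @param medium,params As in [solve_membrane_potential()]; ignored for
#'   trajectories.
#' @param tol Threshold in mM/min.
#' @return Logical flag.
#' @export
is_balanced <- function(x, medium = x, params = x, tol = 0.005) {
  if (inherits(x, "ion_trajectory")) {
    sys <- traj_system(x)
    s <- sys$s; m <- sys$m; p <- sys$p
  } else {
    s <- as_cell_list(x)
    m <- as_medium_list(medium)
    p <- as_params_list(params)
  }
  if (is.infinite(tol)) return(TRUE)
  u <- solve_u_core(s, m, p)
  f <- derivs_core(net_fluxes_core(s, m, p, u))
  conc_deriv <- f - c(s$na, s$k, s$cl, s$l) * sum(f) / so_total(m)
  max(abs(conc_deriv)) < tol
}

#' Balanced-state summary of a run
#'
#' Runs the system (or takes an existing trajectory) and returns a one-row
#' summary of the final state: concentrations, membrane potential, cell
#' water, impermeant-osmolyte valence and OSOR (ratio of pump-mediated to
#' leak K+ influx), plus the balanced flag.
#'
#' @param x A [datap()] parameter set or an `ion_trajectory`.
#' @param ... Passed to [simulate_system()] when `x` is a parameter set.
#' @return A one-row tibble.
#' @export
#' @examples
#' balanced_state(datap_u937())
balanced_state <- function(x, ...) {
  traj <- if (inherits(x, "ion_trajectory")) x else simulate_system(x, ...)
  sys <- traj_system(traj)
  last <- traj[nrow(traj), ]
  ft <- flux_table(traj)
  tibble::tibble(
    t = last$t,
    balanced = isTRUE(attr(traj, "balanced")),
    na = last$na, k = last$k, l = last$l, cl = last$cl,
    U = last$U, VA1000 = last$VA1000, A_V = 1000 / last$VA1000,
    z = attr(traj, "z"),
    OSOR = osor(ft)
  )
}

#' Chain a run into a new medium
#'
#' Builds the parameter set for a follow-up run that starts from the final
#' internal state of `x` in a new external medium, with
#' `kv = S_o(new) / S_o(old)` so the osmotic water shift at the medium
#' change is applied automatically. Rate coefficients carry over unless
#' overridden.
#'
#' @param x An `ion_trajectory`.
#' @param ... New medium fields (`na0`, `k0`, `l0`, `cl0`, `B0`) and/or rate
#'   coefficient overrides, e.g. `beta = 0`.
#' @return A [datap()] parameter set.
#' @export
#' @examples
#' traj <- simulate_system(datap_u937(), t_end = 500)
#' continue_datap(traj, l0 = 0, cl0 = 116, beta = 0)
continue_datap <- function(x, ...) {
  sys <- traj_system(x)
  new <- list(...)
  bad <- setdiff(names(new), DATAP_FIELDS)
  if (length(bad)) {
    rlang::abort(paste0("unknown DATAP field(s): ", paste(bad, collapse = ", ")))
  }
  d <- c(sys$m, sys$p)
  d[names(new)] <- new
  m_new <- as_medium_list(d)
  d$na <- sys$s$na; d$k <- sys$s$k; d$l <- sys$s$l; d$cl <- sys$s$cl
  d$kv <- so_total(m_new) / sys$S_o
  d$hp <- if (!is.null(new$hp)) new$hp else sys$hp
  do.call(datap, d[DATAP_FIELDS])
}

#' @export
glance.ion_trajectory <- function(x, ...) {
  balanced_state(x)
}

#' @export
print.ion_trajectory <- function(x, ...) {
  bal <- isTRUE(attr(x, "balanced"))
  cat(sprintf("# pump-leak trajectory: %d time points over %.4g min (%s)\n",
              nrow(x), x$t[nrow(x)],
              if (bal) "balanced" else "not balanced"))
  NextMethod()
}
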