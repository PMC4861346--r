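# Isotope / analogue tracer kinetics on a balanced background.
#
# A tracer occupies the "Li slot" of the model: it moves through a channel
# (permeability p), a Cl-coupled cotransporter (i_cot), a pump (alpha) and a
# countertransport exchanging it for Na+ (kp). At trace level the background
# state is unaffected, so the tracer obeys a linear one-pool equation
#   dT_i/dt = a - k T_i
# with gain and loss coefficients assembled from the frozen background; the
# solution is exactly monoexponential. A full-model mode integrates the
# tracer in the Li slot of the complete system for cross-validation.

#' Tracer transport parameters
#'
#' @param p Channel permeability of the tracer (1/min).
#' @param i_cot Cl-coupled cotransport coefficient (ml/umol/min).
#' @param alpha Pump rate coefficient acting on the tracer (1/min).
#' @param kp Coupled exchange coefficient against Na+ (ml/umol/min).
#' @return A list of class `tracer_params`.
#' @export
tracer_params <- function(p = 0, i_cot = 0, alpha = 0, kp = 0) {
  stopifnot(p >= 0, i_cot >= 0, alpha >= 0, kp >= 0)
  structure(list(p = p, i_cot = i_cot, alpha = alpha, kp = kp),
            class = "tracer_params")
}

#' @rdname tracer_params
#' @param x A [datap()] parameter set supplying the Na-carrier coefficients.
#' @param kp_na Na/Na coupled-exchange coefficient (ml/umol/min).
#' @param pump Give the tracer slot the Na/K pump coefficient `beta`
#'   (the 22Na view) or no pump at all.
#' @details `tracer_na()` builds the 22Na tracer: channel and cotransport
#'   coefficients of the Na+ carrier (`pna`, `inc`), the pump at `beta`
#'   (or 0 with `pump = "none"`), and the Na/Na exchange coefficient
#'   `kp_na`.
#' @export
tracer_na <- function(x = datap_u937(), kp_na = 0.0008,
                      pump = c("beta", "none")) {
  pump <- match.arg(pump)
  x <- as_datap(x)
  tracer_params(p = x$pna, i_cot = x$inc,
                alpha = if (pump == "beta") x$beta else 0,
                kp = kp_na)
}

#' @rdname tracer_params
#' @details `tracer_li()` builds a Li+ tracer from the Li-slot coefficients
#'   (`pl`, `ilc`, `alpha`, `kp`) of a parameter set.
#' @export
tracer_li <- function(x = datap_u937()) {
  x <- as_datap(x)
  tracer_params(p = x$pl, i_cot = x$ilc, alpha = x$alpha, kp = x$kp)
}

# gain (a, per unit external tracer) and loss (k) coefficients on a frozen
# balanced background
tracer_coefs <- function(sys, tr, u) {
  r <- u_over_g(u)
  list(
    a1 = -tr$p * r + tr$i_cot * sys$m$cl0 + tr$kp * sys$s$na,
    k = -tr$p * r * exp(u) + tr$alpha + tr$i_cot * sys$s$cl +
      tr$kp * sys$m$na0
  )
}

#' Simulate tracer equilibration on a balanced background
#'
#' Computes the gain or loss curve of a trace-level isotope or analogue on a
#' cell at its balanced state. In the default `"frozen"` mode the background
#' is clamped (trace amounts cannot perturb it) and the curve is the exact
#' monoexponential solution of the linear tracer equation. In `"full"` mode
#' the tracer is placed in the Li slot of the complete model and integrated
#' with [simulate_system()]; at trace loads the two agree.
#'
#' @param x A balanced `ion_trajectory` or a [datap()] set (run to balance
#'   first, over `t_balance` min).
#' @param tracer A [tracer_params()] object.
#' @param direction `"gain"` (external tracer, internal starts at 0) or
#'   `"loss"` (internal load, tracer-free outside).
#' @param times Sampling times (min).
#' @param load External tracer concentration for gain, or internal tracer
#'   concentration at t = 0 for loss (mM; trace level).
#' @param mode `"frozen"` (clamped background) or `"full"` (whole-model
#'   integration).
#' @param t_balance Pre-run length when `x` is a parameter set.
#' @param dt Euler step for `"full"` mode.
#' @return A tibble of class `tracer_curve` with columns `t` and `content`
#'   (intracellular tracer concentration, mM), and attributes `direction`,
#'   `rate` (the analytic rate coefficient in frozen mode) and `asymptote`.
#' @export
#' @examples
#' traj <- simulate_system(datap_u937(), t_end = 500)
#' simulate_tracer(traj, tracer_na(kp_na = 0.0008), "loss",
#'                 times = c(5, 10, 20))
simulate_tracer <- function(x, tracer, direction = c("gain", "loss"),
                            times = c(5, 10, 20), load = 1,
                            mode = c("frozen", "full"),
                            t_balance = 1000, dt = 0.1) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  stopifnot(inherits(tracer, "tracer_params"), load >= 0,
            all(times >= 0))
  traj <- if (inherits(x, "ion_trajectory")) x else {
    simulate_system(x, t_end = t_balance, stop_when_balanced = FALSE)
  }
  if (!is_balanced(traj, tol = 0.01)) {
    rlang::abort("background system is not at a balanced state")
  }
  sys <- traj_system(traj)
  times <- sort(times)
  if (mode == "frozen") {
    u <- sys$u
    cf <- tracer_coefs(sys, tracer, u)
    if (direction == "gain") {
      a <- cf$a1 * load
      asym <- if (cf$k > 0) a / cf$k else Inf
      content <- asym * (1 - exp(-cf$k * times))
    } else {
      asym <- 0
      content <- load * exp(-cf$k * times)
    }
    out <- tibble::tibble(t = times, content = content)
    attr(out, "rate") <- cf$k
    attr(out, "asymptote") <- asym
  } else {
    d <- do.call(datap, c(
      sys$m[c("na0", "k0", "cl0", "B0")],
      list(l0 = if (direction == "gain") load else 0, kv = 1),
      sys$s[c("na", "k", "cl")],
      list(l = if (direction == "gain") 0 else load),
      sys$p[c("alpha", "beta", "gamma", "pna", "pk", "pcl",
              "inc", "ikc", "inkcc")],
      list(pl = tracer$p, ilc = tracer$i_cot, ilkcc = 0, kp = tracer$kp,
           hp = 1)
    ))
    d$alpha <- tracer$alpha
    tr <- simulate_system(d, dt = dt, hp = 1,
                          t_end = max(times, dt),
                          stop_when_balanced = FALSE)
    content <- stats::approx(tr$t, tr$l, xout = times, rule = 2)$y
    out <- tibble::tibble(t = times, content = content)
    attr(out, "rate") <- NA_real_
    attr(out, "asymptote") <- NA_real_
  }
  attr(out, "direction") <- direction
  class(out) <- c("tracer_curve", class(out))
  out
}

#' Fit a monoexponential rate coefficient to a tracer curve
#'
#' Loss curves `y = y0 * exp(-k t)` are fitted by log-linear least squares;
#' gain curves `y = y_inf * (1 - exp(-k t))` by nonlinear least squares
#' seeded from a log-linear start. Three time points (the classic 5/10/20
#' min design) suffice. Non-monotone data produce a warning, not a failure.
#'
#' @param curve A `tracer_curve`, or any data frame with columns `t` and
#'   `content`.
#' @param direction `"gain"` or `"loss"`; taken from the curve attribute
#'   when present, otherwise inferred from the trend.
#' @return An object of class `rate_fit`: list with `k` (1/min),
#'   `amplitude` (`y_inf` or `y0`), `direction`, `residual_sd` and the data.
#'   [generics::tidy()] and [generics::glance()] methods are provided.
#' @export
#' @examples
#' curve <- data.frame(t = c(5, 10, 20), content = 100 * exp(-0.05 * c(5, 10, 20)))
#' fit_rate_coefficient(curve)$k
fit_rate_coefficient <- function(curve, direction = NULL) {
  stopifnot(is.data.frame(curve), all(c("t", "content") %in% names(curve)))
  if (nrow(curve) < 3) {
    rlang::abort("need at least 3 time points to fit a rate coefficient")
  }
  if (is.null(direction)) direction <- attr(curve, "direction")
  if (is.null(direction)) {
    direction <- if (stats::cor(curve$t, curve$content) < 0) "loss" else "gain"
  }
  t <- curve$t
  y <- curve$content
  mono <- if (direction == "loss") all(diff(y[order(t)]) <= 0) else
    all(diff(y[order(t)]) >= 0)
  if (!mono) {
    rlang::warn("tracer curve is not monotone; fitting anyway")
  }
  if (direction == "loss") {
    keep <- y > 0
    fit <- stats::lm(log(y[keep]) ~ t[keep])
    k <- -unname(stats::coef(fit)[2])
    amp <- exp(unname(stats::coef(fit)[1]))
    fitted <- amp * exp(-k * t)
  } else {
    yinf0 <- max(y) * 1.05
    z <- pmax(1 - y / yinf0, 1e-8)
    k0 <- max(-unname(stats::coef(stats::lm(log(z) ~ t))[2]), 1e-4)
    nls_fit <- minpack.lm::nlsLM(
      y ~ yinf * (1 - exp(-k * t)),
      start = list(yinf = yinf0, k = k0),
      lower = c(0, 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    cf <- stats::coef(nls_fit)
    k <- unname(cf["k"])
    amp <- unname(cf["yinf"])
    fitted <- amp * (1 - exp(-k * t))
  }
  structure(
    list(k = k, amplitude = amp, direction = direction,
         residual_sd = stats::sd(y - fitted), data = curve,
         fitted = fitted),
    class = "rate_fit"
  )
}

#' @export
tidy.rate_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k", "amplitude"),
    estimate = c(x$k, x$amplitude)
  )
}

#' @export
glance.rate_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k, amplitude = x$amplitude, direction = x$direction,
    residual_sd = x$residual_sd, n = nrow(x$data)
  )
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("monoexponential %s fit: k = %.4g /min, amplitude = %.4g\n",
              x$direction, x$k, x$amplitude))
  invisible(x)
}

#' Estimate the coupled Na/Na exchange coefficient from a tracer rate
#'
#' Finds the exchange coefficient `kp_na` at which the simulated 22Na tracer
#' rate on the balanced background equals an observed equilibration rate
#' coefficient. The simulated rate grows monotonically with `kp_na`, so the
#' scalar root is refined by Brent bisection to 1e-6. A target below the
#' `kp_na = 0` rate is an error: the observed turnover is already explained
#' without exchange.
#'
#' @param observed Either an observed rate coefficient (1/min) or a tracer
#'   curve data frame (fitted with [fit_rate_coefficient()] first).
#' @param x A balanced `ion_trajectory` or [datap()] set.
#' @param tracer Baseline tracer parameters (exchange coefficient ignored);
#'   default the 22Na slot of the background parameters.
#' @param interval Search interval for `kp_na`.
#' @return The estimated `kp_na` (ml/umol/min).
#' @export
#' @examples
#' traj <- simulate_system(datap_u937(), t_end = 500)
#' estimate_kpna(5.8 / 37, traj)
estimate_kpna <- function(observed, x, tracer = NULL,
                          interval = c(0, 0.05)) {
  traj <- if (inherits(x, "ion_trajectory")) x else {
    simulate_system(x, t_end = 1000, stop_when_balanced = FALSE)
  }
  target <- if (is.data.frame(observed)) {
    fit_rate_coefficient(observed)$k
  } else {
    as.numeric(observed)
  }
  if (is.null(tracer)) {
    sys <- traj_system(traj)
    tracer <- tracer_params(p = sys$p$pna, i_cot = sys$p$inc,
                            alpha = sys$p$beta, kp = 0)
  }
  rate_at <- function(kp) {
    tr <- tracer_params(tracer$p, tracer$i_cot, tracer$alpha, kp)
    curve <- simulate_tracer(traj, tr, "loss",
                             times = c(5, 10, 20), load = 1)
    fit_rate_coefficient(curve)$k
  }
  k0 <- rate_at(interval[1])
  if (target < k0 * (1 - 1e-9)) {
    rlang::abort(paste0(
      "observed rate (", signif(target, 4), ") is below the no-exchange rate (",
      signif(k0, 4), "): no coupled exchange needed"))
  }
  if (target <= k0) return(interval[1])
  stats::uniroot(function(kp) rate_at(kp) - target, interval,
                 tol = 1e-6, extendInt = "upX")$root
}

#' Pump rate coefficient from ouabain-sensitive Rb+ influx
#'
#' Inverts the pump K+ influx formula: `beta = influx * gamma / na_i`. This
#' is how the Na/K pump rate coefficient is obtained from the measured
#' intracellular Na+ and the ouabain-sensitive Rb+(K+) influx.
#'
#' @param influx Ouabain-sensitive Rb+ influx (umol/min per ml cell water).
#' @param na_i Intracellular Na+ (mM); must be positive.
#' @param gamma Pump stoichiometry.
#' @return `beta` in 1/min. Vectorized.
#' @export
#' @examples
#' beta_from_rb_influx(1.0034, 38.6) # ~0.039
beta_from_rb_influx <- function(influx, na_i, gamma = 1.5) {
  stopifnot(all(influx >= 0), gamma > 1)
  if (any(na_i <= 0)) rlang::abort("na_i must be positive")
  influx * gamma / na_i
}
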