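# Field order of the DATAP parameter layout. Note that cl0 precedes l0 and cl
# precedes alpha; the order is fixed by the file format.
DATAP_FIELDS <- c(
  "na0", "k0", "cl0", "l0", "B0", "kv", "na", "k", "l", "cl",
  "alpha", "beta", "gamma", "pna", "pk",
  "pl", "pcl", "inc", "ikc", "ilc", "inkcc", "ilkcc", "kp", "hp"
)

MEDIUM_FIELDS <- c("na0", "k0", "l0", "cl0", "B0")
CELL_FIELDS <- c("na", "k", "l", "cl")
RATE_FIELDS <- c("alpha", "beta", "gamma", "pna", "pk", "pl", "pcl",
                 "inc", "ikc", "ilc", "inkcc", "ilkcc", "kp")

#' Build a pump-leak parameter set (DATAP layout)
#'
#' A parameter set is a one-row tibble holding the external medium, the initial
#' intracellular concentrations, and the rate coefficients of every transport
#' pathway, in the column order of the `DATAP.txt` file layout.
#'
#' Concentrations are in mM. `kv` is the ratio of the new external osmolarity
#' to the osmolarity the cell was previously balanced with; at initialization
#' the intracellular concentrations are multiplied by `kv` to represent the
#' instantaneous osmotic water shift. `alpha` and `beta` (1/min) are the Li/K
#' and Na/K pump rate coefficients and `gamma` their pump stoichiometry;
#' `pna`, `pk`, `pl`, `pcl` (1/min) are channel permeability coefficients;
#' `inc`, `ikc`, `ilc` (ml/umol/min) and `inkcc`, `ilkcc` (ml^3/umol^3/min)
#' are cotransport rate coefficients; `kp` (ml/umol/min) drives the Li/Na
#' countertransport. `hp` is the number of integration steps between output
#' rows; with the default 0.1 min step, `hp` also equals the simulated
#' duration in minutes of the standard run schedule.
#'
#' @param na0,k0,cl0,l0 External ion concentrations (mM).
#' @param B0 External concentration of membrane-impermeant osmolytes (mM).
#' @param kv External-to-previous osmolarity ratio (dimensionless).
#' @param na,k,l,cl Intracellular concentrations (mM) before the `kv`
#'   adjustment.
#' @param alpha,beta Li/K and Na/K pump rate coefficients (1/min).
#' @param gamma Pump stoichiometry (Na or Li per K), must exceed 1.
#' @param pna,pk,pl,pcl Channel permeability coefficients (1/min).
#' @param inc,ikc,ilc NC, KC, LC cotransport rate coefficients (ml/umol/min).
#' @param inkcc,ilkcc NKCC, LKCC rate coefficients (ml^3/umol^3/min).
#' @param kp Li/Na countertransport rate coefficient (ml/umol/min).
#' @param hp Integration steps between output rows.
#' @return A one-row tibble of class `datap`.
#' @seealso [datap_u937()], [datap_li_medium()], [read_datap()]
#' @export
#' @examples
#' datap(
#'   na0 = 140, k0 = 5.8, cl0 = 121, l0 = 5, B0 = 48.2, kv = 1.032,
#'   na = 37, k = 158, l = 1e-4, cl = 63, beta = 0.039, pna = 0.00349,
#'   pk = 0.0229, pl = 0.00349, pcl = 0.00426, inc = 3e-5, ilc = 0.00018,
#'   kp = 2e-4
#' )
datap <- function(na0, k0, cl0, l0, B0, kv = 1, na, k, l = 0, cl,
                  alpha = 0, beta = 0, gamma = 1.5, pna = 0, pk = 0,
                  pl = 0, pcl = 0, inc = 0, ikc = 0, ilc = 0,
                  inkcc = 0, ilkcc = 0, kp = 0, hp = 500) {
  x <- tibble::tibble(
    na0 = na0, k0 = k0, cl0 = cl0, l0 = l0, B0 = B0, kv = kv,
    na = na, k = k, l = l, cl = cl,
    alpha = alpha, beta = beta, gamma = gamma, pna = pna, pk = pk,
    pl = pl, pcl = pcl, inc = inc, ikc = ikc, ilc = ilc,
    inkcc = inkcc, ilkcc = ilkcc, kp = kp, hp = hp
  )
  validate_datap(x)
  class(x) <- c("datap", class(x))
  x
}

validate_datap <- function(x) {
  stopifnot(is.data.frame(x), nrow(x) == 1)
  missing <- setdiff(DATAP_FIELDS, names(x))
  if (length(missing)) {
    rlang::abort(paste0("parameter set is missing field(s): ",
                        paste(missing, collapse = ", ")))
  }
  vals <- unlist(x[DATAP_FIELDS])
  if (anyNA(vals) || !is.numeric(vals)) {
    rlang::abort("all DATAP fields must be finite numbers")
  }
  neg <- vals < 0
  if (any(neg)) {
    rlang::abort(paste0("negative value for: ",
                        paste(names(vals)[neg], collapse = ", ")))
  }
  if (x$gamma <= 1) rlang::abort("pump stoichiometry gamma must exceed 1")
  if (x$kv <= 0) rlang::abort("kv must be positive")
  if (x$hp < 1) rlang::abort("hp must be at least 1")
  invisible(x)
}

as_datap <- function(x) {
  if (inherits(x, "datap")) return(x)
  x <- tibble::as_tibble(x)
  validate_datap(x)
  class(x) <- c("datap", class(x))
  x
}

# internal list views used by the numeric core
datap_medium <- function(x) as.list(x[MEDIUM_FIELDS])
datap_params <- function(x) as.list(x[RATE_FIELDS])
datap_cell <- function(x) as.list(x[CELL_FIELDS])

#' Reference U937 parameter set (RPMI + 5 mM LiCl)
#'
#' The parameter set fitted to a typical experiment with U937 cells balanced
#' in RPMI medium with 5 mM LiCl added. Integrated over the standard 500 min
#' schedule it reaches the balanced state with intracellular Na 38.6, K 155.2,
#' Li 4.375 and Cl 72.1 mM at a membrane potential of -47.5 mV.
#'
#' @return A one-row `datap` tibble.
#' @export
#' @examples
#' datap_u937()
datap_u937 <- function() {
  datap(
    na0 = 140, k0 = 5.8, cl0 = 121, l0 = 5, B0 = 48.2, kv = 1.032,
    na = 37, k = 158, l = 0.0001, cl = 63,
    alpha = 0, beta = 0.039, gamma = 1.5,
    pna = 0.00349, pk = 0.0229, pl = 0.00349, pcl = 0.00426,
    inc = 3e-5, ikc = 0, ilc = 0.00018, inkcc = 0, ilkcc = 0,
    kp = 0.0002, hp = 500
  )
}

#' U937 parameter set for a medium with a chosen LiCl addition
#'
#' Builds the medium obtained by adding `li_o` mM LiCl to Li-free RPMI
#' (140 Na, 5.8 K, 116 Cl, 48.2 impermeant; 310 mOsm total): `l0 = li_o`,
#' `cl0 = 116 + li_o`, and `kv = (310 + 2 * li_o) / 310`, so that the osmotic
#' adjustment matches the actual osmolarity change of the medium. At
#' `li_o = 5` this reproduces the reference set of [datap_u937()].
#'
#' @param li_o External LiCl addition (mM).
#' @param ilc,kp Optional overrides of the LC cotransport and Li/Na
#'   countertransport coefficients.
#' @return A one-row `datap` tibble.
#' @export
#' @examples
#' datap_li_medium(10)
#' datap_li_medium(10, ilc = 0.00042)
datap_li_medium <- function(li_o, ilc = 0.00018, kp = 0.0002) {
  base <- datap_u937()
  base$l0 <- li_o
  base$cl0 <- 116 + li_o
  base$kv <- (310 + 2 * li_o) / 310
  base$ilc <- ilc
  base$kp <- kp
  base
}

#' Parameter sets for the transient-response scenarios
#'
#' `datap_ouabain()` is the pump-block scenario: a cell balanced in Li-free
#' RPMI whose Na/K pump is stopped at t = 0 (`beta = 0`; set
#' `residual_beta = 0.001` for the 2.5% residual-activity variant).
#' `datap_na_free_li()` places a normal cell into a medium where all Na+ has
#' been replaced by Li+ (variants: `"base"`, `"li_pump"` with a Li/K pump at
#' alpha 0.004, `"li_pump_lc"` which additionally lowers `pl` and raises
#' `ilc`). `datap_return_to_na()` returns a Li-loaded cell to RPMI with
#' activated pumps. `datap_li_preloaded()` is the Li-preloaded recovery
#' scenario in a Li-free medium without Na (`"no_na"`), with Na but no Li/Na
#' countertransport (`"na_no_kp"`), or with both (`"na_kp"`).
#'
#' @param residual_beta Pump rate coefficient left after the block (1/min).
#' @param variant Scenario variant, see Details.
#' @return A one-row `datap` tibble.
#' @name transient-fixtures
#' @export
datap_ouabain <- function(residual_beta = 0) {
  datap(
    na0 = 140, k0 = 5.8, cl0 = 116, l0 = 0, B0 = 48.2, kv = 1,
    na = 35, k = 156, l = 0, cl = 70,
    alpha = 0, beta = residual_beta, gamma = 1.5,
    pna = 0.00301, pk = 0.023, pl = 0.00301, pcl = 0.00405,
    inc = 3.4e-5, ikc = 0, ilc = 0, inkcc = 0, ilkcc = 0,
    kp = 0, hp = 400
  )
}

#' @rdname transient-fixtures
#' @export
datap_na_free_li <- function(variant = c("base", "li_pump", "li_pump_lc")) {
  variant <- match.arg(variant)
  x <- datap(
    na0 = 0.01, k0 = 5.5, cl0 = 147, l0 = 140, B0 = 17.5, kv = 1,
    na = 37, k = 155, l = 0.0001, cl = 65,
    alpha = 0, beta = 0.039, gamma = 1.5,
    pna = 0.00353, pk = 0.023, pl = 0.00353, pcl = 0.00413,
    inc = 3e-5, ikc = 0, ilc = 3e-5, inkcc = 0, ilkcc = 0,
    kp = 0.0002, hp = 400
  )
  if (variant %in% c("li_pump", "li_pump_lc")) x$alpha <- 0.004
  if (variant == "li_pump_lc") {
    x$pl <- 0.0015
    x$ilc <- 3.8e-5
  }
  x
}

#' @rdname transient-fixtures
#' @export
datap_return_to_na <- function() {
  datap(
    na0 = 140, k0 = 5.8, cl0 = 116, l0 = 0.001, B0 = 48.2, kv = 1,
    na = 2, k = 73, l = 96, cl = 76,
    alpha = 0.04, beta = 0.08, gamma = 1.5,
    pna = 0.00353, pk = 0.023, pl = 0.00353, pcl = 0.00413,
    inc = 3e-5, ikc = 0, ilc = 3e-5, inkcc = 0, ilkcc = 0,
    kp = 0.0002, hp = 150
  )
}

#' @rdname transient-fixtures
#' @export
datap_li_preloaded <- function(variant = c("no_na", "na_no_kp", "na_kp")) {
  variant <- match.arg(variant)
  x <- datap(
    na0 = 140, k0 = 5.8, cl0 = 116, l0 = 0.01, B0 = 48.2, kv = 1,
    na = 2, k = 73, l = 96, cl = 76,
    alpha = 0, beta = 0.039, gamma = 1.5,
    pna = 0.00349, pk = 0.0229, pl = 0.00349, pcl = 0.00426,
    inc = 3e-5, ikc = 0, ilc = 0, inkcc = 0, ilkcc = 0,
    kp = if (variant == "na_kp") 0.0002 else 0, hp = 400
  )
  if (variant == "no_na") {
    x$na0 <- 0.01
    x$B0 <- 188.2
  }
  x
}
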