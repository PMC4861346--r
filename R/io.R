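# DATAP / RESP plain-text formats.
#
# DATAP is two groups of whitespace- or tab-delimited values, optionally
# preceded by header lines naming the fields:
#   na0 k0 cl0 l0 B0 kv na k l cl alpha beta gamma pna pk
#   pl pcl inc ikc ilc inkcc ilkcc kp hp
# Header lines are matched case-insensitively and may be absent (values-only
# dialect). RESP has three parts: A, a parameter echo including the computed
# valence z and final A/V; B, the trajectory; C, the Net/Influx/Efflux flux
# tables plus the OSOR line. All writes are deterministic.

#' Read a DATAP parameter file
#'
#' Parses the 24 numeric values of the DATAP layout in their fixed order,
#' skipping any header lines. Both the headed dialect and a values-only
#' dialect are accepted.
#'
#' @param path Path to the file.
#' @return A [datap()] parameter set.
#' @export
read_datap <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("no such file: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  tokens <- unlist(strsplit(trimws(lines), "[\t ,]+"))
  tokens <- tokens[nzchar(tokens)]
  # drop header tokens: anything that is a known field name (case-insensitive)
  is_field <- tolower(tokens) %in% tolower(DATAP_FIELDS)
  tokens <- tokens[!is_field]
  vals <- suppressWarnings(as.numeric(tokens))
  if (anyNA(vals)) {
    rlang::abort(paste0("non-numeric value in DATAP file: ",
                        tokens[which(is.na(vals))[1]]))
  }
  if (length(vals) < length(DATAP_FIELDS)) {
    rlang::abort(paste0(
      "DATAP file has ", length(vals), " values; missing field: ",
      DATAP_FIELDS[length(vals) + 1]))
  }
  if (length(vals) > length(DATAP_FIELDS)) {
    rlang::abort(paste0("DATAP file has ", length(vals),
                        " values; expected ", length(DATAP_FIELDS)))
  }
  do.call(datap, as.list(stats::setNames(vals, DATAP_FIELDS)))
}

#' Write a DATAP parameter file
#'
#' @param x A [datap()] parameter set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_datap <- function(x, path) {
  x <- as_datap(x)
  g1 <- DATAP_FIELDS[1:15]
  g2 <- DATAP_FIELDS[16:24]
  fmt <- function(v) vapply(v, format, "", scientific = FALSE, trim = TRUE)
  lines <- c(
    paste(g1, collapse = "\t"),
    paste(fmt(unlist(x[g1])), collapse = "\t"),
    paste(g2, collapse = "\t"),
    paste(fmt(unlist(x[g2])), collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

fmt_num <- function(x, digits) formatC(x, format = "f", digits = digits)

resp_traj_lines <- function(traj) {
  header <- c("t", "U", "na", "k", "l", "cl", "(V/A)x1000",
              "mun", "muk", "mul", "mucl", "prna", "prk", "prl", "prcl")
  rows <- vapply(seq_len(nrow(traj)), function(i) {
    r <- traj[i, ]
    paste(c(
      format(r$t, trim = TRUE, scientific = FALSE),
      fmt_num(r$U, 1),
      fmt_num(r$na, 1), fmt_num(r$k, 1), fmt_num(r$l, 3), fmt_num(r$cl, 1),
      fmt_num(r$VA1000, 2),
      fmt_num(r$mun, 1), fmt_num(r$muk, 1), fmt_num(r$mul, 1),
      fmt_num(r$mucl, 1),
      fmt_num(r$prna, 4), fmt_num(r$prk, 4), fmt_num(r$prl, 4),
      fmt_num(r$prcl, 4)
    ), collapse = "\t")
  }, "")
  c(paste(header, collapse = "\t"), rows)
}

resp_flux_lines <- function(ft) {
  blocks <- list(Net = "net", Influx = "influx", Efflux = "efflux")
  unlist(lapply(names(blocks), function(bl) {
    col <- blocks[[bl]]
    head <- paste(c(bl, PATHWAYS), collapse = "\t")
    rows <- vapply(IONS, function(ion) {
      v <- ft[[col]][ft$ion == ion][match(PATHWAYS, ft$pathway[ft$ion == ion])]
      paste(c(ion, fmt_num(v, 4)), collapse = "\t")
    }, "")
    c(head, rows)
  }))
}

#' Write a RESP result file
#'
#' Renders a completed run in the three-part RESP layout: Part A echoes the
#' parameters together with the computed impermeant-osmolyte valence `z` and
#' the final `A/V`; Part B is the trajectory; Part C the Net/Influx/Efflux
#' flux tables with the OSOR line. Potentials are written with 1 decimal,
#' concentrations 1 decimal (Li 3), fluxes 4 decimals.
#'
#' @param traj An `ion_trajectory` from [simulate_system()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_resp()]
#' @export
write_resp <- function(traj, path) {
  sys <- traj_system(traj)
  ft <- flux_table(traj)
  last <- traj[nrow(traj), ]
  pA1 <- c("na0", "k0", "cl0", "l0", "B0", "kv", "alpha", "beta", "gamma",
           "z", "kp", "hp")
  # kv has already been applied at initialization, so the echo is 1 relative
  # to the adjusted state
  vA1 <- c(unlist(sys$m[c("na0", "k0", "cl0", "l0", "B0")]), kv = 1,
           alpha = sys$p$alpha, beta = sys$p$beta, gamma = sys$p$gamma,
           z = attr(traj, "z"), kp = sys$p$kp, hp = sys$hp)
  pA2 <- c("pna", "pk", "pl", "pcl", "inc", "ikc", "ilc", "inkcc", "ilkcc",
           "A/V")
  vA2 <- c(unlist(sys$p[c("pna", "pk", "pl", "pcl", "inc", "ikc", "ilc",
                          "inkcc", "ilkcc")]),
           `A/V` = 1000 / last$VA1000)
  fmt <- function(v) vapply(unname(v), format, "", scientific = TRUE,
                            digits = 6, trim = TRUE)
  lines <- c(
    "A Parameter values",
    paste(pA1, collapse = "\t"),
    paste(fmt(vA1), collapse = "\t"),
    paste(pA2, collapse = "\t"),
    paste(fmt(vA2), collapse = "\t"),
    "B Time course of variables",
    resp_traj_lines(traj),
    "C Flux balance under the balanced state",
    resp_flux_lines(ft),
    paste("OSOR", fmt_num(osor(ft), 2), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a RESP result file
#'
#' Parses a file written by [write_resp()] back into its components.
#'
#' @param path Path to the file.
#' @return A list with `params` (named numeric vector), `trajectory`
#'   (tibble), `fluxes` (tibble with ion, pathway, net, influx, efflux) and
#'   `osor`.
#' @export
read_resp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  secA <- which(startsWith(lines, "A "))
  secB <- which(startsWith(lines, "B "))
  secC <- which(startsWith(lines, "C "))
  if (!length(secA) || !length(secB) || !length(secC)) {
    rlang::abort(paste0("not a RESP file: ", path))
  }
  split_line <- function(l) strsplit(l, "\t", fixed = TRUE)[[1]]
  params <- c(
    stats::setNames(as.numeric(split_line(lines[secA + 2])),
                    split_line(lines[secA + 1])),
    stats::setNames(as.numeric(split_line(lines[secA + 4])),
                    split_line(lines[secA + 3]))
  )
  traj_lines <- lines[(secB + 1):(secC - 1)]
  cols <- split_line(traj_lines[1])
  cols[cols == "(V/A)x1000"] <- "VA1000"
  vals <- lapply(traj_lines[-1], function(l) as.numeric(split_line(l)))
  traj <- tibble::as_tibble(stats::setNames(
    as.data.frame(do.call(rbind, vals)), cols))
  fx <- lines[(secC + 1):length(lines)]
  osor_line <- fx[startsWith(fx, "OSOR")]
  fx <- fx[!startsWith(fx, "OSOR")]
  # every 5 lines form one block (header + 4 ion rows)
  stopifnot(length(fx) %% 5 == 0)
  parse_block <- function(b) {
    vals <- lapply(b[-1], function(l) {
      parts <- split_line(l)
      stats::setNames(list(parts[1], as.numeric(parts[-1])), c("ion", "v"))
    })
    tibble::tibble(
      ion = rep(vapply(vals, `[[`, "", "ion"), each = length(PATHWAYS)),
      pathway = rep(PATHWAYS, times = length(vals)),
      value = unlist(lapply(vals, `[[`, "v"))
    )
  }
  long <- lapply(split(fx, rep(1:3, each = 5)), parse_block)
  fluxes <- long[[1]]
  names(fluxes)[3] <- "net"
  fluxes$influx <- long[[2]]$value
  fluxes$efflux <- long[[3]]$value
  list(
    params = params,
    trajectory = traj,
    fluxes = fluxes,
    osor = as.numeric(split_line(osor_line)[2])
  )
}
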