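#' Membrane-voltage-modified rate constant
#'
#' Rates of transitions that move charge across the membrane are modulated by
#' an Eyring barrier placed a fraction `split` of the way through the field:
#' the forward rate becomes
#' \eqn{k^\circ [X] \exp(-\beta q \Delta\Psi \cdot split)} and the reverse
#' rate carries \eqn{\exp(+\beta q \Delta\Psi (1 - split))}, so that the pair
#' ratio contributes \eqn{\exp(-\beta q \Delta\Psi)} per unit charge moved
#' inward, independent of the barrier position.
#' \eqn{\Delta\Psi = \Psi_{in} - \Psi_{out}} in volts; `q` in elementary
#' charges; the thermal voltage kT/e is 25.7 mV at 298 K.
#'
#' @param k_intrinsic intrinsic rate constant (1/s after absorbing the
#'   concentration factor).
#' @param concentration_factor \[X\]/c0 for a pseudo-first-order direction,
#'   1 otherwise.
#' @param charge signed elementary charges moved inward when the edge is
#'   traversed forward.
#' @param voltage membrane potential in volts.
#' @param split barrier position fraction in (0, 1); default 0.5 (halfway).
#' @param direction `"forward"` or `"reverse"`.
#' @param temperature kelvin.
#' @return modified rate in 1/s.
#' @export
voltage_rate <- function(k_intrinsic, concentration_factor = 1, charge = 0,
                         voltage = 0, split = 0.5,
                         direction = c("forward", "reverse"),
                         temperature = 298.15) {
  direction <- match.arg(direction)
  if (split <= 0 || split >= 1) validation_error("split must lie in (0, 1)")
  u <- charge * voltage / thermal_voltage(temperature)   # beta q dPsi
  fac <- if (direction == "forward") exp(-u * split) else exp(u * (1 - split))
  k_intrinsic * concentration_factor * fac
}

#' Master-equation rate matrix at a condition
#'
#' Assembles the generator Q of the master equation dP/dt = Q P (columns sum
#' to zero; Q\[j, i\] is the rate i -> j) from consistent kinetics: intrinsic
#' rates times side-specific concentration factors on binding edges, times
#' voltage factors on charged edges.
#'
#' @param kin a `consistent_kinetics` from [make_consistent()].
#' @param condition a [condition_set()]; must price every ligand (per side
#'   where edges are side-annotated).
#' @return object of class `rate_matrix`: `Q` (M x M, 1/s), `condition`,
#'   `edges` (per-edge condition-dependent `k_fwd`/`k_rev`), `kin`.
#' @export
build_rate_matrix <- function(kin, condition) {
  stopifnot(inherits(kin, "consistent_kinetics"))
  g <- kin$graph
  M <- nrow(g$states)
  Q <- matrix(0, M, M, dimnames = list(g$states$name, g$states$name))
  ed <- kin$edges
  kf <- numeric(nrow(ed)); kr <- numeric(nrow(ed))
  idx <- match(ed$source, g$states$name)
  jdx <- match(ed$target, g$states$name)
  for (e in seq_len(nrow(ed))) {
    kk <- edge_rates_at(kin, e, condition)
    kf[e] <- kk[1]; kr[e] <- kk[2]
    Q[jdx[e], idx[e]] <- Q[jdx[e], idx[e]] + kk[1]
    Q[idx[e], jdx[e]] <- Q[idx[e], jdx[e]] + kk[2]
  }
  diag(Q) <- diag(Q) - colSums(Q)
  structure(list(Q = Q, condition = condition,
                 edges = cbind(ed[, c("source", "target")],
                               k_fwd = kf, k_rev = kr),
                 kin = kin),
            class = "rate_matrix")
}

#' Steady state of the master equation
#'
#' The unique stationary probability vector in the null space of the
#' generator, extracted by singular value decomposition (robust to stiff
#' rate matrices), plus per-edge net fluxes
#' \eqn{J_{ij} = P_i k_{ij} - P_j k_{ji}}.
#'
#' @param rm a [build_rate_matrix()] result.
#' @return object of class `steady_state_result`: `populations` (named,
#'   sums to 1), `edge_fluxes` (1/s, positive in the stored edge direction),
#'   and the inputs.
#' @export
steady_state <- function(rm) {
  stopifnot(inherits(rm, "rate_matrix"))
  Q <- rm$Q
  s <- svd(Q)
  M <- nrow(Q)
  cutoff <- M * .Machine$double.eps * s$d[1]
  null_dim <- sum(s$d <= cutoff)
  if (null_dim != 1L)
    numeric_error(paste0("reducible kinetic network: null-space dimension ",
                         null_dim))
  p <- s$v[, M]
  p <- p / sum(p)
  if (any(p < -1e-9))
    numeric_error("steady-state populations not non-negative")
  p <- pmax(p, 0); p <- p / sum(p)
  names(p) <- rownames(Q)
  ed <- rm$edges
  flux <- p[ed$source] * ed$k_fwd - p[ed$target] * ed$k_rev
  structure(list(populations = p,
                 edge_fluxes = data.frame(source = ed$source, target = ed$target,
                                          flux = as.numeric(flux)),
                 rate_matrix = rm),
            class = "steady_state_result")
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat("<steady_state_result>\n")
  print(round(x$populations, 5))
  invisible(x)
}

#' Net steady-state flux across a designated reporter edge
#'
#' @param ss a [steady_state()] result.
#' @param reporter length-2 character vector `c(from, to)`; positive return
#'   means net flux from `from` to `to`.
#' @return flux in 1/s (cycle completions per second when the edge is on a
#'   single cycle).
#' @export
reporter_flux <- function(ss, reporter) {
  fe <- find_edge(ss$rate_matrix$kin$graph, reporter[1], reporter[2])
  fe$sign * ss$edge_fluxes$flux[fe$index]
}

# default reporter: first conformational (order-1, charged) edge whose states
# share a bound proton; falls back to the first order-1 edge
default_reporter <- function(kin) {
  g <- kin$graph
  nH <- state_ligand_count(g, "H+")
  ed <- kin$edges
  cand <- which(ed$order == 1 &
                  (if (all(is.na(nH))) TRUE
                   else nH[match(ed$source, g$states$name)] > 0 &
                        nH[match(ed$target, g$states$name)] > 0))
  if (!length(cand)) cand <- which(ed$order == 1)
  if (!length(cand)) cand <- 1L
  c(ed$source[cand[1]], ed$target[cand[1]])
}

#' Turnover numbers over a condition grid
#'
#' Solves the steady state at every grid point and reports the net flux
#' across the reporter edge (for the antiporter fixture the proton-bound
#' IF -> OF conformational edge, so that positive turnover means proton
#' transport out of the cell).
#'
#' @param kin a `consistent_kinetics`.
#' @param grid list of [condition_set()] (see [condition_grid()]).
#' @param reporter `c(from, to)` state pair; defaults to the first
#'   conformational edge whose both states hold a proton.
#' @return data frame with grid values, turnover (1/s) and populations.
#' @export
turnover_scan <- function(kin, grid, reporter = NULL) {
  if (!length(grid)) validation_error("empty condition grid")
  if (is.null(reporter)) reporter <- default_reporter(kin)
  xvals <- attr(grid, "values") %||% seq_along(grid)
  rows <- lapply(seq_along(grid), function(k) {
    ss <- steady_state(build_rate_matrix(kin, grid[[k]]))
    c(x = xvals[k], turnover = reporter_flux(ss, reporter), ss$populations)
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out)[1] <- attr(grid, "axis") %||% "index"
  out
}
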