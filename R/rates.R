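#' Forward/backward rate pair
#'
#' @param k_fwd,k_rev forward and backward rates (1/s, first- or
#'   pseudo-first-order at the condition of definition).
#' @param sigma_fwd,sigma_rev standard errors (1/s).
#' @return object of class `rate_pair`.
#' @export
rate_pair <- function(k_fwd, k_rev, sigma_fwd = NA, sigma_rev = NA) {
  for (v in c(k_fwd, k_rev))
    if (!is.finite(v) || v <= 0) validation_error("rates must be strictly positive")
  for (v in c(sigma_fwd, sigma_rev))
    if (!is.na(v) && v <= 0) validation_error("rate sigmas must be strictly positive")
  structure(list(k_fwd = k_fwd, k_rev = k_rev,
                 sigma_fwd = sigma_fwd, sigma_rev = sigma_rev),
            class = "rate_pair")
}

#' Free-energy difference from a rate pair
#'
#' Detailed balance gives \eqn{\beta\Delta G = -\ln(k_{fwd}/k_{rev})}; the
#' uncertainty follows by first-order propagation,
#' \eqn{\sigma = \sqrt{(\sigma_f/k_f)^2 + (\sigma_r/k_r)^2}}.
#'
#' @param rp a [rate_pair()].
#' @return named numeric `c(dg = , sigma = )` in kT (`sigma` is `NA` when the
#'   pair carries no errors).
#' @export
rates_to_difference <- function(rp) {
  stopifnot(inherits(rp, "rate_pair"))
  dg <- -log(rp$k_fwd / rp$k_rev)
  sigma <- if (is.na(rp$sigma_fwd) || is.na(rp$sigma_rev)) NA_real_
           else sqrt((rp$sigma_fwd / rp$k_fwd)^2 + (rp$sigma_rev / rp$k_rev)^2)
  c(dg = dg, sigma = sigma)
}

#' Project a rate pair onto the detailed-balance consistency line
#'
#' Given a thermodynamically consistent free-energy difference
#' \eqn{\Delta G} for the edge, the consistent pair is the constrained
#' maximum-likelihood point (Gaussian rate errors) on the line
#' \eqn{k_{fwd} = K k_{rev}} with \eqn{K = e^{-\Delta G}}:
#' \deqn{k_{rev}' = \frac{\bar k_{rev} + (\bar\sigma_{rev}^2/\bar\sigma_{fwd}^2) K \bar k_{fwd}}
#'                       {1 + (\bar\sigma_{rev}^2/\bar\sigma_{fwd}^2) K^2},
#'       \qquad k_{fwd}' = K k_{rev}'.}
#' The sigmas are carried through unchanged. Rates with larger relative errors
#' move more; the output satisfies detailed balance exactly.
#'
#' @param rp a [rate_pair()] with both sigmas present.
#' @param dg_consistent consistent free-energy difference in kT (target minus
#'   source, same orientation as the pair).
#' @return a consistent [rate_pair()].
#' @export
project_rate_pair <- function(rp, dg_consistent) {
  stopifnot(inherits(rp, "rate_pair"))
  if (!is.finite(dg_consistent)) validation_error("dg_consistent must be finite")
  if (is.na(rp$sigma_fwd) || is.na(rp$sigma_rev))
    validation_error("rate projection needs both rate sigmas")
  K <- exp(-dg_consistent)
  r2 <- rp$sigma_rev^2 / rp$sigma_fwd^2
  k_rev <- (rp$k_rev + r2 * K * rp$k_fwd) / (1 + r2 * K^2)
  k_fwd <- K * k_rev
  if (!is.finite(k_fwd) || !is.finite(k_rev) || k_fwd <= 0 || k_rev <= 0)
    numeric_error(paste0("rate projection produced a non-positive rate (K = ",
                         signif(K, 4), "); the Gaussian approximation is invalid ",
                         "for such inconsistent inputs - review the input rates"))
  rate_pair(k_fwd, k_rev, rp$sigma_fwd, rp$sigma_rev)
}

#' Thermodynamically consistent kinetics for a whole graph
#'
#' Pipeline: convert every edge's rate pair to a free-energy difference with
#' propagated error, solve the potential graph by weighted maximum likelihood,
#' project each rate pair onto its consistent difference, and recover the
#' intrinsic (concentration-independent) rates by dividing the
#' pseudo-first-order binding rate by \[X\]/c0 at the graph's reference
#' condition. The reference condition must be gradient-free (equal baths, no
#' voltage); the input rates are taken to describe the system in equilibrium
#' at that condition.
#'
#' @param g a [state_graph()] whose every edge carries a rate pair with
#'   sigmas.
#' @return object of class `consistent_kinetics`: element `edges` holds the
#'   consistent pairs (`k_fwd`, `k_rev`, at the reference condition), the
#'   intrinsic rates (`k_fwd0`, `k_rev0`) and the consistent `dg`;
#'   `solution` is the underlying `potential_solution`.
#' @export
make_consistent <- function(g) {
  ed <- g$edges
  if (any(is.na(ed$k_fwd) | is.na(ed$k_rev)))
    validation_error("make_consistent requires a rate pair on every edge")
  rc <- g$reference_condition
  if (!isTRUE(all.equal(rc$voltage, 0)))
    validation_error("reference condition must have zero membrane voltage")
  if (!is.null(rc$pH) && length(rc$pH) > 1 && diff(range(rc$pH)) != 0)
    validation_error("reference condition must be gradient-free")
  sol <- solve_potentials(g)
  out <- ed
  for (e in seq_len(nrow(ed))) {
    pr <- project_rate_pair(rate_pair(ed$k_fwd[e], ed$k_rev[e],
                                      ed$k_fwd_sigma[e], ed$k_rev_sigma[e]),
                            sol$consistent_dg[e])
    out$k_fwd[e] <- pr$k_fwd
    out$k_rev[e] <- pr$k_rev
  }
  out$dg <- sol$consistent_dg
  out$k_fwd0 <- out$k_fwd
  out$k_rev0 <- out$k_rev
  for (e in which(out$order == 2)) {
    x <- reference_concentration(rc, out$ligand[e],
                                 if (is.na(out$side[e])) NA else out$side[e])
    if (out$stoich[e] > 0) out$k_fwd0[e] <- out$k_fwd[e] / x
    else out$k_rev0[e] <- out$k_rev[e] / x
  }
  structure(list(edges = out, solution = sol, graph = g,
                 reference_condition = rc),
            class = "consistent_kinetics")
}

#' @export
print.consistent_kinetics <- function(x, ...) {
  cat("<consistent_kinetics> ", nrow(x$edges), " edges\n", sep = "")
  print(data.frame(edge = paste(x$edges$source, "->", x$edges$target),
                   k_fwd = signif(x$edges$k_fwd, 6),
                   k_rev = signif(x$edges$k_rev, 6),
                   dG_kT = round(x$edges$dg, 3), row.names = NULL))
  invisible(x)
}

# walk a cycle and sum log(k_fwd/k_rev) with orientation, given accessor
# returning c(kf, kr) for edge index in stored orientation
walk_log_ratio <- function(g, cycle, rates_of) {
  cycle <- as.character(cycle)
  if (cycle[1] != cycle[length(cycle)]) cycle <- c(cycle, cycle[1])
  total <- 0
  for (s in seq_len(length(cycle) - 1L)) {
    fe <- find_edge(g, cycle[s], cycle[s + 1L])
    kk <- rates_of(fe$index)
    total <- total + fe$sign * log(kk[1] / kk[2])
  }
  total
}

#' Kinetic cycle closure residual
#'
#' The log-ratio \eqn{\ln(\Pi_+^\circ/\Pi_-^\circ)} of intrinsic forward and
#' backward rate products around a closed walk. Zero (within numerical
#' tolerance) for thermodynamically consistent rates; for inconsistent inputs
#' its negative equals the sum of input free-energy differences over the same
#' orientation. For a raw [state_graph()] the stored (reference-condition)
#' rates are used; around stoichiometrically balanced cycles at a
#' gradient-free reference these give the same residual as intrinsic rates.
#'
#' @param x a `consistent_kinetics` or a [state_graph()] with rate edges.
#' @param cycle character vector of state names forming a closed walk (the
#'   first state may but need not be repeated at the end).
#' @return dimensionless residual; antisymmetric under orientation reversal.
#' @export
cycle_closure_residual <- function(x, cycle) {
  if (inherits(x, "consistent_kinetics")) {
    walk_log_ratio(x$graph, cycle,
                   function(e) c(x$edges$k_fwd0[e], x$edges$k_rev0[e]))
  } else if (inherits(x, "state_graph")) {
    if (any(is.na(x$edges$k_fwd) | is.na(x$edges$k_rev)))
      validation_error("cycle_closure_residual needs rate pairs on the cycle edges")
    walk_log_ratio(x, cycle, function(e) c(x$edges$k_fwd[e], x$edges$k_rev[e]))
  } else validation_error("x must be a state_graph or consistent_kinetics")
}

# condition-dependent rate pair for edge e (stored orientation)
edge_rates_at <- function(kin, e, condition) {
  ed <- kin$edges
  kf <- ed$k_fwd0[e]; kr <- ed$k_rev0[e]
  if (ed$order[e] == 2) {
    x <- ligand_concentration(condition, ed$ligand[e],
                              if (is.na(ed$side[e])) NA else ed$side[e])
    if (ed$stoich[e] > 0) kf <- kf * x else kr <- kr * x
  }
  q <- ed$charge[e]
  if (q != 0 && condition$voltage != 0) {
    kf <- voltage_rate(kf, 1, q, condition$voltage, ed$voltage_split[e],
                       "forward", condition$temperature)
    kr <- voltage_rate(kr, 1, q, condition$voltage, ed$voltage_split[e],
                       "reverse", condition$temperature)
  }
  c(kf, kr)
}

#' Cycle driving potential
#'
#' \eqn{\beta\chi = \ln(\Pi_+/\Pi_-)} around a closed walk, using
#' condition-dependent rates (concentration factors on binding edges, voltage
#' factors on charged edges). For consistent intrinsic rates this reduces to
#' the extrinsic term: the chemical-gradient contribution plus
#' \eqn{-\beta q_{net} \Delta\Psi} for the net charge moved inward per cycle.
#' Zero in equilibrium.
#'
#' @param kin a `consistent_kinetics` from [make_consistent()].
#' @param cycle closed state walk as in [cycle_closure_residual()].
#' @param condition a [condition_set()].
#' @return driving potential in kT.
#' @export
cycle_drive <- function(kin, cycle, condition) {
  stopifnot(inherits(kin, "consistent_kinetics"))
  walk_log_ratio(kin$graph, cycle, function(e) edge_rates_at(kin, e, condition))
}
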