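#' Concentration/pH shift of an edge free-energy difference
#'
#' A first-order (conformational) edge is unaffected by conditions. A
#' second-order binding edge acquires the mass-action term:
#' \eqn{\beta\Delta G([X]) = \beta\Delta G^0 - \ln([X]/c_0)} in the binding
#' direction (for protons this is \eqn{\ln 10 \,(pH - pK_a)}), with the
#' opposite sign for an edge written in the unbinding direction.
#'
#' @param dg_std standard-state free-energy difference in kT (target minus
#'   source).
#' @param ligand ligand name (`NA` for order 1).
#' @param order reaction order, 1 or 2.
#' @param condition a [condition_set()].
#' @param direction `"binding"` if traversing the edge binds one ligand,
#'   `"unbinding"` otherwise.
#' @param side bath side for transporter models (`NA` for a single bath).
#' @return shifted free-energy difference in kT.
#' @export
shift_edge_dg <- function(dg_std, ligand = NA, order = 1, condition,
                          direction = c("binding", "unbinding"), side = NA) {
  if (!order %in% c(1, 2)) validation_error("order must be 1 or 2")
  if (order == 1) return(dg_std)
  direction <- match.arg(direction)
  x <- ligand_concentration(condition, ligand, side)
  stoich <- if (direction == "binding") 1 else -1
  dg_std - stoich * log(x)
}

#' State free energies at a thermodynamic condition
#'
#' Rebuilds the per-state free energies at a given condition by accumulating
#' condition-shifted consistent edge differences along a spanning tree from
#' the reference state. The solved differences are defined at the graph's
#' `reference_condition` (the standard state for dg-specified graphs), so each
#' order-2 edge is shifted by the log-ratio of the target to the reference
#' ligand concentration. The result is independent of the tree: consistent
#' differences close around every cycle, and the concentration shifts close
#' too whenever the cycle is stoichiometrically balanced. An unbalanced cycle
#' (net ligand creation around a loop) is detected and reported as an error.
#'
#' @param sol a `potential_solution` from [solve_potentials()].
#' @param condition a [condition_set()].
#' @param g the graph; defaults to the one stored in `sol`.
#' @return object of class `conditioned_potentials` with `g_at_condition`
#'   (named vector, kT, reference state = 0), `condition` and `provenance`.
#' @export
condition_potentials <- function(sol, condition, g = sol$graph) {
  ed <- g$edges
  sdg <- sol$consistent_dg
  for (e in which(ed$order == 2)) {
    side <- if (is.na(ed$side[e])) NA else ed$side[e]
    x <- ligand_concentration(condition, ed$ligand[e], side)
    x_ref <- reference_concentration(g$reference_condition, ed$ligand[e], side)
    sdg[e] <- sdg[e] - ed$stoich[e] * (log(x) - log(x_ref))
  }
  M <- nrow(g$states)
  G <- rep(NA_real_, M)
  names(G) <- g$states$name
  G[g$reference_state] <- 0
  idx <- match(ed$source, g$states$name)
  jdx <- match(ed$target, g$states$name)
  tree_edge <- rep(FALSE, nrow(ed))
  repeat {
    progressed <- FALSE
    for (e in seq_len(nrow(ed))) {
      gi <- G[idx[e]]; gj <- G[jdx[e]]
      if (!is.na(gi) && is.na(gj)) {
        G[jdx[e]] <- gi + sdg[e]; tree_edge[e] <- TRUE; progressed <- TRUE
      } else if (is.na(gi) && !is.na(gj)) {
        G[idx[e]] <- gj - sdg[e]; tree_edge[e] <- TRUE; progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  # non-tree edges must agree; disagreement means an unbalanced cycle
  for (e in which(!tree_edge)) {
    gap <- G[jdx[e]] - G[idx[e]] - sdg[e]
    if (abs(gap) > 1e-8)
      validation_error(paste0(
        "stoichiometrically unbalanced cycle through edge ", ed$source[e],
        " -> ", ed$target[e], " (net shift ", signif(gap, 4),
        " kT); check ligand/site annotations"))
  }
  structure(list(g_at_condition = G, condition = condition, provenance = sol),
            class = "conditioned_potentials")
}

#' Boltzmann microstate probabilities
#'
#' \eqn{P(i) = e^{-G_i} / \sum_j e^{-G_j}}, computed with a max-shift for
#' overflow safety (stable for free-energy spreads of hundreds of kT).
#'
#' @param cp a [condition_potentials()] result, or a bare numeric vector of
#'   free energies in kT.
#' @return named probability vector summing to 1.
#' @export
state_probabilities <- function(cp) {
  G <- if (inherits(cp, "conditioned_potentials")) cp$g_at_condition else cp
  w <- exp(-(G - min(G)))
  w / sum(w)
}

#' Macrostate free-energy difference
#'
#' \eqn{\beta\Delta G_{\alpha\gamma} = -\ln\left(\sum_{i\in\gamma} e^{-G_i} /
#' \sum_{i\in\alpha} e^{-G_i}\right)}, log-sum-exp stabilized. For singleton
#' macrostates this reduces to \eqn{G_\gamma - G_\alpha}. Antisymmetric under
#' swapping the two macrostates.
#'
#' @param cp a [condition_potentials()] result (or named free-energy vector).
#' @param members_alpha,members_gamma state-name vectors defining the two
#'   macrostates; non-empty and disjoint.
#' @return free-energy difference in kT (gamma relative to alpha).
#' @export
macrostate_dg <- function(cp, members_alpha, members_gamma) {
  G <- if (inherits(cp, "conditioned_potentials")) cp$g_at_condition else cp
  if (!length(members_alpha) || !length(members_gamma))
    validation_error("macrostate member sets must be non-empty")
  if (length(intersect(members_alpha, members_gamma)))
    validation_error("macrostates must be disjoint")
  missing <- setdiff(c(members_alpha, members_gamma), names(G))
  if (length(missing))
    validation_error(paste0("unknown states: ", paste(missing, collapse = ", ")))
  -(logsumexp(-G[members_gamma]) - logsumexp(-G[members_alpha]))
}

#' Titration scan over a condition grid
#'
#' Evaluates microstate probabilities, per-site and total ligand occupancies,
#' and (optionally) macrostate probabilities at every grid point, together
#' with the uptake derivative \eqn{\partial\bar X/\partial x} computed by
#' centered finite differences on the grid (one-sided at the ends).
#'
#' @param sol a `potential_solution`.
#' @param grid a list of [condition_set()] as produced by [condition_grid()].
#' @param ligand ligand whose occupancy is reported (default proton).
#' @param sites site names (without the `site:` prefix) to report; default all
#'   sites that can hold `ligand`.
#' @param macrostate_label optional state-label column name; macrostate
#'   probabilities are summed per distinct label value.
#' @param g the graph; defaults to the one stored in `sol`.
#' @return object of class `titration_result`: `x` (grid values), `P`
#'   (states x points), `site_occupancy`, `total_occupancy`, `uptake`
#'   (derivative of total occupancy), and `macrostate` probabilities.
#' @export
titration_scan <- function(sol, grid, ligand = "H+", sites = NULL,
                           macrostate_label = NULL, g = sol$graph) {
  if (!length(grid)) validation_error("empty condition grid")
  xvals <- attr(grid, "values") %||% seq_along(grid)
  xname <- attr(grid, "axis") %||% "index"
  site_cols <- grep("^site:", names(g$states), value = TRUE)
  if (is.null(sites)) sites <- sub("^site:", "", site_cols)
  missing <- setdiff(paste0("site:", sites), site_cols)
  if (length(missing))
    validation_error(paste0("unknown site(s): ",
                            paste(sub("^site:", "", missing), collapse = ", ")))
  if (!is.null(macrostate_label) && !macrostate_label %in% names(g$states))
    validation_error(paste0("unknown state label: ", macrostate_label))

  M <- nrow(g$states); n <- length(grid)
  P <- matrix(NA_real_, M, n, dimnames = list(g$states$name, NULL))
  for (k in seq_len(n))
    P[, k] <- state_probabilities(condition_potentials(sol, grid[[k]], g))
  occ_state <- if (length(sites)) {
    matrix(vapply(sites, function(s)
      as.numeric(g$states[[paste0("site:", s)]] %in% ligand), numeric(M)),
      nrow = M, dimnames = list(g$states$name, sites))
  } else matrix(0, M, 0, dimnames = list(g$states$name, NULL))
  site_occ <- t(occ_state) %*% P
  nlig <- state_ligand_count(g, ligand)
  if (all(is.na(nlig))) nlig <- rep(0, M)
  total <- as.vector(nlig %*% P)

  macro <- NULL
  if (!is.null(macrostate_label)) {
    lab <- as.character(g$states[[macrostate_label]])
    macro <- rowsum(P, lab)
  }
  structure(list(x = xvals, xname = xname, P = P, site_occupancy = site_occ,
                 total_occupancy = total,
                 uptake = finite_diff(total, xvals),
                 macrostate = macro, grid = grid),
            class = "titration_result")
}

# centered differences, one-sided at the ends
finite_diff <- function(y, x) {
  n <- length(y)
  if (n < 2L) return(rep(NA_real_, n))
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2L) {
    i <- 2:(n - 1)
    d[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  }
  d
}

#' @export
print.titration_result <- function(x, ...) {
  cat("<titration_result> ", length(x$x), " points over ", x$xname, "\n", sep = "")
  utils::str(x$site_occupancy)
  invisible(x)
}
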