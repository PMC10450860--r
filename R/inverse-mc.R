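#' Configuration for the inverse Monte-Carlo fit
#'
#' @param delta maximum uniform step size (in the parameter's unit, e.g. pKa
#'   units); each symmetry group is perturbed by one
#'   \eqn{\delta \sim U(-\Delta, \Delta)} per iteration.
#' @param epsilon RMSD convergence tolerance (stop when reached).
#' @param max_steps iteration cap.
#' @param seed random seed (the trajectory is deterministic given the seed).
#' @param temperature Metropolis temperature; 0 (default) accepts only strict
#'   RMSD decreases.
#' @param unit parameter unit: `"pKa"` (protonation edges; dg = -ln10 * pKa)
#'   or `"kT"` (raw standard-state differences).
#' @return object of class `mc_config`.
#' @export
mc_config <- function(delta = 2, epsilon = 0, max_steps = 1e5, seed = 1,
                      temperature = 0, unit = c("pKa", "kT")) {
  if (delta <= 0) validation_error("delta must be > 0")
  if (epsilon < 0) validation_error("epsilon must be >= 0")
  if (max_steps < 1) validation_error("max_steps must be >= 1")
  structure(list(delta = delta, epsilon = epsilon, max_steps = max_steps,
                 seed = seed, temperature = temperature,
                 unit = match.arg(unit)),
            class = "mc_config")
}

#' Pooled RMSD between model output and training curves
#'
#' Square root of the mean squared deviation pooled over all points of all
#' curves with equal per-point weight. The model must be evaluated on exactly
#' the training x-grids; no interpolation is performed.
#'
#' @param model named list of numeric vectors (or [observable_curve()]s),
#'   one per training curve.
#' @param training named list of [observable_curve()]s.
#' @return dimensionless RMSD.
#' @export
curve_rmsd <- function(model, training) {
  sq <- 0; n <- 0
  for (nm in names(training)) {
    tr <- training[[nm]]
    mo <- model[[nm]]
    if (is.null(mo)) validation_error(paste0("model output missing curve '", nm, "'"))
    y <- if (inherits(mo, "observable_curve")) {
      if (length(mo$x) != length(tr$x) || any(mo$x != tr$x))
        validation_error(paste0("x-grid mismatch for curve '", nm, "'"))
      mo$y
    } else mo
    if (length(y) != length(tr$y))
      validation_error(paste0("x-grid mismatch for curve '", nm, "'"))
    sq <- sq + sum((y - tr$y)^2)
    n <- n + length(y)
  }
  sqrt(sq / n)
}

# fast standard-state solver: precompute the weighted least-squares map
# dg-vector -> state free energies (reference pinned to 0)
make_dg_solver <- function(g) {
  B <- incidence_matrix(g)
  sigma <- g$edges$dg_sigma
  sigma[is.na(sigma)] <- 1
  w <- 1 / sigma
  ref <- match(g$reference_state, g$states$name)
  A <- (B * w)[, -ref, drop = FALSE]
  Smap <- solve(t(A) %*% A, t(A))       # (M-1) x E
  M <- nrow(g$states)
  function(dg) {
    G <- numeric(M)
    G[-ref] <- Smap %*% (w * dg)
    names(G) <- g$states$name
    G
  }
}

#' Titration-curve observable for the inverse fit
#'
#' Builds a fast closure mapping standard-state potentials to proton
#' titration curves on the training x-grids (x is pH). Supported observable
#' labels: `"site:<name>"` (occupancy of one site), `"sites_mean:<a>,<b>"`
#' (mean occupancy over several sites, e.g. symmetric terminal sites) and
#' `"total"` (mean number of bound ligands).
#'
#' @param g a [state_graph()] with `site:` occupancy columns.
#' @param training named list of [observable_curve()]s whose `observable`
#'   labels follow the formats above.
#' @param ligand ligand name (default proton; pH dependence assumes protons).
#' @return function(G_std) -> named list of numeric vectors.
#' @export
titration_observable <- function(g, training, ligand = "H+") {
  M <- nrow(g$states)
  nlig <- state_ligand_count(g, ligand)
  if (all(is.na(nlig))) validation_error("graph has no site: occupancy columns")
  ref <- match(g$reference_state, g$states$name)
  nrel <- nlig - nlig[ref]
  weights <- lapply(training, function(tr) {
    spec <- tr$observable
    if (spec == "total") return(nlig)
    if (grepl("^site:", spec)) sites <- sub("^site:", "", spec)
    else if (grepl("^sites_mean:", spec))
      sites <- strsplit(sub("^sites_mean:", "", spec), ",")[[1]]
    else validation_error(paste0("unknown observable spec: ", spec))
    cols <- paste0("site:", trimws(sites))
    missing <- setdiff(cols, names(g$states))
    if (length(missing))
      validation_error(paste0("unknown site(s): ", paste(missing, collapse = ", ")))
    w <- rowMeans(matrix(vapply(cols, function(cc)
      as.numeric(g$states[[cc]] %in% ligand), numeric(M)), nrow = M))
    w
  })
  grids <- lapply(training, `[[`, "x")
  function(G_std) {
    out <- vector("list", length(training))
    names(out) <- names(training)
    for (k in seq_along(training)) {
      pH <- grids[[k]]
      Gc <- outer(G_std, rep(1, length(pH))) + outer(nrel, pH) * LN10
      W <- exp(-sweep(Gc, 2, apply(Gc, 2, min)))
      P <- sweep(W, 2, colSums(W), "/")
      out[[k]] <- as.vector(weights[[k]] %*% P)
    }
    out
  }
}

#' Inverse Monte-Carlo inference of microscopic edge parameters
#'
#' Zero-temperature Metropolis Monte Carlo: per iteration, one uniform
#' perturbation \eqn{\delta \sim U(-\Delta, \Delta)} is drawn per symmetry
#' group (a lone edge is its own group) and added to every edge parameter in
#' the group; all groups move in the same iteration. The potential graph is
#' re-solved (so the model stays thermodynamically consistent at every step),
#' the pooled RMSD to the training curves is recomputed, and the collective
#' move is accepted iff the RMSD decreased (or, at `temperature > 0`, with
#' Metropolis probability). Stops when RMSD < epsilon or after `max_steps`.
#'
#' @param g a [state_graph()] whose edges carry starting `dg` values;
#'   `symmetry_group` labels couple edges that share one parameter.
#' @param training named list of [observable_curve()]s.
#' @param cfg an [mc_config()].
#' @param observable_fn function mapping standard-state potentials to model
#'   curves; defaults to [titration_observable()] built from the training
#'   labels.
#' @return object of class `mc_fit_result`: `parameters` (per-edge final
#'   values in `cfg$unit`), `graph` (with updated dg), `rmsd_history`
#'   (accepted RMSD per iteration, element 1 = start), `accepted_steps`,
#'   `total_steps`, `seed`, `converged`.
#' @export
mc_infer <- function(g, training, cfg = mc_config(), observable_fn = NULL) {
  stopifnot(inherits(cfg, "mc_config"))
  if (is.null(names(training)) || any(!nzchar(names(training))))
    names(training) <- vapply(training, `[[`, "", "observable")
  if (is.null(observable_fn)) observable_fn <- titration_observable(g, training)
  solver <- make_dg_solver(g)
  ed <- g$edges
  if (any(is.na(ed$dg)))
    validation_error("mc_infer needs starting dg values on every edge")
  to_dg <- if (cfg$unit == "pKa") function(p) -LN10 * p else identity
  from_dg <- if (cfg$unit == "pKa") function(d) -d / LN10 else identity
  p <- from_dg(ed$dg)
  grp <- ed$symmetry_group
  grp[is.na(grp)] <- paste0(".lone", which(is.na(grp)))
  groups <- split(seq_along(p), grp)

  eval_rmsd <- function(p) {
    y <- observable_fn(solver(to_dg(p)))
    r <- tryCatch(curve_rmsd(y, training), error = function(e) NA_real_)
    if (!is.finite(r)) NA_real_ else r
  }
  set.seed(cfg$seed)
  r <- eval_rmsd(p)
  if (!is.finite(r)) numeric_error("non-finite RMSD at the starting parameters")
  hist <- numeric(cfg$max_steps + 1L)
  hist[1] <- r
  accepted <- 0L
  total <- 0L
  while (total < cfg$max_steps && r >= cfg$epsilon) {
    total <- total + 1L
    pn <- p
    for (idx in groups) pn[idx] <- pn[idx] + stats::runif(1, -cfg$delta, cfg$delta)
    rn <- eval_rmsd(pn)
    ok <- is.finite(rn) &&
      (rn < r || (cfg$temperature > 0 &&
                  stats::runif(1) < exp(-(rn - r) / cfg$temperature)))
    if (ok) { p <- pn; r <- rn; accepted <- accepted + 1L }
    hist[total + 1L] <- r
  }
  g$edges$dg <- to_dg(p)
  structure(list(parameters = data.frame(source = ed$source, target = ed$target,
                                         value = p, unit = cfg$unit,
                                         group = grp),
                 graph = g, rmsd_history = hist[seq_len(total + 1L)],
                 accepted_steps = accepted, total_steps = total,
                 seed = cfg$seed, converged = r < cfg$epsilon, rmsd = r),
            class = "mc_fit_result")
}

#' @export
print.mc_fit_result <- function(x, ...) {
  cat("<mc_fit_result> ", x$total_steps, " steps, ", x$accepted_steps,
      " accepted; final RMSD ", signif(x$rmsd, 4),
      if (x$converged) " (converged)" else "", "\n", sep = "")
  invisible(x)
}

#' Three-site protonation cube model (8 states, 12 edges)
#'
#' Builds the microstate graph of a triprotic molecule with two symmetric
#' terminal sites and one central site: states are labelled in binary
#' (terminal/central/terminal digits, a 1 meaning proton bound; e.g. `010` =
#' central protonated), the 12 protonation edges point in the binding
#' direction, and edges related by the terminal mirror symmetry share a
#' `symmetry_group` (7 groups in total). All pKa values start at 7.
#'
#' @param pka optional named vector of starting pKa values keyed
#'   `"<from> <to>"` in binary labels (e.g. `"000 010"`); unnamed scalar sets
#'   all edges.
#' @param dg_sigma uncertainty assigned to every edge (equal weights).
#' @return a [state_graph()] with site columns `site:N1`, `site:N2` (central),
#'   `site:N3` and label `N_protons`.
#' @export
dtpa_model_builder <- function(pka = 7, dg_sigma = 0.1) {
  bits <- expand.grid(b3 = 0:1, b2 = 0:1, b1 = 0:1)[, 3:1]
  lab <- apply(bits, 1, paste0, collapse = "")
  occ <- function(b) ifelse(b == 1, "H+", "")
  states <- data.frame(name = lab,
                       N_protons = rowSums(bits),
                       `site:N1` = occ(bits$b1), `site:N2` = occ(bits$b2),
                       `site:N3` = occ(bits$b3), check.names = FALSE)
  edges <- NULL
  for (i in seq_len(8)) for (b in 1:3) if (bits[i, b] == 0) {
    tgt <- bits[i, ]; tgt[b] <- 1
    j <- which(apply(bits, 1, paste0, collapse = "") ==
                 paste0(tgt, collapse = ""))
    edges <- rbind(edges, data.frame(source = lab[i], target = lab[j]))
  }
  key <- paste(edges$source, edges$target)
  mirror_lab <- function(s) paste0(rev(strsplit(s, "")[[1]]), collapse = "")
  mkey <- paste(vapply(edges$source, mirror_lab, ""),
                vapply(edges$target, mirror_lab, ""))
  group <- character(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    pairidx <- sort(unique(c(e, which(key == mkey[e]))))
    group[e] <- paste0("g", paste(pairidx, collapse = "_"))
  }
  if (is.null(names(pka))) pka_e <- rep(pka[1], nrow(edges))
  else {
    pka_e <- pka[key]
    if (any(is.na(pka_e)))
      validation_error(paste0("missing pKa for edge(s): ",
                              paste(key[is.na(pka_e)], collapse = "; ")))
  }
  edges$dg <- -LN10 * as.numeric(pka_e)
  edges$dg_sigma <- dg_sigma
  edges$ligand <- "H+"
  edges$order <- 2
  edges$symmetry_group <- group
  state_graph(states, edges, reference_state = "000")
}
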