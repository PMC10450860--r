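#' Built-in model systems
#'
#' Programmatic generators for the three reference systems used throughout
#' the tests and documentation: a two-proton binding site (square potential
#' graph), the three-site protonation cube of the polyamine chelator DTPA,
#' and a six-state alternating-access sodium/proton antiporter with a leak
#' pathway. All generators are pure functions of their arguments (plus a seed
#' for the random-graph generator) and return [state_graph()] objects;
#' [write_state_graph()] serializes them to the CSV dialect.
#'
#' @name fixtures
NULL

#' Two-site proton binding model
#'
#' Four states (empty `00`, singly bound `10`/`01`, doubly bound `11`) and
#' four protonation edges forming one cycle. The two sites are symmetric.
#' `"independent"` sets every pKa to 7; `"cooperative"` downshifts the first
#' binding event and upshifts the second by `shift` pKa units (binding one
#' proton makes the second more favourable); `"anticooperative"` does the
#' reverse. Any variant satisfies cycle closure exactly:
#' pKa(1st,A) + pKa(2nd,B) - pKa(2nd,A) - pKa(1st,B) = 0 by symmetry.
#'
#' @param variant `"independent"`, `"cooperative"` or `"anticooperative"`.
#' @param pka0 centre pKa (default 7).
#' @param shift symmetric pKa shift magnitude (default 1.5 units).
#' @param dg_sigma per-edge uncertainty in kT (equal weights).
#' @return a [state_graph()].
#' @export
generate_two_site <- function(variant = c("independent", "cooperative",
                                          "anticooperative"),
                              pka0 = 7, shift = 1.5, dg_sigma = 0.05) {
  variant <- match.arg(variant)
  d <- switch(variant, independent = 0, cooperative = shift,
              anticooperative = -shift)
  pka_first <- pka0 - d / 2
  pka_second <- pka0 + d / 2
  states <- data.frame(name = c("00", "10", "01", "11"),
                       N_protons = c(0, 1, 1, 2),
                       `site:s1` = c("", "H+", "", "H+"),
                       `site:s2` = c("", "", "H+", "H+"),
                       check.names = FALSE)
  edges <- data.frame(source = c("00", "00", "10", "01"),
                      target = c("10", "01", "11", "11"),
                      dg = -LN10 * c(pka_first, pka_first, pka_second, pka_second),
                      dg_sigma = dg_sigma,
                      ligand = "H+", order = 2,
                      symmetry_group = c("first", "first", "second", "second"))
  state_graph(states, edges, reference_state = "00")
}

# reference input block of the antiporter model (rates in 1/s at 100 mM Na+,
# pH 8, no voltage)
antiporter_input_rates <- function() {
  data.frame(
    source = c("IF(H+)", "OF(H+)", "OF(0)", "OF(Na+)", "IF(Na+)", "IF(0)", "OF(0)"),
    target = c("OF(H+)", "OF(0)", "OF(Na+)", "IF(Na+)", "IF(0)", "IF(H+)", "IF(0)"),
    k_fwd = c(8000, 6000, 320e6, 8000, 70e6, 200, 100),
    k_fwd_sigma = c(100, 100, 1.7e6, 100, 9.5e6, 25, 31.62),
    k_rev = c(5000, 200, 170e6, 5000, 320e6, 8000, 135),
    k_rev_sigma = c(100, 15, 10e6, 100, 1.7e6, 400, 31.62),
    stringsAsFactors = FALSE)
}

#' Six-state sodium/proton antiporter model
#'
#' Alternating-access transporter with a single binding site competed for by
#' a proton and the driving cation: states IF(H+), OF(H+), IF(X), OF(X),
#' IF(0), OF(0) (inward-/outward-facing conformations). The seven edges carry
#' the reference order-of-magnitude input rate pairs with uncertainties,
#' defined at the gradient-free reference condition of 100 mM driving ion and
#' pH 8. Binding edges are side-annotated (IF binds from `in`, OF from
#' `out`); conformational edges with a bound ion carry the transported charge
#' (out-moving proton: -1 inward; in-moving cation: +`charge` inward), so an
#' applied membrane voltage modulates them; the empty-carrier leak edge is
#' uncharged.
#'
#' @param charge driving-ion valence: `1` (electroneutral Na+/H+ cycle) or
#'   `2` (electrogenic divalent cation M2+/H+).
#' @param leak `"small"` (reference leak pair 100/135 per s), `"none"` (leak
#'   edge removed), or `"large"` (a synthetic stand-in, reference pair x 10,
#'   transitions on the order of 1000 per s).
#' @return a [state_graph()] whose `reference_condition` is 100 mM driving
#'   ion, pH 8, 0 mV, 298.15 K.
#' @export
generate_antiporter <- function(charge = 1, leak = c("small", "none", "large")) {
  leak <- match.arg(leak)
  if (!charge %in% c(1, 2)) validation_error("charge variant must be 1 or 2")
  ion <- if (charge == 1) "Na+" else "M2+"
  nm <- function(s) sub("Na\\+", ion, s)
  states <- data.frame(
    name = nm(c("IF(H+)", "OF(H+)", "OF(0)", "OF(Na+)", "IF(Na+)", "IF(0)")),
    conformation = c("IF", "OF", "OF", "OF", "IF", "IF"),
    `site:s` = c("H+", "H+", "", ion, ion, ""),
    check.names = FALSE)
  ed <- antiporter_input_rates()
  ed$source <- nm(ed$source); ed$target <- nm(ed$target)
  ed$ligand <- c(NA, "H+", ion, NA, ion, "H+", NA)
  ed$order <- ifelse(is.na(ed$ligand), 1, 2)
  ed$side <- c(NA, "out", "out", NA, "in", "in", NA)
  # charge moved from out to in when traversing source -> target
  ed$charge <- c(-1, 0, 0, charge, 0, 0, 0)
  if (leak == "none") ed <- ed[-7, ]
  if (leak == "large") {
    ed$k_fwd[7] <- 1000; ed$k_rev[7] <- 1350
    ed$k_fwd_sigma[7] <- 316.2; ed$k_rev_sigma[7] <- 316.2
  }
  ref <- condition_set(concentrations = stats::setNames(list(0.1), ion), pH = 8)
  state_graph(states, ed, reference_state = nm("IF(H+)"),
              reference_condition = ref)
}

#' Published microscopic pKa set of the DTPA three-site model
#'
#' Named by `"<from> <to>"` binary state labels (terminal/central/terminal
#' digits); these are the inferred values reported for the full NMR data set.
#'
#' @return named numeric vector of 12 pKa values.
#' @export
dtpa_pka_table <- function() {
  c("000 001" = 9.0, "000 010" = 10.1, "000 100" = 9.0,
    "001 011" = 9.0, "001 101" = 9.8, "010 011" = 7.9,
    "010 110" = 7.9, "100 101" = 9.8, "100 110" = 9.0,
    "011 111" = 5.5, "101 111" = 4.7, "110 111" = 5.5)
}

#' DTPA cube model with synthetic titration curves
#'
#' Builds the 8-state protonation cube at a given pKa table (default: the
#' reference inferred set) and, optionally, synthetic titration curves
#' (central-site and mean-terminal-site occupancy versus pH) computed through
#' the forward model. These synthetic curves stand in for the digitized NMR
#' training data in tests. A pKa set whose cycle sums do not close triggers a
#' warning; the potential solve reconciles it.
#'
#' @param pka named pKa vector as in [dtpa_pka_table()].
#' @param curves logical; also return synthetic curves?
#' @param pH_grid pH grid for the synthetic curves (default 2 to 12 by 0.25).
#' @return a [state_graph()], or (with `curves = TRUE`) a list with elements
#'   `graph` and `curves` (named list of [observable_curve()]s, labels
#'   `"site:N2"` and `"sites_mean:N1,N3"`).
#' @export
generate_dtpa <- function(pka = dtpa_pka_table(), curves = FALSE,
                          pH_grid = seq(2, 12, by = 0.25)) {
  g <- dtpa_model_builder(pka = pka)
  resid <- vapply(cycle_basis(g), function(cyc) {
    s <- 0
    for (k in seq_len(length(cyc) - 1L)) {
      fe <- find_edge(g, cyc[k], cyc[k + 1L])
      s <- s + fe$sign * g$edges$dg[fe$index]
    }
    s
  }, 0)
  if (any(abs(resid) > 1e-9))
    warning("pKa set violates cycle closure (worst residual ",
            signif(resid[which.max(abs(resid))], 3),
            " kT on ", sum(abs(resid) > 1e-9), " basis cycle(s)); ",
            "the potential solve will reconcile it", call. = FALSE)
  if (!curves) return(g)
  specs <- list(central = "site:N2", terminal = "sites_mean:N1,N3")
  dummy <- lapply(specs, function(sp)
    observable_curve(pH_grid, rep(0, length(pH_grid)), sp))
  obs <- titration_observable(g, dummy)
  G <- make_dg_solver(g)(g$edges$dg)
  y <- obs(G)
  trn <- lapply(names(specs), function(nm)
    observable_curve(pH_grid, y[[nm]], specs[[nm]]))
  names(trn) <- names(specs)
  list(graph = g, curves = trn)
}

#' Random connected test graph
#'
#' A random spanning tree plus random extra edges, Gaussian free-energy
#' differences (sd 2 kT) and uniform positive uncertainties; reproducible by
#' seed. Used for oracle comparisons of the potential solver.
#'
#' @param n_states,n_edges graph size; `n_edges >= n_states - 1` and at most
#'   the number of distinct pairs.
#' @param seed random seed.
#' @return a [state_graph()].
#' @export
generate_random_graph <- function(n_states, n_edges, seed) {
  if (n_edges < n_states - 1L)
    validation_error("need at least n_states - 1 edges for connectivity")
  if (n_edges > n_states * (n_states - 1L) / 2L)
    validation_error("too many edges for a simple graph")
  set.seed(seed)
  nms <- paste0("S", seq_len(n_states))
  src <- tgt <- character(0)
  for (i in 2:n_states) {            # random tree
    j <- sample(i - 1L, 1L)
    src <- c(src, nms[j]); tgt <- c(tgt, nms[i])
  }
  key <- paste(pmin(src, tgt), pmax(src, tgt))
  while (length(src) < n_edges) {
    ij <- sample(n_states, 2L)
    k <- paste(min(nms[ij]), max(nms[ij]))
    if (!k %in% key) {
      src <- c(src, nms[ij[1]]); tgt <- c(tgt, nms[ij[2]]); key <- c(key, k)
    }
  }
  edges <- data.frame(source = src, target = tgt,
                      dg = stats::rnorm(n_edges, 0, 2),
                      dg_sigma = stats::runif(n_edges, 0.05, 0.5))
  state_graph(data.frame(name = nms), edges)
}
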