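#' State graphs for kinetic cycle models
#'
#' A `state_graph` holds the microstates of a kinetic/thermodynamic model and
#' the directed processes connecting them. Each state is a row of a data frame
#' with a unique `name`, arbitrary label columns (e.g. `N_protons`,
#' `conformation`) and binding-site occupancy columns prefixed `site:` whose
#' entries name the bound ligand (empty when vacant). Each edge connects
#' `source` to `target` and carries either a standard-state free-energy
#' difference `dg` (kT, meaning G(target) - G(source)) with its standard error
#' `dg_sigma`, or a forward/backward rate pair `k_fwd`/`k_rev` (1/s, defined at
#' the graph's reference condition) with errors. Ligand-binding processes
#' (reaction order 2) name their `ligand`; the binding direction is inferred
#' from the site occupancies of the two states. `charge` is the signed number
#' of elementary charges moved from the outside to the inside of the membrane
#' when traversing source -> target (0 for non-electrogenic steps) and
#' `voltage_split` the fractional barrier position (default 0.5). `side` marks
#' which bath an order-2 edge binds from (`in`/`out`) in transporter models.
#'
#' @param states data frame with at least a `name` column.
#' @param edges data frame with `source`, `target` and the optional columns
#'   above.
#' @param reference_state state pinned to G = 0; defaults to the first state.
#' @param reference_condition [condition_set()] at which rate inputs are
#'   defined; defaults to the standard state (all concentrations 1 M, pH 0,
#'   no voltage).
#' @return object of class `state_graph`.
#' @seealso [load_state_graph()], [validate_graph()], [solve_potentials()]
#' @export
state_graph <- function(states, edges, reference_state = NULL,
                        reference_condition = NULL) {
  states <- as.data.frame(states, stringsAsFactors = FALSE, check.names = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"name" %in% names(states)) format_error("states table missing column 'name'")
  states$name <- as.character(states$name)
  if (anyDuplicated(states$name))
    validation_error("duplicate state names in states table")
  for (col in c("source", "target"))
    if (!col %in% names(edges)) format_error(paste0("edges table missing column '", col, "'"))

  defaults <- list(dg = NA_real_, dg_sigma = NA_real_,
                   k_fwd = NA_real_, k_fwd_sigma = NA_real_,
                   k_rev = NA_real_, k_rev_sigma = NA_real_,
                   ligand = NA_character_, order = NA_real_, charge = 0,
                   side = NA_character_, voltage_split = 0.5,
                   symmetry_group = NA_character_)
  for (nm in names(defaults))
    if (!nm %in% names(edges)) edges[[nm]] <- defaults[[nm]]
  num_cols <- c("dg", "dg_sigma", "k_fwd", "k_fwd_sigma", "k_rev", "k_rev_sigma",
                "order", "charge", "voltage_split")
  for (nm in num_cols) edges[[nm]] <- num_or_na(edges[[nm]])
  edges$charge[is.na(edges$charge)] <- 0
  edges$voltage_split[is.na(edges$voltage_split)] <- 0.5
  for (nm in c("source", "target", "ligand", "side", "symmetry_group"))
    edges[[nm]] <- chr_or_na(edges[[nm]])
  edges$order[is.na(edges$order)] <- ifelse(is.na(edges$ligand[is.na(edges$order)]), 1, 2)

  unknown <- setdiff(c(edges$source, edges$target), states$name)
  if (length(unknown))
    validation_error(paste0("edge references unknown state(s): ",
                            paste(unknown, collapse = ", ")))

  pair_key <- apply(cbind(pmin(edges$source, edges$target),
                          pmax(edges$source, edges$target)), 1, paste, collapse = "|")
  if (anyDuplicated(pair_key))
    validation_error(paste0("parallel edges between the same state pair: ",
                            pair_key[duplicated(pair_key)][1]))

  has_dg <- !is.na(edges$dg)
  has_rates <- !is.na(edges$k_fwd) & !is.na(edges$k_rev)
  bad <- which(!(has_dg | has_rates))
  if (length(bad))
    validation_error(paste0("edge ", edges$source[bad[1]], " -> ", edges$target[bad[1]],
                            " has neither a free-energy difference nor a rate pair"))
  both <- which(has_dg & has_rates)
  if (length(both))
    validation_error(paste0("edge ", edges$source[both[1]], " -> ", edges$target[both[1]],
                            " has both a free-energy difference and a rate pair; give one"))
  for (nm in c("k_fwd", "k_fwd_sigma", "k_rev", "k_rev_sigma")) {
    v <- edges[[nm]]
    if (any(!is.na(v) & v <= 0))
      validation_error(paste0("column ", nm, " must be strictly positive where present"))
  }
  if (any(!is.na(edges$dg_sigma) & edges$dg_sigma <= 0))
    validation_error("dg_sigma must be strictly positive where present")
  bad_order <- which(!( (edges$order == 2 & !is.na(edges$ligand)) |
                        (edges$order == 1 & is.na(edges$ligand)) ))
  if (length(bad_order))
    validation_error(paste0("edge ", edges$source[bad_order[1]], " -> ",
                            edges$target[bad_order[1]],
                            ": order 2 requires a ligand and order 1 forbids one"))

  if (is.null(reference_state)) reference_state <- states$name[1]
  if (!reference_state %in% states$name)
    validation_error(paste0("unknown reference state: ", reference_state))
  if (is.null(reference_condition))
    reference_condition <- condition_set(pH = 0)
  g <- structure(list(states = states, edges = edges,
                      reference_state = reference_state,
                      reference_condition = reference_condition),
                 class = "state_graph")
  comps <- graph_components(g)
  if (max(comps) > 1L) {
    parts <- split(states$name, comps)
    validation_error(paste0("state graph is disconnected; components: ",
                            paste(vapply(parts, paste, "", collapse = ","),
                                  collapse = " | ")))
  }
  g$edges$stoich <- edge_stoichiometry(g)
  g
}

#' @export
print.state_graph <- function(x, ...) {
  cat("<state_graph> ", nrow(x$states), " states, ", nrow(x$edges), " edges; ",
      "cycle basis size ", cycle_basis_size(x), "\n", sep = "")
  cat("  reference state:", x$reference_state, "\n")
  invisible(x)
}

# --- structural helpers -----------------------------------------------------

as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    g$edges[, c("source", "target")], directed = FALSE,
    vertices = data.frame(name = g$states$name))
}

graph_components <- function(g) {
  igraph::components(as_igraph(g))$membership[g$states$name]
}

#' Number of independent cycles (|E| - |V| + 1 for a connected graph)
#' @param g a [state_graph()].
#' @return integer cycle basis size.
#' @export
cycle_basis_size <- function(g) nrow(g$edges) - nrow(g$states) + 1L

# list of closed walks (state-name vectors, first == last), one per non-tree
# edge of a BFS spanning tree
#' Fundamental cycle basis of the graph
#' @param g a [state_graph()].
#' @return list of character vectors; each is a closed state walk.
#' @export
cycle_basis <- function(g) {
  ig <- as_igraph(g)
  mst <- igraph::mst(ig)
  in_tree <- rep(FALSE, nrow(g$edges))
  tree_ends <- igraph::as_edgelist(mst)
  tree_key <- apply(cbind(pmin(tree_ends[, 1], tree_ends[, 2]),
                          pmax(tree_ends[, 1], tree_ends[, 2])), 1, paste, collapse = "|")
  edge_key <- apply(cbind(pmin(g$edges$source, g$edges$target),
                          pmax(g$edges$source, g$edges$target)), 1, paste, collapse = "|")
  in_tree <- edge_key %in% tree_key
  lapply(which(!in_tree), function(e) {
    p <- igraph::shortest_paths(mst, from = g$edges$target[e],
                                to = g$edges$source[e])$vpath[[1]]
    c(g$edges$source[e], names(p))
  })
}

# per-state count of bound ligand molecules, from site: columns
state_ligand_count <- function(g, ligand) {
  site_cols <- grep("^site:", names(g$states), value = TRUE)
  if (!length(site_cols)) return(rep(NA_real_, nrow(g$states)))
  occ <- as.matrix(g$states[, site_cols, drop = FALSE])
  rowSums(matrix(occ %in% ligand, nrow = nrow(occ)))
}

# +1 if traversing source -> target binds one ligand molecule, -1 if it
# releases one; NA for order-1 edges
edge_stoichiometry <- function(g) {
  st <- rep(NA_real_, nrow(g$edges))
  idx <- match(g$edges$source, g$states$name)
  jdx <- match(g$edges$target, g$states$name)
  for (e in which(g$edges$order == 2)) {
    n <- state_ligand_count(g, g$edges$ligand[e])
    if (all(is.na(n)))
      validation_error(paste0("order-2 edge ", g$edges$source[e], " -> ",
                              g$edges$target[e], " requires 'site:' occupancy ",
                              "columns to determine the binding direction"))
    d <- n[jdx[e]] - n[idx[e]]
    if (!d %in% c(-1, 1))
      validation_error(paste0("edge ", g$edges$source[e], " -> ", g$edges$target[e],
                              " is order 2 but the ", g$edges$ligand[e],
                              " count changes by ", d))
    st[e] <- d
  }
  st
}

# locate an edge between two states; returns index and orientation (+1 when
# stored as from -> to, -1 when stored reversed)
find_edge <- function(g, from, to) {
  e <- which(g$edges$source == from & g$edges$target == to)
  if (length(e)) return(list(index = e[1], sign = 1))
  e <- which(g$edges$source == to & g$edges$target == from)
  if (length(e)) return(list(index = e[1], sign = -1))
  validation_error(paste0("no edge between ", from, " and ", to))
}

# --- file I/O ---------------------------------------------------------------

GRAPH_CSV_MAP <- c(source = "state1", target = "state2", dg = "dg",
                   dg_sigma = "dg_sigma", k_fwd = "k12", k_fwd_sigma = "k12_sigma",
                   k_rev = "k21", k_rev_sigma = "k21_sigma", ligand = "ligand",
                   order = "order", charge = "charge", side = "side",
                   voltage_split = "voltage_split", symmetry_group = "symmetry_group")

#' Load a state graph from CSV definitions
#'
#' `states_path` must have a `name` column; label columns and `site:` occupancy
#' columns are carried through. `graph_path` must have columns
#' `state1,state2`, plus either `dg` (with `dg_sigma`) or the rate columns
#' `k12,k12_sigma,k21,k21_sigma`, and optionally
#' `ligand,order,charge,side,voltage_split,symmetry_group`; empty cells mean
#' "not set".
#'
#' @param states_path,graph_path CSV file paths.
#' @param reference_state optional state name pinned to G = 0.
#' @param reference_condition optional [condition_set()] (or path to a
#'   conditions YAML file) at which rate inputs are defined.
#' @return a validated [state_graph()].
#' @export
load_state_graph <- function(states_path, graph_path, reference_state = NULL,
                             reference_condition = NULL) {
  for (p in c(states_path, graph_path))
    if (!file.exists(p)) format_error(paste0("input file not found: ", p))
  states <- utils::read.csv(states_path, stringsAsFactors = FALSE,
                            check.names = FALSE, colClasses = "character")
  graph <- utils::read.csv(graph_path, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  for (col in c("state1", "state2"))
    if (!col %in% names(graph)) format_error(paste0("graph file missing column '", col, "'"))
  edges <- data.frame(row.names = seq_len(nrow(graph)))
  for (internal in names(GRAPH_CSV_MAP)) {
    csv <- GRAPH_CSV_MAP[[internal]]
    if (csv %in% names(graph)) edges[[internal]] <- graph[[csv]]
  }
  if (is.character(reference_condition))
    reference_condition <- load_conditions(reference_condition)
  state_graph(states, edges, reference_state = reference_state,
              reference_condition = reference_condition)
}

fmt_cell <- function(x) {
  if (is.numeric(x)) ifelse(is.na(x), "", sprintf("%.17g", x))
  else ifelse(is.na(x), "", as.character(x))
}

#' Write a state graph to CSV files
#'
#' Writes `states.csv` and `graph.csv` into `dir` using the same dialect as
#' [load_state_graph()]; numeric fields round-trip at full double precision.
#'
#' @param g a [state_graph()].
#' @param dir output directory (created if missing).
#' @return invisibly, the two file paths.
#' @export
write_state_graph <- function(g, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- file.path(dir, "states.csv")
  gp <- file.path(dir, "graph.csv")
  st <- g$states
  for (nm in names(st)) st[[nm]] <- fmt_cell(st[[nm]])
  utils::write.csv(st, sp, row.names = FALSE, quote = FALSE)
  ed <- g$edges
  out <- data.frame(row.names = seq_len(nrow(ed)))
  for (internal in names(GRAPH_CSV_MAP))
    out[[GRAPH_CSV_MAP[[internal]]]] <- fmt_cell(ed[[internal]])
  utils::write.csv(out, gp, row.names = FALSE, quote = FALSE)
  invisible(c(states = sp, graph = gp))
}

#' Diagnostics report for a state graph
#'
#' Reports connectivity, cycle basis size, edges lacking uncertainties and
#' symmetry-group membership. Reporting only; loaders raise on hard errors.
#'
#' @param g a [state_graph()].
#' @return object of class `graph_diagnostics`.
#' @export
validate_graph <- function(g) {
  ed <- g$edges
  no_sigma <- which((!is.na(ed$dg) & is.na(ed$dg_sigma)) |
                    (!is.na(ed$k_fwd) & (is.na(ed$k_fwd_sigma) | is.na(ed$k_rev_sigma))))
  groups <- split(seq_len(nrow(ed)), ed$symmetry_group)
  structure(list(
    n_states = nrow(g$states), n_edges = nrow(ed),
    connected = max(graph_components(g)) == 1L,
    cycle_basis_size = cycle_basis_size(g),
    edges_without_uncertainty = no_sigma,
    symmetry_groups = groups,
    note = if (cycle_basis_size(g) == 0L) "no closure constraints (tree)" else NULL
  ), class = "graph_diagnostics")
}

#' @export
print.graph_diagnostics <- function(x, ...) {
  cat("<graph_diagnostics>\n")
  cat("  states:", x$n_states, " edges:", x$n_edges, "\n")
  cat("  connected:", x$connected, " cycle basis size:", x$cycle_basis_size, "\n")
  if (length(x$edges_without_uncertainty))
    cat("  edges lacking uncertainties:",
        paste(x$edges_without_uncertainty, collapse = ", "), "\n")
  if (length(x$symmetry_groups))
    cat("  symmetry groups:", length(x$symmetry_groups), "\n")
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}
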