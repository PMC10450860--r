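ln10 <- log(10)

test_that("shift_edge_dg applies the mass-action term with the right sign", {
  cs <- condition_set(concentrations = list(X = 0.5), pH = 7)
  # pKa 7 site at pH 7: shifted protonation dg is 0
  expect_equal(shift_edge_dg(-ln10 * 7, "H+", 2, cs, "binding"), 0)
  # order 1 untouched
  expect_equal(shift_edge_dg(1.23, NA, 1, cs), 1.23)
  # doubling [X] lowers binding dg by exactly ln 2
  d1 <- shift_edge_dg(-1, "X", 2, cs, "binding")
  cs2 <- condition_set(concentrations = list(X = 1.0), pH = 7)
  expect_equal(d1 - shift_edge_dg(-1, "X", 2, cs2, "binding"), log(2))
  # unbinding direction gets the opposite sign
  expect_equal(shift_edge_dg(1, "X", 2, cs, "unbinding"),
               -shift_edge_dg(-1, "X", 2, cs, "binding"))
  # dG_bind([X] = KD) = 0: dg_std = ln KD, evaluated at [X] = KD
  kd <- 0.024
  csk <- condition_set(concentrations = list(X = kd))
  expect_equal(shift_edge_dg(log(kd), "X", 2, csk, "binding"), 0)
  expect_error(shift_edge_dg(-1, "Y", 2, cs, "binding"), "Y")
})

test_that("sodium KD values derive from the consistent antiporter dgs", {
  g <- generate_antiporter()
  sol <- solve_potentials(g)
  # binding direction IF(0) -> IF(Na+) is the reverse of the stored edge
  e_if <- kinconsist:::find_edge(g, "IF(Na+)", "IF(0)")
  dg_bind_if <- -sol$consistent_dg[e_if$index]    # at 100 mM
  expect_equal(0.1 * exp(dg_bind_if) * 1e3, 24, tolerance = 0.5 / 24)
  e_of <- kinconsist:::find_edge(g, "OF(0)", "OF(Na+)")
  expect_equal(0.1 * exp(sol$consistent_dg[e_of$index]) * 1e3, 52,
               tolerance = 0.5 / 52)
})

test_that("conditioned potentials follow pH and are spanning-tree independent", {
  ts <- generate_two_site()
  sol <- solve_potentials(ts)
  cp7 <- condition_potentials(sol, condition_set(pH = 7))
  expect_equal(unname(cp7$g_at_condition), rep(0, 4), tolerance = 1e-12)
  cp8 <- condition_potentials(sol, condition_set(pH = 8))
  G <- cp8$g_at_condition
  expect_equal(unname(G[c("10", "01")] - G["00"]), rep(ln10, 2),
               tolerance = 1e-12)
  expect_equal(unname(G["11"] - G["00"]), 2 * ln10, tolerance = 1e-12)
  # tree independence on a cyclic graph: reorder edges (different tree) and
  # compare
  g <- generate_antiporter()
  sola <- solve_potentials(g)
  gb <- g; perm <- c(7, 3, 5, 1, 6, 2, 4)
  gb$edges <- g$edges[perm, ]
  solb <- sola; solb$consistent_dg <- sola$consistent_dg[perm]; solb$graph <- gb
  cs <- condition_set(concentrations = list("Na+" = 0.02), pH = 6.5)
  expect_equal(condition_potentials(sola, cs)$g_at_condition,
               condition_potentials(solb, cs, gb)$g_at_condition,
               tolerance = 1e-10)
})

test_that("unbalanced cycles are detected when conditioning", {
  # square cycle where one parallel branch binds and the other does not
  st <- data.frame(name = c("A", "B", "C"),
                   `site:s` = c("", "X", ""), check.names = FALSE)
  ed <- data.frame(source = c("A", "B", "A"), target = c("B", "C", "C"),
                   dg = c(-1, 1, 0), dg_sigma = 0.1,
                   ligand = c("X", "X", NA), order = c(2, 2, 1))
  g <- state_graph(st, ed)
  sol <- solve_potentials(g)
  # balanced: A->B binds, B->C releases; closes for any [X]
  expect_silent(condition_potentials(sol, condition_set(concentrations = list(X = 0.3))))
  ed2 <- ed; ed2$ligand[2] <- NA; ed2$order[2] <- 1
  g2 <- state_graph(st, ed2)
  sol2 <- solve_potentials(g2)
  expect_error(condition_potentials(sol2, condition_set(concentrations = list(X = 0.3))),
               "unbalanced cycle")
})

test_that("Boltzmann probabilities match closed forms and stay normalized", {
  expect_equal(unname(state_probabilities(c(A = 1, B = 1))), c(0.5, 0.5))
  expect_equal(unname(state_probabilities(c(A = 0, B = log(3)))), c(0.75, 0.25))
  # extreme spreads: no overflow, exact normalization
  p <- state_probabilities(c(a = 0, b = 500, c = -500))
  expect_equal(sum(p), 1)
  expect_equal(unname(p["c"]), 1, tolerance = 1e-12)
  ts <- generate_two_site()
  cp <- condition_potentials(solve_potentials(ts), condition_set(pH = 7))
  p4 <- state_probabilities(cp)
  expect_equal(sum(p4), 1, tolerance = 1e-12)
  expect_equal(unname(p4["10"] + p4["01"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(p4["00"]), 0.25, tolerance = 1e-12)
})

test_that("macrostate free energies reduce, cancel and ignore high-G members", {
  G <- c(A = 0.3, B = 1.7, C = -0.4)
  expect_equal(macrostate_dg(G, "A", "B"), 1.4, tolerance = 1e-12)
  expect_equal(macrostate_dg(G, c("A", "B"), "C"),
               -macrostate_dg(G, "C", c("A", "B")), tolerance = 1e-12)
  G2 <- c(G, D = G[["C"]] + 50)
  expect_lt(abs(macrostate_dg(G2, "A", c("C", "D")) -
                macrostate_dg(G, "A", "C")), 1e-10)
  expect_error(macrostate_dg(G, character(0), "A"), "non-empty")
  expect_error(macrostate_dg(G, c("A", "B"), c("B", "C")), "disjoint")
})

test_that("titration scans reproduce the two-site model", {
  ts <- generate_two_site()
  sol <- solve_potentials(ts)
  grid <- condition_grid(condition_set(pH = 7), "pH", seq(2, 12, by = 0.1))
  tr <- titration_scan(sol, grid, macrostate_label = "N_protons")
  i7 <- which(tr$x == 7)
  expect_equal(tr$total_occupancy[i7], 1.0, tolerance = 1e-10)
  expect_equal(unname(tr$macrostate["1", i7]), 0.5, tolerance = 1e-10)
  expect_equal(unname(tr$macrostate["0", i7]), 0.25, tolerance = 1e-10)
  # saturation limits
  expect_equal(tr$total_occupancy[1], 2, tolerance = 1e-3)
  expect_equal(tr$total_occupancy[length(tr$x)], 0, tolerance = 1e-3)
  expect_true(all(abs(colSums(tr$P) - 1) < 1e-12))
  expect_error(titration_scan(sol, grid, sites = "nope"), "unknown site")
})

test_that("cooperativity suppresses N=1 and anticooperativity flattens uptake", {
  grid <- condition_grid(condition_set(pH = 7), "pH", seq(2, 12, by = 0.1))
  res <- lapply(c("independent", "cooperative", "anticooperative"),
                function(v) titration_scan(solve_potentials(generate_two_site(v)),
                                           grid, macrostate_label = "N_protons"))
  names(res) <- c("ind", "coop", "anti")
  i7 <- which(res$ind$x == 7)
  expect_lt(res$coop$macrostate["1", i7], res$ind$macrostate["1", i7])
  expect_gt(res$anti$macrostate["1", i7], res$ind$macrostate["1", i7])
  expect_lt(max(abs(res$anti$uptake)), max(abs(res$ind$uptake)))
  expect_gt(max(abs(res$coop$uptake)), max(abs(res$ind$uptake)))
})

test_that("antiporter sodium-binding free energy plateaus at high pH", {
  g <- generate_antiporter()
  sol <- solve_potentials(g)
  bound <- c("IF(Na+)", "OF(Na+)")
  free <- c("IF(0)", "OF(0)", "IF(H+)", "OF(H+)")
  dg_at <- function(pH) {
    cp <- condition_potentials(sol, condition_set(
      concentrations = list("Na+" = 0.1), pH = pH))
    macrostate_dg(cp, free, bound)
  }
  vals <- vapply(c(4, 5, 6, 9, 10, 11), dg_at, 0)
  # strongly pH dependent below pH 7, flat above
  expect_gt(abs(vals[2] - vals[1]), 0.5)
  expect_lt(abs(vals[6] - vals[4]), 0.05)
  # weak binding at low pH: less favourable than at high pH
  expect_gt(vals[1], vals[6])
})
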