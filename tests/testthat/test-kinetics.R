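test_that("voltage factors follow the Eyring split and pair-ratio contract", {
  expect_equal(voltage_rate(100, 1, 1, 0), 100)
  # beta q dPsi / 2 = 1  =>  forward scaled by exp(-1)
  vT <- 8.617333262e-5 * 298.15
  expect_equal(voltage_rate(100, 1, 1, 2 * vT / 2 * 2, split = 0.5),
               100 * exp(-1))
  # pair ratio contributes exp(-beta q dPsi) regardless of the split
  for (split in c(0.2, 0.5, 0.8)) {
    f <- voltage_rate(50, 1, 2, 0.05, split, "forward")
    r <- voltage_rate(80, 1, 2, 0.05, split, "reverse")
    expect_equal((f / 50) / (r / 80), exp(-2 * 0.05 / vT), tolerance = 1e-12)
  }
  expect_error(voltage_rate(1, 1, 1, 0, split = 1.2), "split")
})

test_that("the rate matrix is a generator reproducing the consistent rates", {
  kin <- make_consistent(generate_antiporter())
  rm_ <- build_rate_matrix(kin, kin$reference_condition)
  Q <- rm_$Q
  expect_equal(max(abs(colSums(Q))), 0, tolerance = 1e-10 * max(Q))
  offdiag <- Q; diag(offdiag) <- 0
  expect_true(all(offdiag >= 0))
  # entries at the reference condition equal the consistent pseudo-first-order
  # rates of the reference block
  for (e in seq_len(nrow(kin$edges))) {
    i <- kin$edges$source[e]; j <- kin$edges$target[e]
    expect_equal(Q[j, i], kin$edges$k_fwd[e], tolerance = 1e-10)
    expect_equal(Q[i, j], kin$edges$k_rev[e], tolerance = 1e-10)
  }
})

test_that("zero ligand concentration still yields a valid generator", {
  kin <- make_consistent(generate_antiporter())
  cs <- condition_set(concentrations = list("Na+" = 1e-300), pH = 8)
  Q <- build_rate_matrix(kin, cs)$Q
  expect_equal(Q["OF(Na+)", "OF(0)"], 0, tolerance = 1e-280)
  expect_equal(max(abs(colSums(Q))), 0, tolerance = 1e-10 * max(Q))
})

test_that("equilibrium steady state is Boltzmann with zero edge fluxes", {
  g <- generate_antiporter()
  kin <- make_consistent(g)
  ss <- steady_state(build_rate_matrix(kin, g$reference_condition))
  pb <- state_probabilities(condition_potentials(kin$solution,
                                                 g$reference_condition))
  expect_equal(ss$populations, pb, tolerance = 1e-10)
  max_rate <- max(kin$edges$k_fwd, kin$edges$k_rev)
  expect_true(all(abs(ss$edge_fluxes$flux) < 1e-10 * max_rate))
  expect_equal(sum(ss$populations), 1, tolerance = 1e-12)
})

test_that("steady state matches long-time master-equation integration", {
  # moderate rate spread: the exp(Qt) oracle is accurate, assert 1e-8/component
  ukin <- uniporter_kinetics()
  ucs <- condition_set(concentrations = list(X = c("in" = 0.002, "out" = 0.08)))
  uQ <- build_rate_matrix(ukin, ucs)$Q
  uss <- steady_state(build_rate_matrix(ukin, ucs))
  expect_lt(max(abs(unname(uss$populations) - oracle_steady_state(uQ))), 1e-8)
  # stiff antiporter (rates span 3e8 .. 1e2): the oracle itself carries
  # ~1e-7 rounding, compare at that level; flux balance carries the tight bound
  kin <- make_consistent(generate_antiporter())
  cs <- condition_set(concentrations = list("Na+" = c("in" = 0.01, "out" = 0.1)),
                      pH = c("in" = 7.4, "out" = 7), voltage = -0.05)
  Q <- build_rate_matrix(kin, cs)$Q
  ss <- steady_state(build_rate_matrix(kin, cs))
  expect_lt(max(abs(unname(ss$populations) - oracle_steady_state(Q, t_total = 1))),
            1e-6)
  expect_lt(max(abs(Q %*% ss$populations)), 1e-10 * max(Q))
})

test_that("flux balance holds at every state out of equilibrium", {
  kin <- make_consistent(generate_antiporter())
  cs <- condition_set(concentrations = list("Na+" = c("in" = 0.01, "out" = 0.3)),
                      pH = c("in" = 7.4, "out" = 7), voltage = 0.03)
  ss <- steady_state(build_rate_matrix(kin, cs))
  g <- kin$graph
  max_rate <- max(kin$edges$k_fwd, kin$edges$k_rev)
  for (s in g$states$name) {
    inflow <- sum(ss$edge_fluxes$flux[ss$edge_fluxes$target == s]) -
      sum(ss$edge_fluxes$flux[ss$edge_fluxes$source == s])
    expect_lt(abs(inflow), 1e-10 * max_rate)
  }
})

test_that("single-cycle networks carry one cycle flux on every edge", {
  kin <- make_consistent(generate_antiporter(leak = "none"))
  cs <- condition_set(concentrations = list("Na+" = c("in" = 0.01, "out" = 0.1)),
                      pH = c("in" = 7.4, "out" = 7))
  ss <- steady_state(build_rate_matrix(kin, cs))
  # orient fluxes along the outer cycle
  cyc <- antiporter_outer_cycle()
  fl <- vapply(seq_along(cyc), function(k) {
    to <- cyc[if (k == length(cyc)) 1 else k + 1]
    reporter_flux(ss, c(cyc[k], to))
  }, 0)
  expect_lt(diff(range(fl)), 1e-8 * max(abs(fl)))
  # zero drive => zero flux; sign(flux) follows sign(chi)
  chi <- cycle_drive(kin, cyc, cs)
  expect_equal(sign(fl[1]), sign(chi))
  eq <- condition_set(concentrations = list("Na+" = 0.1), pH = 8)
  expect_lt(abs(reporter_flux(steady_state(build_rate_matrix(kin, eq)),
                              cyc[1:2])), 1e-8)
})

test_that("reducible networks are rejected", {
  st <- data.frame(name = c("A", "B", "C"))
  ed <- data.frame(source = c("A", "B"), target = c("B", "C"),
                   k_fwd = c(1, 5), k_rev = c(2, 5),
                   k_fwd_sigma = 0.1, k_rev_sigma = 0.1)
  kin <- make_consistent(state_graph(st, ed))
  kin$edges$k_fwd0[2] <- 0; kin$edges$k_rev0[2] <- 0   # cut the bridge
  expect_error(steady_state(build_rate_matrix(kin, condition_set())),
               "reducible")
})

test_that("electroneutral turnover sign is voltage independent; electrogenic reverses", {
  kin <- make_consistent(generate_antiporter())
  rep_edge <- c("IF(H+)", "OF(H+)")
  base <- condition_set(concentrations = list("Na+" = c("in" = 0.01, "out" = 0.1)),
                        pH = c("in" = 7.4, "out" = 7))
  signs <- vapply(seq(-0.1, 0.1, by = 0.025), function(v) {
    cs <- base; cs$voltage <- v
    sign(reporter_flux(steady_state(build_rate_matrix(kin, cs)), rep_edge))
  }, 0)
  expect_true(all(signs == signs[1]))
  # divalent driving ion, no gradient, 0 mV: protons flow in reverse
  kin2 <- make_consistent(generate_antiporter(charge = 2))
  cs2 <- condition_set(concentrations = list("M2+" = c("in" = 0.01, "out" = 0.01)),
                       pH = c("in" = 7.4, "out" = 7))
  expect_lt(reporter_flux(steady_state(build_rate_matrix(kin2, cs2)), rep_edge), 0)
})

test_that("turnover scans: zero at equilibrium, monotone in the sodium gradient", {
  kin <- make_consistent(generate_antiporter())
  base <- condition_set(concentrations = list("Na+" = c("in" = 0.01, "out" = 0.01)),
                        pH = c("in" = 7, "out" = 7))
  grid <- condition_grid(base, "Na+", c(0.01, 0.03, 0.1, 0.3, 1), side = "out")
  tv <- turnover_scan(kin, grid)
  expect_true(all(diff(tv$turnover) > 0))
  eq_grid <- condition_grid(base, "voltage", 0)
  expect_lt(abs(turnover_scan(kin, eq_grid)$turnover[1]), 1e-8)
  # default reporter is the proton-bound conformational edge
  expect_equal(kinconsist:::default_reporter(kin), c("IF(H+)", "OF(H+)"))
})

test_that("small leak barely changes turnover; large leak degrades coupling", {
  conds <- condition_set(concentrations = list("Na+" = c("in" = 0.01, "out" = 0.1)),
                         pH = c("in" = 7.4, "out" = 7))
  tv <- vapply(c("none", "small", "large"), function(l) {
    kin <- make_consistent(generate_antiporter(leak = l))
    reporter_flux(steady_state(build_rate_matrix(kin, conds)),
                  c("IF(H+)", "OF(H+)"))
  }, 0)
  expect_equal(tv[["small"]], tv[["none"]], tolerance = 0.05)
  expect_gt(abs(tv[["large"]] - tv[["none"]]) / abs(tv[["none"]]), 0.05)
})
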