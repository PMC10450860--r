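# independent oracles used to freeze expected values; kept deliberately
# different from the implementation paths they check

# dense normal-equations weighted least squares via pseudoinverse of the
# full (singular) system, then gauge shift to the reference state
oracle_solve_wls <- function(g) {
  B <- matrix(0, nrow(g$edges), nrow(g$states),
              dimnames = list(NULL, g$states$name))
  for (e in seq_len(nrow(g$edges))) {
    B[e, g$edges$source[e]] <- -1
    B[e, g$edges$target[e]] <- 1
  }
  w2 <- 1 / g$edges$dg_sigma^2
  A <- t(B) %*% (B * w2)
  b <- t(B) %*% (g$edges$dg * w2)
  G <- as.vector(MASS::ginv(A) %*% b)
  names(G) <- g$states$name
  G - G[g$reference_state]
}

# 1-D numeric minimization of the weighted distance to the consistency line
oracle_project <- function(k_fwd, k_rev, s_fwd, s_rev, dg) {
  K <- exp(-dg)
  obj <- function(kr) ((K * kr - k_fwd) / s_fwd)^2 + ((kr - k_rev) / s_rev)^2
  opt <- stats::optimize(obj, c(1e-12, 10 * max(k_fwd / K, k_rev)), tol = 1e-14)
  c(k_fwd = K * opt$minimum, k_rev = opt$minimum)
}

# long-time master-equation propagation from a uniform start, by scaling and
# squaring of the matrix exponential
oracle_steady_state <- function(Q, t_total = NULL) {
  M <- nrow(Q)
  if (is.null(t_total)) t_total <- 50 / min(abs(diag(Q)[diag(Q) != 0]))
  P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * t_total)))
  as.vector(P %*% rep(1 / M, M))
}

# tiny fixtures -------------------------------------------------------------

two_state_graph <- function(dg = 1, sigma = 0.1) {
  state_graph(data.frame(name = c("A", "B")),
              data.frame(source = "A", target = "B",
                         dg = dg, dg_sigma = sigma))
}

triangle_graph <- function(dg = c(1, 1, -2), sigma = c(1, 1, 1)) {
  state_graph(data.frame(name = c("A", "B", "C")),
              data.frame(source = c("A", "B", "C"),
                         target = c("B", "C", "A"),
                         dg = dg, dg_sigma = sigma))
}

# minimal 4-state uniporter (bind in -> carry -> release out -> return):
# moderate rate spread so the matrix-exponential oracle is itself accurate
uniporter_kinetics <- function() {
  st <- data.frame(name = c("E_in", "XE_in", "XE_out", "E_out"),
                   `site:s` = c("", "X", "X", ""), check.names = FALSE)
  ed <- data.frame(source = c("E_in", "XE_in", "XE_out", "E_out"),
                   target = c("XE_in", "XE_out", "E_out", "E_in"),
                   k_fwd = c(900, 120, 450, 80),
                   k_rev = c(300, 100, 700, 60),
                   k_fwd_sigma = c(30, 10, 20, 8),
                   k_rev_sigma = c(20, 10, 30, 6),
                   ligand = c("X", NA, "X", NA),
                   order = c(2, 1, 2, 1),
                   side = c("in", NA, "out", NA))
  ref <- condition_set(concentrations = list(X = 0.05))
  make_consistent(state_graph(st, ed, reference_condition = ref))
}

antiporter_outer_cycle <- function(ion = "Na+") {
  sub_ion <- function(s) sub("Na\\+", ion, s)
  sub_ion(c("IF(H+)", "OF(H+)", "OF(0)", "OF(Na+)", "IF(Na+)", "IF(0)"))
}
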