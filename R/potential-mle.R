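#' Maximum-likelihood state free energies on a potential graph
#'
#' Given per-edge free-energy differences \eqn{\Delta\bar G_{ij}} with standard
#' errors \eqn{\bar\sigma_{ij}}, finds the state free energies \eqn{\{G_i\}}
#' minimizing the weighted residual
#' \deqn{\sum_{(i,j)} \left(\frac{(G_j - G_i) - \Delta\bar G_{ij}}{\bar\sigma_{ij}}\right)^2,}
#' i.e. the weighted least-squares solution of the incidence system, solved
#' densely by QR. The solution is unique up to an additive constant on a
#' connected graph; it is returned shifted so the reference state is exactly 0.
#' The resulting edge differences `consistent_dg` satisfy cycle closure (the
#' Wegscheider condition) by construction.
#'
#' @param g a [state_graph()] whose every edge carries `dg` and `dg_sigma`.
#'   Edges given as rate pairs are converted first via [rates_to_difference()].
#' @return object of class `potential_solution` with elements `g` (named
#'   vector of state free energies, kT), `sigma_g`, `covariance` (kT^2, in the
#'   pseudoinverse gauge), `consistent_dg`, `residuals`
#'   (consistent minus input, per edge), and `graph`.
#' @references the per-state uncertainties come from the pseudoinverse of the
#'   Fisher information, see [state_uncertainties()].
#' @export
solve_potentials <- function(g) {
  eg <- edge_dg_inputs(g)
  M <- nrow(g$states); E <- nrow(g$edges)
  if (any(!is.finite(eg$sigma)) || any(eg$sigma <= 0))
    validation_error("every edge needs a finite positive dg_sigma (or rate sigmas)")
  B <- incidence_matrix(g)
  w <- 1 / eg$sigma
  fit <- qr(B * w)
  if (fit$rank < M - 1L)
    numeric_error("incidence system rank-deficient beyond the expected gauge mode")
  # pin the gauge by QR on the reduced system (drop reference column)
  ref <- match(g$reference_state, g$states$name)
  Bred <- (B * w)[, -ref, drop = FALSE]
  coef <- qr.coef(qr(Bred), eg$dg * w)
  G <- numeric(M)
  G[-ref] <- coef
  names(G) <- g$states$name
  cdg <- as.vector(B %*% G)
  unc <- state_uncertainties(g)
  structure(list(g = G, sigma_g = unc$sigma_g, covariance = unc$covariance,
                 consistent_dg = cdg, residuals = cdg - eg$dg,
                 input_dg = eg$dg, input_sigma = eg$sigma, graph = g),
            class = "potential_solution")
}

#' @export
print.potential_solution <- function(x, ...) {
  cat("<potential_solution> ", length(x$g), " states (reference '",
      x$graph$reference_state, "' = 0)\n", sep = "")
  print(data.frame(state = names(x$g), G_kT = round(x$g, 4),
                   sigma_kT = round(x$sigma_g, 4), row.names = NULL))
  invisible(x)
}

# E x M incidence matrix: -1 at source, +1 at target
incidence_matrix <- function(g) {
  M <- nrow(g$states); E <- nrow(g$edges)
  B <- matrix(0, E, M, dimnames = list(NULL, g$states$name))
  B[cbind(seq_len(E), match(g$edges$source, g$states$name))] <- -1
  B[cbind(seq_len(E), match(g$edges$target, g$states$name))] <- 1
  B
}

# per-edge (dg, sigma), converting rate pairs where necessary
edge_dg_inputs <- function(g) {
  ed <- g$edges
  dg <- ed$dg; sigma <- ed$dg_sigma
  need <- which(is.na(dg))
  for (e in need) {
    conv <- rates_to_difference(rate_pair(ed$k_fwd[e], ed$k_rev[e],
                                          ed$k_fwd_sigma[e], ed$k_rev_sigma[e]))
    dg[e] <- conv[["dg"]]
    sigma[e] <- conv[["sigma"]]
  }
  list(dg = dg, sigma = sigma)
}

#' Fisher information matrix of the free-energy likelihood
#'
#' Assembles the matrix with entries
#' \eqn{I_{nm} = \sum_{(i,j)} (2/\bar\sigma_{ij}^2)} times +1 on the diagonal
#' for states incident to the edge and -1 between its endpoints — i.e. twice
#' the \eqn{\bar\sigma^{-2}}-weighted graph Laplacian, following the
#' likelihood convention whose exponent carries no factor 1/2. Symmetric,
#' zero row sums, rank M-1 on a connected graph. The covariance in
#' [state_uncertainties()] uses the standard-Gaussian convention (half this
#' matrix), so that a single-edge graph reports its input sigma exactly.
#'
#' @inheritParams solve_potentials
#' @return M x M matrix in 1/kT^2.
#' @export
fisher_information <- function(g) {
  2 * weighted_laplacian(g)
}

weighted_laplacian <- function(g) {
  eg <- edge_dg_inputs(g)
  if (any(!is.finite(eg$sigma)) || any(eg$sigma <= 0))
    validation_error("every edge needs a finite positive dg_sigma (or rate sigmas)")
  B <- incidence_matrix(g)
  t(B) %*% (B / eg$sigma^2)
}

#' Per-state uncertainties and covariance of the potential solution
#'
#' The covariance is the Moore-Penrose pseudoinverse (via SVD, relative
#' singular-value cutoff `max(dim) * eps * s_max`) of the 1/sigma^2-weighted
#' graph Laplacian — the Hessian of the standard Gaussian negative
#' log-likelihood. Exactly one zero mode (the gauge) is expected for a
#' connected graph. `sigma_g[i]` is the square root of the i-th diagonal
#' element. Reported in the pseudoinverse gauge, not the fixed-reference gauge.
#'
#' @inheritParams solve_potentials
#' @return list with `sigma_g` (named vector, kT) and `covariance` (kT^2).
#' @export
state_uncertainties <- function(g) {
  H <- weighted_laplacian(g)
  s <- svd(H)
  cutoff <- max(dim(H)) * .Machine$double.eps * s$d[1]
  keep <- s$d > cutoff
  if (sum(!keep) != 1L)
    numeric_error(paste0("expected exactly one zero mode in the information matrix, found ",
                         sum(!keep)))
  dinv <- ifelse(keep, 1 / s$d, 0)
  C <- s$v %*% (dinv * t(s$u))
  dimnames(C) <- dimnames(H)
  list(sigma_g = stats::setNames(sqrt(pmax(diag(C), 0)), g$states$name),
       covariance = C)
}

#' Uncertainty of a consistent edge free-energy difference
#'
#' Returns \eqn{\sqrt{C_{ii} + C_{jj} - 2 C_{ij}}} for the edge's two states,
#' using the covariance of a [solve_potentials()] result. Gauge-free.
#'
#' @param sol a `potential_solution`.
#' @param from,to state names of the edge (either orientation).
#' @return standard error in kT.
#' @export
edge_sigma <- function(sol, from, to) {
  fe <- find_edge(sol$graph, from, to)   # errors if the edge does not exist
  i <- match(from, sol$graph$states$name)
  j <- match(to, sol$graph$states$name)
  C <- sol$covariance
  sqrt(max(C[i, i] + C[j, j] - 2 * C[i, j], 0))
}
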