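#' SparCC compositional basis correlations
#'
#' Estimates pairwise basis correlations between taxa from compositional
#' count data, following the log-ratio variance approach of Friedman & Alm
#' (2012). For each resample, taxon fractions are drawn per sample from
#' Dirichlet(counts + 1), the variation matrix
#' \eqn{T_{ij} = var(\log(x_i/x_j))} is computed, and basis variances
#' \eqn{\omega} are obtained under the sparsity assumption by solving the
#' linear system \eqn{t = (diag(|P_i|) + A)\,\omega}, where \eqn{P_i} is
#' the set of non-excluded partners of taxon i and A the partner adjacency.
#' The most strongly correlated pair above `exclusion_threshold` is
#' excluded each iteration, and the final correlations
#' \eqn{\rho_{ij} = (\omega_i + \omega_j - T_{ij}) /
#' (2\sqrt{\omega_i \omega_j})} are clipped to \[-1, 1\] and averaged over
#' resamples.
#'
#' @param table a [count_table()] with at least 4 taxa and 3 samples
#' @param n_exclusion_iters maximum number of strongly-correlated pairs to
#'   exclude from the basis-variance estimation (default 10)
#' @param exclusion_threshold absolute correlation above which a pair is
#'   eligible for exclusion (default 0.1)
#' @param n_resamples Dirichlet resamples averaged (default 20)
#' @param seed RNG seed; a given seed reproduces the matrix exactly
#' @return symmetric `"interaction_matrix"` of correlations in \[-1, 1\]
#'   with method `"sparcc"`.
#' @references Friedman J, Alm EJ (2012) Inferring correlation networks
#'   from genomic survey data. PLoS Comput Biol 8:e1002687.
#' @export
sparcc_correlations <- function(table, n_exclusion_iters = 10,
                                exclusion_threshold = 0.1,
                                n_resamples = 20, seed = NULL) {
  stopifnot(inherits(table, "count_table"))
  if (ncol(table) < 3) stop("need at least 3 samples for SparCC")
  table <- drop_empty_taxa(table)
  n <- nrow(table)
  if (n < 4) stop("need at least 4 taxa for basis-variance estimation")
  m <- unclass(table)
  with_seed(seed, {
    acc <- matrix(0, n, n)
    for (b in seq_len(n_resamples)) {
      fr <- rdirichlet_fractions(m)
      acc <- acc + sparcc_once(log(fr), n_exclusion_iters, exclusion_threshold)
    }
    rho <- acc / n_resamples
  })
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  dimnames(rho) <- list(rownames(m), rownames(m))
  new_interaction_matrix(rho, "sparcc")
}

## One Dirichlet(counts + 1) fraction draw per sample (columns).
rdirichlet_fractions <- function(m) {
  g <- matrix(stats::rgamma(length(m), shape = m + 1, rate = 1),
              nrow = nrow(m))
  sweep(g, 2, colSums(g), "/")
}

## Basis correlations for one log-fraction matrix (taxa x samples).
sparcc_once <- function(y, n_excl, th) {
  n <- nrow(y)
  v <- stats::cov(t(y))
  tmat <- outer(diag(v), diag(v), "+") - 2 * v   # T_ij = var(log x_i/x_j)
  include <- matrix(TRUE, n, n)
  diag(include) <- FALSE
  rho <- solve_basis(tmat, include)
  for (k in seq_len(n_excl)) {
    cand <- abs(rho)
    cand[!include] <- 0
    cand[lower.tri(cand, diag = TRUE)] <- 0
    # keep every taxon with at least 3 partners so the system stays solvable
    deg <- rowSums(include)
    cand[deg <= 3, ] <- 0
    cand[, deg <= 3] <- 0
    mx <- max(cand)
    if (mx < th) break
    ij <- which(cand == mx, arr.ind = TRUE)[1, ]
    include[ij[1], ij[2]] <- include[ij[2], ij[1]] <- FALSE
    rho <- solve_basis(tmat, include)
  }
  rho
}

## Solve t = (diag(deg) + A) omega for the basis variances and convert to
## correlations. With nothing excluded this reduces to the closed form
## omega_i = (t_i - T_tot / (2n - 2)) / (n - 2).
solve_basis <- function(tmat, include) {
  deg <- rowSums(include)
  tvec <- rowSums(tmat * include)
  a <- diag(deg) + include
  omega <- tryCatch(solve(a, tvec), error = function(e) rep(NA_real_, nrow(a)))
  if (anyNA(omega)) omega <- rep(mean(tvec) / (2 * nrow(a) - 2), nrow(a))
  omega <- pmax(omega, 1e-12)
  den <- 2 * sqrt(outer(omega, omega))
  rho <- (outer(omega, omega, "+") - tmat) / den
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  rho
}
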