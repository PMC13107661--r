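#' Sample binary disease indicators from a pairwise (Ising) model
#'
#' Draws `n` rows from the pairwise binary Markov random field
#' \eqn{P(x) \propto \exp(h'x + x' \Theta x / 2)} with 0/1 coding, by Gibbs
#' sampling. Chains are run in parallel blocks: `ceiling(n / per_chain)`
#' independent chains are advanced through `burn_in` full sweeps, after
#' which one state is retained from each chain every `thin` sweeps until
#' `n` rows are collected. All chain updates are vectorised across chains,
#' so the cost is dominated by `burn_in + thin * per_chain` sweeps.
#'
#' @param theta Symmetric coupling matrix with zero diagonal.
#' @param intercepts Length-p vector of node intercepts (log-odds when all
#'   other diseases are absent).
#' @param n Number of rows to draw.
#' @param burn_in Gibbs burn-in sweeps (default 500).
#' @param thin Sweeps between retained states of the same chain (default 10).
#' @param per_chain Retained states per chain (default 10).
#' @param seed Optional seed.
#' @return An `n x p` binary matrix with column names from `theta`.
#' @export
sample_ising <- function(theta, intercepts, n, burn_in = 500, thin = 10,
                         per_chain = 10, seed = NULL) {
  p <- ncol(theta)
  if (!isTRUE(all.equal(theta, t(theta), tolerance = 1e-10)))
    stop("coupling matrix must be symmetric")
  if (any(abs(diag(theta)) > 1e-12))
    stop("coupling matrix must have zero diagonal")
  if (length(intercepts) != p)
    stop("intercepts must have length ncol(theta)")
  with_seed(seed, {
    per_chain <- max(1L, min(per_chain, n))
    n_chain <- as.integer(ceiling(n / per_chain))
    X <- matrix(rbinom(n_chain * p, 1, plogis(rep(intercepts,
                                                  each = n_chain))),
                n_chain, p)
    sweep_once <- function(X) {
      for (j in seq_len(p)) {
        logit <- intercepts[j] + X %*% theta[, j]
        X[, j] <- as.numeric(runif(n_chain) < plogis(logit))
      }
      X
    }
    for (s in seq_len(burn_in)) X <- sweep_once(X)
    out <- matrix(0, n_chain * per_chain, p)
    out[seq_len(n_chain), ] <- X
    if (per_chain > 1) {
      for (k in 2:per_chain) {
        for (s in seq_len(thin)) X <- sweep_once(X)
        out[(k - 1) * n_chain + seq_len(n_chain), ] <- X
      }
    }
    out <- out[seq_len(n), , drop = FALSE]
    colnames(out) <- colnames(theta)
    out
  })
}

#' Mean-field intercept calibration for target prevalences
#'
#' Chooses node intercepts so that the Ising model's marginal prevalences
#' approximate `target`, using the naive mean-field identity
#' \eqn{h_j = logit(\pi_j) - \sum_k \theta_{jk} \pi_k} refined by a few
#' fixed-point iterations against Gibbs-sampled marginals.
#'
#' @param theta Symmetric coupling matrix.
#' @param target Target marginal prevalences in (0,1).
#' @param refine Number of stochastic refinement iterations (default 2;
#'   0 gives the closed-form mean-field intercepts).
#' @param n_mc Monte-Carlo sample size per refinement.
#' @param seed Optional seed for the refinement draws.
#' @return Length-p intercept vector.
#' @export
calibrate_intercepts <- function(theta, target, refine = 2, n_mc = 4000,
                                 seed = NULL) {
  stopifnot(all(target > 0), all(target < 1))
  h <- qlogis(target) - as.numeric(theta %*% target)
  if (refine > 0) {
    with_seed(seed, {
      for (it in seq_len(refine)) {
        X <- sample_ising(theta, h, n_mc, burn_in = 200, per_chain = 4)
        emp <- pmin(pmax(colMeans(X), 1 / n_mc), 1 - 1 / n_mc)
        h <- h + (qlogis(target) - qlogis(emp))
      }
    })
  }
  h
}
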