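#' Nodewise L1-penalized logistic regressions
#'
#' Estimates the conditional dependence structure of binary disease
#' indicators by regressing each disease on all others with an
#' L1-penalized logistic regression (the binary special case of the mixed
#' graphical model, i.e. Ising neighborhood selection). The penalty for
#' each node is chosen by the extended BIC over a log-spaced lambda path:
#' `EBIC = deviance + df * log(n) + 2 * gamma * df * log(p - 1)`.
#' Intercepts are always included and never penalized; predictors are not
#' standardized (all variables are 0/1 indicators).
#'
#' @param X `n x p` binary matrix with column names.
#' @param gamma EBIC hyperparameter (default 0.25).
#' @param nlambda Path length (default 50).
#' @param lambda_min_ratio Smallest lambda as a fraction of lambda_max.
#' @param rule `"ebic"` (default) or `"cv"` (10-fold deviance
#'   cross-validation).
#' @return A `p x p` matrix `B` of fitted neighbor coefficients; row `j`
#'   holds the coefficients of the regression of disease `j` on the others
#'   (`B[j, j] = 0`). The selected lambdas are attached as attribute
#'   `"lambda"`.
#' @export
fit_nodewise <- function(X, gamma = 0.25, nlambda = 50,
                         lambda_min_ratio = 0.01,
                         rule = c("ebic", "cv")) {
  rule <- match.arg(rule)
  p <- ncol(X)
  n <- nrow(X)
  if (n < 1 || p < 2) stop("need n >= 1 and at least two diseases")
  cm <- colMeans(X)
  if (any(cm == 0 | cm == 1))
    stop("constant columns found (",
         paste(colnames(X)[cm == 0 | cm == 1], collapse = ", "),
         "): run the prevalence filter before network estimation")
  B <- matrix(0, p, p, dimnames = list(colnames(X), colnames(X)))
  lambdas <- numeric(p)
  for (j in seq_len(p)) {
    y <- X[, j]
    Z <- X[, -j, drop = FALSE]
    fit <- glmnet::glmnet(Z, y, family = "binomial", nlambda = nlambda,
                          lambda.min.ratio = lambda_min_ratio,
                          standardize = FALSE)
    if (rule == "ebic") {
      dev <- (1 - fit$dev.ratio) * fit$nulldev
      ebic <- dev + fit$df * log(n) + 2 * gamma * fit$df * log(p - 1)
      k <- which.min(ebic)
      lam <- fit$lambda[k]
      beta <- as.numeric(fit$beta[, k])
    } else {
      cvf <- glmnet::cv.glmnet(Z, y, family = "binomial",
                               lambda = fit$lambda, standardize = FALSE)
      lam <- cvf$lambda.1se
      beta <- as.numeric(coef(cvf, s = lam))[-1]
    }
    B[j, -j] <- beta
    lambdas[j] <- lam
  }
  attr(B, "lambda") <- lambdas
  B
}

#' Aggregate nodewise coefficients into a disease network
#'
#' Combines the two directed coefficients of each disease pair into one
#' undirected edge. Under the AND rule an edge is kept only when both
#' regressions select it; its weight is the mean of the two coefficients.
#' Pairs whose coefficients disagree in sign are set to zero
#' (conservative). The result is a symmetric signed weighted adjacency
#' matrix approximating the pairwise conditional associations.
#'
#' @param B `p x p` nodewise coefficient matrix (from [fit_nodewise()]).
#' @param rule `"AND"` (default) or `"OR"`.
#' @param stratum Optional `(sex, age_group)` character vector recorded as
#'   metadata.
#' @param wave Optional wave year.
#' @param n_fit Optional sample size used for the fit.
#' @return A `disease_network` object: list with `nodes`, symmetric
#'   `weights` (zero diagonal), `stratum`, `wave`, `n_fit`.
#' @export
aggregate_network <- function(B, rule = c("AND", "OR"), stratum = NULL,
                              wave = NULL, n_fit = NULL) {
  rule <- match.arg(rule)
  stopifnot(nrow(B) == ncol(B))
  W <- (B + t(B)) / 2
  present <- if (rule == "AND") (B != 0) & (t(B) != 0) else
    (B != 0) | (t(B) != 0)
  W[!present] <- 0
  W[B * t(B) < 0] <- 0   # sign conflict -> no edge
  diag(W) <- 0
  disease_network(W, stratum = stratum, wave = wave, n_fit = n_fit)
}

#' Construct a disease network object
#'
#' @param weights Symmetric numeric matrix with zero diagonal and dimnames.
#' @param stratum,wave,n_fit Metadata (stratum, wave year, fitting n).
#' @return A `disease_network` object.
#' @export
disease_network <- function(weights, stratum = NULL, wave = NULL,
                            n_fit = NULL) {
  if (!isTRUE(all.equal(weights, t(weights), tolerance = 1e-8)))
    stop("network weights must be symmetric")
  if (any(!is.finite(weights))) stop("network weights must be finite")
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  structure(list(nodes = colnames(weights), weights = weights,
                 stratum = stratum, wave = wave, n_fit = n_fit),
            class = "disease_network")
}

#' @export
print.disease_network <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat("Disease network:", length(x$nodes), "diseases,", ne, "edges")
  if (!is.null(x$stratum))
    cat(" [", paste(x$stratum, collapse = " "), "]", sep = "")
  if (!is.null(x$wave)) cat(" wave", x$wave)
  if (!is.null(x$n_fit)) cat(" (n =", x$n_fit, ")")
  cat("\n")
  invisible(x)
}

#' Convert a disease network to an igraph graph
#'
#' @param network A `disease_network`.
#' @param absolute Use absolute edge weights (default FALSE).
#' @return An undirected weighted `igraph` graph.
#' @export
as_igraph <- function(network, absolute = FALSE) {
  W <- network$weights
  if (absolute) W <- abs(W)
  igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Edge list of a disease network
#'
#' @param network A `disease_network`.
#' @return Data frame `source`, `target`, `weight`, sorted by |weight|
#'   descending.
#' @export
network_edges <- function(network) {
  W <- network$weights
  idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  out <- data.frame(source = rownames(W)[idx[, 1]],
                    target = colnames(W)[idx[, 2]],
                    weight = W[idx], stringsAsFactors = FALSE)
  out[order(-abs(out$weight), out$source, out$target), , drop = FALSE]
}

#' Export a network as GraphML plus a weighted edge-list TSV
#'
#' @param network A `disease_network`.
#' @param path Base path without extension; writes `<path>.graphml` and
#'   `<path>_edges.tsv`.
#' @return Invisibly, the two file paths.
#' @export
export_network <- function(network, path) {
  g <- as_igraph(network)
  f1 <- paste0(path, ".graphml")
  f2 <- paste0(path, "_edges.tsv")
  igraph::write_graph(g, f1, format = "graphml")
  ed <- network_edges(network)
  write.table(ed, f2, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(f1, f2))
}

#' Estimate one disease network per stratum and wave
#'
#' For each (sex, age group, wave) cell, fits the nodewise model on the
#' cumulative diagnoses of the persons still under observation at that
#' wave, and aggregates to a `disease_network`. Diseases that are constant
#' within a cell are dropped from that cell's network with a warning.
#' Empty cells are skipped with a warning.
#'
#' @param cohort A filtered `morb_cohort`.
#' @param waves Wave years (default 2011, 2016, 2019).
#' @param sexes,age_groups Strata to estimate (defaults: all).
#' @param gamma,nlambda Passed to [fit_nodewise()].
#' @return Named list of `disease_network` objects
#'   (`<sex>_<age_group>_<wave>`).
#' @export
estimate_networks <- function(cohort, waves = WAVES, sexes = SEXES,
                              age_groups = AGE_GROUPS, gamma = 0.25,
                              nlambda = 50) {
  stopifnot(inherits(cohort, "morb_cohort"))
  out <- list()
  for (sx in sexes) for (ag in age_groups) {
    in_stratum <- cohort$persons$sex == sx & cohort$persons$age_group == ag
    for (w in waves) {
      sel <- in_stratum & survivors_at_wave(cohort, w)
      key <- stratum_key(sx, ag, w)
      if (!any(sel)) {
        warning("empty stratum ", key, ": skipped")
        next
      }
      X <- cohort$waves[[as.character(w)]][sel, , drop = FALSE]
      cs <- colSums(X)
      # a logistic fit needs at least two cases and two non-cases
      ok <- cs >= 2 & cs <= nrow(X) - 2
      if (!all(ok))
        warning("dropping (near-)constant diseases in ", key, ": ",
                paste(colnames(X)[!ok], collapse = ", "))
      X <- X[, ok, drop = FALSE]
      if (ncol(X) < 2) {
        warning("fewer than two variable diseases in ", key, ": skipped")
        next
      }
      B <- fit_nodewise(X, gamma = gamma, nlambda = nlambda)
      out[[key]] <- aggregate_network(B, stratum = c(sx, ag), wave = w,
                                      n_fit = nrow(X))
    }
  }
  out
}

stratum_key <- function(sex, age_group, wave = NULL) {
  ag <- gsub("[-+]", "", age_group)
  if (is.null(wave)) paste(sex, ag, sep = "_") else
    paste(sex, ag, wave, sep = "_")
}
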