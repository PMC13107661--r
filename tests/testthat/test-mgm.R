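test_that("independent columns give an empty selected network", {
  set.seed(31)
  X <- matrix(rbinom(20000 * 8, 1, rep(seq(0.1, 0.45, length.out = 8),
                                       each = 20000)), 20000, 8,
              dimnames = list(NULL, paste0("d", 1:8)))
  B <- fit_nodewise(X)
  expect_true(all(B == 0))
})

test_that("chain support is recovered and matches the unpenalized MLE", {
  th <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  th[1, 2] <- th[2, 1] <- 1
  th[2, 3] <- th[3, 2] <- 1
  X <- sample_ising(th, c(-1, -1, -1), 20000, seed = 33)
  B <- fit_nodewise(X)
  net <- aggregate_network(B)
  W <- net$weights
  expect_true(W["a", "b"] != 0)
  expect_true(W["b", "c"] != 0)
  expect_identical(W["a", "c"], 0)
  # oracle: unpenalized conditional MLE on the same data, support by
  # thresholding |beta| > 0.1
  for (j in 1:3) {
    fit <- glm(X[, j] ~ X[, -j], family = binomial())
    mle <- coef(fit)[-1]
    sel_oracle <- abs(mle) > 0.1
    sel_pkg <- B[j, -j] != 0
    expect_equal(unname(sel_pkg), unname(sel_oracle))
    # selected coefficients are close to the MLE
    expect_equal(unname(B[j, -j][sel_pkg]), unname(mle[sel_oracle]),
                 tolerance = 0.25)
  }
})

test_that("degenerate n does not crash and yields empty neighborhoods", {
  set.seed(35)
  X <- matrix(rbinom(12 * 20, 1, 0.5), 12, 20,
              dimnames = list(NULL, paste0("d", 1:20)))
  B <- fit_nodewise(X)
  expect_true(mean(B != 0) < 0.05)
})

test_that("constant columns are rejected with filter advice", {
  X <- cbind(d1 = c(0, 1, 0, 1), d2 = c(1, 1, 1, 1))
  expect_error(fit_nodewise(X), "prevalence filter")
})

test_that("aggregation applies the AND rule, mean combine and symmetry", {
  B <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  B["a", "b"] <- 0.6
  B["b", "a"] <- 0.4
  B["b", "c"] <- 0.6    # one-sided: dropped under AND
  net <- aggregate_network(B)
  expect_equal(net$weights["a", "b"], 0.5)
  expect_identical(net$weights["b", "c"], 0)
  expect_equal(net$weights, t(net$weights))
  # sign conflicts are zeroed
  B2 <- B
  B2["a", "b"] <- 0.6
  B2["b", "a"] <- -0.4
  expect_identical(aggregate_network(B2)$weights["a", "b"], 0)
  # OR rule keeps one-sided edges
  expect_equal(aggregate_network(B, rule = "OR")$weights["b", "c"], 0.3)
})

test_that("selected support is monotone along the penalty path", {
  fx <- simulate_planted_blocks(p = 12, K = 3, n = 4000, seed = 37)
  X <- fx$X
  for (j in c(1, 5)) {
    fit <- glmnet::glmnet(X[, -j], X[, j], family = "binomial",
                          nlambda = 50, lambda.min.ratio = 0.01,
                          standardize = FALSE)
    expect_true(all(diff(fit$df) >= 0))
  }
})

test_that("nodewise selection agrees with exact-likelihood search (p=4)", {
  # oracle: BIC over all 64 graphs on 4 nodes, with exact Ising
  # likelihood maximized per support
  exact_bic_support <- function(X) {
    p <- ncol(X)
    pairs <- t(utils::combn(p, 2))
    patt <- as.matrix(expand.grid(rep(list(0:1), nrow(pairs))))
    states <- as.matrix(expand.grid(rep(list(0:1), p)))
    cnt <- table(factor(apply(X, 1, paste, collapse = ""),
                        levels = apply(states, 1, paste, collapse = "")))
    cnt <- as.numeric(cnt)
    best <- NULL
    for (r in seq_len(nrow(patt))) {
      active <- which(patt[r, ] == 1)
      k <- p + length(active)
      nll <- function(par) {
        h <- par[1:p]
        th <- matrix(0, p, p)
        for (ii in seq_along(active)) {
          e <- pairs[active[ii], ]
          th[e[1], e[2]] <- th[e[2], e[1]] <- par[p + ii]
        }
        loge <- states %*% h + rowSums((states %*% th) * states) / 2
        -(sum(cnt * loge) - sum(cnt) * log(sum(exp(loge))))
      }
      opt <- optim(rep(0, k), nll, method = "BFGS")
      bic <- 2 * opt$value + k * log(nrow(X))
      if (is.null(best) || bic < best$bic)
        best <- list(bic = bic, support = patt[r, ])
    }
    best$support
  }
  hits <- 0
  n_seeds <- 5
  for (s in seq_len(n_seeds)) {
    th <- matrix(0, 4, 4, dimnames = rep(list(letters[1:4]), 2))
    th[1, 2] <- th[2, 1] <- 0.9
    th[3, 4] <- th[4, 3] <- 0.9
    X <- sample_ising(th, rep(-1, 4), 10000, seed = 300 + s)
    oracle <- exact_bic_support(X)
    W <- aggregate_network(fit_nodewise(X))$weights
    pairs <- t(utils::combn(4, 2))
    est <- vapply(seq_len(nrow(pairs)), function(r)
      as.integer(W[pairs[r, 1], pairs[r, 2]] != 0), integer(1))
    if (all(est == oracle)) hits <- hits + 1
  }
  expect_gte(hits, n_seeds - 1)
})

test_that("stratified estimation returns one network per cell", {
  cfg <- sim_config(n_per_stratum = 500, seed = 41)
  ch <- apply_inclusion_filter(simulate_cohort(cfg))
  nets <- suppressWarnings(
    estimate_networks(ch, waves = 2011, sexes = "F",
                      age_groups = "60-69"))
  expect_length(nets, 1)
  net <- nets[[1]]
  expect_s3_class(net, "disease_network")
  expect_equal(net$weights, t(net$weights))
  expect_true(all(diag(net$weights) == 0))
  expect_equal(net$wave, 2011)
  # closed cohort: survivor counts never increase across waves
  n_surv <- sapply(c(2011, 2016, 2019), function(w)
    sum(ch$persons$sex == "F" & ch$persons$age_group == "60-69" &
          ch$persons$time >= c(`2011` = 0, `2016` = 5,
                               `2019` = 8)[as.character(w)]))
  expect_true(all(diff(n_surv) <= 0))
})

test_that("network export round-trips through edge list and GraphML", {
  net <- random_network(6, seed = 5)
  d <- tempfile()
  dir.create(d)
  export_network(net, file.path(d, "net"))
  ed <- read.delim(file.path(d, "net_edges.tsv"))
  expect_equal(nrow(ed), sum(net$weights[upper.tri(net$weights)] != 0))
  g <- igraph::read_graph(file.path(d, "net.graphml"),
                          format = "graphml")
  expect_equal(igraph::vcount(g), 6)
  expect_equal(igraph::ecount(g), nrow(ed))
  unlink(d, recursive = TRUE)
})
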