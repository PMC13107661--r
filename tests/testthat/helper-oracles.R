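# Independent oracles used to validate the package's estimators on tiny
# problems: exact enumeration of Ising distributions, Floyd-Warshall
# betweenness with path counting, hand-evaluated modularity, and
# exhaustive DAG scoring.

# Exact distribution of a 0/1 Ising model by enumerating all 2^p states.
# Returns states matrix and probability vector.
ising_enumerate <- function(theta, h) {
  p <- length(h)
  states <- as.matrix(expand.grid(rep(list(0:1), p)))
  colnames(states) <- colnames(theta)
  loge <- states %*% h + rowSums((states %*% theta) * states) / 2
  pr <- as.numeric(exp(loge - max(loge)))
  list(states = states, prob = pr / sum(pr))
}

# Conditional log-odds-ratio of x_i, x_j given the rest, from an exact
# state distribution (equals theta_ij for a pairwise model).
exact_conditional_logor <- function(enum, i, j, rest_value) {
  st <- enum$states
  keep <- rep(TRUE, nrow(st))
  rest <- setdiff(seq_len(ncol(st)), c(i, j))
  for (k in seq_along(rest))
    keep <- keep & st[, rest[k]] == rest_value[k]
  pr <- enum$prob[keep]
  s <- st[keep, c(i, j), drop = FALSE]
  p11 <- pr[s[, 1] == 1 & s[, 2] == 1]
  p00 <- pr[s[, 1] == 0 & s[, 2] == 0]
  p10 <- pr[s[, 1] == 1 & s[, 2] == 0]
  p01 <- pr[s[, 1] == 0 & s[, 2] == 1]
  log(p11 * p00 / (p10 * p01))
}

# Brute-force weighted betweenness by Floyd-Warshall with shortest-path
# counting; edge lengths 1/|w|; fractional credit for ties.
brute_betweenness <- function(W) {
  p <- nrow(W)
  len <- ifelse(W != 0, 1 / abs(W), Inf)
  d <- len
  cnt <- ifelse(W != 0, 1, 0)
  diag(d) <- 0
  diag(cnt) <- 0
  for (k in seq_len(p)) for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j || i == k || j == k) next
    alt <- d[i, k] + d[k, j]
    if (alt < d[i, j] - 1e-12) {
      d[i, j] <- alt
      cnt[i, j] <- cnt[i, k] * cnt[k, j]
    } else if (is.finite(alt) && abs(alt - d[i, j]) <= 1e-12) {
      cnt[i, j] <- cnt[i, j] + cnt[i, k] * cnt[k, j]
    }
  }
  btw <- numeric(p)
  for (v in seq_len(p)) for (s in seq_len(p)) for (t in seq_len(p)) {
    if (s >= t || s == v || t == v) next
    if (!is.finite(d[s, t]) || cnt[s, t] == 0) next
    if (abs(d[s, v] + d[v, t] - d[s, t]) <= 1e-12)
      btw[v] <- btw[v] + cnt[s, v] * cnt[v, t] / cnt[s, t]
  }
  setNames(btw, rownames(W))
}

# Direct evaluation of Newman weighted modularity (ordered-pair form).
modularity_by_hand <- function(W, memb) {
  A <- abs(W)
  two_m <- sum(A)
  if (two_m == 0) return(0)
  k <- rowSums(A)
  q <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(A)))
    if (memb[i] == memb[j])
      q <- q + A[i, j] / two_m - k[i] * k[j] / two_m^2
  as.numeric(q)
}

# All 25 DAGs on 3 labelled nodes, as a list of adjacency matrices.
all_dags3 <- function(nodes = c("A", "B", "C")) {
  out <- list()
  edges <- rbind(c(1, 2), c(1, 3), c(2, 3))
  # each unordered pair is absent (0), forward (1) or backward (2)
  for (a in 0:2) for (b in 0:2) for (cc in 0:2) {
    adj <- matrix(0L, 3, 3, dimnames = list(nodes, nodes))
    conf <- c(a, b, cc)
    for (e in 1:3) {
      if (conf[e] == 1) adj[edges[e, 1], edges[e, 2]] <- 1L
      if (conf[e] == 2) adj[edges[e, 2], edges[e, 1]] <- 1L
    }
    # cyclic only when all three pairs oriented in a cycle
    g <- adj
    acyclic <- TRUE
    rem <- 1:3
    while (length(rem) > 0) {
      sinks <- rem[rowSums(g[rem, rem, drop = FALSE]) == 0]
      if (length(sinks) == 0) { acyclic <- FALSE; break }
      rem <- setdiff(rem, sinks)
    }
    if (acyclic) out[[length(out) + 1L]] <- adj
  }
  out
}

# Discrete BIC score of a DAG on binary data, computed from contingency
# tables with table() (independent of the package's scorer).
dag_bic_oracle <- function(adj, X) {
  n <- nrow(X)
  total <- 0
  for (j in seq_len(ncol(X))) {
    pa <- which(adj[, j] == 1)
    if (length(pa) == 0) {
      tab <- table(X[, j])
      ll <- sum(tab * log(tab / n))
      df <- 1
    } else {
      conf <- apply(X[, pa, drop = FALSE], 1, paste, collapse = "")
      tab <- table(conf, X[, j])
      rowt <- rowSums(tab)
      ll <- sum(tab[tab > 0] * log(tab[tab > 0])) -
        sum(rowt[rowt > 0] * log(rowt[rowt > 0]))
      df <- 2^length(pa)
    }
    total <- total + ll - df / 2 * log(n)
  }
  total
}

# Random weighted graph for oracle comparisons.
random_network <- function(p, edge_prob = 0.35, seed = 1) {
  set.seed(seed)
  W <- matrix(0, p, p, dimnames = list(letters[seq_len(p)],
                                       letters[seq_len(p)]))
  for (i in seq_len(p - 1)) for (j in (i + 1):p)
    if (runif(1) < edge_prob)
      W[i, j] <- W[j, i] <- round(runif(1, 0.2, 1), 3) *
        sample(c(-1, 1), 1)
  disease_network(W)
}

# Edge-set F1 between an estimated and a true adjacency support.
edge_f1 <- function(est, tru) {
  ut <- upper.tri(tru)
  tp <- sum(est[ut] & tru[ut])
  fp <- sum(est[ut] & !tru[ut])
  fn <- sum(!est[ut] & tru[ut])
  if (2 * tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}
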