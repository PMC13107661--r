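COMMUNITY_ALGORITHMS <- c("edge_betweenness", "fast_greedy", "louvain",
                          "walktrap", "spinglass", "optimal",
                          "label_propagation")

# tie-break priority when several algorithms reach the same modularity
ALGORITHM_PRIORITY <- c("optimal", "louvain", "walktrap", "fast_greedy",
                        "spinglass", "edge_betweenness",
                        "label_propagation")

#' Construct a partition result
#'
#' @param algorithm Algorithm name.
#' @param membership Named integer vector, one community id per disease.
#' @param modularity Newman weighted modularity of the partition.
#' @param label_map Optional named character vector community id -> label.
#' @return A `partition_result` object.
#' @export
partition_result <- function(algorithm, membership, modularity,
                             label_map = NULL) {
  stopifnot(!is.null(names(membership)))
  structure(list(algorithm = algorithm,
                 membership = setNames(as.integer(membership),
                                       names(membership)),
                 modularity = modularity, label_map = label_map),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat("Partition (", x$algorithm, "): ",
      length(unique(x$membership)), " communities, Q = ",
      round(x$modularity, 4), "\n", sep = "")
  if (!is.null(x$label_map))
    cat("  labels:", paste(x$label_map, collapse = ", "), "\n")
  invisible(x)
}

#' Newman weighted modularity of a disease partition
#'
#' Computes modularity Q on the absolute edge weights (community structure
#' of an association network is defined on association magnitude; signs are
#' documented as ignored).
#'
#' @param network A `disease_network`.
#' @param membership Named community vector covering every node.
#' @return Modularity Q (0 for a single all-in-one community or an empty
#'   edge set).
#' @export
compute_modularity <- function(network, membership) {
  miss <- setdiff(network$nodes, names(membership))
  if (length(miss) > 0)
    stop("membership missing nodes: ", paste(miss, collapse = ", "))
  g <- as_igraph(network, absolute = TRUE)
  if (igraph::ecount(g) == 0) return(0)
  igraph::modularity(g, membership[network$nodes],
                     weights = igraph::E(g)$weight)
}

#' Run the bank of seven community-detection algorithms
#'
#' Applies edge-betweenness, fast-greedy, Louvain, walktrap, spinglass,
#' exact modularity optimization ("optimal") and label propagation to the
#' absolute-weight network, returning one hard partition per algorithm.
#' Stochastic algorithms run under a fixed seed; label propagation takes a
#' consensus over `lp_restarts` runs (two diseases share a community when
#' they co-occur in more than half of the runs). Spinglass requires a
#' connected graph and is run per connected component; isolated diseases
#' form their own community under every algorithm. "optimal" is gated to
#' networks of at most `optimal_max_nodes` nodes (exact maximization is
#' exponential) and skipped with a warning above that.
#'
#' @param network A `disease_network`.
#' @param seed Seed for the stochastic algorithms (default 1).
#' @param algorithms Subset of algorithms to run (default: all seven).
#' @param lp_restarts Label-propagation consensus runs (default 25).
#' @param optimal_max_nodes Node-count gate for "optimal" (default 35).
#' @return Named list of `partition_result` objects.
#' @export
run_algorithm_bank <- function(network, seed = 1,
                               algorithms = COMMUNITY_ALGORITHMS,
                               lp_restarts = 25, optimal_max_nodes = 35) {
  algorithms <- match.arg(algorithms, COMMUNITY_ALGORITHMS,
                          several.ok = TRUE)
  g <- as_igraph(network, absolute = TRUE)
  nodes <- network$nodes
  out <- list()
  for (alg in algorithms) {
    if (alg == "optimal" && length(nodes) > optimal_max_nodes) {
      warning("'optimal' skipped: network larger than ",
              optimal_max_nodes, " nodes")
      next
    }
    memb <- with_seed(child_seed(seed, alg), {
      switch(alg,
        edge_betweenness = igraph::membership(withCallingHandlers(
          igraph::cluster_edge_betweenness(
            g, weights = if (igraph::ecount(g) > 0)
              1 / igraph::E(g)$weight else NULL),
          warning = function(w) {
            if (grepl("highest modularity score", conditionMessage(w)))
              invokeRestart("muffleWarning")
          })),
        fast_greedy = igraph::membership(igraph::cluster_fast_greedy(g)),
        louvain = igraph::membership(igraph::cluster_louvain(g)),
        walktrap = igraph::membership(igraph::cluster_walktrap(g)),
        spinglass = component_wise(g, function(sg)
          igraph::cluster_spinglass(sg)),
        optimal = igraph::membership(igraph::cluster_optimal(g)),
        label_propagation = lp_consensus(g, lp_restarts))
    })
    memb <- setNames(as.integer(memb[nodes]), nodes)
    out[[alg]] <- partition_result(alg, memb,
                                   compute_modularity(network, memb))
  }
  out
}

# Run a community algorithm per connected component; singleton or
# edgeless components become their own community.
component_wise <- function(g, fun) {
  comp <- igraph::components(g)
  memb <- integer(igraph::vcount(g))
  names(memb) <- igraph::V(g)$name
  offset <- 0L
  for (k in seq_len(comp$no)) {
    vs <- which(comp$membership == k)
    if (length(vs) == 1) {
      memb[vs] <- offset + 1L
      offset <- offset + 1L
      next
    }
    sg <- igraph::induced_subgraph(g, vs)
    if (igraph::ecount(sg) == 0) {
      memb[vs] <- offset + seq_along(vs)
      offset <- offset + length(vs)
      next
    }
    cl <- igraph::membership(fun(sg))
    memb[vs] <- offset + as.integer(cl)
    offset <- offset + max(as.integer(cl))
  }
  memb
}

# Consensus label propagation: co-classification graph over `restarts`
# runs, communities = components of majority agreement.
lp_consensus <- function(g, restarts) {
  n <- igraph::vcount(g)
  agree <- matrix(0L, n, n)
  for (r in seq_len(restarts)) {
    m <- igraph::membership(igraph::cluster_label_prop(g))
    agree <- agree + outer(m, m, "==")
  }
  ga <- igraph::graph_from_adjacency_matrix(agree > restarts / 2,
                                            mode = "undirected",
                                            diag = FALSE)
  memb <- igraph::components(ga)$membership
  names(memb) <- igraph::V(g)$name
  memb
}

#' Select the best partition by modularity
#'
#' Returns the partition with maximal modularity; exact ties are broken by
#' a fixed algorithm priority (optimal > louvain > walktrap > fast-greedy >
#' spinglass > edge-betweenness > label-propagation).
#'
#' @param results List of `partition_result` objects
#'   (from [run_algorithm_bank()]).
#' @return The selected `partition_result`.
#' @export
select_partition <- function(results) {
  if (length(results) == 0) stop("no partition results to select from")
  q <- vapply(results, function(r) r$modularity, numeric(1))
  best <- which(q >= max(q) - 1e-12)
  if (length(best) > 1) {
    pr <- match(vapply(results[best], function(r) r$algorithm,
                       character(1)), ALGORITHM_PRIORITY)
    best <- best[which.min(pr)]
  }
  results[[best[1L]]]
}

#' Label the communities of a partition
#'
#' Communities are labeled through anchor diseases: `label_rules` maps
#' anchor disease codes to human pattern labels (e.g. heart failure ->
#' cardiovascular). A community receives the label of the first anchor (in
#' rule order) it contains; anchor-free communities are labeled
#' `"other-1"`, `"other-2"`, ... A duplicated label gets a numeric suffix.
#'
#' @param partition A `partition_result`.
#' @param label_rules Named character vector: `c(code = label, ...)`. An
#'   anchor code appearing twice is a configuration error.
#' @return The partition with `label_map` filled in.
#' @export
label_patterns <- function(partition, label_rules = default_label_rules()) {
  if (anyDuplicated(names(label_rules)))
    stop("anchor disease appears in two label rules: ",
         paste(unique(names(label_rules)[duplicated(names(label_rules))]),
               collapse = ", "))
  memb <- partition$membership
  comms <- sort(unique(memb))
  label_map <- character(length(comms))
  names(label_map) <- as.character(comms)
  other_k <- 0L
  for (i in seq_along(comms)) {
    members <- names(memb)[memb == comms[i]]
    anchors <- names(label_rules)[names(label_rules) %in% members]
    if (length(anchors) > 0) {
      label_map[i] <- label_rules[[anchors[1L]]]
    } else {
      other_k <- other_k + 1L
      label_map[i] <- paste0("other-", other_k)
    }
  }
  dup <- duplicated(label_map)
  if (any(dup))
    label_map[dup] <- paste0(label_map[dup], "-",
                             seq_len(sum(dup)) + 1L)
  partition$label_map <- label_map
  partition
}

#' Default anchor-disease label rules
#'
#' Anchors the four multimorbidity patterns by their clinically dominant
#' diseases: heart failure (cardiovascular), dementia (neuropsychiatric),
#' COPD (respiratory-digestive) and diabetes (metabolic-pain).
#'
#' @return Named character vector of label rules.
#' @export
default_label_rules <- function() {
  c(hf = "cardiovascular", dem = "neuropsychiatric",
    copd = "respiratory_digestive", diab = "metabolic_pain")
}

#' Pattern label of each disease under a labeled partition
#'
#' @param partition A labeled `partition_result`.
#' @return Named character vector disease -> pattern label.
#' @export
pattern_labels <- function(partition) {
  if (is.null(partition$label_map))
    stop("partition has no label map; call label_patterns() first")
  setNames(partition$label_map[as.character(partition$membership)],
           names(partition$membership))
}

#' Exact modularity-optimal partition by exhaustive search
#'
#' Enumerates every partition of the node set (Bell-number many) and
#' returns the one maximizing Newman weighted modularity on absolute
#' weights. Only feasible for small graphs; gated at 13 nodes.
#'
#' @param network A `disease_network` with at most 13 nodes.
#' @return A `partition_result` with algorithm `"exhaustive"`.
#' @export
brute_force_partition <- function(network) {
  p <- length(network$nodes)
  if (p > 13) stop("exhaustive partition search is gated at 13 nodes")
  A <- abs(network$weights)
  res <- exact_partition_cpp(A)
  memb <- setNames(as.integer(res$membership), network$nodes)
  partition_result("exhaustive", memb, res$modularity)
}

#' Adjusted Rand Index between two partitions
#'
#' Computed on the intersection of the two node sets.
#'
#' @param m1,m2 Named membership vectors or `partition_result` objects.
#' @return ARI in [-1, 1].
#' @export
partition_ari <- function(m1, m2) {
  if (inherits(m1, "partition_result")) m1 <- m1$membership
  if (inherits(m2, "partition_result")) m2 <- m2$membership
  shared <- intersect(names(m1), names(m2))
  if (length(shared) < 2) stop("fewer than two shared nodes")
  a <- mclust::adjustedRandIndex(m1[shared], m2[shared])
  if (is.nan(a)) {
    # degenerate partitions (all singletons or all one community): the
    # chance-correction denominator vanishes; fall back to exact
    # co-membership agreement
    same <- identical(outer(m1[shared], m1[shared], "=="),
                      outer(m2[shared], m2[shared], "=="))
    a <- as.numeric(same)
  }
  a
}
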