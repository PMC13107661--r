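#' Disease centrality and score table
#'
#' Combines, for every disease, the strength centrality of the undirected
#' network (sum of absolute incident edge weights), the in-degree of the
#' Bayesian network (number of parents: how strongly the disease is
#' "caused" by others), weighted betweenness and closeness, and the
#' combined score `strength + in_degree` used for pattern assignment.
#'
#' @param network A `disease_network`.
#' @param dag A `disease_dag` on the same node set.
#' @return A data frame: `disease`, `strength`, `in_degree`,
#'   `betweenness`, `closeness`, `score`.
#' @export
compute_scores <- function(network, dag) {
  if (!setequal(network$nodes, dag$nodes))
    stop("network and DAG node sets differ")
  strength <- setNames(rowSums(abs(network$weights)), network$nodes)
  indeg <- dag_in_degree(dag)[network$nodes]
  cent <- path_centralities(network)
  data.frame(disease = network$nodes,
             strength = as.numeric(strength),
             in_degree = as.integer(indeg),
             betweenness = cent$betweenness,
             closeness = cent$closeness,
             score = as.numeric(strength) + as.integer(indeg),
             stringsAsFactors = FALSE, row.names = NULL)
}

# label per disease from a partition (label_map if present, else the
# community id as character)
partition_disease_labels <- function(partition) {
  if (!is.null(partition$label_map))
    pattern_labels(partition)
  else
    setNames(as.character(partition$membership),
             names(partition$membership))
}

#' Assign one multimorbidity pattern to a person
#'
#' The tie-break cascade: (1) if all the person's diseases fall in one
#' pattern, that pattern; (2) otherwise the pattern containing the most of
#' the person's diseases; (3) on ties, the pattern whose member diseases
#' of this person have the largest summed score; (4) residual ties go to
#' the lexicographically smallest pattern label.
#'
#' @param diseases Character vector of the person's diagnosed disease
#'   codes.
#' @param partition A (preferably labeled) `partition_result`.
#' @param scores Score table from [compute_scores()] (or a named numeric
#'   vector of per-disease scores).
#' @return The pattern label (character scalar).
#' @export
assign_pattern <- function(diseases, partition, scores) {
  labels <- partition_disease_labels(partition)
  present <- intersect(diseases, names(labels))
  if (length(present) == 0)
    stop("person has no diagnosed disease present in the partition")
  sc <- if (is.data.frame(scores))
    setNames(scores$score, scores$disease) else scores
  pats <- labels[present]
  tab <- table(pats)
  cand <- names(tab)[tab == max(tab)]
  if (length(cand) > 1) {
    ssum <- vapply(cand, function(pt)
      sum(sc[present[pats == pt]], na.rm = TRUE), numeric(1))
    cand <- cand[ssum == max(ssum)]
  }
  sort(cand)[1L]
}

# Vectorised assignment of all rows of a binary matrix. Implements the
# same cascade as assign_pattern(): count dominates, then summed score,
# then lexicographic label order (columns are sorted by label).
assign_matrix <- function(X, labels, scores) {
  codes <- intersect(colnames(X), names(labels))
  X <- X[, codes, drop = FALSE]
  lab <- labels[codes]
  sc <- scores[codes]
  sc[is.na(sc)] <- 0
  pats <- sort(unique(lab))
  Lmat <- sapply(pats, function(pt) as.numeric(lab == pt))
  counts <- X %*% Lmat
  ssum <- X %*% (Lmat * sc)
  gap <- sum(abs(sc)) + 1
  key <- counts * gap + ssum
  win <- max.col(key, ties.method = "first")
  out <- pats[win]
  out[rowSums(X) == 0] <- NA_character_
  out
}

#' Assign patterns to every person at every wave
#'
#' Applies the assignment cascade to the cumulative diagnoses of each
#' person at each wave they are still under observation, using the wave's
#' partition and score table. Partitions and scores may be given per wave
#' (named list) or once (applied to all waves).
#'
#' @param cohort A `morb_cohort`.
#' @param partitions A `partition_result` or named list of them per wave.
#' @param scores A score table (or named list per wave).
#' @param waves Waves to assign (default all).
#' @return Data frame `person_id`, `wave`, `pattern` (NA for persons with
#'   no diagnosed disease at that wave).
#' @export
assign_all_waves <- function(cohort, partitions, scores, waves = WAVES) {
  stopifnot(inherits(cohort, "morb_cohort"))
  get_wave <- function(x, w) {
    if (inherits(x, "partition_result") || is.data.frame(x) ||
        (is.numeric(x) && !is.null(names(x)))) return(x)
    x[[as.character(w)]]
  }
  out <- list()
  for (w in waves) {
    part <- get_wave(partitions, w)
    scw <- get_wave(scores, w)
    sc <- if (is.data.frame(scw)) setNames(scw$score, scw$disease) else scw
    labels <- partition_disease_labels(part)
    alive <- survivors_at_wave(cohort, w)
    X <- cohort$waves[[as.character(w)]][alive, , drop = FALSE]
    out[[as.character(w)]] <- data.frame(
      person_id = cohort$persons$person_id[alive],
      wave = as.integer(w),
      pattern = assign_matrix(X, labels, sc),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
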