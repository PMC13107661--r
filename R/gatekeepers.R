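#' Weighted betweenness and closeness centralities
#'
#' Shortest paths use edge length `1/|w|` (stronger associations are
#' shorter), the standard transform for strength-weighted association
#' networks. Betweenness counts the shortest paths between other disease
#' pairs passing through a disease, with fractional credit for ties;
#' closeness is the inverse mean distance to reachable diseases only
#' (disconnected pairs are excluded from the average; isolated diseases
#' get closeness 0).
#'
#' @param network A `disease_network`.
#' @return Data frame `disease`, `betweenness`, `closeness`.
#' @export
path_centralities <- function(network) {
  p <- length(network$nodes)
  W <- abs(network$weights)
  if (all(W == 0))
    return(data.frame(disease = network$nodes, betweenness = rep(0, p),
                      closeness = rep(0, p), stringsAsFactors = FALSE))
  g <- as_igraph(network, absolute = TRUE)
  len <- 1 / igraph::E(g)$weight
  btw <- igraph::betweenness(g, weights = len, directed = FALSE)
  D <- igraph::distances(g, weights = len)
  clo <- apply(D, 1, function(d) {
    d <- d[is.finite(d) & d > 0]
    if (length(d) == 0) 0 else 1 / mean(d)
  })
  data.frame(disease = network$nodes,
             betweenness = as.numeric(btw[network$nodes]),
             closeness = as.numeric(clo[network$nodes]),
             stringsAsFactors = FALSE)
}

#' Top gatekeeper diseases by betweenness centrality
#'
#' Gatekeepers are the diseases ranking highest in betweenness: they sit
#' on the shortest paths linking otherwise weakly connected diseases or
#' disease groups. Ties are broken by strength centrality, then
#' lexicographically.
#'
#' @param network A `disease_network`.
#' @param k Number of gatekeepers (default 5).
#' @return Character vector of `k` disease codes, in rank order.
#' @export
top_gatekeepers <- function(network, k = 5) {
  p <- length(network$nodes)
  if (k > p) stop("k exceeds the number of diseases")
  cent <- path_centralities(network)
  strength <- rowSums(abs(network$weights))
  ord <- order(-cent$betweenness, -strength, cent$disease)
  cent$disease[ord][seq_len(k)]
}

#' Strongest comorbid dyads of the gatekeeper diseases
#'
#' For each gatekeeper, takes its `m` incident edges of largest absolute
#' weight. The pooled list is deduplicated (a dyad joining two gatekeepers
#' is counted once), so at most `k * m` dyads are returned. A gatekeeper
#' with fewer than `m` neighbors contributes all of them (logged as a
#' message).
#'
#' @param network A `disease_network`.
#' @param gatekeepers Nonempty character vector of gatekeeper codes.
#' @param m Dyads per gatekeeper (default 5).
#' @return Data frame `gatekeeper`, `partner`, `weight` (absolute),
#'   sorted by weight descending within gatekeeper.
#' @export
strongest_dyads <- function(network, gatekeepers, m = 5) {
  if (length(gatekeepers) == 0) stop("gatekeepers must be nonempty")
  W <- abs(network$weights)
  out <- list()
  for (gk in gatekeepers) {
    w <- W[gk, ]
    nb <- names(w)[w > 0]
    if (length(nb) < m)
      message("gatekeeper ", gk, " has only ", length(nb), " neighbors")
    nb <- nb[order(-w[nb], nb)][seq_len(min(m, length(nb)))]
    if (length(nb) > 0)
      out[[gk]] <- data.frame(gatekeeper = gk, partner = nb,
                              weight = as.numeric(w[nb]),
                              stringsAsFactors = FALSE)
  }
  dy <- do.call(rbind, out)
  if (is.null(dy)) return(data.frame(gatekeeper = character(),
                                     partner = character(),
                                     weight = numeric()))
  key <- apply(dy[, c("gatekeeper", "partner")], 1, function(r)
    paste(sort(r), collapse = "|"))
  dy <- dy[!duplicated(key), , drop = FALSE]
  rownames(dy) <- NULL
  dy
}

#' Flag persons exposed to at least one strong dyad at baseline
#'
#' A person is exposed when both members of at least one dyad are among
#' their diagnoses at the baseline (2011) wave.
#'
#' @param cohort A `morb_cohort`.
#' @param dyads Dyad table from [strongest_dyads()].
#' @param wave Wave defining exposure (default 2011).
#' @return Named logical vector (person ids).
#' @export
flag_exposure <- function(cohort, dyads, wave = 2011) {
  X <- cohort$waves[[as.character(wave)]]
  flag <- rep(FALSE, nrow(X))
  if (nrow(dyads) > 0) {
    for (r in seq_len(nrow(dyads))) {
      a <- dyads$gatekeeper[r]; b <- dyads$partner[r]
      if (a %in% colnames(X) && b %in% colnames(X))
        flag <- flag | (X[, a] == 1 & X[, b] == 1)
    }
  }
  setNames(flag, rownames(X))
}
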