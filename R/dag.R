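#' Learn a Bayesian network of diseases by hill climbing
#'
#' Greedy structure search over directed acyclic graphs maximizing the
#' decomposable discrete BIC score (per-family multinomial log-likelihood
#' minus `(df/2) log n`, df = number of parent configurations). Moves are
#' single-edge additions, deletions and reversals; a tabu list of the last
#' `tabu` applied moves forbids their immediate inverses; the search is
#' repeated from `restarts` random initial DAGs (the first start is the
#' empty graph) and the best-scoring final DAG is returned. Family scores
#' are cached, so re-scored parent sets are free.
#'
#' @param X `n x p` binary matrix with column names and no constant
#'   columns.
#' @param max_parents Parent-set size cap (default 4).
#' @param restarts Number of searches (default 2; first from the empty
#'   DAG).
#' @param tabu Tabu-list length (default 100).
#' @param seed Seed for the random restarts.
#' @return A `disease_dag`: list with `nodes`, binary `adj` matrix
#'   (`adj[i, j] = 1` for edge i -> j) and the final `score`.
#' @export
learn_dag <- function(X, max_parents = 4, restarts = 2, tabu = 100,
                      seed = NULL) {
  p <- ncol(X)
  n <- nrow(X)
  cm <- colMeans(X)
  if (any(cm == 0 | cm == 1))
    stop("constant columns found: filter diseases before DAG learning")
  cache <- new.env(parent = emptyenv())
  fam_score <- function(j, parents) {
    key <- paste0(j, "|", paste(sort(parents), collapse = ","))
    v <- cache[[key]]
    if (!is.null(v)) return(v)
    y <- X[, j]
    k <- length(parents)
    if (k == 0) {
      s <- sum(y)
      cnt <- c(n - s, s)
      ll <- sum(cnt[cnt > 0] * log(cnt[cnt > 0])) - n * log(n)
      df <- 1
    } else {
      idx <- as.integer(X[, parents, drop = FALSE] %*% 2^(seq_len(k) - 1))
      code <- idx + as.integer(y) * 2^k + 1L
      cnt <- tabulate(code, nbins = 2^(k + 1))
      tot <- cnt[seq_len(2^k)] + cnt[2^k + seq_len(2^k)]
      ll <- sum(cnt[cnt > 0] * log(cnt[cnt > 0])) -
        sum(tot[tot > 0] * log(tot[tot > 0]))
      df <- 2^k
    }
    v <- ll - df / 2 * log(n)
    cache[[key]] <- v
    v
  }
  has_path <- function(adj, from, to) {
    # DFS: does a directed path from -> to exist?
    if (from == to) return(TRUE)
    seen <- logical(p)
    stack <- from
    while (length(stack) > 0) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (v == to) return(TRUE)
      if (seen[v]) next
      seen[v] <- TRUE
      stack <- c(stack, which(adj[v, ] == 1 & !seen))
    }
    FALSE
  }
  climb <- function(adj) {
    parents <- lapply(seq_len(p), function(j) which(adj[, j] == 1))
    score <- sum(vapply(seq_len(p), function(j) fam_score(j, parents[[j]]),
                        numeric(1)))
    tabu_list <- character(0)
    repeat {
      best_delta <- 1e-8
      best_move <- NULL
      for (j in seq_len(p)) {
        sj <- fam_score(j, parents[[j]])
        for (i in seq_len(p)) {
          if (i == j) next
          if (adj[i, j] == 1) {
            # delete i -> j
            if (!paste("del", i, j) %in% tabu_list) {
              d <- fam_score(j, setdiff(parents[[j]], i)) - sj
              if (d > best_delta) {
                best_delta <- d; best_move <- c("del", i, j)
              }
            }
            # reverse i -> j (becomes j -> i)
            if (length(parents[[i]]) < max_parents &&
                !paste("rev", i, j) %in% tabu_list) {
              adj2 <- adj
              adj2[i, j] <- 0
              if (!has_path(adj2, i, j)) {
                d <- (fam_score(j, setdiff(parents[[j]], i)) - sj) +
                  (fam_score(i, c(parents[[i]], j)) -
                     fam_score(i, parents[[i]]))
                if (d > best_delta) {
                  best_delta <- d; best_move <- c("rev", i, j)
                }
              }
            }
          } else if (adj[j, i] == 0 &&
                     length(parents[[j]]) < max_parents &&
                     !paste("add", i, j) %in% tabu_list) {
            # add i -> j
            if (!has_path(adj, j, i)) {
              d <- fam_score(j, c(parents[[j]], i)) - sj
              if (d > best_delta) {
                best_delta <- d; best_move <- c("add", i, j)
              }
            }
          }
        }
      }
      if (is.null(best_move)) break
      i <- as.integer(best_move[2]); j <- as.integer(best_move[3])
      inverse <- switch(best_move[1],
                        add = paste("del", i, j),
                        del = paste("add", i, j),
                        rev = paste("rev", j, i))
      tabu_list <- utils::tail(c(tabu_list, inverse), tabu)
      if (best_move[1] == "add") {
        adj[i, j] <- 1
      } else if (best_move[1] == "del") {
        adj[i, j] <- 0
      } else {
        adj[i, j] <- 0
        adj[j, i] <- 1
      }
      parents <- lapply(seq_len(p), function(jj) which(adj[, jj] == 1))
      score <- score + best_delta
    }
    list(adj = adj, score = score)
  }
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(max(1, restarts))) {
      adj0 <- matrix(0L, p, p)
      if (r > 1) {
        ord <- sample.int(p)
        for (a in seq_len(p - 1)) for (b in (a + 1):p) {
          if (runif(1) < 2 / p && sum(adj0[, ord[b]]) < max_parents)
            adj0[ord[a], ord[b]] <- 1L
        }
      }
      res <- climb(adj0)
      if (is.null(best) || res$score > best$score) best <- res
    }
    dimnames(best$adj) <- list(colnames(X), colnames(X))
    structure(list(nodes = colnames(X), adj = best$adj,
                   score = best$score), class = "disease_dag")
  })
}

#' @export
print.disease_dag <- function(x, ...) {
  cat("Disease DAG:", length(x$nodes), "nodes,", sum(x$adj), "edges,",
      "BIC score", round(x$score, 2), "\n")
  invisible(x)
}

#' Acyclicity check for a disease DAG
#'
#' @param dag A `disease_dag`.
#' @return TRUE when the adjacency matrix is acyclic.
#' @export
is_acyclic <- function(dag) {
  adj <- dag$adj
  # repeatedly strip sink-free nodes; acyclic iff everything strips
  repeat {
    if (nrow(adj) == 0) return(TRUE)
    sinks <- which(rowSums(adj) == 0)
    if (length(sinks) == 0) return(FALSE)
    adj <- adj[-sinks, -sinks, drop = FALSE]
  }
}

#' In-degree (number of parents) per disease
#'
#' @param dag A `disease_dag`.
#' @return Named integer vector.
#' @export
dag_in_degree <- function(dag) {
  setNames(as.integer(colSums(dag$adj)), dag$nodes)
}
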