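# two unit-weight triangles joined by one bridge edge
two_triangles <- function() {
  W <- matrix(0, 6, 6, dimnames = rep(list(letters[1:6]), 2))
  W["a", "b"] <- W["b", "c"] <- W["a", "c"] <- 1
  W["d", "e"] <- W["e", "f"] <- W["d", "f"] <- 1
  W["c", "d"] <- 1
  disease_network(pmax(W, t(W)))
}

test_that("modularity matches direct evaluation of the formula", {
  net <- two_triangles()
  memb <- setNames(c(1, 1, 1, 2, 2, 2), letters[1:6])
  expect_equal(compute_modularity(net, memb), 5 / 14, tolerance = 1e-10)
  expect_equal(compute_modularity(net, memb),
               modularity_by_hand(net$weights, memb))
  # all nodes in one community: Q = 0
  expect_equal(compute_modularity(net, setNames(rep(1, 6), letters[1:6])),
               0)
  expect_error(compute_modularity(net, memb[1:4]), "missing nodes")
})

test_that("planted two-community split maximizes Q over all partitions", {
  net <- two_triangles()
  bf <- brute_force_partition(net)
  memb <- setNames(c(1, 1, 1, 2, 2, 2), letters[1:6])
  expect_equal(bf$modularity, compute_modularity(net, memb),
               tolerance = 1e-10)
  expect_equal(partition_ari(bf$membership, memb), 1)
  # a random membership scores strictly less
  set.seed(7)
  rnd <- setNames(sample(1:2, 6, TRUE), letters[1:6])
  if (partition_ari(rnd, memb) < 1)
    expect_lt(compute_modularity(net, rnd), bf$modularity)
})

test_that("all seven algorithms resolve four disjoint cliques", {
  p <- 12
  W <- matrix(0, p, p, dimnames = rep(list(letters[1:p]), 2))
  truth <- rep(1:4, each = 3)
  for (i in 1:(p - 1)) for (j in (i + 1):p)
    if (truth[i] == truth[j]) W[i, j] <- W[j, i] <- 1
  net <- disease_network(W)
  bank <- run_algorithm_bank(net, seed = 3)
  expect_length(bank, 7)
  for (b in bank)
    expect_equal(partition_ari(b$membership,
                               setNames(truth, letters[1:p])), 1)
})

test_that("empty edge set yields singleton communities with Q = 0", {
  W <- matrix(0, 4, 4, dimnames = rep(list(letters[1:4]), 2))
  net <- disease_network(W)
  bank <- run_algorithm_bank(net, seed = 1,
                             algorithms = c("fast_greedy", "louvain",
                                            "spinglass", "walktrap"))
  for (b in bank) {
    expect_equal(length(unique(b$membership)), 4)
    expect_equal(b$modularity, 0)
  }
})

test_that("the algorithm bank is deterministic under a fixed seed", {
  net <- random_network(10, seed = 8)
  b1 <- run_algorithm_bank(net, seed = 5)
  b2 <- run_algorithm_bank(net, seed = 5)
  expect_identical(lapply(b1, `[[`, "membership"),
                   lapply(b2, `[[`, "membership"))
})

test_that("selection takes the modularity argmax with priority ties", {
  m <- setNames(c(1, 1, 2, 2), letters[1:4])
  r1 <- partition_result("fast_greedy", m, 0.30)
  r2 <- partition_result("louvain", m, 0.35)
  r3 <- partition_result("walktrap", m, 0.35)
  expect_equal(select_partition(list(r1, r2, r3))$algorithm, "louvain")
  # equal Q everywhere: priority order decides
  r4 <- partition_result("label_propagation", m, 0.35)
  expect_equal(select_partition(list(r4, r3))$algorithm, "walktrap")
  expect_error(select_partition(list()), "no partition")
})

test_that("selected modularity equals the exhaustive optimum on small graphs", {
  for (s in 1:8) {
    net <- random_network(sample(5:9, 1), edge_prob = 0.4, seed = 40 + s)
    bank <- suppressWarnings(run_algorithm_bank(net, seed = s))
    sel <- select_partition(bank)
    bf <- brute_force_partition(net)
    expect_equal(sel$modularity, bf$modularity, tolerance = 1e-9)
  }
})

test_that("labeling attaches anchors and falls back to other-k", {
  memb <- setNames(c(1, 1, 2, 2, 3), c("hf", "htn", "dem", "epi", "xyz"))
  part <- partition_result("optimal", memb, 0.4)
  lab <- label_patterns(part)
  pl <- pattern_labels(lab)
  expect_equal(unname(pl["hf"]), "cardiovascular")
  expect_equal(unname(pl["dem"]), "neuropsychiatric")
  expect_equal(unname(pl["xyz"]), "other-1")
  expect_error(label_patterns(part, c(hf = "a", hf = "b")),
               "two label rules")
})

test_that("planted four-block fixture yields four labeled patterns", {
  fx <- simulate_planted_blocks(p = 20, K = 4, n = 10000, seed = 11)
  net <- aggregate_network(fit_nodewise(fx$X))
  sel <- select_partition(suppressWarnings(
    run_algorithm_bank(net, seed = 2)))
  hubs <- fx$catalog$code[fx$catalog$hub]
  rules <- setNames(c("cardiovascular", "neuropsychiatric",
                      "respiratory_digestive", "metabolic_pain"), hubs)
  lab <- label_patterns(sel, rules)
  expect_setequal(unique(unname(lab$label_map)),
                  c("cardiovascular", "neuropsychiatric",
                    "respiratory_digestive", "metabolic_pain"))
})
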