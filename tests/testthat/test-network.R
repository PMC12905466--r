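test_that("network construction validates edges and collapses duplicates", {
  net <- build_network(data.frame(a = "LAMA5", b = "LAMB1",
                                  channel = "experimental_ppi"),
                       seed_genes = c("LAMA5", "LAMB1"))
  expect_equal(unname(network_summary(net)), c(2, 1, 1, 1.0))

  # duplicate provenance rows collapse to one connectivity edge
  dup <- data.frame(a = c("A", "A", "B"), b = c("B", "B", "A"),
                    channel = c("experimental_ppi", "curated",
                                "textmining"))
  net2 <- build_network(dup)
  expect_equal(unname(network_summary(net2)["n_edges"]), 1)
  expect_identical(nrow(net2$edges), 3L)      # provenance kept

  expect_error(build_network(data.frame(a = "A", b = "A",
                                        channel = "curated")),
               "self-loop")
  expect_error(build_network(data.frame(a = "A", b = "B",
                                        channel = "psychic")),
               "unknown evidence channel")
  # empty edge list
  expect_equal(unname(network_summary(build_network())["n_edges"]), 0)
  # triangle
  tri <- build_network(data.frame(a = c("A", "B", "C"),
                                  b = c("B", "C", "A"),
                                  channel = "curated"))
  expect_equal(unname(network_summary(tri)), c(3, 3, 1, 1.0))
})

test_that("trivial connector cases behave as specified", {
  edges <- data.frame(a = c("S1", "H"), b = c("S2", "S3"),
                      channel = "experimental_ppi")
  net <- build_network(edges, seed_genes = c("S1", "S2"))
  # seeds already connected
  sol0 <- find_minimal_connectors(net, c("S1", "S2"))
  expect_identical(sol0$k, 0L)
  expect_identical(sol0$status, "already_connected")
  # empty seed set is an error
  expect_error(find_minimal_connectors(net, character()), "empty seed")
  # unconnectable within k_max is a result, not an exception
  net2 <- build_network(NULL, seed_genes = c("S1", "S2"))
  solx <- find_minimal_connectors(net2, c("S1", "S2"), k_max = 2)
  expect_false(solx$connected)
  expect_identical(solx$status, "unconnectable_at_k_max")
})

test_that("one hub adjacent to all of three isolated seeds is the unique solution", {
  seeds <- c("S1", "S2", "S3")
  edges <- rbind(data.frame(a = "HUB", b = seeds,
                            channel = "experimental_ppi"),
                 data.frame(a = "D1", b = c("S1", "S2"),
                            channel = "experimental_ppi"))
  net <- build_network(edges, seed_genes = seeds)
  sol <- find_minimal_connectors(net, seeds)
  expect_identical(sol$k, 1L)
  expect_identical(sol$all_minimal, list("HUB"))
  # brute force over all single candidates agrees
  adj <- adjacency_from_edges(edges, net$nodes)
  singles <- Filter(function(x) oracle_connected(adj, c(seeds, x)),
                    setdiff(net$nodes, seeds))
  expect_identical(sort(unlist(singles)), "HUB")
})

test_that("exhaustive search agrees with the subset oracle on random graphs", {
  set.seed(202)
  n_graphs <- 100
  for (i in seq_len(n_graphs)) {
    g <- random_edges(n = sample(8:15, 1), p = runif(1, 0.1, 0.35))
    seeds <- sample(g$nodes, sample(2:4, 1))
    net <- build_network(g$edges, seed_genes = seeds)
    candidates <- sort(setdiff(net$nodes, seeds))
    sol <- find_minimal_connectors(net, seeds, candidate_pool = candidates,
                                   k_max = 3)
    adj <- adjacency_from_edges(g$edges, net$nodes)
    want <- oracle_min_connectors(adj, seeds, candidates, k_max = 3)
    expect_identical(sol$k, if (is.na(want$k)) NA_integer_ else
      as.integer(want$k), info = paste("graph", i))
    if (!is.na(want$k)) {
      norm <- function(sets) sort(vapply(sets, paste, "", collapse = "|"))
      expect_identical(norm(sol$all_minimal), norm(want$sets),
                       info = paste("graph", i))
    }
  }
})

test_that("returned connector sets are irreducible and solution order is deterministic", {
  set.seed(99)
  for (i in 1:20) {
    g <- random_edges(n = 12, p = 0.15)
    seeds <- sample(g$nodes, 3)
    net <- build_network(g$edges, seed_genes = seeds)
    sol <- find_minimal_connectors(net, seeds,
                                   candidate_pool = setdiff(net$nodes,
                                                            seeds),
                                   k_max = 3)
    if (sol$connected && sol$k > 0) {
      adj <- adjacency_from_edges(g$edges, net$nodes)
      for (s in sol$all_minimal)
        for (drop in s)
          expect_false(oracle_connected(adj, c(seeds, setdiff(s, drop))),
                       info = "removing any added node must disconnect")
      # deterministic lexicographic ordering
      keys <- vapply(sol$all_minimal, paste, "", collapse = "|")
      expect_identical(keys, sort(keys))
    }
    # adding edges never increases the minimum cardinality
    extra <- data.frame(a = seeds[1], b = setdiff(net$nodes, seeds)[1],
                        channel = "curated")
    net2 <- build_network(rbind(g$edges, extra), seed_genes = seeds)
    sol2 <- find_minimal_connectors(net2, seeds,
                                    candidate_pool = setdiff(net2$nodes,
                                                             seeds),
                                    k_max = 3)
    if (sol$connected && sol2$connected) expect_lte(sol2$k, sol$k)
  }
})

test_that("the case-study network fixture has the published structure: unique single connector", {
  net <- build_network(fig5_synthetic_edges(),
                       seed_genes = high_confidence_genes())
  sol <- find_minimal_connectors(net, high_confidence_genes(), k_max = 3)
  expect_identical(sol$k, 1L)
  expect_identical(sol$all_minimal, list("CDK6"))
})
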