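# Transition kernel, edge lengths, ground metric, neighbor measures, and
# per-edge curvature.

test_that("mass-action transition probabilities follow direct arithmetic", {
  tri <- build_network(adj_from_edges(list(c("A", "B"), c("B", "C"), c("A", "C"))))
  P <- transition_probabilities(tri, uniform_weights(tri))
  expect_true(all(abs(P[P > 0] - 0.5) < 1e-12))
  expect_equal(unname(rowSums(P)), rep(1, 3), tolerance = 1e-12)

  pth <- build_network(adj_from_edges(list(c("A", "B"), c("B", "C"))))
  P <- transition_probabilities(pth, c(A = 1, B = 1, C = 3))
  expect_equal(P["B", "C"], 3 / 4, tolerance = 1e-12)
  expect_equal(P["B", "A"], 1 / 4, tolerance = 1e-12)
  expect_equal(P["A", "B"], 1, tolerance = 1e-12)
  expect_equal(P["A", "C"], 0)
})

test_that("a zero-weight neighbor gets zero probability but rows stay normalized", {
  st <- build_network(adj_from_edges(list(c("C0", "L1"), c("C0", "L2"),
                                          c("C0", "L3"))))
  P <- transition_probabilities(st, c(C0 = 1, L1 = 0, L2 = 1, L3 = 1))
  expect_equal(P["C0", "L1"], 0)
  expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
})

test_that("zero neighbor-weight sums error and the pseudocount resolves them", {
  pth <- build_network(adj_from_edges(list(c("A", "B"), c("B", "C"))))
  expect_error(transition_probabilities(pth, c(A = 1, B = 0, C = 1)),
               "zero total neighbor weight.*pseudocount")
  P <- transition_probabilities(pth, c(A = 1, B = 0, C = 1), pseudocount = 0.1)
  expect_equal(unname(rowSums(P)), rep(1, 3), tolerance = 1e-12)
})

test_that("edge lengths invert the mean two-way transition probability", {
  tri <- build_network(adj_from_edges(list(c("A", "B"), c("B", "C"), c("A", "C"))))
  P <- transition_probabilities(tri, uniform_weights(tri))
  lens <- edge_lengths(P, graph = tri)
  expect_equal(unname(lens), rep(2, 3), tolerance = 1e-12)

  pth <- build_network(adj_from_edges(list(c("A", "B"), c("B", "C"))))
  P <- transition_probabilities(pth, uniform_weights(pth))
  lens <- edge_lengths(P, graph = pth)
  expect_equal(unname(lens[["A|B"]]), 4 / 3, tolerance = 1e-12)
})

test_that("edge lengths are invariant to global weight scaling", {
  fx <- make_fixture("random_connected", n = 10, p = 0.3,
                     weights = "lognormal", seed = 21)
  P1 <- transition_probabilities(fx$graph, fx$features[, 1])
  P2 <- transition_probabilities(fx$graph, 2 * fx$features[, 1])
  expect_equal(edge_lengths(P1, graph = fx$graph),
               edge_lengths(P2, graph = fx$graph), tolerance = 1e-12)
})

test_that("an edge with zero two-way probability is rejected with a pseudocount hint", {
  k4 <- build_network(adj_from_edges(list(c("A", "B"), c("A", "C"), c("A", "D"),
                                          c("B", "C"), c("B", "D"), c("C", "D"))))
  P <- transition_probabilities(k4, c(A = 0, B = 0, C = 1, D = 1))
  expect_error(edge_lengths(P, graph = k4), "A.*B.*pseudocount")
  P2 <- transition_probabilities(k4, c(A = 0, B = 0, C = 1, D = 1),
                                 pseudocount = 1e-3)
  expect_true(all(is.finite(edge_lengths(P2, graph = k4))))
})

test_that("shortest-path distances match exhaustive simple-path enumeration", {
  A <- adj_from_edges(list(c("A", "B"), c("B", "C"), c("C", "D")))
  g <- build_network(A)
  D <- shortest_path_metric(g)
  expect_equal(D["A", "D"], 3)
  expect_true(all(diag(D) == 0))

  tri <- adj_from_edges(list(c("A", "B"), c("B", "C"), c("A", "C")))
  gt <- build_network(tri)
  lens <- c("A|B" = 2, "B|C" = 2, "A|C" = 5)
  Dt <- shortest_path_metric(gt, lens)
  expect_equal(Dt["C", "A"], 4)  # detour through B beats the direct edge
  for (u in rownames(tri)) {
    for (v in colnames(tri)) {
      if (u == v) next
      expect_equal(Dt[u, v], brute_shortest_path(tri, as.list(lens), u, v),
                   tolerance = 1e-12)
    }
  }
})

test_that("neighbor measures follow the mass-action normalization", {
  st <- build_network(adj_from_edges(list(c("C0", "L1"), c("C0", "L2"),
                                          c("C0", "L3"))))
  mu <- neighbor_measure(st, c(C0 = 9, L1 = 2, L2 = 1, L3 = 1), "C0")
  expect_equal(mu[["L1"]], 0.5, tolerance = 1e-12)
  expect_equal(mu[["L2"]], 0.25, tolerance = 1e-12)
  expect_equal(mu[["L3"]], 0.25, tolerance = 1e-12)

  leaf <- neighbor_measure(st, c(C0 = 9, L1 = 2, L2 = 1, L3 = 1), "L1")
  expect_equal(leaf, structure(c(C0 = 1), node = "L1", alpha = 0))

  set.seed(5)
  for (r in 1:10) {
    w <- stats::setNames(stats::rlnorm(4), c("C0", "L1", "L2", "L3"))
    expect_equal(sum(neighbor_measure(st, w, "C0")), 1, tolerance = 1e-12)
  }
})

test_that("idleness places alpha mass on the node itself", {
  tri <- build_network(adj_from_edges(list(c("A", "B"), c("B", "C"), c("A", "C"))))
  mu <- neighbor_measure(tri, uniform_weights(tri), "A", alpha = 0.25)
  expect_equal(mu[["A"]], 0.25, tolerance = 1e-12)
  expect_equal(sum(mu), 1, tolerance = 1e-12)
  expect_equal(mu[["B"]], 0.375, tolerance = 1e-12)
  expect_error(neighbor_measure(tri, uniform_weights(tri), "A", alpha = 1),
               "alpha")
})

test_that("spot curvatures: triangle 1/2, path interior 0, barbell bridge -2/3", {
  tri <- build_network(adj_from_edges(list(c("A", "B"), c("B", "C"), c("A", "C"))))
  res <- compute_all_edges(tri, uniform_weights(tri), mode = "hop")
  expect_equal(res$kappa, rep(0.5, 3), tolerance = 1e-12)

  pth <- make_fixture("path", n = 3)
  res <- compute_all_edges(pth$graph, pth$features[, 1], mode = "hop")
  expect_equal(res$kappa, rep(0, 2), tolerance = 1e-12)

  bb <- make_fixture("barbell")
  res <- compute_all_edges(bb$graph, bb$features[, 1], mode = "hop")
  bridge <- res$kappa[res$node_u == "G1" & res$node_v == "G2"]
  expect_equal(bridge, -2 / 3, tolerance = 1e-12)
})

test_that("complete-graph curvature matches the closed form (n-2)/(n-1)", {
  for (n in 3:8) {
    fx <- make_fixture("complete", n = n)
    res <- compute_all_edges(fx$graph, fx$features[, 1], mode = "hop")
    expect_equal(res$kappa, rep((n - 2) / (n - 1), nrow(res)),
                 tolerance = 1e-12)
  }
})

test_that("curvature is invariant to global weight scaling", {
  fx <- make_fixture("random_connected", n = 12, p = 0.3,
                     weights = "lognormal", seed = 31)
  for (mode in c("hop", "weighted")) {
    r1 <- compute_all_edges(fx$graph, fx$features[, 1], mode = mode)
    r2 <- compute_all_edges(fx$graph, 7.3 * fx$features[, 1], mode = mode)
    expect_equal(r1$kappa, r2$kappa, tolerance = 1e-10)
  }
})

test_that("curvature never exceeds 1 and is independent of edge orientation", {
  fx <- make_fixture("random_connected", n = 12, p = 0.35,
                     weights = "lognormal", seed = 41)
  D <- shortest_path_metric(fx$graph)
  ed <- edge_table(fx$graph)
  res <- compute_all_edges(fx$graph, fx$features[, 1], mode = "hop")
  expect_true(all(res$kappa <= 1 + 1e-12))
  for (k in seq_len(nrow(ed))) {
    mu <- neighbor_measure(fx$graph, fx$features[, 1], ed$node_u[k])
    nu <- neighbor_measure(fx$graph, fx$features[, 1], ed$node_v[k])
    fwd <- edge_curvature(mu, nu, D)
    rev <- edge_curvature(nu, mu, D)
    expect_equal(fwd$kappa, rev$kappa, tolerance = 1e-10)
    expect_equal(fwd$kappa, res$kappa[k], tolerance = 1e-10)
  }
})

test_that("relabeling nodes permutes the output without changing values", {
  fx <- make_fixture("random_connected", n = 9, p = 0.4,
                     weights = "lognormal", seed = 51)
  w <- fx$features[, 1]
  r1 <- compute_all_edges(fx$graph, w, mode = "weighted")
  relabel <- stats::setNames(paste0("X", rev(seq_along(w))), names(w))
  A2 <- fx$adjacency
  dimnames(A2) <- list(relabel[rownames(A2)], relabel[colnames(A2)])
  g2 <- build_network(A2)
  w2 <- stats::setNames(w, relabel[names(w)])
  r2 <- compute_all_edges(g2, w2, mode = "weighted")
  key1 <- paste(relabel[r1$node_u], relabel[r1$node_v], sep = "|")
  key1 <- vapply(strsplit(key1, "|", fixed = TRUE),
                 function(p) paste(sort(p), collapse = "|"), "")
  key2 <- paste(r2$node_u, r2$node_v, sep = "|")
  expect_setequal(key1, key2)
  expect_equal(r1$kappa[match(key2, key1)], r2$kappa, tolerance = 1e-10)
})

test_that("hop and weighted modes coincide on regular graphs with uniform weights", {
  cyc <- igraph::make_ring(8)
  cyc <- igraph::set_vertex_attr(cyc, "name", value = paste0("G", 1:8))
  w <- stats::setNames(rep(1, 8), paste0("G", 1:8))
  r_hop <- compute_all_edges(cyc, w, mode = "hop")
  r_wt <- compute_all_edges(cyc, w, mode = "weighted")
  expect_equal(r_hop$kappa, r_wt$kappa, tolerance = 1e-10)

  for (n in c(4, 6)) {
    fx <- make_fixture("complete", n = n)
    expect_equal(compute_all_edges(fx$graph, fx$features[, 1], mode = "hop")$kappa,
                 compute_all_edges(fx$graph, fx$features[, 1], mode = "weighted")$kappa,
                 tolerance = 1e-10)
  }
})

test_that("scaling every edge length by c > 0 leaves curvature unchanged", {
  fx <- make_fixture("random_connected", n = 10, p = 0.35,
                     weights = "lognormal", seed = 61)
  P <- transition_probabilities(fx$graph, fx$features[, 1])
  lens <- edge_lengths(P, graph = fx$graph)
  ed <- edge_table(fx$graph)
  for (c_scale in c(0.2, 5)) {
    D1 <- shortest_path_metric(fx$graph, lens)
    D2 <- shortest_path_metric(fx$graph, c_scale * lens)
    for (k in seq_len(min(5L, nrow(ed)))) {
      mu <- neighbor_measure(fx$graph, fx$features[, 1], ed$node_u[k])
      nu <- neighbor_measure(fx$graph, fx$features[, 1], ed$node_v[k])
      expect_equal(edge_curvature(mu, nu, D1)$kappa,
                   edge_curvature(mu, nu, D2)$kappa, tolerance = 1e-10)
    }
  }
})
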