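# Exact Wasserstein-1: LP solver and brute-force oracle, checked against
# each other and against hand-derivable transport plans.

test_that("identical measures have zero transport distance", {
  g <- build_network(adj_from_edges(list(c("A", "B"), c("B", "C"), c("A", "C"))))
  D <- shortest_path_metric(g)
  mu <- neighbor_measure(g, c(A = 1, B = 2, C = 3), "A")
  expect_equal(wasserstein1(mu, mu, D), 0)
  expect_equal(brute_force_w1(mu, mu, D), 0)
})

test_that("unnormalized measures are rejected", {
  D <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  bad <- c(A = 0.5, B = 0.2)
  ok <- c(A = 0.5, B = 0.5)
  expect_error(wasserstein1(bad, ok, D), "not normalized")
  expect_error(wasserstein1(ok, bad, D), "not normalized")
})

test_that("triangle neighbor measures are 1/2 apart (shared neighbor at cost zero)", {
  g <- build_network(adj_from_edges(list(c("A", "B"), c("B", "C"), c("A", "C"))))
  D <- shortest_path_metric(g)
  w <- uniform_weights(g)
  mu <- neighbor_measure(g, w, "A")
  nu <- neighbor_measure(g, w, "B")
  expect_equal(wasserstein1(mu, nu, D), 0.5, tolerance = 1e-12)
  expect_equal(brute_force_w1(mu, nu, D), 0.5, tolerance = 1e-12)
})

test_that("barbell bridge measures are 5/3 apart", {
  fx <- make_fixture("barbell")
  g <- fx$graph
  D <- shortest_path_metric(g)
  w <- uniform_weights(g)
  mu <- neighbor_measure(g, w, "G1")
  nu <- neighbor_measure(g, w, "G2")
  expect_equal(wasserstein1(mu, nu, D), 5 / 3, tolerance = 1e-12)
  expect_equal(brute_force_w1(mu, nu, D), 5 / 3, tolerance = 1e-12)
})

test_that("the oracle refuses supports beyond its guard", {
  fx <- make_fixture("complete", n = 8)
  g <- fx$graph
  D <- shortest_path_metric(g)
  w <- uniform_weights(g)
  mu <- neighbor_measure(g, w, "G1")
  nu <- neighbor_measure(g, w, "G2")
  expect_error(brute_force_w1(mu, nu, D), "support sizes 7 x 7")
  expect_silent(brute_force_w1(mu, nu, D, max_support = 7))
})

test_that("LP solver and brute-force oracle agree on random measures", {
  set.seed(71)
  for (r in 1:30) {
    m <- sample(2:5, 1)
    n <- sample(2:5, 1)
    labs <- paste0("N", seq_len(m + n))
    D <- matrix(sample(1:4, (m + n)^2, TRUE), m + n, m + n,
                dimnames = list(labs, labs))
    D <- (D + t(D)) / 2
    diag(D) <- 0
    a <- stats::runif(m)
    mu <- stats::setNames(a / sum(a), labs[seq_len(m)])
    b <- stats::runif(n)
    nu <- stats::setNames(b / sum(b), labs[m + seq_len(n)])
    expect_equal(wasserstein1(mu, nu, D), brute_force_w1(mu, nu, D),
                 tolerance = 1e-8)
  }
})

test_that("transport distance is symmetric in its arguments", {
  fx <- make_fixture("random_connected", n = 7, p = 0.45,
                     weights = "lognormal", seed = 13)
  g <- fx$graph
  D <- shortest_path_metric(g)
  ed <- edge_table(g)
  for (k in seq_len(nrow(ed))) {
    mu <- neighbor_measure(g, fx$features[, 1], ed$node_u[k])
    nu <- neighbor_measure(g, fx$features[, 1], ed$node_v[k])
    expect_equal(wasserstein1(mu, nu, D), wasserstein1(nu, mu, D),
                 tolerance = 1e-10)
  }
})
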