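# Synthetic fixtures: toy and random networks plus matching feature
# tables, in exactly the CSV-ready labeled-matrix format the readers
# expect. All randomness in the package lives here and is seed-controlled.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

fixture_graph <- function(topology, n, k, p, max_tries) {
  g <- switch(topology,
    triangle = igraph::make_full_graph(3L),
    path = {
      if (n < 2L) stop("path needs n >= 2", call. = FALSE)
      igraph::make_ring(n, circular = FALSE)
    },
    star = {
      if (k < 1L) stop("star needs k >= 1 leaves", call. = FALSE)
      igraph::make_star(k + 1L, mode = "undirected", center = 1L)
    },
    barbell = {
      # two hubs joined by a bridge, each carrying two pendant leaves:
      # G1-G2 bridge, G1~{G3,G4}, G2~{G5,G6}
      igraph::graph_from_edgelist(
        cbind(c(1L, 1L, 1L, 2L, 2L), c(2L, 3L, 4L, 5L, 6L)),
        directed = FALSE)
    },
    complete = {
      if (n < 2L) stop("complete needs n >= 2", call. = FALSE)
      igraph::make_full_graph(n)
    },
    random_connected = {
      gg <- NULL
      for (t in seq_len(max_tries)) {
        cand <- igraph::sample_gnp(n, p)
        if (igraph::is_connected(cand) && igraph::ecount(cand) > 0L) {
          gg <- cand
          break
        }
      }
      if (is.null(gg)) {
        stop(sprintf(paste0("no connected graph found in %d draws at n = %d, ",
                            "p = %g; increase the edge probability"),
                     max_tries, n, p), call. = FALSE)
      }
      gg
    },
    stop("unknown topology '", topology, "'", call. = FALSE)
  )
  igraph::set_vertex_attr(g, "name", value = paste0("G", seq_len(igraph::vcount(g))))
}

#' Generate a synthetic network + feature-table fixture
#'
#' Builds a toy or random interaction network together with a matching
#' nonnegative feature table, in the same labeled-matrix form the CSV
#' readers produce. Node labels are `G1, G2, ...`, sample labels
#' `S1, S2, ...`. Identical arguments and seed give identical output.
#'
#' Topologies: `"triangle"` (3-clique), `"path"` (chain of `n`),
#' `"star"` (`k` leaves around a center, the center is `G1`),
#' `"barbell"` (hubs `G1`-`G2` joined by a bridge, leaves `G3`,`G4` on
#' `G1` and `G5`,`G6` on `G2` — the canonical negatively curved bridge),
#' `"complete"` (`K_n`), `"random_connected"` (Erdos-Renyi `G(n, p)`
#' redrawn until connected).
#'
#' Weight schemes: `"uniform"` sets every value to `weight_value`
#' (the toy-example convention of unit node weights); `"lognormal"` draws
#' i.i.d. log-normal values per node and sample — positive and
#' right-skewed, a reasonable stand-in for normalized expression; a numeric
#' vector (one value per node) is recycled across samples.
#'
#' @param topology One of the topology names above.
#' @param n Number of nodes (`path`, `complete`, `random_connected`).
#' @param k Number of leaves (`star`).
#' @param p Edge probability (`random_connected`).
#' @param weights `"uniform"`, `"lognormal"`, or a numeric vector.
#' @param weight_value Constant for `"uniform"` (default 1).
#' @param meanlog,sdlog Log-normal parameters (defaults 0 and 1).
#' @param n_samples Number of sample columns (default 1).
#' @param perturb Optional `list(node =, fold =, sample =)`: the
#'   single-gene overexpression scenario (e.g. a 10-fold increase). All
#'   samples share the first sample's baseline weights, and the named
#'   node's weight is multiplied by `fold` in the chosen sample, so the
#'   perturbed entry is the only difference between samples.
#' @param seed Optional integer; the RNG state is restored afterwards.
#' @param max_tries Redraw budget for `random_connected` (default 100).
#' @return A list with `features` (matrix, nodes x samples), `adjacency`
#'   (binary symmetric matrix with zero diagonal), and `graph` (igraph).
#' @examples
#' fx <- make_fixture("random_connected", n = 20, p = 0.2, seed = 7)
#' dim(fx$adjacency)
#' @export
make_fixture <- function(topology = c("triangle", "path", "star", "barbell",
                                      "complete", "random_connected"),
                         n = 5L, k = 3L, p = 0.3, weights = "uniform",
                         weight_value = 1, meanlog = 0, sdlog = 1,
                         n_samples = 1L, perturb = NULL, seed = NULL,
                         max_tries = 100L) {
  topology <- match.arg(topology)
  with_seed(seed, {
    g <- fixture_graph(topology, n, k, p, max_tries)
    vn <- igraph::V(g)$name
    nv <- length(vn)
    X <- if (is.numeric(weights)) {
      if (length(weights) != nv) {
        stop(sprintf("weight vector of length %d for %d nodes",
                     length(weights), nv), call. = FALSE)
      }
      matrix(rep(weights, n_samples), nv, n_samples)
    } else if (identical(weights, "uniform")) {
      matrix(weight_value, nv, n_samples)
    } else if (identical(weights, "lognormal")) {
      matrix(stats::rlnorm(nv * n_samples, meanlog, sdlog), nv, n_samples)
    } else {
      stop("weights must be 'uniform', 'lognormal', or a numeric vector",
           call. = FALSE)
    }
    dimnames(X) <- list(vn, paste0("S", seq_len(n_samples)))
    if (!is.null(perturb)) {
      # perturbation scenario: every sample shares the baseline draw and
      # differs only in the perturbed entry
      X <- matrix(rep(X[, 1L], n_samples), nv, n_samples,
                  dimnames = dimnames(X))
      if (!all(c("node", "fold", "sample") %in% names(perturb))) {
        stop("perturb must be list(node =, fold =, sample =)", call. = FALSE)
      }
      if (!perturb$node %in% vn) {
        stop("perturb node '", perturb$node, "' not in the network",
             call. = FALSE)
      }
      X[perturb$node, perturb$sample] <- X[perturb$node, perturb$sample] *
        perturb$fold
    }
    A <- as.matrix(igraph::as_adjacency_matrix(g, type = "both", sparse = FALSE))
    dimnames(A) <- list(vn, vn)
    list(features = X, adjacency = A, graph = g)
  })
}

#' Write a fixture to a directory as the two input CSVs
#'
#' @param fixture A list from [make_fixture()].
#' @param dir Target directory (created if missing).
#' @return Named character vector with the `features` and `adjacency`
#'   paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp <- file.path(dir, "features.csv")
  ap <- file.path(dir, "adjacency.csv")
  write_feature_table(fixture$features, fp)
  write_adjacency(fixture$adjacency, ap)
  invisible(c(features = fp, adjacency = ap))
}
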