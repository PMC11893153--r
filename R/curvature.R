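# The curvature engine: mass-action transition kernel, edge-length
# transform, shortest-path ground metric, neighbor measures, and
# Ollivier-Ricci curvature per edge.

# Align a node-weight vector to the graph's vertices, by name when named.
align_weights <- function(graph, weights, pseudocount = 0) {
  vn <- igraph::V(graph)$name
  if (pseudocount < 0) stop("pseudocount must be nonnegative", call. = FALSE)
  if (!is.numeric(weights)) stop("node weights must be numeric", call. = FALSE)
  if (!is.null(names(weights))) {
    missing_w <- setdiff(vn, names(weights))
    if (length(missing_w)) {
      stop("no weight for node(s): ", paste(missing_w, collapse = ", "),
           call. = FALSE)
    }
    weights <- weights[vn]
  } else if (length(weights) != length(vn)) {
    stop(sprintf("unnamed weight vector of length %d for %d nodes",
                 length(weights), length(vn)), call. = FALSE)
  }
  if (anyNA(weights)) stop("node weights contain missing values", call. = FALSE)
  if (any(weights < 0)) {
    stop(sprintf("negative weight for node '%s'", vn[which(weights < 0)[1L]]),
         call. = FALSE)
  }
  w <- as.numeric(weights) + pseudocount
  names(w) <- vn
  w
}

#' Mass-action transition probabilities
#'
#' The random-walk kernel induced by node weights: the probability of
#' stepping from node \eqn{i} to an adjacent node \eqn{j} is the weight of
#' \eqn{j} normalized by the total weight of \eqn{i}'s neighbors,
#' \deqn{p_{i,j} = w_j / \sum_{k \sim i} w_k,}
#' and 0 for non-adjacent pairs. Each row sums to 1.
#'
#' @param graph An igraph graph from [build_network()].
#' @param weights Nonnegative node weights: a numeric vector, named by node
#'   label or in vertex order (typically one sample's column of a feature
#'   table).
#' @param pseudocount Nonnegative constant added to every weight before
#'   normalization. The default 0 keeps the kernel exactly mass-action; a
#'   positive value is the supported way to handle nodes whose neighbors
#'   all have zero measured weight.
#' @return A dense row-stochastic matrix with node labels as dimnames;
#'   entry (i, j) is zero exactly when i and j are not adjacent.
#' @export
transition_probabilities <- function(graph, weights, pseudocount = 0) {
  w <- align_weights(graph, weights, pseudocount)
  vn <- names(w)
  n <- length(vn)
  P <- matrix(0, n, n, dimnames = list(vn, vn))
  adj <- igraph::as_adj_list(graph)
  for (i in seq_len(n)) {
    nb <- as.integer(adj[[i]])
    s <- sum(w[nb])
    if (s <= 0) {
      stop(sprintf(paste0("node '%s' has zero total neighbor weight; ",
                          "Ollivier-Ricci curvature is undefined there ",
                          "(consider pseudocount > 0)"), vn[i]), call. = FALSE)
    }
    P[i, nb] <- w[nb] / s
  }
  P
}

#' Transition-based edge lengths
#'
#' Transforms the transition kernel into edge lengths for the weighted
#' ground metric: an edge carrying high transition probability in either
#' direction should be short, so each edge (i, j) gets
#' \deqn{\tilde w_{ij} = (p_{i,j} + p_{j,i})/2, \qquad
#'       \mathrm{length}(i,j) = 1/\tilde w_{ij}.}
#'
#' @param kernel Row-stochastic matrix from [transition_probabilities()].
#' @param edges Canonical edge table (see [edge_table()]); computed from
#'   `graph` when supplied instead.
#' @param graph Optional igraph graph, used to derive `edges`.
#' @return Named positive numeric vector of lengths, one per canonical edge,
#'   names `"u|v"`.
#' @export
edge_lengths <- function(kernel, edges = NULL, graph = NULL) {
  if (is.null(edges)) {
    if (is.null(graph)) stop("supply either 'edges' or 'graph'", call. = FALSE)
    edges <- edge_table(graph)
  }
  p_uv <- kernel[cbind(edges$node_u, edges$node_v)]
  p_vu <- kernel[cbind(edges$node_v, edges$node_u)]
  wt <- (p_uv + p_vu) / 2
  if (any(wt <= 0)) {
    k <- which(wt <= 0)[1L]
    stop(sprintf(paste0("edge ('%s', '%s') has zero transition probability in ",
                        "both directions; its length is undefined ",
                        "(consider pseudocount > 0)"),
                 edges$node_u[k], edges$node_v[k]), call. = FALSE)
  }
  stats::setNames(1 / wt, paste(edges$node_u, edges$node_v, sep = "|"))
}

#' Shortest-path ground metric
#'
#' All-pairs shortest-path distances: the distance between two nodes is the
#' minimum total edge length over all connecting paths. With `lengths =
#' NULL` every edge has length 1 (the hop metric); otherwise the lengths
#' from [edge_lengths()] are used (the weighted hop metric). The direct
#' edge between adjacent nodes is not assumed shortest — a multi-hop route
#' may be cheaper.
#'
#' @param graph An igraph graph with vertex names.
#' @param lengths `NULL` for hop distance, or a named vector of positive
#'   edge lengths as returned by [edge_lengths()].
#' @return Symmetric distance matrix with node labels as dimnames.
#' @export
shortest_path_metric <- function(graph, lengths = NULL) {
  if (is.null(lengths)) {
    D <- igraph::distances(graph, algorithm = "unweighted")
  } else {
    if (any(!is.finite(lengths)) || any(lengths <= 0)) {
      stop("edge lengths must be positive and finite", call. = FALSE)
    }
    el <- igraph::as_edgelist(graph, names = TRUE)
    key <- paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]), sep = "|")
    missing_len <- setdiff(key, names(lengths))
    if (length(missing_len)) {
      stop("no length for edge(s): ", paste(missing_len, collapse = ", "),
           call. = FALSE)
    }
    D <- igraph::distances(graph, weights = unname(lengths[key]),
                           algorithm = "dijkstra")
  }
  D
}

#' Neighbor probability measure of a node
#'
#' The probability distribution a node spreads over its neighborhood,
#' defined by the mass-action principle: neighbor \eqn{k} receives mass
#' \deqn{\mu_i(k) = r_k / \sum_{j \sim i} r_j,}
#' where \eqn{r_k} is the node weight (e.g. the RNA-seq value), and
#' non-neighbors receive 0. With idleness `alpha > 0` the node keeps mass
#' `alpha` on itself and the neighbor masses are scaled by `1 - alpha`; the
#' default `alpha = 0` places all mass on the neighbors.
#'
#' @inheritParams transition_probabilities
#' @param node Node label (or vertex index).
#' @param alpha Idleness, in `[0, 1)`.
#' @return Named numeric vector of masses over the support (neighbors of
#'   `node`, plus `node` itself when `alpha > 0`), summing to 1, with
#'   attributes `node` and `alpha`.
#' @export
neighbor_measure <- function(graph, weights, node, alpha = 0, pseudocount = 0) {
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0, 1)", call. = FALSE)
  w <- align_weights(graph, weights, pseudocount)
  vn <- names(w)
  if (is.character(node)) {
    if (!node %in% vn) stop("unknown node '", node, "'", call. = FALSE)
    i <- match(node, vn)
  } else {
    i <- as.integer(node)
  }
  nb <- as.integer(igraph::neighbors(graph, i))
  s <- sum(w[nb])
  if (s <= 0) {
    stop(sprintf("node '%s' has zero total neighbor weight (consider pseudocount > 0)",
                 vn[i]), call. = FALSE)
  }
  masses <- (1 - alpha) * w[nb] / s
  support <- vn[nb]
  if (alpha > 0) {
    masses <- c(masses, alpha)
    support <- c(support, vn[i])
  }
  structure(stats::setNames(as.numeric(masses), support),
            node = vn[i], alpha = alpha)
}

#' Ollivier-Ricci curvature of one edge
#'
#' \deqn{\kappa(i,j) = 1 - W_1(\mu_i, \mu_j) / d(i,j),}
#' where \eqn{\mu_i, \mu_j} are the endpoint neighbor measures, \eqn{W_1}
#' their Wasserstein-1 distance under the ground metric, and \eqn{d(i,j)}
#' the shortest-path distance between the endpoints under the same metric.
#' Always \eqn{\le 1}; positive on well-overlapping neighborhoods
#' (robust edges), negative on bridge-like bottlenecks (fragile edges).
#'
#' @param mu_i,mu_j Neighbor measures of the two endpoints
#'   (see [neighbor_measure()]).
#' @param metric Distance matrix from [shortest_path_metric()]; must be the
#'   same metric for both the transport cost and the denominator.
#' @param edge Optional character pair naming the endpoints; defaults to the
#'   `node` attributes of the measures.
#' @return A list with `edge` (canonical label pair), `kappa`, `w1` and
#'   `d`.
#' @export
edge_curvature <- function(mu_i, mu_j, metric,
                           edge = c(attr(mu_i, "node"), attr(mu_j, "node"))) {
  if (length(edge) != 2L || anyNA(edge)) {
    stop("'edge' must name the two endpoint nodes", call. = FALSE)
  }
  d <- metric[edge[1L], edge[2L]]
  if (!is.finite(d) || d <= 0) {
    stop(sprintf("invalid endpoint distance d('%s','%s') = %g",
                 edge[1L], edge[2L], d), call. = FALSE)
  }
  w1 <- wasserstein1(mu_i, mu_j, metric)
  list(edge = c(min(edge), max(edge)), kappa = 1 - w1 / d, w1 = w1, d = d)
}

#' Ollivier-Ricci curvature of every edge for one weight assignment
#'
#' Runs the full engine for a single node-weighting (one sample): builds
#' the mass-action kernel, derives the ground metric for the requested
#' mode, and computes curvature for each edge via exact Wasserstein-1
#' transport between the endpoint neighbor measures. Deterministic and
#' independent of edge iteration order.
#'
#' @inheritParams transition_probabilities
#' @param mode `"weighted"` for the transition-based edge lengths (see
#'   [edge_lengths()]) or `"hop"` for unit lengths.
#' @param alpha Idleness in `[0, 1)` (see [neighbor_measure()]).
#' @return `data.frame` with one row per edge in canonical order: columns
#'   `node_u`, `node_v`, `kappa`, `w1`, `d`.
#' @examples
#' fx <- make_fixture("triangle")
#' g <- build_network(fx$adjacency)
#' compute_all_edges(g, fx$features[, 1], mode = "hop")
#' @export
compute_all_edges <- function(graph, weights, mode = c("weighted", "hop"),
                              alpha = 0, pseudocount = 0) {
  mode <- match.arg(mode)
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0, 1)", call. = FALSE)
  P <- transition_probabilities(graph, weights, pseudocount)
  ed <- edge_table(graph)
  lens <- if (mode == "weighted") edge_lengths(P, edges = ed) else NULL
  D <- shortest_path_metric(graph, lens)
  vn <- rownames(P)

  # mu_i equals row i of the kernel when alpha = 0 (same normalization)
  measure_of <- function(i) {
    m <- P[i, ]
    supp <- which(m > 0)
    masses <- (1 - alpha) * m[supp]
    idx <- supp
    if (alpha > 0) {
      masses <- c(masses, alpha)
      idx <- c(supp, i)
    }
    list(idx = idx, mass = as.numeric(masses))
  }
  measures <- lapply(seq_along(vn), measure_of)

  iu <- match(ed$node_u, vn)
  iv <- match(ed$node_v, vn)
  kappa <- w1 <- d <- numeric(nrow(ed))
  for (k in seq_len(nrow(ed))) {
    mu <- measures[[iu[k]]]
    nu <- measures[[iv[k]]]
    w1[k] <- w1_solve(mu$mass, nu$mass,
                      D[mu$idx, nu$idx, drop = FALSE])
    d[k] <- D[iu[k], iv[k]]
    kappa[k] <- 1 - w1[k] / d[k]
  }
  data.frame(node_u = ed$node_u, node_v = ed$node_v,
             kappa = kappa, w1 = w1, d = d, stringsAsFactors = FALSE)
}
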