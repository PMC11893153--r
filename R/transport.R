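# Exact Wasserstein-1 via the transportation linear program, plus an
# independent brute-force oracle used only for verification.

MASS_TOL <- 1e-12

#' Wasserstein-1 (Earth Mover's) distance between two node measures
#'
#' Computes the exact optimum of the transportation problem
#' \deqn{W_1(\mu,\nu) = \min_{\pi} \sum_{x,y} \pi(x,y)\, d(x,y)}
#' over couplings \eqn{\pi} of \eqn{\mu} and \eqn{\nu}, with the graph
#' shortest-path distance as ground cost. Solved as a linear program
#' (simplex method); the optimal value is unique even when the optimal plan
#' is not, so the result is deterministic.
#'
#' @param mu,nu Probability measures over node labels: named nonnegative
#'   numeric vectors summing to 1 (see [neighbor_measure()]).
#' @param metric Full pairwise distance matrix with node labels as dimnames
#'   covering the union of the two supports (see [shortest_path_metric()]).
#' @return The distance, a nonnegative scalar.
#' @export
wasserstein1 <- function(mu, nu, metric) {
  check_measure(mu)
  check_measure(nu)
  a <- mu[mu > 0]
  b <- nu[nu > 0]
  missing_nodes <- setdiff(c(names(a), names(b)), rownames(metric))
  if (length(missing_nodes)) {
    stop("metric does not cover support node(s): ",
         paste(missing_nodes, collapse = ", "), call. = FALSE)
  }
  w1_solve(unname(a), unname(b),
           metric[names(a), names(b), drop = FALSE])
}

check_measure <- function(m) {
  if (!is.numeric(m) || is.null(names(m))) {
    stop("a node measure must be a named numeric vector", call. = FALSE)
  }
  if (any(m < 0)) stop("node measure has negative mass", call. = FALSE)
  if (abs(sum(m) - 1) > 1e-8) {
    stop(sprintf("node measure is not normalized (total mass %.10g)", sum(m)),
         call. = FALSE)
  }
  invisible(m)
}

# Core solver on bare vectors: a (m), b (n), cost (m x n).
w1_solve <- function(a, b, cost) {
  m <- length(a)
  n <- length(b)
  if (m == 1L) return(max(sum(b * cost[1L, ]), 0))
  if (n == 1L) return(max(sum(a * cost[, 1L]), 0))
  nv <- m * n
  # equality constraints: m row sums + first n-1 column sums (the last
  # column constraint is linearly dependent and must be dropped)
  A3 <- matrix(0, m + n - 1L, nv)
  for (i in seq_len(m)) A3[i, ((i - 1L) * n + 1L):(i * n)] <- 1
  for (j in seq_len(n - 1L)) A3[cbind(m + j, (seq_len(m) - 1L) * n + j)] <- 1
  sol <- boot::simplex(a = as.vector(t(cost)), A3 = A3, b3 = c(a, b[-n]),
                       maxi = FALSE)
  if (sol$solved != 1L) {
    stop("transportation linear program failed to solve", call. = FALSE)
  }
  max(sol$value, 0)
}

#' Brute-force Wasserstein-1 oracle
#'
#' Independent exact computation of the transportation optimum, used to
#' verify [wasserstein1()]. Enumerates the vertices of the transportation
#' polytope by the generalized northwest-corner construction: repeatedly
#' pick any remaining (row, column) cell, ship the minimum of the two
#' residual masses, and delete whichever side is exhausted. Every basic
#' feasible solution arises from some pick order, so the minimum over all
#' orders (with branch-and-bound pruning) is the exact optimum. When both
#' supports have equal size and uniform masses the result is additionally
#' cross-checked against minimization over all support permutations
#' (a Birkhoff-type argument makes a permutation optimal in that case).
#'
#' The enumeration is exponential, hence the support-size guard.
#'
#' @inheritParams wasserstein1
#' @param max_support Maximum allowed support size per measure (default 6).
#' @return The distance, a nonnegative scalar.
#' @export
brute_force_w1 <- function(mu, nu, metric, max_support = 6L) {
  check_measure(mu)
  check_measure(nu)
  a <- mu[mu > 0]
  b <- nu[nu > 0]
  if (length(a) > max_support || length(b) > max_support) {
    stop(sprintf("brute-force oracle refused: support sizes %d x %d exceed max_support = %d",
                 length(a), length(b), max_support), call. = FALSE)
  }
  cost <- metric[names(a), names(b), drop = FALSE]
  val <- w1_enumerate_cpp(unname(a), unname(b), unname(cost))
  m <- length(a)
  if (m == length(b) && all(abs(a - 1 / m) < MASS_TOL) &&
      all(abs(b - 1 / m) < MASS_TOL)) {
    pval <- min_permutation_cost_cpp(unname(cost)) / m
    if (abs(pval - val) > 1e-9) {
      stop(sprintf("oracle self-check failed: enumeration %.12g vs permutation %.12g",
                   val, pval), call. = FALSE)
    }
  }
  val
}
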