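#' Ollivier-Ricci curvature of an interaction network over a cohort
#'
#' The main entry point. For each sample, the feature values are mapped
#' onto the network nodes as weights, the mass-action random-walk kernel
#' and neighbor measures are built, and every edge receives its
#' Ollivier-Ricci curvature
#' \deqn{\kappa(i,j) = 1 - W_1(\mu_i, \mu_j)/d(i,j),}
#' computed by exact optimal transport under the chosen ground metric.
#' Columns are independent: each sample's curvature depends only on that
#' sample's weights.
#'
#' Positive curvature marks robust edges (the endpoints share many
#' alternative routes, e.g. triangles); negative curvature marks fragile,
#' bridge-like edges whose removal would disconnect information flow.
#'
#' @param x Feature table: a nonnegative numeric matrix or data frame
#'   (rows = features, columns = samples) with feature labels as row
#'   names, or a path to a CSV in the [read_feature_table()] layout.
#' @param graph The interaction network: an igraph graph from
#'   [build_network()], a labeled square adjacency matrix, or a path to an
#'   adjacency CSV. Node labels must match the feature labels (matching is
#'   by label, not position).
#' @param mode Ground metric: `"weighted"` (default) uses edge lengths
#'   derived from the transition probabilities, `"hop"` uses unit lengths.
#' @param alpha Idleness in `[0, 1)`: probability mass each node's measure
#'   keeps on itself (default 0, the pure mass-action measure).
#' @param pseudocount Nonnegative constant added to all node weights
#'   (default 0); the supported way to handle zero neighbor-weight sums.
#' @param on_error `"stop"` (default) aborts on the first sample whose
#'   weights make curvature undefined; `"skip"` drops such samples with a
#'   warning naming them.
#' @param ... Passed to [build_network()] (e.g. `symmetrize`,
#'   `largest_component`) when `graph` is an adjacency matrix or path.
#' @return An object of class `"orc"`: a list with components
#'   \describe{
#'     \item{curvature}{numeric matrix, edges x samples;
#'       rownames `"u|v"`.}
#'     \item{edges}{data frame `node_u`, `node_v` in canonical order.}
#'     \item{graph}{the igraph network.}
#'     \item{mode, alpha, pseudocount}{the configuration used.}
#'   }
#' @examples
#' fx <- make_fixture("barbell", n_samples = 2,
#'                    perturb = list(node = "G3", fold = 10, sample = 2))
#' fit <- orc(fx$features, fx$adjacency, mode = "hop")
#' fit
#' delta_curvature(fit, "S1", "S2")
#' @seealso [delta_curvature()], [compute_all_edges()],
#'   [write_curvature_table()]
#' @export
orc <- function(x, graph, mode = c("weighted", "hop"), alpha = 0,
                pseudocount = 0, on_error = c("stop", "skip"), ...) {
  mode <- match.arg(mode)
  on_error <- match.arg(on_error)
  if (is.character(x) && length(x) == 1L) x <- read_feature_table(x)
  if (is.data.frame(x)) x <- as.matrix(x)
  validate_feature_table(x)
  if (!igraph::is_igraph(graph)) {
    graph <- build_network(graph, feature_labels = rownames(x), ...)
  } else {
    if (is.null(igraph::V(graph)$name)) {
      stop("graph vertices must be named with feature labels", call. = FALSE)
    }
  }
  vn <- igraph::V(graph)$name
  missing_feat <- setdiff(vn, rownames(x))
  if (length(missing_feat)) {
    stop("no feature measurements for node(s): ",
         paste(missing_feat, collapse = ", "), call. = FALSE)
  }

  ed <- edge_table(graph)
  samples <- colnames(x)
  cols <- vector("list", length(samples))
  names(cols) <- samples
  for (s in samples) {
    res <- tryCatch(
      compute_all_edges(graph, x[vn, s], mode = mode, alpha = alpha,
                        pseudocount = pseudocount),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      if (on_error == "stop") {
        stop(sprintf("sample '%s': %s", s, conditionMessage(res)),
             call. = FALSE)
      }
      warning(sprintf("sample '%s' skipped: %s", s, conditionMessage(res)))
      next
    }
    cols[[s]] <- res$kappa
  }
  kept <- !vapply(cols, is.null, logical(1L))
  if (!any(kept)) stop("curvature undefined for every sample", call. = FALSE)
  K <- do.call(cbind, cols[kept])
  rownames(K) <- paste(ed$node_u, ed$node_v, sep = "|")
  colnames(K) <- samples[kept]
  new_orc(curvature = K, edges = ed, graph = graph, mode = mode,
          alpha = alpha, pseudocount = pseudocount, call = match.call())
}

new_orc <- function(curvature, edges, graph, mode, alpha, pseudocount, call) {
  structure(list(curvature = curvature, edges = edges, graph = graph,
                 mode = mode, alpha = alpha, pseudocount = pseudocount,
                 call = call),
            class = "orc")
}

#' @export
print.orc <- function(x, ...) {
  cat(sprintf("Ollivier-Ricci curvature: %d edges x %d sample%s\n",
              nrow(x$curvature), ncol(x$curvature),
              if (ncol(x$curvature) == 1L) "" else "s"))
  if (!is.na(x$mode)) {
    cat(sprintf("mode: %s, alpha = %g, pseudocount = %g\n",
                x$mode, x$alpha, x$pseudocount))
  }
  k <- x$curvature
  cat(sprintf("kappa range: [%.4g, %.4g]; %d%% of edge-sample values positive\n",
              min(k), max(k), round(100 * mean(k > 0))))
  n_show <- min(6L, nrow(k))
  df <- data.frame(edge = rownames(k)[seq_len(n_show)],
                   round(k[seq_len(n_show), , drop = FALSE], 4),
                   check.names = FALSE, row.names = NULL)
  print(df)
  if (nrow(k) > n_show) cat(sprintf("... %d more edges\n", nrow(k) - n_show))
  invisible(x)
}

#' @export
summary.orc <- function(object, ...) {
  k <- object$curvature
  per_sample <- t(apply(k, 2L, function(v) {
    c(min = min(v), q1 = unname(stats::quantile(v, 0.25)),
      median = stats::median(v),
      q3 = unname(stats::quantile(v, 0.75)), max = max(v),
      frac_positive = mean(v > 0))
  }))
  mean_k <- rowMeans(k)
  ord <- order(mean_k)
  structure(list(n_edges = nrow(k), n_samples = ncol(k),
                 mode = object$mode, alpha = object$alpha,
                 per_sample = per_sample,
                 most_fragile = data.frame(edge = rownames(k)[ord[seq_len(min(5L, nrow(k)))]],
                                           mean_kappa = mean_k[ord[seq_len(min(5L, nrow(k)))]],
                                           row.names = NULL),
                 most_robust = data.frame(edge = rownames(k)[rev(ord)[seq_len(min(5L, nrow(k)))]],
                                          mean_kappa = mean_k[rev(ord)[seq_len(min(5L, nrow(k)))]],
                                          row.names = NULL)),
            class = "summary.orc")
}

#' @export
print.summary.orc <- function(x, ...) {
  cat(sprintf("Ollivier-Ricci curvature summary: %d edges x %d samples (mode %s, alpha %g)\n\n",
              x$n_edges, x$n_samples, x$mode, x$alpha))
  cat("Per-sample kappa distribution:\n")
  print(round(x$per_sample, 4))
  cat("\nMost fragile edges (lowest mean kappa):\n")
  print(transform(x$most_fragile, mean_kappa = round(mean_kappa, 4)))
  cat("\nMost robust edges (highest mean kappa):\n")
  print(transform(x$most_robust, mean_kappa = round(mean_kappa, 4)))
  invisible(x)
}

#' @export
coef.orc <- function(object, ...) object$curvature

#' @export
as.matrix.orc <- function(x, ...) x$curvature

#' @export
as.data.frame.orc <- function(x, ..., long = FALSE) {
  wide <- data.frame(x$edges, x$curvature, check.names = FALSE,
                     row.names = NULL, stringsAsFactors = FALSE)
  if (!long) return(wide)
  samples <- colnames(x$curvature)
  data.frame(node_u = rep(x$edges$node_u, times = length(samples)),
             node_v = rep(x$edges$node_v, times = length(samples)),
             sample = rep(samples, each = nrow(x$edges)),
             kappa = as.vector(x$curvature), stringsAsFactors = FALSE)
}

#' Plot edge curvature
#'
#' For a single sample (or a chosen one) draws the network with edges
#' colored by curvature sign and magnitude (blue = fragile / negative,
#' red = robust / positive); falls back to a histogram of all
#' edge-by-sample values when the graph is unavailable.
#'
#' @param x An [orc] object.
#' @param sample Sample label or index to display (default first).
#' @param ... Passed to [igraph::plot.igraph()] or [graphics::hist()].
#' @export
plot.orc <- function(x, sample = 1L, ...) {
  k <- x$curvature
  if (is.null(x$graph)) {
    graphics::hist(k, breaks = 20, main = "Edge curvature",
                   xlab = expression(kappa), ...)
    return(invisible(x))
  }
  ks <- k[, sample]
  lim <- max(abs(ks), 1e-9)
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(101)
  cid <- 1L + round(50 * (1 + pmax(pmin(ks / lim, 1), -1)))
  key <- paste(x$edges$node_u, x$edges$node_v, sep = "|")
  el <- igraph::as_edgelist(x$graph, names = TRUE)
  gkey <- paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]), sep = "|")
  ecol <- pal[cid][match(gkey, key)]
  igraph::plot.igraph(x$graph, edge.color = ecol, edge.width = 3,
                      vertex.color = "grey90", vertex.label.color = "black",
                      ...)
  invisible(x)
}

#' Node-level curvature aggregation
#'
#' Sums the curvature of all edges incident to each node (a discrete
#' analogue of scalar curvature). This aggregation is a reporting
#' convenience layered on the edge-level definition, not part of the
#' curvature formulation itself.
#'
#' @param object An [orc] object with its graph attached.
#' @return Numeric matrix, nodes x samples.
#' @export
node_curvature <- function(object) {
  stopifnot(inherits(object, "orc"))
  if (is.null(object$graph)) {
    stop("node_curvature needs the graph; refit with orc()", call. = FALSE)
  }
  vn <- igraph::V(object$graph)$name
  out <- matrix(0, length(vn), ncol(object$curvature),
                dimnames = list(vn, colnames(object$curvature)))
  for (k in seq_len(nrow(object$edges))) {
    out[object$edges$node_u[k], ] <- out[object$edges$node_u[k], ] +
      object$curvature[k, ]
    out[object$edges$node_v[k], ] <- out[object$edges$node_v[k], ] +
      object$curvature[k, ]
  }
  out
}
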