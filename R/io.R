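#' Read a feature-by-sample table from CSV
#'
#' Reads a nonnegative measurement matrix (rows = features such as genes or
#' proteins, columns = samples) from a comma-separated file whose first
#' column holds the feature labels and whose header row holds the sample
#' labels.
#'
#' @param path Path to a CSV file.
#' @return A numeric matrix (features x samples) with feature labels as row
#'   names and sample labels as column names. Row and column order of the
#'   file is preserved.
#' @seealso [write_feature_table()], [build_network()]
#' @export
read_feature_table <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    stop("'path' must be a single file path", call. = FALSE)
  }
  if (!file.exists(path)) {
    stop("feature table file not found: '", path, "'", call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = NA)
  if (ncol(df) < 2L) {
    stop("feature table must have a label column plus at least one sample column",
         call. = FALSE)
  }
  labels <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(coerced) & !is.na(v))[1L]
      if (is.na(bad)) bad <- which(is.na(v))[1L]
      stop(sprintf("non-numeric value '%s' at feature '%s', sample '%s'",
                   v[bad], labels[bad], colnames(vals)[j]), call. = FALSE)
    }
  }
  x <- as.matrix(vals)
  rownames(x) <- labels
  validate_feature_table(x)
  x
}

#' Validate a feature table
#'
#' Checks the invariants of the feature-by-sample matrix: numeric, no
#' missing entries, all values nonnegative, unique feature and sample
#' labels.
#'
#' @param x A numeric matrix with row and column names.
#' @return `x`, invisibly, if valid; otherwise an error naming the first
#'   offending cell or label.
#' @export
validate_feature_table <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("feature table must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("feature table must have feature (row) and sample (column) labels",
         call. = FALSE)
  }
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at feature '%s', sample '%s'",
                 rownames(x)[idx[1L]], colnames(x)[idx[2L]]), call. = FALSE)
  }
  if (any(x < 0)) {
    idx <- which(x < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative value %g at feature '%s', sample '%s' (measurements must be nonnegative)",
                 x[idx[1L], idx[2L]], rownames(x)[idx[1L]], colnames(x)[idx[2L]]),
         call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    stop("duplicate feature label: '",
         rownames(x)[anyDuplicated(rownames(x))], "'", call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate sample label: '",
         colnames(x)[anyDuplicated(colnames(x))], "'", call. = FALSE)
  }
  invisible(x)
}

#' Write a feature table to CSV
#'
#' Inverse of [read_feature_table()]; the first column (`feature`) holds row
#' labels.
#'
#' @param x Numeric feature-by-sample matrix with dimnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  validate_feature_table(x)
  df <- data.frame(feature = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an adjacency matrix from CSV
#'
#' Reads a square labeled matrix in the same CSV layout as
#' [read_feature_table()] (first column and header row both carry the node
#' labels).
#'
#' @param path Path to a CSV file.
#' @return A numeric square matrix with identical row and column labels.
#' @export
read_adjacency <- function(path) {
  if (!file.exists(path)) {
    stop("adjacency file not found: '", path, "'", call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1L]])
  A <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(A)) stop("adjacency entries must be numeric", call. = FALSE)
  rownames(A) <- labels
  if (nrow(A) != ncol(A)) {
    stop(sprintf("adjacency matrix must be square (got %d x %d)",
                 nrow(A), ncol(A)), call. = FALSE)
  }
  A
}

#' Write an adjacency matrix to CSV
#'
#' @param A Square numeric matrix with dimnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(A, path) {
  df <- data.frame(node = rownames(A), A, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a validated interaction network from an adjacency matrix
#'
#' Converts a labeled square adjacency matrix into a simple, undirected,
#' connected igraph graph. Any strictly positive off-diagonal entry becomes
#' an edge; entry magnitudes are never used as edge weights (edge lengths
#' come from the transition-probability transform, see [edge_lengths()]).
#' Diagonal entries (self-loops) are dropped with a warning.
#'
#' By default the function errors on an asymmetric matrix and on a
#' disconnected graph, since the curvature computation requires a simple,
#' undirected, connected network. Both checks can be relaxed explicitly.
#'
#' @param adjacency Square numeric matrix with node labels as dimnames, or a
#'   path to a CSV file in the [read_adjacency()] layout.
#' @param feature_labels Optional character vector of feature labels (for
#'   example `rownames()` of a feature table). When given, the adjacency
#'   labels must match this set exactly (order-insensitive; matching is by
#'   label, never by position) and the node order is canonicalized to it.
#' @param symmetrize If `TRUE`, an asymmetric matrix is symmetrized by
#'   taking the elementwise maximum, with a warning, instead of erroring.
#' @param largest_component If `TRUE`, a disconnected graph is restricted to
#'   its largest connected component, with a warning, instead of erroring.
#' @return An [igraph::igraph] object with vertex names.
#' @export
build_network <- function(adjacency, feature_labels = NULL,
                          symmetrize = FALSE, largest_component = FALSE) {
  if (is.character(adjacency) && length(adjacency) == 1L) {
    adjacency <- read_adjacency(adjacency)
  }
  A <- as.matrix(adjacency)
  if (nrow(A) != ncol(A)) {
    stop(sprintf("adjacency matrix must be square (got %d x %d)",
                 nrow(A), ncol(A)), call. = FALSE)
  }
  labs <- rownames(A)
  if (is.null(labs)) labs <- colnames(A)
  if (is.null(labs)) {
    stop("adjacency matrix must carry node labels as dimnames", call. = FALSE)
  }
  if (anyDuplicated(labs)) {
    stop("duplicate node label in adjacency: '", labs[anyDuplicated(labs)],
         "'", call. = FALSE)
  }
  rownames(A) <- labs
  if (is.null(colnames(A))) {
    colnames(A) <- labs
  } else {
    if (!setequal(colnames(A), labs)) {
      stop("adjacency row and column labels differ", call. = FALSE)
    }
    A <- A[, labs, drop = FALSE]
  }
  if (anyNA(A)) stop("adjacency matrix contains missing values", call. = FALSE)
  if (any(A < 0)) stop("adjacency entries must be nonnegative", call. = FALSE)

  if (!is.null(feature_labels)) {
    not_in_adj <- setdiff(feature_labels, labs)
    not_in_feat <- setdiff(labs, feature_labels)
    if (length(not_in_adj) || length(not_in_feat)) {
      stop("adjacency and feature labels differ; ",
           "missing from adjacency: {",
           paste(not_in_adj, collapse = ", "),
           "}; missing from feature table: {",
           paste(not_in_feat, collapse = ", "), "}", call. = FALSE)
    }
    A <- A[feature_labels, feature_labels, drop = FALSE]
  }

  if (!isTRUE(all.equal(unname(A > 0), unname(t(A) > 0)))) {
    if (symmetrize) {
      warning("adjacency matrix is asymmetric; symmetrizing with elementwise maximum")
      A <- pmax(A, t(A))
    } else {
      bad <- which((A > 0) != (t(A) > 0), arr.ind = TRUE)[1L, ]
      stop(sprintf(paste0("adjacency matrix is asymmetric at ('%s', '%s'); ",
                          "use symmetrize = TRUE to symmetrize"),
                   rownames(A)[bad[1L]], colnames(A)[bad[2L]]), call. = FALSE)
    }
  }
  if (any(diag(A) > 0)) {
    warning(sprintf("%d nonzero diagonal entries (self-loops) dropped",
                    sum(diag(A) > 0)))
    diag(A) <- 0
  }

  g <- igraph::graph_from_adjacency_matrix((A > 0) * 1, mode = "undirected")
  if (!igraph::is_connected(g)) {
    comp <- igraph::components(g)
    if (largest_component) {
      warning(sprintf("network has %d components; restricting to largest (%d of %d nodes)",
                      comp$no, max(comp$csize), igraph::vcount(g)))
      g <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
    } else {
      stop(sprintf(paste0("interaction network is not connected (%d components); ",
                          "use largest_component = TRUE to keep the largest"),
           comp$no), call. = FALSE)
    }
  }
  if (igraph::ecount(g) == 0L) {
    stop("interaction network has no edges", call. = FALSE)
  }
  g
}

#' Canonical edge table of a network
#'
#' Returns the edges as a two-column data frame in canonical order:
#' within an edge the lexicographically smaller label first, and rows sorted
#' lexicographically by (node_u, node_v). All curvature output follows this
#' ordering, which makes results stable under input permutation.
#'
#' @param graph An igraph graph with vertex names.
#' @return `data.frame` with character columns `node_u`, `node_v`.
#' @export
edge_table <- function(graph) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  u <- pmin(el[, 1L], el[, 2L])
  v <- pmax(el[, 1L], el[, 2L])
  ord <- order(u, v, method = "radix")
  data.frame(node_u = u[ord], node_v = v[ord], stringsAsFactors = FALSE)
}

#' Write an edge curvature table to CSV
#'
#' Writes one row per edge with columns `node_u`, `node_v` (canonical
#' order) followed by one column per sample. Values are printed with enough
#' digits that re-reading reproduces them to within 1e-12.
#'
#' @param x An [orc] result, or a numeric matrix (edges x samples) paired
#'   with `edges`.
#' @param path Output file path.
#' @param edges Edge data frame (`node_u`, `node_v`) when `x` is a bare
#'   matrix; ignored for [orc] objects.
#' @return `path`, invisibly.
#' @seealso [read_curvature_table()]
#' @export
write_curvature_table <- function(x, path, edges = NULL) {
  if (inherits(x, "orc")) {
    edges <- x$edges
    x <- x$curvature
  }
  if (is.null(edges) || nrow(edges) == 0L || is.null(x) || nrow(x) == 0L) {
    stop("refusing to write an empty curvature table (no edges)", call. = FALSE)
  }
  if (nrow(x) != nrow(edges)) {
    stop("curvature matrix and edge table disagree on the number of edges",
         call. = FALSE)
  }
  df <- data.frame(node_u = edges$node_u, node_v = edges$node_v,
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_len(ncol(x))) df[[colnames(x)[j]]] <- sprintf("%.17g", x[, j])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an edge curvature table from CSV
#'
#' Reads a table written by [write_curvature_table()] back into an [orc]
#' object (without the underlying graph), suitable for
#' [delta_curvature()].
#'
#' @param path Path to a curvature CSV.
#' @return An object of class `"orc"` with `edges` and `curvature` fields;
#'   `graph` is `NULL`.
#' @export
read_curvature_table <- function(path) {
  if (!file.exists(path)) {
    stop("curvature table file not found: '", path, "'", call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L || !all(c("node_u", "node_v") %in% colnames(df)[1:2])) {
    stop("curvature table must have node_u, node_v plus sample columns",
         call. = FALSE)
  }
  K <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(K) <- paste(df$node_u, df$node_v, sep = "|")
  new_orc(curvature = K,
          edges = df[, 1:2],
          graph = NULL, mode = NA_character_, alpha = NA_real_,
          pseudocount = NA_real_, call = sys.call())
}

#' Write the long-format variant of a curvature table
#'
#' One row per (edge, sample) pair with columns `node_u`, `node_v`,
#' `sample`, `kappa`.
#'
#' @inheritParams write_curvature_table
#' @return `path`, invisibly.
#' @export
write_curvature_long <- function(x, path) {
  stopifnot(inherits(x, "orc"))
  df <- as.data.frame(x, long = TRUE)
  df$kappa <- sprintf("%.17g", df$kappa)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
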