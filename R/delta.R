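#' Differential (delta) curvature between samples or groups
#'
#' Edge-wise change in Ollivier-Ricci curvature between two conditions:
#' for each edge, the mean curvature over the samples in `b` minus the mean
#' over the samples in `a`. With single samples this is a plain
#' per-edge difference. Because curvature responds to the weights of a
#' node's whole neighborhood, a perturbation of one gene shows up as delta
#' on edges it does not touch — the cascading, non-local signature of a
#' robustness change.
#'
#' Group comparison uses the edge-wise arithmetic mean; no statistical
#' test is attached — delta values are reported raw.
#'
#' @param object An [orc] object (from [orc()] or
#'   [read_curvature_table()]).
#' @param a,b Sample labels (or index vectors): the reference condition
#'   `a` and the comparison condition `b`. Vectors denote groups.
#' @return Object of class `"orc_delta"`: a data frame with columns
#'   `node_u`, `node_v`, `delta_kappa`, with attributes `a` and `b`.
#'   Antisymmetric: swapping `a` and `b` negates `delta_kappa`.
#' @export
delta_curvature <- function(object, a, b) {
  stopifnot(inherits(object, "orc"))
  K <- object$curvature
  resolve <- function(sel, what) {
    if (length(sel) == 0L) stop("empty sample group for '", what, "'",
                                call. = FALSE)
    if (is.numeric(sel)) {
      if (any(sel < 1 | sel > ncol(K))) {
        stop("sample index out of range for '", what, "'", call. = FALSE)
      }
      return(as.integer(sel))
    }
    idx <- match(sel, colnames(K))
    if (anyNA(idx)) {
      stop("unknown sample label(s) in '", what, "': ",
           paste(sel[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    idx
  }
  ia <- resolve(a, "a")
  ib <- resolve(b, "b")
  delta <- rowMeans(K[, ib, drop = FALSE]) - rowMeans(K[, ia, drop = FALSE])
  structure(data.frame(object$edges, delta_kappa = unname(delta),
                       stringsAsFactors = FALSE, row.names = NULL),
            a = colnames(K)[ia], b = colnames(K)[ib],
            class = c("orc_delta", "data.frame"))
}

#' @export
print.orc_delta <- function(x, ...) {
  cat(sprintf("Delta curvature (b - a): a = {%s}, b = {%s}\n",
              paste(attr(x, "a"), collapse = ", "),
              paste(attr(x, "b"), collapse = ", ")))
  changed <- sum(abs(x$delta_kappa) > 1e-12)
  cat(sprintf("%d of %d edges changed; |delta| max %.4g\n",
              changed, nrow(x), max(abs(x$delta_kappa))))
  print.data.frame(utils::head(x[order(-abs(x$delta_kappa)), ], 10L),
                   row.names = FALSE)
  if (nrow(x) > 10L) cat("... (sorted by |delta|, top 10 shown)\n")
  invisible(x)
}

#' Write a delta-curvature table to CSV
#'
#' Columns `node_u`, `node_v`, `delta_kappa`.
#'
#' @param x An `orc_delta` object from [delta_curvature()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_delta_table <- function(x, path) {
  stopifnot(inherits(x, "orc_delta"))
  df <- data.frame(node_u = x$node_u, node_v = x$node_v,
                   delta_kappa = sprintf("%.17g", x$delta_kappa),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
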