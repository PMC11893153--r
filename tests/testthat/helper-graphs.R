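# Shared helpers: small labeled adjacency builders and an independent
# shortest-path oracle (exhaustive simple-path enumeration).

adj_from_edges <- function(edges, nodes = sort(unique(unlist(edges)))) {
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (e in edges) {
    A[e[1], e[2]] <- 1
    A[e[2], e[1]] <- 1
  }
  A
}

uniform_weights <- function(graph, value = 1) {
  stats::setNames(rep(value, igraph::vcount(graph)), igraph::V(graph)$name)
}

# exhaustive shortest path over all simple paths (oracle for small graphs)
brute_shortest_path <- function(adjacency, lengths, from, to) {
  nodes <- rownames(adjacency)
  best <- Inf
  recurse <- function(at, visited, acc) {
    if (at == to) {
      best <<- min(best, acc)
      return(invisible(NULL))
    }
    for (nxt in nodes[adjacency[at, ] > 0]) {
      if (nxt %in% visited) next
      key <- paste(min(at, nxt), max(at, nxt), sep = "|")
      recurse(nxt, c(visited, nxt), acc + lengths[[key]])
    }
    invisible(NULL)
  }
  recurse(from, from, 0)
  best
}

# triangle + pendant branch + bridge to a leafy hub pair: one connected
# graph containing the canonical robust (triangle) and fragile
# (branch, bridge) motifs
motif_adjacency <- function() {
  adj_from_edges(list(
    c("A", "B"), c("A", "C"), c("B", "C"),   # triangle
    c("C", "P"),                             # pendant branch
    c("C", "U"),                             # connector
    c("U", "U1"), c("U", "U2"),              # hub U leaves
    c("U", "V"),                             # bridge
    c("V", "V1"), c("V", "V2")               # hub V leaves
  ))
}
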