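# Independent brute-force oracles and tiny graph builders used across the
# suite. Everything here is deliberately naive and written without touching
# the implementation paths (or igraph) it is meant to check.

# random simple graph as a character edge matrix + vertex vector
random_edge_set <- function(n, p, seed) {
  set.seed(seed)
  labs <- sprintf("v%02d", seq_len(n))
  pairs <- t(combn(labs, 2L))
  keep <- runif(nrow(pairs)) < p
  list(vertices = labs, edges = pairs[keep, , drop = FALSE])
}

oracle_adjlist <- function(vertices, edges) {
  adj <- setNames(vector("list", length(vertices)), vertices)
  for (v in vertices) adj[[v]] <- character()
  if (nrow(edges) > 0L) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1L]; b <- edges[i, 2L]
      adj[[a]] <- union(adj[[a]], b)
      adj[[b]] <- union(adj[[b]], a)
    }
  }
  adj
}

# components by iterative reachability expansion
oracle_components <- function(vertices, edges) {
  adj <- oracle_adjlist(vertices, edges)
  left <- vertices
  comps <- list()
  while (length(left) > 0L) {
    comp <- left[1L]
    repeat {
      grown <- union(comp, unlist(adj[comp]))
      if (length(grown) == length(comp)) break
      comp <- grown
    }
    comps <- c(comps, list(sort(comp, method = "radix")))
    left <- setdiff(left, comp)
  }
  comps[order(vapply(comps, `[`, character(1L), 1L), method = "radix")]
}

oracle_bfs_dist <- function(adj, s) {
  d <- setNames(rep(Inf, length(adj)), names(adj))
  d[s] <- 0
  frontier <- s
  while (length(frontier) > 0L) {
    nxt <- setdiff(unique(unlist(adj[frontier])), names(d)[is.finite(d)])
    if (length(nxt) > 0L) d[nxt] <- d[frontier[1L]] + 1
    frontier <- nxt
  }
  d
}

# betweenness by explicit enumeration of all shortest paths per pair
oracle_betweenness <- function(vertices, edges) {
  adj <- oracle_adjlist(vertices, edges)
  dist <- lapply(setNames(vertices, vertices),
                 function(s) oracle_bfs_dist(adj, s))
  paths_to <- function(s, t) {
    if (s == t) return(list(t))
    preds <- intersect(adj[[t]], names(which(dist[[s]] == dist[[s]][t] - 1)))
    out <- list()
    for (w in preds) {
      out <- c(out, lapply(paths_to(s, w), function(p) c(p, t)))
    }
    out
  }
  bc <- setNames(numeric(length(vertices)), vertices)
  n <- length(vertices)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      s <- vertices[i]; t <- vertices[j]
      if (!is.finite(dist[[s]][t])) next
      sp <- paths_to(s, t)
      for (p in sp) {
        interior <- p[-c(1L, length(p))]
        bc[interior] <- bc[interior] + 1 / length(sp)
      }
    }
  }
  bc
}

# maximal cliques by exhaustive subset scan over all 2^n vertex subsets,
# represented as bitmasks so the scan stays fast for n <= 12
oracle_cliques <- function(vertices, edges, min_size = 3L) {
  adj <- oracle_adjlist(vertices, edges)
  n <- length(vertices)
  bit <- 2^(seq_len(n) - 1L)
  adj_mask <- vapply(seq_len(n), function(i) {
    sum(bit[match(adj[[vertices[i]]], vertices)]) + bit[i]
  }, numeric(1L))
  masks <- seq_len(2^n - 1L)
  size <- rowSums(outer(masks, bit, function(m, b) bitwAnd(m, b) > 0L))
  ok <- size >= min_size
  for (i in seq_len(n)) {
    in_set <- bitwAnd(masks, bit[i]) > 0L
    # members of the subset must all lie inside vertex i's closed neighborhood
    outside <- bitwAnd(masks, bitwAnd(bitwNot(as.integer(adj_mask[i])),
                                      2^n - 1L)) > 0L
    ok <- ok & !(in_set & outside)
  }
  cliques <- lapply(masks[ok], function(m) vertices[bitwAnd(m, bit) > 0L])
  maximal <- Filter(function(cl) {
    ext <- Reduce(intersect, adj[cl])
    length(setdiff(ext, cl)) == 0L
  }, cliques)
  maximal <- lapply(maximal, sort, method = "radix")
  if (length(maximal) == 0L) return(maximal)
  first <- vapply(maximal, `[`, character(1L), 1L)
  maximal[order(-lengths(maximal), rank(first, ties.method = "first"))]
}

# canonical form of a list of label sets, for set-of-sets comparison
canon_sets <- function(sets) {
  sets <- lapply(unname(sets), sort, method = "radix")
  keys <- vapply(sets, paste, character(1L), collapse = "|")
  unname(sort(keys, method = "radix"))
}

# small fixed graphs
triangle_graph <- function() {
  make_network(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
}

two_triangles_bridge <- function() {
  make_network(rbind(
    c("a1", "a2"), c("a1", "a3"), c("a2", "a3"),
    c("b1", "b2"), c("b1", "b3"), c("b2", "b3"),
    c("v", "a1"), c("v", "b1")
  ))
}

partition_ok <- function(clustering, labels) {
  members <- unlist(clustering$clusters)
  !anyDuplicated(members) && setequal(members, labels)
}
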