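# Clique-based cluster extension.
#
# The post-processing step enumerates the maximal cliques of the original
# network and merges a cluster of n vertices with a maximal clique when the
# two share n-1 vertices, replacing the cluster by the union. Merging can
# only reduce (never raise) the number of clusters, and the result may
# overlap.

#' Maximal cliques of at least a given size
#'
#' @param g an igraph graph with named vertices.
#' @param min_size smallest clique size to report (default 3).
#' @return list of character vectors (each sorted ascending), ordered by
#'   descending clique size then smallest member label; no clique is a
#'   subset of another.
#' @export
maximal_cliques <- function(g, min_size = 3L) {
  cl <- igraph::max_cliques(g, min = min_size)
  cl <- lapply(cl, function(v) label_sort(igraph::V(g)$name[as.integer(v)]))
  if (length(cl) == 0L) return(cl)
  first <- vapply(cl, `[`, character(1L), 1L)
  cl[order(-lengths(cl), rank(first, ties.method = "first"))]
}

#' Merge clusters with maximal cliques sharing all but one member
#'
#' Clusters are processed in ascending size order (ties by smallest member
#' label). A cluster of n vertices is merged with the first clique — in
#' descending clique-size order — that shares exactly n-1 of its members
#' (`at_least = TRUE` relaxes the condition to n-1 or more); the union
#' replaces the cluster. Each cluster merges at most once, in a single
#' sweep; duplicate resulting clusters are collapsed, so the cluster count
#' never increases. The result is flagged overlapping.
#'
#' @param clustering a `clustering` over the same graph the cliques were
#'   enumerated from.
#' @param cliques list of vertex-label sets as returned by
#'   [maximal_cliques()].
#' @param at_least merge on an overlap of at least n-1 members rather than
#'   exactly n-1.
#' @return an overlapping `clustering` with at most as many clusters as the
#'   input.
#' @export
extend_clusters <- function(clustering, cliques, at_least = FALSE) {
  stopifnot(inherits(clustering, "clustering"))
  clusters <- clustering$clusters
  if (length(clusters) > 0L) {
    first <- vapply(clusters, `[`, character(1L), 1L)
    clusters <- clusters[order(lengths(clusters),
                               rank(first, ties.method = "first"))]
  }
  out <- vector("list", length(clusters))
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    n <- length(cl)
    merged <- cl
    for (q in cliques) {
      shared <- sum(cl %in% q)
      # a merge must share at least one vertex, else the union could be
      # disconnected (only relevant to singleton clusters, where n-1 = 0)
      hit <- if (at_least) shared >= max(n - 1L, 1L)
             else n >= 2L && shared == n - 1L
      if (hit) {
        merged <- label_sort(union(cl, q))
        break
      }
    }
    out[[i]] <- merged
  }
  out <- unique(out)
  new_clustering(out, clustering$universe, overlapping = TRUE)
}
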