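# Divisive clustering driven by creative-element removal.
#
# A creative element is a low-degree vertex weakly attached to several hubs;
# such vertices tend to sit on the borders between modules. The clustering
# loop repeatedly removes the highest-scoring creative vertices from a
# sub-network, takes the connected components of the remainder as seeds,
# greedily reattaches the removed vertices, and recurses on the resulting
# clusters until each dequeued sub-network is unsplittable.

#' Hubs of a graph: the top fraction of vertices by degree
#'
#' Selects exactly `ceiling(hub_fraction * |V|)` vertices by descending
#' degree, ties broken by ascending label.
#'
#' @param g a nonempty igraph graph with named vertices.
#' @param hub_fraction fraction of vertices to declare hubs, in (0, 1].
#' @return character vector of hub labels.
#' @export
find_hubs <- function(g, hub_fraction = 0.2) {
  n <- igraph::vcount(g)
  if (n == 0L) stop("graph must be nonempty")
  stopifnot(hub_fraction > 0, hub_fraction <= 1)
  k <- ceiling(hub_fraction * n)
  d <- degree_map(g)           # names ascending
  names(d)[order(-d, seq_along(d))][seq_len(k)]
}

#' Creative-element scores
#'
#' For every vertex whose neighborhood contains at least one hub, the score
#' is the fraction of its neighbors that are hubs: hub-neighbor count
#' divided by degree. A vertex attached to several hubs through few edges
#' scores high; vertices with no hub neighbor are outside the score domain.
#'
#' @param g an igraph graph with named vertices.
#' @param hubs character vector of hub labels (subset of the vertex set).
#' @return object of class `creative_scores`: list with `scores` (named
#'   numeric on the eligible vertices, ascending label order), `hubs`, and
#'   `eligible` (the scored labels).
#' @export
creative_scores <- function(g, hubs) {
  hubs <- unique(as.character(hubs))
  missing <- setdiff(hubs, igraph::V(g)$name)
  if (length(missing) > 0L) {
    stop("hub labels not in graph: ", paste(missing, collapse = ", "))
  }
  labels <- igraph::V(g)$name
  adj <- igraph::as_adj_list(g)
  is_hub <- labels %in% hubs
  hub_n <- vapply(adj, function(nb) sum(is_hub[as.integer(nb)]), numeric(1L))
  deg <- lengths(adj)
  eligible <- hub_n >= 1L
  scores <- hub_n[eligible] / deg[eligible]
  names(scores) <- labels[eligible]
  scores <- scores[label_sort(names(scores))]
  structure(list(scores = scores, hubs = label_sort(hubs),
                 eligible = names(scores)),
            class = "creative_scores")
}

#' @export
print.creative_scores <- function(x, ...) {
  cat(sprintf("creative_scores: %d eligible vertex(es), %d hub(s)\n",
              length(x$scores), length(x$hubs)))
  invisible(x)
}

#' Select the most creative vertices
#'
#' Takes the top `ceiling(creative_fraction * n_eligible)` scored vertices
#' by descending score, ties broken by ascending label.
#'
#' @param cs a `creative_scores` object.
#' @param creative_fraction fraction of eligible vertices to select,
#'   in (0, 1].
#' @return character vector of selected labels (empty if none eligible).
#' @export
select_creative <- function(cs, creative_fraction = 0.15) {
  stopifnot(creative_fraction > 0, creative_fraction <= 1)
  s <- cs$scores
  if (length(s) == 0L) return(character())
  k <- ceiling(creative_fraction * length(s))
  names(s)[order(-s, seq_along(s))][seq_len(k)]
}

#' Greedily reattach removed vertices to growing seed clusters
#'
#' Each removed (creative) vertex is appended to the growing cluster holding
#' the most of its neighbors, counting creative vertices assigned earlier.
#' Assignment order is descending creative score (ties ascending label);
#' count ties between clusters go to the larger cluster, then to the cluster
#' with the smallest member label. A vertex with no neighbor in any growing
#' cluster becomes a singleton cluster.
#'
#' @param seeds list of pairwise-disjoint nonempty character vectors.
#' @param creative character vector of removed vertices, disjoint from all
#'   seeds; seeds and creative together must cover the graph.
#' @param g the igraph sub-network the seeds were derived from.
#' @param scores optional named numeric creative scores used for the
#'   assignment order; unscored vertices are ordered by label last.
#' @param normalized divide the neighbor overlap by the current cluster
#'   size before comparing clusters.
#' @return list of character vectors partitioning the vertices of `g`.
#' @export
expand_seeds <- function(seeds, creative, g, scores = NULL,
                         normalized = FALSE) {
  creative <- unique(as.character(creative))
  if (length(seeds) == 0L) stop("seeds must be nonempty")
  seed_members <- unlist(seeds, use.names = FALSE)
  if (anyDuplicated(seed_members)) stop("seeds must be pairwise disjoint")
  if (length(intersect(seed_members, creative)) > 0L) {
    stop("creative vertices must be disjoint from the seeds")
  }
  if (!setequal(c(seed_members, creative), igraph::V(g)$name)) {
    stop("seeds and creative vertices must cover the graph")
  }
  clusters <- lapply(seeds, function(x) label_sort(as.character(x)))
  ord_score <- if (is.null(scores)) rep(0, length(creative)) else {
    s <- scores[creative]
    s[is.na(s)] <- -Inf
    as.numeric(s)
  }
  lab_rank <- rank(creative, ties.method = "first")
  creative <- creative[order(-ord_score, lab_rank)]
  adj <- igraph::as_adj_list(g)
  labels <- igraph::V(g)$name
  for (v in creative) {
    nb <- labels[as.integer(adj[[match(v, labels)]])]
    overlap <- vapply(clusters, function(cl) sum(nb %in% cl), numeric(1L))
    if (max(overlap) == 0) {
      clusters <- c(clusters, list(v))
      next
    }
    crit <- if (normalized) overlap / lengths(clusters) else overlap
    first <- vapply(clusters, `[`, character(1L), 1L)
    best <- order(-crit, -lengths(clusters),
                  rank(first, ties.method = "first"))[1L]
    clusters[[best]] <- label_sort(c(clusters[[best]], v))
  }
  clusters
}

#' Divisive creative-element clustering
#'
#' Starting from the whole network, repeatedly dequeues a sub-network and
#' either declares it a terminal cluster or splits it: hubs and creative
#' scores are recomputed within the sub-network, the top creative vertices
#' are removed, and if the remainder falls apart its components seed new
#' clusters to which the removed vertices are greedily reattached
#' ([expand_seeds()]); those clusters are enqueued for further splitting. A
#' dequeued sub-network is terminal when it has at most `min_size` vertices
#' or when removing its creative vertices leaves it connected (or empty) —
#' it is then not clusterable. The result is always a partition of the
#' vertex set.
#'
#' @param g a nonempty igraph graph with named vertices.
#' @param hub_fraction fraction of vertices treated as hubs within each
#'   dequeued sub-network.
#' @param creative_fraction fraction of eligible vertices removed per
#'   iteration.
#' @param min_size sub-networks of at most this many vertices are terminal.
#' @param normalized passed to [expand_seeds()].
#' @param verbose log one line per dequeued sub-network to stderr.
#' @return a non-overlapping `clustering` covering every vertex of `g`.
#' @export
c_element_cluster <- function(g, hub_fraction = 0.2, creative_fraction = 0.15,
                              min_size = 3L, normalized = FALSE,
                              verbose = FALSE) {
  if (igraph::vcount(g) == 0L) stop("graph must be nonempty")
  stopifnot(min_size >= 1L)
  queue <- list(vertex_labels(g))
  done <- list()
  while (length(queue) > 0L) {
    members <- queue[[1L]]
    queue <- queue[-1L]
    if (length(members) <= min_size) {
      done <- c(done, list(members))
      next
    }
    sub <- graph_subset(g, members)
    hubs <- find_hubs(sub, hub_fraction)
    cs <- creative_scores(sub, hubs)
    creative <- select_creative(cs, creative_fraction)
    remainder <- setdiff(members, creative)
    parts <- if (length(remainder) > 0L) {
      graph_components(graph_subset(sub, remainder))
    } else list()
    if (verbose) {
      message(sprintf(
        "sub-network n=%d: %d hub(s), %d creative removed, %d component(s)",
        length(members), length(hubs), length(creative), length(parts)))
    }
    if (length(parts) <= 1L) {
      # removal left the sub-network connected (or empty): not clusterable
      done <- c(done, list(members))
      next
    }
    children <- expand_seeds(parts, creative, sub, scores = cs$scores,
                             normalized = normalized)
    for (child in children) {
      if (length(child) == 1L && child %in% creative) {
        # detached creative vertex: terminal singleton, never re-queued
        done <- c(done, list(child))
      } else {
        queue <- c(queue, list(child))
      }
    }
  }
  new_clustering(done, vertex_labels(g), overlapping = FALSE)
}
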