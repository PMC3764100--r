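# Classical vertex centrality measures.
#
# Twelve measures commonly used to rank vertices of an undirected simple
# graph. Distance-based measures (closeness, eccentricity, radiality) are
# computed within each connected component so every score stays finite on
# disconnected graphs; vertices in singleton components score 0.

CENTRALITY_MEASURES <- c(
  "degree", "leverage", "local_leader", "strict_leader", "closeness",
  "eccentricity", "radiality", "betweenness", "pagerank", "eigenvector",
  "power", "clustering_coefficient", "k_step_markov"
)

#' Compute a classical centrality measure
#'
#' Returns one finite score per vertex for the requested measure:
#' \describe{
#'   \item{degree}{number of distinct neighbors.}
#'   \item{leverage}{mean over neighbors w of (k_v - k_w)/(k_v + k_w);
#'     isolated vertices score 0.}
#'   \item{local_leader / strict_leader}{indicator (1/0): the vertex's
#'     degree is at least / strictly greater than every neighbor's degree.}
#'   \item{closeness}{reciprocal of the sum of shortest-path distances to
#'     the other vertices of the vertex's component; 0 in singleton
#'     components.}
#'   \item{eccentricity}{reciprocal of the within-component eccentricity
#'     (greatest distance to any vertex of the component); 0 in singleton
#'     components.}
#'   \item{radiality}{mean over the other vertices w of the component of
#'     (component diameter + 1 - d(v, w)); 0 in singleton components.}
#'   \item{betweenness}{unnormalized shortest-path betweenness.}
#'   \item{pagerank}{PageRank with damping `damping` (default 0.85);
#'     scores sum to 1.}
#'   \item{eigenvector}{leading adjacency eigenvector, scaled to maximum 1.}
#'   \item{power}{Bonacich power centrality with attenuation `beta`;
#'     default 1/(largest adjacency eigenvalue + `beta_tol`).}
#'   \item{clustering_coefficient}{local clustering coefficient
#'     (triangle density of the neighborhood); degree < 2 scores 0.}
#'   \item{k_step_markov}{expected number of visits to the vertex in the
#'     first `k_steps` (default 6) steps of random walks started uniformly
#'     over all vertices.}
#' }
#'
#' @param g an igraph graph with named vertices; must be nonempty.
#' @param measure one of the names above.
#' @param damping PageRank damping factor.
#' @param beta Bonacich attenuation; `NULL` for the spectral default.
#' @param beta_tol offset added to the leading eigenvalue for the default
#'   `beta`.
#' @param k_steps walk length for `k_step_markov`.
#' @return object of class `centrality_result`: list with `measure` and a
#'   named numeric `scores` vector (names in ascending label order).
#' @export
classical_centrality <- function(g, measure, damping = 0.85, beta = NULL,
                                 beta_tol = 0.01, k_steps = 6L) {
  if (igraph::vcount(g) == 0L) stop("graph must be nonempty")
  if (!is.character(measure) || length(measure) != 1L ||
      !(measure %in% CENTRALITY_MEASURES)) {
    stop("unknown centrality measure: ", paste(measure, collapse = ", "))
  }
  labels <- igraph::V(g)$name
  deg <- igraph::degree(g)
  scores <- switch(measure,
    degree = deg,
    leverage = {
      adj <- igraph::as_adj_list(g)
      vapply(seq_along(labels), function(i) {
        kw <- deg[as.integer(adj[[i]])]
        if (length(kw) == 0L) return(0)
        mean((deg[i] - kw) / (deg[i] + kw))
      }, numeric(1L))
    },
    local_leader = leader_indicator(g, deg, strict = FALSE),
    strict_leader = leader_indicator(g, deg, strict = TRUE),
    closeness = per_component(g, function(d, diam) {
      s <- rowSums(d)
      ifelse(s > 0, 1 / s, 0)
    }),
    eccentricity = per_component(g, function(d, diam) {
      e <- apply(d, 1L, max)
      ifelse(e > 0, 1 / e, 0)
    }),
    radiality = per_component(g, function(d, diam) {
      n <- nrow(d)
      if (n == 1L) return(0)
      rowSums(diam + 1 - d) / (n - 1) - (diam + 1) / (n - 1)
    }),
    betweenness = igraph::betweenness(g, directed = FALSE),
    pagerank = igraph::page_rank(g, damping = damping)$vector,
    eigenvector = igraph::eigen_centrality(g)$vector,
    power = {
      if (is.null(beta)) {
        lambda <- max(eigen(as.matrix(igraph::as_adjacency_matrix(g)),
                            symmetric = TRUE, only.values = TRUE)$values)
        beta <- 1 / (lambda + beta_tol)
      }
      igraph::power_centrality(g, exponent = beta, rescale = FALSE)
    },
    clustering_coefficient =
      igraph::transitivity(g, type = "local", isolates = "zero"),
    k_step_markov = k_step_markov_scores(g, k_steps)
  )
  scores <- as.numeric(scores)
  names(scores) <- labels
  structure(list(measure = measure, scores = scores[label_sort(labels)]),
            class = "centrality_result")
}

leader_indicator <- function(g, deg, strict) {
  adj <- igraph::as_adj_list(g)
  vapply(seq_along(deg), function(i) {
    kw <- deg[as.integer(adj[[i]])]
    ok <- if (strict) all(deg[i] > kw) else all(deg[i] >= kw)
    as.numeric(ok)
  }, numeric(1L))
}

# apply fn(distance_matrix, diameter) within each connected component
per_component <- function(g, fn) {
  labels <- igraph::V(g)$name
  out <- numeric(length(labels))
  names(out) <- labels
  for (comp in graph_components(g)) {
    if (length(comp) == 1L) {
      out[comp] <- 0
      next
    }
    sub <- graph_subset(g, comp)
    d <- igraph::distances(sub)
    val <- fn(d, max(d))
    out[rownames(d)] <- val
  }
  out[labels]
}

# cumulative visit counts of a K-step random walk from a uniform start
k_step_markov_scores <- function(g, k_steps) {
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  rs <- rowSums(a)
  p <- a / ifelse(rs > 0, rs, 1)   # rows of isolated vertices stay zero
  x <- rep(1 / nrow(a), nrow(a))
  total <- numeric(nrow(a))
  for (step in seq_len(k_steps)) {
    x <- as.numeric(x %*% p)
    total <- total + x
  }
  total
}

#' @export
print.centrality_result <- function(x, ...) {
  cat(sprintf("centrality_result: %s over %d vertices\n",
              x$measure, length(x$scores)))
  top <- top_ranked(x, min(5L, length(x$scores)))
  cat("top:", paste(sprintf("%s=%.4g", top, x$scores[top]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Top-ranked vertices of a centrality result
#'
#' @param result a `centrality_result`.
#' @param k number of vertices to return (capped at the number scored).
#' @return character vector of labels ordered by descending score, ties
#'   broken by ascending label.
#' @export
top_ranked <- function(result, k) {
  stopifnot(k >= 1L)
  s <- result$scores
  labs <- label_sort(names(s))
  s <- s[labs]
  labs[order(-s, seq_along(labs))][seq_len(min(k, length(s)))]
}
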