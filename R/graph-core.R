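# Graph data model and file I/O.
#
# Graphs are plain igraph objects: undirected, simple (no self-loops, no
# multi-edges), with a mandatory character `name` vertex attribute. Vertex
# labels are opaque, case-sensitive strings; all label ordering in the
# package uses C-locale (radix) collation so output is locale-independent.

# locale-independent label sort used everywhere ordering matters
label_sort <- function(x) {
  if (is.null(x)) return(character())
  sort(x, method = "radix")
}

#' Build a simple undirected labeled graph
#'
#' Constructs an igraph graph from a two-column character edge matrix and an
#' optional set of additional (possibly isolated) vertices. Self-loops are
#' dropped with a warning and parallel/reversed duplicate edges are
#' collapsed, so the result is always a simple undirected graph.
#'
#' @param edges two-column character matrix (or data frame) of endpoints;
#'   may have zero rows.
#' @param vertices optional character vector of vertex labels to include in
#'   addition to all edge endpoints.
#' @return an undirected simple igraph graph with vertices in ascending
#'   label order.
#' @export
make_network <- function(edges, vertices = character()) {
  edges <- as.matrix(edges)
  if (ncol(edges) == 0L || nrow(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  if (ncol(edges) != 2L) stop("edge matrix must have exactly two columns")
  storage.mode(edges) <- "character"
  loops <- edges[, 1L] == edges[, 2L]
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  # canonical undirected orientation, then dedupe
  flip <- edges[, 1L] > edges[, 2L]
  edges[flip, ] <- edges[flip, c(2L, 1L), drop = FALSE]
  edges <- unique(edges)
  labels <- label_sort(unique(c(as.vector(edges), vertices)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1L], to = edges[, 2L],
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = labels)
  )
  g
}

#' Vertex labels of a graph
#' @param g an igraph graph with named vertices.
#' @return character vector of labels in ascending label order.
#' @export
vertex_labels <- function(g) label_sort(igraph::V(g)$name)

#' Read an undirected network from an edge-list file
#'
#' Supports two dialects. `tsv`: two tab-separated columns per line, one
#' edge per line; lines starting with `#` are skipped; `header = TRUE`
#' skips the first non-comment line. `sif`: whitespace-separated
#' `source interaction target [target ...]` records where the interaction
#' type is ignored; a single-column SIF line declares an isolated vertex.
#'
#' Self-loops are dropped with a warning; duplicate and reversed edges are
#' collapsed. Isolated vertices can only be represented in the SIF dialect.
#'
#' @param path path to the file (or a connection).
#' @param format `"tsv"` or `"sif"`.
#' @param header logical; skip the first non-comment line (TSV only).
#' @return an undirected simple igraph graph.
#' @export
read_edge_list <- function(path, format = c("tsv", "sif"), header = FALSE) {
  format <- match.arg(format)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (format == "tsv" && header && length(lines) > 0L) {
    lines <- lines[-1L]
    lineno <- lineno[-1L]
  }
  if (length(lines) == 0L) stop("empty input: no edges found")
  if (format == "tsv") {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 2L)
    if (length(bad) > 0L) {
      stop(sprintf("malformed TSV edge line %d: expected 2 columns, got %d",
                   lineno[bad[1L]], lengths(parts)[bad[1L]]))
    }
    edges <- matrix(unlist(parts), ncol = 2L, byrow = TRUE)
    singles <- character()
  } else {
    parts <- strsplit(trimws(lines), "[ \t]+")
    bad <- which(lengths(parts) == 2L)
    if (length(bad) > 0L) {
      stop(sprintf(
        "malformed SIF line %d: expected 1 or >= 3 columns, got 2",
        lineno[bad[1L]]))
    }
    singles <- unlist(lapply(parts[lengths(parts) == 1L], `[`, 1L))
    multi <- parts[lengths(parts) >= 3L]
    edges <- do.call(rbind, c(list(matrix(character(), ncol = 2L)),
      lapply(multi, function(p) cbind(p[1L], p[-(1:2)]))))
  }
  make_network(edges, vertices = singles)
}

#' Write a graph as a two-column TSV edge list
#'
#' Edges are written in canonical orientation (smaller label first) and
#' ascending order, so equal graphs produce byte-identical files.
#'
#' @param g an igraph graph with named vertices.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_edgelist(g)
  if (nrow(el) > 0L) {
    flip <- el[, 1L] > el[, 2L]
    el[flip, ] <- el[flip, c(2L, 1L), drop = FALSE]
    el <- el[order(el[, 1L], el[, 2L], method = "radix"), , drop = FALSE]
  }
  writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), path)
  invisible(path)
}

#' Induced subgraph on a set of vertex labels
#'
#' @param g an igraph graph with named vertices.
#' @param keep character vector of labels to retain; must all be in `g`.
#' @return the subgraph induced by `keep` (its vertices and every edge of
#'   `g` with both endpoints in `keep`).
#' @export
graph_subset <- function(g, keep) {
  keep <- unique(as.character(keep))
  missing <- setdiff(keep, igraph::V(g)$name)
  if (length(missing) > 0L) {
    stop("labels not in graph: ", paste(missing, collapse = ", "))
  }
  igraph::induced_subgraph(g, keep)
}

#' Connected components as label sets
#'
#' @param g an igraph graph with named vertices.
#' @return list of character vectors (each sorted ascending), one per
#'   connected component, ordered by each component's smallest label.
#' @export
graph_components <- function(g) {
  comp <- igraph::components(g)
  sets <- unname(split(igraph::V(g)$name, comp$membership))
  sets <- lapply(sets, label_sort)
  sets[order(vapply(sets, `[`, character(1L), 1L), method = "radix")]
}

#' Vertex degrees as a named vector
#'
#' @param g an igraph graph with named vertices.
#' @return named integer vector, names in ascending label order.
#' @export
degree_map <- function(g) {
  d <- igraph::degree(g, loops = FALSE)
  d <- d[label_sort(names(d))]
  storage.mode(d) <- "integer"
  d
}

# ---- Clustering container -------------------------------------------------

#' Construct a clustering over a graph
#'
#' A `clustering` holds an ordered list of vertex-set clusters together with
#' the vertex universe of the source graph. A non-overlapping clustering
#' must be a partition of the universe; an overlapping one (as produced by
#' [extend_clusters()]) may repeat vertices across clusters.
#'
#' @param clusters list of nonempty character vectors of vertex labels.
#' @param universe character vector of all vertex labels of the source
#'   graph.
#' @param overlapping logical; clusters may share vertices.
#' @return an object of class `clustering`.
#' @export
new_clustering <- function(clusters, universe, overlapping = FALSE) {
  clusters <- lapply(clusters, function(x) label_sort(unique(as.character(x))))
  universe <- label_sort(unique(as.character(universe)))
  if (any(lengths(clusters) == 0L)) stop("clusters must be nonempty")
  members <- unlist(clusters, use.names = FALSE)
  if (!all(members %in% universe)) {
    stop("cluster members must belong to the graph vertex set")
  }
  if (!overlapping) {
    if (anyDuplicated(members)) stop("non-overlapping clusters must be disjoint")
    if (!setequal(members, universe)) {
      stop("non-overlapping clustering must cover every vertex")
    }
  }
  structure(
    list(clusters = canonical_cluster_order(clusters),
         universe = universe, overlapping = overlapping),
    class = "clustering"
  )
}

# descending size, ties by smallest member label
canonical_cluster_order <- function(clusters) {
  if (length(clusters) == 0L) return(clusters)
  first <- vapply(clusters, `[`, character(1L), 1L)
  clusters[order(-lengths(clusters), rank(first, ties.method = "first"))]
}

#' @export
print.clustering <- function(x, ...) {
  cat(sprintf("clustering: %d cluster(s) over %d vertices%s\n",
              length(x$clusters), length(x$universe),
              if (x$overlapping) " (overlapping)" else ""))
  sizes <- lengths(x$clusters)
  cat("sizes:", paste(sizes, collapse = " "), "\n")
  invisible(x)
}

#' Write a clustering as TSV (one cluster per line)
#'
#' Each line holds the tab-separated member labels of one cluster; clusters
#' appear by descending size (ties by smallest label) and members ascending,
#' so equal clusterings produce byte-identical files.
#'
#' @param clustering a `clustering` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_clustering <- function(clustering, path) {
  lines <- vapply(clustering$clusters, paste, character(1L), collapse = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a clustering from TSV (one cluster per line)
#'
#' @param path input file path.
#' @param universe character vector of all graph vertex labels; defaults to
#'   the union of cluster members.
#' @param overlapping logical flag for the resulting clustering.
#' @return a `clustering` object.
#' @export
read_clustering <- function(path, universe = NULL, overlapping = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty clustering file")
  clusters <- strsplit(lines, "\t", fixed = TRUE)
  if (is.null(universe)) universe <- unique(unlist(clusters))
  new_clustering(clusters, universe, overlapping = overlapping)
}
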