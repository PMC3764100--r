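# Benchmark fixtures and synthetic network generators.
#
# Everything here is a pure function of its arguments (including the
# seed), so every pipeline stage is testable without network downloads:
# the packaged Zachary karate-club benchmark, planted-module networks with
# known ground truth, matching synthetic annotations, and a two-module toy
# whose bridge vertices are creative elements by construction.

# evaluate code under a temporary RNG state; restores the caller's state
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  })
  set.seed(seed)
  force(code)
}

#' The Zachary karate-club benchmark graph
#'
#' Reads the edge list packaged under `extdata/karate.tsv`: the standard
#' 34-vertex, 78-edge social network with vertex labels `"1"` to `"34"`,
#' a classic benchmark for community detection.
#'
#' @return an igraph graph with 34 vertices and 78 edges.
#' @export
karate_graph <- function() {
  path <- system.file("extdata", "karate.tsv", package = "creclust",
                      mustWork = TRUE)
  read_edge_list(path, format = "tsv")
}

#' Planted-module random network with optional bridge vertices
#'
#' Generates a PPI-like benchmark graph with known module structure:
#' within-module edges are drawn independently with probability `p_in`,
#' between-module edges with probability `p_out`, and each bridge vertex
#' is attached by single edges to one highest-degree vertex (a module-level
#' hub) in each of two distinct modules — the minimal "weak connections to
#' hubs" topology of a creative element.
#'
#' @param sizes positive integer module sizes (must sum to at least 2).
#' @param p_in within-module edge probability; `p_out < p_in`.
#' @param p_out between-module edge probability.
#' @param n_bridges number of bridge vertices to add.
#' @param seed RNG seed; identical arguments give identical output.
#' @return list with `graph` (igraph), and `truth`, an object of class
#'   `planted_truth` holding `membership` (named integer module index over
#'   the non-bridge vertices), `modules` (list of label sets) and
#'   `bridges` (character labels).
#' @export
planted_modules <- function(sizes, p_in, p_out, n_bridges = 0L, seed = 1L) {
  stopifnot(length(sizes) >= 1L, all(sizes >= 1L),
            p_out >= 0, p_out < p_in, p_in <= 1, n_bridges >= 0L)
  if (sum(sizes) < 2L) stop("module sizes must sum to at least 2")
  width <- nchar(as.character(max(sizes)))
  modules <- lapply(seq_along(sizes), function(k) {
    sprintf("M%d_%0*d", k, width, seq_len(sizes[k]))
  })
  membership <- rep(seq_along(sizes), sizes)
  names(membership) <- unlist(modules)
  with_seed(seed, {
    edges <- list()
    for (k in seq_along(modules)) {
      if (sizes[k] >= 2L) {
        pairs <- t(utils::combn(modules[[k]], 2L))
        keep <- stats::runif(nrow(pairs)) < p_in
        edges[[length(edges) + 1L]] <- pairs[keep, , drop = FALSE]
      }
    }
    if (length(modules) >= 2L && p_out > 0) {
      for (k in seq_len(length(modules) - 1L)) {
        for (j in seq(k + 1L, length(modules))) {
          pairs <- as.matrix(expand.grid(modules[[k]], modules[[j]],
                                         stringsAsFactors = FALSE))
          keep <- stats::runif(nrow(pairs)) < p_out
          edges[[length(edges) + 1L]] <- pairs[keep, , drop = FALSE]
        }
      }
    }
    base_edges <- do.call(rbind, c(list(matrix(character(), ncol = 2L)),
                                   edges))
    bridges <- if (n_bridges > 0L) sprintf("B%d", seq_len(n_bridges))
               else character()
    if (n_bridges > 0L) {
      # degrees from the module-level edges decide each module's hub
      deg <- table(factor(as.vector(base_edges),
                          levels = names(membership)))
      for (b in bridges) {
        targets <- sample(seq_along(modules), 2L)
        for (k in targets) {
          dk <- deg[modules[[k]]]
          top <- names(dk)[dk == max(dk)]
          anchor <- if (length(top) == 1L) top else sample(top, 1L)
          base_edges <- rbind(base_edges, c(b, anchor))
        }
      }
    }
    g <- make_network(base_edges, vertices = c(names(membership), bridges))
    truth <- structure(list(membership = membership, modules = modules,
                            bridges = bridges),
                       class = "planted_truth")
    list(graph = g, truth = truth)
  })
}

#' Synthetic annotations matching a planted truth
#'
#' Gives every module `terms_per_module` dedicated terms annotating all of
#' its members; bridge vertices carry no annotation. With probability
#' `noise`, each individual (protein, term) annotation is reassigned to a
#' protein drawn uniformly from the whole network. At `noise = 0` the
#' annotation-derived modules coincide exactly with the planted modules.
#'
#' @param truth a `planted_truth` (see [planted_modules()]).
#' @param terms_per_module number of dedicated terms per module.
#' @param noise per-annotation reassignment probability in [0, 1].
#' @param seed RNG seed.
#' @return an `annotation_map` whose universe is the full vertex set
#'   (module members plus bridges).
#' @export
synthetic_annotations <- function(truth, terms_per_module = 1L, noise = 0,
                                  seed = 1L) {
  stopifnot(inherits(truth, "planted_truth"),
            terms_per_module >= 1L, noise >= 0, noise <= 1)
  all_proteins <- c(names(truth$membership), truth$bridges)
  prot <- character()
  term <- character()
  for (k in seq_along(truth$modules)) {
    for (j in seq_len(terms_per_module)) {
      prot <- c(prot, truth$modules[[k]])
      term <- c(term, rep(sprintf("T%d_%d", k, j),
                          length(truth$modules[[k]])))
    }
  }
  with_seed(seed, {
    if (noise > 0 && length(prot) > 0L) {
      flip <- stats::runif(length(prot)) < noise
      prot[flip] <- sample(all_proteins, sum(flip), replace = TRUE)
    }
    keep <- !duplicated(paste0(prot, "\r", term))
    annotations <- lapply(split(term[keep], prot[keep]), unique)
    new_annotation_map(annotations, aspect = "other",
                       universe = all_proteins)
  })
}

#' Two-module toy network bridged only by creative elements
#'
#' Builds two hub-centered modules — a hub adjacent to every module member
#' plus a sparse ring among the members — joined exclusively through two
#' low-degree bridge vertices, each adjacent to both hubs and nothing
#' else. By construction the bridges attain the maximum creative score
#' (1: every neighbor is a hub) while every other vertex keeps at least
#' one non-hub neighbor, and removing the bridges disconnects the graph.
#'
#' @param module_size vertices per module including its hub; at least 4.
#' @param seed RNG seed (rotates the member rings; the topology is
#'   isomorphic across seeds).
#' @return list with `graph` (igraph) and `bridges` (the two designated
#'   bridge labels).
#' @export
csermely_toy <- function(module_size = 8L, seed = 1L) {
  stopifnot(module_size >= 4L)
  mm <- module_size - 1L           # members per module besides the hub
  with_seed(seed, {
    edges <- matrix(character(), ncol = 2L)
    hubs <- c("h1", "h2")
    for (side in 1:2) {
      members <- sprintf("m%d_%02d", side, seq_len(mm))
      rot <- sample.int(mm, 1L) - 1L
      ring <- members[((seq_len(mm) - 1L + rot) %% mm) + 1L]
      edges <- rbind(edges, cbind(hubs[side], members))
      nxt <- ring[c(seq(2L, mm), 1L)]
      edges <- rbind(edges, cbind(ring, nxt))
      if (mm >= 5L) {
        o <- mm %/% 2L
        far <- ring[((seq_len(mm) - 1L + o) %% mm) + 1L]
        edges <- rbind(edges, cbind(ring, far))
      }
    }
    bridges <- c("x1", "x2")
    edges <- rbind(edges, cbind(bridges, hubs[1L]), cbind(bridges, hubs[2L]))
    list(graph = make_network(edges), bridges = bridges)
  })
}
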