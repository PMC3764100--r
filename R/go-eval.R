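# Cluster-quality evaluation against annotation-derived functional modules.
#
# Every annotation term defines a functional module: the set of proteins
# carrying that term (flat annotation sets; no ontology-graph propagation).
# Three agreement measures are computed per cluster, each in [0, 1]:
# Jaccard (best intersection-over-union against any module),
# precision-recall (best product of cluster precision and module recall),
# and semantic density (mean pairwise annotation-specificity weight among
# the cluster's annotated members). Singleton clusters score 0 on all
# three; summaries are size-weighted means over clusters.

#' Construct an annotation map
#'
#' @param annotations named list mapping protein label to a character
#'   vector of term identifiers (possibly empty).
#' @param aspect annotation aspect: `"BP"`, `"CC"` or `"other"`.
#' @param universe either an integer — the number of proteins in the
#'   evaluated network — or a character vector of its protein labels;
#'   `NULL` uses the number of annotated proteins.
#' @return object of class `annotation_map` with elements `terms` (the
#'   per-protein term sets), `aspect` and `universe_size`.
#' @export
new_annotation_map <- function(annotations, aspect = c("BP", "CC", "other"),
                               universe = NULL) {
  aspect <- match.arg(aspect)
  stopifnot(is.list(annotations))
  annotations <- lapply(annotations, function(x) label_sort(unique(as.character(x))))
  annotations <- annotations[label_sort(names(annotations))]
  n_ann <- length(annotations)
  universe_size <- if (is.null(universe)) n_ann
    else if (is.character(universe)) length(unique(universe))
    else as.integer(universe)
  if (universe_size < n_ann) {
    stop("universe_size must cover every annotated protein")
  }
  structure(list(terms = annotations, aspect = aspect,
                 universe_size = universe_size),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("annotation_map (%s): %d annotated protein(s), %d term(s), universe %d\n",
              x$aspect, length(x$terms),
              length(unique(unlist(x$terms))), x$universe_size))
  invisible(x)
}

#' Read protein annotations from GAF or two-column TSV
#'
#' GAF dialect: tab-separated; comment lines starting with `!` are
#' skipped; the protein is column 2, the term column 5, and column 9 is
#' the aspect code, filtered to `P` for `aspect = "BP"` and `C` for
#' `aspect = "CC"` (`"other"` keeps every row). TSV dialect: two columns,
#' protein then term, no aspect filtering.
#'
#' @param path file path (or connection).
#' @param format `"tsv"` or `"gaf"`.
#' @param aspect annotation aspect recorded on (and, for GAF, filtered
#'   into) the result.
#' @param universe passed to [new_annotation_map()].
#' @return an `annotation_map`.
#' @export
read_annotations <- function(path, format = c("tsv", "gaf"),
                             aspect = c("BP", "CC", "other"),
                             universe = NULL) {
  format <- match.arg(format)
  aspect <- match.arg(aspect)
  lines <- readLines(path)
  if (format == "gaf") {
    keep <- !startsWith(lines, "!") & nzchar(trimws(lines))
  } else {
    keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  }
  lineno <- which(keep)
  lines <- lines[keep]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "tsv") {
    bad <- which(lengths(parts) != 2L)
    if (length(bad) > 0L) {
      stop(sprintf("malformed annotation TSV line %d: expected 2 columns",
                   lineno[bad[1L]]))
    }
    prot <- vapply(parts, `[`, character(1L), 1L)
    term <- vapply(parts, `[`, character(1L), 2L)
  } else {
    bad <- which(lengths(parts) < 9L)
    if (length(bad) > 0L) {
      stop(sprintf("malformed GAF line %d: expected >= 9 columns, got %d",
                   lineno[bad[1L]], lengths(parts)[bad[1L]]))
    }
    prot <- vapply(parts, `[`, character(1L), 2L)
    term <- vapply(parts, `[`, character(1L), 5L)
    code <- vapply(parts, `[`, character(1L), 9L)
    wanted <- switch(aspect, BP = "P", CC = "C", other = unique(code))
    sel <- code %in% wanted
    prot <- prot[sel]
    term <- term[sel]
  }
  annotations <- if (length(prot) == 0L) structure(list(), names = character())
    else lapply(split(term, prot), function(x) unique(x))
  new_annotation_map(annotations, aspect = aspect, universe = universe)
}

#' Derive functional modules from an annotation map
#'
#' Inverts the protein-to-terms map: each term yields the module of all
#' proteins annotated with it.
#'
#' @param a an `annotation_map`.
#' @return named list mapping term to a sorted character vector of
#'   proteins (term names in ascending order).
#' @export
derive_modules <- function(a) {
  stopifnot(inherits(a, "annotation_map"))
  prot <- rep(names(a$terms), lengths(a$terms))
  term <- unlist(a$terms, use.names = FALSE)
  if (length(term) == 0L) return(structure(list(), names = character()))
  mods <- lapply(split(prot, term), function(x) label_sort(unique(x)))
  mods[label_sort(names(mods))]
}

#' Jaccard agreement of a cluster with its best-matching module
#'
#' Maximum over modules of intersection size over union size. Singleton
#' clusters score 0 by policy, as does any cluster when no modules exist.
#'
#' @param members character vector of cluster member labels.
#' @param modules named list of modules ([derive_modules()]).
#' @return a value in [0, 1].
#' @export
jaccard_score <- function(members, modules) {
  members <- unique(as.character(members))
  if (length(members) < 2L || length(modules) == 0L) return(0)
  max(vapply(modules, function(m) {
    i <- length(intersect(members, m))
    i / (length(members) + length(m) - i)
  }, numeric(1L)))
}

#' Precision-recall agreement of a cluster with its best-matching module
#'
#' Maximum over modules of (precision) x (recall) =
#' (|intersection|/|cluster|) x (|intersection|/|module|). Singleton
#' clusters score 0 by policy; no modules scores 0.
#'
#' @inheritParams jaccard_score
#' @return a value in [0, 1].
#' @export
pr_score <- function(members, modules) {
  members <- unique(as.character(members))
  if (length(members) < 2L || length(modules) == 0L) return(0)
  max(vapply(modules, function(m) {
    i <- length(intersect(members, m))
    (i / length(members)) * (i / length(m))
  }, numeric(1L)))
}

# per-term annotation frequency f_A = |module| / universe_size
term_frequencies <- function(a) {
  mods <- derive_modules(a)
  if (a$universe_size == 0L) stop("universe_size must be positive")
  vapply(mods, function(m) length(m) / a$universe_size, numeric(1L))
}

pair_weight_from_freq <- function(terms_p, terms_q, f, f_min,
                                  form = c("log", "linear")) {
  form <- match.arg(form)
  shared <- intersect(terms_p, terms_q)
  if (length(shared) == 0L) return(0)
  f_star <- min(f[shared])
  if (form == "linear") return(1 - f_star)
  if (f_star >= 1) return(0)       # a term annotating everything carries
  if (f_min >= 1) return(0)        # no information about specificity
  min(1, log(f_star) / log(f_min))
}

#' Annotation-specificity weight of a protein pair
#'
#' The weight reflects how specific the most informative shared term of
#' the two proteins is. With `f_A` the fraction of the network's proteins
#' annotated with term A, the pair's rarest shared term A* gives weight
#' `log(f_A*) / log(f_min)` where `f_min` is the rarest frequency in the
#' whole corpus — 1 when the pair shares the corpus's rarest term, 0 when
#' their only shared terms annotate every protein. `form = "linear"` uses
#' `1 - f_A*` instead. Pairs sharing no term (or with an unannotated
#' member) weigh 0.
#'
#' @param p,q protein labels.
#' @param a an `annotation_map`; its `universe_size` must be positive.
#' @param form weight normalization, `"log"` (default) or `"linear"`.
#' @return a value in [0, 1].
#' @export
pair_weight <- function(p, q, a, form = c("log", "linear")) {
  stopifnot(inherits(a, "annotation_map"))
  form <- match.arg(form)
  f <- term_frequencies(a)
  f_min <- if (length(f) > 0L) min(f) else 1
  pair_weight_from_freq(a$terms[[p]], a$terms[[q]], f, f_min, form)
}

#' Semantic density of a cluster
#'
#' Mean [pair_weight()] over all unordered pairs of annotated proteins in
#' the cluster. Clusters with fewer than two annotated members score 0
#' (extending the singleton-zero policy).
#'
#' @param members character vector of cluster member labels.
#' @param a an `annotation_map`.
#' @param form passed to [pair_weight()].
#' @return a value in [0, 1].
#' @export
semantic_density <- function(members, a, form = c("log", "linear")) {
  stopifnot(inherits(a, "annotation_map"))
  form <- match.arg(form)
  members <- unique(as.character(members))
  annotated <- members[members %in% names(a$terms)]
  annotated <- annotated[lengths(a$terms[annotated]) > 0L]
  if (length(annotated) < 2L) return(0)
  f <- term_frequencies(a)
  f_min <- min(f)
  pairs <- utils::combn(annotated, 2L)
  w <- apply(pairs, 2L, function(pq) {
    pair_weight_from_freq(a$terms[[pq[1L]]], a$terms[[pq[2L]]],
                          f, f_min, form)
  })
  mean(w)
}

#' Size-weighted evaluation of a clustering against annotation modules
#'
#' Computes Jaccard, precision-recall and semantic density per cluster and
#' their size-weighted means `sum(|c| * v(c)) / sum(|c|)`. With
#' `include_unclustered = TRUE` (default), network vertices absent from
#' every cluster are appended as zero-scoring singleton clusters before
#' averaging, so partial clusterings are not rewarded for dropping
#' vertices.
#'
#' @param clustering a `clustering`.
#' @param a an `annotation_map`.
#' @param include_unclustered append unclustered vertices as singletons.
#' @param form passed to the density computation.
#' @return object of class `evaluation_report`: list with `per_cluster`
#'   (data frame: size, jaccard, pr, density per cluster, in the
#'   clustering's canonical order) and `weighted` (named numeric of the
#'   three size-weighted means).
#' @export
weighted_summary <- function(clustering, a, include_unclustered = TRUE,
                             form = c("log", "linear")) {
  stopifnot(inherits(clustering, "clustering"), inherits(a, "annotation_map"))
  form <- match.arg(form)
  clusters <- clustering$clusters
  if (length(clusters) == 0L) stop("empty clustering")
  if (include_unclustered) {
    left <- setdiff(clustering$universe, unlist(clusters))
    clusters <- c(clusters, as.list(left))
  }
  modules <- derive_modules(a)
  per <- data.frame(
    cluster = vapply(clusters, paste, character(1L), collapse = ","),
    size = lengths(clusters),
    jaccard = vapply(clusters, jaccard_score, numeric(1L), modules = modules),
    pr = vapply(clusters, pr_score, numeric(1L), modules = modules),
    density = vapply(clusters, semantic_density, numeric(1L), a = a,
                     form = form),
    stringsAsFactors = FALSE
  )
  w <- per$size / sum(per$size)
  weighted <- c(jaccard = sum(w * per$jaccard),
                pr = sum(w * per$pr),
                density = sum(w * per$density))
  structure(list(per_cluster = per, weighted = weighted),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report over %d cluster(s)\n", nrow(x$per_cluster)))
  cat(sprintf("weighted: jaccard=%.4f pr=%.4f density=%.4f\n",
              x$weighted["jaccard"], x$weighted["pr"], x$weighted["density"]))
  invisible(x)
}
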