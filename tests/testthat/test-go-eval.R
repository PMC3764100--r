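test_that("annotation parsing handles TSV and GAF dialects", {
  a <- read_annotations(textConnection("p1\tT1\np2\tT1\n"), format = "tsv")
  expect_length(a$terms, 2)
  expect_identical(derive_modules(a), list(T1 = c("p1", "p2")))

  gaf <- paste(
    "!gaf-version: 2.1",
    paste("DB", "p1", "S1", "", "GO:1", "REF", "IEA", "", "F",
          rep("", 8), sep = "\t"),
    sep = "\n")
  expect_length(read_annotations(textConnection(gaf), format = "gaf",
                                 aspect = "BP")$terms, 0)

  gaf2 <- paste(
    paste("DB", "p1", "S1", "", "GO:1", "REF", "IEA", "", "P", sep = "\t"),
    paste("DB", "p1", "S1", "", "GO:1", "REF", "IEA", "", "P", sep = "\t"),
    paste("DB", "p2", "S2", "", "GO:2", "REF", "IEA", "", "C", sep = "\t"),
    sep = "\n")
  a2 <- read_annotations(textConnection(gaf2), format = "gaf", aspect = "BP")
  expect_identical(a2$terms, list(p1 = "GO:1"))  # duplicate row stored once
  a3 <- read_annotations(textConnection(gaf2), format = "gaf", aspect = "CC")
  expect_identical(a3$terms, list(p2 = "GO:2"))

  expect_error(read_annotations(textConnection("p1\tT1\tx\n"),
                                format = "tsv"), "line 1")
  expect_error(read_annotations(textConnection("a\tb\tc\n"),
                                format = "gaf"), "line 1")
})

test_that("module derivation inverts the annotation map", {
  a <- new_annotation_map(list(p1 = "T1", p2 = c("T1", "T2")))
  expect_identical(derive_modules(a),
                   list(T1 = c("p1", "p2"), T2 = "p2"))
  expect_length(derive_modules(new_annotation_map(list())), 0)

  # round-trip on a random 50-protein, 10-term map
  set.seed(42)
  prot <- sprintf("p%02d", 1:50)
  ann <- lapply(setNames(prot, prot),
                function(p) sample(sprintf("T%d", 1:10), sample(1:4, 1)))
  a2 <- new_annotation_map(ann)
  mods <- derive_modules(a2)
  back <- lapply(setNames(prot, prot), function(p) {
    sort(names(Filter(function(m) p %in% m, mods)), method = "radix")
  })
  expect_identical(back, a2$terms)
})

test_that("jaccard and pr scores match worked values and policies", {
  mods <- list(A = c("p2", "p3", "p4"))
  expect_equal(jaccard_score(c("p1", "p2", "p3"), mods), 0.5)
  expect_equal(pr_score(c("p1", "p2", "p3"), mods), 4 / 9)
  expect_equal(jaccard_score(c("p2", "p3", "p4"), mods), 1.0)
  expect_equal(pr_score(c("p2", "p3", "p4"), mods), 1.0)
  expect_equal(pr_score(c("x", "y"), mods), 0)
  # singleton policy and missing-module fallback
  expect_equal(jaccard_score("p1", mods), 0)
  expect_equal(pr_score("p1", mods), 0)
  expect_equal(jaccard_score(c("p1", "p2"), list()), 0)
})

test_that("adding a member of the best module never lowers pr against it", {
  set.seed(9)
  for (i in 1:10) {
    mods <- lapply(setNames(1:4, sprintf("T%d", 1:4)),
                   function(k) sprintf("p%02d", sample(1:20, sample(3:8, 1))))
    cl <- sprintf("p%02d", sample(1:20, 4))
    best <- which.max(vapply(mods, function(m) {
      i <- length(intersect(cl, m)); (i / length(cl)) * (i / length(m))
    }, numeric(1)))
    extra <- setdiff(mods[[best]], cl)
    if (length(extra) == 0) next
    pr_before <- {
      i <- length(intersect(cl, mods[[best]]))
      (i / length(cl)) * (i / length(mods[[best]]))
    }
    cl2 <- c(cl, extra[1])
    i2 <- length(intersect(cl2, mods[[best]]))
    pr_after <- (i2 / length(cl2)) * (i2 / length(mods[[best]]))
    expect_gte(pr_after, pr_before)
    expect_gte(pr_score(cl2, mods), pr_after - 1e-12)
  }
})

test_that("pair weight hits its endpoints and is symmetric", {
  a <- new_annotation_map(
    list(p1 = c("RARE", "COMMON"), p2 = c("RARE", "COMMON"),
         p3 = "COMMON", p4 = "COMMON"),
    universe = 4)
  # p1,p2 share the rarest term in the corpus
  expect_equal(pair_weight("p1", "p2", a), 1)
  # p3,p4 share only a term annotating every protein
  expect_equal(pair_weight("p3", "p4", a), 0)
  expect_equal(pair_weight("p1", "p3", a), 0)  # shared term has f = 1
  # no shared term
  b <- new_annotation_map(list(p1 = "X", p2 = "Y"), universe = 2)
  expect_equal(pair_weight("p1", "p2", b), 0)
  # symmetry on random maps
  set.seed(5)
  ann <- lapply(setNames(1:8, sprintf("p%d", 1:8)),
                function(i) sample(sprintf("T%d", 1:5), sample(0:3, 1)))
  m <- new_annotation_map(ann, universe = 8)
  for (i in 1:10) {
    pq <- sample(names(m$terms), 2)
    expect_equal(pair_weight(pq[1], pq[2], m), pair_weight(pq[2], pq[1], m))
  }
  # linear form endpoint
  expect_equal(pair_weight("p1", "p2", a, form = "linear"), 1 - 2 / 4)
})

test_that("semantic density averages pair weights with the singleton rule", {
  a <- new_annotation_map(
    list(p1 = "RARE", p2 = "RARE", p3 = "RARE", q = "OTHER",
         z1 = "F1", z2 = "F1", z3 = "F1", z4 = "F1"),
    universe = 8)
  w <- pair_weight("p1", "p2", a)
  expect_equal(semantic_density(c("p1", "p2"), a), w)       # single pair
  expect_equal(semantic_density(c("p1", "p2", "p3"), a), w) # constant mean
  expect_equal(semantic_density("p1", a), 0)                # singleton
  expect_equal(semantic_density(c("p1", "unannotated"), a), 0)
  expect_gte(w, 0); expect_lte(w, 1)
})

test_that("weighted summary averages by cluster size and counts leftovers", {
  a <- new_annotation_map(list(p1 = "T1", p2 = "T1", p3 = "T1"),
                          universe = 4)
  cl <- new_clustering(list(c("p1", "p2", "p3"), "p4"),
                       universe = c("p1", "p2", "p3", "p4"))
  rep <- weighted_summary(cl, a)
  # sizes 3 and 1 with per-cluster jaccard 1 and 0
  expect_equal(unname(rep$weighted["jaccard"]), 0.75)
  expect_equal(unname(rep$weighted["pr"]), 0.75)

  # unclustered vertices appended as zero-scoring singletons
  partial <- new_clustering(list(c("p1", "p2", "p3")),
                            universe = c("p1", "p2", "p3", "p4"),
                            overlapping = TRUE)
  rep2 <- weighted_summary(partial, a, include_unclustered = TRUE)
  expect_equal(unname(rep2$weighted["jaccard"]), 0.75)
  rep3 <- weighted_summary(partial, a, include_unclustered = FALSE)
  expect_equal(unname(rep3$weighted["jaccard"]), 1.0)

  expect_error(weighted_summary(
    structure(list(clusters = list(), universe = "p1", overlapping = FALSE),
              class = "clustering"), a), "empty")
})

test_that("planted-truth clusters on noise-free annotations score perfectly", {
  # equal module sizes so every dedicated term has the same frequency and
  # within-module pair weights all sit at the specificity endpoint
  sim <- planted_modules(c(8, 8, 8), p_in = 1, p_out = 0, n_bridges = 0,
                         seed = 11)
  truth_cl <- new_clustering(sim$truth$modules,
                             universe = vertex_labels(sim$graph))
  ann <- synthetic_annotations(sim$truth, terms_per_module = 2, noise = 0,
                               seed = 11)
  rep <- weighted_summary(truth_cl, ann)
  expect_equal(unname(rep$weighted["jaccard"]), 1.0)
  expect_equal(unname(rep$weighted["pr"]), 1.0)
  expect_equal(unname(rep$weighted["density"]), 1.0)
})
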