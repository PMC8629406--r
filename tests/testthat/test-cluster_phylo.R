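test_that("AF matrix places calls and zero-fills absences", {
  calls <- make_calls("A", pos = 1L, af = 0.2, depth = 0L, alt_reads = 0L)
  m <- build_af_matrix(calls, samples = c("A", "B"))
  expect_equal(dim(m), c(2L, 1L))
  expect_equal(unname(m["A", 1L]), 0.2)
  expect_equal(unname(m["B", 1L]), 0)
})

test_that("synonymous exclusion drops loci and can empty the matrix", {
  calls <- rbind(
    make_calls("A", pos = 1L, effect = "synonymous"),
    make_calls("A", pos = 2L, effect = "non_synonymous"),
    make_calls("B", pos = 1L, effect = "synonymous"))
  m <- build_af_matrix(calls, exclude_synonymous = TRUE)
  expect_equal(ncol(m), 1L)  # total loci - synonymous loci
  syn_only <- calls[calls$effect == "synonymous", ]
  expect_error(build_af_matrix(syn_only, exclude_synonymous = TRUE),
               "synonymous")
})

test_that("clustering merges identical samples at height zero and recovers
           constructed pairs at k = 2", {
  m <- rbind(S1 = c(0.5, 0.5, 0, 0), S2 = c(0.5, 0.5, 0, 0))
  cl <- cluster_samples(m)
  expect_equal(cl$sample_hclust$height[1L], 0)

  m2 <- rbind(A1 = c(1, 1, 0, 0), A2 = c(1, 1.01, 0, 0),
              B1 = c(0, 0, 1, 1), B2 = c(0, 0.01, 1, 1))
  cl2 <- cluster_samples(m2, k = 2L)
  expect_equal(unname(cl2$clusters["A1"]), unname(cl2$clusters["A2"]))
  expect_equal(unname(cl2$clusters["B1"]), unname(cl2$clusters["B2"]))
  expect_false(cl2$clusters[["A1"]] == cl2$clusters[["B1"]])

  m3 <- m2
  m3[1, 1] <- NaN
  expect_error(cluster_samples(m3), "NaN")
})

test_that("clustering is invariant to row permutation", {
  set.seed(41)
  m <- matrix(runif(5 * 8), nrow = 5,
              dimnames = list(paste0("S", 1:5), NULL))
  c1 <- cluster_samples(m)
  c2 <- cluster_samples(m[sample(5), , drop = FALSE])
  expect_equal(cophenetic(c1$sample_hclust), cophenetic(c2$sample_hclust))
})

test_that("AF distances are metric", {
  m <- rbind(A = c(0, 0), B = c(0.3, 0.4))
  expect_equal(unname(af_distance(m)["A", "B"]), 0.5)
  expect_equal(unname(af_distance(rbind(A = c(0.1, 0.2),
                                        B = c(0.1, 0.2)))["A", "B"]), 0)
  set.seed(42)
  for (rep in 1:100) {
    m <- matrix(runif(3 * 6), nrow = 3, dimnames = list(c("a", "b", "c"),
                                                        NULL))
    for (metric in c("euclidean", "manhattan")) {
      d <- af_distance(m, metric)
      expect_equal(d, t(d), tolerance = 1e-12)
      expect_equal(unname(diag(d)), rep(0, 3))
      expect_lte(d["a", "c"], d["a", "b"] + d["b", "c"] + 1e-12)
    }
  }
})

test_that("NJ recovers a known additive 5-taxon tree exactly", {
  true <- ape::read.tree(text = "(((a:1,b:2):1,(c:3,d:4):1):0.5,o:10);")
  d <- cophenetic(true)
  tr <- build_patient_tree(d, "o")
  expect_equal(attr(tr, "outgroup"), "o")
  expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(true)), 0)
  # branch lengths are recovered: patristic distances match the input
  d2 <- cophenetic(tr)[rownames(d), colnames(d)]
  expect_equal(d2, d, tolerance = 1e-8)
})

test_that("NJ recovers random additive topologies (spot check)", {
  set.seed(43)
  for (rep in 1:20) {
    n <- sample(6:10, 1L)
    true <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, 0.1, 2))
    d <- cophenetic(true)
    tr <- build_patient_tree(d, true$tip.label[1L])
    expect_equal(phangorn::RF.dist(ape::unroot(tr), true), 0)
  }
})

test_that("outgroup rooting preserves the unrooted topology and
           branch lengths stay nonnegative on noisy matrices", {
  set.seed(44)
  for (rep in 1:20) {
    n <- 6L
    m <- matrix(runif(n * 12), nrow = n,
                dimnames = list(paste0("S", 1:n), NULL))
    d <- af_distance(m)
    tr <- build_patient_tree(d, "S1")
    expect_true(all(tr$edge.length >= 0))
    raw <- ape::nj(as.dist(d))
    expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(raw)), 0)
  }
})

test_that("tree building validates its inputs", {
  d <- af_distance(rbind(A = c(0, 1), B = c(1, 0)))
  expect_error(build_patient_tree(d, "A"), "3 taxa")
  d3 <- af_distance(rbind(A = c(0, 1), B = c(1, 0), C = c(1, 1)))
  expect_error(build_patient_tree(d3, "Z"), "outgroup")
  tr <- build_patient_tree(d3, "C")  # 3 taxa: star resolved by rooting
  expect_setequal(tr$tip.label, c("A", "B", "C"))
})

test_that("cherries are the leaf pairs sharing an immediate ancestor", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  p <- tree_leaf_pairs(tr)
  expect_equal(nrow(p), 2L)
  expect_true(all(c("A", "C") %in% c(p$sample_a)))
  cat_tree <- ape::read.tree(text = "(((A,B),C),D);")
  p2 <- tree_leaf_pairs(cat_tree)
  expect_equal(nrow(p2), 1L)
  expect_equal(c(p2$sample_a, p2$sample_b), c("A", "B"))
  # outgroup exclusion
  p3 <- tree_leaf_pairs(ape::read.tree(text = "((A,B),(C,OUT));"),
                        exclude = "OUT")
  expect_equal(nrow(p3), 1L)
})
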