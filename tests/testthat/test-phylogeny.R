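test_that("protein distance matrix is a proper identity distance", {
  p1 <- "MKTAYIAKQRQISFVKSHFSRQ"
  d <- protein_distance_matrix(c(a = p1, b = p1, c = "MKTAYIAKQRQISFVKAAAAAA"))
  expect_equal(d["a", "b"], 0)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  ## hand-computed: c matches a over 16 of 22 aligned columns
  expect_equal(d["a", "c"], 1 - 16 / 22, tolerance = 1e-9)
})

test_that("neighbor joining recovers random additive trees exactly", {
  set.seed(1234)
  for (k in 1:50) {
    nt <- sample(4:8, 1)
    tr <- ape::rtree(nt, br = runif)
    tr$edge.length <- tr$edge.length + 0.05  # keep branches comfortably positive
    d <- cophenetic(tr)
    d <- d[sort(rownames(d)), sort(colnames(d))]
    got <- nj_tree(d)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(got)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("three taxa resolve to the unique star topology", {
  d <- matrix(c(0, .2, .4, .2, 0, .4, .4, .4, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  tr <- nj_tree(d)
  expect_equal(ape::Ntip(tr), 3L)
  expect_equal(tr$Nnode, 1L)
})

test_that("bootstrap supports separate two clean clades", {
  set.seed(99)
  base1 <- generate_transposase(200, "DD34E", seed = 1)$protein
  base2 <- generate_transposase(200, "DD37D", seed = 2)$protein
  mut <- function(p, k, seed) {
    set.seed(seed)
    x <- chars(p)
    at <- sample(seq_along(x), k)
    x[at] <- sample(tlemine:::AA20, k, replace = TRUE)
    paste(x, collapse = "")
  }
  seqs <- c(a1 = mut(base1, 3, 11), a2 = mut(base1, 3, 12),
            a3 = mut(base1, 3, 13), b1 = mut(base2, 3, 14),
            b2 = mut(base2, 3, 15), b3 = mut(base2, 3, 16))
  res <- bootstrap_nj(seqs, n_replicates = 100, seed = 7)
  expect_s3_class(res$tree, "phylo")
  expect_true(all(res$support >= 0 & res$support <= 100))
  ## internal splits separating the two clades are near-unanimous
  expect_gte(sort(res$support, decreasing = TRUE)[2], 95)
  expect_error(bootstrap_nj(seqs, n_replicates = 0), "positive")

  ## fixed seed reproducibility
  res2 <- bootstrap_nj(seqs, n_replicates = 100, seed = 7)
  expect_identical(ape::write.tree(res$tree), ape::write.tree(res2$tree))
})

test_that("newick export preserves topology and supports", {
  d <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  d["a", "b"] <- d["b", "a"] <- 0.1
  d["c", "d"] <- d["d", "c"] <- 0.1
  tr <- nj_tree(d)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(tr, path)
  back <- ape::read.tree(path)
  expect_equal(sort(back$tip.label), letters[1:4])
})
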