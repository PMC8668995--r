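test_that("three taxa give the closed-form star lengths", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, dimnames = list(c("a", "b", "c"),
                                                               c("a", "b", "c")))
  t <- neighbor_joining(D)
  expect_equal(sort(t$tip.label), c("a", "b", "c"))
  dd <- leaf_distances(t)
  expect_equal(dd["a", "b"], 3)
  expect_equal(dd["a", "c"], 4)
  expect_equal(dd["b", "c"], 5)
})

test_that("neighbor joining exactly recovers random additive trees", {
  set.seed(17)
  for (n in c(4, 6, 9, 12)) {
    t0 <- ape::rtree(n)
    D <- leaf_distances(t0)
    t1 <- neighbor_joining(D)
    expect_same_topology(t1, t0)
    expect_equal(leaf_distances(t1)[rownames(D), colnames(D)], D, tolerance = 1e-8)
    # cross-check against the reference NJ implementation
    expect_same_topology(t1, ape::nj(D))
  }
})

test_that("neighbor joining validates its inputs", {
  D <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(neighbor_joining(D), "at least 3")
  D3 <- matrix(c(0, 1, 2, 9, 0, 1, 2, 1, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(D3), "symmetric")
  D3b <- matrix(c(0, 1, NA, 1, 0, 1, NA, 1, 0), 3,
                dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(D3b), "NA")
})

test_that("negative NJ branch lengths are clamped with the deficit on the sister", {
  # classic non-additive matrix driving one branch negative
  D <- matrix(c(0, 5, 9, 9, 4,
                5, 0, 10, 10, 5,
                9, 10, 0, 8, 3,
                9, 10, 8, 0, 3,
                4, 5, 3, 3, 0), 5, byrow = TRUE,
              dimnames = list(letters[1:5], letters[1:5]))
  D["a", "b"] <- D["b", "a"] <- 0.1 # force a negative estimate
  t <- neighbor_joining(D)
  expect_true(all(t$edge.length >= 0))
})

test_that("midpoint rooting halves the tree diameter", {
  # balanced quartet: root on the central edge, equal heights
  tq <- from_newick("((a:1,b:1):1,(c:1,d:1):1);")
  r <- midpoint_root(ape::unroot(tq))
  depth <- ape::node.depth.edgelength(r)
  expect_equal(max(depth), 2)
  # caterpillar with one long terminal branch: root sits on that branch
  tc <- from_newick("(((a:1,b:1):1,c:1):1,d:10);")
  rc <- midpoint_root(ape::unroot(tc))
  dd <- leaf_distances(tc)
  expect_equal(max(ape::node.depth.edgelength(rc)), max(dd) / 2)
  root_children <- rc$edge[rc$edge[, 1] == length(rc$tip.label) + 1L, 2]
  expect_true(any(root_children <= length(rc$tip.label) &
                  rc$tip.label[root_children[root_children <= length(rc$tip.label)]] == "d"))

  set.seed(23)
  for (k in 1:8) {
    t0 <- ape::rtree(sample(4:10, 1))
    r0 <- midpoint_root(t0)
    expect_equal(max(ape::node.depth.edgelength(r0)),
                 max(leaf_distances(t0)) / 2, tolerance = 1e-10)
  }
})

test_that("a zero-length tree has no midpoint and warns", {
  t0 <- ape::rtree(4)
  t0$edge.length[] <- 0
  expect_warning(midpoint_root(t0), "no midpoint")
})

test_that("newick round-trips preserve topology, lengths and support labels", {
  t <- from_newick("(a:1,b:1);")
  expect_equal(sort(t$tip.label), c("a", "b"))
  expect_equal(to_newick(t), "(a:1,b:1);")

  ts <- from_newick("((a:1,b:1)0.97:0.5,c:2);")
  expect_true("0.97" %in% ts$node.label)
  expect_true(grepl("0.97", to_newick(ts)))

  set.seed(29)
  for (k in 1:10) {
    t0 <- ape::rtree(sample(3:15, 1))
    t1 <- from_newick(to_newick(t0))
    expect_same_topology(t0, t1)
    expect_equal(sort(t1$edge.length), sort(t0$edge.length), tolerance = 1e-6)
  }

  expect_error(from_newick("((a:1,b:1);"), "unbalanced")
  expect_error(from_newick("(a:1,b:1));"), "character 10")
  expect_error(from_newick("(a:1,a:2);"), "duplicate leaf label")
})

test_that("Robinson-Foulds distance counts one-sided bipartitions", {
  t1 <- from_newick("((a,b),(c,d));")
  expect_equal(robinson_foulds(t1, t1), 0)
  t2 <- from_newick("((a,c),(b,d));")
  expect_equal(robinson_foulds(t1, t2), 2)
  expect_equal(robinson_foulds(t2, t1), 2)
  t3 <- from_newick("((a,b),(c,e));")
  expect_error(robinson_foulds(t1, t3), "leaf sets differ")
})

test_that("Poisson correction transforms p-distances monotonically", {
  expect_equal(poisson_correct(0), 0)
  expect_gt(poisson_correct(0.5), 0.5)
  expect_error(poisson_correct(1), "Poisson")
})
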