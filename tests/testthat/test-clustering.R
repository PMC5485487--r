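test_that("correlation distance matches the direct Pearson formula", {
  x <- c(10, 20, 30, 40); y <- c(40, 10, 30, 20)
  m <- cbind(S1 = x, S2 = y)
  rownames(m) <- paste0("t", 1:4)
  d <- correlation_distance(m)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(d["S1", "S2"], 1 - r, tolerance = 1e-12)
  expect_equal(diag(unclass(d)), c(S1 = 0, S2 = 0))
  # identical and anticorrelated columns hit the range ends
  expect_equal(unname(correlation_distance(cbind(a = x, b = x))[1, 2]), 0)
  expect_equal(unname(correlation_distance(cbind(a = x, b = -x))[1, 2]), 2)
})

test_that("zero-variance samples are rejected by name", {
  m <- cbind(ok = c(1, 2, 3), flat = c(4, 4, 4))
  expect_error(correlation_distance(m), "flat", class = "sip_validation_error")
})

test_that("correlation distance is invariant to affine rescaling", {
  sipcall:::with_seed(21, {
    for (i in 1:10) {
      p <- random_profile(5)
      m <- unclass(p)
      m2 <- sweep(sweep(m, 2, runif(5, 0.5, 3), "*"), 2, runif(5, -2, 2), "+")
      expect_equal(unclass(correlation_distance(m)),
                   unclass(correlation_distance(m2)), tolerance = 1e-9)
    }
  })
})

test_that("ward linkage matches the exhaustive oracle on random profiles", {
  sipcall:::with_seed(31, {
    for (i in 1:20) {
      d <- correlation_distance(random_profile(sample(4:6, 1)))
      got <- ward_linkage(d)
      want <- ward_oracle(d)
      expect_identical(got$merge, want$merge)
      expect_equal(got$height, want$height, tolerance = 1e-9)
      expect_false(is.unsorted(got$height))  # no inversions
    }
  })
})

test_that("identical samples merge first at height zero", {
  p <- unclass(random_profile(4))
  m <- cbind(p, DUP = p[, 2])
  tree <- ward_linkage(correlation_distance(m))
  expect_equal(tree$height[1], 0)
  expect_setequal(tree$merge[1, ], c(-2L, -5L))
})

test_that("tree topology is invariant under sample relabeling", {
  sipcall:::with_seed(41, {
    p <- unclass(random_profile(6))
    t1 <- ward_linkage(correlation_distance(p))
    perm <- sample(ncol(p))
    t2 <- ward_linkage(correlation_distance(p[, perm]))
    key <- function(tr) sort(vapply(cluster_splits(tr), paste, "", collapse = "+"))
    expect_identical(key(t1), key(t2))
    expect_equal(sort(t1$height), sort(t2$height), tolerance = 1e-9)
  })
})

test_that("bootstrap support is seeded, reproducible, and 0/100 at n_boot 1", {
  p <- two_block_profile()
  b1 <- bootstrap_support(p, n_boot = 25, seed = 7)
  b2 <- bootstrap_support(p, n_boot = 25, seed = 7)
  expect_identical(b1$bp, b2$bp)
  b3 <- bootstrap_support(p, n_boot = 1, seed = 7)
  expect_true(all(b3$bp %in% c(0, 100)))
  expect_error(bootstrap_support(p[1, , drop = FALSE], 10, 1),
               class = "sip_validation_error")
})

test_that("newick export matches a hand-written caterpillar and round-trips", {
  cat4 <- structure(list(
    merge = rbind(c(-1L, -2L), c(-3L, 1L), c(-4L, 2L)),
    height = c(1, 2, 3), labels = c("A", "B", "C", "D"), bp = NULL),
    class = "sip_dendrogram")
  expect_equal(to_newick(cat4), "(D:3,(C:2,(A:1,B:1):1):1);")

  two <- structure(list(merge = rbind(c(-1L, -2L)), height = 0.5,
                        labels = c("A", "B"), bp = NULL),
                   class = "sip_dendrogram")
  expect_equal(to_newick(two), "(A:0.5,B:0.5);")

  # parse with an independent reader: topology and heights survive
  tree <- ward_linkage(correlation_distance(two_block_profile()))
  phy <- ape::read.tree(text = to_newick(tree))
  expect_equal(sort(phy$tip.label), sort(tree$labels))
  clades <- lapply(seq_len(phy$Nnode) + length(phy$tip.label), function(nd) {
    sort(ape::extract.clade(phy, nd)$tip.label)
  })
  for (s in cluster_splits(tree)) {
    expect_true(any(vapply(clades, identical, TRUE, y = s)))
  }
  # leaf depths equal the root height (ultrametric by construction)
  depths <- ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)]
  expect_equal(unname(depths), rep(max(tree$height), length(tree$labels)),
               tolerance = 1e-9)
})

test_that("bootstrap percentages ride along as newick node labels", {
  tree <- bootstrap_support(two_block_profile(), n_boot = 20, seed = 3)
  phy <- ape::read.tree(text = to_newick(tree))
  expect_true(all(as.numeric(phy$node.label) >= 0 &
                  as.numeric(phy$node.label) <= 100))
})
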