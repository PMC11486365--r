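test_that("the dissimilarity matrix is symmetric with zero diagonal", {
  s <- build_chain(torsion_prescription("GCGCGC"))
  shifted <- perturb_chain(s, mcq_default_angles(), 30)
  m <- mcq_dissimilarity(list(a = s, b = s, c = shifted))
  expect_equal(diag(m), c(a = 0, b = 0, c = 0))
  expect_equal(m, t(m))
  expect_equal(m["a", "b"], 0)
  expect_equal(m["a", "c"], 30, tolerance = 1e-6)
  expect_error(mcq_dissimilarity(list(a = s)), "at least two")
})

test_that("incomparable model pairs warn and leave NA entries", {
  set.seed(61)
  a <- synthetic_torsions(4, sequence = "AAAA")
  b <- synthetic_torsions(4, sequence = "CCCC")
  expect_warning(m <- mcq_dissimilarity(list(x = a, y = b)),
                 "undefined")
  expect_true(is.na(m["x", "y"]))
  expect_error(mds_embed(m), "undefined")
  expect_error(k_medoids(m, 1), "undefined")
  expect_error(mcq_dendrogram(m), "undefined")
})

test_that("classical MDS reproduces Euclidean configurations", {
  # two points embed at +/- d/2 on one axis
  m2 <- matrix(c(0, 8, 8, 0), 2, 2,
               dimnames = list(c("p", "q"), c("p", "q")))
  e2 <- mds_embed(m2)
  expect_equal(sort(abs(e2$dim1)), c(4, 4))
  expect_equal(e2$dim2, c(0, 0))
  expect_true(attr(e2, "degenerate"))

  # three collinear points, distances 1, 1, 2
  m3 <- as.matrix(stats::dist(c(0, 1, 2)))
  rownames(m3) <- colnames(m3) <- letters[1:3]
  e3 <- mds_embed(m3)
  got <- as.matrix(stats::dist(e3[, c("dim1", "dim2")]))
  expect_equal(unname(got), unname(m3), tolerance = 1e-9)

  # unit square
  pts <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  m4 <- as.matrix(stats::dist(pts))
  rownames(m4) <- colnames(m4) <- paste0("v", 1:4)
  e4 <- mds_embed(m4)
  got <- as.matrix(stats::dist(e4[, c("dim1", "dim2")]))
  expect_equal(unname(got), unname(m4), tolerance = 1e-9)
})

test_that("MDS agrees with an explicit Torgerson double-centering oracle", {
  set.seed(62)
  for (i in 1:5) {
    n <- sample(4:10, 1)
    m <- planar_dissim(n)
    rownames(m) <- colnames(m) <- paste0("p", seq_len(n))
    # oracle: B = -J D^2 J / 2, top-2 eigenpairs
    j <- diag(n) - matrix(1 / n, n, n)
    b <- -0.5 * j %*% (m^2) %*% j
    eig <- eigen(b, symmetric = TRUE)
    oracle <- eig$vectors[, 1:2] %*% diag(sqrt(pmax(eig$values[1:2], 0)))
    e <- mds_embed(m)
    got <- as.matrix(stats::dist(e[, c("dim1", "dim2")]))
    want <- as.matrix(stats::dist(oracle))
    expect_equal(unname(got), unname(want), tolerance = 1e-9)
    expect_equal(unname(got), unname(m), tolerance = 1e-9)
    # centroid at origin
    expect_equal(unname(colMeans(as.matrix(e[, c("dim1", "dim2")]))),
                 c(0, 0), tolerance = 1e-9)
  }
})

test_that("MDS clamps negative eigenvalues of non-Euclidean input", {
  # four points with strongly non-Euclidean distances
  m <- matrix(10, 4, 4) - diag(10, 4)
  m[1, 2] <- m[2, 1] <- 1
  rownames(m) <- colnames(m) <- paste0("x", 1:4)
  e <- mds_embed(m)
  expect_true(any(attr(e, "eigenvalues") < 0))
  expect_true(all(is.finite(as.matrix(e[, c("dim1", "dim2")]))))
})

test_that("k-medoids obeys its invariants and simple optima", {
  set.seed(63)
  m <- random_dissim(7)
  # k = n: every point its own medoid at zero cost
  all_meds <- k_medoids(m, 7)
  expect_equal(all_meds$total_cost, 0)
  expect_true(all(all_meds$assignment$is_medoid))

  # k = 1: the point minimizing total dissimilarity
  one <- k_medoids(m, 1)
  expect_equal(one$total_cost, min(colSums(m)))
  expect_equal(one$medoids, rownames(m)[which.min(colSums(m))])

  # assignment maps each point to its nearest medoid
  km <- k_medoids(m, 3)
  med_idx <- match(km$medoids, rownames(m))
  for (i in seq_len(nrow(m))) {
    own <- med_idx[km$assignment$cluster[i]]
    expect_equal(m[i, own], min(m[i, med_idx]))
  }
  expect_equal(km$total_cost, sum(km$assignment$dissimilarity))
})

test_that("PAM separates well-separated blocks", {
  set.seed(64)
  # two blocks: within 5, between 100
  m <- matrix(100, 6, 6)
  m[1:3, 1:3] <- 5
  m[4:6, 4:6] <- 5
  diag(m) <- 0
  rownames(m) <- colnames(m) <- paste0("s", 1:6)
  km <- k_medoids(m, 2)
  blocks <- split(km$assignment$label, km$assignment$cluster)
  expect_equal(unname(sort(vapply(blocks, length, integer(1)))),
               c(3L, 3L))
  expect_true(all(c("s1", "s2", "s3") %in% blocks[[1]]) ||
                all(c("s1", "s2", "s3") %in% blocks[[2]]))
  expect_equal(km$total_cost, pam_bruteforce_cost(m, 2))
})

test_that("PAM attains the exhaustive optimum on small random matrices", {
  set.seed(65)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    k <- sample(1:3, 1)
    m <- random_dissim(n)
    km <- k_medoids(m, k)
    expect_equal(km$total_cost, pam_bruteforce_cost(m, k),
                 tolerance = 1e-9)
  }
})

test_that("k_medoids never does worse than the cluster::pam reference", {
  skip_if_not_installed("cluster")
  set.seed(66)
  n_equal <- 0
  for (i in 1:10) {
    m <- random_dissim(sample(5:9, 1))
    k <- sample(2:3, 1)
    km <- k_medoids(m, k)
    ref <- cluster::pam(stats::as.dist(m), k)
    ref_cost <- sum(apply(m[, ref$id.med, drop = FALSE], 1, min))
    # exact enumeration can only match or beat the BUILD+SWAP heuristic
    expect_lte(km$total_cost, ref_cost + 1e-9)
    n_equal <- n_equal + (abs(km$total_cost - ref_cost) < 1e-9)
  }
  expect_gte(n_equal, 8) # the heuristic is optimal on most instances
})

test_that("the PAM search path is a valid local optimum near the exact one", {
  set.seed(71)
  for (i in 1:10) {
    m <- random_dissim(sample(5:8, 1))
    k <- sample(2:3, 1)
    exact <- k_medoids(m, k, method = "exact")
    pam <- k_medoids(m, k, method = "pam")
    expect_gte(pam$total_cost, exact$total_cost - 1e-9)
    # on the well-separated block matrix both routes coincide
  }
  m <- matrix(100, 6, 6)
  m[1:3, 1:3] <- 5
  m[4:6, 4:6] <- 5
  diag(m) <- 0
  rownames(m) <- colnames(m) <- paste0("s", 1:6)
  expect_equal(k_medoids(m, 2, method = "pam")$total_cost,
               k_medoids(m, 2, method = "exact")$total_cost)
})

test_that("k-medoids validates k and restarts never worsen the cost", {
  set.seed(67)
  m <- random_dissim(6)
  expect_error(k_medoids(m, 0), "between 1 and")
  expect_error(k_medoids(m, 7), "between 1 and")
  base <- k_medoids(m, 2)
  restarted <- k_medoids(m, 2, restarts = 5, seed = 9)
  expect_lte(restarted$total_cost, base$total_cost + 1e-12)
})

test_that("the dendrogram is average-linkage with sensible heights", {
  # two points merge at their distance
  m2 <- matrix(c(0, 7, 7, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  hc <- mcq_dendrogram(m2)
  expect_equal(hc$height, 7)

  # hand-computed UPGMA on a 4x4 two-block matrix:
  # merge (1,2) at 2, (3,4) at 4, top at mean(10,12,10,12) = 11
  m4 <- matrix(c(0, 2, 10, 12,
                 2, 0, 10, 12,
                 10, 10, 0, 4,
                 12, 12, 4, 0), 4, 4, byrow = TRUE)
  rownames(m4) <- colnames(m4) <- paste0("t", 1:4)
  hc4 <- mcq_dendrogram(m4)
  expect_equal(sort(hc4$height), c(2, 4, 11))

  # identical points: all merges at height 0
  m0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(mcq_dendrogram(m0)$height, c(0, 0))

  # heights are monotone non-decreasing (ultrametric for average linkage)
  set.seed(68)
  hcr <- mcq_dendrogram(random_dissim(8))
  expect_true(all(diff(hcr$height) >= 0))
})

test_that("newick serialization round-trips through ape", {
  set.seed(69)
  m <- random_dissim(5)
  hc <- mcq_dendrogram(m)
  nwk <- as_newick(hc)
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, rownames(m))
  # root-to-tip path length equals half the top merge height (UPGMA)
  depths <- ape::node.depth.edgelength(tree)[seq_len(5)]
  expect_equal(unname(depths), rep(max(hc$height) / 2, 5),
               tolerance = 1e-9)
})

test_that("tidy and glance summarize clustering objects", {
  set.seed(70)
  m <- random_dissim(6)
  km <- k_medoids(m, 2)
  td <- generics::tidy(km)
  expect_equal(nrow(td), 6)
  expect_equal(sum(td$is_medoid), 2)
  gl <- generics::glance(km)
  expect_equal(gl$k, 2)
  expect_equal(gl$total_cost, km$total_cost)
})
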