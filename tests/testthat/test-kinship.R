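test_that("genomic matrix equals the hand-computed MM'/p", {
  g <- matrix(c(0, 1, 2, 2,
                1, 1, 0, 2,
                2, 0, 1, 0), nrow = 4,
              dimnames = list(c("a", "b", "c", "d"), c("m1", "m2", "m3")))
  K <- genomic_matrix(g)
  M <- scale(g)
  expect_equal(unclass(K), tcrossprod(M) / 3, tolerance = 1e-12,
               ignore_attr = TRUE)
  # duplicated genotypes give identical rows and K12 = K11
  g2 <- rbind(g, a2 = g["a", ])
  K2 <- genomic_matrix(g2)
  expect_equal(K2["a", "a2"], K2["a", "a"], tolerance = 1e-12)

  expect_error(genomic_matrix(cbind(g, mono = c(1, 1, 1, 1))), "filter")
})

test_that("genomic matrix diagonal averages (n-1)/n with unit-variance columns", {
  g <- random_dosages(200, 1000)
  K <- genomic_matrix(g)
  # columns scaled by the n-1 sd make mean(diag) exactly (n-1)/n
  expect_equal(mean(diag(K)), 199 / 200, tolerance = 1e-10)
  ev <- eigen(unclass(K), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))
})

test_that("pedigree matrix reproduces textbook relationships", {
  ped <- pedigree(id = c("f1", "f2", "s1", "s2"),
                  parent1 = c(NA, NA, "f1", "f1"),
                  parent2 = c(NA, NA, "f2", "f2"))
  A <- pedigree_matrix(ped)
  expect_equal(A["s1", "s2"], 0.5)
  expect_equal(unname(diag(A)), rep(1, 4))

  # selfing drives the diagonal to 2 and leaves other entries unchanged
  ped2 <- pedigree(id = c("f1", "f2", "x", "line"),
                   parent1 = c(NA, NA, "f1", "x"),
                   parent2 = c(NA, NA, "f2", "x"),
                   selfing = c(0, 0, 0, 30))
  A2 <- pedigree_matrix(ped2)
  expect_equal(A2["line", "line"], 2, tolerance = 1e-8)
  expect_equal(A2["line", "f1"], A2["x", "f1"])
  # finite selfing: F4-type line from a non-inbred cross has A_ii = 1.875
  ped3 <- pedigree(id = c("f1", "f2", "x", "line"),
                   parent1 = c(NA, NA, "f1", "x"),
                   parent2 = c(NA, NA, "f2", "x"),
                   selfing = c(0, 0, 0, 2))
  expect_equal(pedigree_matrix(ped3)["line", "line"], 1.875)

  expect_error(pedigree(id = c("a", "b"), parent1 = c("b", "a"),
                        parent2 = c(NA, NA)), "cycle")
  expect_error(pedigree("a", "a", NA), "own parent")
  # COP view is half the numerator relationship
  expect_equal(cop_matrix(ped)["s1", "s2"], 0.25)
})

test_that("pedigree matrix matches gene-dropping IBD estimates", {
  set.seed(42)
  ped <- random_pedigree(30, nf = 8, max_selfing = 2)
  A <- pedigree_matrix(ped)
  gd <- gene_drop_A(ped, nrep = 1e5)
  # entrywise agreement at Monte Carlo precision: with ~465 distinct
  # entries a 3 SE band must hold for (almost) all of them, and a 5 SE
  # band (family-wise) for every one
  z_ok <- abs(A - gd$A) <= 3 * gd$se + 1e-9
  expect_gte(mean(z_ok), 0.99)
  expect_true(all(abs(A - gd$A) <= 5 * gd$se + 1e-9))
})

test_that("distance summary computes the off-diagonal median on standardized markers", {
  g <- random_dosages(6, 30)
  g[2, ] <- g[1, ]  # identical pair
  ds <- distance_summary(g)
  expect_equal(ds$d2[1, 2], 0)
  expect_equal(unname(diag(ds$d2)), rep(0, 6))

  # permuting individuals leaves the median unchanged
  perm <- sample(nrow(g))
  expect_equal(distance_summary(g[perm, ])$m, ds$m)

  # hand-computable 3 x 2 configuration: standardized coordinates are
  # known, so pairwise squared distances and their median follow by hand
  gh <- matrix(c(0, 1, 2,
                 0, 2, 1), nrow = 3,
               dimnames = list(c("a", "b", "c"), c("m1", "m2")))
  M <- scale(gh)
  d2_hand <- c(sum((M[1, ] - M[2, ])^2), sum((M[1, ] - M[3, ])^2),
               sum((M[2, ] - M[3, ])^2))
  expect_equal(distance_summary(gh)$m, stats::median(d2_hand))
})

test_that("Gaussian kernels follow exp(-c d2 / m) with unit diagonal", {
  g <- random_dosages(7, 40)  # odd pair count: the median is an entry
  ds <- distance_summary(g)
  ks <- gaussian_kernels(ds)
  expect_equal(length(ks), 3L)
  for (K in ks) {
    expect_identical(unname(diag(K)), rep(1, 7))
    expect_true(all(K > 0 & K <= 1))
  }
  expect_equal(attr(ks[[2]], "bandwidth"), 1 / ds$m)
  # entry at d2 = m with multiplier 1 equals exp(-1) exactly
  i <- which(abs(ds$d2 - ds$m) < 1e-12 & upper.tri(ds$d2), arr.ind = TRUE)[1, ]
  expect_equal(ks[[2]][i[1], i[2]], exp(-1), tolerance = 1e-12)
  # larger multipliers shrink every off-diagonal entry
  off <- upper.tri(ds$d2)
  expect_true(all(ks[[3]][off] <= ks[[2]][off]))
  expect_true(all(ks[[2]][off] <= ks[[1]][off]))
  # extreme multipliers approach identity / all-ones
  ext <- gaussian_kernels(ds, multipliers = c(1e-8, 1e8))
  expect_lt(max(abs(ext[[1]] - 1)), 1e-4)
  expect_lt(max(ext[[2]][off]), 1e-4)
})

test_that("Nei's standard distance matches hand arithmetic and flags fixation", {
  expect_equal(nei_distance(c(0.3, 0.8), c(0.3, 0.8)), 0)
  expect_equal(nei_distance(c(1, 0), c(0, 1)), Inf)
  expect_equal(nei_distance(c(0.5, 0.5), c(1, 0)),
               -log(0.5 / sqrt(0.5 * 1)), tolerance = 1e-12)
  expect_equal(-log(0.5 / sqrt(0.5)), log(sqrt(2)))
  # symmetry and self-distance over random profiles
  set.seed(5)
  for (i in 1:5) {
    a <- stats::runif(20); b <- stats::runif(20)
    expect_equal(nei_distance(a, b), nei_distance(b, a))
    expect_equal(nei_distance(a, a), 0)
  }
  # matrix variant agrees with the scalar function
  f <- matrix(stats::runif(12), 4, 3,
              dimnames = list(paste0("l", 1:4), NULL))
  D <- nei_distance_matrix(f)
  expect_equal(D["l1", "l3"], nei_distance(f[1, ], f[3, ]))
  expect_equal(unname(diag(D)), rep(0, 4))
})

test_that("PCA scores carry explained variance and a fixed sign convention", {
  g <- random_dosages(20, 50)
  pc <- pca_scores(g, 3)
  expect_equal(dim(pc$scores), c(20L, 3L))
  expect_true(all(pc$explained >= 0) && sum(pc$explained) <= 1 + 1e-12)
  # sign convention is invariant to a global sign flip of the data pattern
  pr <- stats::prcomp(g)
  for (j in 1:3) {
    l <- pr$rotation[, j]
    s <- sign(l[which.max(abs(l))])
    expect_equal(unname(pc$scores[, j]), unname(s * pr$x[, j]))
  }
})
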