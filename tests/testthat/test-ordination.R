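euclid <- function(pts) as.matrix(dist(pts))

test_that("PCoA reproduces Euclidean configurations exactly", {
  set.seed(21)
  pts <- matrix(rnorm(8), 4, 2, dimnames = list(paste0("s", 1:4), NULL))
  D <- euclid(pts)
  E <- pcoa_embed(D, 2)
  expect_lt(max(abs(euclid(E$points) - D)), 1e-9)

  # collinear points need only one axis; the rest of the spectrum vanishes
  line <- matrix(c(0, 1, 2.5), ncol = 1,
                 dimnames = list(paste0("p", 1:3), NULL))
  E1 <- pcoa_embed(euclid(line), 1)
  resid <- E1$diagnostics$eigenvalues[-1]
  expect_true(all(abs(resid) < 1e-9))
})

test_that("PCoA of the unit equilateral triangle has a doubly degenerate spectrum", {
  D <- matrix(1, 3, 3) - diag(3)
  dimnames(D) <- list(paste0("v", 1:3), paste0("v", 1:3))
  E <- pcoa_embed(D, 2)
  ev <- E$diagnostics$eigenvalues
  expect_equal(ev[1], ev[2], tolerance = 1e-12)
  expect_gt(ev[1], 0)
  expect_equal(unname(euclid(E$points)[upper.tri(diag(3))]), rep(1, 3),
               tolerance = 1e-9)
})

test_that("PCoA errors informatively when asked for more axes than the spectrum supports", {
  line <- matrix(c(0, 1, 2), ncol = 1, dimnames = list(paste0("p", 1:3), NULL))
  expect_error(pcoa_embed(euclid(line), 2), "1 positive eigenvalue")
  expect_error(pcoa_embed(euclid(line), 5), "at most n - 1")
})

test_that("PCoA explained variance share is non-decreasing in d", {
  set.seed(31)
  m <- matrix(rpois(10 * 20, 12), 10, 20,
              dimnames = list(paste0("s", 1:10), paste0("f", 1:20)))
  D <- bray_curtis(m)
  E <- pcoa_embed(D, 5)
  ev <- E$diagnostics$eigenvalues
  pos <- ev[ev > 0]
  share <- cumsum(pos) / sum(pos)
  expect_true(all(diff(share) >= -1e-12))
})

test_that("Sammon stress trace is non-increasing and vanishes for perfect configurations", {
  set.seed(5)
  pts <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("s", 1:10), NULL))
  D <- euclid(pts)
  E <- sammon_embed(D, 2)
  expect_lt(E$diagnostics$stress, 1e-6)
  expect_true(all(diff(E$diagnostics$stress_trace) <= 0))

  # projecting 3-D points to 2-D: stress positive, trace still monotone
  pts3 <- matrix(rnorm(30), 10, 3, dimnames = list(paste0("s", 1:10), NULL))
  E2 <- sammon_embed(euclid(pts3), 2)
  expect_true(all(diff(E2$diagnostics$stress_trace) <= 0))
  expect_lte(E2$diagnostics$stress,
             E2$diagnostics$stress_trace[1] + 1e-15)
})

test_that("Sammon rejects duplicate samples with advice", {
  D <- euclid(matrix(c(0, 0, 1, 0, 0, 0), 3, 2, byrow = TRUE,
                     dimnames = list(paste0("s", 1:3), NULL)))
  expect_error(sammon_embed(D, 1), "duplicate samples")
})

test_that("Sammon matches a 100-restart random-start oracle on 10-point problems", {
  set.seed(77)
  pts <- matrix(rnorm(10 * 5), 10, 5, dimnames = list(paste0("s", 1:10), NULL))
  D <- euclid(pts)
  E <- sammon_embed(D, 2, max_iter = 200)
  oracle <- Inf
  scale0 <- median(D[upper.tri(D)])
  for (r in 1:100) {
    init <- matrix(rnorm(20, sd = scale0), 10, 2,
                   dimnames = list(rownames(D), NULL))
    st <- sammon_embed(D, 2, init = init, max_iter = 200)$diagnostics$stress
    if (st < oracle) oracle <- st
  }
  expect_lte(E$diagnostics$stress, oracle * 1.05)
})

test_that("Sammon stress is comparable to the classic MASS implementation", {
  skip_if_not_installed("MASS")
  set.seed(13)
  pts <- matrix(rnorm(12 * 4), 12, 4, dimnames = list(paste0("s", 1:12), NULL))
  D <- euclid(pts)
  ours <- sammon_embed(D, 2)$diagnostics$stress
  ref <- suppressWarnings(
    MASS::sammon(as.dist(D), k = 2, trace = FALSE))$stress
  expect_lte(ours, ref * 1.10)
})

test_that("NMDS recovers rank-consistent structure and is seed-deterministic", {
  set.seed(9)
  pts <- matrix(rnorm(12 * 2), 12, 2, dimnames = list(paste0("s", 1:12), NULL))
  D <- euclid(pts)
  E <- nmds_embed(D, 2, n_starts = 5, seed = 4)
  expect_lt(E$diagnostics$stress, 0.01)

  E2 <- nmds_embed(D, 2, n_starts = 5, seed = 4)
  expect_identical(E$points, E2$points)

  allsame <- matrix(1, 4, 4) - diag(4)
  dimnames(allsame) <- list(paste0("s", 1:4), paste0("s", 1:4))
  expect_error(nmds_embed(allsame, 2), "degenerate")
})

test_that("NMDS stress does not increase with embedding dimension", {
  set.seed(10)
  m <- matrix(rpois(12 * 25, 10), 12, 25,
              dimnames = list(paste0("s", 1:12), paste0("f", 1:25)))
  D <- bray_curtis(m)
  s2 <- nmds_embed(D, 2, n_starts = 8, seed = 1)$diagnostics$stress
  s3 <- nmds_embed(D, 3, n_starts = 8, seed = 1)$diagnostics$stress
  expect_lte(s3, s2 + 1e-8)
})

test_that("masked low-rank completion recovers planted structure", {
  # dense exact-rank-2 matrix: reconstruction is numerically exact
  set.seed(12)
  U <- matrix(rnorm(20 * 2), 20, 2); V <- matrix(rnorm(30 * 2), 30, 2)
  X <- U %*% t(V)
  cm <- microtraj:::complete_low_rank(X, 2)
  expect_lt(max(abs(cm$reconstruction - X)), 1e-8)

  # planted rank-3 with 20% missing entries at 40 x 60
  set.seed(13)
  U <- matrix(rnorm(40 * 3), 40, 3); V <- matrix(rnorm(60 * 3), 60, 3)
  X <- U %*% t(V)
  mask <- matrix(runif(40 * 60) < 0.2, 40, 60)
  Xm <- X; Xm[mask] <- NA
  cm <- microtraj:::complete_low_rank(Xm, 3, max_iter = 2000, tol = 1e-9)
  rmse <- sqrt(mean((cm$reconstruction[mask] - X[mask])^2))
  expect_lt(rmse, 0.05)
})

test_that("RPCA embedding is deterministic and rejects infeasible ranks", {
  d <- tiny_design(seed = 3, n_features = 30)
  tab <- generate_counts(d)
  E1 <- rpca_embed(tab, 3)
  E2 <- rpca_embed(tab, 3)
  expect_identical(E1$points, E2$points)
  expect_equal(E1$dimension, 3L)
  expect_error(rpca_embed(tab[1:10, ], 10), "smaller than")
})

test_that("embedded coordinates are centred with a fixed sign convention", {
  d <- tiny_design(seed = 3, n_features = 30)
  tab <- generate_counts(d)
  D <- bray_curtis(tab)
  for (E in list(pcoa_embed(D, 3), sammon_embed(D, 3),
                 nmds_embed(D, 2, n_starts = 3, seed = 1),
                 rpca_embed(tab, 3))) {
    expect_lt(max(abs(colMeans(E$points))), 1e-8)
    for (j in seq_len(ncol(E$points))) {
      expect_gte(E$points[which.max(abs(E$points[, j])), j], 0)
    }
  }
})

test_that("distances reconstructed from embeddings are Euclidean", {
  E <- manual_embedding(matrix(c(0, 3), 2, 1,
                               dimnames = list(c("a", "b"), NULL)))
  expect_equal(reconstruct_distance(E)["a", "b"], 3)

  set.seed(14)
  pts <- matrix(rnorm(15), 5, 3, dimnames = list(paste0("s", 1:5), NULL))
  D <- euclid(pts)
  expect_equal(reconstruct_distance(pcoa_embed(D, 3)), D, tolerance = 1e-9)

  R <- reconstruct_distance(manual_embedding(
    matrix(rnorm(12), 6, 2, dimnames = list(paste0("s", 1:6), NULL))))
  for (i in 1:6) for (j in 1:6) for (k in 1:6) {
    expect_lte(R[i, j], R[i, k] + R[k, j] + 1e-12)
  }
})

test_that("dimensionality sweeps run each dimension and report skips", {
  set.seed(15)
  pts <- matrix(rnorm(10 * 3), 10, 3, dimnames = list(paste0("s", 1:10), NULL))
  D <- euclid(pts)
  sw <- sweep_embeddings(D, "pcoa", dims = c(2L, 3L, 9L))
  expect_named(sw$embeddings, c("d2", "d3"))
  expect_equal(sw$skipped$dimension, 9L)  # only 3 positive eigenvalues
  expect_match(sw$skipped$reason, "positive eigenvalue")

  one <- sweep_embeddings(D, "sammon", dims = 2L, seed = 5)
  direct <- sammon_embed(D, 2, seed = substream_seed(5, "sammon_d2"))
  expect_equal(one$embeddings$d2$points, direct$points)

  expect_error(sweep_embeddings(D, "pcoa", dims = integer(0)), "empty")
})
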