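test_that("trajectories are grouped by replicate and ordered by day", {
  d <- tiny_design()
  md <- generate_metadata(d)
  E <- manual_embedding(matrix(rnorm(90 * 2), 90, 2,
                               dimnames = list(md$sample_id, NULL)))
  trajs <- build_trajectories(E, md)
  expect_length(trajs, 18L)  # 3 soils x 2 treatments x 3 replicates
  expect_true(all(vapply(trajs, function(t) nrow(t$coords), 0L) == 5L))
  expect_true(all(vapply(trajs, function(t) !is.unsorted(t$days), TRUE)))

  # one missing sampling day leaves a 4-point trajectory
  drop <- md$sample_id[md$soil == "ANT" & md$treatment == "control" &
                         md$replicate == 1 & md$day == 57]
  md4 <- md[md$sample_id != drop, ]
  E4 <- manual_embedding(E$points[md4$sample_id, ])
  t4 <- build_trajectories(E4, md4)
  lens <- vapply(t4, function(t) nrow(t$coords), 0L)
  expect_equal(sort(unique(lens)), c(4L, 5L))
  expect_equal(sum(lens == 4L), 1L)

  # duplicated (replicate, day) is an error
  md_dup <- md
  md_dup$day[md_dup$sample_id == drop] <- 28L
  expect_error(build_trajectories(E, md_dup), "duplicate")

  # a single-time-point replicate is an error
  md1 <- md[!(md$soil == "G" & md$treatment == "control" &
                md$replicate == 3 & md$day > 0), ]
  E1 <- manual_embedding(E$points[md1$sample_id, ])
  expect_error(build_trajectories(E1, md1), "single time point")
})

test_that("trajectory displacement vectors subtract endpoint coordinates", {
  coords <- rbind(c(0, 0), c(1, 5), c(3, 4))
  rownames(coords) <- c("a", "b", "c")
  t <- structure(list(soil = "S", treatment = "control", replicate = 1L,
                      days = c(0L, 14L, 249L), coords = coords),
                 class = "trajectory")
  expect_equal(trajectory_vector(t, 0, 249), c(3, 4))
  expect_equal(trajectory_vector(t, 14, 14), c(0, 0))
  expect_error(trajectory_vector(t, 0, 57), "57")

  t1 <- structure(list(soil = "S", treatment = "control", replicate = 1L,
                       days = c(0L, 249L),
                       coords = matrix(c(5, 2), 2, 1)),
                  class = "trajectory")
  expect_equal(trajectory_vector(t1, 0, 249), -3)
})

test_that("cosine similarity hits its analytic anchors and error cases", {
  expect_equal(cos_theta(c(1, 0), c(2, 0)), 1.0)
  expect_equal(cos_theta(c(1, 0), c(0, 3)), 0.0)
  expect_equal(cos_theta(c(1, 1), c(-2, -2)), -1.0)
  expect_error(cos_theta(c(0, 0), c(1, 0)), "zero-norm")
})

test_that("cosine similarity is scale-invariant and rotation-invariant", {
  set.seed(33)
  for (i in 1:20) {
    u <- rnorm(4); v <- rnorm(4)
    a <- runif(1, 0.1, 10); b <- runif(1, 0.1, 10)
    expect_equal(cos_theta(u, v), cos_theta(a * u, b * v), tolerance = 1e-12)
    Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
    expect_equal(cos_theta(u, v), cos_theta(as.numeric(Q %*% u),
                                            as.numeric(Q %*% v)),
                 tolerance = 1e-9)
  }
})

test_that("treatment-trajectory comparison averages over all control x inoculated pairs", {
  days <- c(0L, 249L)
  md <- expand.grid(treatment = c("control", "inoculated"),
                    replicate = 1:3, day = days,
                    stringsAsFactors = FALSE)
  md$soil <- "ANT"
  md$sample_id <- sprintf("%s_r%d_d%d", md$treatment, md$replicate, md$day)
  # all replicates move along (1, 1): perfectly aligned
  coords <- t(vapply(seq_len(nrow(md)), function(i) {
    jitter <- md$replicate[i] * 10
    if (md$day[i] == 0) c(jitter, jitter) else c(jitter + 1, jitter + 1)
  }, numeric(2)))
  rownames(coords) <- md$sample_id
  trajs <- build_trajectories(raw_embedding(coords), md)
  cmp <- compare_treatment_trajectories(trajs, "ANT", 0, 249)
  expect_equal(nrow(cmp$pairs), 9L)
  expect_equal(cmp$mean, 1.0)
  expect_equal(cmp$sd, 0)

  # single pair: mean equals the lone cosine, sd 0
  md1 <- md[md$replicate == 1, ]
  trajs1 <- build_trajectories(raw_embedding(coords[md1$sample_id, ]), md1)
  cmp1 <- compare_treatment_trajectories(trajs1, "ANT", 0, 249)
  expect_equal(nrow(cmp1$pairs), 1L)
  expect_equal(cmp1$mean, cmp1$pairs$cos_theta[1])
  expect_equal(cmp1$sd, 0)
})

test_that("smoothness distinguishes straight, reversing, and right-angled paths", {
  straight <- structure(list(soil = "S", treatment = "c", replicate = 1L,
                             days = 0:3,
                             coords = cbind(0:3, 0:3)),
                        class = "trajectory")
  expect_equal(smoothness(straight), 1.0)

  zigzag <- structure(list(soil = "S", treatment = "c", replicate = 1L,
                           days = 0:3,
                           coords = cbind(c(0, 1, 0, 1), 0)),
                      class = "trajectory")
  expect_equal(smoothness(zigzag), -1.0)

  ell <- structure(list(soil = "S", treatment = "c", replicate = 1L,
                        days = 0:3,
                        coords = rbind(c(0, 0), c(1, 0), c(1, 1), c(2, 1))),
                   class = "trajectory")
  expect_equal(smoothness(ell), 0.0)

  short <- structure(list(soil = "S", treatment = "c", replicate = 1L,
                          days = 0:1, coords = cbind(0:1, 0)),
                     class = "trajectory")
  expect_error(smoothness(short), "at least 3")
})

test_that("linearity is net displacement over path length", {
  straight <- structure(list(soil = "S", treatment = "c", replicate = 1L,
                             days = 0:2, coords = cbind(c(0, 1, 2.5), 0)),
                        class = "trajectory")
  expect_equal(linearity(straight), 1.0)

  loop <- structure(list(soil = "S", treatment = "c", replicate = 1L,
                         days = 0:4,
                         coords = rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1),
                                        c(0, 0))),
                    class = "trajectory")
  expect_equal(linearity(loop), 0.0)

  ell <- structure(list(soil = "S", treatment = "c", replicate = 1L,
                        days = 0:2,
                        coords = rbind(c(0, 0), c(1, 0), c(1, 1))),
                   class = "trajectory")
  expect_equal(linearity(ell), sqrt(2) / 2)
})

test_that("trajectory metrics are invariant under rotation and translation of the space", {
  d <- tiny_design(seed = 21)
  md <- generate_metadata(d)
  set.seed(22)
  pts <- matrix(rnorm(90 * 3), 90, 3, dimnames = list(md$sample_id, NULL))
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  pts_rot <- pts %*% Q + matrix(rep(c(5, -2, 7), each = 90), 90, 3)
  t1 <- build_trajectories(raw_embedding(pts), md)
  t2 <- build_trajectories(raw_embedding(pts_rot), md)
  for (k in seq_along(t1)) {
    expect_equal(smoothness(t1[[k]]), smoothness(t2[[k]]), tolerance = 1e-9)
    expect_equal(linearity(t1[[k]]), linearity(t2[[k]]), tolerance = 1e-9)
  }
  c1 <- compare_treatment_trajectories(t1, "AT", 0, 249)
  c2 <- compare_treatment_trajectories(t2, "AT", 0, 249)
  expect_equal(c1$mean, c2$mean, tolerance = 1e-9)
})

test_that("the sweep table covers dimensions, soils, intervals and per-replicate metrics", {
  d <- tiny_design(seed = 23, n_features = 30)
  tab <- generate_counts(d)
  md <- generate_metadata(d)
  D <- bray_curtis(tab)
  sw <- sweep_embeddings(D, "pcoa", dims = c(2L, 3L))
  segs <- list(c(0L, 249L), c(0L, 14L), c(14L, 28L), c(28L, 57L),
               c(57L, 249L))
  out <- sweep_trajectory_metrics(sw, md, intervals = segs)
  means <- out[out$metric == "cos_theta_mean", ]
  expect_equal(nrow(means), 2 * 3 * 5)  # dims x soils x intervals
  lin <- out[out$metric == "linearity", ]
  expect_equal(nrow(lin), 2 * 18)       # dims x trajectories

  # single embedding reproduces the direct calls
  one <- sweep_trajectory_metrics(list(sw$embeddings$d2), md,
                                  intervals = list(c(0L, 249L)))
  trajs <- build_trajectories(sw$embeddings$d2, md)
  cmp <- compare_treatment_trajectories(trajs, "ANT", 0, 249)
  got <- one$value[one$soil == "ANT" & one$metric == "cos_theta_mean"]
  expect_equal(got, cmp$mean)
})
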