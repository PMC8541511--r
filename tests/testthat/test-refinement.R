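test_that("temporal projection sums frames and conserves mass", {
  set.seed(1)
  one <- array(runif(12), c(3, 4, 1))
  expect_equal(temporal_projection(one), one[, , 1L])
  two <- array(runif(24), c(3, 4, 2))
  expect_equal(temporal_projection(two), two[, , 1L] + two[, , 2L])
  expect_equal(sum(temporal_projection(two)), sum(two))
  expect_gte(min(temporal_projection(two)), 0)
})

test_that("iterative centroid is exact on point masses and symmetric maps", {
  m <- matrix(0, 40, 50)
  m[11, 21] <- 5                      # 0-based (10, 20)
  ctr <- iterative_centroid(m)
  expect_equal(c(ctr$cx, ctr$cy), c(10, 20))
  expect_equal(unname(ctr$trajectory[, "cx"]), rep(10, 11),
               tolerance = 1e-12)
  # 180-degree-symmetric map: centroid stays at the center
  set.seed(4)
  half <- matrix(runif(20 * 41), 20, 41)
  sym <- half + half[rev(seq_len(20)), rev(seq_len(41))]
  ctr2 <- iterative_centroid(sym)
  expect_equal(c(ctr2$cx, ctr2$cy), c((20 - 1) / 2, (41 - 1) / 2),
               tolerance = 1e-9)
  expect_error(iterative_centroid(matrix(0, 5, 5)),
               class = "valveseg_refinement_error")
})

test_that("centroid migrates to the heavy blob within 2 px", {
  gauss <- function(cx, cy, s, amp, sx = 80, sy = 80) {
    r <- matrix(0:(sx - 1), sx, sy)
    cc <- matrix(0:(sy - 1), sx, sy, byrow = TRUE)
    amp * exp(-((r - cx)^2 + (cc - cy)^2) / (2 * s^2))
  }
  mp <- gauss(40, 20, 3, 10) + gauss(40, 60, 3, 1)   # masses 10 : 1, 40 px apart
  ctr <- iterative_centroid(mp)
  expect_lt(sqrt((ctr$cx - 40)^2 + (ctr$cy - 20)^2), 2)
})

test_that("connected components: base cases and 6-connectivity", {
  mk <- array(0, c(4, 4, 2)); mk[2, 2, 1] <- 1
  cc <- connected_components_3d(mk)
  expect_identical(cc$n_clusters, 1L)
  expect_identical(cc$sizes, 1L)
  # diagonal voxels are not connected
  mk2 <- array(0, c(3, 3, 1)); mk2[1, 1, 1] <- 1; mk2[2, 2, 1] <- 1
  expect_identical(connected_components_3d(mk2)$n_clusters, 2L)
  # temporal adjacency does connect
  mk3 <- array(0, c(3, 3, 2)); mk3[1, 1, 1] <- 1; mk3[1, 1, 2] <- 1
  expect_identical(connected_components_3d(mk3)$n_clusters, 1L)
})

test_that("labeling partition matches the BFS flood-fill oracle", {
  set.seed(11)
  for (k in 1:50) {
    mk <- array(as.numeric(runif(5 * 5 * 4) < 0.3), c(5, 5, 4))
    cs <- connected_components_3d(mk)
    expect_identical(cluster_partition(cs), bfs_components(mk))
  }
})

test_that("labels follow first-encounter order of the row-major scan", {
  mk <- array(0, c(4, 4, 2))
  mk[3, 1, 1] <- 1            # later row ...
  mk[1, 4, 2] <- 1            # ... but the (row 0, col 3) voxel scans first
  cs <- connected_components_3d(mk)
  expect_identical(cs$labels[1, 4, 2], 1L)
  expect_identical(cs$labels[3, 1, 1], 2L)
})

test_that("cluster selection: distance rule, ties, and error cases", {
  mk <- array(0, c(6, 6, 1))
  mk[1, 1, 1] <- 1            # cluster 1 at (0,0)
  mk[6, 6, 1] <- 1            # cluster 2 at (5,5)
  cs <- connected_components_3d(mk)
  sel <- select_cluster(cs, list(cx = 1, cy = 1))
  expect_identical(attr(sel, "cluster_id"), 1L)
  expect_identical(sum(sel), 1)
  # single cluster comes back unchanged
  one <- array(0, c(3, 3, 2)); one[2, 2, ] <- 1
  cs1 <- connected_components_3d(one)
  expect_equal(unclass(select_cluster(cs1, list(cx = 0, cy = 0))),
               one, ignore_attr = TRUE)
  # exact tie -> smallest id
  tie <- array(0, c(5, 5, 1)); tie[1, 3, 1] <- 1; tie[5, 3, 1] <- 1
  cst <- connected_components_3d(tie)
  expect_identical(attr(select_cluster(cst, list(cx = 2, cy = 2)),
                        "cluster_id"), 1L)
  empty <- connected_components_3d(array(0, c(2, 2, 1)))
  expect_error(select_cluster(empty, list(cx = 0, cy = 0)),
               class = "valveseg_refinement_error")
})

test_that("refinement never adds voxels and returns one component", {
  set.seed(21)
  for (k in 1:10) {
    mk <- array(as.numeric(runif(8 * 8 * 3) < 0.2), c(8, 8, 3))
    if (sum(mk) == 0) next
    cs <- connected_components_3d(mk)
    sel <- select_cluster(cs, list(cx = runif(1, 0, 7), cy = runif(1, 0, 7)))
    expect_true(all(sel <= mk))
    expect_identical(connected_components_3d(unclass(sel))$n_clusters, 1L)
  }
})
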