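# Refinement of the binary segmentation: locate the valve by an iterative
# Gaussian-attenuated centroid of the accumulated sparse component, then keep
# only the spatiotemporally connected component of the mask closest (in the
# spatial plane) to that location. Temporal connectivity matters: open
# leaflets form two spatial blobs per frame, but across the closing frames
# they merge into a single spatiotemporal cluster.

#' Accumulate the sparse component over frames
#'
#' Entrywise sum over the frame axis: a 2-D map whose large values mark
#' locations where bright fast-moving structure appears most frequently.
#'
#' @param S3D nonnegative `sx x sy x t` array (or pixels x frames matrix with
#'   `sx`/`sy` attributes).
#' @return nonnegative `sx x sy` matrix.
#' @export
temporal_projection <- function(S3D) {
  S3 <- as_video3d(S3D)
  assert_nonneg_array(S3, "S3D")
  rowSums(S3, dims = 2L)
}

#' Iterative Gaussian-attenuated centroid
#'
#' Alternates computing the mass-weighted centroid of the accumulation map
#' with pointwise multiplication by an isotropic Gaussian centered at that
#' centroid, with decreasing scale `sigma`; outlying structure is attenuated
#' and the centroid migrates toward the dominant (valve) blob. Coordinates
#' are 0-based `(row, col)`.
#'
#' @param S_map nonnegative `sx x sy` matrix with positive total mass.
#' @param n_iters number of centroid/attenuation rounds (default 11).
#' @param sigma_schedule decreasing positive vector of length `n_iters`;
#'   default geometric decay from `max(sx, sy)/4` to `max(sx, sy)/16`.
#' @return list of class `valve_centroid` with elements `cx` (row), `cy`
#'   (col) and the per-iteration `trajectory` (n_iters x 2).
#' @export
iterative_centroid <- function(S_map, n_iters = 11L, sigma_schedule = NULL) {
  if (!is.matrix(S_map)) vs_validation_error("`S_map` must be a matrix")
  assert_nonneg_array(S_map, "S_map")
  n_iters <- assert_count(n_iters, "n_iters", 1L)
  sx <- nrow(S_map); sy <- ncol(S_map)
  if (is.null(sigma_schedule)) {
    s0 <- max(sx, sy) / 4; s1 <- max(sx, sy) / 16
    sigma_schedule <- if (n_iters == 1L) s0 else {
      s0 * (s1 / s0)^((seq_len(n_iters) - 1) / (n_iters - 1))
    }
  }
  if (length(sigma_schedule) != n_iters || any(sigma_schedule <= 0)) {
    vs_validation_error("`sigma_schedule` must be positive, length n_iters")
  }
  rows <- matrix(0:(sx - 1), sx, sy)
  cols <- matrix(0:(sy - 1), sx, sy, byrow = TRUE)
  traj <- matrix(NA_real_, n_iters, 2L, dimnames = list(NULL, c("cx", "cy")))
  m <- S_map
  for (i in seq_len(n_iters)) {
    v <- sum(m)
    if (v <= 0) {
      vs_refinement_error("accumulation map has zero mass", stage = "centroid")
    }
    cx <- sum(m * rows) / v
    cy <- sum(m * cols) / v
    traj[i, ] <- c(cx, cy)
    sg <- sigma_schedule[i]
    # 1/(2 pi sigma^2) kept for fidelity; centroids are scale-invariant.
    m <- m * (exp(-((rows - cx)^2 + (cols - cy)^2) / (2 * sg^2)) /
                (2 * pi * sg^2))
  }
  structure(list(cx = unname(traj[n_iters, 1L]),
                 cy = unname(traj[n_iters, 2L]),
                 trajectory = traj),
            class = "valve_centroid")
}

#' @export
print.valve_centroid <- function(x, ...) {
  cat(sprintf("<valve_centroid> (row %.2f, col %.2f) after %d iterations\n",
              x$cx, x$cy, nrow(x$trajectory)))
  invisible(x)
}

#' Spatiotemporal connected components of a binary mask
#'
#' Labels foreground voxels under 6-connectivity (face-adjacent in the 3-D
#' row/col/frame lattice). Labels are assigned in first-encounter order under
#' a row-major, frame-minor scan (row slowest, then column, then frame).
#'
#' @param mask binary `sx x sy x t` array (or pixels x frames matrix with
#'   `sx`/`sy` attributes).
#' @return list of class `cluster_set`: `labels` (`sx x sy x t` integer
#'   array, 0 = background), `n_clusters`, `sizes`, and `voxel_lists` (one
#'   integer matrix of 0-based `(row, col, frame)` per cluster).
#' @export
connected_components_3d <- function(mask) {
  m3 <- as_video3d(mask)
  if (anyNA(m3) || !all(m3 %in% c(0, 1))) {
    vs_validation_error("`mask` must be binary (0/1)")
  }
  d <- dim(m3)
  fg <- which(m3 > 0)
  labels <- array(0L, d)
  if (length(fg) == 0L) {
    return(structure(list(labels = labels, n_clusters = 0L,
                          sizes = integer(0), voxel_lists = list()),
                     class = "cluster_set"))
  }
  n <- length(fg)
  id <- array(0L, d)          # consecutive index per foreground voxel
  id[fg] <- seq_len(n)
  parent <- seq_len(n)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # face-adjacent pairs along each axis, both endpoints foreground
  pair_list <- list()
  if (d[1L] > 1L) {
    a <- m3[-d[1L], , , drop = FALSE] & m3[-1L, , , drop = FALSE]
    pair_list[[1L]] <- cbind(id[-d[1L], , ][a], id[-1L, , ][a])
  }
  if (d[2L] > 1L) {
    a <- m3[, -d[2L], , drop = FALSE] & m3[, -1L, , drop = FALSE]
    pair_list[[2L]] <- cbind(id[, -d[2L], ][a], id[, -1L, ][a])
  }
  if (d[3L] > 1L) {
    a <- m3[, , -d[3L], drop = FALSE] & m3[, , -1L, drop = FALSE]
    pair_list[[3L]] <- cbind(id[, , -d[3L]][a], id[, , -1L][a])
  }
  pairs <- do.call(rbind, pair_list)
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    for (k in seq_len(nrow(pairs))) {
      ra <- find_root(pairs[k, 1L])
      rb <- find_root(pairs[k, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find_root, integer(1))
  # 0-based coordinates of each foreground voxel
  fg0 <- fg - 1L
  row <- fg0 %% d[1L]
  col <- (fg0 %/% d[1L]) %% d[2L]
  frm <- fg0 %/% (d[1L] * d[2L])
  # first-encounter relabeling: row slowest, col, then frame
  scan_key <- (row * d[2L] + col) * d[3L] + frm
  ord <- order(scan_key)
  relabel <- integer(n)
  next_lab <- 0L
  for (i in ord) {
    r <- root[i]
    if (relabel[r] == 0L) {
      next_lab <- next_lab + 1L
      relabel[r] <- next_lab
    }
  }
  lab <- relabel[root]
  labels[fg] <- lab
  voxel_lists <- lapply(seq_len(next_lab), function(k) {
    sel <- lab == k
    cbind(row = row[sel], col = col[sel], frame = frm[sel])
  })
  structure(
    list(labels = labels, n_clusters = next_lab,
         sizes = vapply(voxel_lists, nrow, integer(1)),
         voxel_lists = voxel_lists),
    class = "cluster_set"
  )
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s), sizes: %s\n", x$n_clusters,
              paste(utils::head(sort(x$sizes, decreasing = TRUE), 8L),
                    collapse = ", ")))
  invisible(x)
}

#' Keep the cluster spatially closest to the centroid
#'
#' For every cluster, the minimum over its voxels of the Euclidean distance
#' between the voxel's spatial coordinates and the centroid (the frame axis
#' is ignored: the centroid is spatial). The cluster attaining the smallest
#' such distance is kept; ties break toward the smallest cluster id.
#'
#' @param clusters a [connected_components_3d()] result with at least one
#'   cluster.
#' @param centroid a [iterative_centroid()] result (or list with `cx`, `cy`).
#' @return binary `sx x sy x t` array of class `binary_mask` containing only
#'   the selected cluster; attributes `cluster_id` and `cluster_distance`.
#' @export
select_cluster <- function(clusters, centroid) {
  if (!inherits(clusters, "cluster_set")) {
    vs_validation_error("`clusters` must be a cluster_set")
  }
  if (clusters$n_clusters < 1L) {
    vs_refinement_error("empty cluster set: nothing to select",
                        stage = "clustering")
  }
  dmin <- vapply(clusters$voxel_lists, function(vx) {
    min(sqrt((vx[, "row"] - centroid$cx)^2 + (vx[, "col"] - centroid$cy)^2))
  }, numeric(1))
  best <- which.min(dmin)   # ties -> smallest id
  out <- (clusters$labels == best) * 1
  attr(out, "cluster_id") <- as.integer(best)
  attr(out, "cluster_distance") <- dmin[best]
  class(out) <- "binary_mask"
  out
}

#' Distance table of clusters to a centroid
#'
#' Diagnostic companion of [select_cluster()]: one row per cluster with its
#' id, voxel count and minimal spatial distance to the centroid.
#'
#' @inheritParams select_cluster
#' @return data.frame with columns `id`, `size`, `min_distance`.
#' @export
cluster_distance_table <- function(clusters, centroid) {
  dmin <- vapply(clusters$voxel_lists, function(vx) {
    min(sqrt((vx[, "row"] - centroid$cx)^2 + (vx[, "col"] - centroid$cy)^2))
  }, numeric(1))
  data.frame(id = seq_len(clusters$n_clusters), size = clusters$sizes,
             min_distance = dmin)
}
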