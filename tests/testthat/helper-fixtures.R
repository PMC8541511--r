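# Shared fixtures and independent oracles.

# A small easy-contrast phantom used by fast unit tests.
small_phantom_spec <- function(seed = 7L, noise_sigma = 0.01, ...) {
  phantom_spec(height = 48L, width = 48L, n_frames = 16L, valve_length = 12L,
               hinge_position = c(14L, 24L), swing_period = 8L,
               noise_sigma = noise_sigma, seed = seed, ...)
}

# Reduced-iteration configs so unit tests stay fast; contracts do not depend
# on the iteration counts.
fast_fact_cfg <- function(...) {
  factorization_config(n_outer_iters = 40L, n_init_nmf_iters = 60L, ...)
}
fast_seg_cfg <- function(...) segmentation_config(n_iters = 150L, ...)

# Exhaustive minimum of the segmentation energy over all binary masks.
enum_binary_min <- function(S3, W3, cfg) {
  d <- dim(S3)
  n <- prod(d)
  stopifnot(n <= 12)
  best <- Inf
  for (k in 0:(2^n - 1)) {
    bmask <- array(as.numeric(bitwAnd(k, 2^(0:(n - 1))) > 0), d)
    e <- energy(bmask, S3, W3, cfg)
    if (e < best) best <- e
  }
  best
}

# Independent BFS flood-fill labeling over 6-connectivity; returns the
# partition as a canonical list (each component a sorted vector of linear
# voxel indices, components ordered by their smallest index).
bfs_components <- function(mask3) {
  d <- dim(mask3)
  fg <- which(mask3 > 0)
  seen <- logical(length(fg))
  names(seen) <- as.character(fg)
  fgset <- new.env(hash = TRUE)
  for (v in fg) assign(as.character(v), TRUE, envir = fgset)
  comps <- list()
  coords <- function(v) {
    v0 <- v - 1L
    c(v0 %% d[1L], (v0 %/% d[1L]) %% d[2L], v0 %/% (d[1L] * d[2L]))
  }
  lin <- function(r, c, f) as.integer(r + 1L + c * d[1L] + f * d[1L] * d[2L])
  visited <- new.env(hash = TRUE)
  for (start in fg) {
    if (!is.null(visited[[as.character(start)]])) next
    queue <- start
    visited[[as.character(start)]] <- TRUE
    comp <- integer(0)
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      comp <- c(comp, v)
      rcf <- coords(v)
      for (delta in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                         c(0, 0, 1), c(0, 0, -1))) {
        r <- rcf[1L] + delta[1L]; cc <- rcf[2L] + delta[2L]
        f <- rcf[3L] + delta[3L]
        if (r < 0 || r >= d[1L] || cc < 0 || cc >= d[2L] ||
            f < 0 || f >= d[3L]) next
        w <- lin(r, cc, f)
        if (!is.null(fgset[[as.character(w)]]) &&
            is.null(visited[[as.character(w)]])) {
          visited[[as.character(w)]] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(vapply(comps, min, numeric(1)))]
}

# Canonical partition of a cluster_set for comparison with the BFS oracle.
cluster_partition <- function(cs) {
  comps <- lapply(seq_len(cs$n_clusters), function(k) {
    sort(which(cs$labels == k))
  })
  comps[order(vapply(comps, min, numeric(1)))]
}

# Naive per-position window score scan.
naive_window_scan <- function(S3, hw, ww) {
  d <- dim(S3)
  best <- NULL; best_score <- -Inf
  for (r0 in 0:(d[1L] - hw)) {
    for (c0 in 0:(d[2L] - ww)) {
      sc <- sum(S3[r0 + seq_len(hw), c0 + seq_len(ww), ]^2)
      if (sc > best_score + 1e-12) {
        best_score <- sc
        best <- c(r0, c0)
      }
    }
  }
  list(row0 = best[1L], col0 = best[2L], score = best_score)
}

# Bounding-box-plus-margin window size for a truth mask.
truth_window_size <- function(truth_mask, margin = 3L) {
  bb <- which(truth_mask == 1, arr.ind = TRUE)
  c(diff(range(bb[, 1L])) + margin, diff(range(bb[, 2L])) + margin)
}
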