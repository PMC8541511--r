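# Robust nonnegative matrix factorization of the pixels x frames video
# matrix, X ~ W H + S + N: nonnegative low-rank W H (rigid myocardium),
# nonnegative sparse S (fast-moving valve), Gaussian residual N.
#
# The l1 penalty on S is debiased by Bregman iterations: the running
# subgradient p is folded into the soft-threshold argument, so that entries
# already detected as positive (p = 1 there) are no longer shrunk. The
# low-rank subproblem is approximated by a single multiplicative update per
# outer iteration, and the scheme relies on early stopping (a fixed number of
# outer iterations) rather than on convergence.

#' Nonnegative soft threshold
#'
#' The pointwise proximal operator of the l1 norm restricted to nonnegative
#' values: `u - lam` where `u > lam`, 0 otherwise (negative inputs map to 0).
#'
#' @param u numeric scalar, vector or matrix.
#' @param lam nonnegative threshold.
#' @return object shaped like `u`.
#' @export
soft_threshold_nonneg <- function(u, lam) {
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0) {
    vs_validation_error("`lam` must be a single nonnegative number")
  }
  out <- u - lam
  out[out < 0] <- 0
  out
}

#' Configuration for the robust factorizations
#'
#' Defaults follow the published hyperparameter tables: sparsity weight
#' `lam = 0.1` and `rank = 2` for muscle detection; `mu1 = 1`, `mu2 = 0.4`
#' and rank 5 for the windowing variant (pass `rank = 5` there). The scheme
#' runs a plain multiplicative NMF for `n_init_nmf_iters` iterations (S = 0),
#' then exactly `n_outer_iters = 100` debiased outer iterations.
#'
#' @param rank factorization rank `r < min(s, t)`.
#' @param lam sparsity weight of the muscle-detection model.
#' @param mu1,mu2 sparsity and exclusion weights of the windowing model.
#' @param n_outer_iters outer (Bregman) iterations; early stopping is by
#'   count, never by tolerance.
#' @param n_init_nmf_iters multiplicative NMF iterations used to initialize.
#' @param eps denominator guard added to every multiplicative update.
#' @param seed seed for the uniform `(0, 1]` initialization of W and H.
#' @return an object of class `factorization_config`.
#' @export
factorization_config <- function(rank = 2L, lam = 0.1, mu1 = 1, mu2 = 0.4,
                                 n_outer_iters = 100L,
                                 n_init_nmf_iters = 200L, eps = 1e-12,
                                 seed = 1L) {
  rank <- assert_count(rank, "rank", 1L)
  assert_scalar_number(lam, "lam", 0)
  assert_scalar_number(mu1, "mu1", 0)
  assert_scalar_number(mu2, "mu2", 0)
  n_outer_iters <- assert_count(n_outer_iters, "n_outer_iters", 1L)
  n_init_nmf_iters <- assert_count(n_init_nmf_iters, "n_init_nmf_iters", 0L)
  assert_scalar_number(eps, "eps", 0)
  seed <- assert_count(seed, "seed")
  structure(
    list(rank = rank, lam = lam, mu1 = mu1, mu2 = mu2,
         n_outer_iters = n_outer_iters, n_init_nmf_iters = n_init_nmf_iters,
         eps = eps, seed = seed),
    class = "factorization_config"
  )
}

check_video_matrix <- function(X) {
  if (!is.matrix(X)) vs_validation_error("`X` must be a pixels x frames matrix")
  assert_nonneg_array(X, "X")
  X
}

# One multiplicative step for W given S (Algorithm line 3): the numerator
# |A| - A with A = (S - X) H^T equals 2 * ((X - S) H^T)_+ .
update_W <- function(W, H, X, S, eps) {
  A <- (S - X) %*% t(H)
  W * (abs(A) - A) / (2 * (W %*% (H %*% t(H))) + eps)
}

update_H <- function(W, H, X, S, eps) {
  A <- t(W) %*% (S - X)
  H * (abs(A) - A) / (2 * ((t(W) %*% W) %*% H) + eps)
}

# Rescale columns of W to unit Euclidean norm, compensating rows of H; the
# product W H is invariant and the scale ambiguity is removed. Zero columns
# are left untouched.
normalize_wh <- function(W, H) {
  nrm <- sqrt(colSums(W^2))
  pos <- nrm > 0
  if (any(pos)) {
    W[, pos] <- sweep(W[, pos, drop = FALSE], 2L, nrm[pos], "/")
    H[pos, ] <- H[pos, , drop = FALSE] * nrm[pos]
  }
  list(W = W, H = H)
}

#' Plain NMF by multiplicative updates
#'
#' Lee-Seung multiplicative updates for `min ||X - W H||_F^2` with W, H
#' entrywise nonnegative, initialized uniform `(0, 1]` from `seed`. Used to
#' warm-start the robust factorizations (first update with S = 0 solves a
#' usual NMF problem).
#'
#' @param X nonnegative matrix `s x t`.
#' @param rank factorization rank, `1 <= rank < min(s, t)`.
#' @param n_iters number of update sweeps.
#' @param seed initialization seed.
#' @param W0,H0 optional explicit initialization (overrides `seed`).
#' @param eps denominator guard.
#' @return list with `W`, `H` and `objective_trace` (squared Frobenius error
#'   after every sweep).
#' @export
nmf_multiplicative <- function(X, rank, n_iters = 200L, seed = 1L,
                               W0 = NULL, H0 = NULL, eps = 1e-12) {
  check_video_matrix(X)
  rank <- assert_count(rank, "rank", 1L)
  if (rank >= min(dim(X))) {
    vs_validation_error("`rank` must be < min(s, t)")
  }
  s <- nrow(X); tt <- ncol(X)
  if (is.null(W0) || is.null(H0)) {
    init <- with_seed(seed, list(
      W = matrix(1 - stats::runif(s * rank), s, rank),
      H = matrix(1 - stats::runif(rank * tt), rank, tt)
    ))
    W <- W0 %||% init$W
    H <- H0 %||% init$H
  } else {
    W <- W0; H <- H0
  }
  S0 <- matrix(0, s, tt)
  trace <- numeric(n_iters)
  for (it in seq_len(n_iters)) {
    W <- update_W(W, H, X, S0, eps)
    H <- update_H(W, H, X, S0, eps)
    trace[it] <- sum((X - W %*% H)^2)
  }
  list(W = W, H = H, objective_trace = trace)
}

# Shared alternation driver for the debiased factorizations. `exclusion`
# switches between the muscle-detection update lines (threshold lam) and the
# windowing lines (thresholds mu1, exclusion mu2); with mu2 = 0 the two
# coincide algebraically.
rnmf_driver <- function(X, cfg, exclusion = FALSE, freeze_p = FALSE,
                        keep_diagnostics = TRUE) {
  check_video_matrix(X)
  if (!inherits(cfg, "factorization_config")) {
    cfg <- do.call(factorization_config, as.list(cfg))
  }
  if (cfg$rank >= min(dim(X))) {
    vs_validation_error("`rank` must be < min(s, t)")
  }
  lam <- if (exclusion) cfg$mu1 else cfg$lam
  mu2 <- if (exclusion) cfg$mu2 else 0
  if (exclusion && cfg$mu1 <= 0) {
    vs_validation_error("exclusion variant requires mu1 > 0")
  }
  if (!exclusion && lam == 0 && cfg$n_outer_iters > 0) {
    warning("lam = 0: S is unconstrained and the decomposition is not unique",
            call. = FALSE)
  }
  s <- nrow(X); tt <- ncol(X)
  init <- nmf_multiplicative(X, cfg$rank, n_iters = cfg$n_init_nmf_iters,
                             seed = cfg$seed, eps = cfg$eps)
  W <- init$W; H <- init$H
  S <- matrix(0, s, tt)
  p <- matrix(0, s, tt)
  trace <- numeric(cfg$n_outer_iters)
  diag_min <- if (keep_diagnostics) matrix(NA_real_, cfg$n_outer_iters, 3L)
  diag_sub <- if (keep_diagnostics) numeric(cfg$n_outer_iters)
  for (it in seq_len(cfg$n_outer_iters)) {
    WH <- W %*% H
    S <- soft_threshold_nonneg(X - WH + lam * p - mu2 * WH, lam)
    # With lam = 0 the threshold ignores p entirely; skip the (undefined)
    # 1/lam subgradient update in that degenerate case.
    if (!freeze_p && lam > 0) {
      p <- p + (X - WH - S - mu2 * WH) / lam
    }
    Seff <- if (mu2 > 0) S + 0.5 * mu2 * S else S
    W <- update_W(W, H, X, Seff, cfg$eps)
    H <- update_H(W, H, X, Seff, cfg$eps)
    nm <- normalize_wh(W, H)
    W <- nm$W; H <- nm$H
    if (anyNA(W) || anyNA(H) || anyNA(S) || anyNA(p)) {
      vs_numerical_error(sprintf(
        "NaN encountered in factorization at outer iteration %d", it
      ), iteration = it)
    }
    trace[it] <- sum((X - W %*% H - S)^2)
    if (keep_diagnostics) {
      diag_min[it, ] <- c(min(W), min(H), min(S))
      pos <- S > 0
      diag_sub[it] <- if (freeze_p || !any(pos)) 0 else max(abs(p[pos] - 1))
    }
  }
  res <- list(
    W = W, H = H, S = S, p = p, r = cfg$rank,
    objective_trace = trace, config = cfg,
    exclusion = exclusion, freeze_p = freeze_p,
    sx = attr(X, "sx"), sy = attr(X, "sy")
  )
  if (keep_diagnostics) {
    colnames(diag_min) <- c("min_W", "min_H", "min_S")
    res$diagnostics <- list(min_entries = diag_min,
                            subgradient_deviation = diag_sub)
  }
  structure(res, class = "factorization_result")
}

#' Bregman-debiased robust NMF (muscle detection)
#'
#' Decomposes X into nonnegative low-rank W H plus nonnegative sparse S.
#' After initializing with plain NMF (S = 0), each outer iteration performs,
#' in order: the nonnegative soft-threshold update of S (argument
#' `X - W H + lam * p`), the subgradient update
#' `p <- p + (X - W H - S) / lam`, one multiplicative step for W, one for H,
#' then column normalization of W with row compensation of H. Wherever
#' `S > 0` the subgradient satisfies `p = 1`, so positive detections are not
#' shrunk on subsequent iterations ("bias-free").
#'
#' @param X nonnegative pixels x frames matrix (see [video_to_matrix()]).
#' @param cfg a [factorization_config()].
#' @param freeze_p keep `p = 0` throughout, i.e. classical (biased) robust
#'   NMF with a plain soft threshold; used as the ablation baseline.
#' @param keep_diagnostics record per-iteration minima of W, H, S and the
#'   worst deviation of `p` from 1 on the support of S.
#' @return an object of class `factorization_result`: list with `W` (s x r),
#'   `H` (r x t), `S` (s x t), subgradient `p`, rank `r` and
#'   `objective_trace` of `||X - W H - S||_F^2`.
#' @export
bregman_rnmf <- function(X, cfg = factorization_config(),
                         freeze_p = FALSE, keep_diagnostics = TRUE) {
  rnmf_driver(X, cfg, exclusion = FALSE, freeze_p = freeze_p,
              keep_diagnostics = keep_diagnostics)
}

#' Exclusion-regularized robust NMF (windowing)
#'
#' Same alternation as [bregman_rnmf()] but with the additional term
#' `mu2 * <W H, S>` enforcing exclusionary supports of the low-rank and
#' sparse parts: the S-threshold argument becomes
#' `X - W H + mu1 * p - mu2 * W H`, the p-update subtracts
#' `mu2 * (W H) / mu1`, and the multiplicative numerators use
#' `S - X + mu2 * S / 2`. With `mu2 = 0` every line reduces to the
#' muscle-detection update.
#'
#' @inheritParams bregman_rnmf
#' @export
exclusion_rnmf <- function(X, cfg = factorization_config(rank = 5L),
                           freeze_p = FALSE, keep_diagnostics = TRUE) {
  rnmf_driver(X, cfg, exclusion = TRUE, freeze_p = freeze_p,
              keep_diagnostics = keep_diagnostics)
}

#' @export
print.factorization_result <- function(x, ...) {
  cat(sprintf(
    "<factorization_result> %s rank %d, %d outer iters, final ||X-WH-S||^2 = %.4g, nnz(S) = %d\n",
    if (x$exclusion) "exclusion-RNMF" else "Bregman-RNMF",
    x$r, length(x$objective_trace),
    utils::tail(x$objective_trace, 1L), sum(x$S > 0)
  ))
  invisible(x)
}
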