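# Expectation-maximisation engine for the linear Poisson model.
#
# The observed data are per-tumor count vectors H_j over the flattened
# (ADC bin x visit) grid. The model is m_j = P %*% Q[, j] with component
# PMFs in the columns of P (each summing to 1 over the grid) and
# non-negative per-tumor weights Q. The extended Poisson log-likelihood
#   l = sum_ij [ H_ij log m_ij - m_ij ]
# treats the per-tumor total as informative (no multinomial constraint),
# so at the fixed point sum_k Q_kj = sum_i H_ij exactly whenever the model
# has support wherever counts exist.
#
# Updates are the canonical multiplicative (KL/Poisson) EM updates; both
# the P step and the Q step are individually monotone in l.

rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), ncol = n)
  sweep(x, 2, colSums(x), "/")  # columns are draws
}

extended_poisson_ll <- function(H, m) {
  pos <- m > 0
  if (any(H[!pos] > 0)) return(-Inf)
  sum(H[pos] * log(m[pos])) - sum(m)
}

em_init <- function(H, k_free, k_fixed, free_support = NULL) {
  occupied <- rowSums(H) > 0
  if (!is.null(free_support)) occupied <- occupied & free_support
  P_free <- matrix(0, nrow(H), k_free)
  if (k_free > 0) {
    draws <- rdirichlet(k_free, rep(1, sum(occupied)))
    P_free[occupied, ] <- draws
  }
  Q <- matrix(rep(colSums(H) / (k_free + k_fixed), each = k_free + k_fixed),
              nrow = k_free + k_fixed)
  list(P_free = P_free, Q = Q)
}

# Run EM from one initialisation. P_fixed columns (if any) are frozen;
# only the k_free trailing components and all weights are updated.
em_run <- function(H, P_fixed, init, max_iter, tol) {
  k_fixed <- if (is.null(P_fixed)) 0L else ncol(P_fixed)
  k_free <- ncol(init$P_free)
  P <- cbind(P_fixed, init$P_free)
  Q <- init$Q
  free_cols <- if (k_free > 0) k_fixed + seq_len(k_free) else integer(0)

  ll_hist <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    m <- P %*% Q
    R <- H / m
    R[!is.finite(R)] <- 0
    if (k_free > 0) {
      num <- P[, free_cols, drop = FALSE] *
        (R %*% t(Q[free_cols, , drop = FALSE]))
      cs <- colSums(num)
      cs[cs == 0] <- 1
      P[, free_cols] <- sweep(num, 2, cs, "/")
      m <- P %*% Q
      R <- H / m
      R[!is.finite(R)] <- 0
    }
    Q <- Q * (t(P) %*% R)
    m <- P %*% Q
    ll <- extended_poisson_ll(H, m)
    ll_hist <- c(ll_hist, ll)
    if (is.finite(ll) && is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(P = P, Q = Q, loglik = ll_hist[length(ll_hist)], ll_history = ll_hist,
       iterations = length(ll_hist))
}

#' Maximum-likelihood EM fit of shared PMF components to count histograms
#'
#' Fits `k_free` probability-mass-function components (plus optional frozen
#' components in `P_fixed`) and per-tumor non-negative weights to a set of
#' histograms by maximising the extended Poisson likelihood, with multiple
#' seeded random restarts to avoid poor local maxima. This is the training
#' engine behind [lpm_train_control()] and [lpm_add_treatment()].
#'
#' @param H Numeric matrix of counts, one column per tumor, rows in
#'   [grid_cells()] order.
#' @param k_free Number of components to learn (\eqn{\ge} 0; \eqn{\ge} 1
#'   when `P_fixed` is `NULL`).
#' @param P_fixed Optional matrix of frozen component PMFs (columns).
#' @param restarts Number of random restarts (best final likelihood wins).
#' @param seed Integer seed; all initialisation randomness derives from it.
#' @param max_iter,tol Convergence controls: stop when the relative
#'   log-likelihood change falls below `tol` or after `max_iter` iterations.
#' @param free_support Optional logical vector over grid cells restricting
#'   where free components may carry mass (multiplicative updates preserve
#'   zeros, so the restriction is exact). Used in second-stage training to
#'   keep treatment components on the cells where the treated cohort shows
#'   excess over the frozen control model: the extended likelihood is
#'   invariant under mixing control-expressible mass into a free component
#'   (per-tumor weights compensate), so without the restriction the
#'   treatment weight QT is identified only up to that degeneracy; the
#'   restriction selects the minimal-QT (lower-bound) solution.
#' @return A list with `P` (all components, frozen first), `Q` (weights,
#'   components x tumors), `loglik`, `ll_history` (best restart), and
#'   `restart_logliks`.
#' @export
em_fit <- function(H, k_free, P_fixed = NULL, restarts = 20L, seed = 1L,
                   max_iter = 2000L, tol = 1e-8, free_support = NULL) {
  H <- as.matrix(H)
  if (ncol(H) == 0) abort("no histograms supplied")
  k_fixed <- if (is.null(P_fixed)) 0L else ncol(P_fixed)
  if (k_free < 0 || k_free + k_fixed < 1) abort("at least one component is required")
  occ <- rowSums(H) > 0
  if (!is.null(free_support)) occ <- occ & free_support
  if (k_free > sum(occ)) {
    abort("more free components than occupied bins")
  }
  if (restarts < 1) abort("restarts must be >= 1")

  if (k_free == 0) {
    res <- em_run(H, P_fixed, list(P_free = matrix(0, nrow(H), 0),
                                   Q = matrix(rep(colSums(H) / k_fixed,
                                                  each = k_fixed),
                                              nrow = k_fixed)),
                  max_iter, tol)
    res$restart_logliks <- res$loglik
    return(res)
  }

  inits <- withr::with_seed(seed, {
    lapply(seq_len(restarts),
           function(r) em_init(H, k_free, k_fixed, free_support))
  })
  runs <- lapply(inits, function(ini) em_run(H, P_fixed, ini, max_iter, tol))
  lls <- vapply(runs, `[[`, numeric(1), "loglik")
  best <- runs[[which.max(lls)]]
  best$restart_logliks <- lls
  best
}

# Weights-only EM fit of one histogram against fixed component PMFs.
# Bins where no component has support cannot be explained; their counts are
# reported as `excess` and excluded from the likelihood.
fit_weights <- function(P, h, max_iter = 2000L, tol = 1e-10) {
  supp <- rowSums(P) > 1e-12  # denormal tails count as unsupported
  excess <- sum(h[!supp])
  Ps <- P[supp, , drop = FALSE]
  hs <- h[supp]
  sk <- colSums(Ps)
  K <- ncol(P)
  q <- rep(sum(hs) / K, K)
  ll_old <- -Inf
  iters <- 0L
  for (it in seq_len(max_iter)) {
    m <- as.vector(Ps %*% q)
    r <- hs / m
    r[!is.finite(r)] <- 0
    q <- q * as.vector(crossprod(Ps, r)) / sk
    m <- as.vector(Ps %*% q)
    ll <- extended_poisson_ll(hs, m)
    iters <- it
    if (is.finite(ll) && is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  q[q < 1e-12 * max(sum(hs), 1)] <- 0
  m_full <- as.vector(P %*% q)
  list(weights = q, expected = m_full, loglik = ll, excess = excess,
       support = supp, iterations = iters)
}

# Observed Fisher information of the extended Poisson likelihood over the
# weights (PMFs fixed), and its (pseudo-)inverse as the weight covariance.
weight_covariance <- function(P, h, q) {
  m <- as.vector(P %*% q)
  w <- ifelse(m > 1e-12, h / m^2, 0)
  info <- crossprod(P, P * w)
  cov <- tryCatch(solve(info), error = function(e) NULL)
  singular <- is.null(cov)
  if (singular) {
    s <- svd(info)
    pos <- s$d > max(s$d[1], 0) * 1e-12
    cov <- s$v[, pos, drop = FALSE] %*%
      (t(s$u[, pos, drop = FALSE]) / s$d[pos])
  }
  cov <- (cov + t(cov)) / 2
  attr(cov, "singular") <- singular
  cov
}

#' Pooled Poisson chi-square per degree of freedom
#'
#' Goodness-of-fit between observed and model-expected counts. Within each
#' visit, adjacent ADC bins are pooled until each group's expected count
#' reaches `floor` (default 5) so the Poisson chi-square approximation is
#' valid; a trailing under-floor group is merged backwards. The statistic is
#' \eqn{\sum (O-E)^2/E} over pooled groups divided by (groups - n_params).
#'
#' @param observed,expected Numeric vectors over the flattened grid cells.
#' @param n_params Number of fitted parameters charged against the degrees
#'   of freedom (the number of fitted weights for a weights-only fit).
#' @param grid The [bin_grid()] the vectors are flattened over (pooling
#'   never crosses a visit boundary). If `NULL` a single block is assumed.
#' @param floor Minimum pooled expected count.
#' @return A list with `value` (chi2/df), `chi2`, `df`, `n_groups`,
#'   `n_pooled_bins`, and per-group tibble `groups`.
#' @export
chi2_per_df <- function(observed, expected, n_params, grid = NULL,
                        floor = 5) {
  stopifnot(length(observed) == length(expected))
  blocks <- if (is.null(grid)) {
    list(seq_along(observed))
  } else {
    cells <- grid_cells(grid)
    split(cells$cell, factor(cells$visit, levels = grid$visits))
  }
  obs_g <- numeric(0); exp_g <- numeric(0); size_g <- integer(0)
  for (idx in blocks) {
    o_acc <- 0; e_acc <- 0; n_acc <- 0L
    start_len <- length(obs_g)
    for (i in idx) {
      o_acc <- o_acc + observed[i]; e_acc <- e_acc + expected[i]
      n_acc <- n_acc + 1L
      if (e_acc >= floor) {
        obs_g <- c(obs_g, o_acc); exp_g <- c(exp_g, e_acc)
        size_g <- c(size_g, n_acc)
        o_acc <- 0; e_acc <- 0; n_acc <- 0L
      }
    }
    if (n_acc > 0) {
      if (length(obs_g) > start_len) {
        last <- length(obs_g)
        obs_g[last] <- obs_g[last] + o_acc
        exp_g[last] <- exp_g[last] + e_acc
        size_g[last] <- size_g[last] + n_acc
      } else if (e_acc > 0 || o_acc > 0) {
        obs_g <- c(obs_g, o_acc); exp_g <- c(exp_g, e_acc)
        size_g <- c(size_g, n_acc)
      }
    }
  }
  keep <- exp_g > 0
  obs_g <- obs_g[keep]; exp_g <- exp_g[keep]; size_g <- size_g[keep]
  df <- length(obs_g) - n_params
  if (df <= 0) abort("non-positive degrees of freedom in chi2_per_df")
  chi2 <- sum((obs_g - exp_g)^2 / exp_g)
  list(value = chi2 / df, chi2 = chi2, df = df,
       n_groups = length(obs_g), n_pooled_bins = sum(size_g > 1),
       groups = tibble::tibble(observed = obs_g, expected = exp_g,
                               bins = size_g))
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# Merge near-duplicate free components (linear models are commonly
# degenerate); merging stabilises the weight covariance.
merge_degenerate <- function(P, Q, mergeable, threshold = 0.999) {
  repeat {
    k <- ncol(P)
    idx <- which(mergeable)
    pair <- NULL
    if (length(idx) >= 2) {
      for (a in idx) {
        for (b in idx[idx > a]) {
          if (cosine_sim(P[, a], P[, b]) > threshold) { pair <- c(a, b); break }
        }
        if (!is.null(pair)) break
      }
    }
    if (is.null(pair)) return(list(P = P, Q = Q, mergeable = mergeable))
    a <- pair[1]; b <- pair[2]
    wa <- sum(Q[a, ]); wb <- sum(Q[b, ])
    wtot <- wa + wb
    P[, a] <- if (wtot > 0) (P[, a] * wa + P[, b] * wb) / wtot
              else (P[, a] + P[, b]) / 2
    P[, a] <- P[, a] / sum(P[, a])
    Q[a, ] <- Q[a, ] + Q[b, ]
    P <- P[, -b, drop = FALSE]
    Q <- Q[-b, , drop = FALSE]
    mergeable <- mergeable[-b]
  }
}
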