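# Local linear kernel smoothers in one and two dimensions.
#
# These are the smoothing primitives behind the mean function and the
# covariance surface.  At every evaluation point a weighted linear (1D) or
# planar (2D) fit is solved and its intercept returned.  Near the boundary,
# or wherever the local design is singular (too few distinct support
# points), the bandwidth is widened geometrically (x1.5, up to 5 times)
# before giving up.

MAX_WIDEN <- 5L

# ---- 1D ---------------------------------------------------------------

ll_fit_1d <- function(times, values, h, g, kfun) {
  for (i in 0:MAX_WIDEN) {
    hh <- h * 1.5^i
    d <- times - g
    w <- kfun(d / hh)
    pos <- w > 0
    if (length(unique(times[pos])) < 2L) next
    s0 <- sum(w); s1 <- sum(w * d); s2 <- sum(w * d^2)
    t0 <- sum(w * values); t1 <- sum(w * d * values)
    den <- s0 * s2 - s1^2
    if (!is.finite(den) || den <= max(abs(s0 * s2), .Machine$double.xmin) * 1e-12) next
    return((s2 * t0 - s1 * t1) / den)
  }
  stop(sprintf(
    "singular local design at t = %g even after bandwidth widening", g))
}

#' Local linear kernel smoother (one-dimensional)
#'
#' Fits, at every grid point, a kernel-weighted straight line centred at
#' that point and returns its intercept.  Local linear fits reproduce
#' linear functions exactly for any bandwidth and have better boundary
#' behaviour than local constant (Nadaraya-Watson) smoothing, which
#' matters here because weight records cluster at gestational week 0 and
#' near term.
#'
#' @param times,values paired observations (at least 2 distinct times).
#' @param bandwidth kernel bandwidth in the units of \code{times} (> 0).
#' @param grid strictly increasing evaluation points.
#' @param kernel \code{"gaussian"} (default) or \code{"epanechnikov"}.
#' @return an object of class \code{"gw_smooth1d"}: list with elements
#'   \code{grid}, \code{values}, \code{bandwidth}, \code{kernel}.
#' @seealso [local_linear_2d()], [select_bandwidth_gcv()]
#' @export
local_linear_1d <- function(times, values, bandwidth, grid,
                            kernel = c("gaussian", "epanechnikov")) {
  kernel <- match.arg(kernel)
  stopifnot(length(times) == length(values), bandwidth > 0)
  ok <- is.finite(times) & is.finite(values)
  times <- times[ok]; values <- values[ok]
  if (length(unique(times)) < 2L) {
    stop("need at least 2 distinct observation times")
  }
  if (any(diff(grid) <= 0)) stop("'grid' must be strictly increasing")
  kfun <- kernel_fun(kernel)
  vals <- vapply(grid, function(g) ll_fit_1d(times, values, bandwidth, g, kfun),
                 numeric(1))
  structure(list(grid = grid, values = vals, bandwidth = bandwidth,
                 kernel = kernel),
            class = "gw_smooth1d")
}

# ---- 2D ---------------------------------------------------------------

ll_fit_2d <- function(ds, dt, v, kfun, h1, h2) {
  for (i in 0:MAX_WIDEN) {
    f <- 1.5^i
    w <- kfun(ds / (h1 * f)) * kfun(dt / (h2 * f))
    if (sum(w > 0) < 3L) next
    X <- cbind(1, ds, dt)
    A <- crossprod(X, X * w)
    if (!all(is.finite(A))) next
    rc <- rcond(A)
    if (!is.finite(rc) || rc < 1e-12) next
    b <- crossprod(X, v * w)
    sol <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(sol)) next
    return(sol[1L])
  }
  stop("rank-deficient local design in 2D smoother even after bandwidth widening")
}

#' Local linear kernel smoother (two-dimensional)
#'
#' Fits, at every node of \code{grid x grid}, a kernel-weighted plane
#' centred at the node and returns its intercept.  The returned surface is
#' symmetrized as \code{(S + t(S)) / 2}; when the input triples are known
#' to be symmetric (as the raw covariances are, since every unordered pair
#' enters in both orders), set \code{symmetric_data = TRUE} to evaluate
#' only the upper triangle and mirror it, which halves the work and makes
#' the symmetry exact by construction.
#'
#' @param s,t,values coordinate/value triples of the scattered data.
#' @param bandwidths length-2 positive bandwidths for the two axes.
#' @param grid strictly increasing evaluation points (same for both axes).
#' @param kernel kernel name as in [local_linear_1d()].
#' @param symmetric_data logical; see Details.
#' @return an object of class \code{"gw_smooth2d"}: list with \code{grid},
#'   \code{surface} (length(grid) x length(grid)), \code{bandwidths},
#'   \code{kernel}.
#' @export
local_linear_2d <- function(s, t, values, bandwidths, grid,
                            kernel = c("gaussian", "epanechnikov"),
                            symmetric_data = FALSE) {
  kernel <- match.arg(kernel)
  stopifnot(length(s) == length(t), length(t) == length(values),
            length(bandwidths) == 2L, all(bandwidths > 0))
  ok <- is.finite(s) & is.finite(t) & is.finite(values)
  s <- s[ok]; t <- t[ok]; values <- values[ok]
  loc <- unique(cbind(s, t))
  if (nrow(loc) < 3L || qr(cbind(1, loc))$rank < 3L) {
    stop("need at least 3 non-collinear (s, t) locations")
  }
  if (any(diff(grid) <= 0)) stop("'grid' must be strictly increasing")
  kfun <- kernel_fun(kernel)
  G <- length(grid)
  surf <- matrix(NA_real_, G, G)
  h1 <- bandwidths[1L]; h2 <- bandwidths[2L]
  for (i in seq_len(G)) {
    jmax <- if (symmetric_data) i else G
    dsi <- s - grid[i]
    for (j in seq_len(jmax)) {
      surf[i, j] <- ll_fit_2d(dsi, t - grid[j], values, kfun, h1, h2)
    }
  }
  if (symmetric_data) {
    surf[upper.tri(surf)] <- t(surf)[upper.tri(surf)]
  } else {
    surf <- (surf + t(surf)) / 2
  }
  structure(list(grid = grid, surface = surf, bandwidths = bandwidths,
                 kernel = kernel),
            class = "gw_smooth2d")
}

# Smoother for the covariance diagonal: local planar fit in coordinates
# rotated 45 degrees, with a linear term along the diagonal direction
# u = (s + t)/sqrt(2) and a quadratic term in the perpendicular direction
# v = (t - s)/sqrt(2), evaluated at v = 0.  Used for G~(t), the smoothed
# diagonal of the covariance surface, which the off-diagonal-only surface
# smoother cannot pin down near s = t.
smooth_cov_diagonal <- function(s, t, values, bandwidths, grid,
                                kernel = "gaussian") {
  kfun <- kernel_fun(kernel)
  u <- (s + t) / sqrt(2)
  v <- (t - s) / sqrt(2)
  h1 <- bandwidths[1L]; h2 <- bandwidths[2L]
  vapply(grid, function(g) {
    du <- u - sqrt(2) * g
    for (i in 0:MAX_WIDEN) {
      f <- 1.5^i
      w <- kfun(du / (h1 * f)) * kfun(v / (h2 * f))
      if (sum(w > 0) < 3L) next
      X <- cbind(1, du, v^2)
      A <- crossprod(X, X * w)
      if (!all(is.finite(A))) next
      rc <- rcond(A)
      if (!is.finite(rc) || rc < 1e-12) next
      b <- crossprod(X, values * w)
      sol <- tryCatch(solve(A, b), error = function(e) NULL)
      if (is.null(sol)) next
      return(sol[1L])
    }
    stop(sprintf("diagonal smoother: singular local design at t = %g", g))
  }, numeric(1))
}

# ---- bandwidth selection ---------------------------------------------

#' Generalized cross-validation bandwidth selection
#'
#' Scores each candidate bandwidth by GCV,
#' \eqn{n \cdot RSS / (n - tr(S))^2}, where \eqn{S} is the smoother matrix
#' of the 1D local linear fit at the observation points, and returns the
#' candidate with the smallest score.  Ties (scores equal to within 1e-10
#' relative) break to the smaller bandwidth.  For large samples the score
#' is computed on an evenly spaced (by time order) subsample of at most
#' \code{max_points} observations to bound the quadratic cost.
#'
#' @param times,values paired observations.
#' @param candidates non-empty vector of positive candidate bandwidths.
#' @param kernel kernel name as in [local_linear_1d()].
#' @param max_points cap on the number of points entering the score.
#' @return the selected bandwidth (scalar).
#' @export
select_bandwidth_gcv <- function(times, values, candidates,
                                 kernel = c("gaussian", "epanechnikov"),
                                 max_points = 2000L) {
  kernel <- match.arg(kernel)
  if (length(candidates) < 1L) stop("empty candidate list")
  stopifnot(all(candidates > 0))
  ok <- is.finite(times) & is.finite(values)
  times <- times[ok]; values <- values[ok]
  ord <- order(times)
  times <- times[ord]; values <- values[ord]
  n_all <- length(times)
  if (n_all > max_points) {
    idx <- unique(round(seq(1L, n_all, length.out = max_points)))
    times <- times[idx]; values <- values[idx]
  }
  n <- length(times)
  kfun <- kernel_fun(kernel)
  # D[i, j] = times[j] - times[i]: local deviations for the fit centred at i
  D <- matrix(times, n, n, byrow = TRUE) - times
  cand <- sort(unique(candidates))
  scores <- vapply(cand, function(h) {
    K <- kfun(D / h)
    S0 <- rowSums(K)
    S1 <- rowSums(K * D)
    S2 <- rowSums(K * D * D)
    den <- S0 * S2 - S1^2
    if (any(!is.finite(den)) || any(den <= 0)) return(Inf)
    L <- K * (S2 - D * S1)          # S2, S1 recycle down columns = per row i
    fitted <- as.vector(L %*% values) / den
    tr <- kfun(0) * S2 / den        # diagonal elements of the smoother matrix
    trace <- sum(tr)
    if (!is.finite(trace) || trace >= n) return(Inf)
    rss <- sum((values - fitted)^2)
    n * rss / (n - trace)^2
  }, numeric(1))
  if (all(!is.finite(scores))) {
    stop("no candidate bandwidth produced a valid local linear fit")
  }
  best <- min(scores)
  # ties are judged on the scale of the data variance so that an exact fit
  # (RSS at rounding level) counts as a tie for every bandwidth
  tol <- 1e-10 * max(stats::var(values), .Machine$double.xmin)
  cand[which(scores <= best + tol)[1L]]
}

# GCV for the 2D planar smoother on scattered (s, t, value) triples, used
# to pick the covariance-surface bandwidth.  Evaluated on an evenly spaced
# (by s-order) subsample of at most max_points triples; isotropic
# candidates.
select_bandwidth_gcv_2d <- function(s, t, values, candidates,
                                    kernel = "gaussian",
                                    max_points = 1500L) {
  stopifnot(length(candidates) >= 1L, all(candidates > 0))
  n_all <- length(s)
  if (n_all > max_points) {
    ord <- order(s, t)
    idx <- unique(round(seq(1L, n_all, length.out = max_points)))
    s <- s[ord][idx]; t <- t[ord][idx]; values <- values[ord][idx]
  }
  n <- length(s)
  kfun <- kernel_fun(kernel)
  Ds <- matrix(s, n, n, byrow = TRUE) - s   # Ds[i, j] = s[j] - s[i]
  Dt <- matrix(t, n, n, byrow = TRUE) - t
  cand <- sort(unique(candidates))
  scores <- vapply(cand, function(h) {
    K <- kfun(Ds / h) * kfun(Dt / h)
    fitted <- numeric(n)
    hat <- numeric(n)
    for (i in seq_len(n)) {
      w <- K[i, ]
      X <- cbind(1, Ds[i, ], Dt[i, ])
      A <- crossprod(X, X * w)
      if (!all(is.finite(A)) || rcond(A) < 1e-12) return(Inf)
      li <- solve(A, t(X * w))[1L, ]
      fitted[i] <- sum(li * values)
      hat[i] <- li[i]
    }
    trace <- sum(hat)
    if (!is.finite(trace) || trace >= n) return(Inf)
    n * sum((values - fitted)^2) / (n - trace)^2
  }, numeric(1))
  if (all(!is.finite(scores))) {
    stop("no candidate bandwidth produced a valid local planar fit")
  }
  best <- min(scores)
  tol <- 1e-10 * max(stats::var(values), .Machine$double.xmin)
  cand[which(scores <= best + tol)[1L]]
}
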