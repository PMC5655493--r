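# Shared numerical helpers: trapezoid quadrature, interpolation, kernels.

#' Trapezoid quadrature weights
#'
#' Weights \code{w} such that \code{sum(w * f(grid))} approximates the
#' integral of \code{f} over \code{range(grid)} by the composite trapezoid
#' rule.  All quadrature in the package (eigenfunction normalization, FVE,
#' noise-variance averaging) uses these weights.
#'
#' @param grid strictly increasing numeric vector of evaluation points.
#' @return numeric vector of the same length as \code{grid}.
#' @export
trapz_weights <- function(grid) {
  n <- length(grid)
  if (n < 2L || any(diff(grid) <= 0)) {
    stop("'grid' must be strictly increasing with at least 2 points")
  }
  d <- diff(grid)
  w <- numeric(n)
  w[1L] <- d[1L] / 2
  w[n] <- d[n - 1L] / 2
  if (n > 2L) w[2:(n - 1L)] <- (d[-1L] + d[-(n - 1L)]) / 2
  w
}

trapz <- function(grid, values) sum(trapz_weights(grid) * values)

# linear interpolation clamped to the end values outside the grid
lin_interp <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, rule = 2)$y
}

# bilinear interpolation of a surface given on grid x grid
bilinear_interp <- function(grid, surface, x, y) {
  n <- length(grid)
  x <- pmin(pmax(x, grid[1L]), grid[n])
  y <- pmin(pmax(y, grid[1L]), grid[n])
  i <- pmin(pmax(findInterval(x, grid), 1L), n - 1L)
  j <- pmin(pmax(findInterval(y, grid), 1L), n - 1L)
  x1 <- grid[i]; x2 <- grid[i + 1L]
  y1 <- grid[j]; y2 <- grid[j + 1L]
  tx <- ifelse(x2 > x1, (x - x1) / (x2 - x1), 0)
  ty <- ifelse(y2 > y1, (y - y1) / (y2 - y1), 0)
  s11 <- surface[cbind(i, j)]
  s21 <- surface[cbind(i + 1L, j)]
  s12 <- surface[cbind(i, j + 1L)]
  s22 <- surface[cbind(i + 1L, j + 1L)]
  (1 - tx) * (1 - ty) * s11 + tx * (1 - ty) * s21 +
    (1 - tx) * ty * s12 + tx * ty * s22
}

kernel_fun <- function(kernel = c("gaussian", "epanechnikov")) {
  kernel <- match.arg(kernel)
  switch(kernel,
    gaussian = function(u) stats::dnorm(u),
    epanechnikov = function(u) ifelse(abs(u) <= 1, 0.75 * (1 - u^2), 0)
  )
}

default_grid <- function(domain = c(0, 42), n = 51L) {
  seq(domain[1L], domain[2L], length.out = n)
}
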