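#' Rest (straight) state of a bundle
#'
#' The zero-angle state: all filaments straight, horizontal, evenly spaced
#' across the bundle width.
#'
#' @param params A [bundle_params()] object.
#' @return An `m x n` numeric matrix of segment angles (all zero), the only
#'   degrees of freedom of the model.
#' @export
#' @examples
#' theta <- rest_state(bundle_params(m = 3, n = 4))
rest_state <- function(params) {
  stopifnot(inherits(params, "bundle_params"))
  matrix(0, params$m, params$n)
}

check_state <- function(params, theta) {
  stopifnot(
    "theta must be an m x n numeric matrix" =
      is.matrix(theta) && is.numeric(theta) &&
      nrow(theta) == params$m && ncol(theta) == params$n,
    "theta must be finite" = all(is.finite(theta))
  )
  invisible(theta)
}

#' Node coordinates of a bundle state
#'
#' Maps the angle matrix to planar coordinates: point `j` of filament `i` is
#' the cumulative sum of `(l cos(theta_ik), l sin(theta_ik))` over `k <= j`,
#' offset vertically by `(i-1) W/(m-1)`. The `j = 0` points are fixed at
#' `x = 0`. Every segment has length exactly `l` (the filaments are
#' inextensible by construction).
#'
#' @param params A [bundle_params()] object.
#' @param theta `m x n` angle matrix.
#' @return A list with `x` and `y`, both `m x (n+1)` matrices (columns are
#'   points `j = 0..n`).
#' @seealso [bundle_coordinates()] for a tidy per-node table.
#' @export
coordinates_from_angles <- function(params, theta) {
  check_state(params, theta)
  d <- param_derived(params)
  x <- cbind(0, t(apply(d$l * cos(theta), 1, cumsum)))
  y <- cbind(0, t(apply(d$l * sin(theta), 1, cumsum))) +
    (seq_len(params$m) - 1) * d$d0
  dimnames(x) <- dimnames(y) <- NULL
  list(x = x, y = y)
}

#' Tidy node-coordinate table
#'
#' @inheritParams coordinates_from_angles
#' @return A tibble with columns `filament` (1..m), `index` (0..n), `x`, `y`.
#' @export
bundle_coordinates <- function(params, theta) {
  co <- coordinates_from_angles(params, theta)
  tibble::tibble(
    filament = rep(seq_len(params$m), params$n + 1L),
    index = rep(0:params$n, each = params$m),
    x = as.vector(co$x),
    y = as.vector(co$y)
  )
}

#' Spring distances between neighbouring filaments
#'
#' Computes the vertical and diagonal point-pair distances consumed by the
#' spring potentials. For neighbour pair `(i, i+1)`:
#' * `d[i, j+1] = |P(i+1, j) - P(i, j)|` for points `j = 0..n`;
#' * `d_plus[i, j]  = |P(i+1, j) - P(i, j-1)|`, the "+" diagonals,
#'   spanning point pairs `(j-1, j)` for `j = 1..n`;
#' * `d_minus[i, j] = |P(i+1, j-1) - P(i, j)|`, the "-" diagonals.
#'
#' The end diagonals that would need a point outside `0..n` do not exist,
#' which is why both diagonal matrices have `n` (not `n+1`) columns.
#'
#' @inheritParams coordinates_from_angles
#' @param coords Optional precomputed coordinate list from
#'   [coordinates_from_angles()] (or any list of `x`, `y` matrices of the
#'   same shape, e.g. a rigidly translated copy).
#' @return A list of matrices `d` (`(m-1) x (n+1)`), `d_plus` and `d_minus`
#'   (both `(m-1) x n`).
#' @export
pair_distances <- function(params, theta, coords = NULL) {
  if (is.null(coords)) coords <- coordinates_from_angles(params, theta)
  m <- params$m; n <- params$n
  up <- seq(2L, m); lo <- seq(1L, m - 1L)
  dist2 <- function(dx, dy) sqrt(dx^2 + dy^2)
  d <- dist2(coords$x[up, , drop = FALSE] - coords$x[lo, , drop = FALSE],
             coords$y[up, , drop = FALSE] - coords$y[lo, , drop = FALSE])
  jp <- 2:(n + 1L); jm <- 1:n  # columns: point j vs point j-1
  d_plus <- dist2(coords$x[up, jp, drop = FALSE] - coords$x[lo, jm, drop = FALSE],
                  coords$y[up, jp, drop = FALSE] - coords$y[lo, jm, drop = FALSE])
  d_minus <- dist2(coords$x[up, jm, drop = FALSE] - coords$x[lo, jp, drop = FALSE],
                   coords$y[up, jm, drop = FALSE] - coords$y[lo, jp, drop = FALSE])
  list(d = d, d_plus = d_plus, d_minus = d_minus)
}

#' Overlap-penalty triangle areas
#'
#' Each quad between filaments `i, i+1` and points `j-1, j` is split into
#' two triangles whose areas feed the overlap penalty: half the absolute 2-D
#' cross product of the vertical spring vector and the "+" diagonal vector.
#' At rest every area equals `A0 = l/(2 (m-1))`; an area reaching zero means
#' the filaments touch locally.
#'
#' @inheritParams pair_distances
#' @return A list of `(m-1) x n` matrices `A1` (triangle on points
#'   `(i,j-1), (i+1,j-1), (i+1,j)`) and `A2` (triangle on
#'   `(i,j), (i+1,j), (i,j-1)` closed through the "+" diagonal).
#' @export
triangle_areas <- function(params, theta, coords = NULL) {
  if (is.null(coords)) coords <- coordinates_from_angles(params, theta)
  m <- params$m; n <- params$n
  up <- seq(2L, m); lo <- seq(1L, m - 1L)
  j0 <- 1:n; j1 <- 2:(n + 1L)  # point j-1 and point j as matrix columns
  x0 <- coords$x[lo, j0, drop = FALSE]; y0 <- coords$y[lo, j0, drop = FALSE]
  x1 <- coords$x[up, j0, drop = FALSE]; y1 <- coords$y[up, j0, drop = FALSE]
  x2 <- coords$x[up, j1, drop = FALSE]; y2 <- coords$y[up, j1, drop = FALSE]
  x3 <- coords$x[lo, j1, drop = FALSE]; y3 <- coords$y[lo, j1, drop = FALSE]
  A1 <- 0.5 * abs((x1 - x0) * (y2 - y0) - (y1 - y0) * (x2 - x0))
  A2 <- 0.5 * abs((x2 - x3) * (y2 - y0) - (y2 - y3) * (x2 - x0))
  list(A1 = A1, A2 = A2)
}
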