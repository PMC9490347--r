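#' Model parameters for a planar filament bundle
#'
#' Collects every material, penalty, load and discretization constant of the
#' bundle model. The bundle is a stack of `m` inextensible filaments of
#' non-dimensional arc length `L` spanning a width `W` (fixed at 1 after
#' non-dimensionalization, see [nondimensionalize()]). Each filament is
#' discretized into `n` straight segments of length `l = L/n`, parametrized
#' purely by segment angles; neighbouring filaments are coupled by vertical
#' and diagonal Hookean springs of stiffness `K` and by an exponential
#' overlap penalty on the cell areas between them.
#'
#' Derived constants, available via [param_derived()]:
#' * `l = L/n`, the segment length;
#' * `d0 = W/(m-1)`, the rest separation of neighbouring filaments;
#' * `d0_diag = sqrt(d0^2 + l^2)`, the rest length of the diagonal springs;
#' * `A0 = l/(2*(m-1))`, the rest area of each overlap triangle;
#' * `B`, the length-m vector of bending stiffnesses: `B_r * B_in` on the
#'   two outer filaments, `B_in` on the interior ones.
#'
#' @param m Number of filaments (integer, >= 2).
#' @param n Segments per filament (integer, >= 2). Default 200.
#' @param L Non-dimensional filament length (> 0).
#' @param K Spring (matrix) stiffness (>= 0).
#' @param B_in Bending stiffness of the interior filaments (> 0).
#' @param B_r Ratio of outer to inner bending stiffness (>= 1); models a
#'   stiff outer sheath or supported environment.
#' @param Nc Axial compressive load applied to every filament end (>= 0).
#' @param Np Pinching load: `+Np` pushes the top filament down, `-Np` pushes
#'   the bottom filament up (>= 0 for compression; any real accepted).
#' @param C1 Overlap penalty amplitude (> 0). Default `1e6`.
#' @param C2 Overlap penalty decay rate (> 0). Default 100: the penalty only
#'   becomes appreciable once a triangle shrinks below ~10% of its rest area.
#'   Lower values emulate a strain-hardening matrix.
#' @param C3 Boundary-constraint stiffness (> 0). Default `1e5`.
#' @param boundary `"clamped"` (pinned ends plus horizontal end tangents) or
#'   `"pinned"` (no end-to-end deflection only). Clamped implies pinned.
#' @param W Bundle width; fixed at 1 in the non-dimensional model.
#' @param Nc_pattern Optional length-`m` multiplier vector for the axial
#'   load per filament (default all 1).
#' @param Np_pattern Optional `m x n` multiplier matrix for the pinching
#'   load per node; the default is `+1` on the top filament, `-1` on the
#'   bottom one, 0 elsewhere (uniform outer-filament pinching). Supplying a
#'   different pattern models e.g. one-end or mid-point pinching.
#'
#' @return An object of class `bundle_params` (a named list).
#' @seealso [rest_state()], [bundle_energy()], [minimize_energy()]
#' @export
#' @examples
#' p <- bundle_params(m = 10, n = 100, L = 5, K = 2, Nc = 0.5)
#' p
bundle_params <- function(m = 10L, n = 200L, L = 5, K = 2, B_in = 1,
                          B_r = 1, Nc = 0, Np = 0,
                          C1 = 1e6, C2 = 100, C3 = 1e5,
                          boundary = c("clamped", "pinned"), W = 1,
                          Nc_pattern = NULL, Np_pattern = NULL) {
  boundary <- match.arg(boundary)
  m <- as.integer(m); n <- as.integer(n)
  L <- as.numeric(L); W <- as.numeric(W); K <- as.numeric(K)
  B_in <- as.numeric(B_in); B_r <- as.numeric(B_r)
  Nc <- as.numeric(Nc); Np <- as.numeric(Np)
  C1 <- as.numeric(C1); C2 <- as.numeric(C2); C3 <- as.numeric(C3)
  stopifnot(
    "m must be an integer >= 2" = length(m) == 1 && !is.na(m) && m >= 2,
    "n must be an integer >= 2" = length(n) == 1 && !is.na(n) && n >= 2,
    "L must be positive" = is.numeric(L) && L > 0,
    "W must be positive" = is.numeric(W) && W > 0,
    "K must be non-negative" = is.numeric(K) && K >= 0,
    "B_in must be positive" = is.numeric(B_in) && B_in > 0,
    "B_r must be >= 1" = is.numeric(B_r) && B_r >= 1,
    "Nc must be non-negative" = is.numeric(Nc) && Nc >= 0,
    "Np must be numeric" = is.numeric(Np),
    "C1 must be positive" = C1 > 0,
    "C2 must be positive" = C2 > 0,
    "C3 must be positive" = C3 > 0
  )
  if (!is.null(Nc_pattern)) {
    stopifnot("Nc_pattern must have length m" = length(Nc_pattern) == m)
    Nc_pattern <- as.numeric(Nc_pattern)
  }
  if (!is.null(Np_pattern)) {
    stopifnot("Np_pattern must be an m x n matrix" =
                is.matrix(Np_pattern) && all(dim(Np_pattern) == c(m, n)))
  }
  structure(
    list(m = m, n = n, L = L, W = W, K = K, B_in = B_in, B_r = B_r,
         Nc = Nc, Np = Np, C1 = C1, C2 = C2, C3 = C3,
         boundary = boundary,
         Nc_pattern = Nc_pattern, Np_pattern = Np_pattern),
    class = "bundle_params"
  )
}

#' Derived geometric and stiffness constants of a parameter set
#'
#' @param params A [bundle_params()] object.
#' @return A list with `l`, `d0`, `d0_diag`, `A0` and the per-filament
#'   bending stiffness vector `B`.
#' @export
param_derived <- function(params) {
  stopifnot(inherits(params, "bundle_params"))
  l <- params$L / params$n
  d0 <- params$W / (params$m - 1)
  B <- rep(params$B_in, params$m)
  B[c(1, params$m)] <- params$B_r * params$B_in
  list(l = l, d0 = d0, d0_diag = sqrt(d0^2 + l^2),
       A0 = l / (2 * (params$m - 1)), B = B)
}

#' @export
print.bundle_params <- function(x, ...) {
  d <- param_derived(x)
  cat("<bundle_params>\n")
  cat(sprintf("  %d filaments x %d segments, L = %g, W = %g (%s ends)\n",
              x$m, x$n, x$L, x$W, x$boundary))
  cat(sprintf("  K = %g, B_in = %g, B_r = %g; loads Nc = %g, Np = %g\n",
              x$K, x$B_in, x$B_r, x$Nc, x$Np))
  cat(sprintf("  penalties C1 = %g, C2 = %g, C3 = %g\n", x$C1, x$C2, x$C3))
  cat(sprintf("  derived: l = %g, d0 = %g, A0 = %g\n", d$l, d$d0, d$A0))
  invisible(x)
}

#' Update fields of a parameter set
#'
#' Convenience wrapper used heavily by sweeps: returns a copy of `params`
#' with the named fields replaced, re-validated.
#'
#' @param params A [bundle_params()] object.
#' @param ... Named fields to replace (any argument of [bundle_params()]).
#' @return A new `bundle_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "bundle_params"))
  new <- utils::modifyList(unclass(params), list(...), keep.null = TRUE)
  do.call(bundle_params, new)
}

# effective per-filament axial loads and per-node pinching loads
load_tables <- function(params) {
  ncv <- if (is.null(params$Nc_pattern)) rep(1, params$m) else params$Nc_pattern
  if (is.null(params$Np_pattern)) {
    npm <- matrix(0, params$m, params$n)
    npm[params$m, ] <- 1
    npm[1, ] <- -1
  } else {
    npm <- params$Np_pattern
  }
  list(Nc = params$Nc * ncv, Np = params$Np * npm)
}

# key for sweep caching: a stable text fingerprint of all parameter fields
params_key <- function(params) {
  lt <- load_tables(params)
  paste(
    paste(deparse(unclass(params)[c("m", "n", "L", "W", "K", "B_in", "B_r",
                                    "C1", "C2", "C3", "boundary")]),
          collapse = ""),
    format(params$Nc, digits = 15), format(params$Np, digits = 15),
    format(sum(lt$Nc), digits = 15), format(sum(lt$Np * seq_along(lt$Np)),
                                            digits = 15),
    sep = "|"
  )
}
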