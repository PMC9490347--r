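#' Triangular-kink geometry
#'
#' The analytic internal-buckling model idealizes a buckled inner filament
#' as a zig-zag of `2n` triangular kinks: compressing the filament end by
#' `Delta` at fixed arc length `L` forces a kink amplitude
#' `D = sqrt(Delta (2L - Delta)) / (2n)`, a kink base half-length
#' `l_t = (L - Delta)/(2n)` and a kink angle
#' `theta_t = arctan(2 n D / (L - Delta))`.
#'
#' @param Delta End displacement (`0 <= Delta < L`).
#' @param n Half the number of kinks (positive integer).
#' @param L Filament length (> 0).
#' @return A list with `D`, `theta_t`, `l_t`.
#' @export
#' @examples
#' kink_geometry(0.1, n = 2, L = 5)
kink_geometry <- function(Delta, n, L) {
  stopifnot("Delta must satisfy 0 <= Delta < L" =
              all(Delta >= 0 & Delta < L),
            "n must be >= 1" = all(n >= 1), "L must be positive" = L > 0)
  D <- sqrt(Delta * (2 * L - Delta)) / (2 * n)
  list(D = D,
       theta_t = atan(2 * n * D / (L - Delta)),
       l_t = (L - Delta) / (2 * n))
}

#' Spring (matrix-stretching) energy of the kinked filament
#'
#' Closed form of the elastic-matrix deformation energy accumulated by the
#' triangular kinks: `Ee(Delta) = K Delta (L - Delta) (2L - Delta) /
#' (2 n^2 L)`. It equals the integral of the per-unit-length Hookean
#' density `(K/2) ((d(x) - d0)/d0)^2 / L` over one kink flank
#' (`d(x) = 2nD x/(L - Delta) + d0`), times `6n` for the `2n` kink copies
#' and the six spring connections (two vertical, four diagonal) per node.
#' The factor `1/L` keeps the spring count per unit length fixed as `L`
#' varies. Its slope at `Delta = 0` is `K L / n^2`, the spring term of
#' [excess_load()].
#'
#' @inheritParams kink_geometry
#' @param K Spring stiffness (>= 0).
#' @return Energy scalar (vectorized over `Delta`).
#' @export
kink_spring_energy <- function(Delta, K, L, n) {
  stopifnot(all(Delta >= 0 & Delta < L))
  K * Delta * (L - Delta) * (2 * L - Delta) / (2 * n^2 * L)
}

#' Bending energy of the kinked filament
#'
#' The discrete tan-squared curvature cost of the `2n` kink corners:
#' `Eb(Delta) = (2 n^2 B_in / (L - Delta)) tan^2(2 arctan(2nD/(L-Delta)))`.
#' Its slope at `Delta = 0` is `16 n^2 B_in / L^2`, the bending term of
#' [excess_load()].
#'
#' @inheritParams kink_geometry
#' @param B_in Inner bending stiffness (> 0).
#' @return Energy scalar (vectorized over `Delta`).
#' @export
kink_bending_energy <- function(Delta, B_in, L, n) {
  g <- kink_geometry(Delta, n, L)
  arg <- 2 * atan(2 * n * g$D / (L - Delta))
  if (any(abs(arg) >= pi / 2)) stop("kink angle reached the tan singularity")
  2 * n^2 * B_in / (L - Delta) * tan(arg)^2
}

#' Excess internal-buckling load of wavemode n
#'
#' The load (beyond the Euler boundary contribution) at which the straight
#' inner filament becomes unstable to a `2n`-kink zig-zag:
#' `Ne(n) = K L / n^2 + 16 n^2 B_in / L^2`, i.e. the slope at `Delta = 0`
#' of the kink spring-plus-bending energy. The spring term falls with `n`
#' (higher modes have smaller amplitude, hence stretch the matrix less)
#' while the bending term grows with `n`, so the selected mode is
#' intermediate.
#'
#' @param n Wavemode (half the kink count); any positive real, so the
#'   expression can be minimized continuously; vectorized.
#' @inheritParams kink_spring_energy
#' @inheritParams kink_bending_energy
#' @return The excess load `Ne(n)`.
#' @export
#' @examples
#' excess_load(2, K = 2, B_in = 1, L = 5)  # 2.5 + 2.56
excess_load <- function(n, K, B_in, L) {
  stopifnot(all(n > 0))
  K * L / n^2 + 16 * n^2 * B_in / L^2
}

#' Optimal internal-buckling wavemode and its excess load
#'
#' Minimizes [excess_load()] over real `n > 0`:
#' `n_star = K^(1/4) L^(3/4) / (2 B_in^(1/4))` and
#' `Ne_star = 8 sqrt(K B_in / L)`. Also reports the best integer mode by
#' brute force over `1..n_max`.
#'
#' @inheritParams excess_load
#' @param n_max Upper bound for the integer search (default 50).
#' @return A list with `n_star`, `Ne_star`, `n_int` (best integer mode)
#'   and `Ne_int`.
#' @export
optimal_mode <- function(K, B_in, L, n_max = 50L) {
  stopifnot(K > 0, B_in > 0, L > 0)
  n_star <- K^0.25 * L^0.75 / (2 * B_in^0.25)
  Ne_star <- 8 * sqrt(K * B_in / L)
  ns <- seq_len(n_max)
  Ne <- excess_load(ns, K, B_in, L)
  i <- which.min(Ne)
  list(n_star = n_star, Ne_star = Ne_star, n_int = ns[i], Ne_int = Ne[i])
}

#' Analytic critical load for internal buckling
#'
#' The closed-form criterion `Nc_star = alpha sqrt(K B_in / L) +
#' ne^2 pi^2 B_in / L^2`. The first term is the minimized kink-model excess
#' load with the shape-dependent prefactor promoted to a fitting constant
#' `alpha` (the pure triangular-kink value is 8; numerically locating the
#' transition across parameter sets gives about 10.61, see [fit_alpha()]).
#' The second term is the Euler load of the boundary conditions: mode
#' `ne = 1` for pinned ends, `ne = 2` for clamped ends. The lateral decay
#' of the buckling amplitude across neighbouring filaments enters the
#' derivation only through a factor proportional to the rest separation,
#' which cancels in the strain ratio, so the criterion is independent of
#' the filament count and is absorbed into `alpha`.
#'
#' @inheritParams excess_load
#' @param alpha Dimensionless prefactor (> 0), default 10.61.
#' @param ne Euler mode of the boundary conditions: 1 (pinned) or 2
#'   (clamped).
#' @return The critical axial load `Nc_star`.
#' @export
#' @examples
#' analytic_critical_load(K = 2, B_in = 1, L = 5, ne = 2)
analytic_critical_load <- function(K, B_in, L, alpha = 10.61, ne = 2L) {
  stopifnot(K >= 0, B_in > 0, L > 0, alpha > 0, ne %in% c(1L, 2L))
  alpha * sqrt(K * B_in / L) + ne^2 * pi^2 * B_in / L^2
}

#' Euler mode implied by a boundary condition
#' @param boundary `"pinned"` or `"clamped"`.
#' @return 1 for pinned, 2 for clamped.
#' @export
euler_mode <- function(boundary = c("clamped", "pinned")) {
  if (match.arg(boundary) == "pinned") 1L else 2L
}

#' Energy curvature of the straight state along candidate buckling modes
#'
#' Linear-stability probe of the rest state: the directional second
#' derivative of the total energy along a trial deformation mode,
#' evaluated from the analytic gradient by a symmetric difference,
#' minimized over a dictionary of candidate modes. A negative value means
#' the straight bundle is unstable — some admissible deformation lowers
#' the energy — which is the sharp criterion for the onset of a
#' supercritical buckling transition.
#'
#' The dictionary contains, for wavemodes `k = 1..k_max`: whole-bundle
#' arches (uniform across filaments; `cos(k pi s/L)` profiles for pinned
#' ends, `sin(2 k pi s/L)` for clamped ends, both with zero net end
#' deflection), mirror-antisymmetric (pinching-type) variants of the same
#' arches, and interior multi-arch modes with a lateral envelope that
#' vanishes on the outer filaments. All trial modes respect the boundary
#' penalties to leading order, so the probe measures the physical terms,
#' not the constraint stiffness.
#'
#' @param params A [bundle_params()] object.
#' @param k_max Largest wavemode probed (default 6).
#' @param amplitude Probe amplitude in radians (default 1e-2).
#' @return The minimum directional curvature over the dictionary
#'   (attribute `mode` names the minimizing entry).
#' @export
stability_curvature <- function(params, k_max = 6L, amplitude = 1e-2) {
  m <- params$m; n <- params$n; L <- params$L
  s <- (seq_len(n) - 0.5) * L / n
  clamped <- params$boundary == "clamped"
  taper <- sin(pi * s / L)
  env <- sin(pi * (seq_len(m) - 1) / (m - 1))
  w <- (2 * seq_len(m) - (m + 1)) / (m - 1)
  modes <- list()
  for (k in seq_len(k_max)) {
    arch <- if (clamped) sin(2 * pi * k * s / L) else cos(pi * k * s / L)
    modes[[paste0("global_k", k)]] <- matrix(rep(arch, each = m), m, n)
    modes[[paste0("pinch_k", k)]] <- outer(-w, arch)
    modes[[paste0("internal_k", k)]] <-
      outer(env, taper * sin(2 * pi * k * s / L))
  }
  curv <- vapply(modes, function(mode) {
    gp <- energy_gradient(params, amplitude * mode)
    gm <- energy_gradient(params, -amplitude * mode)
    sum((gp - gm) * mode) / (2 * amplitude)
  }, numeric(1))
  structure(min(curv), mode = names(curv)[which.min(curv)])
}

#' Numerically locate a critical axial load by bisection
#'
#' Brackets the smallest `Nc` at which the straight bundle state loses
#' stability: at each trial load the energy is minimized from the rest
#' state plus a small fixed-seed random perturbation, and the result is
#' classified. Below the critical load the perturbation relaxes back to
#' the straight state; above it, the state flows into a buckled basin.
#' Bisection stops once the bracket is narrower than `tol` and the
#' midpoint is returned.
#'
#' Two detection modes:
#' * `"internal"` (default) — at each trial load the energy is minimized
#'   from the perturbed rest state and the result is classified; buckled
#'   iff the classifier label is `internal`. Intended for stiff-sheath
#'   set-ups (`B_r` large, `Np = 0`) where global buckling is excluded by
#'   construction; past the instability the state flows to a
#'   large-amplitude collapse, so the label is unambiguous.
#' * `"any"` — buckled iff the straight state is linearly unstable, i.e.
#'   the energy curvature [stability_curvature()] along some candidate
#'   deformation mode is negative. Near a smooth (supercritical)
#'   bifurcation such as global Euler buckling the buckled amplitude grows
#'   continuously from zero, relaxation of a small random perturbation
#'   cannot resolve the onset within floating-point granularity, and the
#'   curvature sign is the sharp criterion for leaving the straight state.
#'
#' @param params A [bundle_params()] object; its `Nc` field is overridden
#'   by the trial loads.
#' @param bracket Length-2 numeric `c(lo, hi)`. `lo` must be stable and
#'   `hi` buckled; the default brackets from the Euler load up to the
#'   analytic prediction scaled well past its fitted range.
#' @param tol Bracket width at which to stop (default 0.05).
#' @param mode Detection mode, see above.
#' @param perturb_amplitude,seed Perturbation used for every trial
#'   (`"internal"` mode).
#' @param check_bracket Verify that the endpoints straddle the transition
#'   (two extra trials); on by default.
#' @param tol_grad,max_iter Passed to [minimize_energy()] in `"internal"`
#'   mode.
#' @param k_max Largest wavemode probed in `"any"` mode.
#' @return An object of class `critical_load`: list with `value` (the
#'   midpoint), `bracket`, `trace` (tibble of trial loads and outcomes)
#'   and `params`.
#' @export
numerical_critical_load <- function(params, bracket = NULL, tol = 0.05,
                                    mode = c("internal", "any"),
                                    perturb_amplitude = 1e-3, seed = 0L,
                                    check_bracket = TRUE,
                                    tol_grad = 1e-7, max_iter = 10000L,
                                    k_max = 6L) {
  mode <- match.arg(mode)
  ne <- euler_mode(params$boundary)
  if (is.null(bracket)) {
    euler <- ne^2 * pi^2 * params$B_in / params$L^2
    bracket <- c(1.02 * euler,
                 euler + 3 * 8 * sqrt(max(params$K, 1e-8) *
                                        params$B_in / params$L))
  }
  stopifnot(length(bracket) == 2, bracket[1] < bracket[2])

  buckled_at <- function(Nc) {
    p <- update_params(params, Nc = Nc)
    if (mode == "internal") {
      theta0 <- perturb_state(p, amplitude = perturb_amplitude, seed = seed)
      fit <- minimize_energy(p, theta0, tol = tol_grad, max_iter = max_iter)
      lab <- classify_state(p, fit$theta)$label
      list(buckled = lab == "internal", label = as.character(lab),
           curvature = NA_real_)
    } else {
      cv <- stability_curvature(p, k_max = k_max)
      list(buckled = cv < 0, label = NA_character_, curvature = cv)
    }
  }

  trace <- list()
  note <- function(Nc, out) {
    trace[[length(trace) + 1L]] <<-
      tibble::tibble(Nc = Nc, buckled = out$buckled, label = out$label,
                     curvature = out$curvature)
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (check_bracket) {
    out_lo <- buckled_at(lo); note(lo, out_lo)
    if (out_lo$buckled) stop("lower bracket endpoint is already buckled")
    out_hi <- buckled_at(hi); note(hi, out_hi)
    if (!out_hi$buckled) stop("upper bracket endpoint is not buckled")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    out <- buckled_at(mid); note(mid, out)
    if (out$buckled) hi <- mid else lo <- mid
  }
  structure(list(value = (lo + hi) / 2, bracket = c(lo, hi),
                 trace = dplyr::bind_rows(trace), params = params),
            class = "critical_load")
}

#' @export
print.critical_load <- function(x, ...) {
  cat(sprintf("<critical_load>  Nc* = %.4f (bracket [%.4f, %.4f], %d trials)\n",
              x$value, x$bracket[1], x$bracket[2], nrow(x$trace)))
  invisible(x)
}

#' Fit the critical-load prefactor alpha
#'
#' Given measured critical loads over parameter sets, inverts the analytic
#' criterion per record, `alpha_i = (Nc_star_i - ne^2 pi^2 B_in/L^2) /
#' sqrt(K B_in / L)`, and pools them by least squares of the excess load
#' against `sqrt(K B_in / L)` through the origin. Records whose excess
#' load is non-positive (below their Euler load) are flagged and excluded
#' from the pooled fit.
#'
#' @param records A data frame with columns `K`, `B_in` (or `B`), `L`,
#'   `ne` and `Nc_star`; an `m` column is carried through if present.
#' @return An object of class `alpha_fit` with elements `alpha` (pooled),
#'   `records` (tibble with per-record `alpha` and `excluded` flag) and
#'   `n_used`.
#' @export
#' @examples
#' recs <- tibble::tibble(K = c(1, 2), B_in = 1, L = 5, ne = 2,
#'                        Nc_star = analytic_critical_load(c(1, 2), 1, 5,
#'                                                         alpha = 9))
#' fit_alpha(recs)$alpha  # 9
fit_alpha <- function(records) {
  records <- tibble::as_tibble(records)
  if (!"B_in" %in% names(records) && "B" %in% names(records)) {
    records$B_in <- records$B
  }
  need <- c("K", "B_in", "L", "ne", "Nc_star")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    stop("records is missing columns: ", paste(missing, collapse = ", "))
  }
  stopifnot("at least one record required" = nrow(records) >= 1)
  euler <- records$ne^2 * pi^2 * records$B_in / records$L^2
  s <- sqrt(records$K * records$B_in / records$L)
  excess <- records$Nc_star - euler
  records$alpha <- excess / s
  records$excluded <- excess <= 0
  used <- !records$excluded
  if (!any(used)) stop("all records fall below their Euler load")
  alpha <- sum(excess[used] * s[used]) / sum(s[used]^2)
  structure(list(alpha = alpha, records = records, n_used = sum(used)),
            class = "alpha_fit")
}

#' @export
print.alpha_fit <- function(x, ...) {
  cat(sprintf("<alpha_fit>  alpha = %.3f from %d record(s)", x$alpha,
              x$n_used))
  if (any(x$records$excluded)) {
    cat(sprintf(" (%d excluded below Euler)", sum(x$records$excluded)))
  }
  cat("\n")
  invisible(x)
}

#' @export
tidy.alpha_fit <- function(x, ...) x$records

#' @export
glance.alpha_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, n_used = x$n_used,
                 n_excluded = sum(x$records$excluded),
                 alpha_min = min(x$records$alpha[!x$records$excluded]),
                 alpha_max = max(x$records$alpha[!x$records$excluded]))
}
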