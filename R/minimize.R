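#' Archetypal seed states
#'
#' Small-amplitude template configurations used to start local minimization
#' inside each deformation basin:
#' * `undeformed` — the zero matrix;
#' * `global` — a single-arch profile `a cos(pi s/L)` identical across all
#'   filaments (whole-bundle Euler bow);
#' * `pinched` — the same arch with mirror-antisymmetric signs about the
#'   mid-row, so upper and lower filaments bow towards each other (its
#'   pinching parameter is exactly 1);
#' * `internal` — a multi-arch profile with the wavemode taken from
#'   [optimal_mode()] (rounded to the nearest integer >= 1), modulated
#'   axially and scaled by a lateral envelope that peaks at the bundle
#'   centre and vanishes on the outer filaments.
#'
#' @param params A [bundle_params()] object.
#' @param kind One of `"undeformed"`, `"global"`, `"pinched"`, `"internal"`.
#' @param amplitude Peak angle amplitude in radians (default 0.01: small
#'   enough to stay near each basin, large enough to break the straight
#'   state's symmetry).
#' @param mode Optional integer wavemode override for the internal seed.
#' @return An `m x n` angle matrix.
#' @export
seed_state <- function(params, kind = c("undeformed", "global", "pinched",
                                        "internal"),
                       amplitude = 0.01, mode = NULL) {
  kind <- match.arg(kind)
  stopifnot("amplitude must be >= 0" = amplitude >= 0)
  m <- params$m; n <- params$n; L <- params$L
  if (kind == "undeformed") return(rest_state(params))
  s <- (seq_len(n) - 0.5) * (L / n)  # segment mid-arclength
  arch <- cos(pi * s / L)
  if (kind == "global") {
    theta <- matrix(rep(amplitude * arch, each = m), m, n)
  } else if (kind == "pinched") {
    w <- (2 * seq_len(m) - (m + 1)) / (m - 1)  # -1 bottom .. +1 top
    theta <- outer(-w, amplitude * arch)
  } else {
    k <- if (is.null(mode)) {
      max(1L, as.integer(round(optimal_mode(params$K, params$B_in, L)$n_star)))
    } else {
      as.integer(mode)
    }
    env <- sin(pi * (seq_len(m) - 1) / (m - 1))  # 0 on outer rows
    # 2k arches tapered towards the ends; orthogonal to the taper, so the
    # seed carries no net end deflection and no pinned-penalty energy
    axial <- sin(pi * s / L) * sin(2 * pi * k * s / L)
    theta <- amplitude * outer(env, axial)
  }
  theta
}

#' Randomly perturb a bundle state
#'
#' Adds independent uniform noise in `[-amplitude, amplitude]` to every
#' angle. Used with a small amplitude (default `1e-3`) to probe the local
#' stability of a state: a stable state relaxes back, an unstable one flows
#' away. The global RNG state is restored afterwards, so the perturbation
#' is reproducible via `seed` without side effects.
#'
#' @param params A [bundle_params()] object.
#' @param theta State to perturb; defaults to the rest state.
#' @param amplitude Noise half-width in radians.
#' @param seed Integer RNG seed (default 0).
#' @return A perturbed `m x n` angle matrix.
#' @export
perturb_state <- function(params, theta = NULL, amplitude = 1e-3, seed = 0L) {
  if (is.null(theta)) theta <- rest_state(params)
  check_state(params, theta)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  theta + matrix(stats::runif(length(theta), -amplitude, amplitude),
                 nrow(theta), ncol(theta))
}

#' Minimize the bundle energy with L-BFGS
#'
#' Runs limited-memory BFGS (via [stats::optim()], method `"L-BFGS-B"`)
#' on the full energy functional with the analytic gradient. Convergence
#' is declared when the gradient infinity-norm falls below `tol`; if the
#' line search stalls earlier, minimization is restarted from the current
#' iterate (which resets the curvature memory) up to `restarts` times.
#' Non-finite trial energies (bending singularities) are replaced by a
#' large finite value so the line search backtracks away from them.
#'
#' @param params A [bundle_params()] object.
#' @param theta0 Starting `m x n` angle matrix (must have finite energy).
#' @param tol Gradient infinity-norm tolerance (default `1e-6`, small
#'   enough that the classification quantities of [classify_state()] are
#'   stable well below their thresholds).
#' @param max_iter Total iteration budget (default 20000).
#' @param restarts Maximum number of L-BFGS restarts (default 6).
#' @return An object of class `bundle_fit`: a list with `params`, `theta`
#'   (the located stationary state), `energy` (an `energy_breakdown`),
#'   `converged`, `iterations`, `grad_norm` and `seed_energy`.
#' @export
#' @examples
#' p <- bundle_params(m = 4, n = 30, K = 2, Nc = 0.5, boundary = "pinned")
#' fit <- minimize_energy(p, perturb_state(p))
#' glance(fit)
minimize_energy <- function(params, theta0, tol = 1e-6, max_iter = 20000L,
                            restarts = 6L) {
  check_state(params, theta0)
  m <- params$m; n <- params$n
  big <- 1e12
  # the axial load contributes a constant m*Nc*L at the rest state (the
  # loading potential uses the absolute end coordinate); optimizing the
  # shifted energy E - offset leaves gradients and minima untouched but
  # keeps the objective near zero, so the line search resolves the very
  # shallow energy decreases that accompany a weakly unstable straight
  # state instead of drowning them in floating-point granularity
  offset <- sum(load_tables(params)$Nc) * params$L

  cache <- new.env(parent = emptyenv())
  evaluate <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$res)
    res <- energy_call(params, matrix(par, m, n),
                       want_grad = TRUE, want_pressure = FALSE)
    cache$par <- par
    cache$res <- res
    res
  }
  fn <- function(par) {
    res <- evaluate(par)
    if (!res$finite || !is.finite(res$total)) big else res$total - offset
  }
  gr <- function(par) {
    res <- evaluate(par)
    g <- res$grad
    if (!res$finite || any(!is.finite(g))) g[] <- 0
    as.vector(g)
  }

  e0 <- fn(as.vector(theta0))
  if (e0 >= big) stop("starting state has non-finite energy")

  par <- as.vector(theta0)
  iterations <- 0L
  for (round in seq_len(restarts + 1L)) {
    opt <- stats::optim(par, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = max_iter - iterations,
                                       factr = 10, pgtol = tol, lmm = 20))
    iterations <- iterations + opt$counts[["function"]]
    moved <- !isTRUE(all.equal(par, opt$par, tolerance = 0))
    par <- opt$par
    g <- energy_gradient(params, matrix(par, m, n))
    grad_norm <- max(abs(g))
    if (grad_norm <= tol || iterations >= max_iter || !moved) break
  }

  theta <- matrix(par, m, n)
  structure(
    list(params = params, theta = theta, energy = bundle_energy(params, theta),
         converged = grad_norm <= tol, iterations = iterations,
         grad_norm = grad_norm, seed_energy = e0 + offset),
    class = "bundle_fit"
  )
}

#' @export
print.bundle_fit <- function(x, ...) {
  cl <- classify_state(x$params, x$theta)
  cat(sprintf(
    "<bundle_fit>  %s, E = %s (%sconverged, %d evals, |grad| = %.2e)\n",
    cl$label, format(x$energy$total, digits = 10),
    if (x$converged) "" else "NOT ", x$iterations, x$grad_norm))
  invisible(x)
}

#' Glance at a minimization result
#'
#' @param x A `bundle_fit` from [minimize_energy()].
#' @param ... Unused.
#' @return A one-row tibble: `label`, `energy`, `converged`, `iterations`,
#'   `grad_norm`, plus the classification quantities.
#' @export
glance.bundle_fit <- function(x, ...) {
  cl <- classify_state(x$params, x$theta)
  tibble::tibble(label = cl$label, energy = x$energy$total,
                 converged = x$converged, iterations = x$iterations,
                 grad_norm = x$grad_norm,
                 moment_all = cl$moment_all, moment_outer = cl$moment_outer,
                 moment_inner = cl$moment_inner, pinch = cl$pinch)
}

#' Tidy a minimization result into its energy terms
#'
#' @param x A `bundle_fit`.
#' @param ... Unused.
#' @return The [tidy.energy_breakdown()] table of the fitted state.
#' @export
tidy.bundle_fit <- function(x, ...) tidy(x$energy)

#' Enumerate the local minima reachable from the archetypal seeds
#'
#' Minimizes from each of the four archetypal seeds (each nudged by a small
#' fixed-seed perturbation so that unstable symmetric states reveal their
#' instability), classifies the results, and merges duplicates: two results
#' are the same minimum when they carry the same label and their total
#' energies differ by less than `merge_tol` (relatively). Distinct labels
#' within `merge_tol` of the lowest energy are retained and flagged
#' co-minimal. Total energies include the constant axial-load offset
#' `m * Nc * L`, matching the bookkeeping used for the published phase
#' diagrams.
#'
#' @param params A [bundle_params()] object.
#' @param amplitude Seed amplitude in radians (default 0.01).
#' @param perturb_amplitude Stability-probing noise amplitude (default 1e-3).
#' @param seed Integer seed for the probe noise.
#' @param merge_tol Relative energy tolerance for merging/co-minimality
#'   (default 0.01, i.e. 1%).
#' @param tol,max_iter Passed to [minimize_energy()].
#' @return A tibble of distinct minima sorted by energy, with columns
#'   `label`, `energy`, `co_minimal`, `converged`, `grad_norm`,
#'   `seed_kind`, and a list-column `fit` of `bundle_fit` objects.
#' @export
enumerate_minima <- function(params, amplitude = 0.01,
                             perturb_amplitude = 1e-3, seed = 0L,
                             merge_tol = 0.01, tol = 1e-6,
                             max_iter = 20000L) {
  kinds <- c("undeformed", "global", "pinched", "internal")
  fits <- purrr::imap(stats::setNames(kinds, kinds), function(kind, .) {
    i <- match(kind, kinds)
    theta0 <- perturb_state(params, seed_state(params, kind, amplitude),
                            amplitude = perturb_amplitude,
                            seed = seed + i - 1L)
    tryCatch(minimize_energy(params, theta0, tol = tol,
                             max_iter = max_iter),
             error = function(e) NULL)
  })
  fits <- purrr::compact(fits)
  if (!length(fits)) stop("no seed produced a finite stationary state")
  rows <- purrr::imap_dfr(fits, function(fit, kind) {
    cl <- classify_state(fit$params, fit$theta)
    tibble::tibble(label = cl$label, energy = fit$energy$total,
                   converged = fit$converged, grad_norm = fit$grad_norm,
                   seed_kind = kind, fit = list(fit))
  })
  rows <- rows[order(rows$energy), ]
  # two seeds that landed on the numerically identical state (energies equal
  # to ~1e-7 relative) are one minimum: keep the best-converged copy, so a
  # convergence residue cannot double-count it under a noisy label
  same <- rep(1L, nrow(rows))
  if (nrow(rows) > 1) {
    for (r in 2:nrow(rows)) {
      close <- abs(rows$energy[r] - rows$energy[r - 1]) <
        1e-7 * max(abs(rows$energy[r - 1]), 1)
      same[r] <- if (close) same[r - 1] else same[r - 1] + 1L
    }
  }
  rows <- dplyr::slice_min(dplyr::group_by(rows, .group = same),
                           order_by = grad_norm, n = 1, with_ties = FALSE)
  rows <- dplyr::arrange(dplyr::ungroup(rows), energy)
  rows$.group <- NULL
  keep <- rep(TRUE, nrow(rows))
  for (a in seq_len(nrow(rows))) {
    if (!keep[a]) next
    for (b in seq_len(nrow(rows))) {
      if (b <= a || !keep[b]) next
      same <- rows$label[b] == rows$label[a]
      close <- abs(rows$energy[b] - rows$energy[a]) <
        merge_tol * max(abs(rows$energy[a]), 1e-8)
      if (same && close) keep[b] <- FALSE
    }
  }
  rows <- rows[keep, ]
  rows$co_minimal <- abs(rows$energy - rows$energy[1]) <
    merge_tol * max(abs(rows$energy[1]), 1e-8)
  rows[, c("label", "energy", "co_minimal", "converged", "grad_norm",
           "seed_kind", "fit")]
}
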