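#' Full energy breakdown of a bundle state
#'
#' Evaluates every term of the bundle energy functional
#' `E = Eb + Ee + El + Ec`:
#' * `Eb` — discrete bending energy, `sum (B_i/2l) tan^2(theta_ij -
#'   theta_i(j-1))` over interior joints; the tan-of-turning-angle
#'   curvature measure comes from the circumscribed circle of adjacent
#'   segments, and its continuum limit is the standard `(B/2) integral
#'   kappa^2 ds` (so a single pinned filament recovers the Euler load
#'   `pi^2 B / L^2`).
#' * `Ee1`, `Ee1_plus`, `Ee1_minus` — Hookean spring energies of the
#'   vertical and diagonal springs joining neighbouring filaments, with
#'   rest lengths `d0` and `d0_diag`: each spring contributes
#'   `l * (K/2L) * ((d - d0)/d0)^2`. The stiffness is a per-unit-length
#'   density `K/L` — the spring count per unit length stays fixed as `L`
#'   varies — which is the normalization under which the analytic
#'   internal-buckling criterion (spring term `K L / n^2`, critical load
#'   `alpha * sqrt(K B / L)`) describes the same system as the energy
#'   functional.
#' * `Ee2` — exponential overlap penalty `C1 exp(-C2 A / A0)` summed over
#'   the two triangles of every inter-filament quad; it diverges as
#'   filaments approach local contact.
#' * `El1` — axial load potential `sum_i Nc_i x_in` (note: the absolute end
#'   coordinate, so the rest state has `El1 = m Nc L`).
#' * `El2` — pinching potential `sum Np(ij) (y_ij - y_i0)`; by default
#'   `+Np` on the top filament and `-Np` on the bottom one.
#' * `Ec1` — pinned-end penalty `C3 (y_in - y_i0)^2`.
#' * `Ec2` — clamped-end penalty `C3 (theta_i1^2 + theta_in^2)`, present
#'   only for `boundary = "clamped"`.
#'
#' An angle difference of `pi/2` between adjacent segments makes the bending
#' term singular; such states are reported with `finite = FALSE` rather
#' than clamped, so a minimizer rejects the step instead of seeing a
#' corrupted landscape.
#'
#' @param params A [bundle_params()] object.
#' @param theta `m x n` angle matrix.
#' @return An object of class `energy_breakdown`: a list with every
#'   component above, `Eb_filament` (per-filament bending), `total`, and
#'   the logical `finite`.
#' @export
#' @examples
#' p <- bundle_params(m = 10, n = 50, Nc = 2)
#' bundle_energy(p, rest_state(p))$total  # = m * Nc * L = 100
bundle_energy <- function(params, theta) {
  res <- energy_call(params, theta, want_grad = FALSE, want_pressure = FALSE)
  structure(res[c("Eb", "Eb_filament", "Ee1", "Ee1_plus", "Ee1_minus",
                  "Ee2", "El1", "El2", "Ec1", "Ec2", "total", "finite")],
            class = "energy_breakdown")
}

energy_call <- function(params, theta, want_grad, want_pressure) {
  check_state(params, theta)
  d <- param_derived(params)
  lt <- load_tables(params)
  # spring stiffness enters as a per-unit-length density K/L: the number of
  # springs per unit length is held fixed as L varies, which is the
  # normalization under which the internal-buckling criterion's K*L/n^2
  # spring term and the phase-diagram load scales are consistent
  energy_core(theta, d$l, d$d0, d$d0_diag, d$A0, params$K / params$L, d$B,
              params$C1, params$C2, params$C3, lt$Nc, lt$Np,
              params$boundary == "clamped", want_grad, want_pressure)
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("<energy_breakdown>  total =", format(x$total, digits = 10),
      if (!x$finite) " (NON-FINITE)" else "", "\n")
  terms <- c("Eb", "Ee1", "Ee1_plus", "Ee1_minus", "Ee2",
             "El1", "El2", "Ec1", "Ec2")
  for (t in terms) cat(sprintf("  %-10s %s\n", t, format(x[[t]], digits = 8)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an energy breakdown into a term/energy table
#'
#' @param x An `energy_breakdown` from [bundle_energy()].
#' @param ... Unused.
#' @return A tibble with columns `term` and `energy`.
#' @export
tidy.energy_breakdown <- function(x, ...) {
  terms <- c("Eb", "Ee1", "Ee1_plus", "Ee1_minus", "Ee2",
             "El1", "El2", "Ec1", "Ec2", "total")
  tibble::tibble(term = terms,
                 energy = unname(vapply(terms, function(t) x[[t]],
                                        numeric(1))))
}

#' Analytic energy gradient with respect to the segment angles
#'
#' The gradient is assembled by the chain rule: coordinate-space gradients
#' of the spring, overlap, load and pinned-end terms are pushed back through
#' the cumulative-sum parametrization (a suffix sum per filament), and the
#' bending and clamped-end terms contribute directly in angle space. The
#' contract, enforced by the test suite, is agreement with central finite
#' differences of [bundle_energy()] to a relative error below `1e-5`.
#'
#' At the rest state with only an axial load the gradient is exactly zero:
#' `d x_in / d theta = -l sin(theta) = 0`, so buckling arises as an
#' instability, not a first-order tilt.
#'
#' @inheritParams bundle_energy
#' @return An `m x n` matrix `dE/dtheta`, with attribute `finite`.
#' @export
energy_gradient <- function(params, theta) {
  res <- energy_call(params, theta, want_grad = TRUE, want_pressure = FALSE)
  structure(res$grad, finite = res$finite)
}

#' Internal interaction-pressure field
#'
#' The magnitude of the gradient of the interaction energy
#' `Ee = Ee1 + Ee1_plus + Ee1_minus + Ee2` with respect to each node's
#' coordinates: a per-node measure of how hard the spring matrix and the
#' contact penalty press on the filament. Internally buckled minima
#' concentrate this pressure into sharp localized spikes, whereas pinched
#' minima spread a much lower pressure uniformly.
#'
#' @inheritParams bundle_energy
#' @param as `"tibble"` (default) for a tidy per-node table that can be
#'   written straight to CSV, or `"matrix"` for the raw `m x (n+1)` field.
#' @return A tibble with columns `filament`, `index`, `x`, `y`, `pressure`,
#'   or the bare matrix.
#' @export
interaction_pressure <- function(params, theta, as = c("tibble", "matrix")) {
  as <- match.arg(as)
  res <- energy_call(params, theta, want_grad = FALSE, want_pressure = TRUE)
  if (as == "matrix") return(res$pressure)
  out <- bundle_coordinates(params, theta)
  out$pressure <- as.vector(res$pressure)
  out
}
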