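#' Non-dimensionalize physical bundle parameters
#'
#' Scales physical measurements into the model's non-dimensional units:
#' lengths by the bundle width `W` (so the model width is 1 and
#' `L = length/width`), bending stiffnesses of circular-section filaments
#' via `B = pi E R^4 / 2`, and loads by the reference bending stiffness
#' `B_s` times the squared width, `N' = N / (B_s W^2)` (implemented as
#' stated for the reference system; the returned `load_divisor` carries
#' the divisor so callers can scale loads themselves).
#'
#' @param width_mm Bundle width (mm, > 0).
#' @param length_mm Bundle length (mm, > 0).
#' @param E_outer_MPa,E_inner_MPa Young's moduli of the sheath and interior
#'   filaments (MPa, > 0).
#' @param R_outer_mm,R_inner_mm Effective circular-section radii (mm, > 0).
#' @param B_s Reference bending stiffness (default 0.01).
#' @return A one-row tibble: `L`, `B_outer`, `B_inner`, `B_r`,
#'   `load_divisor`.
#' @export
#' @examples
#' # optic-nerve-like inputs: width 3.55 mm, length 28 mm
#' nondimensionalize(3.55, 28, 44.6, 5.4, 0.37, effective_radius(3.55, 15))
nondimensionalize <- function(width_mm, length_mm, E_outer_MPa, E_inner_MPa,
                              R_outer_mm, R_inner_mm, B_s = 0.01) {
  stopifnot(width_mm > 0, length_mm > 0, E_outer_MPa > 0, E_inner_MPa > 0,
            R_outer_mm > 0, R_inner_mm > 0, B_s > 0)
  B_outer <- pi * E_outer_MPa * R_outer_mm^4 / 2
  B_inner <- pi * E_inner_MPa * R_inner_mm^4 / 2
  tibble::tibble(
    L = length_mm / width_mm,
    B_outer = B_outer, B_inner = B_inner, B_r = B_outer / B_inner,
    load_divisor = B_s * width_mm^2
  )
}

#' Effective filament radius of a sub-bundled nerve
#'
#' A bundle of width `w` packing `count` sub-bundles across its diameter
#' gives each an effective circular radius `w / (2 count)`.
#'
#' @param width_mm Bundle width (mm).
#' @param count Number of sub-bundles across the width.
#' @return Effective radius in mm.
#' @export
#' @examples
#' effective_radius(3.55, 15)  # ~0.12 mm
effective_radius <- function(width_mm, count) {
  stopifnot(width_mm > 0, count > 0)
  width_mm / (2 * count)
}

config_keys <- c("m", "n", "L", "K", "B_in", "B_r", "Nc", "Np",
                 "C1", "C2", "C3", "boundary", "W")

#' Load model parameters from a JSON config
#'
#' The config is a flat JSON object whose keys are arguments of
#' [bundle_params()]; missing keys take the model defaults, unknown keys
#' are rejected by name. An empty config therefore yields the full default
#' parameter set.
#'
#' @param path Path to a JSON file.
#' @return A [bundle_params()] object.
#' @export
load_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), config_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(bundle_params, cfg)
}

#' Save model parameters to a JSON config
#'
#' @param params A [bundle_params()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(params, path) {
  stopifnot(inherits(params, "bundle_params"))
  jsonlite::write_json(unclass(params)[config_keys], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Named parameter presets
#'
#' Bundled configuration files for the standard study set-ups: the default
#' clamped survey (`"clamped-default"`), the pinned-only variant
#' (`"pinned"`), the twenty-filament variant (`"m20"`), the softer and
#' stiffer matrices (`"K1"`, `"K4"`), and the strain-hardening matrix with
#' `C2 = 40` (`"C2-40"`).
#'
#' @param name Preset name; with no argument, lists the available names.
#' @return A [bundle_params()] object, or a character vector of names.
#' @export
load_preset <- function(name = NULL) {
  dir <- system.file("extdata", "presets", package = "filbuckle")
  avail <- sub("\\.json$", "", list.files(dir, pattern = "\\.json$"))
  if (is.null(name)) return(avail)
  if (!name %in% avail) {
    stop("unknown preset \"", name, "\"; available: ",
         paste(avail, collapse = ", "))
  }
  load_config(file.path(dir, paste0(name, ".json")))
}

#' Save / load a bundle state with its parameters
#'
#' JSON container with a `meta` object (the parameter fields) and a
#' row-major `theta` vector; round-trips losslessly at full double
#' precision.
#'
#' @param params A [bundle_params()] object.
#' @param theta `m x n` angle matrix.
#' @param path File path.
#' @return `save_state()` returns `path` invisibly; `load_state()` returns
#'   a list with `params` and `theta`.
#' @export
save_state <- function(params, theta, path) {
  check_state(params, theta)
  jsonlite::write_json(
    list(meta = unclass(params)[config_keys],
         theta = as.vector(t(theta))),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname save_state
#' @export
load_state <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!all(c("meta", "theta") %in% names(obj))) {
    stop("not a bundle state container: ", path)
  }
  params <- do.call(bundle_params, as.list(obj$meta))
  theta <- matrix(obj$theta, params$m, params$n, byrow = TRUE)
  check_state(params, theta)
  list(params = params, theta = theta)
}

#' Plot filament centrelines of a bundle state
#'
#' @param params A [bundle_params()] object.
#' @param theta `m x n` angle matrix.
#' @return A ggplot object.
#' @export
plot_bundle <- function(params, theta) {
  df <- bundle_coordinates(params, theta)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$filament)) +
    ggplot2::geom_path(ggplot2::aes(colour = factor(.data$filament)),
                       show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x", y = "y") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a located minimum
#'
#' Centrelines of the fitted state, annotated with its classification.
#'
#' @param object A `bundle_fit` from [minimize_energy()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bundle_fit <- function(object, ...) {
  cl <- classify_state(object$params, object$theta)
  plot_bundle(object$params, object$theta) +
    ggplot2::ggtitle(sprintf("%s  (E = %.4g)", cl$label,
                             object$energy$total))
}

#' Plot an interaction-pressure field
#'
#' Filament centrelines coloured by the per-node interaction pressure.
#'
#' @param pressure A tibble from [interaction_pressure()].
#' @return A ggplot object.
#' @export
plot_pressure <- function(pressure) {
  ggplot2::ggplot(pressure,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               group = .data$filament,
                               colour = .data$pressure)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_colour_viridis_c(option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
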