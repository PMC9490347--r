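#' Sweep the (Nc, Np, Br) phase space
#'
#' Runs [enumerate_minima()] on every triplet of the supplied load and
#' sheath-stiffness grids and records, per cell, the co-minimal deformation
#' labels and their energies. Cells whose minimization fails are recorded
#' with an error message rather than aborting the sweep. Cells are cached
#' by a content fingerprint of the full parameter set, so re-running a
#' sweep with an extended grid (or a variant preset) only computes the new
#' cells when the same cache environment is supplied.
#'
#' @param params Base [bundle_params()] object (its `Nc`, `Np`, `B_r` are
#'   overridden cell by cell).
#' @param Nc,Np,Br Numeric grid vectors.
#' @param seed Seed for the per-cell stability perturbations.
#' @param cache Optional environment used as a cell cache.
#' @param ... Passed to [enumerate_minima()] (e.g. `tol`, `max_iter`).
#' @return A tibble of class `phase_table` with one row per cell: `Nc`,
#'   `Np`, `Br`, list-columns `labels` and `energies` (co-minimal set,
#'   energies ascending), flattened `label1`, `energy1`, `label2`,
#'   `energy2`, `n_minima`, and `error` (NA unless the cell failed).
#' @export
#' @examples
#' \donttest{
#' p <- bundle_params(m = 6, n = 40, boundary = "pinned")
#' run_sweep(p, Nc = c(0, 1), Np = 0, Br = 1)
#' }
run_sweep <- function(params, Nc, Np, Br, seed = 0L, cache = NULL, ...) {
  grid <- tidyr::expand_grid(Br = Br, Np = Np, Nc = Nc)
  rows <- purrr::pmap(grid, function(Br, Np, Nc) {
    p <- update_params(params, Nc = Nc, Np = Np, B_r = Br)
    key <- paste(params_key(p), seed, sep = "|")
    if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
    row <- tryCatch({
      mins <- enumerate_minima(p, seed = seed, ...)
      co <- mins[mins$co_minimal, ]
      tibble::tibble(
        Nc = Nc, Np = Np, Br = Br,
        labels = list(as.character(co$label)),
        energies = list(co$energy),
        label1 = as.character(co$label[1]), energy1 = co$energy[1],
        label2 = if (nrow(co) > 1) as.character(co$label[2]) else NA_character_,
        energy2 = if (nrow(co) > 1) co$energy[2] else NA_real_,
        n_minima = nrow(mins), error = NA_character_
      )
    }, error = function(e) {
      tibble::tibble(Nc = Nc, Np = Np, Br = Br,
                     labels = list(character()), energies = list(numeric()),
                     label1 = NA_character_, energy1 = NA_real_,
                     label2 = NA_character_, energy2 = NA_real_,
                     n_minima = 0L, error = conditionMessage(e))
    })
    if (!is.null(cache)) cache[[key]] <- row
    row
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("phase_table", class(out))
  out
}

phase_csv_cols <- c("Nc", "Np", "Br", "label1", "energy1", "label2",
                    "energy2")

#' Write a phase table to CSV
#'
#' Flat CSV with columns `Nc,Np,Br,label1,energy1,label2,energy2`; the
#' second label/energy pair is empty unless the cell has co-minimal
#' distinct modes. Round-trips losslessly through [read_phase_table()]
#' (energies at full double precision).
#'
#' @param table A `phase_table` from [run_sweep()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phase_table <- function(table, path) {
  stopifnot(inherits(table, "data.frame"))
  flat <- tibble::as_tibble(table)[intersect(phase_csv_cols, names(table))]
  readr::write_csv(flat, path, na = "")
  invisible(path)
}

#' Read a phase table from CSV
#'
#' @param path A CSV written by [write_phase_table()].
#' @return A `phase_table` tibble (with the `labels`/`energies`
#'   list-columns reconstructed).
#' @export
read_phase_table <- function(path) {
  flat <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(
      Nc = readr::col_double(), Np = readr::col_double(),
      Br = readr::col_double(), label1 = readr::col_character(),
      energy1 = readr::col_double(), label2 = readr::col_character(),
      energy2 = readr::col_double()
    ), na = ""),
    warning = function(w) stop("malformed phase table: ",
                               conditionMessage(w))
  )
  missing <- setdiff(phase_csv_cols, names(flat))
  if (length(missing)) {
    stop("malformed phase table: missing columns ",
         paste(missing, collapse = ", "))
  }
  probs <- readr::problems(flat)
  if (nrow(probs)) {
    stop(sprintf("malformed phase table at line %d: expected %s, got %s",
                 probs$row[1] + 1L, probs$expected[1], probs$actual[1]))
  }
  out <- dplyr::mutate(
    flat,
    labels = purrr::map2(label1, label2, function(a, b) {
      as.character(stats::na.omit(c(a, b)))
    }),
    energies = purrr::map2(energy1, energy2, function(a, b) {
      as.numeric(stats::na.omit(c(a, b)))
    }),
    n_minima = lengths(labels), error = NA_character_,
    .after = "Br"
  )
  out <- out[, c("Nc", "Np", "Br", "labels", "energies", "label1",
                 "energy1", "label2", "energy2", "n_minima", "error")]
  class(out) <- c("phase_table", class(out))
  out
}

#' Heat-map of a phase table
#'
#' One tile per (Nc, Np) cell, faceted by the sheath-stiffness ratio `Br`,
#' filled by the lowest-energy deformation label; cells with a distinct
#' co-minimal second mode are marked with a dot.
#'
#' @param object A `phase_table` from [run_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phase_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$Nc, y = .data$Np)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$label1), colour = "grey30") +
    ggplot2::geom_point(data = df[!is.na(df$label2), ],
                        ggplot2::aes(colour = .data$label2), size = 1) +
    ggplot2::facet_wrap(~Br, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_brewer(palette = "Set2", name = "minimum") +
    ggplot2::scale_colour_brewer(palette = "Dark2", name = "co-minimal") +
    ggplot2::theme_minimal()
}
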